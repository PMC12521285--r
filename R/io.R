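# File I/O (FASTA via Biostrings, MGF peak lists), pipeline configuration
# and the end-to-end pipeline driver.

#' Read protein records from FASTA
#'
#' Headers are parsed for the accession: SwissProt-style
#' `sp|ACC|NAME` (or `tr|ACC|NAME`) dialect yields `ACC`, otherwise the
#' first whitespace-delimited token. Sequences are uppercased and may be
#' wrapped at any width. Non-canonical residues are rejected with the
#' record and position named.
#'
#' @param path FASTA file path.
#' @return List of `protein_record`s.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (!length(aas)) stop("FASTA file is empty: ", path)
  lapply(seq_along(aas), function(i) {
    header <- names(aas)[i]
    first <- strsplit(header, "\\s+")[[1]][1]
    parts <- strsplit(first, "|", fixed = TRUE)[[1]]
    acc <- if (length(parts) >= 2L && parts[1] %in% c("sp", "tr"))
      parts[2] else first
    nm <- if (length(parts) >= 3L && parts[1] %in% c("sp", "tr"))
      parts[3] else first
    protein_record(acc, toupper(as.character(aas[[i]])), nm)
  })
}

#' Write protein records as FASTA
#'
#' Round-trips with [read_fasta()]: accession and sequence are
#' preserved.
#'
#' @param proteins List of `protein_record`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  seqs <- Biostrings::AAStringSet(vapply(proteins, `[[`, "", "sequence"))
  names(seqs) <- vapply(proteins, function(p)
    if (identical(p$accession, p$name)) p$accession
    else paste(p$accession, p$name), "")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read an MGF peak-list file
#'
#' Honors `PEPMASS` (second field, when present, is the precursor
#' intensity), `CHARGE` (dialects `4+`, `+4`, `4` accepted; absent
#' charge is recorded as unknown), `RTINSECONDS` and `TITLE`; numeric
#' body lines are parsed as (m/z, intensity) fragment peaks. Malformed
#' BEGIN/END pairing is rejected with the offending line number.
#'
#' @param path MGF file path.
#' @return List of spectrum records (`title`, `scan`, `rt`, `pepmass`,
#'   `pep_intensity`, `charge`, `peaks`), one per `BEGIN IONS` block.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path)
  spectra <- list()
  inside <- FALSE
  cur <- NULL
  scan_ctr <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (inside) stop("MGF: BEGIN IONS inside an open block at line ", ln)
      inside <- TRUE
      scan_ctr <- scan_ctr + 1L
      cur <- list(title = NA_character_, scan = scan_ctr, rt = NA_real_,
                  pepmass = NA_real_, pep_intensity = NA_real_,
                  charge = NA_integer_, mzs = numeric(0),
                  ints = numeric(0))
      next
    }
    if (line == "END IONS") {
      if (!inside) stop("MGF: END IONS without BEGIN IONS at line ", ln)
      inside <- FALSE
      cur$peaks <- data.frame(mz = cur$mzs, intensity = cur$ints)
      cur$mzs <- cur$ints <- NULL
      spectra[[length(spectra) + 1L]] <- cur
      cur <- NULL
      next
    }
    if (!inside) next  # header junk between blocks is ignored
    if (grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      val <- sub("^[^=]*=", "", line)
      if (key == "TITLE") cur$title <- val
      else if (key == "RTINSECONDS") cur$rt <- as.numeric(val)
      else if (key == "PEPMASS") {
        fields <- strsplit(trimws(val), "\\s+")[[1]]
        cur$pepmass <- as.numeric(fields[1])
        if (length(fields) >= 2L) cur$pep_intensity <- as.numeric(fields[2])
      } else if (key == "CHARGE") {
        v <- sub("\\+$", "", trimws(val))
        v <- sub("^\\+", "", v)
        if (grepl("-", v, fixed = TRUE))
          stop("MGF: negative charge unsupported at line ", ln)
        cur$charge <- as.integer(v)
      }
      next
    }
    fields <- strsplit(line, "[ \t]+")[[1]]
    mzv <- suppressWarnings(as.numeric(fields[1]))
    if (is.na(mzv)) stop("MGF: unparseable line ", ln, ": ", line)
    iv <- if (length(fields) >= 2L)
      suppressWarnings(as.numeric(fields[2])) else 0
    cur$mzs <- c(cur$mzs, mzv)
    cur$ints <- c(cur$ints, iv)
  }
  if (inside) stop("MGF: unterminated BEGIN IONS block at end of file")
  spectra
}

#' Precursor observations from a spectrum list
#'
#' One row per MS2 spectrum, carrying its selected-precursor m/z,
#' charge (NA when unknown) and intensity — the MS1-level evidence used
#' by [match_precursors()].
#'
#' @param spectra List from [read_mgf()] or [simulate_dataset()].
#' @return data.frame: `scan`, `rt`, `mz`, `charge`, `intensity`.
#' @export
precursor_observations <- function(spectra) {
  if (!length(spectra))
    return(data.frame(scan = integer(0), rt = numeric(0), mz = numeric(0),
                      charge = integer(0), intensity = numeric(0)))
  data.frame(
    scan = vapply(spectra, function(s) as.integer(s$scan), 0L),
    rt = vapply(spectra, function(s) as.numeric(s$rt), 0),
    mz = vapply(spectra, function(s) as.numeric(s$pepmass), 0),
    charge = vapply(spectra, function(s) as.integer(s$charge), 0L),
    intensity = vapply(spectra, function(s)
      if (is.na(s$pep_intensity)) 0 else as.numeric(s$pep_intensity), 0))
}

#' Pipeline configuration
#'
#' Defaults reproduce the standard search parameters of the targeted
#' disulfide workflow: 3 missed cleavages, 10 ppm precursor and 0.6 Da
#' fragment tolerance, charges 1-5, survey window m/z 400-1600,
#' precursor intensity floor 5e3.
#'
#' @param fasta Path(s) to input FASTA.
#' @param spectra Path to input MGF.
#' @param out_dir Output directory for TSV tables.
#' @param enum An `enumeration_config`.
#' @param match A `match_config`.
#' @param seed Seed used by simulation-backed runs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, spectra, out_dir = ".",
                            enum = enumeration_config(),
                            match = match_config(), seed = 1L) {
  structure(list(fasta = fasta, spectra = spectra, out_dir = out_dir,
                 enum = enum, match = match, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full disulfide-mapping pipeline
#'
#' digest -> enumerate -> match -> annotate -> quantify. Reads proteins
#' and spectra, enumerates disulfide candidates, matches precursors at
#' ppm tolerance, annotates the MS2 spectra of matched scans with
#' bridge-aware fragments, summarizes bonds and compares bridged vs
#' reduced (CAM) form intensities. Writes `candidates.tsv`,
#' `matches.tsv`, `bonds.tsv`, `comparisons.tsv` and `run_log.txt` to
#' the output directory.
#'
#' @param cfg A `pipeline_config`.
#' @return List with `proteins`, `species`, `candidates`, `matches`,
#'   `annotated`, `bonds`, `comparisons`, `log` (character vector of
#'   stage messages).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  logs <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    logs <<- c(logs, msg)
    message(msg)
  }
  say("parameters: ppm_tol=%g frag_tol=%g Da, min_intensity=%g, charges=%s, window=%g-%g, max_missed=%d",
      cfg$match$ppm_tol, cfg$match$frag_tol, cfg$match$min_intensity,
      paste(range(cfg$enum$charges), collapse = "-"),
      cfg$enum$mz_range[1], cfg$enum$mz_range[2], cfg$enum$max_missed)

  proteins <- unlist(lapply(cfg$fasta, read_fasta), recursive = FALSE)
  say("stage fasta: %d protein(s)", length(proteins))

  species <- enumerate_species(proteins, cfg$enum)
  cand <- candidate_ions(species, cfg$enum)
  say("stage enumerate: %d species, %d candidate ions",
      length(species), nrow(cand))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  write_candidates(cand, file.path(cfg$out_dir, "candidates.tsv"))

  spectra <- if (file.exists(cfg$spectra)) read_mgf(cfg$spectra) else
    stop("spectra file not found: ", cfg$spectra)
  obs <- precursor_observations(spectra)
  if (!nrow(obs)) say("stage spectra: empty spectra file (no scans)")
  else say("stage spectra: %d MS2 scan(s)", nrow(obs))

  matches <- match_precursors(obs, cand, cfg$match)
  say("stage match: %d precursor match(es)", nrow(matches))
  utils::write.table(
    within(matches, { theo_mz <- sprintf("%.4f", theo_mz)
                      obs_mz <- sprintf("%.4f", obs_mz)
                      ppm <- sprintf("%.1f", ppm) }),
    file.path(cfg$out_dir, "matches.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # annotate MS2 spectra of matched scans
  skey <- vapply(species, species_key, "")
  annotated <- list()
  if (nrow(matches)) {
    for (i in seq_len(nrow(matches))) {
      sc <- matches$scan[i]
      spz <- spectra[[which(vapply(spectra, `[[`, 0L, "scan") == sc)[1]]]
      if (!nrow(spz$peaks)) next
      sp_obj <- species[[match(matches$species_id[i], skey)]]
      frag <- generate_fragments(
        sp_obj, charges = seq_len(max(1L, min(matches$cand_charge[i] - 1L, 3L))))
      annotated[[length(annotated) + 1L]] <- list(
        scan = sc, species_id = matches$species_id[i],
        annotated = annotate_spectrum(spz$peaks, frag, cfg$match))
    }
  }
  say("stage annotate: %d spectrum annotation(s)", length(annotated))

  bonds <- summarize_bonds(matches, annotated)
  say("stage quantify: %d bond(s)", nrow(bonds))
  utils::write.table(bonds, file.path(cfg$out_dir, "bonds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # bridged vs reduced comparison: reduced counterparts of matched species
  comparisons <- NULL
  if (nrow(matches)) {
    uniq <- unique(matches$species_id)
    pair_rows <- list(); red_cands <- list()
    for (sid in uniq) {
      sp_obj <- species[[match(sid, skey)]]
      bond <- .bond_id(.species_meta(sp_obj)$acc_a, .species_meta(sp_obj)$cys_a,
                       .species_meta(sp_obj)$acc_b, .species_meta(sp_obj)$cys_b,
                       sp_obj$topology)
      for (red in reduced_counterparts(sp_obj)) {
        rid <- sprintf("linear|%s:%d-%d{%s}", red$accession, red$start,
                       red$end, mod_string(red))
        grid <- mz_grid(red, cfg$enum)
        if (nrow(grid))
          red_cands[[length(red_cands) + 1L]] <- data.frame(
            species_id = rid, charge = grid$charge, mz = grid$mz,
            stringsAsFactors = FALSE)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          bond = bond, bridged_id = sid, reduced_id = rid,
          stringsAsFactors = FALSE)
      }
    }
    pairing <- unique(do.call(rbind, pair_rows))
    red_matches <- if (length(red_cands))
      match_precursors(obs, unique(do.call(rbind, red_cands)), cfg$match)
    else matches[0, ]
    allm <- rbind(matches[, c("species_id", "intensity")],
                  red_matches[, c("species_id", "intensity")])
    comparisons <- compare_forms(allm, pairing)
    utils::write.table(comparisons,
                       file.path(cfg$out_dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(logs, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(proteins = proteins, species = species, candidates = cand,
                 matches = matches, annotated = annotated, bonds = bonds,
                 comparisons = comparisons, log = logs))
}
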