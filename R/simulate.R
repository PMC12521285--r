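# Synthetic ground-truthed LC-MS data: fixture proteins that regenerate
# the printed disulfide-linked peptides on digestion, and a deterministic
# MGF-level spectrum simulator with planted species, decoys and noise.

# Deterministic filler for fixture construction: a 10-residue cycle with
# no C, K, R, P, M or aromatic residues, so cleavage and cysteine
# chemistry are fully controlled by the planted segments.
.FILLER_CYCLE <- c("A", "D", "G", "E", "S", "T", "V", "N", "Q", "H")

# assemble a synthetic protein: planted segments at fixed Met1-based
# positions, lysines at `kpos`, filler elsewhere; validates consistency.
.assemble_fixture <- function(len, segments, kpos = integer(0)) {
  chars <- rep(NA_character_, len)
  for (seg in segments) {
    at <- seg$at
    s <- strsplit(seg$seq, "", fixed = TRUE)[[1]]
    idx <- at:(at + length(s) - 1L)
    if (max(idx) > len) stop("segment overruns fixture length")
    conflict <- !is.na(chars[idx]) & chars[idx] != s
    if (any(conflict)) stop("conflicting fixture segments at position ",
                            idx[conflict][1])
    chars[idx] <- s
  }
  for (k in kpos) {
    if (!is.na(chars[k]) && chars[k] != "K")
      stop("lysine position ", k, " conflicts with a planted segment")
    chars[k] <- "K"
  }
  gaps <- which(is.na(chars))
  chars[gaps] <- .FILLER_CYCLE[(gaps - 1L) %% length(.FILLER_CYCLE) + 1L]
  paste(chars, collapse = "")
}

#' Synthetic VDAC fixture proteins
#'
#' Three synthetic "mini-isoform" records that embed, at Met1-based
#' locants consistent with the rat VDAC numbering, the disulfide-linked
#' tryptic peptides reported for the VDAC1/2/3 isoform system, between
#' K/R cleavage context residues — so digesting the fixtures regenerates
#' exactly those peptides at their published coordinates. Filler
#' residues are a deterministic non-cysteine cycle; the records are
#' synthetic stand-ins (accessions suffixed `syn`), not database
#' sequences. The VDAC3 stand-in carries the full cysteine census
#' (Cys 2, 8, 36, 65, 122, 165, 229) and starts with an initiator Met
#' that maturation removes, leaving Cys2 as the N-terminal residue.
#'
#' @return List of three `protein_record`s: VDAC3syn (283 aa),
#'   VDAC1syn (283 aa), VDAC2syn (295 aa).
#' @export
#' @examples
#' fx <- make_fixtures()
#' substring(fx[[1]]$sequence, 35, 53)   # SCSGVEFSTSGHAYTDTGK
make_fixtures <- function() {
  vdac3 <- .assemble_fixture(
    283,
    segments = list(
      list(at = 1L,   seq = "M"),
      list(at = 2L,   seq = "CSTPTYCDLGK"),        # Cys2, Cys8
      list(at = 33L,  seq = "TKSCSGVEFSTSGHAYTDTGK"), # Cys36
      list(at = 62L,  seq = "YKVCNYGLIFTQK"),      # Cys65 (missed K63)
      list(at = 114L, seq = "LK"),                 # Leu114 semi-tryptic start
      list(at = 120L, seq = "RSCFELTAK"),          # Arg120-Lys128, Cys122
      list(at = 129L, seq = "VSTDAESTHNAGW"),      # Val129-Trp141
      list(at = 142L, seq = "K"),
      list(at = 164L, seq = "LCQNNFALGYK"),        # Cys165
      list(at = 229L, seq = "CSVAK")               # Cys229
    ),
    kpos = c(32L, 61L, 89L, 101L, 113L, 119L, 156L, 163L, 189L, 204L,
             224L, 247L, 263L)
  )
  vdac1 <- .assemble_fixture(
    283,
    segments = list(
      list(at = 1L,   seq = "M"),
      list(at = 121L, seq = "EHINLGCDVDFDIAGPSIR"), # Cys127
      list(at = 225L, seq = "YQVDPDACFSAK")         # Cys232
    ),
    kpos = c(15L, 30L, 45L, 60L, 75L, 90L, 105L, 120L, 155L, 170L, 185L,
             200L, 215L, 224L, 250L, 265L)
  )
  vdac2 <- .assemble_fixture(
    295,
    segments = list(
      list(at = 1L,   seq = "M"),
      list(at = 47L,  seq = "SCSGVEFSTSGSSNTDTGK")  # Cys48
    ),
    kpos = c(15L, 30L, 46L, 80L, 95L, 110L, 125L, 140L, 155L, 170L,
             185L, 200L, 215L, 230L, 245L, 260L, 275L, 290L)
  )
  list(protein_record("VDAC3syn", vdac3, "synthetic VDAC3 stand-in"),
       protein_record("VDAC1syn", vdac1, "synthetic VDAC1 stand-in"),
       protein_record("VDAC2syn", vdac2, "synthetic VDAC2 stand-in"))
}

#' Simulation specification
#'
#' Fully determines a synthetic dataset: identical specifications
#' (including the seed) produce byte-identical MGF output.
#'
#' @param planted List of entries `list(species = <disulfide_species or
#'   peptidoform>, intensity = <MS1 apex>)`; every in-window charge
#'   state of each species is emitted.
#' @param ms1_ppm_sd Gaussian MS1 mass-error scale in ppm (default 1.0).
#' @param ms2_da_sd Gaussian MS2 mass-error scale in Da (default 0.15).
#' @param noise_peaks Poisson mean of uniform noise peaks per MS2
#'   spectrum (default 0).
#' @param n_decoys Number of decoy peptide precursors planted as
#'   unmatchable singles (default 0).
#' @param seed Integer random seed.
#' @param cfg `enumeration_config` supplying charge range and scan
#'   window.
#' @param avoid_mz Numeric vector of candidate m/z values decoys must
#'   stay at least 50 ppm away from (planted ion m/z are always
#'   avoided).
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(planted, ms1_ppm_sd = 1.0, ms2_da_sd = 0.15,
                            noise_peaks = 0, n_decoys = 0L, seed = 1L,
                            cfg = enumeration_config(),
                            avoid_mz = numeric(0)) {
  stopifnot(ms1_ppm_sd >= 0, ms2_da_sd >= 0, noise_peaks >= 0,
            n_decoys >= 0)
  structure(list(planted = planted, ms1_ppm_sd = ms1_ppm_sd,
                 ms2_da_sd = ms2_da_sd, noise_peaks = noise_peaks,
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed),
                 cfg = cfg, avoid_mz = as.numeric(avoid_mz)),
            class = "simulation_spec")
}

# decoy peptides: tryptic peptides of a deterministically scrambled
# fixture, all-CAM, kept only if >= 50 ppm from every avoided m/z
.decoy_candidates <- function(n_decoys, avoid, cfg) {
  fx <- make_fixtures()
  scrambled <- lapply(seq_along(fx), function(i) {
    chars <- strsplit(fx[[i]]$sequence, "", fixed = TRUE)[[1]]
    chars <- chars[chars != "C"]            # keep decoys bridge-free
    protein_record(paste0("DECOY", i),
                   paste(sample(chars), collapse = ""))
  })
  out <- list()
  for (pr in scrambled) {
    d <- digest(mature(pr), max_missed = 0L, min_length = 6L,
                max_length = 30L)
    for (r in seq_len(nrow(d))) {
      pf <- peptidoform(d$sequence[r], pr$accession, d$start[r], d$end[r])
      for (z in 2:3) {
        m <- mz(peptidoform_mass(pf), z)
        if (m < cfg$mz_range[1] || m > cfg$mz_range[2]) next
        if (length(avoid) && any(abs(m - avoid) / avoid * 1e6 < 50)) next
        out[[length(out) + 1L]] <- list(pf = pf, charge = z, mz = m)
        break
      }
      if (length(out) >= n_decoys) return(out)
    }
  }
  out
}

#' Simulate a synthetic LC-MS dataset
#'
#' For each planted species and in-window charge: one MS2 spectrum whose
#' precursor (PEPMASS) is the theoretical m/z perturbed by Gaussian ppm
#' error at the configured MS1 scale, with the specified apex intensity;
#' fragment peaks come from [generate_fragments()] (charges 1 to
#' min(z - 1, 3)) perturbed at the Da-scale MS2 error, with log-uniform
#' intensities, plus a Poisson-distributed count of uniform noise peaks.
#' Decoy peptides are emitted as unmatchable precursor singles at least
#' 50 ppm from every avoided m/z. With zero error scales and zero noise
#' the emitted m/z values are bit-identical to theory. Planted species
#' with no in-window charge state are recorded as `out_of_window` in the
#' ground truth rather than emitted.
#'
#' @param spec A `simulation_spec`.
#' @return List with `spectra` (list of spectrum records: `title`,
#'   `scan`, `rt`, `pepmass`, `pep_intensity`, `charge`, `peaks`),
#'   `ground_truth` (data.frame: `species_id`, `charge`, `true_mz`,
#'   `intensity`, `scan`, `status`) and `decoys` (data.frame).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  cfg <- spec$cfg
  spectra <- list(); gt <- list(); scan <- 0L
  planted_mz <- numeric(0)
  for (pi in seq_along(spec$planted)) {
    pl <- spec$planted[[pi]]
    sp <- pl$species
    sid <- if (inherits(sp, "disulfide_species")) species_key(sp)
    else sprintf("linear|%s:%d-%d{%s}", sp$accession, sp$start, sp$end,
                 mod_string(sp))
    grid <- mz_grid(sp, cfg)
    if (!nrow(grid)) {
      gt[[length(gt) + 1L]] <- data.frame(
        species_id = sid, charge = NA_integer_, true_mz = NA_real_,
        intensity = pl$intensity, scan = NA_integer_,
        status = "out_of_window", stringsAsFactors = FALSE)
      next
    }
    for (g in seq_len(nrow(grid))) {
      z <- grid$charge[g]; theo <- grid$mz[g]
      scan <- scan + 1L
      obs <- theo * (1 + stats::rnorm(1) * spec$ms1_ppm_sd * 1e-6)
      planted_mz <- c(planted_mz, theo)
      frag <- if (inherits(sp, "disulfide_species"))
        generate_fragments(sp, charges = seq_len(max(1L, min(z - 1L, 3L))))
      else NULL
      if (!is.null(frag)) {
        fmz <- frag$mz + stats::rnorm(nrow(frag)) * spec$ms2_da_sd
        fint <- 10^stats::runif(nrow(frag), 2, 5)
      } else { fmz <- numeric(0); fint <- numeric(0) }
      nnoise <- if (spec$noise_peaks > 0) stats::rpois(1, spec$noise_peaks) else 0L
      if (nnoise > 0) {
        fmz <- c(fmz, stats::runif(nnoise, cfg$mz_range[1], cfg$mz_range[2]))
        fint <- c(fint, 10^stats::runif(nnoise, 2, 4))
      }
      o <- order(fmz)
      spectra[[scan]] <- list(
        title = sprintf("scan=%d planted=%d z=%d", scan, pi, z),
        scan = scan, rt = stats::runif(1, 600, 4800),
        pepmass = obs, pep_intensity = pl$intensity, charge = z,
        peaks = data.frame(mz = fmz[o], intensity = fint[o]))
      gt[[length(gt) + 1L]] <- data.frame(
        species_id = sid, charge = z, true_mz = theo,
        intensity = pl$intensity, scan = scan, status = "emitted",
        stringsAsFactors = FALSE)
    }
  }
  decoys <- data.frame(accession = character(0), sequence = character(0),
                       charge = integer(0), mz = numeric(0),
                       scan = integer(0), stringsAsFactors = FALSE)
  if (spec$n_decoys > 0L) {
    dc <- .decoy_candidates(spec$n_decoys,
                            unique(c(spec$avoid_mz, planted_mz)), cfg)
    for (d in dc) {
      scan <- scan + 1L
      obs <- d$mz * (1 + stats::rnorm(1) * spec$ms1_ppm_sd * 1e-6)
      spectra[[scan]] <- list(
        title = sprintf("scan=%d decoy %s", scan, d$pf$accession),
        scan = scan, rt = stats::runif(1, 600, 4800),
        pepmass = obs, pep_intensity = 10^stats::runif(1, 4, 6),
        charge = d$charge,
        peaks = data.frame(mz = numeric(0), intensity = numeric(0)))
      decoys <- rbind(decoys, data.frame(
        accession = d$pf$accession, sequence = d$pf$sequence,
        charge = d$charge, mz = d$mz, scan = scan,
        stringsAsFactors = FALSE))
    }
  }
  gtd <- if (length(gt)) do.call(rbind, gt)
  else data.frame(species_id = character(0), charge = integer(0),
                  true_mz = numeric(0), intensity = numeric(0),
                  scan = integer(0), status = character(0),
                  stringsAsFactors = FALSE)
  rownames(gtd) <- NULL
  list(spectra = spectra, ground_truth = gtd, decoys = decoys)
}

#' Write simulated spectra as MGF
#'
#' Fixed-format output (`PEPMASS` to 6 decimals, peaks to 4): identical
#' datasets serialize to identical bytes.
#'
#' @param dataset Result of [simulate_dataset()], or its `spectra`
#'   element.
#' @param path Output MGF path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(dataset, path) {
  spectra <- if (!is.null(dataset$spectra)) dataset$spectra else dataset
  con <- file(path, "wb")
  on.exit(close(con))
  for (sp in spectra) {
    lines <- c("BEGIN IONS",
               paste0("TITLE=", sp$title),
               sprintf("RTINSECONDS=%.2f", sp$rt),
               sprintf("PEPMASS=%.6f %.1f", sp$pepmass, sp$pep_intensity),
               sprintf("CHARGE=%d+", sp$charge))
    if (nrow(sp$peaks))
      lines <- c(lines, sprintf("%.4f %.1f", sp$peaks$mz,
                                sp$peaks$intensity))
    lines <- c(lines, "END IONS", "")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write ground truth as TSV
#' @param dataset Result of [simulate_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(dataset, path) {
  utils::write.table(dataset$ground_truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
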