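# Enumeration of candidate disulfide species: loop-linked peptides,
# intra-protein and inter-protein cross-linked peptide pairs, with full
# modification combinatorics, and their m/z grids over the instrument's
# charge and scan ranges.

#' Enumeration configuration
#'
#' Defaults reproduce a typical Orbitrap survey acquisition and search
#' setup: at most 3 variable modifications per chain, non-bridged
#' cysteines carboxyamidomethylated or trioxidized, precursor charges
#' 1-5, survey window m/z 400-1600, tryptic peptides of 5-50 residues
#' with up to 3 missed cleavages.
#'
#' @param max_var_mods Maximum variable modifications per chain.
#' @param cys_states Allowed states for non-bridged cysteines; subset of
#'   `c("cam", "triox", "free")`.
#' @param charges Integer charge range considered.
#' @param mz_range Survey scan m/z window, length-2 numeric.
#' @param length_range Peptide length bounds for candidate generation.
#' @param max_missed Maximum missed cleavages for candidate digestion.
#' @param allow_homodimer Enumerate pairings of a peptide with an
#'   identical copy of itself (homodimeric bridges)? Default FALSE.
#' @return Object of class `enumeration_config`.
#' @export
enumeration_config <- function(max_var_mods = 3L,
                               cys_states = c("cam", "triox"),
                               charges = 1:5,
                               mz_range = c(400, 1600),
                               length_range = c(5L, 50L),
                               max_missed = 3L,
                               allow_homodimer = FALSE) {
  if (max_var_mods < 0) stop("max_var_mods must be >= 0")
  stopifnot(all(cys_states %in% c("cam", "triox", "free")),
            length(mz_range) == 2L, mz_range[1] < mz_range[2],
            all(charges >= 1L))
  structure(list(max_var_mods = as.integer(max_var_mods),
                 cys_states = cys_states, charges = as.integer(charges),
                 mz_range = as.numeric(mz_range),
                 length_range = as.integer(length_range),
                 max_missed = as.integer(max_missed),
                 allow_homodimer = isTRUE(allow_homodimer)),
            class = "enumeration_config")
}

#' Enumerate peptidoforms of a located peptide
#'
#' Emits every assignment of: cysteine states drawn from the allowed set
#' plus the linkable half-disulfide state; methionine-oxidation subsets;
#' protein N-terminal acetylation (only when the peptide starts at the
#' mature N-terminus); pyroglutamate formation (only when the first
#' residue is Q or E, and not combined with acetylation) — subject to the
#' per-chain variable-modification cap. The half-disulfide state and the
#' fixed carboxyamidomethyl state do not count against the cap.
#'
#' @param peptide One-row data.frame (or list) with `start`, `end`,
#'   `sequence` as produced by [digest()].
#' @param protein The parent `protein_record`.
#' @param cfg An `enumeration_config`.
#' @return List of `peptidoform` objects; no duplicates.
#' @export
enumerate_peptidoforms <- function(peptide, protein, cfg = enumeration_config()) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(cfg, "enumeration_config"))
  seqs <- peptide$sequence
  chars <- strsplit(seqs, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_nterm <- peptide$start == mature_start(protein)

  slots <- list()   # each: data.frame(position, name) options incl. NA name
  for (p in which(chars == "C")) {
    states <- unique(c(cfg$cys_states, "ssbond_half"))
    states[states == "free"] <- NA_character_
    slots[[length(slots) + 1L]] <- list(position = p, options = states)
  }
  for (p in which(chars == "M"))
    slots[[length(slots) + 1L]] <- list(position = p,
                                        options = c(NA_character_, "ox_m"))
  if (is_nterm)
    slots[[length(slots) + 1L]] <- list(position = 0L,
                                        options = c(NA_character_, "acetyl_nterm"))
  if (chars[1] == "Q")
    slots[[length(slots) + 1L]] <- list(position = 1L,
                                        options = c(NA_character_, "pyroglu_q"))
  if (chars[1] == "E")
    slots[[length(slots) + 1L]] <- list(position = 1L,
                                        options = c(NA_character_, "pyroglu_e"))

  if (!length(slots)) {
    return(list(peptidoform(seqs, protein$accession, peptide$start,
                            peptide$end, protein_nterm = is_nterm)))
  }
  grid <- expand.grid(lapply(slots, function(s) seq_along(s$options)),
                      KEEP.OUT.ATTRS = FALSE)
  reg <- modification_registry()
  var_names <- reg$name[reg$kind == "variable"]
  out <- vector("list", nrow(grid))
  kept <- 0L
  for (g in seq_len(nrow(grid))) {
    pos <- integer(0); nm <- character(0)
    for (si in seq_along(slots)) {
      choice <- slots[[si]]$options[grid[g, si]]
      if (!is.na(choice)) { pos <- c(pos, slots[[si]]$position); nm <- c(nm, choice) }
    }
    if (sum(nm %in% var_names) > cfg$max_var_mods) next
    if ("acetyl_nterm" %in% nm && any(nm %in% c("pyroglu_q", "pyroglu_e"))) next
    kept <- kept + 1L
    out[[kept]] <- peptidoform(
      seqs, protein$accession, peptide$start, peptide$end,
      mods = if (length(pos)) data.frame(position = pos, name = nm) else NULL,
      protein_nterm = is_nterm)
  }
  out[seq_len(kept)]
}

#' Construct a disulfide species
#'
#' A loop-linked peptide (one chain, one intramolecular bridge) or a
#' cross-linked pair (two chains, one bridge). Every bridged cysteine
#' must carry the half-disulfide state (`ssbond_half`, -1.007825 Da), so
#' the species neutral mass is simply the sum of chain peptidoform
#' masses (net -2.015650 Da per bridge relative to free thiols).
#'
#' @param chains List of one or two `peptidoform` objects.
#' @param bridge List with integer vectors `chain` and `pos` (length 2
#'   each): the chain index and peptide-relative Cys position of the two
#'   bridge ends.
#' @return Object of class `disulfide_species` with fields `topology`
#'   (`"loop"`, `"intra"`, `"inter"`), `chains`, `bridge`, `mass`.
#' @export
disulfide_species <- function(chains, bridge) {
  stopifnot(is.list(chains), length(chains) %in% 1:2,
            all(vapply(chains, inherits, TRUE, "peptidoform")),
            length(bridge$chain) == 2L, length(bridge$pos) == 2L)
  if (length(chains) == 1L) {
    if (!all(bridge$chain == 1L) || bridge$pos[1] == bridge$pos[2])
      stop("loop species needs one chain and two distinct Cys positions")
  } else {
    if (!setequal(bridge$chain, 1:2))
      stop("pair species needs the bridge to join chain 1 and chain 2")
  }
  # canonical chain order for pairs
  if (length(chains) == 2L) {
    key <- vapply(chains, function(p)
      paste(p$accession, sprintf("%06d", p$start), sprintf("%06d", p$end),
            mod_string(p)), "")
    if (key[2] < key[1]) {
      chains <- chains[c(2, 1)]
      bridge$chain <- 3L - bridge$chain
    }
    o <- order(bridge$chain)
    bridge$chain <- bridge$chain[o]; bridge$pos <- bridge$pos[o]
  } else {
    o <- order(bridge$pos)
    bridge$pos <- bridge$pos[o]
  }
  for (k in 1:2) {
    ch <- chains[[bridge$chain[k]]]
    pchars <- strsplit(ch$sequence, "", fixed = TRUE)[[1]]
    if (pchars[bridge$pos[k]] != "C")
      stop("bridge position ", bridge$pos[k], " is not a cysteine")
    if (cys_state(ch, bridge$pos[k]) != "ssbond_half")
      stop("bridged Cys must carry the half-disulfide state")
  }
  # no dangling half-disulfide on non-bridged cysteines
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    for (cp in cys_positions(ch)) {
      bridged <- any(bridge$chain == ci & bridge$pos == cp)
      if (!bridged && cys_state(ch, cp) == "ssbond_half")
        stop("non-bridged Cys carries half-disulfide state")
    }
  }
  topology <- if (length(chains) == 1L) "loop"
  else if (chains[[1]]$accession == chains[[2]]$accession) "intra"
  else "inter"
  mass <- sum(vapply(chains, peptidoform_mass, 0))
  structure(list(topology = topology, chains = chains, bridge = bridge,
                 mass = mass),
            class = "disulfide_species")
}

#' @export
print.disulfide_species <- function(x, ...) {
  cat(sprintf("<disulfide_species> %s, M = %.4f\n  %s\n",
              x$topology, x$mass, species_key(x)))
  invisible(x)
}

#' Met1-based positions of the two bridged cysteines
#' @param sp A `disulfide_species`.
#' @return Integer vector of length 2 (sorted within chain order).
#' @export
bridge_sites <- function(sp) {
  vapply(1:2, function(k) {
    ch <- sp$chains[[sp$bridge$chain[k]]]
    ch$start + sp$bridge$pos[k] - 1L
  }, 0L)
}

#' Canonical identity key of a disulfide species
#'
#' Chain locants, modification multiset and bridge pair in canonical
#' order; used for deduplication and as the species id in tables.
#'
#' @param sp A `disulfide_species`.
#' @return Single string.
#' @export
species_key <- function(sp) {
  chain_str <- vapply(sp$chains, function(p)
    sprintf("%s:%d-%d{%s}", p$accession, p$start, p$end, mod_string(p)), "")
  gs <- bridge_sites(sp)
  paste0(sp$topology, "|", paste(chain_str, collapse = "+"),
         "@", paste(gs, collapse = "~"))
}

# variants grouped by their set of half-disulfide positions
.variants_by_half <- function(variants) {
  halves <- lapply(variants, function(p) {
    sel <- p$mods$name == "ssbond_half"
    sort(p$mods$position[sel])
  })
  keys <- vapply(halves, paste, "", collapse = ",")
  split(variants, keys)
}

#' Enumerate candidate disulfide species
#'
#' Digests every protein (trypsin, missed cleavages and length bounds
#' from `cfg`), then emits (a) loop species for every peptide with two
#' or more cysteines, one per unordered Cys pair; (b) intra-protein pair
#' species for every unordered pair of distinct, non-overlapping
#' peptides of one protein; (c) inter-protein pair species for every
#' peptide pair across distinct proteins — each combined with the
#' peptidoform variants of the non-bridged positions, deduplicated on
#' the canonical species key. Initiator methionines are removed before
#' digestion ([mature()]).
#'
#' @param proteins List of `protein_record` objects (>= 1).
#' @param cfg An `enumeration_config`.
#' @param remove_met Apply initiator-Met removal (default TRUE).
#' @return List of `disulfide_species`.
#' @export
enumerate_species <- function(proteins, cfg = enumeration_config(),
                              remove_met = TRUE) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  stopifnot(length(proteins) >= 1L)
  proteins <- lapply(proteins, mature, remove = remove_met)

  # per-protein cys-containing peptides and their modification variants
  pep_tabs <- lapply(proteins, function(pr) {
    d <- digest(pr, cleavage_rule("trypsin"), max_missed = cfg$max_missed,
                min_length = cfg$length_range[1],
                max_length = cfg$length_range[2])
    d[grepl("C", d$sequence, fixed = TRUE), , drop = FALSE]
  })
  variants <- lapply(seq_along(proteins), function(i) {
    tab <- pep_tabs[[i]]
    lapply(seq_len(nrow(tab)), function(r)
      .variants_by_half(enumerate_peptidoforms(tab[r, ], proteins[[i]], cfg)))
  })

  seen <- new.env(parent = emptyenv())
  out <- list()
  add <- function(sp) {
    k <- species_key(sp)
    if (!exists(k, envir = seen)) {
      assign(k, TRUE, envir = seen)
      out[[length(out) + 1L]] <<- sp
    }
  }

  # (a) loop species
  for (i in seq_along(proteins)) {
    tab <- pep_tabs[[i]]
    for (r in seq_len(nrow(tab))) {
      cpos <- gregexpr("C", tab$sequence[r], fixed = TRUE)[[1]]
      if (length(cpos) < 2L) next
      for (a in seq_along(cpos)[-length(cpos)]) for (b in (a + 1L):length(cpos)) {
        key <- paste(sort(c(cpos[a], cpos[b])), collapse = ",")
        for (v in variants[[i]][[r]][[key]] %||% list())
          add(disulfide_species(list(v),
                                list(chain = c(1L, 1L),
                                     pos = c(cpos[a], cpos[b]))))
      }
    }
  }

  # flat index of (protein, peptide row) for pairing
  idx <- do.call(rbind, lapply(seq_along(proteins), function(i) {
    tab <- pep_tabs[[i]]
    if (!nrow(tab)) return(NULL)
    data.frame(prot = i, row = seq_len(nrow(tab)), start = tab$start,
               end = tab$end, stringsAsFactors = FALSE)
  }))
  np <- if (is.null(idx)) 0L else nrow(idx)
  if (np >= 1L) for (u in seq_len(np)) for (v in u:np) {
    same_loc <- idx$prot[u] == idx$prot[v] && idx$row[u] == idx$row[v]
    if (same_loc && !cfg$allow_homodimer) next
    if (idx$prot[u] == idx$prot[v] && !same_loc) {
      # intra-protein: distinct peptides must not overlap
      if (idx$start[u] <= idx$end[v] && idx$start[v] <= idx$end[u]) next
    }
    vu <- variants[[idx$prot[u]]][[idx$row[u]]]
    vv <- variants[[idx$prot[v]]][[idx$row[v]]]
    cu <- gregexpr("C", pep_tabs[[idx$prot[u]]]$sequence[idx$row[u]],
                   fixed = TRUE)[[1]]
    cv <- gregexpr("C", pep_tabs[[idx$prot[v]]]$sequence[idx$row[v]],
                   fixed = TRUE)[[1]]
    for (ca in cu) for (cb in cv) {
      for (pa in vu[[as.character(ca)]] %||% list())
        for (pb in vv[[as.character(cb)]] %||% list())
          add(disulfide_species(list(pa, pb),
                                list(chain = c(1L, 2L), pos = c(ca, cb))))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Candidate ions of a species over the charge and scan ranges
#'
#' One candidate per charge in `cfg$charges` whose m/z falls inside
#' `cfg$mz_range`; possibly none.
#'
#' @param species A `disulfide_species` (or any object with a `mass`
#'   field and `peptidoform`s are accepted via `neutral_mass`).
#' @param cfg An `enumeration_config`.
#' @return data.frame with columns `charge`, `mz`.
#' @export
mz_grid <- function(species, cfg = enumeration_config()) {
  mass <- if (inherits(species, "disulfide_species")) species$mass
  else if (inherits(species, "peptidoform")) peptidoform_mass(species)
  else as.numeric(species)
  if (mass <= 0) stop("species mass must be positive")
  mzs <- mz(mass, cfg$charges)
  keep <- mzs >= cfg$mz_range[1] & mzs <= cfg$mz_range[2]
  data.frame(charge = cfg$charges[keep], mz = mzs[keep])
}

# one-row metadata for a species' chains
.species_meta <- function(sp) {
  ch <- sp$chains
  gs <- bridge_sites(sp)
  a <- ch[[1]]; b <- if (length(ch) == 2L) ch[[2]] else NULL
  data.frame(
    species_id = species_key(sp), topology = sp$topology,
    acc_a = a$accession, start_a = a$start, end_a = a$end,
    seq_a = a$sequence, mods_a = mod_string(a),
    acc_b = if (is.null(b)) NA_character_ else b$accession,
    start_b = if (is.null(b)) NA_integer_ else b$start,
    end_b = if (is.null(b)) NA_integer_ else b$end,
    seq_b = if (is.null(b)) NA_character_ else b$sequence,
    mods_b = if (is.null(b)) NA_character_ else mod_string(b),
    cys_a = gs[1], cys_b = gs[2],
    neutral_mass = sp$mass, stringsAsFactors = FALSE)
}

#' Candidate ion table for a list of species
#'
#' Expands every species into its in-window charge states and attaches
#' chain metadata (accessions, Met1-based locants, sequences,
#' modification strings, topology, bridged Cys positions).
#'
#' @param species_list List of `disulfide_species`.
#' @param cfg An `enumeration_config`.
#' @return data.frame, one row per (species, charge) candidate ion.
#' @export
candidate_ions <- function(species_list, cfg = enumeration_config()) {
  if (inherits(species_list, "disulfide_species"))
    species_list <- list(species_list)
  rows <- lapply(species_list, function(sp) {
    grid <- mz_grid(sp, cfg)
    if (!nrow(grid)) return(NULL)
    meta <- .species_meta(sp)
    cbind(meta[rep(1L, nrow(grid)), , drop = FALSE], grid, row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(cbind(.species_meta(disulfide_species(
      list(peptidoform("CC", mods = data.frame(position = 1:2,
                                               name = "ssbond_half"))),
      list(chain = c(1L, 1L), pos = c(1L, 2L))))[0, ],
      data.frame(charge = integer(0), mz = numeric(0))))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write a candidate table as TSV
#'
#' m/z and neutral mass are printed to 4 decimals.
#'
#' @param candidates data.frame from [candidate_ions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  out <- candidates
  out$neutral_mass <- sprintf("%.4f", out$neutral_mass)
  out$mz <- sprintf("%.4f", out$mz)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reduced-form (carboxyamidomethylated) counterparts of a species
#'
#' For abundance comparison: each chain of a bridged species is returned
#' as a stand-alone peptidoform with the bridged cysteine(s)
#' carboxyamidomethylated and every other assignment kept.
#'
#' @param sp A `disulfide_species`.
#' @return List of `peptidoform` objects (one per chain).
#' @export
reduced_counterparts <- function(sp) {
  stopifnot(inherits(sp, "disulfide_species"))
  lapply(seq_along(sp$chains), function(ci) {
    ch <- sp$chains[[ci]]
    m <- ch$mods
    sel <- m$name == "ssbond_half"
    m$name[sel] <- "cam"
    peptidoform(ch$sequence, ch$accession, ch$start, ch$end, mods = m,
                protein_nterm = ch$protein_nterm)
  })
}
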