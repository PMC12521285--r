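# Relative-abundance comparison of bridged vs carboxyamidomethylated
# cysteine forms, and the bond-level summary report.

#' Abundance category from a bridged/reduced intensity ratio
#'
#' Deterministic step function operationalizing the verbal categories
#' used when comparing molecular-ion intensities: ratio >= 10
#' `predominant`, 0.1 <= ratio < 10 `comparable`, 0.01 <= ratio < 0.1
#' `low`, ratio < 0.01 `trace`. Thresholds are configurable.
#'
#' @param ratio Non-negative ratio (may be `Inf`).
#' @param thresholds Numeric length-3 descending cut points.
#' @return Character vector of categories.
#' @export
abundance_category <- function(ratio, thresholds = c(10, 0.1, 0.01)) {
  stopifnot(all(ratio >= 0 | is.infinite(ratio)))
  ifelse(ratio >= thresholds[1], "predominant",
         ifelse(ratio >= thresholds[2], "comparable",
                ifelse(ratio >= thresholds[3], "low", "trace")))
}

#' Compare bridged and reduced (CAM) form intensities
#'
#' For each bridged/reduced pairing, the intensity metric of a form is
#' the apex: the maximum precursor intensity over all its matched charge
#' states and scans. The ratio bridged/reduced is `Inf` when no reduced
#' form was observed and `0` when no bridged form was observed (noted
#' "bonded not detected"); pairings with neither form observed are
#' omitted with a message.
#'
#' @param matches data.frame from [match_precursors()] (needs
#'   `species_id`/`form_id` and `intensity`); the id column used is
#'   `form_id` if present, else `species_id`.
#' @param pairing data.frame with columns `bond`, `bridged_id`,
#'   `reduced_id` (several reduced ids per bond allowed; intensities are
#'   pooled by maximum).
#' @return data.frame: `bond`, `bridged_intensity`, `reduced_intensity`,
#'   `ratio`, `category`, `note`.
#' @export
compare_forms <- function(matches, pairing) {
  idcol <- if (!is.null(matches$form_id)) "form_id" else "species_id"
  apex <- function(ids) {
    sel <- matches[[idcol]] %in% ids
    if (!any(sel)) NA_real_ else max(matches$intensity[sel])
  }
  out <- list()
  for (b in unique(pairing$bond)) {
    rows <- pairing[pairing$bond == b, ]
    bi <- apex(unique(rows$bridged_id))
    ri <- apex(unique(rows$reduced_id))
    if (is.na(bi) && is.na(ri)) {
      message("compare_forms: bond ", b, " - neither form observed; omitted")
      next
    }
    note <- ""
    if (is.na(ri)) { ratio <- Inf; note <- "reduced not detected" }
    else if (is.na(bi)) { ratio <- 0; note <- "bonded not detected" }
    else ratio <- bi / ri
    out[[length(out) + 1L]] <- data.frame(
      bond = b, bridged_intensity = bi, reduced_intensity = ri,
      ratio = ratio, category = abundance_category(ratio), note = note,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(bond = character(0), bridged_intensity = numeric(0),
                      reduced_intensity = numeric(0), ratio = numeric(0),
                      category = character(0), note = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# canonical unordered bond id "ACC/Cys <-> ACC/Cys" from candidate columns
.bond_id <- function(acc_a, cys_a, acc_b, cys_b, topology) {
  vapply(seq_along(acc_a), function(i) {
    a2 <- if (is.na(acc_b[i])) acc_a[i] else acc_b[i]
    ends <- c(sprintf("%s/Cys%d", acc_a[i], cys_a[i]),
              sprintf("%s/Cys%d", a2, cys_b[i]))
    paste(sort(ends), collapse = "<->")
  }, "")
}

#' Summarize precursor matches into bond-level reports
#'
#' Groups matches by the unordered cysteine-pair identity (protein/Cys
#' on both ends, Met1-based) across all charge states and peptidoform
#' variants. Bonds supported only at MS1 are flagged `precursor-only`;
#' a bond is MS2-confirmed when an annotated spectrum for one of its
#' species has at least one matched fragment on each chain (pair
#' topologies) or at least one bridge-opened fragment (loops).
#'
#' @param matches data.frame from [match_precursors()] against a
#'   disulfide candidate table (needs `species_id`, `acc_a`, `cys_a`,
#'   `acc_b`, `cys_b`, `topology`, `cand_charge`, `ppm`).
#' @param spectra Optional list of entries `list(species_id, annotated)`
#'   where `annotated` is an `annotated_spectrum`.
#' @return data.frame: `bond`, `topology`, `n_ions`, `charges`,
#'   `best_ppm`, `ms2_supported`, `status`.
#' @export
summarize_bonds <- function(matches, spectra = NULL) {
  if (!nrow(matches))
    return(data.frame(bond = character(0), topology = character(0),
                      n_ions = integer(0), charges = character(0),
                      best_ppm = numeric(0), ms2_supported = logical(0),
                      status = character(0), stringsAsFactors = FALSE))
  bond <- .bond_id(matches$acc_a, matches$cys_a, matches$acc_b,
                   matches$cys_b, matches$topology)
  ms2_ok_species <- character(0)
  if (!is.null(spectra)) for (entry in spectra) {
    ann <- entry$annotated
    if (!nrow(ann$assignments)) next
    is_loop <- !("B" %in% ann$assignments$chain) &&
      all(ann$assignments$chain == "A") && length(ann$coverage) == 1L
    ok <- if (is_loop)
      any(ann$assignments$variant %in% c("thiol", "persulfide", "dha"))
    else all(c("A", "B") %in% ann$assignments$chain)
    if (ok) ms2_ok_species <- c(ms2_ok_species, entry$species_id)
  }
  out <- lapply(split(seq_len(nrow(matches)), bond), function(ix) {
    m <- matches[ix, ]
    ms2 <- any(m$species_id %in% ms2_ok_species)
    data.frame(
      bond = bond[ix[1]], topology = m$topology[1],
      n_ions = nrow(m),
      charges = paste(sort(unique(m$cand_charge)), collapse = ","),
      best_ppm = m$ppm[which.min(abs(m$ppm))],
      ms2_supported = ms2,
      status = if (ms2) "ms2-confirmed" else "precursor-only",
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$bond), , drop = FALSE]
  rownames(res) <- NULL
  res
}
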