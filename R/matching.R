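# MS1 precursor matching at ppm tolerance, MS2 fragment generation for
# bridged species (intact-bridge, S-S/S-C cleavage and neutral-loss
# variants) and greedy spectrum annotation.

#' Matching configuration
#'
#' Precursor matching is ppm-based (high-resolution survey scans);
#' fragment matching is dalton-based (ion-trap MS2 detection).
#'
#' @param ppm_tol Precursor tolerance in ppm (default 10).
#' @param frag_tol Fragment tolerance in Da (default 0.6).
#' @param min_intensity Minimum precursor intensity (default 5e3).
#' @return Object of class `match_config`.
#' @export
match_config <- function(ppm_tol = 10, frag_tol = 0.6, min_intensity = 5e3) {
  if (ppm_tol <= 0 || frag_tol <= 0) stop("tolerances must be positive")
  structure(list(ppm_tol = ppm_tol, frag_tol = frag_tol,
                 min_intensity = min_intensity), class = "match_config")
}

#' Match precursor observations against candidate ions
#'
#' Returns every (observation, candidate) pair whose charges agree (an
#' observation with unknown charge matches any candidate charge), whose
#' signed ppm error is within tolerance, and whose intensity reaches the
#' precursor floor. All qualifying candidates are reported, sorted by
#' |ppm| ascending within each observation — no winner-takes-all.
#'
#' @param observations data.frame with columns `mz`, `intensity` and
#'   optionally `scan`, `rt`, `charge` (NA = unknown).
#' @param candidates data.frame from [candidate_ions()] (needs `mz`,
#'   `charge`; other columns are carried through).
#' @param cfg A `match_config`.
#' @return data.frame: observation columns (`scan`, `obs_mz`,
#'   `obs_charge`, `intensity`) followed by candidate columns and `ppm`.
#' @export
match_precursors <- function(observations, candidates, cfg = match_config()) {
  stopifnot(inherits(cfg, "match_config"))
  obs <- as.data.frame(observations)
  if (is.null(obs$scan)) obs$scan <- seq_len(nrow(obs))
  if (is.null(obs$charge)) obs$charge <- NA_integer_
  cand <- as.data.frame(candidates)
  empty <- {
    cc <- cand[0, , drop = FALSE]
    names(cc)[names(cc) == "mz"] <- "theo_mz"
    names(cc)[names(cc) == "charge"] <- "cand_charge"
    cbind(data.frame(scan = integer(0), obs_mz = numeric(0),
                     obs_charge = integer(0), intensity = numeric(0)),
          cc, data.frame(ppm = numeric(0)))
  }
  if (!nrow(obs) || !nrow(cand)) return(empty)
  o <- order(cand$mz)
  cand <- cand[o, , drop = FALSE]
  cmz <- cand$mz
  res <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    if (obs$intensity[i] < cfg$min_intensity) next
    # |obs - theo|/theo <= tol  <=>  theo in [obs/(1+tol), obs/(1-tol)]
    lo <- obs$mz[i] / (1 + cfg$ppm_tol * 1e-6)
    hi <- obs$mz[i] / (1 - cfg$ppm_tol * 1e-6)
    a <- findInterval(lo, cmz, left.open = TRUE) + 1L
    b <- findInterval(hi, cmz)
    if (a > b) next
    hit <- a:b
    if (!is.na(obs$charge[i])) hit <- hit[cand$charge[hit] == obs$charge[i]]
    if (!length(hit)) next
    pp <- ppm_error(obs$mz[i], cmz[hit])
    ord <- order(abs(pp))
    block <- cand[hit[ord], , drop = FALSE]
    names(block)[names(block) == "mz"] <- "theo_mz"
    names(block)[names(block) == "charge"] <- "cand_charge"
    res[[i]] <- cbind(
      data.frame(scan = obs$scan[i], obs_mz = obs$mz[i],
                 obs_charge = obs$charge[i], intensity = obs$intensity[i]),
      block, data.frame(ppm = pp[ord]), row.names = NULL)
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# neutral mass of a b/y fragment of one chain, given an explicit delta for
# the chain's bridged Cys when it lies inside the fragment span.
.frag_neutral <- function(chain, series, index, bridged_pos, bridged_delta) {
  chars <- strsplit(chain$sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  span <- if (series == "b") seq_len(index) else (n - index + 1L):n
  m <- sum(.AA_MONO[chars[span]])
  if (series == "y") m <- m + .CONST$water
  if (nrow(chain$mods)) {
    inside <- chain$mods$position %in% span |
      (chain$mods$position == 0L & series == "b") |
      (chain$mods$position == 0L & series == "y" & index == n)
    keep <- inside & !(chain$mods$position %in% bridged_pos &
                         chain$mods$name == "ssbond_half")
    if (any(keep)) m <- m + sum(.mod_delta(chain$mods$name[keep]))
  }
  if (length(bridged_pos) && any(bridged_pos %in% span))
    m <- m + sum(bridged_delta[bridged_pos %in% span])
  m
}

# bridge-cleavage variant deltas applied at a bridged Cys, relative to the
# free-thiol cysteine: S-S homolysis leaves the thiol (0), S-S/S-C
# cleavages transfer sulfur (persulfide, +S) or strip the side-chain
# sulfur (dehydroalanine, -H2S).
.BRIDGE_VARIANTS <- c(thiol = 0,
                      persulfide = 31.972071,
                      dha = -(31.972071 + 2 * 1.007825))

#' Generate theoretical fragment ions of a disulfide species
#'
#' For pair species: full b/y series per chain. Fragments that contain
#' the bridged cysteine are emitted with the intact bridge (the entire
#' partner chain attached, net -2 x 1.007825 Da for the bridge) and, as
#' disulfide-specific variants, with the bridge cleaved at the S-S or
#' S-C bond: `thiol` (partner removed, cysteine restored to the free
#' thiol), `persulfide` (+31.972071 Da) and `dha` (dehydroalanine,
#' -33.987721 Da). For loop species: b/y ions outside the loop span are
#' emitted normally (the ring, when fully contained, stays intact);
#' cleavages inside the loop are emitted only in combination with a
#' bridge-cleavage variant, because the ring must open to release them.
#' Every ion is also emitted with -H2O and -NH3 neutral losses.
#'
#' @param species A `disulfide_species`.
#' @param charges Integer vector of fragment charges (default 1; typical
#'   practice is 1..min(precursor charge - 1, 3)).
#' @return data.frame with columns `chain` ("A"/"B"; "A" for loops),
#'   `series`, `index`, `loss` ("", "-H2O", "-NH3"), `variant`
#'   ("plain", "intact", "thiol", "persulfide", "dha"), `charge`, `mz`,
#'   `label` (e.g. `"A:y7*"`, `"B:b5§"`).
#' @export
generate_fragments <- function(species, charges = 1L) {
  stopifnot(inherits(species, "disulfide_species"))
  losses <- stats::setNames(c(0, -.CONST$water, -.CONST$ammonia),
                            c("", "-H2O", "-NH3"))
  rows <- list()
  emit <- function(chain_id, series, index, variant, neutral) {
    for (li in seq_along(losses)) for (z in charges) {
      rows[[length(rows) + 1L]] <<- list(
        chain = chain_id, series = series, index = index,
        loss = names(losses)[li], variant = variant, charge = z,
        mz = mz(neutral + losses[[li]], z))
    }
  }

  if (species$topology == "loop") {
    ch <- species$chains[[1]]
    n <- nchar(ch$sequence)
    p1 <- species$bridge$pos[1]; p2 <- species$bridge$pos[2]
    for (series in c("b", "y")) {
      for (index in seq_len(n - 1L)) {
        span_lo <- if (series == "b") 1L else n - index + 1L
        span_hi <- if (series == "b") index else n
        has1 <- p1 >= span_lo && p1 <= span_hi
        has2 <- p2 >= span_lo && p2 <= span_hi
        if (has1 && has2) {
          # ring fully contained: intact bridge (-2H relative to thiols)
          neutral <- .frag_neutral(ch, series, index, c(p1, p2),
                                   rep(-.CONST$hydrogen, 2))
          emit("A", series, index, "intact", neutral)
        } else if (has1 || has2) {
          # cleavage inside the loop: only bridge-opened variants
          bp <- if (has1) p1 else p2
          for (v in names(.BRIDGE_VARIANTS))
            emit("A", series, index, v,
                 .frag_neutral(ch, series, index, bp, .BRIDGE_VARIANTS[[v]]))
        } else {
          emit("A", series, index, "plain",
               .frag_neutral(ch, series, index, integer(0), numeric(0)))
        }
      }
    }
  } else {
    partner_mass <- vapply(species$chains, peptidoform_mass, 0)
    for (ci in 1:2) {
      ch <- species$chains[[ci]]
      chain_id <- c("A", "B")[ci]
      bp <- species$bridge$pos[species$bridge$chain == ci]
      n <- nchar(ch$sequence)
      for (series in c("b", "y")) {
        for (index in seq_len(n - 1L)) {
          span_lo <- if (series == "b") 1L else n - index + 1L
          span_hi <- if (series == "b") index else n
          if (bp >= span_lo && bp <= span_hi) {
            # intact: own Cys at -H plus the whole partner chain (whose
            # bridged Cys already carries -H), net -2H for the bridge
            neutral <- .frag_neutral(ch, series, index, bp,
                                     -.CONST$hydrogen) +
              partner_mass[3L - ci]
            emit(chain_id, series, index, "intact", neutral)
            for (v in names(.BRIDGE_VARIANTS))
              emit(chain_id, series, index, v,
                   .frag_neutral(ch, series, index, bp, .BRIDGE_VARIANTS[[v]]))
          } else {
            emit(chain_id, series, index, "plain",
                 .frag_neutral(ch, series, index, integer(0), numeric(0)))
          }
        }
      }
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  lossmark <- stats::setNames(c("", "*", "**"),
                              c("", "-H2O", "-NH3"))[out$loss]
  varmark <- ifelse(out$variant %in% c("thiol", "persulfide", "dha"),
                    "§", "")
  zmark <- ifelse(out$charge > 1L, paste0("^", out$charge), "")
  out$label <- paste0(out$chain, ":", out$series, out$index,
                      lossmark, varmark, zmark)
  rownames(out) <- NULL
  out
}

# complexity rank for tie-breaking: plain/intact < neutral loss < bridge variant
.variant_rank <- function(frag) {
  r <- ifelse(frag$variant %in% c("thiol", "persulfide", "dha"), 2L, 0L)
  r + ifelse(frag$loss == "", 0L, 1L)
}

#' Annotate an MS2 spectrum with theoretical fragments
#'
#' Greedy nearest-mass assignment within the fragment tolerance: each
#' observed peak receives at most one label, ties broken by smaller
#' |delta m| then by simpler variant (plain before neutral loss before
#' bridge-cleavage variant). Per-chain b/y coverage is the fraction of
#' backbone cleavage sites (length - 1) covered by at least one matched
#' b or y ion.
#'
#' @param peaks data.frame with columns `mz`, `intensity` (centroided).
#' @param fragments data.frame from [generate_fragments()].
#' @param cfg A `match_config` (uses `frag_tol`).
#' @return Object of class `annotated_spectrum`: list with
#'   `assignments` (peak_mz, intensity, label, series, index, chain,
#'   variant, loss, charge, theo_mz, delta), `coverage` (named per
#'   chain), `n_unassigned`.
#' @export
annotate_spectrum <- function(peaks, fragments, cfg = match_config()) {
  stopifnot(inherits(cfg, "match_config"))
  peaks <- as.data.frame(peaks)
  asg <- list()
  n_un <- 0L
  if (nrow(fragments)) {
    rank <- .variant_rank(fragments)
    for (i in seq_len(nrow(peaks))) {
      d <- abs(peaks$mz[i] - fragments$mz)
      ok <- which(d <= cfg$frag_tol)
      if (!length(ok)) { n_un <- n_un + 1L; next }
      ord <- ok[order(d[ok], rank[ok], fragments$label[ok])]
      j <- ord[1]
      asg[[length(asg) + 1L]] <- data.frame(
        peak_mz = peaks$mz[i], intensity = peaks$intensity[i],
        label = fragments$label[j], series = fragments$series[j],
        index = fragments$index[j], chain = fragments$chain[j],
        variant = fragments$variant[j], loss = fragments$loss[j],
        charge = fragments$charge[j], theo_mz = fragments$mz[j],
        delta = peaks$mz[i] - fragments$mz[j], stringsAsFactors = FALSE)
    }
  } else n_un <- nrow(peaks)
  assignments <- if (length(asg)) do.call(rbind, asg)
  else data.frame(peak_mz = numeric(0), intensity = numeric(0),
                  label = character(0), series = character(0),
                  index = integer(0), chain = character(0),
                  variant = character(0), loss = character(0),
                  charge = integer(0), theo_mz = numeric(0),
                  delta = numeric(0), stringsAsFactors = FALSE)
  chains <- unique(fragments$chain)
  cov <- vapply(chains, function(cid) {
    nfrag <- fragments[fragments$chain == cid, ]
    n <- max(nfrag$index) + 1L   # chain length
    a <- assignments[assignments$chain == cid, ]
    if (!nrow(a)) return(0)
    sites <- unique(ifelse(a$series == "b", a$index, n - a$index))
    length(sites) / (n - 1L)
  }, 0)
  structure(list(assignments = assignments, coverage = cov,
                 n_unassigned = n_un),
            class = "annotated_spectrum")
}

#' @export
print.annotated_spectrum <- function(x, ...) {
  cat(sprintf("<annotated_spectrum> %d assigned, %d unassigned; coverage %s\n",
              nrow(x$assignments), x$n_unassigned,
              paste(sprintf("%s=%.2f", names(x$coverage), x$coverage),
                    collapse = ", ")))
  invisible(x)
}
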