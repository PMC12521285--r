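# Protein maturation (initiator-Met handling), in-silico proteolysis with
# missed cleavages and optional chymotryptic-like non-specific activity,
# and sequence-coverage mapping. All peptide coordinates are Met1-based:
# they refer to the full database sequence even when Met1 is removed from
# the mature chain.

#' Construct a protein record
#'
#' @param accession Accession string (e.g. a SwissProt accession).
#' @param sequence Full database sequence, initiator Met included if the
#'   entry has one. Canonical residues only.
#' @param name Display name; defaults to the accession.
#' @return Object of class `protein_record` with fields `accession`,
#'   `name`, `sequence`, `met_removed` (logical) and `length`.
#' @export
protein_record <- function(accession, sequence, name = accession) {
  .check_sequence(sequence, paste0("protein ", accession))
  structure(list(accession = accession, name = name,
                 sequence = toupper(sequence),
                 met_removed = FALSE, length = nchar(sequence)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%s), %d aa%s\n", x$accession, x$name,
              x$length, if (x$met_removed) ", Met1 removed" else ""))
  invisible(x)
}

#' Apply initiator-methionine removal
#'
#' If the sequence starts with M, the mature chain begins at position 2
#' and the record is flagged `met_removed`. Coordinates of derived
#' peptides are unchanged (still Met1-based). Records not starting with M
#' are returned unchanged.
#'
#' @param protein A `protein_record`.
#' @param remove Set `FALSE` to disable Met removal.
#' @return The (possibly flagged) `protein_record`.
#' @export
mature <- function(protein, remove = TRUE) {
  stopifnot(inherits(protein, "protein_record"))
  if (remove && startsWith(protein$sequence, "M")) {
    if (protein$length == 1L)
      stop("mature chain of ", protein$accession, " would be empty")
    protein$met_removed <- TRUE
  }
  protein
}

# first Met1-based position of the mature chain
mature_start <- function(protein) if (protein$met_removed) 2L else 1L

#' Length of the mature chain
#' @param protein A `protein_record`.
#' @return Integer residue count of the mature chain.
#' @export
mature_length <- function(protein) protein$length - (mature_start(protein) - 1L)

#' Proteolytic cleavage rules
#'
#' `trypsin` cleaves C-terminally to K or R, `chymotrypsin_like` to
#' F, W, Y, L or M; both are blocked when the next residue is proline
#' (classic rules). Proline blocking can be disabled.
#'
#' @param name `"trypsin"` or `"chymotrypsin_like"`.
#' @param block_proline Logical; block cleavage before P (default TRUE).
#' @return Object of class `cleavage_rule`.
#' @export
cleavage_rule <- function(name = c("trypsin", "chymotrypsin_like"),
                          block_proline = TRUE) {
  name <- match.arg(name)
  residues <- switch(name, trypsin = c("K", "R"),
                     chymotrypsin_like = c("F", "W", "Y", "L", "M"))
  structure(list(name = name, residues = residues,
                 blocked_by = if (block_proline) "P" else character(0)),
            class = "cleavage_rule")
}

# Met1-based positions after which the chain is cut (C-terminal side),
# within [from, to]; the chain end itself is not listed here.
.cut_sites <- function(chars, rule, from, to) {
  pos <- from:(to - 1L)
  hit <- chars[pos] %in% rule$residues
  if (length(rule$blocked_by))
    hit <- hit & !(chars[pos + 1L] %in% rule$blocked_by)
  pos[hit]
}

#' In-silico digestion
#'
#' Enumerates every peptide between consecutive cleavage sites carrying
#' 0..`max_missed` internal missed cleavages, on the mature chain. With
#' `semi_chymo = TRUE` an additional pass emits semi-specific peptides
#' with one tryptic (or chain-terminal) boundary and one
#' chymotryptic-like boundary, mimicking the residual chymotryptic
#' activity of trypsin at mildly acidic pH; these are tagged
#' `"semi"` and are intended for coverage mapping.
#'
#' @param protein A `protein_record` (run [mature()] first if initiator
#'   Met handling is wanted).
#' @param rule A `cleavage_rule`; default trypsin.
#' @param max_missed Maximum internal missed cleavages (default 3).
#' @param min_length,max_length Peptide length bounds (defaults 1, Inf).
#' @param semi_chymo Also emit semi-specific chymotryptic-like peptides.
#' @return data.frame with columns `accession`, `start`, `end`, `length`,
#'   `missed`, `specificity` (`"tryptic"` or `"semi"`), `sequence`,
#'   sorted by (start, end); deterministic.
#' @export
digest <- function(protein, rule = cleavage_rule("trypsin"), max_missed = 3L,
                   min_length = 1L, max_length = Inf, semi_chymo = FALSE) {
  stopifnot(inherits(protein, "protein_record"), inherits(rule, "cleavage_rule"))
  if (max_missed < 0) stop("max_missed must be >= 0")
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  from <- mature_start(protein); to <- protein$length
  sites <- .cut_sites(chars, rule, from, to)
  # boundaries: position after which a peptide may start/end
  bounds <- c(from - 1L, sites, to)
  nb <- length(bounds)
  out <- list()
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    for (j in (i + 1L):jmax) {
      s <- bounds[i] + 1L; e <- bounds[j]
      len <- e - s + 1L
      if (len < min_length || len > max_length) next
      out[[length(out) + 1L]] <- c(s, e, j - i - 1L)
    }
  }
  res <- if (length(out)) {
    m <- do.call(rbind, out)
    data.frame(accession = protein$accession, start = m[, 1], end = m[, 2],
               length = m[, 2] - m[, 1] + 1L, missed = m[, 3],
               specificity = "tryptic", stringsAsFactors = FALSE)
  } else {
    data.frame(accession = character(0), start = integer(0), end = integer(0),
               length = integer(0), missed = integer(0),
               specificity = character(0), stringsAsFactors = FALSE)
  }
  if (semi_chymo) {
    crule <- cleavage_rule("chymotrypsin_like",
                           block_proline = length(rule$blocked_by) > 0)
    csites <- setdiff(.cut_sites(chars, crule, from, to), sites)
    semi <- list()
    tb <- bounds
    for (cs in csites) {
      # chymo C-terminus, tryptic/terminal N-terminus
      left <- tb[tb < cs]
      for (b in left) {
        s <- b + 1L; e <- cs; len <- e - s + 1L
        nmiss <- sum(sites > s - 1L & sites < e)
        if (len >= min_length && len <= max_length && nmiss <= max_missed)
          semi[[length(semi) + 1L]] <- c(s, e, nmiss)
      }
      # chymo N-terminus, tryptic/terminal C-terminus
      right <- tb[tb > cs]
      for (b in right) {
        s <- cs + 1L; e <- b; len <- e - s + 1L
        nmiss <- sum(sites >= s & sites < e)
        if (len >= min_length && len <= max_length && nmiss <= max_missed)
          semi[[length(semi) + 1L]] <- c(s, e, nmiss)
      }
    }
    if (length(semi)) {
      m <- unique(do.call(rbind, semi))
      res <- rbind(res, data.frame(
        accession = protein$accession, start = m[, 1], end = m[, 2],
        length = m[, 2] - m[, 1] + 1L, missed = m[, 3],
        specificity = "semi", stringsAsFactors = FALSE))
    }
  }
  res <- res[order(res$start, res$end, res$specificity), , drop = FALSE]
  rownames(res) <- NULL
  res$sequence <- substring(protein$sequence, res$start, res$end)
  res
}

#' Sequence coverage of a protein by a peptide set
#'
#' Fraction of the mature chain covered by the union of peptide
#' intervals, plus the merged interval list (Met1-based, inclusive).
#'
#' @param peptides data.frame with `start`/`end` columns (as from
#'   [digest()]); all peptides must lie within the protein.
#' @param protein A `protein_record`.
#' @return List with `fraction` (covered / mature length) and
#'   `intervals` (data.frame `start`, `end`).
#' @export
coverage <- function(peptides, protein) {
  stopifnot(inherits(protein, "protein_record"))
  if (!nrow(peptides))
    return(list(fraction = 0,
                intervals = data.frame(start = integer(0), end = integer(0))))
  if (any(peptides$start < 1L) || any(peptides$end > protein$length) ||
      any(peptides$start > peptides$end))
    stop("peptide outside protein sequence bounds")
  o <- order(peptides$start, peptides$end)
  s <- peptides$start[o]; e <- peptides$end[o]
  ms <- s[1]; me <- e[1]
  keep_s <- integer(0); keep_e <- integer(0)
  for (k in seq_along(s)[-1]) {
    if (s[k] <= me + 1L) me <- max(me, e[k])
    else { keep_s <- c(keep_s, ms); keep_e <- c(keep_e, me); ms <- s[k]; me <- e[k] }
  }
  keep_s <- c(keep_s, ms); keep_e <- c(keep_e, me)
  covered <- sum(keep_e - keep_s + 1L)
  list(fraction = covered / mature_length(protein),
       intervals = data.frame(start = keep_s, end = keep_e))
}
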