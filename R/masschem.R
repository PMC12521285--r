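# Monoisotopic mass arithmetic: residue masses, modification deltas,
# peptidoform neutral mass, m/z and ppm error. All masses in daltons,
# monoisotopic only.

# 5-decimal monoisotopic residue (i.e. dehydrated amino acid) masses.
# I and L are distinct letters with identical mass; no isobaric collapsing.
.AA_MONO <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.CONST <- list(
  proton   = 1.007276,
  hydrogen = 1.007825,
  water    = 18.010565,
  ammonia  = 17.026549,
  sulfur   = 31.972071
)

#' Monoisotopic residue masses
#'
#' Returns the monoisotopic residue masses (Da) of the 20 canonical amino
#' acids, i.e. the mass each residue contributes inside a peptide chain
#' (free amino acid minus water). Glycine, 57.02146 Da, is the minimum.
#'
#' @return Named numeric vector over the 20 canonical one-letter codes.
#' @export
#' @examples
#' amino_acid_masses()[["G"]]
amino_acid_masses <- function() .AA_MONO

#' Fundamental mass constants
#'
#' Monoisotopic masses (Da) used throughout: `proton` (1.007276),
#' `hydrogen` (1.007825, the neutral atom), `water` (18.010565),
#' `ammonia` (17.026549) and `sulfur` (31.972071).
#'
#' @return Named list of masses in Da.
#' @export
mass_constants <- function() .CONST

# Modification registry. `cys_state` marks the mutually exclusive per-cysteine
# states (carboxyamidomethyl, trioxidation, half-disulfide; "free" is the
# absence of any of them). The half-disulfide delta is stored at full
# hydrogen-atom precision -1.007825; engines print the rounded -1.0078.
.MODS <- data.frame(
  name  = c("cam", "triox", "ssbond_half", "ox_m",
            "acetyl_nterm", "pyroglu_q", "pyroglu_e"),
  delta = c(57.021464, 47.984744, -1.007825, 15.994915,
            42.010565, -17.026549, -18.010565),
  site  = c("C", "C", "C", "M", "protein_nterm", "nterm_Q", "nterm_E"),
  kind  = c("fixed", "variable", "cysteine-state", "variable",
            "variable", "variable", "variable"),
  cys_state = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Modification registry
#'
#' The fixed/variable modification set used for candidate enumeration:
#' carboxyamidomethyl cysteine (`cam`, +57.021464), cysteine trioxidation
#' to sulfonic acid (`triox`, +47.984744), half of a disulfide bridge
#' (`ssbond_half`, -1.007825, the state of a bridge-engaged cysteine),
#' methionine oxidation (`ox_m`, +15.994915), protein N-terminal
#' acetylation (`acetyl_nterm`, +42.010565) and pyroglutamate formation
#' from N-terminal Gln (`pyroglu_q`, -17.026549) or Glu
#' (`pyroglu_e`, -18.010565).
#'
#' @return data.frame with columns `name`, `delta` (Da), `site`, `kind`
#'   and `cys_state` (logical: member of the mutually exclusive
#'   per-cysteine state set).
#' @export
modification_registry <- function() .MODS

.mod_delta <- function(name) {
  i <- match(name, .MODS$name)
  if (anyNA(i)) stop("unknown modification name: ",
                     paste(name[is.na(i)], collapse = ", "))
  .MODS$delta[i]
}

.check_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(what, " must be a single string")
  if (nchar(sequence) == 0L) stop(what, " is empty")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% names(.AA_MONO)))
  if (length(bad))
    stop("non-canonical residue '", chars[bad[1]], "' at position ", bad[1],
         " of ", what)
  chars
}

#' Construct a peptidoform
#'
#' A peptidoform is a located peptide plus position-resolved modification
#' assignments. Positions in `mods` are peptide-relative (1 = first
#' residue); position 0 denotes the peptide N-terminus and is reserved for
#' protein N-terminal acetylation. Start/end coordinates follow the Met1
#' convention: they always refer to the full SwissProt-style sequence even
#' when the initiator methionine is absent from the mature chain.
#'
#' @param sequence Peptide residue sequence (canonical letters only).
#' @param accession Parent protein accession.
#' @param start,end Met1-based inclusive coordinates of the peptide.
#' @param mods data.frame with columns `position` and `name`, or NULL.
#' @param protein_nterm Logical; does the peptide begin at the mature
#'   protein N-terminus (required for `acetyl_nterm`)?
#' @return Object of class `peptidoform`.
#' @export
#' @examples
#' p <- peptidoform("SCSGVEFSTSGHAYTDTGK", accession = "VDAC3",
#'                  start = 35, end = 53)
#' peptidoform_mass(p)
peptidoform <- function(sequence, accession = NA_character_, start = 1L,
                        end = start + nchar(sequence) - 1L, mods = NULL,
                        protein_nterm = FALSE) {
  chars <- .check_sequence(sequence, "peptide sequence")
  start <- as.integer(start); end <- as.integer(end)
  if (end - start + 1L != length(chars))
    stop("sequence length must equal end - start + 1")
  if (is.null(mods)) {
    mods <- data.frame(position = integer(0), name = character(0),
                       stringsAsFactors = FALSE)
  } else {
    mods <- as.data.frame(mods)[, c("position", "name")]
    mods$position <- as.integer(mods$position)
  }
  n <- length(chars)
  if (nrow(mods)) {
    reg <- .MODS[match(mods$name, .MODS$name), ]
    if (anyNA(reg$name))
      stop("unknown modification name: ",
           paste(setdiff(mods$name, .MODS$name), collapse = ", "))
    for (k in seq_len(nrow(mods))) {
      pos <- mods$position[k]; site <- reg$site[k]
      if (site %in% c("C", "M")) {
        if (pos < 1L || pos > n || chars[pos] != site)
          stop("modification '", mods$name[k], "' requires residue ", site,
               " at position ", pos)
      } else if (site == "protein_nterm") {
        if (pos != 0L) stop("acetyl_nterm must sit at position 0")
        if (!protein_nterm)
          stop("acetyl_nterm only allowed on a mature protein N-terminal peptide")
      } else if (site == "nterm_Q") {
        if (pos != 1L || chars[1] != "Q")
          stop("pyroglu_q requires Q as the peptide's first residue")
      } else if (site == "nterm_E") {
        if (pos != 1L || chars[1] != "E")
          stop("pyroglu_e requires E as the peptide's first residue")
      }
    }
    # mutually exclusive cysteine states, one per Cys position
    cyspos <- mods$position[reg$cys_state]
    if (anyDuplicated(cyspos))
      stop("conflicting cysteine-state modifications at position ",
           cyspos[duplicated(cyspos)][1])
    if (sum(mods$name == "acetyl_nterm") > 1L)
      stop("at most one protein N-terminal modification")
    if (sum(mods$name %in% c("pyroglu_q", "pyroglu_e")) > 1L)
      stop("at most one peptide N-terminal modification")
    if (anyDuplicated(mods[, c("position", "name")]))
      stop("duplicate modification assignment")
  }
  structure(list(accession = accession, start = start, end = end,
                 sequence = sequence, mods = mods,
                 protein_nterm = isTRUE(protein_nterm)),
            class = "peptidoform")
}

#' @export
print.peptidoform <- function(x, ...) {
  cat(sprintf("<peptidoform> %s %d-%d %s [%s]\n",
              x$accession, x$start, x$end, x$sequence, mod_string(x)))
  invisible(x)
}

#' Compact modification string for a peptidoform
#'
#' @param p A `peptidoform`.
#' @return Single string like `"cam@2+ssbond_half@7"`, or `""`.
#' @export
mod_string <- function(p) {
  if (!nrow(p$mods)) return("")
  o <- order(p$mods$position, p$mods$name)
  paste(sprintf("%s@%d", p$mods$name[o], p$mods$position[o]), collapse = "+")
}

#' Neutral monoisotopic mass of a peptidoform
#'
#' Sum of residue masses, one water, and all assigned modification deltas.
#' Deterministic and independent of assignment order.
#'
#' @param p A `peptidoform`.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptidoform_mass <- function(p) {
  stopifnot(inherits(p, "peptidoform"))
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  m <- sum(.AA_MONO[chars]) + .CONST$water
  if (nrow(p$mods)) m <- m + sum(.mod_delta(p$mods$name))
  unname(m)
}

#' Mass-to-charge ratio of a protonated species
#'
#' Standard positive electrospray convention:
#' `m/z = (M + z * 1.007276) / z`.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param z Positive integer charge.
#' @return m/z value; strictly decreasing in `z` for fixed mass.
#' @export
#' @examples
#' mz(4000.7843, 4)
mz <- function(neutral_mass, z) {
  if (any(z <= 0) || any(z != as.integer(z)))
    stop("charge z must be a positive integer")
  (neutral_mass + z * .CONST$proton) / z
}

#' Signed parts-per-million mass error
#'
#' `(observed - theoretical) / theoretical * 1e6`.
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return Signed ppm error.
#' @export
#' @examples
#' ppm_error(1001.2056, 1001.2036)
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

# positions (peptide-relative) of cysteines in a peptidoform
cys_positions <- function(p) {
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  which(chars == "C")
}

# the cysteine-state name at a given Cys position: cam/triox/ssbond_half/free
cys_state <- function(p, pos) {
  if (nrow(p$mods)) {
    sel <- p$mods$position == pos &
      p$mods$name %in% .MODS$name[.MODS$cys_state]
    if (any(sel)) return(p$mods$name[sel][1])
  }
  "free"
}
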