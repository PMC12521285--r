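# Independent oracles used by property tests. The mass table below was
# hand-entered separately from the package's table and the summation is
# coded independently of peptidoform_mass().

ORACLE_AA <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
  C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
  H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
  M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
  T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)
ORACLE_WATER <- 18.010565

# brute-force: explicit per-character loop, no vectorized sum
oracle_peptide_mass <- function(sequence, deltas = 0) {
  total <- ORACLE_WATER
  for (ch in strsplit(sequence, "", fixed = TRUE)[[1]]) {
    total <- total + ORACLE_AA[[ch]]
  }
  total + sum(deltas)
}

random_peptide <- function(len, letters = names(ORACLE_AA)) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# brute-force all-pairs precursor matcher (independent of match_precursors)
oracle_match <- function(obs, cand, ppm_tol = 10, min_intensity = 5e3) {
  hits <- list()
  for (i in seq_len(nrow(obs))) {
    if (obs$intensity[i] < min_intensity) next
    for (j in seq_len(nrow(cand))) {
      if (!is.na(obs$charge[i]) && obs$charge[i] != cand$charge[j]) next
      ppm <- (obs$mz[i] - cand$mz[j]) / cand$mz[j] * 1e6
      if (abs(ppm) <= ppm_tol)
        hits[[length(hits) + 1L]] <- c(i = i, j = j)
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# a tiny two-protein toy set with controlled cysteines, no Met/Gln/Glu
# starts and no proline, for pairing-enumeration oracles
toy_proteins <- function() {
  list(
    protein_record("TOYA", "ACAKGGCSKAAAK"),
    protein_record("TOYB", "VVCKTTTCK")
  )
}

# exhaustive independent pairing: every unordered bond combination
# (loop pairs within a peptide, cross pairs between non-overlapping or
# cross-protein peptides), as canonical "acc:cys" strings
oracle_bond_combos <- function(proteins, max_missed, min_len) {
  peps <- list()
  for (pr in proteins) {
    d <- digest(mature(pr), max_missed = max_missed, min_length = min_len)
    for (r in seq_len(nrow(d))) {
      cys <- which(strsplit(d$sequence[r], "")[[1]] == "C")
      if (length(cys))
        peps[[length(peps) + 1L]] <- list(acc = pr$accession,
                                          start = d$start[r],
                                          end = d$end[r],
                                          cys = d$start[r] + cys - 1L)
    }
  }
  combos <- character(0)
  for (u in seq_along(peps)) {
    p <- peps[[u]]
    if (length(p$cys) >= 2L)
      for (a in seq_along(p$cys)[-length(p$cys)])
        for (b in (a + 1L):length(p$cys))
          combos <- c(combos, paste0(
            "loop|", p$acc, ":", p$start, "-", p$end, "@",
            p$cys[a], "~", p$cys[b]))
    for (v in seq_along(peps)) {
      if (v <= u) next
      q <- peps[[v]]
      if (p$acc == q$acc && p$start <= q$end && q$start <= p$end) next
      for (ca in p$cys) for (cb in q$cys) {
        ends <- sort(c(paste0(p$acc, ":", p$start, "-", p$end, "@", ca),
                       paste0(q$acc, ":", q$start, "-", q$end, "@", cb)))
        combos <- c(combos, paste0("pair|", ends[1], "+", ends[2]))
      }
    }
  }
  sort(unique(combos))
}

# strip modification detail from package species keys down to the same
# bond-combination representation the oracle produces
species_bond_combo <- function(sp) {
  gs <- bridge_sites(sp)
  if (sp$topology == "loop") {
    ch <- sp$chains[[1]]
    paste0("loop|", ch$accession, ":", ch$start, "-", ch$end, "@",
           min(gs), "~", max(gs))
  } else {
    ends <- vapply(1:2, function(k) {
      ch <- sp$chains[[sp$bridge$chain[k]]]
      paste0(ch$accession, ":", ch$start, "-", ch$end, "@", gs[k])
    }, "")
    paste0("pair|", paste(sort(ends), collapse = "+"))
  }
}

# a bridged pair species from explicit sequences/positions
make_bridged_pair <- function(seq_a, cys_a, seq_b, cys_b,
                              acc = c("P1", "P2"), start = c(1L, 101L)) {
  pa <- peptidoform(seq_a, acc[1], start[1],
                    mods = data.frame(position = cys_a, name = "ssbond_half"))
  pb <- peptidoform(seq_b, acc[2], start[2],
                    mods = data.frame(position = cys_b, name = "ssbond_half"))
  disulfide_species(list(pa, pb),
                    list(chain = c(1L, 2L), pos = c(cys_a, cys_b)))
}
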