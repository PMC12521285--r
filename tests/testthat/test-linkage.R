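# Disulfide species enumeration: peptidoform combinatorics, bridge mass
# bookkeeping, m/z grids and deduplication.

two_cys_cfg <- enumeration_config(cys_states = "cam")

test_that("cysteine-state combinatorics are exhaustive and duplicate-free", {
  pr <- protein_record("T1", "AAKSCSACDKGG")
  pep <- digest(pr, max_missed = 0, min_length = 4)[1, ]  # SCSACDK, 2 Cys
  pfs <- enumerate_peptidoforms(pep, pr, two_cys_cfg)
  # two cysteines x {cam, bridge-linkable}: 4 assignments
  expect_length(pfs, 4)
  keys <- vapply(pfs, mod_string, "")
  expect_equal(anyDuplicated(keys), 0)
  states <- t(vapply(pfs, function(p) c(cys_state(p, 2), cys_state(p, 5)), c("", "")))
  expect_setequal(apply(states, 1, paste, collapse = "/"),
                  c("cam/cam", "cam/ssbond_half", "ssbond_half/cam",
                    "ssbond_half/ssbond_half"))
})

test_that("N-terminal peptides gain acetylated variants; internal ones do not", {
  fx <- make_fixtures()
  v3 <- mature(fx[[1]])
  d <- digest(v3, max_missed = 0, min_length = 5)
  nt <- d[d$start == 2, ][1, ]
  pfs <- enumerate_peptidoforms(nt, v3, two_cys_cfg)
  expect_true(any(vapply(pfs, function(p)
    any(p$mods$name == "acetyl_nterm"), TRUE)))
  internal <- d[d$start > 2, ][1, ]
  pfs2 <- enumerate_peptidoforms(internal, v3, two_cys_cfg)
  expect_false(any(vapply(pfs2, function(p)
    any(p$mods$name == "acetyl_nterm"), TRUE)))
  # no Cys, no Met, internal start: exactly one peptidoform
  pr <- protein_record("T2", "AAKGGSTVKDD")
  pep <- digest(pr, max_missed = 0)[2, ]
  expect_equal(pep$sequence, "GGSTVK")
  expect_length(enumerate_peptidoforms(pep, pr, two_cys_cfg), 1)
})

test_that("the variable-modification cap prunes assignments", {
  pr <- protein_record("T3", "KMMMMK")
  pep <- digest(pr, max_missed = 1, min_length = 5)
  pep <- pep[pep$sequence == "MMMMK", ]
  pfs <- enumerate_peptidoforms(pep, pr, enumeration_config(max_var_mods = 3))
  # oxidation subsets of 4 Met capped at 3: 15 of 16
  expect_length(pfs, 15)
  pfs2 <- enumerate_peptidoforms(pep, pr, enumeration_config(max_var_mods = 4))
  expect_length(pfs2, 16)
})

make_pair <- function(seq_a, cys_a, seq_b, cys_b,
                      acc = c("P1", "P2"), start = c(1L, 101L)) {
  pa <- peptidoform(seq_a, acc[1], start[1],
                    mods = data.frame(position = cys_a, name = "ssbond_half"))
  pb <- peptidoform(seq_b, acc[2], start[2],
                    mods = data.frame(position = cys_b, name = "ssbond_half"))
  disulfide_species(list(pa, pb), list(chain = c(1L, 2L),
                                       pos = c(cys_a, cys_b)))
}

test_that("pair species masses match the printed cross-link examples", {
  sp <- make_pair("SCSGVEFSTSGHAYTDTGK", 2L, "EHINLGCDVDFDIAGPSIR", 7L)
  expect_equal(sp$mass, 4000.7843, tolerance = 2e-3)
  expect_lt(abs(ppm_error(mz(sp$mass, 4), 1001.2036)), 2)
  sp2 <- make_pair("SCSGVEFSTSGHAYTDTGK", 2L, "LCQNNFALGYK", 2L,
                   acc = c("P1", "P1"))
  expect_equal(sp2$topology, "intra")
  expect_lt(abs(ppm_error(mz(sp2$mass, 4), 801.1120)), 2)
})

test_that("a single-cysteine peptide yields no loop species", {
  pr <- protein_record("T4", "KSCSAVKGGK")
  sps <- enumerate_species(list(pr), two_cys_cfg)
  expect_false(any(vapply(sps, function(s) s$topology, "") == "loop"))
})

test_that("m/z grids honor the charge range and scan window", {
  cfg <- enumeration_config()
  g <- mz_grid(4000.7843, cfg)
  expect_equal(g$charge, 3:5)
  expect_equal(g$mz[g$charge == 4], 1001.2034, tolerance = 1e-4)
  expect_equal(nrow(mz_grid(300, cfg)), 0)
  sp <- make_pair("LCQNNFALGYK", 2L, "YQVDPDACFSAK", 8L)
  expect_equal(sp$mass, 2610.1883, tolerance = 2e-3)
  g2 <- mz_grid(sp, cfg)
  expect_true(any(g2$charge == 4 & abs(g2$mz - 653.554) < 0.01))
})

test_that("bridge mass law holds for random species", {
  set.seed(404)
  for (k in 1:100) {
    # random peptides with one forced Cys each
    mk <- function() {
      s <- random_peptide(sample(5:15, 1),
                          setdiff(names(ORACLE_AA), c("C")))
      pos <- sample(nchar(s), 1)
      substr(s, pos, pos) <- "C"
      list(seq = s, cys = pos)
    }
    a <- mk(); b <- mk()
    sp <- make_pair(a$seq, a$cys, b$seq, b$cys)
    free_sum <- oracle_peptide_mass(a$seq) + oracle_peptide_mass(b$seq)
    expect_equal(sp$mass, free_sum - 2 * 1.007825, tolerance = 1e-9)
    # loop species on a two-Cys peptide
    s2 <- paste0("C", random_peptide(sample(3:10, 1),
                                     setdiff(names(ORACLE_AA), "C")), "C")
    lp <- peptidoform(s2, mods = data.frame(position = c(1, nchar(s2)),
                                            name = "ssbond_half"))
    loop <- disulfide_species(list(lp),
                              list(chain = c(1L, 1L),
                                   pos = c(1L, nchar(s2))))
    expect_equal(loop$mass, oracle_peptide_mass(s2) - 2 * 1.007825,
                 tolerance = 1e-9)
  }
})

test_that("chain order does not change a pair species' identity or mass", {
  pa <- peptidoform("SCSGVEFSTSGHAYTDTGK", "P2", 35,
                    mods = data.frame(position = 2, name = "ssbond_half"))
  pb <- peptidoform("EHINLGCDVDFDIAGPSIR", "P1", 121,
                    mods = data.frame(position = 7, name = "ssbond_half"))
  s1 <- disulfide_species(list(pa, pb), list(chain = c(1L, 2L), pos = c(2L, 7L)))
  s2 <- disulfide_species(list(pb, pa), list(chain = c(1L, 2L), pos = c(7L, 2L)))
  expect_identical(species_key(s1), species_key(s2))
  expect_equal(s1$mass, s2$mass)
})

test_that("CAM vs loop mass difference matches the alkylation offset", {
  s <- "CSTPTYCDLGK"
  cam <- peptidoform(s, mods = data.frame(position = c(1, 7),
                                          name = c("cam", "cam")))
  lp <- peptidoform(s, mods = data.frame(position = c(1, 7),
                                         name = c("ssbond_half", "ssbond_half")))
  delta <- peptidoform_mass(cam) - peptidoform_mass(lp)
  expect_equal(delta, 116.058578, tolerance = 1e-6)
  # consistency with the printed observed 2+ pair 672.2845 / 614.2549
  obs_delta <- 2 * (672.2845 - 614.2549)
  expect_lt(abs(obs_delta - delta), 2e-6 * 1342.55)
})

test_that("enumeration matches an exhaustive independent pairing oracle", {
  prs <- toy_proteins()
  sps <- enumerate_species(prs, enumeration_config(
    cys_states = "cam", max_missed = 1, length_range = c(2L, 50L)))
  got <- sort(unique(vapply(sps, species_bond_combo, "")))
  want <- oracle_bond_combos(prs, max_missed = 1, min_len = 2)
  expect_identical(got, want)
  # and each species key appears exactly once
  keys <- vapply(sps, species_key, "")
  expect_equal(anyDuplicated(keys), 0)
})

test_that("reduced counterparts carboxyamidomethylate the bridged cysteines", {
  sp <- make_pair("SCSGVEFSTSGHAYTDTGK", 2L, "EHINLGCDVDFDIAGPSIR", 7L)
  red <- reduced_counterparts(sp)
  expect_length(red, 2)
  for (r in red) expect_false(any(r$mods$name == "ssbond_half"))
  expect_equal(sum(vapply(red, function(r) sum(r$mods$name == "cam"), 0L)), 2L)
  # mass bookkeeping: reduced sum = species mass + 2*(cam + H)
  expect_equal(sum(vapply(red, peptidoform_mass, 0)),
               sp$mass + 116.058578, tolerance = 1e-9)
})

test_that("bridged cysteines must carry the half-disulfide state", {
  pa <- peptidoform("SCAK", "P1", 1,
                    mods = data.frame(position = 2, name = "cam"))
  pb <- peptidoform("GCAK", "P2", 1,
                    mods = data.frame(position = 2, name = "ssbond_half"))
  expect_error(disulfide_species(list(pa, pb),
                                 list(chain = c(1L, 2L), pos = c(2L, 2L))),
               "half-disulfide")
  expect_error(disulfide_species(list(pb), list(chain = c(1L, 1L),
                                                pos = c(2L, 2L))),
               "distinct")
})
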