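# MS1 precursor matching and bridge-aware MS2 fragment generation and
# annotation.

pair_sp <- function() {
  pa <- peptidoform("SCSGVEFSTSGHAYTDTGK", "V3", 35,
                    mods = data.frame(position = 2, name = "ssbond_half"))
  pb <- peptidoform("EHINLGCDVDFDIAGPSIR", "V1", 121,
                    mods = data.frame(position = 7, name = "ssbond_half"))
  disulfide_species(list(pa, pb), list(chain = c(1L, 2L), pos = c(2L, 7L)))
}

loop_sp <- function() {
  lp <- peptidoform("CSTPTYCDLGK", "V3", 2,
                    mods = data.frame(position = c(1, 7),
                                      name = c("ssbond_half", "ssbond_half")))
  disulfide_species(list(lp), list(chain = c(1L, 1L), pos = c(1L, 7L)))
}

test_that("precursor matching applies ppm, charge and intensity rules", {
  cand <- data.frame(species_id = "s1", charge = 4L, mz = 1001.2036)
  obs <- data.frame(scan = 1, mz = 1001.2056, charge = 4L, intensity = 1e6)
  m <- match_precursors(obs, cand)
  expect_equal(nrow(m), 1)
  expect_equal(round(m$ppm, 1), 2.0)
  # below the precursor intensity floor: excluded regardless of mass
  m2 <- match_precursors(transform(obs, intensity = 4e3), cand)
  expect_equal(nrow(m2), 0)
  # unknown observed charge matches any candidate charge
  obs$charge <- NA_integer_
  expect_equal(nrow(match_precursors(obs, cand)), 1)
  # wrong charge does not
  obs$charge <- 3L
  expect_equal(nrow(match_precursors(obs, cand)), 0)
  # empty candidate list
  expect_equal(nrow(match_precursors(obs, cand[0, ])), 0)
})

test_that("matching equals a brute-force all-pairs scan on random instances", {
  set.seed(505)
  for (k in 1:10) {
    nc <- sample(30:80, 1); no <- sample(20:50, 1)
    cand <- data.frame(species_id = paste0("c", seq_len(nc)),
                       charge = sample(1:5, nc, replace = TRUE),
                       mz = runif(nc, 400, 1600))
    obs <- data.frame(scan = seq_len(no),
                      mz = sample(cand$mz, no, replace = TRUE) *
                        (1 + rnorm(no, 0, 4e-6)),
                      charge = ifelse(runif(no) < 0.2, NA_integer_,
                                      sample(1:5, no, replace = TRUE)),
                      intensity = 10^runif(no, 3, 7))
    got <- match_precursors(obs, cand, match_config(ppm_tol = 10))
    want <- oracle_match(obs, cand, ppm_tol = 10)
    expect_equal(nrow(got), nrow(want))
    got_keys <- sort(paste(got$scan, got$species_id))
    want_keys <- sort(paste(obs$scan[want[, 1]], cand$species_id[want[, 2]]))
    expect_identical(got_keys, want_keys)
  }
})

test_that("the match set is monotone in tolerance", {
  set.seed(506)
  cand <- data.frame(species_id = paste0("c", 1:50),
                     charge = sample(1:5, 50, replace = TRUE),
                     mz = runif(50, 400, 1600))
  obs <- data.frame(scan = 1:50, mz = cand$mz * (1 + rnorm(50, 0, 5e-6)),
                    charge = cand$charge, intensity = 1e6)
  tight <- match_precursors(obs, cand, match_config(ppm_tol = 2))
  wide <- match_precursors(obs, cand, match_config(ppm_tol = 10))
  expect_true(all(paste(tight$scan, tight$species_id) %in%
                    paste(wide$scan, wide$species_id)))
})

test_that("fragment series are complete and bridge-containing ions carry the partner", {
  sp <- pair_sp()
  fr <- generate_fragments(sp, 1L)
  for (cid in c("A", "B")) {
    sub <- fr[fr$chain == cid & fr$loss == "", ]
    expect_setequal(unique(sub$index[sub$series == "b"]), 1:18)
    expect_setequal(unique(sub$index[sub$series == "y"]), 1:18)
  }
  # chain A is the canonically first chain (V1 peptide, bridge Cys at 7):
  # b ions before the bridge are plain, from the bridge onward intact+variants
  subA <- fr[fr$chain == "A" & fr$series == "b" & fr$loss == "", ]
  bridge_pos <- 7
  expect_true(all(subA$variant[subA$index < bridge_pos] == "plain"))
  expect_setequal(unique(subA$variant[subA$index >= bridge_pos]),
                  c("intact", "thiol", "persulfide", "dha"))
  # y1 of a chain ending in K: K + water + proton
  yk <- fr[fr$chain == "B" & fr$series == "y" & fr$index == 1 &
             fr$variant == "plain" & fr$loss == "" & fr$charge == 1, ]
  expect_equal(yk$mz, 147.1128, tolerance = 1e-4)
})

test_that("fragment pairs reconstruct the species mass exactly", {
  sp <- pair_sp()
  fr <- generate_fragments(sp, 1L)
  proton <- mass_constants()$proton
  for (cid in c("A", "B")) {
    n <- max(fr$index[fr$chain == cid]) + 1L
    for (i in c(2, 9, n - 2)) {
      bi <- fr[fr$chain == cid & fr$series == "b" & fr$index == i &
                 fr$variant %in% c("intact", "plain") & fr$loss == "", ]
      yn <- fr[fr$chain == cid & fr$series == "y" & fr$index == n - i &
                 fr$variant %in% c("intact", "plain") & fr$loss == "", ]
      # exactly one of b_i / y_{n-i} holds the bridge (intact); the sum of
      # their neutral masses is the whole species
      expect_equal(sum(bi$mz - proton, yn$mz - proton), sp$mass,
                   tolerance = 1e-9)
    }
  }
})

test_that("loop fragments inside the ring appear only bridge-opened", {
  sp <- loop_sp()   # Cys at relative positions 1 and 7
  fr <- generate_fragments(sp, 1L)
  inside_b <- fr[fr$series == "b" & fr$index %in% 1:6, ]
  expect_setequal(unique(inside_b$variant),
                  c("thiol", "persulfide", "dha"))
  # cleavages C-terminal to the ring keep it intact
  outside_b <- fr[fr$series == "b" & fr$index %in% 7:10, ]
  expect_true(all(outside_b$variant == "intact"))
  # y ions entirely after the ring are plain
  plain_y <- fr[fr$series == "y" & fr$index %in% 1:4, ]
  expect_true(all(plain_y$variant == "plain"))
})

test_that("plain fragment count per chain is length minus one", {
  # bridge on the last residue of one chain: b1..b4 of it are plain
  pb <- peptidoform("CSSSTK", "P2", 1,
                    mods = data.frame(position = 1, name = "ssbond_half"))
  pa <- peptidoform("GAVLC", "P1", 1,
                    mods = data.frame(position = 5, name = "ssbond_half"))
  sp <- disulfide_species(list(pa, pb), list(chain = c(1L, 2L), pos = c(5L, 1L)))
  fr <- generate_fragments(sp, 1L)
  cid <- if (sp$chains[[1]]$sequence == "GAVLC") "A" else "B"
  plain_b <- fr[fr$chain == cid & fr$series == "b" & fr$variant == "plain" &
                  fr$loss == "", ]
  expect_equal(nrow(plain_b), nchar("GAVLC") - 1)
})

test_that("annotation is greedy nearest-mass with documented tie-breaks", {
  sp <- pair_sp()
  fr <- generate_fragments(sp, 1L)
  # self-annotation of exact theoretical peaks: full coverage, 0 unassigned
  th <- fr[fr$loss == "" & fr$charge == 1, ]
  ann <- annotate_spectrum(data.frame(mz = th$mz, intensity = 1e4), fr)
  expect_equal(unname(ann$coverage), c(1, 1))
  expect_equal(ann$n_unassigned, 0)
  # a peak 0.7 Da from everything stays unassigned at 0.6 Da tolerance
  frag1 <- data.frame(chain = "A", series = "b", index = 2, loss = "",
                      variant = "plain", charge = 1, mz = 300.0,
                      label = "A:b2")
  ann2 <- annotate_spectrum(data.frame(mz = 300.7, intensity = 10), frag1)
  expect_equal(nrow(ann2$assignments), 0)
  expect_equal(ann2$n_unassigned, 1)
  # two fragments within tolerance: smaller |delta m| wins
  frag2 <- rbind(frag1,
                 data.frame(chain = "A", series = "b", index = 3, loss = "",
                            variant = "plain", charge = 1, mz = 300.4,
                            label = "A:b3"))
  ann3 <- annotate_spectrum(data.frame(mz = 300.3, intensity = 10), frag2)
  expect_equal(ann3$assignments$label, "A:b3")
  # exact distance tie: simpler variant (plain) beats neutral loss
  # binary-exact quarter offsets so the distances tie exactly
  frag3 <- data.frame(chain = "A", series = c("b", "y"), index = c(2, 5),
                      loss = c("", "-H2O"), variant = "plain", charge = 1,
                      mz = c(300.25, 300.75), label = c("A:b2", "A:y5*"))
  ann4 <- annotate_spectrum(data.frame(mz = 300.5, intensity = 10), frag3)
  expect_equal(ann4$assignments$label, "A:b2")
  # fragment match set is monotone in the Da tolerance
  peaks <- data.frame(mz = th$mz + 0.3, intensity = 10)
  wide <- annotate_spectrum(peaks, fr, match_config(frag_tol = 0.6))
  tight <- annotate_spectrum(peaks, fr, match_config(frag_tol = 0.1))
  expect_gte(nrow(wide$assignments), nrow(tight$assignments))
})
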