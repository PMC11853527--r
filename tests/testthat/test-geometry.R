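test_that("superposition is exact for identical and rigidly moved frames", {
  set.seed(11)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(P, P)$rmsd, 0, tolerance = 1e-10)
  R <- random_rotation()
  moved <- sweep(P %*% t(R), 2, c(3, -7, 12), `+`)
  expect_equal(superpose(moved, P)$rmsd, 0, tolerance = 1e-9)
  expect_error(superpose(P[1:2, ], P[1:2, ]), "at least 3")
  expect_error(superpose(P, P, sel_mobile = 1:4, sel_reference = 1:3), "1:1")
})

test_that("Kabsch RMSD matches the quaternion oracle on random pairs", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    P <- matrix(rnorm(3 * n, sd = 3), n, 3)
    Q <- matrix(rnorm(3 * n, sd = 3), n, 3)
    expect_equal(superpose(P, Q)$rmsd, horn_rmsd(P, Q), tolerance = 1e-6)
  }
})

test_that("RMSD series of a jittered ensemble matches the Gaussian expectation", {
  set.seed(13)
  n_atoms <- 400; nf <- 30; sigma <- 0.5
  base <- matrix(rnorm(3 * n_atoms, sd = 10), n_atoms, 3)
  coords <- array(NA_real_, c(n_atoms, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- base + matrix(rnorm(3 * n_atoms, 0, sigma), n_atoms, 3)
  }
  ens <- structure_ensemble(data.frame(resno = seq_len(n_atoms), resid = "ALA",
                                       elety = "CA"), coords)
  r <- rmsd_series(ens, base)
  # each frame deviates from the (noise-free) reference by ~ sigma*sqrt(3)
  expect_equal(mean(r), sigma * sqrt(3), tolerance = 0.1)

  rigid <- structure_ensemble(ens$atoms,
                              array(rep(base, 3), c(n_atoms, 3, 3)))
  expect_equal(rmsd_series(rigid, 1), rep(0, 3), tolerance = 1e-10)
  expect_length(rmsd_series(structure_ensemble(ens$atoms, base), 1), 1)
})

test_that("RMSF recovers closed-form fluctuation magnitudes", {
  set.seed(14)
  nf <- 500
  base <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 0, 0, 10, 10, 10, 0),
                 5, 3, byrow = TRUE)
  coords <- array(rep(base, nf), c(5, 3, nf))
  coords[5, , ] <- coords[5, , ] + matrix(rnorm(3 * nf, 0, 1), 3, nf)
  ens <- structure_ensemble(data.frame(resno = 1:5, resid = "ALA",
                                       elety = "CA"), coords)
  r <- rmsf(ens, fit_sel = 1:4)   # align on the rigid core
  # one isotropically jittered atom: RMSF ~ sqrt(3 sigma^2); anchors near 0
  expect_equal(r$rmsf[5], sqrt(3), tolerance = 0.1)
  expect_true(all(r$rmsf[1:4] < 0.2))

  two <- array(rep(base, 2), c(5, 3, 2))
  two[5, 3, ] <- c(-1, 1)   # symmetric displacement d = 2 about the mean
  ens2 <- structure_ensemble(ens$atoms, two)
  expect_equal(rmsf(ens2, fit_sel = 1:4)$rmsf[5], 1, tolerance = 1e-6)

  expect_error(rmsf(structure_ensemble(ens$atoms, base)), "2 frames")
})

test_that("salt-bridge occupancy follows the contact construction", {
  always <- pair_distance_ensemble(rep(3.5, 10))
  occ <- salt_bridge_occupancy(always)
  expect_equal(occ$occupancy, 1.0)
  expect_equal(occ$klass, "strong")

  alternating <- pair_distance_ensemble(rep(c(3.5, 8.0), 50))
  occ2 <- salt_bridge_occupancy(alternating)
  expect_equal(occ2$occupancy, 0.5)
  expect_equal(occ2$klass, "weak")

  never <- pair_distance_ensemble(rep(8.0, 10))
  occ3 <- salt_bridge_occupancy(never)
  expect_equal(occ3$occupancy, 0)
  expect_equal(occ3$klass, "none")
})

test_that("occupancy classification is monotone in the contact cutoff", {
  ens <- pair_distance_ensemble(seq(3, 8, length.out = 20))
  rank_of <- c(none = 0, weak = 1, strong = 2)
  occs <- vapply(c(3.5, 4.5, 6, 8.5),
                 function(d) salt_bridge_occupancy(ens, d_on = d)$occupancy,
                 numeric(1))
  expect_true(all(diff(occs) >= 0))
  ranks <- vapply(c(3.5, 4.5, 6, 8.5), function(d) {
    rank_of[[salt_bridge_occupancy(ens, d_on = d)$klass]]
  }, numeric(1))
  expect_true(all(diff(ranks) >= 0))
})

test_that("pairs with missing side-chain atoms are skipped with a warning", {
  ens <- pair_distance_ensemble(rep(3.5, 4))
  ens$atoms$elety[ens$atoms$elety %in% c("NE", "NH1", "NH2")] <- "CB"
  expect_warning(occ <- salt_bridge_occupancy(ens), "skipped")
  expect_equal(nrow(occ), 0)
})

test_that("the packaged salt-bridge fixture recomputes its printed sums", {
  path <- system.file("extdata", "salt_bridge_table_hv1.tsv", package = "hv1kit")
  tab <- parse_salt_bridge_table(path)
  expect_equal(nrow(tab$cells), 33)
  # recomputed sums equal the fixture's printed Sum row, column by column
  expect_identical(tab$sums$n_strong, tab$printed_sums$n_strong)
  expect_identical(tab$sums$n_weak, tab$printed_sums$n_weak)
  wt_d <- tab$sums[tab$sums$column == "WT.d", ]
  expect_equal(c(wt_d$n_strong, wt_d$n_weak), c(7, 5))
  g215e_a <- tab$sums[tab$sums$column == "G215E.a", ]
  expect_equal(c(g215e_a$n_strong, g215e_a$n_weak), c(12, 7))
})

test_that("salt-bridge tables round-trip through the glyph format bit-exactly", {
  path <- system.file("extdata", "salt_bridge_table_hv1.tsv", package = "hv1kit")
  tab <- parse_salt_bridge_table(path)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_salt_bridge_table(tab, tmp)
  reread <- parse_salt_bridge_table(tmp)
  expect_identical(reread$cells, tab$cells)
  expect_identical(reread$sums, tab$sums)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("pair\tWT.d\tWT.a", empty)
  etab <- parse_salt_bridge_table(empty)
  expect_equal(sum(etab$sums$n_strong), 0)
  expect_equal(sum(etab$sums$n_weak), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pair\tWT.d", "R1-D112\t?"), bad)
  expect_error(parse_salt_bridge_table(bad), "unknown cell glyph")
})

test_that("build_salt_bridge_table sums equal recounted cells", {
  occ_a <- salt_bridge_occupancy(pair_distance_ensemble(rep(3.5, 10)))
  occ_b <- salt_bridge_occupancy(pair_distance_ensemble(rep(c(3.5, 8), 5)))
  tab <- build_salt_bridge_table(list(toy.d = occ_a, toy.a = occ_b))
  expect_equal(tab$sums$n_strong, unname(colSums(tab$cells == "strong")))
  expect_equal(tab$sums$n_weak, unname(colSums(tab$cells == "weak")))
  expect_equal(tab$sums$n_strong, c(1, 0))
  expect_equal(tab$sums$n_weak, c(0, 1))
})

test_that("the gasket reference tracks translation and flags missing residues", {
  toy <- generate_toy_ensemble(n_frames = 2, jitter = 0, n_waters = 0, seed = 1)
  ref <- hg_reference(toy$deactivated)
  expect_equal(ref$z0, 0, tolerance = 1e-9)

  shifted <- toy$deactivated
  shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 3
  expect_equal(hg_reference(shifted)$z0, 3, tolerance = 1e-9)

  broken <- toy$deactivated
  keep <- broken$atoms$resno != 150
  broken <- structure_ensemble(broken$atoms[keep, ],
                               broken$coords[keep, , , drop = FALSE])
  expect_error(hg_reference(broken), "missing gasket")
})

test_that("axial shifts recover construction and are antisymmetric", {
  toy <- generate_toy_ensemble(n_frames = 4, displacement_z = 7,
                               jitter = 0.02, seed = 31)
  s_ca <- axial_shift(toy$deactivated, toy$activated, resno = 208)
  expect_equal(s_ca, 7, tolerance = 0.1)
  expect_equal(axial_shift(toy$activated, toy$deactivated, resno = 208),
               -s_ca, tolerance = 1e-9)
  expect_equal(axial_shift(toy$deactivated, toy$deactivated, resno = 208), 0,
               tolerance = 1e-9)
  # helix-range shift equals the brute-force per-residue mean
  helix <- axial_shift(toy$deactivated, toy$activated, resno = 198:220)
  brute <- mean(vapply(198:220, function(r) {
    axial_shift(toy$deactivated, toy$activated, resno = r)
  }, numeric(1)))
  expect_equal(helix, brute, tolerance = 1e-6)
  # side-chain tip marker moves with the helix
  s_tip <- axial_shift(toy$deactivated, toy$activated, resno = 208,
                       atom_mode = "sidechain_tip")
  expect_equal(s_tip, 7, tolerance = 0.1)
  expect_error(axial_shift(toy$deactivated, toy$activated, resno = 999),
               "absent")
})

test_that("water profiles recover constructed dewetted widths", {
  # water density ~2 molecules per 0.5 A slab, the scale at which the
  # one-molecule dewetting level is meaningful
  for (w in c(3.5, 4.5)) {
    toy <- generate_toy_ensemble(n_frames = 80, displacement_z = 0,
                                 n_waters = 160, dewetted_width = w,
                                 jitter = 0, seed = 41)
    prof <- water_axial_profile(toy$deactivated, radius = 8, bin_width = 0.5)
    dw <- dewetted_width(prof, level = 1.0)
    expect_lt(abs(dw$width - w), 0.25)
    expect_false(dw$flagged)
  }
  # dense waters, no exclusion: nothing dewetted
  toy0 <- generate_toy_ensemble(n_frames = 4, n_waters = 3000,
                                dewetted_width = 0, jitter = 0, seed = 42)
  prof0 <- water_axial_profile(toy0$deactivated, radius = 8, bin_width = 0.5)
  expect_equal(dewetted_width(prof0, level = 1.0)$width, 0)
  # no waters at all: full-range dewetting, flagged
  dry <- generate_toy_ensemble(n_frames = 2, n_waters = 0, seed = 43)
  expect_warning(prof_dry <- water_axial_profile(dry$deactivated), "no water")
  expect_true(dewetted_width(prof_dry)$flagged)
})

test_that("ensembles round-trip through multi-model PDB", {
  toy <- generate_toy_ensemble(n_frames = 3, n_waters = 20, jitter = 0.05,
                               seed = 51)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(toy$deactivated, tmp)
  back <- read_ensemble_pdb(tmp)
  expect_equal(n_frames(back), 3)
  expect_equal(back$atoms$resno, toy$deactivated$atoms$resno)
  # PDB coordinates carry 3 decimals
  expect_equal(back$coords, toy$deactivated$coords, tolerance = 1e-3)
})
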