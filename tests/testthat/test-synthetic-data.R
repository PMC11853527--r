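test_that("steady-state current at V_half is the Boltzmann midpoint", {
  p <- channel_params(noise_sd = 0, g_leak = 0.1, delay = 0)
  pr <- voltage_protocol(steps = data.frame(V = 21, dur = 60),
                         pH_o = 6.5, pH_i = 6.5)
  fam <- simulate_family(p, pr)
  tr <- trace_segment(fam$traces[[1]], "step")
  I_end <- tail(tr$I, 1)
  expect_equal(I_end, (0.1 + 32 / 2) * (21 - 0), tolerance = 1e-3)
})

test_that("a one-unit pH gradient displaces the g-V curve by the shift slope", {
  p <- channel_params(noise_sd = 0)
  mk <- function(pH_o) {
    pr <- voltage_protocol(V_hold = -100,
                           steps = data.frame(V = seq(-60, 60, 10), dur = 10),
                           V_repol = -100, pH_o = pH_o, pH_i = 6.5,
                           sample_rate = 500)
    fam <- simulate_family(p, pr)
    act <- suppressWarnings(activation_taus(fam))
    gv <- suppressWarnings(build_gv(act, nernst_potential(pH_o, 6.5)))
    fit_boltzmann(gv)$V_half
  }
  v0 <- mk(6.5)
  v1 <- mk(7.5)
  expect_equal(v1 - v0, p$pH_shift_slope, tolerance = 0.02)
})

test_that("a null channel produces identically zero current", {
  p <- channel_params(g_max = 0, g_leak = 0, noise_sd = 0)
  fam <- simulate_family(p, voltage_protocol())
  for (tr in fam$traces) expect_true(all(tr$I == 0))
})

test_that("simulations are bit-identical under a fixed seed", {
  p <- channel_params(noise_sd = 1, seed = 42L)
  pr <- voltage_protocol(steps = data.frame(V = c(20, 40), dur = 1))
  f1 <- simulate_family(p, pr)
  f2 <- simulate_family(p, pr)
  expect_identical(f1$traces[[1]]$I, f2$traces[[1]]$I)
  expect_identical(f1$traces[[2]]$I, f2$traces[[2]]$I)
  f3 <- simulate_family(channel_params(noise_sd = 1, seed = 43L), pr)
  expect_false(identical(f1$traces[[1]]$I, f3$traces[[1]]$I))
})

test_that("simulator g-V round-trips through the Boltzmann fitter", {
  # noiseless invariant: fitted V_half and k match the generator within 0.1%
  fit <- fit_wt0$boltzmann
  k_gen <- thermal_voltage() / noiseless_params$q_total
  expect_equal(fit$V_half, 21, tolerance = 1e-3)
  expect_equal(fit$k, k_gen, tolerance = 1e-3)
  expect_equal(fit$g_max, 32, tolerance = 1e-3)
})

test_that("open-channel zero-current voltage matches the Nernst potential", {
  # pin the channel open everywhere so I-V crosses zero at E_H
  p <- channel_params(V_half_ref = -250, noise_sd = 0, delay = 0)
  pr <- voltage_protocol(V_hold = -70,
                         steps = data.frame(V = seq(-70, -45, 5), dur = 2),
                         V_repol = -70, pH_o = 7.5, pH_i = 6.5)
  fam <- simulate_family(p, pr)
  iv <- t(vapply(fam$traces, function(tr) {
    seg <- trace_segment(tr, "step")
    c(V = tr$V_test, I = tail(seg$I, 1))
  }, numeric(2)))
  v0 <- vrev_zero_current(iv[, "V"], iv[, "I"])
  expect_equal(v0, nernst_potential(7.5, 6.5), tolerance = 0.1)
})

test_that("tail fast and slow amplitude fractions sum to one", {
  p <- channel_params(noise_sd = 0, tail_fast_fraction = 0.4,
                      tail_fast_ratio = 0.1)
  pr <- voltage_protocol(steps = data.frame(V = 80, dur = 6),
                         V_repol = -60, tail_duration = 10,
                         sample_rate = 5000)
  fam <- simulate_family(p, pr)
  seg <- trace_segment(fam$traces[[1]], "tail")
  f <- fit_exponential(seg, direction = "decaying", n_components = 2)
  expect_equal(f$n_components, 2L)
  A_tot <- f$A + f$second_component[["A2"]]
  expect_equal(f$A / A_tot, 0.4, tolerance = 0.02)
  expect_equal(f$second_component[["A2"]] / A_tot, 0.6, tolerance = 0.02)
})

test_that("leak experiment holding current follows the Ohmic leak formula", {
  p <- channel_params(g_leak = 0.05, noise_sd = 0, seed = 7L)
  pr <- voltage_protocol(V_hold = -40, steps = data.frame(V = 20, dur = 1),
                         interpulse_interval = 30, pH_o = 6.5, pH_i = 6.5,
                         sample_rate = 200)
  rec <- simulate_leak_experiment(p, pr, data.frame(time = 45, new_pH_o = 5.5),
                                  total_duration = 90)
  i_before <- mean(rec$I[rec$t > 38 & rec$t < 44])
  i_after <- mean(rec$I[rec$t > 46 & rec$t < 52])
  # E_H steps 0 -> +58.3 mV, so I_hold shifts by g_leak * (0 - 58.3) (inward)
  expect_equal(i_after - i_before,
               0.05 * (0 - nernst_potential(5.5, 6.5)), tolerance = 0.02)
  expect_lt(i_after - i_before, 0)
})

test_that("leak-free and same-pH exchanges leave the holding current unchanged", {
  pr <- voltage_protocol(V_hold = -40, steps = data.frame(V = 20, dur = 1),
                         sample_rate = 200)
  rec0 <- simulate_leak_experiment(channel_params(g_leak = 0, noise_sd = 0),
                                   pr, data.frame(time = 45, new_pH_o = 5.5),
                                   total_duration = 90)
  i_b <- mean(rec0$I[rec0$t > 38 & rec0$t < 44])
  i_a <- mean(rec0$I[rec0$t > 46 & rec0$t < 52])
  # residual gate relaxation after test pulses stays well below 0.01 pA
  expect_lt(abs(i_a - i_b), 0.01)

  rec_same <- simulate_leak_experiment(channel_params(g_leak = 0.05, noise_sd = 0),
                                       pr, data.frame(time = 45, new_pH_o = 6.5),
                                       total_duration = 90)
  i_b <- mean(rec_same$I[rec_same$t > 38 & rec_same$t < 44])
  i_a <- mean(rec_same$I[rec_same$t > 46 & rec_same$t < 52])
  expect_lt(abs(i_a - i_b), 0.01)
})

test_that("overlapping exchange times are rejected", {
  p <- channel_params()
  pr <- voltage_protocol(steps = data.frame(V = 20, dur = 1))
  expect_error(simulate_leak_experiment(p, pr,
                                        data.frame(time = c(40, 40),
                                                   new_pH_o = c(5.5, 7.5))),
               "strictly increasing")
})

test_that("mutation tables respect hotspot bounds, classes and the seed", {
  tab <- generate_mutation_table(length = 273, n_background = 0,
                                 hotspots = data.frame(center = 200,
                                                       halfwidth = 10,
                                                       n_mut = 50),
                                 seed = 3L)
  expect_equal(nrow(tab), 50)
  expect_true(all(tab$position >= 190 & tab$position <= 210))

  tab_mis <- generate_mutation_table(length = 100, n_background = 40,
                                     class_probs = c(1, 0, 0), seed = 3L)
  expect_true(all(classify_mutation(tab_mis$ref_aa, tab_mis$alt_aa) == "missense"))

  expect_identical(generate_mutation_table(100, 30, seed = 11L),
                   generate_mutation_table(100, 30, seed = 11L))
})

test_that("toy ensembles encode the constructed S4 displacement and dewetting", {
  toy <- generate_toy_ensemble(n_frames = 5, displacement_z = 7,
                               dewetted_width = 4.5, jitter = 0.02, seed = 2L)
  shift <- axial_shift(toy$deactivated, toy$activated, resno = 208)
  expect_equal(shift, 7, tolerance = 0.1)

  rigid <- generate_toy_ensemble(n_frames = 3, displacement_z = 0,
                                 jitter = 0, n_waters = 0, seed = 5L)
  expect_identical(rigid$deactivated$coords, rigid$activated$coords)
  expect_equal(rmsd_series(rigid$deactivated, 1), rep(0, 3), tolerance = 1e-12)
})
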