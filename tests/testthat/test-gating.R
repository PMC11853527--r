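test_that("the g-V curve reproduces the generator's steady-state conductance", {
  act <- suppressWarnings(activation_taus(activation_family0))
  gv <- suppressWarnings(build_gv(act, V_rev = 0))
  k_gen <- thermal_voltage() / 6.2
  g_true <- 32 / (1 + exp((21 - gv$V) / k_gen))
  expect_equal(gv$g, g_true, tolerance = 0.005)
})

test_that("build_gv input handling", {
  fits <- data.frame(V = c(-20, 0, 20), I_ss = c(0, 0, 0))
  gv <- build_gv(fits, V_rev = -60)
  expect_equal(gv$g, c(0, 0, 0))
  expect_equal(nrow(gv), 3)
  expect_error(build_gv(fits[1:2, ], V_rev = -60), "at least 3")
  expect_warning(build_gv(data.frame(V = c(-60.5, 0, 20, 40),
                                     I_ss = c(0, 1, 2, 3)), V_rev = -60),
                 "within 1 mV")
})

test_that("fit_boltzmann recovers noiseless parameters and is scale invariant", {
  V <- seq(-30, 70, 5)
  g <- 10 / (1 + exp((21 - V) / 8))
  fit <- fit_boltzmann(data.frame(V = V, g = g))
  expect_equal(fit$V_half, 21, tolerance = 1e-3)
  expect_equal(fit$k, 8, tolerance = 1e-3)
  expect_equal(predict(fit, 21), fit$g_max / 2, tolerance = 1e-6)

  fit_scaled <- fit_boltzmann(data.frame(V = V, g = 137 * g))
  expect_equal(fit_scaled$V_half, fit$V_half, tolerance = 1e-6)
  expect_equal(fit_scaled$k, fit$k, tolerance = 1e-6)
  expect_equal(fit_scaled$g_max, 137 * fit$g_max, tolerance = 1e-6)
})

test_that("a truncated shallow curve is flagged wide-confidence", {
  V <- seq(30, 80, 10)               # sampled only above the inflection
  g <- 10 / (1 + exp((10 - V) / 25))
  expect_warning(fit <- fit_boltzmann(data.frame(V = V, g = g)),
                 "caution")
  expect_true(fit$wide_confidence)
})

test_that("limiting slope converts an e-fold/25.33 mV curve to one charge", {
  V <- seq(-60, -20, 5)
  gv <- data.frame(V = V, g = exp(V / thermal_voltage(294)))
  res <- limiting_slope_charge(gv, T_K = 294, window = range(V))
  expect_equal(res$e0, 1.0, tolerance = 1e-9)
})

test_that("limiting slope recovers the generating charge at low Po", {
  fam <- simulate_family(noiseless_params, low_po_protocol())
  act <- suppressWarnings(activation_taus(fam))
  gv <- suppressWarnings(build_gv(act, V_rev = nernst_potential(7.5, 6.5)))
  res <- limiting_slope_charge(gv)        # lowest-decade default
  expect_equal(res$e0, 6.2, tolerance = 0.1 / 6.2)
  expect_identical(res$method, "lowest-decade")
})

test_that("a midpoint window halves the apparent charge", {
  p <- channel_params(noise_sd = 0)
  pr <- voltage_protocol(V_hold = -80,
                         steps = data.frame(V = seq(-24, -14, 2), dur = 10),
                         V_repol = -80, pH_o = 7.5, pH_i = 6.5,
                         sample_rate = 200)
  act <- suppressWarnings(activation_taus(simulate_family(p, pr)))
  gv <- suppressWarnings(build_gv(act, V_rev = nernst_potential(7.5, 6.5)))
  res <- limiting_slope_charge(gv, window = c(-24, -14))
  # analytic d ln Po/dV at the midpoint is q/2: low-Po windows are required
  expect_equal(res$e0, 6.2 / 2, tolerance = 0.02)
})

test_that("the limiting-slope estimate rises monotonically toward q as the window moves negative", {
  k_gen <- thermal_voltage() / 6.2
  V <- seq(-80, 0, 2)
  gv <- data.frame(V = V, g = 32 / (1 + exp((-19 - V) / k_gen)))
  centers <- c(-30, -45, -60, -70)
  e0s <- vapply(centers, function(cc) {
    limiting_slope_charge(gv, window = c(cc - 5, cc + 5))$e0
  }, numeric(1))
  expect_true(all(diff(e0s) > 0))
  expect_equal(e0s[length(e0s)], 6.2, tolerance = 0.01)
})

test_that("threshold detection finds the first resolvable tail", {
  vt <- detect_vthres(activation_family0, noise_sd = 0.5, k_sd = 3)
  # most negative V whose instantaneous tail exceeds 1.5 pA
  k_gen <- thermal_voltage() / 6.2
  po <- function(V) 1 / (1 + exp((21 - V) / k_gen))
  amp <- abs(32 * po(seq(0, 100, 10)) * -40)
  expected <- seq(0, 100, 10)[which(amp > 1.5)[1]]
  expect_equal(vt$V_thres, expected)

  expect_error(detect_vthres(simulate_family(channel_params(g_max = 0, noise_sd = 0),
                                             activation_protocol),
                             noise_sd = 0.5),
               "no activation detected")
})

test_that("threshold detection is monotone in the criterion multiple", {
  v3 <- detect_vthres(activation_family0, noise_sd = 0.5, k_sd = 3)$V_thres
  v30 <- detect_vthres(activation_family0, noise_sd = 0.5, k_sd = 30)$V_thres
  expect_gte(v30, v3)
  expect_warning(v0 <- detect_vthres(activation_family0, noise_sd = 0.5, k_sd = 0),
                 "degenerate")
  expect_lte(v0$V_thres, v3)
})
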