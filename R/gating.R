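#' Build a conductance-voltage relation from activation fits
#'
#' Converts per-voltage extrapolated steady-state currents into chord
#' conductances, \eqn{g_H = I_{ss}/(V - V_{rev})}. Points within 1 mV of the
#' reversal potential are dropped with a warning (the division is unstable),
#' and a non-monotone curve is flagged with a warning only.
#'
#' @param fits data frame from [activation_taus()] (columns `V`, `I_ss`).
#' @param V_rev reversal potential used for the driving force (mV).
#' @param pH_o,pH_i,T_K recording conditions stored with the curve.
#' @return An object of class `"gv_curve"`: data frame columns `V`, `g`
#'   (nS), `I_ss`, `V_rev_used`, plus condition attributes.
#' @export
build_gv <- function(fits, V_rev, pH_o = NA, pH_i = NA,
                     T_K = hv1_default_temperature()) {
  stopifnot(is.data.frame(fits), all(c("V", "I_ss") %in% names(fits)))
  if (nrow(fits) < 3) stop("need at least 3 voltages to build a g-V curve")
  near <- abs(fits$V - V_rev) < 1
  if (any(near)) {
    warning("dropped ", sum(near), " point(s) within 1 mV of V_rev")
    fits <- fits[!near, , drop = FALSE]
  }
  g <- conductance(fits$I_ss, fits$V, V_rev)
  out <- data.frame(V = fits$V, g = g, I_ss = fits$I_ss, V_rev_used = V_rev)
  out <- out[order(out$V), , drop = FALSE]
  rownames(out) <- NULL
  if (any(diff(out$g) < -1e-9 * max(abs(out$g)))) {
    warning("g-V curve is not monotone non-decreasing")
  }
  structure(out, class = c("gv_curve", "data.frame"),
            pH_o = pH_o, pH_i = pH_i, T_K = T_K)
}

#' Fit a Boltzmann function to a g-V curve
#'
#' Nonlinear least squares fit of
#' \deqn{g_H(V) = g_{max}\left[1 + e^{(V_{1/2} - V)/k}\right]^{-1}}
#' on the unnormalized conductances, with `g_max` free. At `V = V_half` the
#' fitted conductance equals `g_max / 2`. Curves sampled on only one side of
#' the inflection are fitted but flagged `wide_confidence` (the parameters
#' are then poorly constrained, as seen for channel variants with shallow
#' voltage dependence).
#'
#' @param gv a `"gv_curve"` (or data frame with columns `V`, `g`).
#' @return An object of class `"boltzmann_fit"` with `V_half` (mV), `k`
#'   (mV), `g_max` (nS), `rss`, `wide_confidence`, and the data.
#' @export
fit_boltzmann <- function(gv) {
  stopifnot(all(c("V", "g") %in% names(gv)))
  d <- data.frame(V = gv$V, g = gv$g)
  if (nrow(d) < 4) warning("fewer than 4 points; Boltzmann fit poorly constrained")
  g_max0 <- max(d$g)
  if (g_max0 <= 0) stop("all conductances are non-positive; nothing to fit")
  ## inflection guess from the half-maximum crossing
  Vh0 <- stats::approx(d$g, d$V, xout = g_max0 / 2, ties = "ordered")$y
  if (!is.finite(Vh0)) Vh0 <- stats::median(d$V)
  k0 <- max(diff(range(d$V)) / 8, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ gmax / (1 + exp((Vh - V) / k)), data = d,
                      start = list(gmax = g_max0 * 1.05, Vh = Vh0, k = k0),
                      lower = c(0, -Inf, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Boltzmann fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  wide <- cf[["Vh"]] <= min(d$V) || cf[["Vh"]] >= max(d$V)
  if (wide) warning("V_half outside the sampled range; treat parameters with caution")
  structure(list(V_half = unname(cf[["Vh"]]), k = unname(cf[["k"]]),
                 g_max = unname(cf[["gmax"]]),
                 rss = sum(stats::residuals(fit)^2),
                 wide_confidence = wide, data = d),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V_half = %.2f mV, k = %.2f mV, g_max = %.3g nS%s\n",
              x$V_half, x$k, x$g_max,
              if (x$wide_confidence) "  [wide confidence]" else ""))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(V_half = object$V_half, k = object$k, g_max = object$g_max)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  V <- if (is.null(newdata)) object$data$V else
    if (is.list(newdata)) newdata$V else newdata
  object$g_max / (1 + exp((object$V_half - V) / object$k))
}

#' Gating charge by the limiting-slope method
#'
#' At low open probability, the logarithmic voltage sensitivity of the
#' conductance approaches the total gating charge:
#' \deqn{e_0 = \frac{RT}{F}\, \frac{d \ln g}{dV}\Big|_{P_o \to 0}.}
#' The slope is obtained by linear regression of ln(g) against V over a
#' low-conductance window: by default the most negative contiguous decade of
#' positive conductance (points with `g` within a factor 10 of the smallest
#' positive value); an explicit `(V_lo, V_hi)` window may be supplied
#' instead, for example for protocols sampled in 2 mV steps near threshold.
#' Boltzmann slope factors are deliberately not converted to gating charge
#' here: near the midpoint the apparent charge is roughly half the true
#' total (see the window-placement example in the package tests), which is
#' why the limiting-slope window must sit at low open probability.
#'
#' @param gv a `"gv_curve"` (or data frame with `V`, `g`).
#' @param T_K temperature (K).
#' @param window optional explicit `c(V_lo, V_hi)` (mV).
#' @return An object of class `"gating_charge"` with `e0` (elementary
#'   charges), `V_window`, `slope` (1/mV), `r2`, `n_points`, `method`.
#' @export
limiting_slope_charge <- function(gv, T_K = hv1_default_temperature(),
                                  window = NULL) {
  stopifnot(all(c("V", "g") %in% names(gv)))
  d <- data.frame(V = gv$V, g = gv$g)
  d <- d[is.finite(d$g) & d$g > 0, , drop = FALSE]
  if (nrow(d) == 0) stop("no positive conductances available")
  d <- d[order(d$V), , drop = FALSE]
  if (is.null(window)) {
    g_min <- min(d$g)
    in_decade <- d$g <= 10 * g_min
    ## most negative contiguous run
    r <- rle(in_decade)
    stop_idx <- cumsum(r$lengths)
    first_true <- which(r$values)[1]
    idx <- seq(stop_idx[first_true] - r$lengths[first_true] + 1, stop_idx[first_true])
    sel <- d[idx, , drop = FALSE]
    method <- "lowest-decade"
  } else {
    sel <- d[d$V >= window[1] & d$V <= window[2], , drop = FALSE]
    method <- "explicit-window"
  }
  if (nrow(sel) < 3) stop("need at least 3 positive-g points in the limiting-slope window")
  fit <- stats::lm(log(sel$g) ~ sel$V)
  slope <- unname(stats::coef(fit)[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(sel$g) - mean(log(sel$g)))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  e0 <- slope * thermal_voltage(T_K)
  if (e0 <= 0) stop("non-positive limiting-slope charge; check the window")
  structure(list(e0 = e0, V_window = range(sel$V), slope = slope, r2 = r2,
                 n_points = nrow(sel), method = method, T_K = T_K),
            class = "gating_charge")
}

#' @export
print.gating_charge <- function(x, ...) {
  cat(sprintf("Limiting-slope gating charge: e0 = %.2f (window %g..%g mV, %d pts, r2 = %.4f, %s)\n",
              x$e0, x$V_window[1], x$V_window[2], x$n_points, x$r2, x$method))
  invisible(x)
}

#' Detect the activation threshold from tail currents
#'
#' The activation threshold is the most negative test voltage whose
#' instantaneous tail amplitude upon repolarization exceeds a noise
#' criterion of `k_sd` standard deviations. The instantaneous amplitude is
#' taken as the first tail samples' deviation from the late-tail baseline.
#'
#' @param family a `"trace_family"` whose traces carry tails at a fixed
#'   repolarization voltage.
#' @param noise_sd baseline current noise (pA).
#' @param k_sd criterion multiple (default 3; 0 degenerately reports the
#'   first trace, with a warning).
#' @param n_inst number of tail samples averaged for the instantaneous
#'   amplitude.
#' @return An object of class `"vthres_result"` with `V_thres` (mV),
#'   `criterion_pA`, and the per-voltage amplitude table.
#' @export
detect_vthres <- function(family, noise_sd, k_sd = 3, n_inst = 5) {
  stopifnot(inherits(family, "trace_family"), noise_sd >= 0)
  if (k_sd <= 0) warning("k_sd <= 0: degenerate criterion, first trace will qualify")
  amp <- vapply(family$traces, function(tr) {
    tail_seg <- trace_segment(tr, "tail")
    n <- length(tail_seg$I)
    inst <- mean(tail_seg$I[seq_len(min(n_inst, n))])
    base <- mean(utils::tail(tail_seg$I, max(3L, ceiling(n * 0.1))))
    inst - base
  }, numeric(1))
  V <- vapply(family$traces, function(tr) tr$V_test, numeric(1))
  ord <- order(V)
  V <- V[ord]; amp <- amp[ord]
  criterion <- k_sd * noise_sd
  hit <- abs(amp) > criterion
  if (!any(hit)) stop("no activation detected: no tail exceeds the criterion")
  structure(list(V_thres = V[which(hit)[1]], criterion_sd_multiple = k_sd,
                 criterion_pA = criterion,
                 amplitudes = data.frame(V = V, tail_amp = amp, exceeds = hit)),
            class = "vthres_result")
}

#' @export
print.vthres_result <- function(x, ...) {
  cat(sprintf("Activation threshold: V_thres = %g mV (criterion %.3g pA = %g SD)\n",
              x$V_thres, x$criterion_pA, x$criterion_sd_multiple))
  invisible(x)
}
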