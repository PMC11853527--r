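#' Fit the full gating characterization of a channel from a current family
#'
#' One-stop analysis of a voltage-clamp current family: per-voltage
#' activation and tail fits, the conductance-voltage relation, the Boltzmann
#' fit, the limiting-slope gating charge, the activation threshold, and the
#' conductance density. This is the model-object entry point of the package;
#' the individual stages ([activation_taus()], [build_gv()],
#' [fit_boltzmann()], [limiting_slope_charge()], [detect_vthres()]) remain
#' available for piecewise use.
#'
#' @param family a `"trace_family"` (see [simulate_family()] or
#'   [read_trace_family()]).
#' @param tails optional second `"trace_family"` recorded with a fixed
#'   activating prepulse and varying repolarization voltages; when given,
#'   the deactivation kinetics (and hence the tau-V relation used for
#'   U_tau,deact) come from it rather than from `family`'s own tails.
#' @param V_rev reversal potential (mV); defaults to the proton Nernst
#'   potential at the family's pH (a proton-selective channel).
#' @param noise_sd baseline current noise (pA) for threshold detection.
#' @param charge_window optional explicit limiting-slope window `c(lo, hi)`
#'   (mV).
#' @param k_sd tail-detection criterion multiple.
#' @param T_K temperature (K).
#' @return An object of class `"hv1_fit"` with components `activation`,
#'   `deactivation` (tau tables), `gv`, `boltzmann`, `charge`, `vthres`
#'   (or `NULL` when no tail exceeds the criterion), `g_density` (nS/pF),
#'   `V_rev`, and the recording conditions.
#' @examples
#' fam <- simulate_family(channel_params(noise_sd = 0),
#'                        voltage_protocol(steps = data.frame(V = seq(-10, 70, 10), dur = 8)))
#' fit <- fit_channel(fam, noise_sd = 0.5)
#' coef(fit)
#' @export
fit_channel <- function(family, tails = NULL, V_rev = NULL, noise_sd = 0.5,
                        charge_window = NULL, k_sd = 3,
                        T_K = hv1_default_temperature()) {
  stopifnot(inherits(family, "trace_family"))
  if (is.null(V_rev)) V_rev <- nernst_potential(family$pH_o, family$pH_i, T_K)
  act <- activation_taus(family)
  deact <- deactivation_taus(if (is.null(tails)) family else tails)
  gv <- build_gv(act, V_rev, pH_o = family$pH_o, pH_i = family$pH_i, T_K = T_K)
  bz <- fit_boltzmann(gv)
  charge <- tryCatch(limiting_slope_charge(gv, T_K = T_K, window = charge_window),
                     error = function(e) {
                       warning("limiting-slope charge unavailable: ",
                               conditionMessage(e))
                       NULL
                     })
  vth <- tryCatch(detect_vthres(family, noise_sd = noise_sd, k_sd = k_sd),
                  error = function(e) NULL)
  structure(list(activation = act, deactivation = deact, gv = gv,
                 boltzmann = bz, charge = charge, vthres = vth,
                 g_density = conductance_density(bz$g_max, family$C_m),
                 V_rev = V_rev, C_m = family$C_m,
                 pH_o = family$pH_o, pH_i = family$pH_i, T_K = T_K),
            class = "hv1_fit")
}

#' @export
print.hv1_fit <- function(x, ...) {
  cat("Proton-channel gating fit\n")
  cat(sprintf("  pH %g//%g, V_rev = %.1f mV, C_m = %g pF\n",
              x$pH_o, x$pH_i, x$V_rev, x$C_m))
  cat(sprintf("  g_max = %.3g nS (%.3g nS/pF), V_half = %.1f mV, k = %.2f mV\n",
              x$boltzmann$g_max, x$g_density, x$boltzmann$V_half, x$boltzmann$k))
  if (!is.null(x$charge)) {
    cat(sprintf("  limiting-slope e0 = %.2f (window %g..%g mV)\n",
                x$charge$e0, x$charge$V_window[1], x$charge$V_window[2]))
  }
  if (!is.null(x$vthres)) {
    cat(sprintf("  V_thres = %g mV\n", x$vthres$V_thres))
  }
  invisible(x)
}

#' @export
summary.hv1_fit <- function(object, ...) {
  U_act <- tryCatch(voltage_dependence(object$activation$V, object$activation$tau,
                                       V_range = c(0, 100)),
                    error = function(e) NULL)
  U_deact <- if (length(unique(object$deactivation$V)) >= 3) {
    tryCatch(voltage_dependence(object$deactivation$V, object$deactivation$tau,
                                V_range = c(-100, 20)),
             error = function(e) NULL)
  } else NULL
  out <- list(fit = object, U_act = U_act, U_deact = U_deact,
              theta = if (!is.null(U_act) && !is.null(U_deact))
                theta_ratio(U_deact$U_tau, U_act$U_tau) else NA_real_)
  class(out) <- "summary.hv1_fit"
  out
}

#' @export
print.summary.hv1_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$U_act)) cat(sprintf("  U_act = %.1f mV/e-fold\n", x$U_act$U_tau))
  if (!is.null(x$U_deact)) cat(sprintf("  U_deact = %.1f mV/e-fold\n", x$U_deact$U_tau))
  if (is.finite(x$theta)) cat(sprintf("  theta = %.2f\n", x$theta))
  invisible(x)
}

#' @export
coef.hv1_fit <- function(object, ...) {
  c(g_max = object$boltzmann$g_max,
    V_half = object$boltzmann$V_half,
    k = object$boltzmann$k,
    e0 = if (is.null(object$charge)) NA_real_ else object$charge$e0,
    V_thres = if (is.null(object$vthres)) NA_real_ else object$vthres$V_thres,
    g_density = object$g_density)
}

#' @export
predict.hv1_fit <- function(object, newdata = NULL, ...) {
  predict(object$boltzmann, newdata = newdata, ...)
}

#' @export
residuals.hv1_fit <- function(object, ...) {
  object$gv$g - predict(object$boltzmann, newdata = object$gv$V)
}

#' @export
plot.hv1_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$gv$V, x$gv$g, xlab = "V (mV)", ylab = "g_H (nS)",
       main = "Conductance-voltage", ...)
  Vg <- seq(min(x$gv$V), max(x$gv$V), length.out = 200)
  graphics::lines(Vg, predict(x$boltzmann, Vg))
  tau_all <- rbind(data.frame(V = x$activation$V, tau = x$activation$tau, kind = "act"),
                   data.frame(V = x$deactivation$V, tau = x$deactivation$tau, kind = "deact"))
  plot(tau_all$V, tau_all$tau, log = "y", xlab = "V (mV)", ylab = "tau (s)",
       pch = ifelse(tau_all$kind == "act", 16, 1), main = "Kinetics")
  invisible(x)
}
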