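#' Perturbation energy from a pair of gating time constants
#'
#' Expresses the effect of a mutation on a gating transition as a free-energy
#' change of the underlying kinetic barrier,
#' \deqn{\Delta\Delta G = -RT \ln(\tau_{WT}/\tau_{mut}),}
#' with R in kcal mol^-1 K^-1. A negative value means the mutant crosses the
#' barrier faster than wild type (the barrier is lowered); a positive value
#' means the transition is slowed.
#'
#' @param tau_wt,tau_mut time constants (s) for the reference and mutant
#'   channel at matched conditions (same open probability or driving force).
#' @param T_K absolute temperature (K).
#' @return Perturbation energy in kcal mol^-1.
#' @examples
#' perturbation_energy(2.0, 0.09)  # about -1.8 kcal/mol
#' @export
perturbation_energy <- function(tau_wt, tau_mut, T_K = hv1_default_temperature()) {
  if (any(tau_wt <= 0) || any(tau_mut <= 0)) stop("time constants must be positive")
  -.R_KCAL * T_K * log(tau_wt / tau_mut)
}

#' Voltage dependence of a gating time constant
#'
#' Fits ln(tau) against voltage by linear regression and reports the voltage
#' change producing an e-fold change in tau,
#' \eqn{U_\tau = |1/\mathrm{slope}|} in mV per e-fold. Time constants of
#' two-state gating follow \eqn{\tau(V) = \tau_0 e^{\mp V/U}}, which is linear
#' on semilog axes; regions that lose linearity (for example near the
#' reversal potential, where signal resolution degrades) are excluded by an
#' iterative r-squared screen that drops edge points until the fit is
#' acceptably linear.
#'
#' @param V voltages (mV).
#' @param tau time constants (s), same length as `V`.
#' @param V_range optional `c(lo, hi)` window of voltages used for the fit.
#'   Conventional windows are -100..+20 mV for deactivation and 0..+100 mV
#'   for activation.
#' @param r2_min minimum r-squared accepted before edge points are trimmed.
#' @param min_points minimum number of points retained by the screen.
#' @return A list of class `"hv1_utau"` with `U_tau` (mV per e-fold; `Inf`
#'   flags a voltage-independent tau), `slope` (1/mV, signed), `r2`,
#'   `n_used`, and `V_used`.
#' @export
voltage_dependence <- function(V, tau, V_range = NULL, r2_min = 0.98,
                               min_points = 3) {
  stopifnot(length(V) == length(tau))
  keep <- is.finite(V) & is.finite(tau) & tau > 0
  if (!is.null(V_range)) keep <- keep & V >= V_range[1] & V <= V_range[2]
  V <- V[keep]; tau <- tau[keep]
  if (length(V) < min_points) stop("need at least ", min_points, " tau-V points in range")
  ord <- order(V)
  V <- V[ord]; tau <- tau[ord]
  fit_once <- function(v, lt) {
    fit <- stats::lm(lt ~ v)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((lt - mean(lt))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    list(slope = unname(stats::coef(fit)[2]), r2 = r2)
  }
  lt <- log(tau)
  idx <- seq_along(V)
  f <- fit_once(V[idx], lt[idx])
  ## trim the edge point with the worse leverage on linearity until r2 passes
  while (f$r2 < r2_min && length(idx) > min_points) {
    drop_first <- fit_once(V[idx[-1]], lt[idx[-1]])
    drop_last <- fit_once(V[idx[-length(idx)]], lt[idx[-length(idx)]])
    if (drop_first$r2 >= drop_last$r2) {
      idx <- idx[-1]; f <- drop_first
    } else {
      idx <- idx[-length(idx)]; f <- drop_last
    }
  }
  slope <- f$slope
  U <- if (abs(slope) < .Machine$double.eps^0.5) Inf else abs(1 / slope)
  structure(list(U_tau = U, slope = slope, r2 = f$r2,
                 n_used = length(idx), V_used = V[idx],
                 voltage_independent = !is.finite(U)),
            class = "hv1_utau")
}

#' @export
print.hv1_utau <- function(x, ...) {
  if (x$voltage_independent) {
    cat("Voltage-independent time constant (slope ~ 0)\n")
  } else {
    cat(sprintf("U_tau = %.2f mV per e-fold (slope %+.4g /mV, r2 = %.4f, n = %d)\n",
                x$U_tau, x$slope, x$r2, x$n_used))
  }
  invisible(x)
}

#' Ratio of deactivation to activation voltage dependence
#'
#' \eqn{\theta = U_{\tau,deact} / U_{\tau,act}}. A value of 1 indicates
#' symmetric voltage dependence of opening and closing; theta > 1 flags a
#' closing transition that is less voltage dependent than opening.
#'
#' @param U_deact,U_act voltage dependences (mV per e-fold, > 0). `Inf`
#'   (voltage-independent sentinel) propagates as an `Inf`/`NaN` theta with a
#'   warning.
#' @return Dimensionless ratio.
#' @export
theta_ratio <- function(U_deact, U_act) {
  if (any(!is.finite(c(U_deact, U_act)))) {
    warning("voltage-independent sentinel in theta; result flagged")
  }
  if (any(c(U_deact, U_act) <= 0)) stop("U values must be positive")
  U_deact / U_act
}

#' Standardized kinetics comparison of two fitted channels
#'
#' Compares a mutant channel with a reference (wild-type) channel under the
#' standardization used for symmetric-pH recordings: activation time
#' constants are interpolated at each channel's own half-activation voltage
#' (equal open probability), deactivation time constants at -40 mV (equal
#' driving force), and perturbation energies and the theta ratio are derived
#' from those anchors.
#'
#' @param wt,mut objects of class `"hv1_fit"` (see [fit_channel()]) analysed
#'   at symmetric pH.
#' @param T_K temperature (K).
#' @param V_deact anchor voltage for deactivation (mV, default -40).
#' @return A list of class `"hv1_kinetics_summary"` with the per-channel
#'   anchored time constants, both perturbation energies (kcal/mol),
#'   `U_act`/`U_deact`/`theta` for the mutant, and the anchors used.
#' @export
standardized_summary <- function(wt, mut, T_K = hv1_default_temperature(),
                                 V_deact = -40) {
  stopifnot(inherits(wt, "hv1_fit"), inherits(mut, "hv1_fit"))
  tau_act_wt <- tau_at_voltage(wt$activation, wt$boltzmann$V_half)
  tau_act_mut <- tau_at_voltage(mut$activation, mut$boltzmann$V_half)
  tau_deact_wt <- tau_at_voltage(wt$deactivation, V_deact)
  tau_deact_mut <- tau_at_voltage(mut$deactivation, V_deact)
  U_act <- voltage_dependence(mut$activation$V, mut$activation$tau)
  U_deact <- voltage_dependence(mut$deactivation$V, mut$deactivation$tau)
  structure(list(
    tau_act_wt = tau_act_wt, tau_act_mut = tau_act_mut,
    tau_deact_wt = tau_deact_wt, tau_deact_mut = tau_deact_mut,
    ddG_act = perturbation_energy(tau_act_wt, tau_act_mut, T_K),
    ddG_deact = perturbation_energy(tau_deact_wt, tau_deact_mut, T_K),
    U_act = U_act$U_tau, U_deact = U_deact$U_tau,
    theta = theta_ratio(U_deact$U_tau, U_act$U_tau),
    V_half_wt = wt$boltzmann$V_half, V_half_mut = mut$boltzmann$V_half,
    V_deact = V_deact, T_K = T_K), class = "hv1_kinetics_summary")
}

#' @export
print.hv1_kinetics_summary <- function(x, ...) {
  cat("Standardized kinetics comparison (mutant vs reference)\n")
  cat(sprintf("  tau_act  at V_0.5 : %.3g s (ref %.3g s) -> ddG_act  = %+.2f kcal/mol\n",
              x$tau_act_mut, x$tau_act_wt, x$ddG_act))
  cat(sprintf("  tau_deact at %g mV: %.3g s (ref %.3g s) -> ddG_deact = %+.2f kcal/mol\n",
              x$V_deact, x$tau_deact_mut, x$tau_deact_wt, x$ddG_deact))
  cat(sprintf("  U_act = %.1f, U_deact = %.1f mV/e-fold, theta = %.2f\n",
              x$U_act, x$U_deact, x$theta))
  invisible(x)
}

#' Interpolate a time constant at a target voltage
#'
#' Log-linear interpolation of tau between the two voltages bracketing the
#' target (time constants of two-state gating are exponential in voltage, so
#' interpolation is performed on ln tau).
#'
#' @param tau_table data frame with columns `V` (mV) and `tau` (s).
#' @param V_target voltage (mV) at which to evaluate.
#' @return Interpolated tau (s).
#' @export
tau_at_voltage <- function(tau_table, V_target) {
  V <- tau_table$V; tau <- tau_table$tau
  keep <- is.finite(V) & is.finite(tau) & tau > 0
  V <- V[keep]; tau <- tau[keep]
  if (length(V) == 0) stop("no usable tau-V points")
  at <- abs(V - V_target) < 1e-9
  if (any(at)) return(exp(mean(log(tau[at]))))
  if (length(V) < 2) stop("need at least two tau-V points for interpolation")
  if (V_target < min(V) || V_target > max(V)) {
    stop(sprintf("V = %g mV outside the fitted tau-V range [%g, %g]",
                 V_target, min(V), max(V)))
  }
  exp(stats::approx(V, log(tau), xout = V_target, ties = list("ordered", mean))$y)
}
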