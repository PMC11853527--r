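#' Fit an exponential relaxation to a current segment
#'
#' Least-squares fit of a decaying-basis exponential
#' \deqn{I(t) = C + A\, e^{-(t - t_0)/\tau}}
#' (or the sum of two such terms) to a current segment. Rising relaxations
#' are represented by a negative amplitude, which keeps tau strictly
#' positive, and for rising fits the offset C is the extrapolated steady
#' state. Any initial delay in the activation rise is disregarded by starting
#' the fit window at the first sample where the current has crossed a
#' configurable fraction (default 10%) of its final excursion.
#'
#' Two-component fits report the fast component as (`A`, `tau`) and the slow
#' component as `second_component = c(A2, tau2)` with `tau2 > tau`. A
#' two-component fit is demoted to one component when it is degenerate:
#' `tau/tau2 > 0.8` or either amplitude below twice the residual noise SD.
#'
#' @param trace a `"current_trace"` (see [simulate_family()]), or a list with
#'   numeric fields `t` (s, strictly increasing) and `I` (pA).
#' @param window optional `c(t_start, t_end)` restricting the fit (s).
#' @param direction `"rising"` or `"decaying"`; controls delay trimming only
#'   (the fit itself decides amplitude signs).
#' @param n_components 1 or 2.
#' @param delay_frac fraction of the final excursion used to trim the
#'   activation delay (rising fits only).
#' @param noise_floor currents whose standard deviation falls below this
#'   value (pA) are treated as flat ("no kinetics resolvable").
#' @return An object of class `"exp_fit"`: `A` (pA), `tau` (s), `C` (pA),
#'   `fit_window`, `rss`, `n_components`, `second_component` (or `NULL`),
#'   `steady_state` (C), `noise_sd_est`.
#' @export
fit_exponential <- function(trace, window = NULL,
                            direction = c("rising", "decaying"),
                            n_components = 1, delay_frac = 0.1,
                            noise_floor = 1e-9) {
  direction <- match.arg(direction)
  stopifnot(n_components %in% c(1, 2))
  t <- trace$t; I <- trace$I
  stopifnot(length(t) == length(I), !is.unsorted(t, strictly = TRUE))
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; I <- I[keep]
  }
  if (length(t) < 10) stop("fit window must contain at least 10 samples")
  if (stats::sd(I) < noise_floor) stop("no kinetics resolvable: flat trace")

  ## trim the activation delay: start where the excursion first crosses
  ## delay_frac of its final value
  if (direction == "rising" && delay_frac > 0) {
    tail_n <- max(3L, ceiling(length(I) * 0.05))
    I_final <- mean(utils::tail(I, tail_n))
    excursion <- I_final - I[1]
    if (abs(excursion) > 0) {
      crossed <- which(abs(I - I[1]) >= delay_frac * abs(excursion))
      if (length(crossed) > 0 && crossed[1] > 1) {
        t <- t[crossed[1]:length(t)]
        I <- I[crossed[1]:length(I)]
      }
    }
    if (length(t) < 10) stop("fit window must contain at least 10 samples")
  }

  t0 <- t[1]
  ts <- t - t0
  dt <- min(diff(t))
  span <- max(ts)
  tau_lo <- 2 * dt
  tau_hi <- 10 * span

  ## starting values from log-linear regression of the detrended decay
  tail_n <- max(3L, ceiling(length(I) * 0.05))
  C0 <- mean(utils::tail(I, tail_n))
  resid0 <- I - C0
  A0 <- resid0[1]
  pos <- abs(resid0) > max(abs(A0), 1e-12) * 1e-3
  tau0 <- if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(abs(resid0[pos])) ~ ts[pos]))[2]
    if (is.finite(sl) && sl < 0) min(max(-1 / sl, tau_lo), tau_hi) else span / 3
  } else span / 3

  fit1 <- function() {
    d <- data.frame(ts = ts, I = I)
    ## multi-start over tau guards against the near-linear local minimum
    ## (tau at its upper bound) that shallow noisy relaxations can fall into
    starts <- unique(pmin(pmax(c(tau0, span / 20, span / 5, span), tau_lo), tau_hi))
    best <- NULL
    for (tg in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(I ~ C + A * exp(-ts / tau), data = d,
                          start = list(C = C0, A = A0, tau = tg),
                          lower = c(-Inf, -Inf, tau_lo),
                          upper = c(Inf, Inf, tau_hi),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        cf <- stats::coef(fit)
        best <- list(C = cf[["C"]], A = cf[["A"]], tau = cf[["tau"]],
                     rss = rss, noise = stats::sd(stats::residuals(fit)))
      }
    }
    if (is.null(best)) stop("single-exponential fit failed for every start")
    best
  }
  fit2 <- function() {
    d <- data.frame(ts = ts, I = I)
    fit <- minpack.lm::nlsLM(
      I ~ C + A1 * exp(-ts / tau1) + A2 * exp(-ts / tau2), data = d,
      start = list(C = C0, A1 = A0 * 0.5, tau1 = tau0 * 0.15,
                   A2 = A0 * 0.5, tau2 = tau0),
      lower = c(-Inf, -Inf, tau_lo, -Inf, tau_lo),
      upper = c(Inf, Inf, tau_hi, Inf, tau_hi),
      control = minpack.lm::nls.lm.control(maxiter = 400))
    cf <- stats::coef(fit)
    ## order fast first
    if (cf[["tau1"]] > cf[["tau2"]]) {
      cf[c("A1", "tau1", "A2", "tau2")] <- cf[c("A2", "tau2", "A1", "tau1")]
    }
    list(C = cf[["C"]], A1 = cf[["A1"]], tau1 = cf[["tau1"]],
         A2 = cf[["A2"]], tau2 = cf[["tau2"]],
         rss = sum(stats::residuals(fit)^2),
         noise = stats::sd(stats::residuals(fit)))
  }

  res <- tryCatch({
    if (n_components == 1) {
      f <- fit1()
      list(A = f$A, tau = f$tau, C = f$C, rss = f$rss, noise = f$noise,
           n_components = 1L, second = NULL)
    } else {
      f <- tryCatch(fit2(), error = function(e) NULL)
      degenerate <- is.null(f) ||
        f$tau1 / f$tau2 > 0.8 ||
        abs(f$A1) < 2 * f$noise || abs(f$A2) < 2 * f$noise
      if (degenerate) {
        f1 <- fit1()
        list(A = f1$A, tau = f1$tau, C = f1$C, rss = f1$rss, noise = f1$noise,
             n_components = 1L, second = NULL)
      } else {
        list(A = f$A1, tau = f$tau1, C = f$C, rss = f$rss, noise = f$noise,
             n_components = 2L, second = c(A2 = f$A2, tau2 = f$tau2))
      }
    }
  }, error = function(e) {
    stop("exponential fit did not converge: ", conditionMessage(e))
  })

  structure(list(A = unname(res$A), tau = unname(res$tau), C = unname(res$C),
                 fit_window = c(t0, max(t)), rss = res$rss,
                 n_components = res$n_components,
                 second_component = res$second,
                 steady_state = unname(res$C),
                 noise_sd_est = res$noise),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit (%d component%s): tau = %.4g s, A = %.4g pA, C = %.4g pA\n",
              x$n_components, if (x$n_components > 1) "s" else "", x$tau, x$A, x$C))
  if (!is.null(x$second_component)) {
    cat(sprintf("  slow component: tau2 = %.4g s, A2 = %.4g pA\n",
                x$second_component[["tau2"]], x$second_component[["A2"]]))
  }
  invisible(x)
}

#' Slow time constant of an exponential fit
#'
#' Returns `tau2` for two-component fits and `tau` otherwise.
#' @param fit an `"exp_fit"`.
#' @return Time constant (s).
#' @export
slow_tau <- function(fit) {
  if (!is.null(fit$second_component)) fit$second_component[["tau2"]] else fit$tau
}

#' Per-voltage activation fits for a current family
#'
#' Fits a single rising exponential to the depolarizing-step segment of each
#' trace, yielding the activation time constant and the extrapolated
#' steady-state current at every test voltage. Traces whose fit fails (flat,
#' unresolvable, or non-convergent) are skipped with a warning and listed in
#' the `skipped` attribute.
#'
#' @param family a `"trace_family"`.
#' @param ... passed to [fit_exponential()].
#' @return A data frame sorted by voltage with columns `V` (mV), `tau` (s),
#'   `I_ss` (extrapolated steady state, pA), `A`, `C`, `rss`; the fits
#'   themselves are in attribute `fits`, skip diagnostics in `skipped`.
#' @export
activation_taus <- function(family, ...) {
  stopifnot(inherits(family, "trace_family"))
  rows <- list(); fits <- list(); skipped <- character(0)
  for (tr in family$traces) {
    seg <- trace_segment(tr, "step")
    f <- tryCatch(fit_exponential(seg, direction = "rising", ...),
                  error = function(e) e)
    if (inherits(f, "error")) {
      skipped <- c(skipped, sprintf("%s: %s", tr$label, conditionMessage(f)))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(V = tr$V_test, tau = f$tau,
                                           I_ss = f$steady_state,
                                           A = f$A, C = f$C, rss = f$rss)
    fits[[length(fits) + 1]] <- f
  }
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped), " trace(s): ",
            paste(skipped, collapse = "; "))
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(V = numeric(0), tau = numeric(0), I_ss = numeric(0),
               A = numeric(0), C = numeric(0), rss = numeric(0))
  ord <- order(out$V)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ord]
  attr(out, "skipped") <- skipped
  out
}

#' Per-voltage deactivation (tail) fits for a current family
#'
#' Fits the tail segment of each trace. A two-component fit is attempted
#' first; when degenerate it falls back to a single component (see
#' [fit_exponential()]). Only the slow time constant is reported, following
#' standard practice for two-component proton-channel tails. Tails are
#' conventionally recorded between -100 and 0 mV; repolarization potentials
#' outside that range are accepted with a warning.
#'
#' @param family a `"trace_family"` whose traces carry tail segments.
#' @param ... passed to [fit_exponential()].
#' @return A data frame sorted by voltage with columns `V` (the
#'   repolarization voltage at which the tail decays -- the voltage the
#'   deactivation time constant belongs to), `V_prepulse` (the activating
#'   test voltage), `tau` (slow tail time constant, s), `n_components`,
#'   `rss`; attributes `fits` and `skipped` as for [activation_taus()].
#' @export
deactivation_taus <- function(family, ...) {
  stopifnot(inherits(family, "trace_family"))
  V_rep <- unique(vapply(family$traces, function(tr) tr$V_repol, numeric(1)))
  if (any(V_rep < -100 | V_rep > 0)) {
    warning("tail repolarization outside the conventional -100..0 mV range")
  }
  rows <- list(); fits <- list(); skipped <- character(0)
  for (tr in family$traces) {
    seg <- trace_segment(tr, "tail")
    f <- tryCatch(fit_exponential(seg, direction = "decaying", n_components = 2, ...),
                  error = function(e) e)
    if (inherits(f, "error")) {
      skipped <- c(skipped, sprintf("%s: %s", tr$label, conditionMessage(f)))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(V = tr$V_repol, V_prepulse = tr$V_test,
                                           tau = slow_tau(f),
                                           n_components = f$n_components,
                                           rss = f$rss)
    fits[[length(fits) + 1]] <- f
  }
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped), " tail(s): ",
            paste(skipped, collapse = "; "))
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(V = numeric(0), V_prepulse = numeric(0), tau = numeric(0),
               n_components = integer(0), rss = numeric(0))
  ord <- order(out$V)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ord]
  attr(out, "skipped") <- skipped
  out
}

#' Chord conductance from a steady-state current
#'
#' \eqn{g = I_{ss} / (V - V_{rev})}; with current in pA and voltage in mV the
#' result is in nS.
#'
#' @param I_ss extrapolated steady-state current (pA).
#' @param V test voltage (mV).
#' @param V_rev reversal potential (mV). `|V - V_rev|` must be at least 1 mV
#'   (the division is unstable closer to reversal).
#' @return Conductance (nS).
#' @export
conductance <- function(I_ss, V, V_rev) {
  if (any(abs(V - V_rev) < 1)) {
    stop("driving force below 1 mV: conductance undefined near reversal")
  }
  I_ss / (V - V_rev)
}

#' Conductance density
#'
#' Maximal conductance normalized by cell capacitance, `g_max / C_m` in
#' nS/pF, the size-independent expression level of the channel.
#'
#' @param g_max maximal conductance (nS).
#' @param C_m cell capacitance (pF, > 0).
#' @return Conductance density (nS/pF).
#' @export
conductance_density <- function(g_max, C_m) {
  if (any(C_m <= 0)) stop("cell capacitance must be positive")
  g_max / C_m
}
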