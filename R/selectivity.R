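#' Nernst equilibrium potential for protons
#'
#' Computes the proton Nernst potential \eqn{E_H} from the pH on either side
#' of the membrane. With the transmembrane pH gradient defined as
#' \eqn{\Delta pH = pH_o - pH_i},
#' \deqn{E_H = \frac{\ln 10 \, RT}{F} (pH_i - pH_o) = -\frac{\ln 10 \, RT}{F}\,\Delta pH.}
#' A one-unit outward gradient (pH_o one unit above pH_i) therefore gives
#' \eqn{E_H \approx -58.3} mV at 294 K.
#'
#' @param pH_o,pH_i external and internal pH (each in \[0, 14\]).
#' @param T_K absolute temperature in kelvin.
#' @return Equilibrium potential in mV.
#' @examples
#' nernst_potential(7.5, 6.5)   # about -58.3 mV
#' nernst_potential(5.5, 6.5)   # about +58.3 mV
#' @export
nernst_potential <- function(pH_o, pH_i, T_K = hv1_default_temperature()) {
  stopifnot(all(pH_o >= 0 & pH_o <= 14), all(pH_i >= 0 & pH_i <= 14))
  nernst_slope(T_K) * (pH_i - pH_o)
}

#' Reversal potential from the zero crossing of a steady-state I-V relation
#'
#' Linear interpolation of the zero-current crossing between the two points
#' that bracket it. Used when the channel activates negative to its reversal
#' potential, so the open-channel current itself changes sign within the
#' tested range.
#'
#' @param V test potentials (mV).
#' @param I steady-state currents (pA) at `V`.
#' @return Reversal potential (mV).
#' @seealso [vrev_tail()] for the tail-current method.
#' @export
vrev_zero_current <- function(V, I) {
  stopifnot(length(V) == length(I), length(V) >= 2)
  ord <- order(V)
  V <- V[ord]; I <- I[ord]
  s <- sign(I)
  cross <- which(s[-length(s)] * s[-1] <= 0 & (s[-length(s)] != 0 | s[-1] != 0))
  if (all(s >= 0) || all(s <= 0) || length(cross) == 0) {
    if (any(s == 0)) return(V[which(s == 0)[1]])
    stop("current does not change sign across the tested range; use the tail method")
  }
  i <- cross[1]
  if (I[i] == 0) return(V[i])
  V[i] + (0 - I[i]) * (V[i + 1] - V[i]) / (I[i + 1] - I[i])
}

#' Reversal potential from instantaneous tail-current amplitudes
#'
#' After a fixed activating prepulse, the instantaneous tail amplitude is
#' proportional to the driving force at the repolarization potential; its
#' zero crossing locates the reversal potential. Used when the activation
#' threshold is positive to the reversal potential.
#'
#' @param V repolarization potentials (mV).
#' @param amp instantaneous tail amplitudes (pA) at `V`.
#' @return Reversal potential (mV).
#' @export
vrev_tail <- function(V, amp) {
  if (length(V) < 2) stop("need at least two tail amplitudes to interpolate")
  vrev_zero_current(V, amp)
}

#' Bi-ionic GHK reversal potential for protons against TMA+
#'
#' Goldman-Hodgkin-Katz voltage for two permeant monovalent cations, protons
#' and tetramethylammonium, with TMA+ at the same concentration on both
#' sides:
#' \deqn{V_{rev} = \frac{RT}{F}\ln\frac{r [H]_o + c}{r [H]_i + c}}
#' where \eqn{r = P_H/P_{TMA}} and \eqn{c} is the TMA+ concentration.
#' As \eqn{r \to \infty} the voltage converges to the proton Nernst
#' potential.
#'
#' @param ratio permeability ratio P_H/P_TMA (> 0).
#' @param pH_o,pH_i external/internal pH.
#' @param c_TMA_mM TMA+ concentration (mM), same on both sides.
#' @param T_K temperature (K).
#' @return Reversal potential (mV).
#' @export
ghk_vrev <- function(ratio, pH_o, pH_i, c_TMA_mM = 100,
                     T_K = hv1_default_temperature()) {
  stopifnot(all(ratio > 0), c_TMA_mM >= 0)
  h_o <- 10^(-pH_o)
  h_i <- 10^(-pH_i)
  c <- c_TMA_mM / 1000
  thermal_voltage(T_K) * log((ratio * h_o + c) / (ratio * h_i + c))
}

#' Lower bound on the proton/TMA+ permeability ratio
#'
#' Given that the measured reversal potential deviates from the proton Nernst
#' potential by at most `epsilon` mV, finds the smallest permeability ratio
#' P_H/P_TMA consistent with that observation under the bi-ionic GHK model
#' ([ghk_vrev()]). Solved by bisection on log10(ratio); the GHK deviation
#' from E_H is strictly monotone in the ratio.
#'
#' @param epsilon maximum admissible |V_rev - E_H| (mV, > 0).
#' @param pH_o,pH_i external/internal pH.
#' @param c_TMA_mM TMA+ concentration (mM).
#' @param T_K temperature (K).
#' @param tol relative bisection tolerance on the ratio.
#' @return A list with elements `ratio` (the bound), `epsilon_mV`, and
#'   `informative` (FALSE when the bound falls below 1, i.e. `epsilon` is too
#'   generous to constrain selectivity).
#' @export
permeability_ratio_bound <- function(epsilon, pH_o = 7.5, pH_i = 6.5,
                                     c_TMA_mM = 100,
                                     T_K = hv1_default_temperature(),
                                     tol = 1e-10) {
  stopifnot(epsilon > 0)
  E_H <- nernst_potential(pH_o, pH_i, T_K)
  dev <- function(lr) abs(ghk_vrev(10^lr, pH_o, pH_i, c_TMA_mM, T_K) - E_H) - epsilon
  lo <- -6; hi <- 18
  if (dev(hi) > 0) stop("epsilon unattainably small for the bisection bracket")
  if (dev(lo) < 0) {
    ## even a vanishing proton preference satisfies the constraint
    return(list(ratio = 10^lo, epsilon_mV = epsilon, informative = FALSE))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (dev(mid) > 0) lo <- mid else hi <- mid
  }
  ratio <- 10^hi
  list(ratio = ratio, epsilon_mV = epsilon, informative = ratio >= 1)
}

#' Assess proton selectivity of a measured reversal potential
#'
#' Compares a measured reversal potential with the proton Nernst potential at
#' the experimental pH gradient and reports the deviation.
#'
#' @param V_rev_measured measured reversal potential (mV).
#' @param pH_o,pH_i external/internal pH.
#' @param T_K temperature (K).
#' @param method how V_rev was obtained ("zero-current" or "tail").
#' @return A list of class `"hv1_selectivity"` with `V_rev_measured`, `E_H`,
#'   `delta` (measured minus Nernst) and `method`.
#' @export
selectivity_assessment <- function(V_rev_measured, pH_o, pH_i,
                                   T_K = hv1_default_temperature(),
                                   method = c("zero-current", "tail")) {
  method <- match.arg(method)
  E_H <- nernst_potential(pH_o, pH_i, T_K)
  structure(list(V_rev_measured = V_rev_measured, E_H = E_H,
                 delta = V_rev_measured - E_H, method = method,
                 pH_o = pH_o, pH_i = pH_i, T_K = T_K),
            class = "hv1_selectivity")
}

#' @export
print.hv1_selectivity <- function(x, ...) {
  cat(sprintf("Selectivity (%s method): V_rev = %.2f mV, E_H = %.2f mV, delta = %+.2f mV\n",
              x$method, x$V_rev_measured, x$E_H, x$delta))
  invisible(x)
}
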