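#' Detect a closed-state proton leak from holding-current shifts
#'
#' During a leak experiment the external pH is exchanged while the channel is
#' held closed. A proton-selective leak conductance makes the holding current
#' follow the proton driving force \eqn{V_{hold} - E_H}: each exchange then
#' shifts \eqn{I_{hold}} by \eqn{g_{leak}(E_{H,before} - E_{H,after})}. For
#' each exchange the shift is measured as the difference of mean holding
#' current over quiet windows before and after the exchange, excluding test
#' pulses with a guard band. A leak is declared only when every exchange
#' produces a shift exceeding `k_sd` noise standard deviations with the
#' sign predicted by the change in driving force.
#'
#' @param recording a `"leak_recording"` from [simulate_leak_experiment()],
#'   or a list with fields `t`, `I`, `pH_o` (per sample), `pH_i`, `V_hold`,
#'   `pulse_windows` (data frame `start`/`end`), `exchanges` (data frame
#'   `time`/`new_pH_o`), `T_K`.
#' @param noise_sd baseline current noise (pA); defaults to the value stored
#'   in the recording.
#' @param k_sd criterion multiple (default 3).
#' @param window_s length of the averaging window on each side of an
#'   exchange (s); at least 5 s of clean baseline is required.
#' @param guard_s guard band excluded around each test pulse (s).
#' @return An object of class `"leak_assessment"`: per-exchange table
#'   (`time`, `dI_hold`, `predicted_sign`, `exceeds`, `sign_matches`) and
#'   `leak_detected`.
#' @export
detect_leak <- function(recording, noise_sd = recording$noise_sd, k_sd = 3,
                        window_s = 10, guard_s = 0.5) {
  stopifnot(nrow(recording$exchanges) >= 1, noise_sd >= 0)
  t <- recording$t; I <- recording$I
  ## mask samples inside (guarded) test pulses
  quiet <- rep(TRUE, length(t))
  pw <- recording$pulse_windows
  for (j in seq_len(nrow(pw))) {
    quiet[t >= pw$start[j] - guard_s & t <= pw$end[j] + guard_s] <- FALSE
  }
  E_H_of <- function(pH) nernst_potential(pH, recording$pH_i, recording$T_K)
  ex <- recording$exchanges
  pH_before <- c(recording$pH_o[1], ex$new_pH_o[-nrow(ex)])

  rows <- lapply(seq_len(nrow(ex)), function(j) {
    t_ex <- ex$time[j]
    before <- quiet & t >= t_ex - window_s & t < t_ex
    lim_after <- if (j < nrow(ex)) min(t_ex + window_s, ex$time[j + 1]) else t_ex + window_s
    after <- quiet & t > t_ex & t <= lim_after
    if (sum(before) == 0 || sum(after) == 0) {
      stop("no clean baseline window around exchange at t = ", t_ex, " s")
    }
    if (diff(range(t[before])) < 5) {
      stop("baseline before exchange at t = ", t_ex, " s is shorter than 5 s")
    }
    dI <- mean(I[after]) - mean(I[before])
    dDF <- (recording$V_hold - E_H_of(ex$new_pH_o[j])) -
           (recording$V_hold - E_H_of(pH_before[j]))
    data.frame(time = t_ex, pH_from = pH_before[j], pH_to = ex$new_pH_o[j],
               dI_hold = dI, predicted_sign = sign(dDF))
  })
  shifts <- do.call(rbind, rows)
  criterion <- k_sd * noise_sd
  shifts$exceeds <- abs(shifts$dI_hold) > criterion
  shifts$sign_matches <- sign(shifts$dI_hold) == shifts$predicted_sign &
    shifts$predicted_sign != 0
  structure(list(shifts = shifts,
                 leak_detected = all(shifts$exceeds & shifts$sign_matches),
                 criterion_sd_multiple = k_sd, criterion_pA = criterion),
            class = "leak_assessment")
}

#' @export
print.leak_assessment <- function(x, ...) {
  cat(sprintf("Closed-state leak assessment: leak %sdetected (criterion %.3g pA)\n",
              if (x$leak_detected) "" else "not ", x$criterion_pA))
  print(x$shifts, row.names = FALSE)
  invisible(x)
}
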