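#' Generative parameters for a two-state proton channel
#'
#' Bundles the parameters of the deterministic two-state gating model used by
#' [simulate_family()] and [simulate_leak_experiment()]. The steady-state
#' open probability is a single Boltzmann of total charge `q_total`,
#' \deqn{P_{o,\infty}(V) = \frac{1}{1 + e^{(V_{1/2} - V)/k}}, \quad
#'       k = \frac{RT}{q_{total} F},}
#' and the time constants are exponential in voltage,
#' \eqn{\tau_{act}(V) = \tau_{act,0} e^{-V/U_{act}}} and
#' \eqn{\tau_{deact}(V) = \tau_{deact,0} e^{+V/U_{deact}}}. The half-activation
#' voltage shifts along the voltage axis with the transmembrane pH gradient:
#' `V_half = V_half_ref + pH_shift_slope * (pH_o - pH_i)`, so the default
#' slope of -40 mV/unit moves gating negative when the outside is
#' alkalinized, as observed for proton channels.
#'
#' Defaults describe a wild-type-like hHV1 cell: 32 nS maximal conductance on
#' a 20 pF cell (1.6 nS/pF), 6.2 elementary charges, V_half +21 mV at
#' symmetric pH, activation time constant 2 s at 0 mV with a 40 mV/e-fold
#' voltage dependence, and a deactivation time constant of 0.6 s at -40 mV
#' (stored as its 0 mV anchor `tau_deact0 = 0.6 * exp(40/40)`).
#'
#' @param g_max maximal proton conductance (nS, >= 0).
#' @param q_total effective gating charge (elementary charges, > 0).
#' @param V_half_ref half-activation voltage at symmetric pH (mV).
#' @param pH_shift_slope g-V shift per unit of pH gradient (mV/unit).
#' @param tau_act0 activation time constant at 0 mV (s).
#' @param U_act_true e-fold voltage dependence of activation (mV).
#' @param tau_deact0 deactivation time constant at 0 mV (s).
#' @param U_deact_true e-fold voltage dependence of deactivation (mV).
#' @param delay activation delay (s) emulating the sigmoid onset of dimeric
#'   gating; the exponential rise starts after the delay.
#' @param tail_fast_fraction fraction of the tail amplitude decaying with the
#'   fast component (0-1; 0 gives single-exponential tails).
#' @param tail_fast_ratio ratio of fast to slow tail time constants (< 1).
#' @param g_leak closed-state proton-selective leak conductance (nS).
#' @param C_m cell capacitance (pF, > 0).
#' @param noise_sd additive white Gaussian current noise (pA).
#' @param T_K temperature (K).
#' @param seed RNG seed used by the simulators.
#' @return A list of class `"channel_params"`.
#' @export
channel_params <- function(g_max = 32, q_total = 6.2, V_half_ref = 21,
                           pH_shift_slope = -40,
                           tau_act0 = 2, U_act_true = 40,
                           tau_deact0 = 0.6 * exp(1), U_deact_true = 40,
                           delay = 0.05, tail_fast_fraction = 0.3,
                           tail_fast_ratio = 0.1,
                           g_leak = 0, C_m = 20, noise_sd = 0.5,
                           T_K = hv1_default_temperature(), seed = 1L) {
  stopifnot(g_max >= 0, q_total > 0,
            tail_fast_fraction >= 0, tail_fast_fraction <= 1,
            tail_fast_ratio > 0, tail_fast_ratio < 1,
            C_m > 0, noise_sd >= 0, delay >= 0,
            tau_act0 > 0, tau_deact0 > 0, U_act_true > 0, U_deact_true > 0)
  structure(as.list(environment()), class = "channel_params")
}

#' Voltage-step protocol description
#'
#' @param V_hold holding voltage (mV).
#' @param steps data frame (or list coercible to one) with columns `V`
#'   (test voltage, mV) and `dur` (step duration, s); one trace per row. An
#'   optional `V_repol` column sets a per-trace repolarization voltage (a
#'   fixed activating prepulse with varying repolarization is the standard
#'   protocol for deactivation kinetics).
#' @param V_repol repolarization voltage for the tails (mV), used when
#'   `steps` has no `V_repol` column.
#' @param tail_duration tail recording length (s).
#' @param interpulse_interval time at `V_hold` between pulses (s).
#' @param pH_o,pH_i external/internal pH.
#' @param sample_rate sampling rate (Hz).
#' @return A list of class `"voltage_protocol"`.
#' @export
voltage_protocol <- function(V_hold = -40,
                             steps = data.frame(V = seq(-20, 80, by = 10), dur = 3),
                             V_repol = -40, tail_duration = 2,
                             interpulse_interval = 30,
                             pH_o = 6.5, pH_i = 6.5, sample_rate = 1000) {
  steps <- as.data.frame(steps)
  stopifnot(nrow(steps) >= 1, all(c("V", "dur") %in% names(steps)),
            all(steps$dur > 0), tail_duration > 0, sample_rate > 0,
            interpulse_interval > 0)
  structure(list(V_hold = V_hold, steps = steps, V_repol = V_repol,
                 tail_duration = tail_duration,
                 interpulse_interval = interpulse_interval,
                 pH_o = pH_o, pH_i = pH_i, sample_rate = sample_rate),
            class = "voltage_protocol")
}

## Effective V_half at the protocol's pH gradient.
effective_vhalf <- function(params, pH_o, pH_i) {
  params$V_half_ref + params$pH_shift_slope * (pH_o - pH_i)
}

## Boltzmann steady-state open probability of the generator.
po_inf <- function(V, V_half, k) 1 / (1 + exp((V_half - V) / k))

## Voltage-dependent time constant toward the new steady state.
tau_of <- function(params, V, activating) {
  if (activating) params$tau_act0 * exp(-V / params$U_act_true)
  else params$tau_deact0 * exp(V / params$U_deact_true)
}

#' Simulate a whole-cell voltage-clamp current family
#'
#' Applies a family of depolarizing steps from `V_hold`, each followed by a
#' repolarizing tail, to the two-state channel described by `params`. During
#' a step the open probability relaxes exponentially (after the activation
#' delay) from its holding value toward the Boltzmann steady state; tails at
#' `V_repol` decay as the sum of a fast and a slow exponential split by
#' `tail_fast_fraction`, the slow component carrying the deactivation time
#' constant. The current is
#' \deqn{I(t) = [g_{leak} + g_{max} P_o(t)] (V - E_H) + \epsilon(t)}
#' with \eqn{E_H} the proton Nernst potential at the protocol's pH and
#' Gaussian noise \eqn{\epsilon}. Reproducible under the seed stored in
#' `params`.
#'
#' @param params a [channel_params()] object.
#' @param protocol a [voltage_protocol()] object. Step durations shorter than
#'   3 samples are rejected.
#' @return An object of class `"trace_family"`: a list with `traces` (one
#'   `"current_trace"` per step: fields `t`, `I`, `V_test`, `V_hold`,
#'   `V_repol`, `step_dur`, `tail_dur`, `pH_o`, `pH_i`, `C_m`, `label`) and
#'   protocol metadata. Times start at the step onset; samples with
#'   `t > step_dur` belong to the tail.
#' @export
simulate_family <- function(params, protocol) {
  stopifnot(inherits(params, "channel_params"), inherits(protocol, "voltage_protocol"))
  if (any(protocol$steps$dur < 3 / protocol$sample_rate)) {
    stop("step durations below 3 sample intervals are unresolvable")
  }
  set.seed(params$seed)
  dt <- 1 / protocol$sample_rate
  V_half <- effective_vhalf(params, protocol$pH_o, protocol$pH_i)
  k_gen <- thermal_voltage(params$T_K) / params$q_total
  E_H <- nernst_potential(protocol$pH_o, protocol$pH_i, params$T_K)
  Po_hold <- po_inf(protocol$V_hold, V_half, k_gen)

  traces <- lapply(seq_len(nrow(protocol$steps)), function(i) {
    V <- protocol$steps$V[i]
    dur <- protocol$steps$dur[i]
    V_repol <- if ("V_repol" %in% names(protocol$steps))
      protocol$steps$V_repol[i] else protocol$V_repol
    t_step <- seq(0, dur, by = dt)
    Po_ss <- po_inf(V, V_half, k_gen)
    activating <- Po_ss > Po_hold
    tau <- tau_of(params, V, activating)
    dly <- if (activating) params$delay else 0
    Po_step <- ifelse(t_step < dly, Po_hold,
                      Po_ss + (Po_hold - Po_ss) * exp(-(t_step - dly) / tau))
    I_step <- (params$g_leak + params$g_max * Po_step) * (V - E_H)

    t_tail <- seq(dt, protocol$tail_duration, by = dt)
    Po_end <- Po_step[length(Po_step)]
    Po_rep <- po_inf(V_repol, V_half, k_gen)
    tau_slow <- tau_of(params, V_repol, activating = FALSE)
    tau_fast <- params$tail_fast_ratio * tau_slow
    f <- params$tail_fast_fraction
    decay <- f * exp(-t_tail / tau_fast) + (1 - f) * exp(-t_tail / tau_slow)
    Po_tail <- Po_rep + (Po_end - Po_rep) * decay
    I_tail <- (params$g_leak + params$g_max * Po_tail) * (V_repol - E_H)

    t <- c(t_step, dur + t_tail)
    I <- c(I_step, I_tail)
    if (params$noise_sd > 0) I <- I + stats::rnorm(length(I), 0, params$noise_sd)
    structure(list(t = t, I = I, V_test = V, V_hold = protocol$V_hold,
                   V_repol = V_repol, step_dur = dur,
                   tail_dur = protocol$tail_duration,
                   pH_o = protocol$pH_o, pH_i = protocol$pH_i,
                   C_m = params$C_m,
                   label = sprintf("step_%+d_mV", round(V))),
              class = "current_trace")
  })
  structure(list(traces = traces, protocol = protocol,
                 pH_o = protocol$pH_o, pH_i = protocol$pH_i,
                 T_K = params$T_K, C_m = params$C_m),
            class = "trace_family")
}

#' @export
print.trace_family <- function(x, ...) {
  V <- vapply(x$traces, function(tr) tr$V_test, numeric(1))
  cat(sprintf("Voltage-clamp family: %d traces, V_test %g..%g mV, pH %g//%g\n",
              length(x$traces), min(V), max(V), x$pH_o, x$pH_i))
  invisible(x)
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Current trace %s: %d samples, V_test %g mV, pH %g//%g\n",
              x$label, length(x$t), x$V_test, x$pH_o, x$pH_i))
  invisible(x)
}

#' Extract the step or tail segment of a simulated trace
#'
#' @param trace a `"current_trace"` from [simulate_family()].
#' @param segment `"step"` or `"tail"`.
#' @return A `"current_trace"` restricted to the segment; tail times restart
#'   at zero at the moment of repolarization and `V_test` is replaced by the
#'   repolarization voltage for tail segments.
#' @export
trace_segment <- function(trace, segment = c("step", "tail")) {
  segment <- match.arg(segment)
  out <- trace
  if (segment == "step") {
    keep <- trace$t <= trace$step_dur
    out$t <- trace$t[keep]; out$I <- trace$I[keep]
  } else {
    keep <- trace$t > trace$step_dur
    out$t <- trace$t[keep] - trace$step_dur
    out$I <- trace$I[keep]
    out$V_test <- trace$V_repol
  }
  out
}

#' Simulate a closed-state leak experiment with bath pH exchanges
#'
#' Continuous recording at a holding voltage chosen below activation, with
#' periodic 1 s test pulses, while the external pH is exchanged at given
#' times. The holding current is carried by the closed-state leak
#' conductance, \eqn{I_{hold} = g_{leak} (V_{hold} - E_H)}, and steps to a
#' new level whenever an exchange moves the proton Nernst potential.
#'
#' @param params a [channel_params()] object.
#' @param protocol a [voltage_protocol()] object; `steps[1, ]` defines the
#'   test pulse (voltage and duration), `interpulse_interval` the pulse
#'   period, and `pH_o`/`pH_i` the starting condition.
#' @param exchanges data frame with columns `time` (s, >= 0, strictly
#'   increasing, no duplicates) and `new_pH_o`.
#' @param total_duration recording length (s).
#' @return An object of class `"leak_recording"`: `t`, `I`, `V` (applied
#'   voltage per sample), `pH_o` (per sample), `pulse_windows` (data frame
#'   `start`/`end`), `exchanges`, plus holding metadata.
#' @export
simulate_leak_experiment <- function(params, protocol, exchanges,
                                     total_duration = 90) {
  stopifnot(inherits(params, "channel_params"), inherits(protocol, "voltage_protocol"))
  exchanges <- as.data.frame(exchanges)
  stopifnot(all(c("time", "new_pH_o") %in% names(exchanges)),
            all(exchanges$time >= 0))
  if (anyDuplicated(exchanges$time) || is.unsorted(exchanges$time, strictly = TRUE)) {
    stop("exchange times must be strictly increasing and non-overlapping")
  }
  set.seed(params$seed)
  dt <- 1 / protocol$sample_rate
  t <- seq(0, total_duration, by = dt)
  n <- length(t)

  ## external pH as a step function of time
  pH_o <- rep(protocol$pH_o, n)
  for (j in seq_len(nrow(exchanges))) {
    pH_o[t >= exchanges$time[j]] <- exchanges$new_pH_o[j]
  }
  E_H <- nernst_potential(pH_o, protocol$pH_i, params$T_K)

  ## test pulses of steps[1, ] at the interpulse interval
  V <- rep(protocol$V_hold, n)
  pulse_dur <- protocol$steps$dur[1]
  pulse_V <- protocol$steps$V[1]
  starts <- seq(protocol$interpulse_interval, total_duration - pulse_dur,
                by = protocol$interpulse_interval)
  for (s in starts) V[t >= s & t < s + pulse_dur] <- pulse_V

  ## gate relaxation on the sample grid (exact per-sample exponential update)
  k_gen <- thermal_voltage(params$T_K) / params$q_total
  V_half <- effective_vhalf(params, pH_o, protocol$pH_i)
  Po_ss <- po_inf(V, V_half, k_gen)
  Po <- numeric(n)
  Po[1] <- Po_ss[1]
  for (i in 2:n) {
    activating <- Po_ss[i] > Po[i - 1]
    tau <- tau_of(params, V[i], activating)
    Po[i] <- Po_ss[i] + (Po[i - 1] - Po_ss[i]) * exp(-dt / tau)
  }
  I <- (params$g_leak + params$g_max * Po) * (V - E_H)
  if (params$noise_sd > 0) I <- I + stats::rnorm(n, 0, params$noise_sd)

  structure(list(t = t, I = I, V = V, pH_o = pH_o, pH_i = protocol$pH_i,
                 V_hold = protocol$V_hold,
                 pulse_windows = data.frame(start = starts, end = starts + pulse_dur),
                 exchanges = exchanges, T_K = params$T_K,
                 noise_sd = params$noise_sd),
            class = "leak_recording")
}

#' @export
print.leak_recording <- function(x, ...) {
  cat(sprintf("Leak recording: %.0f s at V_hold %g mV, %d pH exchange(s), %d test pulses\n",
              max(x$t), x$V_hold, nrow(x$exchanges), nrow(x$pulse_windows)))
  invisible(x)
}

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

#' Generate a synthetic somatic-mutation table
#'
#' Draws protein-level mutation records with a uniform positional background
#' plus optional hotspot-concentrated clusters, emulating a multi-database
#' somatic-mutation screen. Classes (missense/silent/stop) are drawn from
#' `class_probs`; each record carries a synthetic source database and tissue.
#'
#' @param length protein length in residues.
#' @param n_background number of background records (uniform positions).
#' @param hotspots data frame with columns `center`, `halfwidth`, `n_mut`;
#'   each hotspot contributes `n_mut` records with positions uniform in
#'   `center +/- halfwidth` (clipped to `[1, length]`).
#' @param class_probs probabilities for (missense, silent, stop); must sum
#'   to 1.
#' @param seed RNG seed.
#' @return A data frame with columns `position`, `ref_aa`, `alt_aa`
#'   (one-letter; `"="` silent, `"*"` stop), `source_db`, `tissue`,
#'   `sample_id`.
#' @export
generate_mutation_table <- function(length, n_background = 100,
                                    hotspots = NULL,
                                    class_probs = c(missense = 0.68,
                                                    silent = 0.26,
                                                    stop = 0.06),
                                    seed = 1L) {
  stopifnot(length >= 1, n_background >= 0,
            abs(sum(class_probs) - 1) < 1e-8, all(class_probs >= 0))
  set.seed(seed)
  pos <- if (n_background > 0) sample.int(length, n_background, replace = TRUE) else integer(0)
  if (!is.null(hotspots)) {
    hotspots <- as.data.frame(hotspots)
    for (j in seq_len(nrow(hotspots))) {
      lo <- max(1, hotspots$center[j] - hotspots$halfwidth[j])
      hi <- min(length, hotspots$center[j] + hotspots$halfwidth[j])
      pos <- c(pos, sample(lo:hi, hotspots$n_mut[j], replace = TRUE))
    }
  }
  n <- length(pos)
  if (n == 0) {
    return(data.frame(position = integer(0), ref_aa = character(0),
                      alt_aa = character(0), source_db = character(0),
                      tissue = character(0), sample_id = character(0)))
  }
  stopifnot(all(pos >= 1), all(pos <= length))
  cls <- sample(c("missense", "silent", "stop"), n, replace = TRUE,
                prob = class_probs)
  ref <- sample(.AA1, n, replace = TRUE)
  alt <- vapply(seq_len(n), function(i) {
    switch(cls[i],
           missense = sample(setdiff(.AA1, ref[i]), 1),
           silent = "=",
           stop = "*")
  }, character(1))
  data.frame(position = pos, ref_aa = ref, alt_aa = alt,
             source_db = sample(c("SYNTHDB-1", "SYNTHDB-2", "SYNTHDB-3"),
                                n, replace = TRUE),
             tissue = sample(c("skin", "lung", "endometrium", "intestine",
                               "liver", "blood"), n, replace = TRUE),
             sample_id = sprintf("S%05d", seq_len(n)))
}

#' Generate a paired toy structural ensemble (deactivated/activated)
#'
#' Builds a minimal geometric mimic of the channel for exercising the
#' structure-geometry operations: four gasket residues (V109, F150, V178,
#' V179; Calpha on a 5 A ring) define the hydrophobic-gasket plane at z = 0;
#' a straight "S4" helix (residues 198-220, 1.5 A rise per residue, with
#' full guanidinium marker atoms CZ/NE/NH1/NH2 on R205/R208/R211); optional
#' extra marker atoms; and water oxygens placed uniformly inside a cylinder
#' about the pore axis, excluding a dewetted slab of the requested width
#' around z = 0. The "activated" copy is identical except that all S4 atoms
#' are translated by `displacement_z` along z. Waters are re-drawn each frame
#' (fluid) but shared between the two copies, and the same per-frame Gaussian
#' jitter is applied to both, so with `displacement_z = 0` the two ensembles
#' are identical.
#'
#' @param n_frames number of frames (>= 1).
#' @param displacement_z S4 translation between the two ensembles (Angstrom).
#' @param n_waters water molecules per frame (0 disables water placement).
#' @param water_radius,water_zmax cylinder radius and half-height (Angstrom)
#'   for water placement.
#' @param dewetted_width width of the water-excluded slab about z = 0
#'   (Angstrom; 0 places waters everywhere).
#' @param jitter per-atom Gaussian coordinate jitter per frame (Angstrom).
#' @param extra_atoms optional data frame with columns `resno`, `resid`,
#'   `elety`, `x`, `y`, `z` appended to the protein topology (for example
#'   acidic partner atoms for salt-bridge toys).
#' @param seed RNG seed.
#' @return A list with elements `deactivated` and `activated`, each a
#'   `"structure_ensemble"` (see [structure_ensemble()]).
#' @export
generate_toy_ensemble <- function(n_frames = 10, displacement_z = 7,
                                  n_waters = 400, water_radius = 8,
                                  water_zmax = 20, dewetted_width = 4.5,
                                  jitter = 0.05, extra_atoms = NULL,
                                  seed = 1L) {
  stopifnot(n_frames >= 1, jitter >= 0, n_waters >= 0)
  set.seed(seed)

  gasket <- data.frame(
    resno = c(109, 150, 178, 179),
    resid = c("VAL", "PHE", "VAL", "VAL"),
    elety = "CA",
    x = 5 * cos(2 * pi * (0:3) / 4),
    y = 5 * sin(2 * pi * (0:3) / 4),
    z = 0)

  s4_res <- 198:220
  s4_names <- ifelse(s4_res %in% c(205, 208, 211), "ARG", "ALA")
  s4 <- data.frame(resno = s4_res, resid = s4_names, elety = "CA",
                   x = 8, y = 0, z = 1.5 * (s4_res - 209))
  arg_extra <- do.call(rbind, lapply(c(205, 208, 211), function(r) {
    zc <- 1.5 * (r - 209)
    data.frame(resno = r, resid = "ARG",
               elety = c("NE", "CZ", "NH1", "NH2"),
               x = 8 - c(1.5, 2.5, 3.2, 3.2),
               y = c(0, 0, 0.6, -0.6),
               z = zc + c(0.5, 1.0, 1.3, 1.3))
  }))
  atoms <- rbind(gasket, s4, arg_extra)
  if (!is.null(extra_atoms)) atoms <- rbind(atoms, as.data.frame(extra_atoms))
  n_prot <- nrow(atoms)

  wat <- if (n_waters > 0) {
    data.frame(resno = max(atoms$resno) + seq_len(n_waters),
               resid = "HOH", elety = "O", x = 0, y = 0, z = 0)
  } else NULL
  topo <- rbind(atoms, wat)
  n_atoms <- nrow(topo)

  xyz0 <- as.matrix(topo[, c("x", "y", "z")])
  coords_a <- array(NA_real_, c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    fr <- xyz0
    if (jitter > 0) {
      fr[seq_len(n_prot), ] <- fr[seq_len(n_prot), ] +
        matrix(stats::rnorm(3 * n_prot, 0, jitter), ncol = 3)
    }
    if (n_waters > 0) {
      ## uniform in the cylinder, rejecting the dewetted slab
      r <- water_radius * sqrt(stats::runif(n_waters))
      th <- stats::runif(n_waters, 0, 2 * pi)
      half <- dewetted_width / 2
      span <- water_zmax - half
      z <- stats::runif(n_waters, 0, 1)
      z <- ifelse(z < 0.5, -water_zmax + 2 * z * span, half + (2 * z - 1) * span)
      fr[n_prot + seq_len(n_waters), ] <- cbind(r * cos(th), r * sin(th), z)
    }
    coords_a[, , f] <- fr
  }
  coords_b <- coords_a
  s4_idx <- which(topo$resno %in% s4_res & topo$resid != "HOH")
  coords_b[s4_idx, 3, ] <- coords_b[s4_idx, 3, ] + displacement_z

  list(deactivated = structure_ensemble(topo[, c("resno", "resid", "elety")],
                                        coords_a, label = "deactivated"),
       activated = structure_ensemble(topo[, c("resno", "resid", "elety")],
                                      coords_b, label = "activated"))
}
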