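# Shared noiseless simulations reused across test files (built once per run).

noiseless_params <- hv1kit::channel_params(noise_sd = 0)

activation_protocol <- hv1kit::voltage_protocol(
  steps = data.frame(V = seq(0, 100, 10), dur = 8),
  tail_duration = 4)

tail_protocol <- hv1kit::voltage_protocol(
  steps = data.frame(V = 80, dur = 6, V_repol = seq(-100, -20, 20)),
  tail_duration = 8)

activation_family0 <- hv1kit::simulate_family(noiseless_params, activation_protocol)
tail_family0 <- hv1kit::simulate_family(noiseless_params, tail_protocol)

fit_wt0 <- suppressWarnings(
  hv1kit::fit_channel(activation_family0, tails = tail_family0, noise_sd = 0.5))

# Low-open-probability protocol for limiting-slope work (pH gradient moves
# the g-V foot away from the reversal potential).
low_po_protocol <- function(V_lo = -48, V_hi = -38, dur = 30, rate = 200) {
  hv1kit::voltage_protocol(
    V_hold = -80, steps = data.frame(V = seq(V_lo, V_hi, 2), dur = dur),
    V_repol = -80, pH_o = 7.5, pH_i = 6.5, sample_rate = rate)
}
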