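# Shared fixtures: reference parameter sets and small helpers.

# control / stimulated ALP parameters (degradation times 5.84 and 6.2 days)
ref_d0_control <- 1 / 5.84
ref_d0_stim <- 1 / 6.2

ref_params_control <- function(t0 = 7) {
  convert_params(
    pscd_params(d0 = ref_d0_control, N0 = 535 * t0^2, Phi0 = 0.8007, t0 = t0),
    "to_amplitude")
}

ref_params_stim <- function(t0 = 7) {
  convert_params(
    pscd_params(d0 = ref_d0_stim, N0 = 535 * t0^2, Phi0 = 0.84, t0 = t0),
    "to_amplitude")
}

# PSCD params matched to an arbitrary initial distribution at t0
params_from_initial <- function(init, d0, t0 = init$time) {
  m <- compute_moments(init)
  convert_params(
    pscd_params(d0 = d0, N0 = m[["N"]], Phi0 = m[["Phi"]], t0 = t0),
    "to_amplitude")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) <= tol),
              label = paste0("max rel err ",
                             signif(max(abs(actual / expected - 1)), 3),
                             " <= ", tol))
}
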