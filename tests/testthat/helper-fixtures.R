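# shared fixtures: default constants, WT-like truth, and an independent
# power-series oracle for the modified Bessel function I0

tc_default <- trap_constants()
wt_params <- motor_params(k0 = 147.0, delta = 1.04, kcat = 5, step_d = 4.3)

# I0(x) = sum_m (x/2)^(2m) / (m!)^2, summed to convergence
bessel_i0_series <- function(x) {
  vapply(x, function(xi) {
    term <- 1; total <- 1; m <- 0
    while (term > 1e-18 * total) {
      m <- m + 1
      term <- term * (xi / 2)^2 / m^2
      total <- total + term
    }
    total
  }, numeric(1))
}

make_events <- function(F, dF = 0, durations, displacement = 4.3,
                        id = "mol01") {
  n <- max(length(F), length(durations), length(displacement))
  data.frame(molecule_id = id,
             duration_s = rep_len(durations, n),
             mean_force_pN = rep_len(F, n),
             force_amp_pN = rep_len(dF, n),
             displacement_nm = rep_len(displacement, n),
             stringsAsFactors = FALSE)
}
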