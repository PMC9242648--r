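test_that("thinning sampler matches the exponential law at dF = 0", {
  tc <- tc_default
  p <- motor_params(147, 1.04)
  set.seed(101)
  d <- sample_event_duration(rep(2, 1e5), 0, 0, p, tc)
  k_emp <- 1 / mean(d)
  expect_equal(k_emp, detachment_rate(2, 0, p, tc), tolerance = 0.01)
})

test_that("thinning sampler reproduces the period-averaged Bessel rate", {
  # the module's central correctness check: dwell times drawn from the
  # time-varying hazard, with uniform binding phase, must average to the
  # closed-form Bessel-corrected rate
  tc <- tc_default
  p <- motor_params(147, 1.04)
  set.seed(202)
  d <- sample_event_duration(rep(2, 1e5), 2, runif(1e5, 0, 2 * pi), p, tc)
  expect_equal(1 / mean(d), detachment_rate(2, 2, p, tc), tolerance = 0.02)
})

test_that("thinning equivalence holds across a parameter grid within 3 MC SE", {
  tc <- tc_default
  n <- 4000
  set.seed(303)
  for (delta in c(0.5, 1.04)) {
    p <- motor_params(147, delta)
    for (F in c(-2, 0, 2)) for (dF in c(0, 1, 3)) {
      d <- sample_event_duration(rep(F, n), dF, runif(n, 0, 2 * pi), p, tc)
      k_true <- detachment_rate(F, dF, p, tc)
      k_emp <- 1 / mean(d)
      # SE of 1/mean for exponential-like data ~ k/sqrt(n)
      expect_lt(abs(k_emp - k_true), 3 * k_true / sqrt(n))
    }
  }
})

test_that("delta = 0 makes dwell times independent of load", {
  tc <- tc_default
  p <- motor_params(100, 0)
  set.seed(7)
  d1 <- sample_event_duration(rep(-4, 2e4), 3, runif(2e4, 0, 2 * pi), p, tc)
  d2 <- sample_event_duration(rep(4, 2e4), 0, runif(2e4, 0, 2 * pi), p, tc)
  expect_equal(mean(d1) / mean(d2), 1, tolerance = 0.05)
  expect_equal(1 / mean(d1), 100, tolerance = 0.03)
})

test_that("simulate_events is reproducible, censors, and carries the step", {
  cfg <- sim_config(wt_params, n_molecules = 3, events_per_molecule = 100,
                    seed = 11)
  ev1 <- simulate_events(cfg, tc_default)
  ev2 <- simulate_events(cfg, tc_default)
  expect_identical(ev1, ev2)
  expect_true(all(ev1$duration_s >= cfg$min_detectable_duration))
  expect_setequal(unique(ev1$molecule_id), c("mol01", "mol02", "mol03"))

  # censoring monotonicity: stricter detector never yields more events
  counts <- vapply(c(0, 0.005, 0.01, 0.02), function(tmin) {
    cfgt <- sim_config(wt_params, n_molecules = 3, events_per_molecule = 100,
                       min_detectable_duration = tmin, seed = 11)
    nrow(simulate_events(cfgt, tc_default))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("uncensored single-force events recover the naive MLE rate", {
  cfg <- sim_config(wt_params, n_molecules = 1, events_per_molecule = 5000,
                    force_range = c(1.5, 1.5), amp_range = c(0, 0),
                    min_detectable_duration = 0, seed = 5)
  ev <- simulate_events(cfg, tc_default)
  k_true <- detachment_rate(1.5, 0, wt_params, tc_default)
  est <- mle_bin_rate(ev$duration_s)
  expect_lt(abs(est["rate"] - k_true), 3 * est["se"])
})

test_that("event displacements average to the true step", {
  cfg <- sim_config(wt_params, n_molecules = 1, events_per_molecule = 1e4,
                    min_detectable_duration = 0, displacement_noise_sd = 1,
                    seed = 9)
  ev <- simulate_events(cfg, tc_default)
  expect_equal(mean(ev$displacement_nm), 4.3, tolerance = 0.05 / 4.3)
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(wt_params, n_molecules = 0), "counts")
  expect_error(sim_config(wt_params, min_detectable_duration = -1), "min_det")
  expect_error(sim_config(wt_params, force_range = c(5, -5)), "force_range")
  expect_error(sim_config(wt_params, amp_range = c(-1, 2)), "amp_range")
})

test_that("simulate_trace renders events at the right place and rejects overlap", {
  tc <- tc_default
  ev <- data.frame(start_time_s = 0.3, duration_s = 0.1, mean_force_pN = 2,
                   force_amp_pN = 2, displacement_nm = 10)
  tr <- simulate_trace(ev, tc, t_total = 1, noise_sd = 0, seed = 1)
  expect_s3_class(tr, "trap_trace")
  expect_true(all(diff(tr$time) > 0))
  inside <- tr$time >= 0.35 & tr$time < 0.39   # two whole periods inside
  outside <- tr$time < 0.25
  expect_equal(mean(tr$bead_A[inside]), 10, tolerance = 1e-6)
  expect_equal(mean(tr$bead_A[outside]), 0, tolerance = 1e-6)
  bad <- rbind(ev, data.frame(start_time_s = 0.35, duration_s = 0.1,
                              mean_force_pN = 0, force_amp_pN = 1,
                              displacement_nm = 0))
  expect_error(simulate_trace(bad, tc), "overlap")
})

test_that("ATPase plate generator is exact without noise and plants outliers", {
  plate <- simulate_atpase_plate(kcat = 5, Kapp = 20, noise_cv = 0, seed = 1)
  nz <- plate$actin_uM > 0
  expect_equal(plate$rate_per_s[nz],
               5 * plate$actin_uM[nz] / (20 + plate$actin_uM[nz]))
  expect_equal(unique(plate$rate_per_s[!nz]), 0.03)

  out <- simulate_atpase_plate(kcat = 5, Kapp = 20, noise_cv = 0.02,
                               n_outliers = 1, outlier_factor = 2.5, seed = 2)
  planted <- which(out$is_planted_outlier)
  trip <- out[out$actin_uM == out$actin_uM[planted], ]
  rej <- reject_triplicate_outliers(trip$rate_per_s)
  expect_true(rej$rejected[which(trip$is_planted_outlier)])
  expect_error(simulate_atpase_plate(-1, 20), "positive")
})

test_that("turnover generator carries its analytic truth", {
  tr <- simulate_turnover_trace(noise_sd = 0)
  truth <- attr(tr, "truth")
  expect_equal(truth$percent_slow, 57)
  expect_equal(min(tr$time_s), 10)  # dead time pre-added
  y0 <- 0.43 * exp(-0.03 * 10) + 0.57 * exp(-0.003 * 10) + 0.05
  expect_equal(tr$fluorescence[1], y0)
  expect_error(simulate_turnover_trace(rate_fast = 0.001, rate_slow = 0.01),
               "exceed")
})

test_that("gel generator is linear with optional saturation", {
  g <- simulate_gel_series(noise_cv = 0, seed = 1)
  hc <- g[g$chain == "HC", ]
  expect_equal(hc$density, 1000 * hc$load_pmol)
  gs <- simulate_gel_series(noise_cv = 0, saturate_top = TRUE,
                            sat_factor = 0.6, seed = 1)
  top <- gs$chain == "HC" & gs$load_pmol == 10
  expect_equal(gs$density[top], 6000)
})
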