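test_that("bin_events counts, prunes and averages per force bin", {
  ev <- make_events(F = c(-1.2, -0.8, 0.3), durations = 0.01)
  b3 <- bin_events(ev, bin_width = 1, min_bin_events = 3)
  expect_equal(nrow(b3), 0)
  b1 <- bin_events(ev, bin_width = 1, min_bin_events = 1)
  expect_equal(nrow(b1), 3)
  expect_equal(b1$n_events, c(1, 1, 1))
  expect_true(all(b1$f_lo < b1$f_hi))

  single <- bin_events(make_events(F = rep(2.2, 50), durations = 0.01),
                       bin_width = 1, min_bin_events = 5)
  expect_equal(nrow(single), 1)
  expect_equal(single$mean_force, 2.2)

  set.seed(1)
  evu <- make_events(F = runif(1e4, -5, 5), durations = 0.01)
  bu <- bin_events(evu, 1, 5)
  expected <- 1e4 / 10
  expect_true(all(abs(bu$n_events - expected) <
                    3 * sqrt(expected * (1 - 1 / 10))))
  empty <- data.frame(molecule_id = character(0), duration_s = numeric(0),
                      mean_force_pN = numeric(0), force_amp_pN = numeric(0),
                      displacement_nm = numeric(0))
  expect_error(bin_events(empty), "no events")
})

test_that("mle_bin_rate implements the truncated-exponential MLE", {
  est <- mle_bin_rate(c(0.01, 0.02, 0.03))
  expect_equal(unname(est["rate"]), 50)
  expect_equal(unname(est["se"]), 50 / sqrt(3), tolerance = 1e-12)
  expect_equal(unname(est["se"]), 28.87, tolerance = 1e-4)

  est_t <- mle_bin_rate(c(0.01, 0.02, 0.03), t_min = 0.005)
  expect_equal(unname(est_t["rate"]), 3 / 0.045)
  # cross-check against numerical maximization of the truncated likelihood
  nll <- function(k) -sum(log(k) - k * (c(0.01, 0.02, 0.03) - 0.005))
  k_num <- optimize(nll, c(1, 500))$minimum
  expect_equal(unname(est_t["rate"]), k_num, tolerance = 1e-4)

  expect_error(mle_bin_rate(c(0.004, 0.02), t_min = 0.005), "censoring")
  expect_error(mle_bin_rate(numeric(0)), "at least one")
})

test_that("truncated MLE is unbiased under heavy simulated censoring", {
  set.seed(77)
  d <- rexp(3e5, 100)
  d <- d[d > 0.002]
  est <- mle_bin_rate(d, t_min = 0.002)
  expect_equal(unname(est["rate"]), 100, tolerance = 0.01)
})

test_that("fit_force_dependence recovers noiseless truth to 4 significant digits", {
  tc <- tc_default
  Fs <- seq(-4, 4, by = 1)
  bins <- data.frame(mean_force = Fs, mean_amp = 2,
                     rate = detachment_rate(Fs, 2, wt_params, tc),
                     rate_se = 1)
  fit <- fit_force_dependence(bins, tc)
  expect_true(fit$converged)
  expect_equal(fit$k0, 147.0, tolerance = 1e-4)
  expect_equal(fit$delta, 1.04, tolerance = 1e-4)
})

test_that("a seeded 300-event molecule recovers truth within 2 SE", {
  cfg <- sim_config(wt_params, n_molecules = 1, events_per_molecule = 300,
                    force_range = c(-4, 4), amp_range = c(2, 2),
                    min_detectable_duration = 0, seed = 13)
  ev <- simulate_events(cfg, tc_default)
  fit <- fit_hfs(ev, tc_default)
  m <- fit$molecules
  expect_lt(abs(m$k0 - 147), 2 * m$k0_se)
  expect_lt(abs(m$delta - 1.04), 2 * m$delta_se)
})

test_that("flat force dependence yields delta near zero and the pooled rate", {
  p0 <- motor_params(100, 0, step_d = 4.3)
  cfg <- sim_config(p0, n_molecules = 1, events_per_molecule = 2000,
                    min_detectable_duration = 0, seed = 17)
  ev <- simulate_events(cfg, tc_default)
  bins <- bin_events(ev, 1, 5)
  rt <- t(vapply(bins$durations, mle_bin_rate, numeric(2), t_min = 0))
  bins$rate <- rt[, "rate"]; bins$rate_se <- rt[, "se"]
  fit <- fit_force_dependence(bins, tc_default)
  expect_lt(fit$delta - 2 * fit$se_delta, 0.02)  # CI reaches 0
  naive <- nrow(ev) / sum(ev$duration_s)
  expect_equal(fit$k0, naive, tolerance = 0.05)
})

test_that("binned and per-event MLE fits agree on large samples", {
  cfg <- sim_config(wt_params, n_molecules = 1, events_per_molecule = 1e4,
                    min_detectable_duration = 0, seed = 23)
  ev <- simulate_events(cfg, tc_default)
  fb <- fit_hfs(ev, tc_default, method = "binned")$molecules
  fm <- fit_hfs(ev, tc_default, method = "mle")$molecules
  expect_equal(fb$k0, fm$k0, tolerance = 0.05)
  expect_equal(fb$delta, fm$delta, tolerance = 0.10)
})

test_that("ignoring the dead time biases rates upward; honoring it does not", {
  # ~30% of events censored at the default 10 ms threshold for these rates
  p <- motor_params(60, 0.5, step_d = 4.3)
  cfg <- sim_config(p, n_molecules = 1, events_per_molecule = 2e4,
                    force_range = c(0, 3), amp_range = c(1, 3),
                    min_detectable_duration = 0.01, seed = 29)
  ev <- simulate_events(cfg, tc_default)
  expect_lt(nrow(ev), 2e4 * 0.85)
  f_ok <- fit_events_mle(ev, tc_default, t_min = 0.01)
  f_naive <- fit_events_mle(ev, tc_default, t_min = 0)
  expect_equal(f_ok$k0, 60, tolerance = 0.05)
  # surviving dwells are all >= the dead time, so the naive estimator sees
  # inflated durations: E[n / sum(t)] = 1/(t_min + 1/k) < k, a downward bias
  expect_lt(f_naive$k0, f_ok$k0)
})

test_that("estimate_step reports mean and SD and powers a group comparison", {
  ev <- make_events(F = 0, durations = 0.01,
                    displacement = rep(4.3, 10))
  expect_equal(unname(estimate_step(ev)), c(4.3, 0))
  expect_error(estimate_step(ev[1:3, ]), ">= 5")

  set.seed(41)
  big <- make_events(F = 0, durations = 0.01,
                     displacement = rnorm(1e4, 4.3, 1.4))
  expect_equal(unname(estimate_step(big)["step"]), 4.3, tolerance = 0.05 / 4.3)

  # molecule-level Welch comparison of a short-step mutant vs WT
  mol_means <- function(mu, seed) {
    set.seed(seed)
    vapply(1:20, function(i) mean(rnorm(100, mu, 1.4)), numeric(1))
  }
  tt <- welch_t_test(mol_means(2.5, 1), mol_means(4.3, 2))
  expect_lt(tt["p"], 0.01)
})

test_that("group summaries average molecules and Welch-test group contrasts", {
  mols <- data.frame(molecule_id = c("a", "b", "c"),
                     k0 = c(100, 120, 140), k0_se = 1,
                     delta = c(1, 1.1, 0.9), delta_se = 0.05,
                     step = c(4, 4.5, 4.2), step_sd = 1, n_events = 100)
  g <- summarize_group(mols, "demo")
  expect_equal(g$k0_mean, 120)
  expect_equal(g$k0_sem, sd(c(100, 120, 140)) / sqrt(3))
  expect_equal(g$k0_sem, 11.547, tolerance = 1e-4)
  expect_error(summarize_group(mols[1, , drop = FALSE]), ">= 2")

  # identical groups: no effect
  ga <- summarize_group(mols, "a"); gb <- summarize_group(mols, "b")
  cmp <- compare_groups(ga, gb)
  expect_equal(cmp$table["k0", "t"], 0)
  expect_equal(cmp$table["k0", "p"], 1)

  # groups drawn at the printed WT / fast-mutant separations are
  # overwhelmingly significant
  set.seed(55)
  wt_k0 <- rnorm(10, 147.0, 6.8 * sqrt(10))
  mut_k0 <- rnorm(12, 315.6, 14.0 * sqrt(12))
  expect_lt(welch_t_test(mut_k0, wt_k0)["p"], 1e-4)
})

test_that("percent_change matches the printed-legend convention", {
  expect_equal(unname(percent_change(315.6, 147.0)["percent"]), 114.69,
               tolerance = 1e-4)
  expect_equal(round(unname(percent_change(315.6, 147.0)["percent"])), 115)
  expect_equal(round(unname(percent_change(101.7, 147.0)["percent"])), -31)
  expect_equal(unname(percent_change(5, 5)["percent"]), 0)
  expect_error(percent_change(1, 0), "nonzero")
  pc <- percent_change(315.6, 147.0, 14.0, 6.8)
  expect_gt(pc["se"], 0)
})

test_that("parameter recovery is calibrated across seeded replicates", {
  # 20 replicates of a 10-molecule WT-like experiment: the replicate means
  # must track truth and 2-SEM intervals must cover it most of the time
  k0s <- deltas <- cov_k0 <- cov_delta <- numeric(20)
  for (r in 1:20) {
    cfg <- sim_config(wt_params, n_molecules = 10,
                      events_per_molecule = 150,
                      min_detectable_duration = 0, seed = 1000 + r)
    fit <- fit_hfs(simulate_events(cfg, tc_default), tc_default)
    g <- fit$group
    k0s[r] <- g$k0_mean; deltas[r] <- g$delta_mean
    cov_k0[r] <- abs(g$k0_mean - 147) < 2 * g$k0_sem
    cov_delta[r] <- abs(g$delta_mean - 1.04) < 2 * g$delta_sem
  }
  expect_equal(mean(k0s), 147, tolerance = 0.05)
  expect_equal(mean(deltas), 1.04, tolerance = 0.08)
  expect_gte(mean(cov_k0), 0.8)
  expect_gte(mean(cov_delta), 0.8)
})
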