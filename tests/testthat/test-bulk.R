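test_that("triplicate rejection follows the companion-wise >50% rule", {
  r1 <- reject_triplicate_outliers(c(10, 10.5, 30))
  expect_equal(r1$rejected, c(FALSE, FALSE, TRUE))
  expect_equal(r1$kept, c(10, 10.5))

  expect_false(any(reject_triplicate_outliers(c(10, 11, 12))$rejected))

  # the reference is each companion value, not the triplet mean:
  # 30 differs from 16 by 87.5% and from 10 by 200%, so it is rejected
  r3 <- reject_triplicate_outliers(c(10, 16, 30))
  expect_equal(r3$rejected, c(FALSE, FALSE, TRUE))

  # a wildly spread triplet still loses at most one value
  r4 <- reject_triplicate_outliers(c(1, 10, 100))
  expect_equal(sum(r4$rejected), 1)

  expect_warning(r5 <- reject_triplicate_outliers(c(1, 2)), "triplicate")
  expect_false(any(r5$rejected))
})

test_that("triplicate rejection is rare at realistic plate noise", {
  set.seed(61)
  n_rej <- 0; n_tot <- 0
  for (i in 1:50) {
    plate <- simulate_atpase_plate(5, 20, noise_cv = 0.05)
    fit <- fit_michaelis_menten(plate)
    n_rej <- n_rej + nrow(fit$rejected)
    n_tot <- n_tot + fit$n_points + nrow(fit$rejected)
  }
  expect_lt(n_rej / n_tot, 0.05)
})

test_that("Michaelis-Menten fitting recovers noiseless truth exactly", {
  plate <- simulate_atpase_plate(5, 20, noise_cv = 0)
  fit <- fit_michaelis_menten(plate)
  expect_equal(fit$kcat, 5, tolerance = 1e-6)
  expect_equal(fit$Kapp, 20, tolerance = 1e-6)
  expect_equal(fit$basal, 0.03)
  expect_false(fit$Kapp_extrapolated)
  # basal wells stay out of the hyperbolic fit
  expect_false(any(fit$data$actin_uM == 0))
  expect_error(fit_michaelis_menten(data.frame(actin_uM = c(0, 1, 2),
                                               rate_per_s = c(1, 2, 3))),
               "4 distinct")
})

test_that("Michaelis-Menten kcat is nearly unbiased over many noisy plates", {
  set.seed(71)
  kcats <- vapply(1:200, function(i) {
    fit_michaelis_menten(simulate_atpase_plate(5, 20, noise_cv = 0.05))$kcat
  }, numeric(1))
  expect_lt(abs(median(kcats) / 5 - 1), 0.01)
})

test_that("a Kapp beyond the tested range is flagged as extrapolated", {
  plate <- simulate_atpase_plate(5, 200, actin_uM = c(2.5, 5, 10, 20, 40),
                                 noise_cv = 0)
  expect_warning(fit <- fit_michaelis_menten(plate), "extrapolation")
  expect_true(fit$Kapp_extrapolated)
})

test_that("control normalization gives unit kcat and is idempotent", {
  plate <- simulate_atpase_plate(5, 20, noise_cv = 0)
  ctrl <- fit_michaelis_menten(plate)
  norm1 <- normalize_to_control(plate, ctrl)
  fit1 <- fit_michaelis_menten(norm1)
  expect_equal(fit1$kcat, 1, tolerance = 1e-6)
  norm2 <- normalize_to_control(norm1, fit1)
  expect_equal(norm2$rate_per_s, norm1$rate_per_s, tolerance = 1e-6)
})

test_that("ratio SE propagation matches the closed formula", {
  r <- propagate_ratio_se(3.0, 0.2, 5.0, 0.3)
  expect_equal(unname(r["ratio"]), 0.6)
  expect_equal(unname(r["se"]), 0.6 * sqrt((0.2 / 3)^2 + (0.3 / 5)^2))
  expect_equal(unname(r["se"]), 0.0538, tolerance = 1e-3)
  expect_equal(unname(propagate_ratio_se(4, 0, 8, 0)), c(0.5, 0))
  sym <- propagate_ratio_se(7, 0.2, 7, 0.2)
  expect_equal(unname(sym["ratio"]), 1)
  expect_equal(unname(sym["se"]), sqrt(2) * 0.2 / 7)
  expect_error(propagate_ratio_se(1, 0.1, -2, 0.1), "positive")

  av <- average_ratios(c(0.6, 0.8), c(0.05, 0.05))
  expect_equal(unname(av["mean"]), 0.7)
  expect_equal(unname(av["se"]), sqrt(2 * 0.05^2) / 2)
})

test_that("biexponential fit recovers a noiseless decay exactly", {
  tr <- simulate_turnover_trace(noise_sd = 0)
  fit <- fit_biexponential(tr)
  expect_false(fit$ambiguous)
  expect_equal(fit$amp_fast, 0.43, tolerance = 1e-4)
  expect_equal(fit$rate_fast, 0.03, tolerance = 1e-4)
  expect_equal(fit$amp_slow, 0.57, tolerance = 1e-4)
  expect_equal(fit$rate_slow, 0.003, tolerance = 1e-4)
  expect_equal(fit$plateau, 0.05, tolerance = 1e-4)
  expect_equal(fit$percent_slow, 57, tolerance = 1e-4)
  expect_equal(fit$percent_fast + fit$percent_slow, 100)
  # normalized curve: unit intercept at t = 0, zero plateau at late times
  expect_equal(predict(fit, data.frame(time_s = 0), normalized = TRUE), 1,
               tolerance = 1e-6)
  expect_equal(predict(fit, data.frame(time_s = 1e7), normalized = TRUE), 0,
               tolerance = 1e-6)
})

test_that("the slow-phase percentage is stable under realistic noise", {
  set.seed(81)
  ps <- vapply(1:100, function(i) {
    fit <- fit_biexponential(simulate_turnover_trace(noise_sd = 0.01))
    fit$percent_slow
  }, numeric(1))
  expect_lt(abs(mean(ps) - 57), 2)
})

test_that("single-exponential data are flagged ambiguous, not errors", {
  tr <- simulate_turnover_trace(amp_fast = 1, rate_fast = 0.01,
                                amp_slow = 1e-12, rate_slow = 0.001,
                                noise_sd = 0.002, seed = 13)
  fit <- fit_biexponential(tr)
  expect_true(fit$ambiguous)
  # poorly separated rates are ambiguous too
  tr2 <- simulate_turnover_trace(rate_fast = 0.005, rate_slow = 0.003,
                                 noise_sd = 0.002, seed = 14)
  expect_true(fit_biexponential(tr2)$ambiguous)
})

test_that("SRX differences reproduce the point-difference convention", {
  d1 <- srx_difference(c(56, 58), c(25, 27))
  expect_equal(unname(d1["difference"]), 31)
  d2 <- srx_difference(c(56, 58), c(15, 17))
  expect_equal(unname(d2["difference"]), 41)
  d3 <- srx_difference(c(67, 69), c(56, 58))
  expect_equal(unname(d3["difference"]), 11)
  same <- srx_difference(c(50, 60), c(50, 60))
  expect_equal(unname(same["difference"]), 0)
  expect_equal(unname(same["p"]), 1)
  expect_error(srx_difference(50, c(1, 2)), "replicates")
})

test_that("gel stoichiometry recovers slope ratios and prunes saturation", {
  g <- simulate_gel_series(noise_cv = 0, seed = 1)
  fit <- fit_gel_stoichiometry(g)
  expect_equal(unname(fit$ELC_HC["ratio"]), 0.19, tolerance = 1e-9)
  expect_equal(unname(fit$RLC_HC["ratio"]), 0.11, tolerance = 1e-9)

  gs <- simulate_gel_series(noise_cv = 0.01, saturate_top = TRUE,
                            sat_factor = 0.5, seed = 2)
  fits <- fit_gel_stoichiometry(gs)
  expect_lt(fits$chains$HC$n_points, 5)   # saturated top load pruned
  expect_false(10 %in% fits$chains$HC$loads)
  expect_equal(unname(fits$ELC_HC["ratio"]), 0.19, tolerance = 0.03)

  # common scaling leaves ratios invariant
  g2 <- g; g2$density <- g2$density * 3.7
  fit2 <- fit_gel_stoichiometry(g2)
  expect_equal(unname(fit2$ELC_HC["ratio"]), unname(fit$ELC_HC["ratio"]))
})

test_that("paired and Welch tests match textbook formulas and handle ties", {
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  got <- paired_t_test(x, y)
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(3))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 2)
  expect_equal(unname(got["t"]), t_oracle)
  expect_equal(unname(got["df"]), 2)
  expect_equal(unname(got["p"]), p_oracle)

  same <- paired_t_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(unname(same["t"]), 0)
  expect_equal(unname(same["p"]), 1)
  expect_equal(unname(welch_t_test(c(3, 3, 3), c(3, 3, 3))["p"]), 1)
  expect_error(paired_t_test(1:3, 1:4), "equal-length")
})
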