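#' Reject a gross outlier within a technical triplicate
#'
#' A measurement is rejected if it differs from BOTH of its two companions by
#' more than 50 percent of the companion's value (the companion, not the
#' triplet mean, is the reference). At most one value is rejected per
#' triplet; if several qualify (possible for wildly spread triplets), the one
#' farthest from the triplet median is dropped.
#'
#' @param triplet Numeric vector of 3 rates. Vectors of other lengths pass
#'   through unfiltered with a warning.
#' @return List with \code{kept} (values), \code{rejected} (logical flags per
#'   input position).
#' @examples
#' reject_triplicate_outliers(c(10, 10.5, 30))$rejected  # F F T
#' @export
reject_triplicate_outliers <- function(triplet) {
  if (length(triplet) != 3) {
    warning("not a triplicate (length ", length(triplet),
            "); passing through unfiltered")
    return(list(kept = triplet, rejected = rep(FALSE, length(triplet))))
  }
  qualifies <- vapply(1:3, function(i) {
    others <- triplet[-i]
    all(abs(triplet[i] - others) / others > 0.5)
  }, logical(1))
  rejected <- rep(FALSE, 3)
  if (any(qualifies)) {
    cand <- which(qualifies)
    drop <- cand[which.max(abs(triplet[cand] - stats::median(triplet)))]
    rejected[drop] <- TRUE
  }
  list(kept = triplet[!rejected], rejected = rejected)
}

#' Fit Michaelis-Menten kinetics to actin-activated ATPase rates
#'
#' Unweighted least-squares fit of \eqn{v = k_{cat} [A] / (K_{app} + [A])} in
#' rate space on post-rejection rates. Zero-actin (basal) wells are reported
#' separately, not included in the hyperbolic fit. When replicates form
#' triplicates per concentration, the >50 percent outlier rule
#' (\code{\link{reject_triplicate_outliers}}) is applied first.
#'
#' @param data Data frame with columns \code{actin_uM} and \code{rate_per_s}
#'   (a \code{replicate} column is optional and unused by the fit itself).
#' @param reject_outliers Apply the triplicate rejection rule per
#'   concentration.
#' @param weighted If \code{TRUE}, weight by inverse within-concentration
#'   variance (default unweighted, matching plate-reader practice).
#' @return An object of class \code{"mm_fit"} with \code{kcat},
#'   \code{kcat_se}, \code{Kapp}, \code{Kapp_se}, \code{basal},
#'   \code{n_points}, \code{rejected} (data frame of dropped points),
#'   \code{Kapp_extrapolated} flag, the underlying \code{nls} \code{fit} and
#'   the post-rejection \code{data}.
#' @examples
#' plate <- simulate_atpase_plate(kcat = 5, Kapp = 20, noise_cv = 0, seed = 1)
#' fit_michaelis_menten(plate)
#' @export
fit_michaelis_menten <- function(data, reject_outliers = TRUE,
                                 weighted = FALSE) {
  req <- c("actin_uM", "rate_per_s")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("data is missing column(s): ",
                         paste(miss, collapse = ", "))
  basal_rows <- data$actin_uM == 0
  basal <- if (any(basal_rows)) mean(data$rate_per_s[basal_rows]) else NA_real_
  d <- data[!basal_rows, , drop = FALSE]
  if (length(unique(d$actin_uM)) < 4)
    stop("need >= 4 distinct non-zero actin concentrations")
  rejected <- d[0, , drop = FALSE]
  if (reject_outliers) {
    keep_idx <- unlist(lapply(split(seq_len(nrow(d)), d$actin_uM),
                              function(ix) {
      if (length(ix) != 3) return(ix)
      r <- reject_triplicate_outliers(d$rate_per_s[ix])
      ix[!r$rejected]
    }))
    rejected <- d[setdiff(seq_len(nrow(d)), keep_idx), , drop = FALSE]
    d <- d[sort(keep_idx), , drop = FALSE]
  }
  kcat0 <- max(d$rate_per_s)
  Kapp0 <- d$actin_uM[which.min(abs(d$rate_per_s - kcat0 / 2))]
  if (Kapp0 <= 0) Kapp0 <- stats::median(d$actin_uM)
  w <- if (weighted) {
    v <- stats::ave(d$rate_per_s, d$actin_uM, FUN = stats::var)
    1 / pmax(v, 1e-12)
  } else rep(1, nrow(d))
  fit <- minpack.lm::nlsLM(rate_per_s ~ kcat * actin_uM / (Kapp + actin_uM),
                           data = d, weights = w,
                           start = list(kcat = kcat0, Kapp = Kapp0),
                           lower = c(kcat = 1e-9, Kapp = 1e-9))
  cf <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  extrapolated <- unname(cf["Kapp"]) > max(d$actin_uM)
  if (extrapolated)
    warning("fitted Kapp exceeds the highest actin concentration tested; ",
            "kcat is an extrapolation")
  structure(list(kcat = unname(cf["kcat"]), kcat_se = unname(se["kcat"]),
                 Kapp = unname(cf["Kapp"]), Kapp_se = unname(se["Kapp"]),
                 basal = basal, n_points = nrow(d), rejected = rejected,
                 Kapp_extrapolated = extrapolated, fit = fit, data = d),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit:\n")
  cat(sprintf("  kcat  %.4g +/- %.3g 1/s\n", x$kcat, x$kcat_se))
  cat(sprintf("  Kapp  %.4g +/- %.3g uM%s\n", x$Kapp, x$Kapp_se,
              if (x$Kapp_extrapolated) "  [extrapolated]" else ""))
  if (!is.na(x$basal)) cat(sprintf("  basal %.4g 1/s (reported separately)\n",
                                   x$basal))
  cat(sprintf("  n = %d points, %d rejected\n", x$n_points, nrow(x$rejected)))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...)
  c(kcat = object$kcat, Kapp = object$Kapp)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  A <- if (is.null(newdata)) object$data$actin_uM else newdata$actin_uM
  object$kcat * A / (object$Kapp + A)
}

#' Normalize ATPase rates to a same-day control kcat
#'
#' Divides rates by the control's fitted \code{kcat}, so the control curve
#' itself has unit kcat by construction. Normalizing an already-normalized
#' control a second time is therefore the identity.
#'
#' @param data Data frame with \code{rate_per_s} (and any other columns).
#' @param control An \code{mm_fit} of the same-day control.
#' @return The data with \code{rate_per_s} rescaled.
#' @export
normalize_to_control <- function(data, control) {
  stopifnot(inherits(control, "mm_fit"))
  data$rate_per_s <- data$rate_per_s / control$kcat
  data
}

#' Standard-error propagation for ratios and ratio averages
#'
#' For independent \eqn{a \pm s_a} and \eqn{b \pm s_b}:
#' \deqn{R = a/b, \quad s_R = R\sqrt{(s_a/a)^2 + (s_b/b)^2};}
#' the average of n ratios carries \eqn{\sqrt{\sum s_i^2}/n}.
#'
#' @param a,b Positive values.
#' @param se_a,se_b Their standard errors.
#' @return \code{propagate_ratio_se}: named vector \code{c(ratio =, se =)}.
#' @examples
#' propagate_ratio_se(3.0, 0.2, 5.0, 0.3)   # 0.600 +/- 0.0538
#' @export
propagate_ratio_se <- function(a, se_a, b, se_b) {
  if (any(a <= 0) || any(b <= 0)) stop("a and b must be positive")
  R <- a / b
  c(ratio = R, se = R * sqrt((se_a / a)^2 + (se_b / b)^2))
}

#' @rdname propagate_ratio_se
#' @param ratios Vector of ratios.
#' @param ses Their standard errors.
#' @return \code{average_ratios}: named vector \code{c(mean =, se =)}.
#' @export
average_ratios <- function(ratios, ses) {
  stopifnot(length(ratios) == length(ses))
  c(mean = mean(ratios), se = sqrt(sum(ses^2)) / length(ratios))
}

#' Five-parameter biexponential fit of a single-ATP-turnover decay
#'
#' Fits \eqn{F(t) = A_f e^{-k_f t} + A_s e^{-k_s t} + C} to a mant-ATP chase
#' fluorescence record (times must already include the instrument dead
#' time). The slow phase is the super-relaxed (SRX) population; its share of
#' the decaying amplitude is
#' \eqn{\%slow = 100\, A_s / (A_f + A_s)}. A fit is flagged ambiguous - the
#' operational form of "ambiguous fits were discarded" - when the two rates
#' separate by less than a factor of 3, when either amplitude's 95 percent
#' CI includes zero, or when the optimizer fails; single-exponential data
#' therefore come back ambiguous, not as an error.
#'
#' Initial rates are chosen by profiling amplitudes (linear for fixed rates)
#' over a log-spaced rate grid, then refined by Levenberg-Marquardt with
#' non-negative amplitude and rate bounds.
#'
#' @param data Data frame with columns \code{time_s}, \code{fluorescence}.
#' @return An object of class \code{"biexp_fit"} with \code{amp_fast},
#'   \code{rate_fast}, \code{amp_slow}, \code{rate_slow}, \code{plateau},
#'   their SEs, \code{percent_slow}, \code{percent_fast}, \code{ambiguous}
#'   (+ \code{ambiguous_reason}), and the data.
#' @examples
#' tr <- simulate_turnover_trace(noise_sd = 0, seed = 1)
#' fit_biexponential(tr)   # percent_slow = 57
#' @export
fit_biexponential <- function(data) {
  req <- c("time_s", "fluorescence")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("data is missing column(s): ",
                         paste(miss, collapse = ", "))
  t <- data$time_s; y <- data$fluorescence
  if (length(t) < 50)
    warning("fewer than 50 time points; biexponential fit may be unstable")
  # profile amplitudes over a rate grid for starting values
  rmin <- 0.5 / (max(t) - min(t)); rmax <- 2 / stats::median(diff(sort(t)))
  grid <- exp(seq(log(rmin), log(rmax), length.out = 25))
  best <- NULL; best_rss <- Inf
  for (i in seq_along(grid)) for (j in seq_len(i - 1)) {
    X <- cbind(exp(-grid[i] * t), exp(-grid[j] * t), 1)
    cf <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    rss <- sum((y - X %*% cf)^2)
    if (rss < best_rss) { best_rss <- rss; best <- unname(c(grid[i], grid[j], cf)) }
  }
  if (is.null(best)) best <- c(rmax / 10, rmin * 2, diff(range(y)) / 2,
                               diff(range(y)) / 2, min(y))
  start <- list(af = max(best[3], 1e-6), kf = best[1],
                as = max(best[4], 1e-6), ks = best[2], C = best[5])
  fit <- tryCatch(
    minpack.lm::nlsLM(fluorescence ~ af * exp(-kf * time_s) +
                        as * exp(-ks * time_s) + C,
                      data = data, start = start,
                      lower = c(af = 0, kf = 1e-12, as = 0, ks = 1e-12,
                                C = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res <- list(amp_fast = NA_real_, rate_fast = NA_real_,
                amp_slow = NA_real_, rate_slow = NA_real_,
                plateau = NA_real_, se = rep(NA_real_, 5),
                percent_slow = NA_real_, percent_fast = NA_real_,
                ambiguous = TRUE, ambiguous_reason = "no convergence",
                fit = NULL, data = data)
    class(res) <- "biexp_fit"
    return(res)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 5))
  names(se) <- names(cf)
  # order phases so rate_fast > rate_slow
  if (cf["kf"] < cf["ks"]) {
    cf <- cf[c("as", "ks", "af", "kf", "C")]
    se <- se[c("as", "ks", "af", "kf", "C")]
    names(cf) <- names(se) <- c("af", "kf", "as", "ks", "C")
  }
  ambiguous_reason <- NULL
  if (!is.finite(cf["ks"]) || cf["ks"] <= 0 ||
      cf["kf"] / cf["ks"] < 3)
    ambiguous_reason <- c(ambiguous_reason, "rate separation < 3x")
  for (amp in c("af", "as"))
    if (!is.na(se[amp]) && cf[amp] - 1.96 * se[amp] <= 0)
      ambiguous_reason <- c(ambiguous_reason,
                            sprintf("amplitude %s CI includes 0", amp))
  tot <- cf["af"] + cf["as"]
  res <- list(amp_fast = unname(cf["af"]), rate_fast = unname(cf["kf"]),
              amp_slow = unname(cf["as"]), rate_slow = unname(cf["ks"]),
              plateau = unname(cf["C"]), se = se,
              percent_slow = unname(100 * cf["as"] / tot),
              percent_fast = unname(100 * cf["af"] / tot),
              ambiguous = length(ambiguous_reason) > 0,
              ambiguous_reason = paste(ambiguous_reason, collapse = "; "),
              fit = fit, data = data)
  class(res) <- "biexp_fit"
  res
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat("Biexponential single-turnover fit:\n")
  if (is.na(x$rate_fast)) { cat("  (did not converge)\n"); return(invisible(x)) }
  cat(sprintf("  fast: amp %.4g, rate %.4g 1/s (DRX)\n",
              x$amp_fast, x$rate_fast))
  cat(sprintf("  slow: amp %.4g, rate %.4g 1/s (SRX)\n",
              x$amp_slow, x$rate_slow))
  cat(sprintf("  plateau %.4g;  %%slow = %.1f, %%fast = %.1f\n",
              x$plateau, x$percent_slow, x$percent_fast))
  if (x$ambiguous) cat("  AMBIGUOUS:", x$ambiguous_reason, "\n")
  invisible(x)
}

#' @export
coef.biexp_fit <- function(object, ...)
  c(amp_fast = object$amp_fast, rate_fast = object$rate_fast,
    amp_slow = object$amp_slow, rate_slow = object$rate_slow,
    plateau = object$plateau)

#' Fitted curve of a biexponential fit, optionally normalized
#'
#' @param object A \code{biexp_fit}.
#' @param newdata Optional data frame with \code{time_s}.
#' @param normalized If \code{TRUE}, rescale so the fitted zero-time
#'   intercept is 1 and the plateau 0.
#' @param ... Unused.
#' @return Fitted fluorescence values.
#' @export
predict.biexp_fit <- function(object, newdata = NULL, normalized = FALSE,
                              ...) {
  t <- if (is.null(newdata)) object$data$time_s else newdata$time_s
  y <- object$amp_fast * exp(-object$rate_fast * t) +
    object$amp_slow * exp(-object$rate_slow * t) + object$plateau
  if (normalized)
    (y - object$plateau) / (object$amp_fast + object$amp_slow)
  else y
}

#' @export
plot.biexp_fit <- function(x, ...) {
  graphics::plot(x$data$time_s, x$data$fluorescence, pch = ".",
                 xlab = "time (s)", ylab = "fluorescence (a.u.)", ...)
  if (!is.na(x$rate_fast))
    graphics::lines(x$data$time_s, predict(x), col = "red3", lwd = 2)
  invisible(x)
}

#' Difference in slow-phase (SRX) percentage between two groups
#'
#' @param group_a,group_b Vectors of per-replicate percent-slow values (a is
#'   typically the reference, e.g. WT, so a positive difference is a
#'   reduction in group b).
#' @param welch Use Welch's correction instead of the pooled-variance test.
#' @return Named vector: \code{difference} (mean_a - mean_b, percentage
#'   points), \code{se} (quadrature of the two SEMs), \code{t}, \code{df},
#'   \code{p}.
#' @examples
#' srx_difference(c(56, 58), c(25, 27))["difference"]   # 31
#' @export
srx_difference <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need >= 2 replicates per group")
  diff <- mean(group_a) - mean(group_b)
  se <- sqrt(stats::var(group_a) / length(group_a) +
               stats::var(group_b) / length(group_b))
  tt <- if (welch) welch_t_test(group_a, group_b)
        else pooled_t_test(group_a, group_b)
  c(difference = diff, se = se, tt)
}

#' Light-chain stoichiometry from gel dilution-series slopes
#'
#' For each chain, fits integrated band density against load by least
#' squares, first pruning saturated top loads: the highest remaining load is
#' dropped while its removal improves the linear fit's R-squared by more
#' than \code{r2_gain} (at least 3 points are always retained; chains that
#' cannot keep 3 are excluded with a message). Light-chain/heavy-chain
#' stoichiometry is the ratio of slopes, with ratio-propagated SE.
#'
#' @param bands Data frame with columns \code{chain} (\code{"HC"},
#'   \code{"ELC"}, \code{"RLC"}), \code{load_pmol}, \code{density}.
#' @param r2_gain R-squared improvement that justifies pruning a top load.
#' @return An object of class \code{"gel_stoich"}: per-chain slopes +/- SE
#'   and points used, and ratios \code{ELC_HC} and \code{RLC_HC} with SEs.
#' @export
fit_gel_stoichiometry <- function(bands, r2_gain = 0.02) {
  req <- c("chain", "load_pmol", "density")
  miss <- setdiff(req, names(bands))
  if (length(miss)) stop("bands is missing column(s): ",
                         paste(miss, collapse = ", "))
  fit_chain <- function(d) {
    if (nrow(d) < 4) {
      message("chain ", d$chain[1], ": fewer than 4 loads; excluded")
      return(NULL)
    }
    d <- d[order(-d$load_pmol), , drop = FALSE]
    repeat {
      if (nrow(d) <= 3) break
      r2 <- function(dd) suppressWarnings(
        summary(stats::lm(density ~ load_pmol, dd))$r.squared)
      if (r2(d[-1, , drop = FALSE]) - r2(d) > r2_gain) {
        d <- d[-1, , drop = FALSE]
      } else break
    }
    m <- stats::lm(density ~ load_pmol, d)
    s <- suppressWarnings(summary(m))$coefficients
    list(slope = s["load_pmol", "Estimate"], se = s["load_pmol", "Std. Error"],
         n_points = nrow(d), loads = d$load_pmol)
  }
  chains <- lapply(split(bands, bands$chain), fit_chain)
  chains <- chains[!vapply(chains, is.null, logical(1))]
  if (is.null(chains$HC)) stop("heavy-chain series missing or unusable")
  ratio_of <- function(lc) {
    if (is.null(chains[[lc]])) return(c(ratio = NA_real_, se = NA_real_))
    propagate_ratio_se(chains[[lc]]$slope, chains[[lc]]$se,
                       chains$HC$slope, chains$HC$se)
  }
  structure(list(chains = chains,
                 ELC_HC = ratio_of("ELC"), RLC_HC = ratio_of("RLC")),
            class = "gel_stoich")
}

#' @export
print.gel_stoich <- function(x, ...) {
  cat("Light-chain stoichiometry (dilution-series slope ratios):\n")
  for (ch in names(x$chains))
    cat(sprintf("  %-3s slope %.4g +/- %.3g (%d points)\n", ch,
                x$chains[[ch]]$slope, x$chains[[ch]]$se,
                x$chains[[ch]]$n_points))
  cat(sprintf("  ELC/HC = %.3f +/- %.3f\n", x$ELC_HC["ratio"], x$ELC_HC["se"]))
  cat(sprintf("  RLC/HC = %.3f +/- %.3f\n", x$RLC_HC["ratio"], x$RLC_HC["se"]))
  invisible(x)
}
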