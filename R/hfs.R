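#' Bin interaction events by mean load force
#'
#' Fixed-width bins spanning the observed force range; bins with fewer than
#' \code{min_bin_events} events are dropped. Bin-level load and amplitude are
#' the within-bin event means.
#'
#' @param events Event data frame (columns \code{duration_s},
#'   \code{mean_force_pN}, \code{force_amp_pN}).
#' @param bin_width Bin width, pN.
#' @param min_bin_events Minimum events for a bin to be kept.
#' @return Data frame with columns \code{f_lo}, \code{f_hi},
#'   \code{mean_force}, \code{mean_amp}, \code{n_events} and a list column
#'   \code{durations}.
#' @export
bin_events <- function(events, bin_width = 1, min_bin_events = 5) {
  if (is.null(events) || nrow(events) == 0) stop("no events to bin")
  F <- events$mean_force_pN
  lo <- floor(min(F) / bin_width) * bin_width
  hi <- ceiling(max(F) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- findInterval(F, breaks, rightmost.closed = TRUE)
  keep <- which(tabulate(idx, length(breaks) - 1) >= min_bin_events)
  out <- do.call(rbind, lapply(keep, function(b) {
    sel <- idx == b
    data.frame(f_lo = breaks[b], f_hi = breaks[b + 1],
               mean_force = mean(F[sel]),
               mean_amp = mean(events$force_amp_pN[sel]),
               n_events = sum(sel))
  }))
  if (is.null(out))
    out <- data.frame(f_lo = numeric(0), f_hi = numeric(0),
                      mean_force = numeric(0), mean_amp = numeric(0),
                      n_events = integer(0))
  out$durations <- lapply(keep, function(b) events$duration_s[idx == b])
  out
}

#' Maximum-likelihood detachment rate from dwell times
#'
#' For dwell times that a detector can only score above a dead time
#' \code{t_min}, the observed durations are left-truncated exponentials; by
#' memorylessness the MLE of the rate is
#' \deqn{\hat k = n / \sum_i (t_i - t_{min}), \qquad SE(\hat k) = \hat k/\sqrt n.}
#' With \code{t_min = 0} this is the naive exponential MLE.
#'
#' @param durations Dwell times, s, all \code{> t_min}.
#' @param t_min Detection dead time (left-truncation point), s.
#' @return Named numeric vector \code{c(rate =, se =)}, 1/s.
#' @examples
#' mle_bin_rate(c(0.01, 0.02, 0.03))          # 50 1/s
#' mle_bin_rate(c(0.01, 0.02, 0.03), 0.005)   # 66.67 1/s
#' @export
mle_bin_rate <- function(durations, t_min = 0) {
  if (t_min < 0) stop("t_min must be >= 0")
  n <- length(durations)
  if (n < 1) stop("need at least one duration")
  if (any(durations <= t_min))
    stop("durations at or below t_min found: inconsistent censoring ",
         "(the detector could not have scored these events)")
  rate <- n / sum(durations - t_min)
  c(rate = rate, se = rate / sqrt(n))
}

#' Fit the load-dependent detachment model to binned rates
#'
#' Weighted nonlinear least squares of per-bin MLE rates against
#' \eqn{k_0 I_0(\bar{\Delta F}\delta/k_BT)\exp(-\bar F \delta /k_BT)}. The
#' fit is performed on the log-rate scale, where the MLE's sampling error is
#' homoscedastic per event (var(log k-hat) ~ 1/n), with weights equal to the
#' bin event counts; weighting raw rates by their estimated \eqn{1/SE^2}
#' couples the weights to the noise and demonstrably biases k0 downward at
#' realistic bin occupancies. When bin counts are available the known
#' finite-sample offset of the log of an exponential-rate MLE,
#' \eqn{E[\log\hat k] - \log k = \log n - \psi(n)}, is subtracted, making
#' the fit unbiased down to a handful of events per bin. Without an
#' \code{n_events} column (e.g. rates supplied directly), an unweighted
#' uncorrected log-scale fit is used.
#'
#' @param bins Output of \code{\link{bin_events}} with \code{rate} and
#'   \code{rate_se} columns (see \code{\link{fit_hfs}}), or any data frame
#'   with \code{mean_force}, \code{mean_amp}, \code{rate}, \code{rate_se}.
#' @param consts A \code{\link{trap_constants}} object.
#' @return List with \code{k0}, \code{delta}, their SEs, the 2x2
#'   \code{covariance}, \code{converged}, \code{delta_at_bound}, and
#'   \code{resid_norm}.
#' @export
fit_force_dependence <- function(bins, consts = trap_constants()) {
  if (nrow(bins) < 3) stop("need >= 3 force bins")
  if (diff(range(bins$mean_force)) < 2)
    stop("force bins must span >= 2 pN")
  kBT <- consts$kBT
  have_n <- "n_events" %in% names(bins)
  w <- if (have_n) bins$n_events else rep(1, nrow(bins))
  lograte <- log(bins$rate) -
    if (have_n) (log(bins$n_events) - digamma(bins$n_events)) else 0
  d <- data.frame(lograte = lograte, mean_force = bins$mean_force,
                  mean_amp = bins$mean_amp)
  sl <- stats::lm(lograte ~ mean_force, data = d, weights = w)
  delta0 <- max(0.01, -unname(stats::coef(sl)[2]) * kBT)
  lk00 <- unname(stats::coef(sl)[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      lograte ~ lk0 + log(besselI(mean_amp * delta / kBT, 0)) -
        mean_force * delta / kBT,
      data = d, weights = w,
      start = list(lk0 = lk00, delta = delta0),
      lower = c(lk0 = -Inf, delta = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(k0 = NA_real_, delta = NA_real_, se_k0 = NA_real_,
                se_delta = NA_real_, covariance = matrix(NA, 2, 2),
                converged = FALSE, delta_at_bound = FALSE,
                resid_norm = NA_real_))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  k0 <- exp(unname(cf["lk0"]))
  # delta method: var(k0) = k0^2 var(log k0); covariance mapped accordingly
  J <- diag(c(k0, 1))
  vck <- J %*% vc %*% J
  list(k0 = k0, delta = unname(cf["delta"]),
       se_k0 = sqrt(vck[1, 1]), se_delta = sqrt(vck[2, 2]),
       covariance = vck, converged = TRUE,
       delta_at_bound = unname(cf["delta"]) <= 1e-8,
       resid_norm = sqrt(sum(stats::residuals(fit)^2)))
}

#' Per-event truncated maximum-likelihood fit of (k0, delta)
#'
#' Full-likelihood alternative to the binned fit: each event contributes
#' \eqn{\log k(F_i, \Delta F_i) - k(F_i,\Delta F_i)(t_i - t_{min})} with the
#' period-averaged rate model. Maximized over \eqn{(\log k_0, \delta)} by
#' quasi-Newton; SEs from the observed information.
#'
#' @param events Event data frame.
#' @param consts A \code{\link{trap_constants}} object.
#' @param t_min Detection dead time, s.
#' @return Same shape as \code{\link{fit_force_dependence}}.
#' @export
fit_events_mle <- function(events, consts = trap_constants(), t_min = 0) {
  if (any(events$duration_s <= t_min))
    stop("durations at or below t_min found: inconsistent censoring")
  kBT <- consts$kBT
  tt <- events$duration_s - t_min
  F <- events$mean_force_pN
  dF <- events$force_amp_pN
  nll <- function(par) {
    k0 <- exp(par[1]); delta <- par[2]
    if (delta < 0) return(1e10)
    k <- k0 * besselI(dF * delta / kBT, 0) * exp(-F * delta / kBT)
    -sum(log(k) - k * tt)
  }
  naive <- length(tt) / sum(tt)
  opt <- stats::optim(c(log(naive), 0.5), nll, method = "BFGS",
                      hessian = TRUE)
  k0 <- exp(opt$par[1]); delta <- opt$par[2]
  vc <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, 2, 2))
  # delta-method: var(k0) = k0^2 var(log k0)
  se_k0 <- k0 * sqrt(vc[1, 1])
  list(k0 = k0, delta = delta, se_k0 = se_k0, se_delta = sqrt(vc[2, 2]),
       covariance = vc, converged = opt$convergence == 0,
       delta_at_bound = delta <= 1e-8, resid_norm = NA_real_)
}

#' Step size from event displacements
#'
#' Mean and SD of per-event displacements (no compliance correction: series
#' compliances make trap-measured steps smaller than the true working
#' stroke, and are not corrected here).
#'
#' @param events Event data frame with \code{displacement_nm}.
#' @return Named vector \code{c(step =, sd =)}, nm.
#' @export
estimate_step <- function(events) {
  d <- events$displacement_nm
  d <- d[!is.na(d)]
  if (length(d) < 5) stop("need >= 5 events with displacement")
  c(step = mean(d), sd = stats::sd(d))
}

#' Fit harmonic-force-spectroscopy parameters per molecule and per group
#'
#' The central model fit: for each molecule, events are binned by mean load,
#' a truncated-exponential MLE rate is computed per bin, and the
#' Bessel-corrected Bell model
#' \eqn{k_{det}(F,\Delta F)=k_0 I_0(\Delta F\delta/k_BT)\exp(-F\delta/k_BT)}
#' is fitted to the bin rates by weighted nonlinear least squares
#' (\code{method = "binned"}, the default) or to all events by full truncated
#' maximum likelihood (\code{method = "mle"}). Step sizes are per-molecule
#' displacement means. Molecule-level estimates are then averaged into group
#' characteristic values (mean +/- SEM for \code{k0} and \code{delta}, mean
#' +/- SD for the step), with non-converged or bound-pinned molecules
#' excluded and reported.
#'
#' @param events Event data frame (\code{molecule_id}, \code{duration_s},
#'   \code{mean_force_pN}, \code{force_amp_pN}, \code{displacement_nm}).
#' @param consts A \code{\link{trap_constants}} object.
#' @param bin_width Force bin width, pN.
#' @param min_bin_events Minimum events per kept bin.
#' @param t_min Detection dead time for the truncated MLE, s. Use 0 for the
#'   naive estimator (uncensored data).
#' @param method \code{"binned"} or \code{"mle"}.
#' @param label Group label carried into summaries.
#' @return An object of class \code{"hfs_fit"}: list with \code{molecules}
#'   (per-molecule data frame), \code{bins} (per-molecule bin tables),
#'   \code{group} (a \code{\link{summarize_group}} result), \code{excluded},
#'   \code{consts}, \code{method}, \code{call}.
#' @examples
#' cfg <- sim_config(motor_params(147, 1.04, step_d = 4.3),
#'                   n_molecules = 3, events_per_molecule = 200,
#'                   min_detectable_duration = 0, seed = 42)
#' fit <- fit_hfs(simulate_events(cfg), label = "WT-like")
#' fit
#' @export
fit_hfs <- function(events, consts = trap_constants(), bin_width = 1,
                    min_bin_events = 5, t_min = 0,
                    method = c("binned", "mle"), label = "group") {
  method <- match.arg(method)
  req <- c("molecule_id", "duration_s", "mean_force_pN", "force_amp_pN")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop("events is missing column(s): ",
                         paste(miss, collapse = ", "))
  ids <- unique(events$molecule_id)
  rows <- list(); bin_tabs <- list(); excluded <- character(0)
  for (id in ids) {
    ev <- events[events$molecule_id == id, , drop = FALSE]
    fit <- if (method == "mle") {
      fit_events_mle(ev, consts, t_min)
    } else {
      bins <- bin_events(ev, bin_width, min_bin_events)
      if (nrow(bins) < 3 || diff(range(bins$mean_force)) < 2) {
        excluded <- c(excluded, id)
        next
      }
      rt <- t(vapply(bins$durations, mle_bin_rate, numeric(2), t_min = t_min))
      bins$rate <- rt[, "rate"]; bins$rate_se <- rt[, "se"]
      bin_tabs[[id]] <- bins[, setdiff(names(bins), "durations")]
      fit_force_dependence(bins, consts)
    }
    if (!isTRUE(fit$converged) || isTRUE(fit$delta_at_bound)) {
      excluded <- c(excluded, id)
      next
    }
    st <- if ("displacement_nm" %in% names(ev) &&
              sum(!is.na(ev$displacement_nm)) >= 5)
      estimate_step(ev) else c(step = NA_real_, sd = NA_real_)
    rows[[id]] <- data.frame(
      molecule_id = id, k0 = fit$k0, k0_se = fit$se_k0,
      delta = fit$delta, delta_se = fit$se_delta,
      step = unname(st["step"]), step_sd = unname(st["sd"]),
      n_events = nrow(ev), stringsAsFactors = FALSE)
  }
  if (length(excluded))
    message("excluded molecule(s) (too few bins / non-convergence / delta at bound): ",
            paste(excluded, collapse = ", "))
  molecules <- do.call(rbind, rows)
  if (is.null(molecules) || nrow(molecules) == 0)
    stop("no molecule produced a usable fit")
  rownames(molecules) <- NULL
  group <- if (nrow(molecules) >= 2) summarize_group(molecules, label) else NULL
  structure(list(molecules = molecules, bins = bin_tabs, group = group,
                 excluded = excluded, consts = consts, method = method,
                 t_min = t_min, label = label, call = match.call()),
            class = "hfs_fit")
}

#' Cross-molecule characteristic values
#'
#' Arithmetic mean and SEM (SD/sqrt(n)) across molecules for \code{k0} and
#' \code{delta}; mean +/- SD for the step size, matching how single-molecule
#' step distributions are conventionally reported.
#'
#' @param molecules Per-molecule data frame (as in an \code{hfs_fit}), or an
#'   \code{hfs_fit} object.
#' @param label Group label.
#' @return An object of class \code{"group_summary"}.
#' @export
summarize_group <- function(molecules, label = "group") {
  if (inherits(molecules, "hfs_fit")) molecules <- molecules$molecules
  n <- nrow(molecules)
  if (n < 2) stop("need >= 2 molecules for a group summary")
  sem <- function(x) stats::sd(x) / sqrt(sum(!is.na(x)))
  structure(list(label = label, n_molecules = n,
                 k0_mean = mean(molecules$k0), k0_sem = sem(molecules$k0),
                 delta_mean = mean(molecules$delta),
                 delta_sem = sem(molecules$delta),
                 step_mean = mean(molecules$step, na.rm = TRUE),
                 step_sd = stats::sd(molecules$step, na.rm = TRUE),
                 molecules = molecules),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s (n = %d molecules)\n", x$label, x$n_molecules))
  cat(sprintf("  k0    %.1f +/- %.1f 1/s (mean +/- SEM)\n", x$k0_mean, x$k0_sem))
  cat(sprintf("  delta %.3f +/- %.3f nm (mean +/- SEM)\n",
              x$delta_mean, x$delta_sem))
  if (!is.na(x$step_mean))
    cat(sprintf("  step  %.2f +/- %.2f nm (mean +/- SD)\n",
                x$step_mean, x$step_sd))
  invisible(x)
}

#' Compare two fitted groups molecule-by-molecule
#'
#' Unpaired Welch t-tests (each molecule an independent replicate) on
#' \code{k0}, \code{delta} and step, plus percent changes of the group means
#' with ratio-propagated SEMs.
#'
#' @param a,b \code{hfs_fit} or \code{group_summary} objects (a is treated
#'   as the mutant/test group, b as the reference).
#' @return An object of class \code{"hfs_comparison"}.
#' @export
compare_groups <- function(a, b) {
  ga <- if (inherits(a, "hfs_fit")) a$group else a
  gb <- if (inherits(b, "hfs_fit")) b$group else b
  stopifnot(inherits(ga, "group_summary"), inherits(gb, "group_summary"))
  one <- function(field) {
    xa <- ga$molecules[[field]]; xb <- gb$molecules[[field]]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    tt <- welch_t_test(xa, xb)
    pc <- percent_change(mean(xa), mean(xb),
                         stats::sd(xa) / sqrt(length(xa)),
                         stats::sd(xb) / sqrt(length(xb)))
    c(mean_a = mean(xa), mean_b = mean(xb),
      percent_change = unname(pc["percent"]), pc_se = unname(pc["se"]),
      t = tt["t"], df = tt["df"], p = tt["p"])
  }
  res <- rbind(k0 = one("k0"), delta = one("delta"), step = one("step"))
  colnames(res) <- c("mean_a", "mean_b", "percent_change", "pc_se",
                     "t", "df", "p")
  structure(list(label_a = ga$label, label_b = gb$label,
                 table = as.data.frame(res)),
            class = "hfs_comparison")
}

#' @export
print.hfs_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Group comparison: %s vs %s (Welch t-test per parameter)\n",
              x$label_a, x$label_b))
  print(round(x$table, digits))
  invisible(x)
}

#' Percent change of a value relative to a reference
#'
#' \code{100 * (mutant/wt - 1)}, with a companion SEM from ratio error
#' propagation when uncertainties are supplied.
#'
#' @param mutant,wt Values (wt must be nonzero).
#' @param sem_mutant,sem_wt Optional SEMs.
#' @return Named vector \code{c(percent =, se =)} (se is \code{NA} without
#'   uncertainties).
#' @examples
#' percent_change(315.6, 147.0)   # +114.7 percent
#' percent_change(101.7, 147.0)   # -30.8 percent
#' @export
percent_change <- function(mutant, wt, sem_mutant = NA_real_,
                           sem_wt = NA_real_) {
  if (wt == 0) stop("reference value must be nonzero")
  pc <- 100 * (mutant / wt - 1)
  se <- if (is.na(sem_mutant) || is.na(sem_wt)) NA_real_ else
    100 * abs(mutant / wt) * sqrt((sem_mutant / mutant)^2 + (sem_wt / wt)^2)
  c(percent = pc, se = se)
}

#' @export
print.hfs_fit <- function(x, ...) {
  cat(sprintf("HFS fit (%s, t_min = %g s): %d molecule(s)\n",
              x$method, x$t_min, nrow(x$molecules)))
  if (!is.null(x$group)) print(x$group)
  invisible(x)
}

#' @export
summary.hfs_fit <- function(object, ...) {
  cat(sprintf("HFS fit, method = %s, dead time t_min = %g s\n",
              object$method, object$t_min))
  cat("\nPer-molecule estimates:\n")
  print(object$molecules, digits = 4)
  if (length(object$excluded))
    cat("\nExcluded molecules:", paste(object$excluded, collapse = ", "), "\n")
  if (!is.null(object$group)) { cat("\n"); print(object$group) }
  invisible(object)
}

#' @export
coef.hfs_fit <- function(object, ...) {
  g <- object$group
  if (is.null(g)) {
    m <- object$molecules[1, ]
    return(c(k0 = m$k0, delta = m$delta, step = m$step))
  }
  c(k0 = g$k0_mean, delta = g$delta_mean, step = g$step_mean)
}

#' Predict detachment rates from a fitted HFS model
#'
#' @param object An \code{hfs_fit}.
#' @param newdata Data frame with columns \code{mean_force_pN} and optionally
#'   \code{force_amp_pN} (defaults to 0).
#' @param ... Unused.
#' @return Predicted detachment rates, 1/s, from the group-mean parameters.
#' @export
predict.hfs_fit <- function(object, newdata, ...) {
  cf <- stats::coef(object)
  dF <- if ("force_amp_pN" %in% names(newdata)) newdata$force_amp_pN else 0
  p <- motor_params(k0 = cf[["k0"]], delta = cf[["delta"]])
  detachment_rate(newdata$mean_force_pN, dF, p, object$consts)
}

#' Simulate events from a fitted HFS model
#'
#' @param object An \code{hfs_fit}.
#' @param nsim Events per molecule.
#' @param seed Integer seed or \code{NULL}.
#' @param n_molecules Number of molecules to simulate.
#' @param ... Passed to \code{\link{sim_config}}.
#' @return An event data frame (see \code{\link{simulate_events}}).
#' @export
simulate.hfs_fit <- function(object, nsim = 200, seed = NULL,
                             n_molecules = nrow(object$molecules), ...) {
  cf <- stats::coef(object)
  p <- motor_params(k0 = cf[["k0"]], delta = cf[["delta"]],
                    step_d = if (is.na(cf[["step"]])) NULL else cf[["step"]])
  cfg <- sim_config(p, n_molecules = n_molecules,
                    events_per_molecule = nsim, seed = seed, ...)
  simulate_events(cfg, object$consts)
}

#' @export
plot.hfs_fit <- function(x, force_grid = NULL, ...) {
  bins <- do.call(rbind, x$bins)
  if (is.null(force_grid)) {
    rng <- if (!is.null(bins)) range(bins$mean_force) else c(-5, 5)
    force_grid <- seq(rng[1], rng[2], length.out = 100)
  }
  pred <- predict(x, data.frame(mean_force_pN = force_grid))
  graphics::plot(force_grid, pred, type = "l", log = "y",
                 xlab = "load force (pN)", ylab = "detachment rate (1/s)",
                 main = sprintf("%s: k0 = %.1f 1/s, delta = %.2f nm",
                                x$label, coef(x)[["k0"]],
                                coef(x)[["delta"]]), ...)
  if (!is.null(bins))
    graphics::points(bins$mean_force, bins$rate, pch = 16,
                     col = grDevices::adjustcolor("steelblue", 0.6))
  invisible(x)
}

#' @export
residuals.hfs_fit <- function(object, ...) {
  bins <- do.call(rbind, object$bins)
  if (is.null(bins)) return(numeric(0))
  pred <- predict(object, data.frame(mean_force_pN = bins$mean_force,
                                     force_amp_pN = bins$mean_amp))
  bins$rate - pred
}
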