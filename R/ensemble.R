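#' Force-dependent duty ratio
#'
#' Fraction of the ATPase cycle a head spends attached under mean load F:
#' \deqn{r(F) = k_{attach} / (k_{attach} + k_{det}(F))}
#' with the force-independent attachment rate
#' \eqn{k_{attach} = (1/k_{cat} - 1/k_0)^{-1}}. At zero load this reduces
#' exactly to \eqn{k_{cat}/k_0}. The detachment rate is evaluated without a
#' sinusoidal component by default (\code{dF = 0}): the oscillation is an
#' instrument artifact, not part of the physiological load.
#'
#' @param F Load force(s), pN (positive = resistive).
#' @param params A \code{\link{motor_params}} with \code{kcat < k0}.
#' @param consts A \code{\link{trap_constants}} object.
#' @param dF Sinusoidal amplitude fed to the Bessel factor, pN.
#' @return Duty ratio(s) in (0, 1).
#' @examples
#' p <- motor_params(147, 1.04, kcat = 5, step_d = 4.3)
#' duty_ratio(0, p)   # = 5/147
#' @export
duty_ratio <- function(F, params, consts = trap_constants(), dF = 0) {
  if (is.null(params$kcat)) stop("params$kcat required for duty ratio")
  ka <- attachment_rate(params$kcat, params$k0)
  ka / (ka + detachment_rate(F, dF, params, consts))
}

.curve_set <- function(F, k0, delta, kcat, d, kBT, dF = 0) {
  kdet <- k0 * besselI(dF * delta / kBT, 0) * exp(-F * delta / kBT)
  ka <- 1 / (1 / kcat - 1 / k0)
  r <- ka / (ka + kdet)
  Fav <- F * r
  vel <- kdet * d
  list(duty_ratio = r, avg_force = Fav, velocity = vel, power = vel * Fav)
}

#' Ensemble duty ratio, average force, velocity and power versus load
#'
#' Evaluates, on a resistive force grid, the ensemble predictions of a motor
#' with parameters \eqn{(k_0, \delta, k_{cat}, d)}:
#' duty ratio \eqn{r(F)}, per-head average force \eqn{F_{av} = F r(F)},
#' gliding velocity \eqn{v(F) = k_{det}(F)\, d}, and average power
#' \eqn{P_{av}(F) = v(F) F_{av}(F)}. Uncertainty bands are pointwise 16th and
#' 84th percentiles over Monte-Carlo parameter draws: independent Gaussians
#' at the supplied SEMs, truncated to the valid region
#' (\eqn{k_0 > k_{cat} > 0}, \eqn{\delta \ge 0}, redrawn on violation).
#'
#' @param params A \code{\link{motor_params}} with \code{kcat}, \code{step_d}
#'   and (for bands) SEM fields set.
#' @param consts A \code{\link{trap_constants}} object.
#' @param force_grid Resistive force grid, pN, \code{>= 0}.
#' @param n_mc Number of Monte-Carlo draws (0 disables bands).
#' @param seed Integer seed or \code{NULL}.
#' @param dF Sinusoidal amplitude in the Bessel factor, pN (0 by default).
#' @return An object of class \code{"ensemble_curves"}: a data frame with
#'   \code{force_pN}, each central curve, and \code{*_lo}/\code{*_hi} bands;
#'   the parameters and settings are attached as attributes.
#' @examples
#' p <- motor_params(147, 1.04, kcat = 5, step_d = 4.3,
#'                   sem_k0 = 6.8, sem_delta = 0.05,
#'                   sem_kcat = 0.2, sd_step = 0.4)
#' ec <- ensemble_curves(p, n_mc = 1000, seed = 1)
#' head(as.data.frame(ec))
#' @export
ensemble_curves <- function(params, consts = trap_constants(),
                            force_grid = seq(0, 10, by = 0.1),
                            n_mc = 10000, seed = NULL, dF = 0) {
  stopifnot(inherits(params, "motor_params"))
  if (is.null(params$kcat) || is.null(params$step_d))
    stop("params must carry kcat and step_d")
  if (any(force_grid < 0)) stop("force_grid must be resistive (>= 0)")
  kBT <- consts$kBT
  central <- .curve_set(force_grid, params$k0, params$delta, params$kcat,
                        params$step_d, kBT, dF)
  out <- data.frame(force_pN = force_grid,
                    duty_ratio = central$duty_ratio,
                    avg_force_pN = central$avg_force,
                    velocity_nm_s = central$velocity,
                    power_pNnm_s = central$power)
  sems <- c(params$sem_k0, params$sem_delta, params$sem_kcat, params$sd_step)
  have_sems <- all(!is.na(sems))
  if (n_mc > 0 && have_sems && any(sems > 0)) {
    draws <- local_seed(seed, {
      need <- n_mc; total <- 0
      k0s <- numeric(0); ds <- numeric(0); kcs <- numeric(0); sts <- numeric(0)
      while (need > 0) {
        m <- ceiling(need * 1.2)
        total <- total + m
        k0 <- stats::rnorm(m, params$k0, params$sem_k0)
        de <- stats::rnorm(m, params$delta, params$sem_delta)
        kc <- stats::rnorm(m, params$kcat, params$sem_kcat)
        st <- stats::rnorm(m, params$step_d, params$sd_step)
        ok <- k0 > kc & kc > 0 & de >= 0
        k0s <- c(k0s, k0[ok]); ds <- c(ds, de[ok])
        kcs <- c(kcs, kc[ok]); sts <- c(sts, st[ok])
        need <- n_mc - length(k0s)
        if (total > 10 * n_mc)
          stop("Monte-Carlo redraw rate exceeds 20%: parameter ",
               "uncertainties are inconsistent with k0 > kcat > 0")
      }
      if ((total - n_mc) / total > 0.2)
        stop("Monte-Carlo redraw rate exceeds 20%: parameter ",
             "uncertainties are inconsistent with k0 > kcat > 0")
      list(k0 = k0s[1:n_mc], delta = ds[1:n_mc],
           kcat = kcs[1:n_mc], step = sts[1:n_mc])
    })
    qs <- function(mat) apply(mat, 2, stats::quantile,
                              probs = c(0.16, 0.84), names = FALSE)
    # draws x grid matrices, fully vectorized
    pref <- draws$k0 * besselI(dF * draws$delta / kBT, 0)
    kdet <- pref * exp(-(draws$delta %o% force_grid) / kBT)
    ka <- 1 / (1 / draws$kcat - 1 / draws$k0)
    r <- ka / (ka + kdet)
    Fav <- sweep(r, 2, force_grid, `*`)
    vel <- kdet * draws$step
    bands <- lapply(list(duty_ratio = r, avg_force = Fav, velocity = vel,
                         power = vel * Fav), qs)
    out$duty_ratio_lo <- bands$duty_ratio[1, ]
    out$duty_ratio_hi <- bands$duty_ratio[2, ]
    out$avg_force_lo <- bands$avg_force[1, ]
    out$avg_force_hi <- bands$avg_force[2, ]
    out$velocity_lo <- bands$velocity[1, ]
    out$velocity_hi <- bands$velocity[2, ]
    out$power_lo <- bands$power[1, ]
    out$power_hi <- bands$power[2, ]
  } else {
    out$duty_ratio_lo <- out$duty_ratio; out$duty_ratio_hi <- out$duty_ratio
    out$avg_force_lo <- out$avg_force_pN; out$avg_force_hi <- out$avg_force_pN
    out$velocity_lo <- out$velocity_nm_s; out$velocity_hi <- out$velocity_nm_s
    out$power_lo <- out$power_pNnm_s; out$power_hi <- out$power_pNnm_s
  }
  structure(out, params = params, consts = consts, n_mc = n_mc,
            seed = seed, dF = dF,
            class = c("ensemble_curves", "data.frame"))
}

#' Delta-method uncertainty cross-check for ensemble curves
#'
#' First-order propagation of the parameter SEMs through each curve by
#' numerical gradients, assuming independent errors. Serves as an analytic
#' cross-check of the Monte-Carlo bands: for small relative uncertainties the
#' delta-method SD should approximate the MC band half-width.
#'
#' @param params,consts,force_grid,dF As in \code{\link{ensemble_curves}}.
#' @return Data frame of pointwise SDs for each curve.
#' @export
delta_method_bands <- function(params, consts = trap_constants(),
                               force_grid = seq(0, 10, by = 0.1), dF = 0) {
  kBT <- consts$kBT
  theta <- c(k0 = params$k0, delta = params$delta, kcat = params$kcat,
             step = params$step_d)
  sems <- c(params$sem_k0, params$sem_delta, params$sem_kcat, params$sd_step)
  fcurves <- function(th)
    .curve_set(force_grid, th[1], th[2], th[3], th[4], kBT, dF)
  base <- fcurves(theta)
  var_acc <- lapply(base, function(x) 0 * x)
  for (j in seq_along(theta)) {
    h <- max(1e-6, 1e-6 * abs(theta[j]))
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    cu <- fcurves(up); cd <- fcurves(dn)
    for (nm in names(base)) {
      g <- (cu[[nm]] - cd[[nm]]) / (2 * h)
      var_acc[[nm]] <- var_acc[[nm]] + (g * sems[j])^2
    }
  }
  data.frame(force_pN = force_grid,
             duty_ratio_sd = sqrt(var_acc$duty_ratio),
             avg_force_sd = sqrt(var_acc$avg_force),
             velocity_sd = sqrt(var_acc$velocity),
             power_sd = sqrt(var_acc$power))
}

#' Qualitative comparison of two ensemble predictions
#'
#' Point-by-point comparison of power output on a shared force grid: at each
#' force, the sign of the difference and whether the uncertainty bands
#' overlap. The summary label (\code{"hyper"}, \code{"hypo"},
#' \code{"within error"}) is decided by majority over the grid: points with
#' disjoint bands vote for the sign of the difference, overlapping points
#' vote within-error.
#'
#' @param a,b \code{ensemble_curves} on the same force grid (a is the test
#'   construct, b the reference).
#' @return An object of class \code{"ensemble_comparison"} with the
#'   per-force table and the summary \code{label}.
#' @export
compare_ensembles <- function(a, b) {
  stopifnot(inherits(a, "ensemble_curves"), inherits(b, "ensemble_curves"))
  if (nrow(a) != nrow(b) || any(abs(a$force_pN - b$force_pN) > 1e-9))
    stop("force grids differ; compare_ensembles needs a shared grid")
  diff_sign <- sign(a$power_pNnm_s - b$power_pNnm_s)
  overlap <- a$power_lo <= b$power_hi & b$power_lo <= a$power_hi
  vote <- ifelse(overlap, 0, diff_sign)
  tab <- data.frame(force_pN = a$force_pN, power_diff = a$power_pNnm_s -
                      b$power_pNnm_s, bands_overlap = overlap)
  counts <- c(hyper = sum(vote > 0), hypo = sum(vote < 0),
              within = sum(vote == 0))
  label <- c("hyper", "hypo", "within error")[which.max(counts)]
  structure(list(table = tab, counts = counts, label = label),
            class = "ensemble_comparison")
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat(sprintf("Ensemble power comparison: %s (hyper %d / hypo %d / within %d grid points)\n",
              x$label, x$counts["hyper"], x$counts["hypo"],
              x$counts["within"]))
  invisible(x)
}

#' @export
print.ensemble_curves <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Ensemble curves on F in [%g, %g] pN (%d points), n_mc = %d\n",
    min(x$force_pN), max(x$force_pN), nrow(x), attr(x, "n_mc")))
  cat(sprintf("  params: k0 = %.4g 1/s, delta = %.4g nm, kcat = %.4g 1/s, d = %.4g nm\n",
              p$k0, p$delta, p$kcat, p$step_d))
  invisible(x)
}

#' @export
plot.ensemble_curves <- function(x, what = c("power", "duty_ratio",
                                             "avg_force", "velocity"), ...) {
  what <- match.arg(what)
  col <- switch(what, power = "power_pNnm_s", duty_ratio = "duty_ratio",
                avg_force = "avg_force_pN", velocity = "velocity_nm_s")
  lohi <- switch(what, power = c("power_lo", "power_hi"),
                 duty_ratio = c("duty_ratio_lo", "duty_ratio_hi"),
                 avg_force = c("avg_force_lo", "avg_force_hi"),
                 velocity = c("velocity_lo", "velocity_hi"))
  ylab <- switch(what, power = "average power (pN nm/s)",
                 duty_ratio = "duty ratio",
                 avg_force = "average force (pN)",
                 velocity = "velocity (nm/s)")
  graphics::plot(x$force_pN, x[[col]], type = "l",
                 xlab = "resistive load (pN)", ylab = ylab, ...)
  graphics::lines(x$force_pN, x[[lohi[1]]], lty = 3)
  graphics::lines(x$force_pN, x[[lohi[2]]], lty = 3)
  invisible(x)
}
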