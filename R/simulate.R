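#' @keywords internal
#' Run code with a locally-set RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for a synthetic harmonic-force-spectroscopy experiment
#'
#' Describes the simulated single-molecule experiment: the true motor
#' parameters, the number of molecules and binding events, the per-event load
#' distributions, and the detector censoring. Defaults emulate a typical
#' dual-beam trap study of beta-cardiac myosin: about ten molecules with a
#' few hundred scored events each, mean loads spanning assistive to resistive
#' (-5 to +5 pN), sinusoidal amplitudes of 1-4 pN, and a minimum scoreable
#' dwell of two oscillation periods (10 ms at 200 Hz).
#'
#' @param true_params A \code{\link{motor_params}} object (requires
#'   \code{step_d} for displacements).
#' @param n_molecules Number of molecules, \code{>= 1}.
#' @param events_per_molecule Binding events attempted per molecule before
#'   censoring, \code{>= 1}.
#' @param force_range Length-2 ordered range of per-event mean load, pN
#'   (positive = resistive).
#' @param amp_range Length-2 ordered range of per-event sinusoidal amplitude,
#'   pN, non-negative.
#' @param min_detectable_duration Hard censoring threshold, s: simulated
#'   events shorter than this are dropped, as a detector needing at least a
#'   couple of oscillation cycles would do.
#' @param displacement_noise_sd SD of Gaussian noise added to the true step
#'   to form each event displacement, nm.
#' @param seed Integer seed, or \code{NULL} to use the current RNG state.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(true_params,
                       n_molecules = 10,
                       events_per_molecule = 300,
                       force_range = c(-5, 5),
                       amp_range = c(1, 4),
                       min_detectable_duration = 0.01,
                       displacement_noise_sd = 1,
                       seed = NULL) {
  stopifnot(inherits(true_params, "motor_params"))
  if (n_molecules < 1 || events_per_molecule < 1)
    stop("counts must be >= 1")
  if (min_detectable_duration < 0)
    stop("min_detectable_duration must be >= 0")
  if (length(force_range) != 2 || diff(force_range) < 0)
    stop("force_range must be an ordered length-2 range")
  if (length(amp_range) != 2 || diff(amp_range) < 0 || any(amp_range < 0))
    stop("amp_range must be an ordered, non-negative length-2 range")
  structure(list(true_params = true_params, n_molecules = n_molecules,
                 events_per_molecule = events_per_molecule,
                 force_range = force_range, amp_range = amp_range,
                 min_detectable_duration = min_detectable_duration,
                 displacement_noise_sd = displacement_noise_sd,
                 seed = seed),
            class = "sim_config")
}

#' Draw event dwell times under a sinusoidally modulated detachment hazard
#'
#' The instantaneous detachment hazard of a bound head under harmonic load is
#' \deqn{k(t) = k_0 \exp\{-\delta (F + \Delta F \cos(2\pi f t + \phi)) / k_B T\},}
#' whose average over one oscillation period is the Bessel-corrected closed
#' form of \code{\link{detachment_rate}}. Dwell times are drawn exactly from
#' this inhomogeneous-exponential survival law by thinning (rejection against
#' the constant envelope hazard \eqn{k_0 \exp(-\delta(F - \Delta F)/k_B T)}).
#'
#' Vectorized over events: \code{F}, \code{dF} and \code{phase} are recycled
#' to a common length and one dwell is drawn for each.
#'
#' @param F Mean load force(s), pN (positive = resistive).
#' @param dF Sinusoidal amplitude(s), pN, \code{>= 0}.
#' @param phase Oscillation phase(s) at the moment of binding, rad.
#' @param params A \code{\link{motor_params}} object.
#' @param consts A \code{\link{trap_constants}} object.
#' @return Numeric vector of dwell durations, s.
#' @export
sample_event_duration <- function(F, dF, phase, params,
                                  consts = trap_constants()) {
  stopifnot(inherits(params, "motor_params"))
  if (any(dF < 0)) stop("dF must be >= 0")
  f <- consts$oscillation_freq
  if (f <= 0) stop("oscillation frequency must be positive")
  n <- max(length(F), length(dF), length(phase))
  F <- rep_len(F, n); dF <- rep_len(dF, n); phase <- rep_len(phase, n)
  beta <- params$delta / consts$kBT
  k_env <- params$k0 * exp(-beta * (F - dF))   # hazard maximum (cos = -1)
  t <- numeric(n)
  pending <- rep(TRUE, n)
  while (any(pending)) {
    idx <- which(pending)
    t[idx] <- t[idx] + stats::rexp(length(idx), rate = k_env[idx])
    # acceptance probability k(t)/k_env = exp(-beta*dF*(cos(.) + 1)) <= 1
    acc <- exp(-beta * dF[idx] *
                 (cos(2 * pi * f * t[idx] + phase[idx]) + 1))
    accepted <- stats::runif(length(idx)) < acc
    pending[idx[accepted]] <- FALSE
  }
  t
}

#' Simulate a table of single-molecule interaction events
#'
#' For each event the mean load is drawn uniformly from
#' \code{cfg$force_range}, the sinusoidal amplitude uniformly from
#' \code{cfg$amp_range}, and the binding phase uniformly on \eqn{[0, 2\pi)}
#' (binding is stochastic relative to the stage oscillation). The dwell is
#' drawn from the time-varying hazard by \code{\link{sample_event_duration}};
#' events shorter than \code{cfg$min_detectable_duration} are dropped, the
#' censoring a real detector imposes. Displacements are the true step plus
#' Gaussian noise.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param consts A \code{\link{trap_constants}} object.
#' @return A data frame with columns \code{molecule_id}, \code{duration_s},
#'   \code{mean_force_pN}, \code{force_amp_pN}, \code{displacement_nm}.
#' @examples
#' cfg <- sim_config(motor_params(147, 1.04, step_d = 4.3),
#'                   n_molecules = 2, events_per_molecule = 50, seed = 1)
#' ev <- simulate_events(cfg)
#' head(ev)
#' @export
simulate_events <- function(cfg, consts = trap_constants()) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$true_params
  local_seed(cfg$seed, {
    out <- vector("list", cfg$n_molecules)
    for (m in seq_len(cfg$n_molecules)) {
      ne <- cfg$events_per_molecule
      F <- stats::runif(ne, cfg$force_range[1], cfg$force_range[2])
      dF <- stats::runif(ne, cfg$amp_range[1], cfg$amp_range[2])
      phase <- stats::runif(ne, 0, 2 * pi)
      dur <- sample_event_duration(F, dF, phase, p, consts)
      step <- if (is.null(p$step_d)) NA_real_ else
        p$step_d + stats::rnorm(ne, 0, cfg$displacement_noise_sd)
      keep <- dur >= cfg$min_detectable_duration
      out[[m]] <- data.frame(
        molecule_id = sprintf("mol%02d", m),
        duration_s = dur[keep],
        mean_force_pN = F[keep],
        force_amp_pN = dF[keep],
        displacement_nm = step[keep],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Render interaction events into a synthetic dumbbell position trace
#'
#' Builds a sampled two-bead position record of the kind a dual-beam trap
#' produces under stage oscillation. While unbound, both beads oscillate at
#' the stage frequency with the unbound baseline amplitude; while a myosin is
#' bound, the bead oscillation amplitude becomes
#' \code{force_amp / kappa_sys} (so that system stiffness times bound
#' amplitude recovers the sinusoidal force amplitude), its phase shifts, and
#' the mean position is offset by the event displacement. Gaussian position
#' noise is added throughout. \code{kappa_sys} is the sum of the two trap
#' stiffnesses.
#'
#' @param events Data frame with columns \code{start_time_s},
#'   \code{duration_s}, \code{mean_force_pN}, \code{force_amp_pN},
#'   \code{displacement_nm}; intervals must not overlap.
#' @param consts A \code{\link{trap_constants}} object.
#' @param t_total Trace length, s; defaults to the last event end plus 0.1 s.
#' @param noise_sd Position noise SD per sample, nm.
#' @param unbound_amplitude Baseline bead oscillation amplitude, nm.
#' @param bound_phase_shift Phase shift of the bead oscillation while bound,
#'   rad.
#' @param seed Integer seed or \code{NULL}.
#' @return An object of class \code{"trap_trace"}: a list with \code{time},
#'   \code{bead_A}, \code{bead_B}, \code{stage} (all nm, equal length,
#'   strictly increasing time), \code{consts}, and the \code{truth} event
#'   table.
#' @export
simulate_trace <- function(events, consts = trap_constants(),
                           t_total = NULL, noise_sd = 2,
                           unbound_amplitude = 25,
                           bound_phase_shift = 1.0,
                           seed = NULL) {
  req <- c("start_time_s", "duration_s", "mean_force_pN", "force_amp_pN",
           "displacement_nm")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop("events is missing column(s): ",
                         paste(miss, collapse = ", "))
  ev <- events[order(events$start_time_s), , drop = FALSE]
  end <- ev$start_time_s + ev$duration_s
  if (nrow(ev) > 1 && any(ev$start_time_s[-1] < end[-nrow(ev)]))
    stop("event intervals overlap")
  if (is.null(t_total))
    t_total <- if (nrow(ev)) max(end) + 0.1 else 1
  fs <- consts$sampling_rate
  f <- consts$oscillation_freq
  kappa_sys <- consts$trap_stiffness_A + consts$trap_stiffness_B
  time <- seq(0, t_total, by = 1 / fs)
  local_seed(seed, {
    stage <- unbound_amplitude * cos(2 * pi * f * time)
    amp <- rep(unbound_amplitude, length(time))
    offset <- numeric(length(time))
    ph <- numeric(length(time))
    if (nrow(ev)) {
      # per-sample event index via interval lookup on [start, end) boundaries
      bounds <- as.vector(rbind(ev$start_time_s, end))
      slot <- findInterval(time, bounds)
      in_ev <- slot %% 2L == 1L
      evi <- (slot[in_ev] + 1L) %/% 2L
      amp[in_ev] <- ev$force_amp_pN[evi] / kappa_sys
      offset[in_ev] <- ev$displacement_nm[evi]
      ph[in_ev] <- bound_phase_shift
    }
    clean <- offset + amp * cos(2 * pi * f * time + ph)
    bead_A <- clean + stats::rnorm(length(time), 0, noise_sd)
    bead_B <- clean + stats::rnorm(length(time), 0, noise_sd)
    structure(list(time = time, bead_A = bead_A, bead_B = bead_B,
                   stage = stage, consts = consts, truth = ev),
              class = "trap_trace")
  })
}

#' @export
print.trap_trace <- function(x, ...) {
  cat(sprintf("Trap trace: %.2f s at %g Hz (%d samples), %d truth events\n",
              max(x$time), x$consts$sampling_rate, length(x$time),
              if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}

#' Simulate a full trace-level harmonic-force-spectroscopy experiment
#'
#' Draws binding events for one molecule from \code{cfg} (uncensored: the
#' detector, not the generator, censors here), lays them out along the trace
#' separated by exponential unbound gaps, and renders the position record
#' with \code{\link{simulate_trace}}.
#'
#' The rendered bead mean offset during binding is taken as
#' \code{mean_force / kappa_sys}, so that the detector convention
#' force = stiffness x offset recovers the true event force; the trace-level
#' "displacement" is thus the load-bearing bead deflection (see the methods
#' vignette for why an uncoupled step size is not recoverable from single
#' events without ensemble averaging).
#'
#' @param cfg A \code{\link{sim_config}} (censoring is ignored here;
#'   \code{n_molecules} traces are produced when \code{molecule > 1}).
#' @param consts A \code{\link{trap_constants}} object.
#' @param gap_mean Mean unbound interval between events, s.
#' @param ... Passed to \code{\link{simulate_trace}} (noise, amplitudes).
#' @param seed Integer seed or \code{NULL}; overrides \code{cfg$seed}.
#' @return A list of \code{"trap_trace"} objects, one per molecule.
#' @export
simulate_hfs_trace <- function(cfg, consts = trap_constants(),
                               gap_mean = 0.05, ..., seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  kappa_sys <- consts$trap_stiffness_A + consts$trap_stiffness_B
  p <- cfg$true_params
  local_seed(seed, {
    lapply(seq_len(cfg$n_molecules), function(m) {
      ne <- cfg$events_per_molecule
      F <- stats::runif(ne, cfg$force_range[1], cfg$force_range[2])
      dF <- stats::runif(ne, cfg$amp_range[1], cfg$amp_range[2])
      phase <- stats::runif(ne, 0, 2 * pi)
      dur <- sample_event_duration(F, dF, phase, p, consts)
      gaps <- gap_mean / 2 + stats::rexp(ne, 1 / gap_mean)
      start <- cumsum(gaps) + c(0, cumsum(dur))[seq_len(ne)]
      ev <- data.frame(molecule_id = sprintf("mol%02d", m),
                       start_time_s = start, duration_s = dur,
                       mean_force_pN = F, force_amp_pN = dF,
                       displacement_nm = F / kappa_sys,
                       stringsAsFactors = FALSE)
      simulate_trace(ev, consts, t_total = max(start + dur) + 2 * gap_mean,
                     ...)
    })
  })
}

#' Simulate an actin-activated ATPase plate
#'
#' Michaelis-Menten mean rates with multiplicative lognormal replicate noise,
#' optionally planting gross outliers of the kind pipetting errors with
#' viscous actin produce (to exercise the triplicate rejection rule).
#'
#' @param kcat Maximal turnover rate, 1/s.
#' @param Kapp Apparent actin affinity, uM.
#' @param actin_uM Actin concentrations, uM (0 entries are basal wells and
#'   pass through un-modelled by the hyperbola: their mean is \code{basal}).
#' @param n_replicates Technical replicates per concentration.
#' @param noise_cv Coefficient of variation of the lognormal replicate noise.
#' @param basal Basal (actin-free) rate, 1/s.
#' @param n_outliers Number of planted outliers.
#' @param outlier_factor Multiplicative factor applied to planted outliers.
#' @param seed Integer seed or \code{NULL}.
#' @return Data frame with columns \code{actin_uM}, \code{replicate},
#'   \code{rate_per_s}, \code{is_planted_outlier}.
#' @export
simulate_atpase_plate <- function(kcat, Kapp,
                                  actin_uM = c(0, 2.5, 5, 10, 20, 30, 50, 80),
                                  n_replicates = 3, noise_cv = 0.05,
                                  basal = 0.03,
                                  n_outliers = 0, outlier_factor = 2.5,
                                  seed = NULL) {
  if (kcat <= 0 || Kapp <= 0) stop("kcat and Kapp must be positive")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  local_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        actin_uM = actin_uM)[, 2:1]
    mu <- ifelse(grid$actin_uM == 0, basal,
                 kcat * grid$actin_uM / (Kapp + grid$actin_uM))
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- if (noise_cv > 0)
      exp(stats::rnorm(nrow(grid), -sdlog^2 / 2, sdlog)) else 1
    grid$rate_per_s <- mu * noise
    grid$is_planted_outlier <- FALSE
    if (n_outliers > 0) {
      pick <- sample(which(grid$actin_uM > 0), n_outliers)
      grid$rate_per_s[pick] <- grid$rate_per_s[pick] * outlier_factor
      grid$is_planted_outlier[pick] <- TRUE
    }
    grid
  })
}

#' Simulate a single-ATP-turnover fluorescence decay
#'
#' Biexponential decay with plateau, Gaussian noise, and an instrument dead
#' time (the recorded times start at \code{dead_time}, as when the dead time
#' is added to the plate-reader clock). Defaults emulate a long-tailed
#' two-headed cardiac myosin: slow (super-relaxed) fraction 57 percent of the
#' decaying amplitude.
#'
#' @param amp_fast,rate_fast Fast (disordered-relaxed) amplitude and rate
#'   (a.u., 1/s).
#' @param amp_slow,rate_slow Slow (super-relaxed) amplitude and rate.
#' @param plateau Fluorescence plateau, a.u.
#' @param t_max Recording length, s.
#' @param dt Sampling interval, s.
#' @param dead_time Dead time between chase and first read, s.
#' @param noise_sd Additive Gaussian noise SD, a.u.
#' @param seed Integer seed or \code{NULL}.
#' @return Data frame with columns \code{time_s}, \code{fluorescence}; the
#'   true parameters (including the analytic percent slow) are attached as
#'   attribute \code{"truth"}.
#' @export
simulate_turnover_trace <- function(amp_fast = 0.43, rate_fast = 0.03,
                                    amp_slow = 0.57, rate_slow = 0.003,
                                    plateau = 0.05,
                                    t_max = 960, dt = 2, dead_time = 10,
                                    noise_sd = 0.005, seed = NULL) {
  if (any(c(amp_fast, amp_slow) < 0) || any(c(rate_fast, rate_slow) <= 0))
    stop("amplitudes must be >= 0 and rates > 0")
  if (rate_fast <= rate_slow) stop("rate_fast must exceed rate_slow")
  local_seed(seed, {
    t <- seq(dead_time, dead_time + t_max, by = dt)
    y <- amp_fast * exp(-rate_fast * t) + amp_slow * exp(-rate_slow * t) +
      plateau + stats::rnorm(length(t), 0, noise_sd)
    out <- data.frame(time_s = t, fluorescence = y)
    attr(out, "truth") <- list(
      amp_fast = amp_fast, rate_fast = rate_fast,
      amp_slow = amp_slow, rate_slow = rate_slow, plateau = plateau,
      percent_slow = 100 * amp_slow / (amp_fast + amp_slow))
    out
  })
}

#' Simulate a light-chain loading gel dilution series
#'
#' Linear integrated band density versus load for the heavy chain and both
#' light chains, with multiplicative noise and an optional saturated top load
#' on the heavy chain (its much higher molecular weight pushes the top of its
#' dilution series out of the linear range first).
#'
#' @param slope_hc Heavy-chain density per pmol, a.u.
#' @param ratio_elc,ratio_rlc True light-chain/heavy-chain slope ratios.
#' @param loads_pmol Loads of the dilution series, pmol.
#' @param noise_cv Multiplicative noise CV.
#' @param saturate_top If \code{TRUE}, the heavy-chain band at the highest
#'   load is attenuated by \code{sat_factor}.
#' @param sat_factor Attenuation factor for the saturated band.
#' @param seed Integer seed or \code{NULL}.
#' @return Data frame with columns \code{chain} (HC/ELC/RLC),
#'   \code{load_pmol}, \code{density}.
#' @export
simulate_gel_series <- function(slope_hc = 1000, ratio_elc = 0.19,
                                ratio_rlc = 0.11,
                                loads_pmol = c(10, 5, 3, 2, 1),
                                noise_cv = 0.02,
                                saturate_top = FALSE, sat_factor = 0.6,
                                seed = NULL) {
  if (slope_hc <= 0 || ratio_elc <= 0 || ratio_rlc <= 0)
    stop("slopes and ratios must be positive")
  local_seed(seed, {
    slopes <- c(HC = slope_hc, ELC = slope_hc * ratio_elc,
                RLC = slope_hc * ratio_rlc)
    sdlog <- sqrt(log(1 + noise_cv^2))
    out <- do.call(rbind, lapply(names(slopes), function(ch) {
      dens <- slopes[[ch]] * loads_pmol
      if (noise_cv > 0)
        dens <- dens * exp(stats::rnorm(length(dens), -sdlog^2 / 2, sdlog))
      if (saturate_top && ch == "HC")
        dens[which.max(loads_pmol)] <- dens[which.max(loads_pmol)] * sat_factor
      data.frame(chain = ch, load_pmol = loads_pmol, density = dens,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
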