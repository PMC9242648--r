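#' Detection settings for trace-level event recovery
#'
#' @param window Demodulation window, s; must cover at least two oscillation
#'   periods so amplitude and phase are well defined.
#' @param threshold_sigmas Entry threshold on the amplitude deviation from
#'   the unbound baseline, in robust baseline SDs.
#' @param min_event_duration Shortest reportable event, s. Defaults to the
#'   simulator's censoring threshold (two periods at 200 Hz) so truth and
#'   detection censor consistently.
#' @param hysteresis_fraction Exit threshold as a fraction of the entry
#'   threshold, in \code{[0, 1)}.
#' @param require_both_beads Require the amplitude deviation on both beads
#'   simultaneously (binding changes the oscillation of both traps).
#' @return An object of class \code{"detection_config"}.
#' @export
detection_config <- function(window = 0.01,
                             threshold_sigmas = 5,
                             min_event_duration = 0.01,
                             hysteresis_fraction = 0.5,
                             require_both_beads = TRUE) {
  if (window <= 0) stop("window must be positive")
  if (threshold_sigmas <= 0) stop("threshold_sigmas must be positive")
  if (hysteresis_fraction < 0 || hysteresis_fraction >= 1)
    stop("hysteresis_fraction must be in [0, 1)")
  structure(list(window = window, threshold_sigmas = threshold_sigmas,
                 min_event_duration = min_event_duration,
                 hysteresis_fraction = hysteresis_fraction,
                 require_both_beads = require_both_beads),
            class = "detection_config")
}

#' Sliding-window demodulation of bead oscillation at the stage frequency
#'
#' Projects each bead position onto in-phase and quadrature references at the
#' stage oscillation frequency over sliding windows (hop = window/2),
#' yielding the local oscillation amplitude and phase of each bead - the two
#' quantities whose change marks a myosin binding event.
#'
#' @param trace A \code{"trap_trace"} object.
#' @param window Window length, s; at least two oscillation periods.
#' @return A data frame of class \code{"demod_series"} with columns
#'   \code{time} (window centres), \code{amplitude_A}, \code{phase_A},
#'   \code{amplitude_B}, \code{phase_B}, \code{offset_A}, \code{offset_B}
#'   (window-mean positions, nm); window and hop attached as attributes.
#' @export
demodulate <- function(trace, window = 0.01) {
  stopifnot(inherits(trace, "trap_trace"))
  f <- trace$consts$oscillation_freq
  fs <- trace$consts$sampling_rate
  if (window < 2 / f) stop("window must cover at least 2 oscillation periods")
  nw <- max(2L, round(window * fs))
  hop <- max(1L, nw %/% 2L)
  n <- length(trace$time)
  if (n < nw) stop("trace shorter than one demodulation window")
  starts <- seq(1L, n - nw + 1L, by = hop)
  cref <- cos(2 * pi * f * trace$time)
  sref <- sin(2 * pi * f * trace$time)
  win_stats <- function(x) {
    # rolling sums via cumsum: projection of x on cos/sin over each window
    cs <- function(v) { s <- cumsum(v); c(s[nw], s[starts[-1] + nw - 1L] - s[starts[-1] - 1L]) }
    I <- 2 / nw * cs(x * cref)
    Q <- 2 / nw * cs(x * sref)
    mu <- cs(x) / nw
    list(amp = sqrt(I^2 + Q^2), phase = atan2(-Q, I), offset = mu)
  }
  a <- win_stats(trace$bead_A)
  b <- win_stats(trace$bead_B)
  out <- data.frame(time = trace$time[starts] + (nw - 1) / (2 * fs),
                    amplitude_A = a$amp, phase_A = a$phase,
                    amplitude_B = b$amp, phase_B = b$phase,
                    offset_A = a$offset, offset_B = b$offset)
  attr(out, "window") <- window
  attr(out, "hop_s") <- hop / fs
  class(out) <- c("demod_series", "data.frame")
  out
}

#' Recover interaction events from a dumbbell trace
#'
#' Binding events are maximal intervals where the bead oscillation amplitude
#' deviates from the unbound baseline by more than
#' \code{threshold_sigmas} robust SDs (exit by hysteresis at a fraction of
#' the entry threshold), lasting at least \code{min_event_duration}. The
#' baseline is the whole-trace median amplitude and its SD the scaled median
#' absolute deviation, both robust to the events themselves.
#'
#' Per event, with system stiffness \code{kappa_sys} the sum of the two trap
#' stiffnesses: duration from the refined threshold crossings; displacement
#' is the mean bead offset from the unbound mean position; mean force is
#' \code{kappa_sys} times that offset; the sinusoidal force amplitude is
#' \code{kappa_sys} times the bound oscillation amplitude (stiffness times
#' bead excursion is the force communicated to the bound head).
#'
#' @param trace A \code{"trap_trace"} object.
#' @param cfg A \code{\link{detection_config}}.
#' @param consts Trap constants; defaults to those embedded in the trace.
#' @return Data frame of detected events with columns \code{molecule_id},
#'   \code{start_time_s}, \code{duration_s}, \code{mean_force_pN},
#'   \code{force_amp_pN}, \code{displacement_nm}. A \code{bound_fraction}
#'   attribute is attached; traces bound more than 80 percent of the time
#'   (no usable unbound baseline) trigger a warning.
#' @export
detect_events <- function(trace, cfg = detection_config(),
                          consts = trace$consts) {
  stopifnot(inherits(trace, "trap_trace"), inherits(cfg, "detection_config"))
  dm <- demodulate(trace, cfg$window)
  hop <- attr(dm, "hop_s")
  kappa_sys <- consts$trap_stiffness_A + consts$trap_stiffness_B

  # sanity check: the unbound bead should oscillate like the stage. Windows
  # whose phasor sits far from the stage reference look bound; a trace made
  # almost entirely of such windows has no usable unbound baseline (the
  # median-phasor baseline below would be contaminated).
  stage_amp <- sqrt(2 * mean(trace$stage^2))
  bound_like <- sqrt((dm$amplitude_A * cos(dm$phase_A) - stage_amp)^2 +
                       (dm$amplitude_A * sin(dm$phase_A))^2) >
    0.3 * stage_amp
  if (mean(bound_like) > 0.8)
    warning("events appear to cover >80% of the trace; ",
            "no reliable unbound baseline")

  dev_of <- function(amp, phase) {
    # deviation of the complex oscillation phasor from its unbound baseline
    # (median phasor): captures amplitude and phase change together, and is
    # linear in the fraction of the window covered by an event, so
    # half-level crossings locate edges without bias
    zI <- amp * cos(phase); zQ <- amp * sin(phase)
    dz <- sqrt((zI - stats::median(zI))^2 + (zQ - stats::median(zQ))^2)
    sig <- stats::mad(dz, center = 0)
    if (!is.finite(sig) || sig <= 0) sig <- 1e-12
    dz / sig
  }
  dev_A <- dev_of(dm$amplitude_A, dm$phase_A)
  dev_B <- dev_of(dm$amplitude_B, dm$phase_B)
  dev <- if (cfg$require_both_beads) pmin(dev_A, dev_B) else pmax(dev_A, dev_B)

  hi <- cfg$threshold_sigmas
  lo <- hi * cfg$hysteresis_fraction
  state <- logical(length(dev))
  cur <- FALSE
  for (i in seq_along(dev)) {
    cur <- if (cur) dev[i] > lo else dev[i] > hi
    state[i] <- cur
  }
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts_i <- ends - r$lengths + 1L
  seg <- data.frame(i0 = starts_i[r$values], i1 = ends[r$values])

  bound_fraction <- mean(state)
  if (bound_fraction > 0.8)
    warning("events cover >80% of the trace; no reliable unbound baseline")

  # unbound reference level from raw samples outside detected segments
  mid <- (trace$bead_A + trace$bead_B) / 2
  if (nrow(seg)) {
    bounds <- as.vector(rbind(dm$time[seg$i0] - hop / 2,
                              dm$time[seg$i1] + hop / 2))
    in_event_sample <- findInterval(trace$time, bounds) %% 2L == 1L
  } else in_event_sample <- rep(FALSE, length(trace$time))
  base_pos <- if (any(!in_event_sample)) mean(mid[!in_event_sample]) else 0

  out <- data.frame(molecule_id = character(0), start_time_s = numeric(0),
                    duration_s = numeric(0), mean_force_pN = numeric(0),
                    force_amp_pN = numeric(0), displacement_nm = numeric(0),
                    stringsAsFactors = FALSE)
  half_cross <- function(i_edge, rising, target) {
    # bracket the half-level crossing of the dev ramp and interpolate: a step
    # change smeared by the rectangular demodulation window ramps linearly
    # through the true edge, so the half-level crossing locates the edge
    # without bias
    n <- length(dev)
    idx <- seq(max(1L, i_edge - 3L), min(n, i_edge + 3L))
    above <- idx[dev[idx] >= target]
    if (!length(above)) return(dm$time[i_edge])
    if (rising) {
      j <- min(above)
      if (j == 1L) return(dm$time[1L])
      j0 <- j - 1L; j1 <- j
    } else {
      j <- max(above)
      if (j == n) return(dm$time[n])
      j0 <- j; j1 <- j + 1L
    }
    if (dev[j1] == dev[j0]) return(dm$time[j])
    dm$time[j0] + (target - dev[j0]) * (dm$time[j1] - dm$time[j0]) /
      (dev[j1] - dev[j0])
  }
  floor_lvl <- stats::median(dev)
  for (j in seq_len(nrow(seg))) {
    seg_idx <- seq(seg$i0[j], seg$i1[j])
    lvl <- if (length(seg_idx) >= 3)
      stats::median(dev[seg_idx[-c(1, length(seg_idx))]])
    else max(dev[seg_idx])
    # two passes: edges from a provisional level, then the bound level
    # re-estimated from windows fully inside those edges (short events never
    # reach the plateau in edge-straddling windows), then final edges.
    # the noise floor lifts the dev ramp like a Rician magnitude, so aim at
    # the floor-corrected half level.
    for (pass in 1:2) {
      target <- sqrt((lvl / 2)^2 + floor_lvl^2)
      t0 <- half_cross(seg$i0[j], TRUE, target)
      t1 <- half_cross(seg$i1[j], FALSE, target)
      core <- which(dm$time >= t0 + cfg$window / 2 &
                      dm$time <= t1 - cfg$window / 2)
      if (!length(core))
        core <- seg_idx[which.min(abs(dm$time[seg_idx] - (t0 + t1) / 2))]
      lvl <- stats::median(dev[core])
    }
    dur <- t1 - t0
    if (dur < cfg$min_event_duration) next
    amp_bound <- mean((dm$amplitude_A[core] + dm$amplitude_B[core]) / 2)
    offset <- mean((dm$offset_A[core] + dm$offset_B[core]) / 2) - base_pos
    out <- rbind(out, data.frame(
      molecule_id = "trace", start_time_s = t0, duration_s = dur,
      mean_force_pN = kappa_sys * offset,
      force_amp_pN = kappa_sys * amp_bound,
      displacement_nm = offset, stringsAsFactors = FALSE))
  }
  attr(out, "bound_fraction") <- bound_fraction
  out
}
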