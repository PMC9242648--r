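#' Physical and instrument constants for a dual-beam trap experiment
#'
#' Bundles the thermal energy and the instrument settings that the
#' load-dependent detachment model and the trace simulator/detector need.
#' Defaults describe a typical dual-beam optical trap running harmonic force
#' spectroscopy: sample chamber at 23 degC, stage oscillating at 200 Hz, trap
#' stiffnesses in the 0.08-0.10 pN/nm range.
#'
#' @param temperature_C Sample temperature in degrees Celsius.
#' @param kBT Thermal energy in pN nm. Computed from \code{temperature_C}
#'   when \code{NULL}; if supplied it must agree with the temperature within
#'   0.1 percent.
#' @param oscillation_freq Stage oscillation frequency, Hz.
#' @param trap_stiffness_A,trap_stiffness_B Trap stiffnesses, pN/nm, each in
#'   (0, 1).
#' @param sampling_rate Position sampling rate, Hz. Must exceed ten times the
#'   oscillation frequency so the oscillation is well resolved.
#' @return An object of class \code{"trap_constants"}.
#' @examples
#' tc <- trap_constants()
#' tc$kBT   # ~4.0888 pN nm at 23 degC
#' @export
trap_constants <- function(temperature_C = 23,
                           kBT = NULL,
                           oscillation_freq = 200,
                           trap_stiffness_A = 0.09,
                           trap_stiffness_B = 0.09,
                           sampling_rate = 5000) {
  kB <- 1.380649e-2  # pN nm / K
  kBT_expected <- kB * (temperature_C + 273.15)
  if (is.null(kBT)) kBT <- kBT_expected
  if (kBT <= 0) stop("kBT must be positive")
  if (abs(kBT - kBT_expected) / kBT_expected > 1e-3)
    stop("kBT inconsistent with temperature_C (must agree within 0.1%)")
  if (oscillation_freq <= 0) stop("oscillation_freq must be positive")
  if (oscillation_freq >= sampling_rate / 10)
    stop("oscillation_freq must be below sampling_rate/10")
  for (k in c(trap_stiffness_A, trap_stiffness_B))
    if (k <= 0 || k >= 1) stop("trap stiffnesses must lie in (0, 1) pN/nm")
  structure(list(kBT = kBT,
                 temperature_C = temperature_C,
                 oscillation_freq = oscillation_freq,
                 trap_stiffness_A = trap_stiffness_A,
                 trap_stiffness_B = trap_stiffness_B,
                 sampling_rate = sampling_rate),
            class = "trap_constants")
}

#' @export
print.trap_constants <- function(x, ...) {
  cat("Trap constants:\n")
  cat(sprintf("  kBT            %.4f pN nm (%g degC)\n", x$kBT, x$temperature_C))
  cat(sprintf("  oscillation    %g Hz\n", x$oscillation_freq))
  cat(sprintf("  stiffness A/B  %.3f / %.3f pN/nm\n",
              x$trap_stiffness_A, x$trap_stiffness_B))
  cat(sprintf("  sampling rate  %g Hz\n", x$sampling_rate))
  invisible(x)
}

#' Kinetic parameters of a single myosin motor
#'
#' @param k0 Detachment rate at zero load, 1/s.
#' @param delta Force-sensitivity distance parameter, nm.
#' @param kcat Actin-activated maximal turnover rate, 1/s (optional; required
#'   for duty-ratio work and must then satisfy \code{kcat < k0}).
#' @param step_d Working-stroke (step) size, nm. Non-positive values are
#'   allowed but flagged with a warning.
#' @param sem_k0,sem_delta,sem_kcat,sd_step Uncertainties in matching units
#'   (SEMs across molecules for the rates and delta, SD for the step).
#' @return An object of class \code{"motor_params"}.
#' @examples
#' wt <- motor_params(k0 = 147.0, delta = 1.04, kcat = 5, step_d = 4.3)
#' @export
motor_params <- function(k0, delta, kcat = NULL, step_d = NULL,
                         sem_k0 = NA_real_, sem_delta = NA_real_,
                         sem_kcat = NA_real_, sd_step = NA_real_) {
  if (!is.numeric(k0) || k0 <= 0) stop("k0 must be positive")
  if (!is.numeric(delta) || delta < 0) stop("delta must be >= 0")
  if (!is.null(kcat)) {
    if (kcat <= 0) stop("kcat must be positive")
    if (kcat >= k0)
      stop("kcat must be < k0: the attachment rate 1/(1/kcat - 1/k0) ",
           "and the duty ratio are otherwise ill-defined")
  }
  if (!is.null(step_d) && step_d <= 0)
    warning("step_d <= 0 nm; check sign conventions")
  structure(list(k0 = k0, delta = delta, kcat = kcat, step_d = step_d,
                 sem_k0 = sem_k0, sem_delta = sem_delta,
                 sem_kcat = sem_kcat, sd_step = sd_step),
            class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  fmt <- function(v, se, unit) {
    if (is.null(v)) return("--")
    if (is.na(se)) sprintf("%.4g %s", v, unit)
    else sprintf("%.4g +/- %.3g %s", v, se, unit)
  }
  cat("Motor parameters:\n")
  cat("  k0    ", fmt(x$k0, x$sem_k0, "1/s"), "\n")
  cat("  delta ", fmt(x$delta, x$sem_delta, "nm"), "\n")
  cat("  kcat  ", fmt(x$kcat, x$sem_kcat, "1/s"), "\n")
  cat("  step  ", fmt(x$step_d, x$sd_step, "nm"), "\n")
  invisible(x)
}

#' Serialize / deserialize motor parameters as flat JSON
#'
#' Uses unit-suffixed keys (\code{k0_per_s}, \code{delta_nm}, \code{kcat_per_s},
#' \code{step_nm}, plus \code{*_sem} / \code{step_sd} uncertainty fields).
#'
#' @param params A \code{motor_params} object.
#' @param path File path.
#' @return \code{write_motor_params} returns \code{path} invisibly;
#'   \code{read_motor_params} returns a \code{motor_params} object.
#' @export
write_motor_params <- function(params, path) {
  stopifnot(inherits(params, "motor_params"))
  x <- list(k0_per_s = params$k0, delta_nm = params$delta,
            kcat_per_s = params$kcat, step_nm = params$step_d,
            k0_sem = params$sem_k0, delta_sem = params$sem_delta,
            kcat_sem = params$sem_kcat, step_sd = params$sd_step)
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_motor_params
#' @export
read_motor_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_or <- function(v, default) if (is.null(v) || length(v) == 0 || is.na(v)) default else as.numeric(v)
  motor_params(k0 = as.numeric(x$k0_per_s), delta = as.numeric(x$delta_nm),
               kcat = if (is.null(x$kcat_per_s)) NULL else as.numeric(x$kcat_per_s),
               step_d = if (is.null(x$step_nm)) NULL else as.numeric(x$step_nm),
               sem_k0 = num_or(x$k0_sem, NA_real_),
               sem_delta = num_or(x$delta_sem, NA_real_),
               sem_kcat = num_or(x$kcat_sem, NA_real_),
               sd_step = num_or(x$step_sd, NA_real_))
}

#' Modified Bessel function of the first kind, order zero
#'
#' Thin wrapper around \code{\link[base]{besselI}} used by the sinusoidal-load
#' correction of the detachment-rate model. Defined for all reals by symmetry,
#' I0(-x) = I0(x).
#'
#' @param x Numeric vector, dimensionless argument.
#' @return I0(x), same length as \code{x}.
#' @examples
#' bessel_i0(0)    # 1
#' bessel_i0(1)    # 1.266066
#' @export
bessel_i0 <- function(x) besselI(abs(x), nu = 0)

#' Load-dependent actin detachment rate under harmonic force
#'
#' The detachment rate of a myosin head experiencing a mean load \code{F} plus
#' a sinusoidal load of amplitude \code{dF} is modelled as a Bell/Arrhenius
#' exponential in the mean load, corrected for the oscillation by a zero-order
#' modified Bessel factor:
#' \deqn{k_{det}(F, \Delta F) = k_0 \, I_0(\Delta F \delta / k_B T)\,
#'       \exp(-F \delta / k_B T).}
#' Positive \code{F} is resistive (opposing the working stroke), so the rate
#' decreases with resistive load and increases with assistive load.
#'
#' @param F Mean load force, pN (positive = resistive). Vectorized.
#' @param dF Sinusoidal force amplitude, pN, \code{>= 0}. Vectorized.
#' @param params A \code{\link{motor_params}} object (uses \code{k0},
#'   \code{delta}).
#' @param consts A \code{\link{trap_constants}} object (uses \code{kBT}).
#' @return Detachment rate(s), 1/s.
#' @examples
#' wt <- motor_params(k0 = 147, delta = 1.04)
#' tc <- trap_constants()
#' detachment_rate(2, 0, wt, tc)   # 88.4 1/s
#' detachment_rate(2, 2, wt, tc)   # 94.2 1/s
#' @export
detachment_rate <- function(F, dF, params, consts = trap_constants()) {
  stopifnot(inherits(params, "motor_params"))
  if (any(dF < 0)) stop("dF must be >= 0")
  params$k0 * bessel_i0(dF * params$delta / consts$kBT) *
    exp(-F * params$delta / consts$kBT)
}

#' Force-independent attachment rate from turnover and detachment rates
#'
#' With total cycle time 1/kcat partitioned into attached time 1/k0 and
#' detached time 1/k_attach, the attachment rate is the harmonic difference
#' \deqn{k_{attach} = \left(1/k_{cat} - 1/k_0\right)^{-1}.}
#'
#' @param kcat Actin-activated maximal turnover rate, 1/s.
#' @param k0 Detachment rate at zero load, 1/s. Must exceed \code{kcat}.
#' @return Attachment rate, 1/s.
#' @examples
#' attachment_rate(5, 147)   # 5.176 1/s
#' @export
attachment_rate <- function(kcat, k0) {
  if (any(kcat <= 0) || any(k0 <= 0)) stop("rates must be positive")
  if (any(kcat >= k0))
    stop("kcat must be < k0; attachment rate is otherwise ill-defined")
  1 / (1 / kcat - 1 / k0)
}
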