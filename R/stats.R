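.t_wrap <- function(x, y, paired, var.equal) {
  # degenerate inputs (zero variance throughout) are reported as no effect
  degenerate <- if (paired) stats::var(x - y) == 0
                else stats::var(x) == 0 && stats::var(y) == 0 &&
                     mean(x) == mean(y)
  if (degenerate) {
    df <- if (paired) length(x) - 1 else length(x) + length(y) - 2
    return(c(t = 0, df = df, p = 1))
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = var.equal)
  c(t = unname(tt$statistic), df = unname(tt$parameter),
    p = unname(tt$p.value))
}

#' Paired and two-sample t tests
#'
#' Thin wrappers over \code{\link[stats]{t.test}} with the conventions used
#' throughout this package: \code{paired_t_test} for matched same-day
#' control designs, \code{welch_t_test} for unequal-variance group
#' comparisons (Welch-Satterthwaite df), \code{pooled_t_test} for the
#' classical equal-variance test. Degenerate zero-variance identical inputs
#' return \code{t = 0, p = 1} rather than an error.
#'
#' @param x,y Numeric vectors (equal length for the paired test; length
#'   \code{>= 2} each otherwise).
#' @return Named vector \code{c(t =, df =, p =)} (two-sided p).
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired test needs equal-length vectors")
  if (length(x) < 2) stop("need >= 2 pairs")
  .t_wrap(x, y, paired = TRUE, var.equal = FALSE)
}

#' @rdname paired_t_test
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  .t_wrap(x, y, paired = FALSE, var.equal = FALSE)
}

#' @rdname paired_t_test
#' @export
pooled_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  .t_wrap(x, y, paired = FALSE, var.equal = TRUE)
}
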