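#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)`, with the sample (n-1) standard deviation.
#' The n-1 convention is used for every CV in the package: replicate CVs,
#' the t0-reference CV, and interassay CVs.
#'
#' @param x Numeric vector, length >= 2, with a nonzero mean.
#' @return CV in percent.
#' @export
#' @examples
#' cv_pct(c(8.5, 10, 11.5)) # 15
cv_pct <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

#' Round half away from zero
#'
#' R's `round()` rounds half to even; tabulated percentages here use the
#' conventional half-up rule (2.5 -> 3).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Multiplicative lognormal noise with mean exactly 1 and the given CV.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# Lognormal draws with the given arithmetic mean and CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  mean * rlnorm_cv(n, cv)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
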