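#' Power-formula factor f(alpha, P)
#'
#' The normal-approximation factor for a two-group comparison,
#' `f = (z_{1 - alpha/2} + z_P)^2` with standard normal quantiles; 10.5 (to
#' one decimal) for alpha = 0.05 and power 0.90. Computed from quantiles, so
#' arbitrary levels are supported.
#'
#' @param alpha two-sided significance level, in (0, 1).
#' @param power target power, in (0, 1).
#' @return the unrounded factor.
#' @export
factor_f <- function(alpha, power) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(power) || power <= 0 || power >= 1)
    stop("power must be in (0, 1)")
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2
}

#' Required sample size per group
#'
#' `n = ceil(f(alpha, P) * sigma^2 * 2 / delta^2)`, where `sigma` is the
#' standard deviation of the inter-test differences and `delta` the
#' magnitude of the difference to detect. The unrounded factor is used, and
#' the result is rounded up to an integer (minimum 1).
#'
#' @param sigma SD of inter-test differences (same units as `delta`).
#' @param delta difference to detect (> 0).
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.90).
#' @return integer sample size per group.
#' @export
required_n <- function(sigma, delta, alpha = 0.05, power = 0.90) {
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (!is.numeric(delta) || delta <= 0) stop("delta must be > 0")
  n <- ceiling(factor_f(alpha, power) * sigma^2 * 2 / delta^2)
  max(1L, as.integer(n))
}

#' Percent sample-size reduction against published values
#'
#' @param n_this sample size achieved here (>= 1).
#' @param n_published vector of published sample sizes (>= 1).
#' @return integer percent reductions, `round(100 * (n_pub - n_this) /
#'   n_pub)`, named after `n_published` if it has names.
#' @export
modality_comparison <- function(n_this, n_published) {
  stopifnot(n_this >= 1, all(n_published >= 1))
  out <- round(100 * (n_published - n_this) / n_published)
  names(out) <- names(n_published)
  out
}

#' Sample-size table from measured limits of agreement
#'
#' Converts LoA half-widths to inter-test difference SDs (`sigma =
#' halfwidth / 1.96`) and tabulates the required per-group sample size for
#' each condition.
#'
#' @param loa_halfwidths named numeric vector of LoA half-widths (deg/cm).
#' @param delta difference to detect (deg/cm).
#' @param alpha,power as in [required_n()].
#' @return data.frame with `condition`, `loa_halfwidth`, `sigma`, `n`.
#' @export
sample_size_table <- function(loa_halfwidths, delta, alpha = 0.05, power = 0.90) {
  sigma <- loa_halfwidths / 1.96
  data.frame(
    condition = names(loa_halfwidths) %||% seq_along(loa_halfwidths),
    loa_halfwidth = as.numeric(loa_halfwidths),
    sigma = as.numeric(sigma),
    n = vapply(sigma, required_n, integer(1), delta = delta,
               alpha = alpha, power = power),
    row.names = NULL
  )
}
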