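#' Wrap phase values to the half-open interval [-pi, pi)
#'
#' The wrapping convention is half-open: an input of exactly `pi` maps to
#' `-pi`. This mirrors the two's-complement-like convention of phase images
#' produced by displacement-encoded sequences.
#'
#' @param x numeric vector/array of phase values in radians.
#' @return values congruent to `x` modulo `2*pi`, in `[-pi, pi)`.
#' @export
wrap_to_pi <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the previous global RNG state so
#' simulation functions are deterministic under a given seed without
#' perturbing the caller's random stream.
#'
#' @param seed integer seed, or NULL to run `code` with the current stream.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic 31-bit substream seed derived from a master seed and a tag,
# so independent pipeline stages can be re-run in isolation.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 0
  m <- 2147480009  # largest prime below 2^31 - 3500
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

# Truncated normal sampler (rejection; acceptance is high for the widths used
# here). sd = 0 degenerates to the clamped mean.
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(n >= 0, lower <= upper)
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0)
  tries <- 0
  while (length(out) < n && tries < 1000) {
    x <- stats::rnorm(2 * n + 10, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
    tries <- tries + 1
  }
  if (length(out) < n) {
    # pathological window: fall back to inverse-CDF sampling
    pl <- stats::pnorm(lower, mean, sd)
    pu <- stats::pnorm(upper, mean, sd)
    out <- c(out, stats::qnorm(stats::runif(n - length(out), pl, pu), mean, sd))
  }
  out[seq_len(n)]
}

# Connected component of a logical matrix containing (row, col), 4-connected.
# Iterative dilation intersected with the region; grids here are small.
connected_component <- function(region, row, col) {
  stopifnot(isTRUE(region[row, col]))
  nr <- nrow(region); nc <- ncol(region)
  comp <- matrix(FALSE, nr, nc)
  comp[row, col] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -nc]
    grown[, -nc] <- grown[, -nc] | comp[, -1]
    grown <- grown & region
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# Short deterministic hash of an R object (provenance stamping in reports).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  m <- 2147480009
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% m
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
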