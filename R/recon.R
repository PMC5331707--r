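#' Reconstruction parameters
#'
#' @param smooth_sd_px Gaussian spatial smoothing SD, pixels (0 disables).
#' @param fit_order polynomial order of the through-zero temporal fit.
#' @return list of class `recon_params`.
#' @export
recon_params <- function(smooth_sd_px = 1.0, fit_order = 4L) {
  stopifnot(smooth_sd_px >= 0, fit_order >= 1, fit_order == round(fit_order))
  structure(list(smooth_sd_px = smooth_sd_px, fit_order = as.integer(fit_order)),
            class = "recon_params")
}

# Quality map for path-following: negative variance of the wrapped phase
# gradients to the 4 masked neighbors. Smooth regions unwrap first; noisy or
# aliased regions last, so errors cannot propagate into clean tissue.
unwrap_quality <- function(wrapped, mask) {
  nr <- nrow(wrapped); nc <- ncol(wrapped)
  shift <- function(m, dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr); cs <- seq_len(nc)
    out[rs[rs + dr >= 1 & rs + dr <= nr], cs[cs + dc >= 1 & cs + dc <= nc]] <-
      m[rs[rs + dr >= 1 & rs + dr <= nr] + dr, cs[cs + dc >= 1 & cs + dc <= nc] + dc]
    out
  }
  w <- wrapped; w[!mask] <- NA_real_
  ds <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  s1 <- s2 <- cnt <- matrix(0, nr, nc)
  for (i in 1:4) {
    g <- shift(w, ds[[i]][1], ds[[i]][2]) - w
    g <- g - 2 * pi * round(g / (2 * pi))  # fast wrap; boundary convention irrelevant here
    ok <- !is.na(g)
    g[!ok] <- 0
    s1 <- s1 + g
    s2 <- s2 + g^2
    cnt <- cnt + ok
  }
  v <- matrix(0, nr, nc)
  n2 <- cnt >= 2
  v[n2] <- (s2[n2] - s1[n2]^2 / cnt[n2]) / (cnt[n2] - 1)
  -v
}

#' Unwrap a wrapped phase image by quality-guided region growing
#'
#' Path-following unwrapping: starting from a seed pixel, pixels are visited
#' in order of decreasing quality (negative local variance of wrapped phase
#' gradients); each pixel's value is its wrapped value plus the multiple of
#' `2*pi` that brings it within `pi` of the mean of its already-unwrapped
#' 4-neighbors. On fields whose true neighboring-pixel phase differences are
#' below `pi`, the result equals the true phase up to one global `2*pi*m`
#' constant.
#'
#' @param wrapped wrapped phase matrix, values in `[-pi, pi)`.
#' @param mask logical matrix; only masked pixels are unwrapped.
#' @param seed_point integer `c(row, col)` inside the mask. Default: the
#'   masked pixel of maximum `quality`.
#' @param quality optional quality matrix; computed from `wrapped` if `NULL`.
#' @return matrix of unwrapped phase; mask pixels not 4-connected to the seed
#'   are `NA` (with a warning and attribute `n_unreachable`).
#' @export
unwrap_phase <- function(wrapped, mask, seed_point = NULL, quality = NULL) {
  stopifnot(is.matrix(wrapped), identical(dim(wrapped), dim(mask)))
  if (!any(mask)) stop("empty mask")
  if (is.null(quality)) quality <- unwrap_quality(wrapped, mask)
  if (is.null(seed_point)) {
    q <- quality; q[!mask] <- -Inf
    i <- which.max(q)
    seed_point <- c((i - 1) %% nrow(wrapped) + 1, (i - 1) %/% nrow(wrapped) + 1)
  }
  sr <- as.integer(seed_point[1]); sc <- as.integer(seed_point[2])
  if (sr < 1 || sr > nrow(mask) || sc < 1 || sc > ncol(mask) || !mask[sr, sc])
    stop("seed point outside mask")
  res <- .unwrap_region_grow(wrapped, mask, quality, sr - 1L, sc - 1L)
  out <- res$unwrapped
  unreachable <- sum(mask & !res$visited)
  if (unreachable > 0) {
    warning(sprintf("%d mask pixel(s) not reachable from the seed were excluded",
                    unreachable))
  }
  attr(out, "n_unreachable") <- unreachable
  out
}

#' Convert unwrapped phase to displacement
#'
#' Inverts the displacement encoding `phase = 2*pi*k*u`. Because unwrapping
#' only determines phase up to a global `2*pi` constant, the constant is
#' resolved by choosing, among shifts `m` in `{-1, 0, 1}` wraps, the one that
#' minimizes the magnitude of the spatial median displacement (bulk
#' myocardial displacement is small compared with one encoding period).
#'
#' @param phase unwrapped phase matrix or vector (radians; NA allowed).
#' @param k encoding frequency, cycles/mm.
#' @param resolve_offset apply the global-offset rule (default TRUE).
#' @return displacement in mm, same shape as `phase`.
#' @export
phase_to_displacement <- function(phase, k, resolve_offset = TRUE) {
  stopifnot(k > 0)
  u <- phase / (2 * pi * k)
  if (resolve_offset) {
    med <- stats::median(u, na.rm = TRUE)
    if (is.finite(med)) {
      m <- (-1):1
      u <- u + m[which.min(abs(med + m / k))] / k
    }
  }
  u
}

#' Mask-restricted Gaussian spatial smoothing
#'
#' Each masked value is replaced by a Gaussian-weighted average of masked
#' values only, with weights renormalized at mask edges. A kernel SD of 0 is
#' the identity.
#'
#' @param values numeric vector of per-point values, or a matrix of values on
#'   the full grid (then `mask` selects the points).
#' @param coords two-column matrix of point coordinates in pixels (rows match
#'   `values` when `values` is a vector).
#' @param kernel_sd_px Gaussian SD in pixels.
#' @param weights optional precomputed normalized weight matrix from
#'   [smoothing_weights()].
#' @return smoothed vector of per-point values.
#' @export
spatial_smooth <- function(values, coords, kernel_sd_px, weights = NULL) {
  stopifnot(kernel_sd_px >= 0)
  if (kernel_sd_px == 0 && is.null(weights)) return(values)
  if (is.null(weights)) weights <- smoothing_weights(coords, kernel_sd_px)
  as.numeric(weights %*% values)
}

#' Precompute normalized Gaussian smoothing weights for a point set
#'
#' @param coords two-column matrix of pixel coordinates.
#' @param kernel_sd_px Gaussian SD in pixels; 0 gives the identity matrix.
#' @return row-normalized dense weight matrix.
#' @export
smoothing_weights <- function(coords, kernel_sd_px) {
  n <- nrow(coords)
  if (kernel_sd_px == 0) return(diag(n))
  d2 <- outer(coords[, 1], coords[, 1], "-")^2 +
        outer(coords[, 2], coords[, 2], "-")^2
  w <- exp(-d2 / (2 * kernel_sd_px^2))
  w[d2 > (4 * kernel_sd_px)^2] <- 0  # truncate far tail
  w / rowSums(w)
}

#' Least-squares temporal fit constrained through zero at the first frame
#'
#' Fits each column of a frames-by-points matrix to a polynomial in time with
#' no intercept (basis `t, t^2, ..., t^order`), so the fitted trajectory is
#' exactly zero at the end-diastolic reference frame.
#'
#' @param series numeric matrix, frames x points (or a vector for one point).
#' @param times frame times (first must be 0).
#' @param order polynomial order; must be `< length(times)`.
#' @return fitted values at `times`, same shape as `series`.
#' @export
temporal_fit <- function(series, times, order = 4L) {
  vec <- is.null(dim(series))
  if (vec) series <- matrix(series, ncol = 1)
  nf <- nrow(series)
  stopifnot(length(times) == nf, times[1] == 0)
  if (order >= nf) stop("basis order must be smaller than the number of frames")
  tn <- times / max(times)
  B <- outer(tn, seq_len(order), "^")
  coef <- qr.coef(qr(B), series)
  fitted <- B %*% coef
  if (vec) as.numeric(fitted) else fitted
}

#' Reconstruct displacement trajectories from one slice acquisition
#'
#' Runs the full per-slice chain: per-frame quality-guided phase unwrapping
#' of both encoding directions (automatic seed at the masked pixel of
#' maximum magnitude), phase-to-displacement conversion with global offset
#' resolution, mask-restricted spatial smoothing, and a through-zero
#' polynomial temporal fit.
#'
#' @param acq a `slice_acquisition`.
#' @param params a [recon_params()].
#' @return an object of class `displacement_trajectories` with per-point
#'   end-diastolic positions `x0`, `y0` (mm) and frames-by-points
#'   displacement matrices `ux`, `uy` (mm).
#' @export
build_trajectories <- function(acq, params = recon_params()) {
  stopifnot(inherits(acq, "slice_acquisition"))
  mask <- acq$myocardial_mask
  nf <- dim(acq$phase_x)[3]
  # automatic seed: masked pixel with maximum magnitude intensity
  mag <- acq$magnitude[, , 1]
  mag[!mask] <- -Inf
  i <- which.max(mag)
  seed_pt <- c((i - 1) %% nrow(mask) + 1, (i - 1) %/% nrow(mask) + 1)
  # restrict to the mask component reachable from the seed
  comp <- connected_component(mask, seed_pt[1], seed_pt[2])
  dropped <- sum(mask & !comp)
  if (dropped > 0)
    warning(sprintf("%d mask pixel(s) disconnected from the seed were excluded",
                    dropped))
  pts <- which(comp)
  rows <- (pts - 1) %% nrow(mask) + 1
  cols <- (pts - 1) %/% nrow(mask) + 1
  coords_px <- cbind(rows, cols)
  W <- if (params$smooth_sd_px > 0)
    smoothing_weights(coords_px, params$smooth_sd_px) else NULL
  m <- length(pts)
  ux <- matrix(0, nf, m)
  uy <- matrix(0, nf, m)
  for (f in seq_len(nf)) {
    for (dir in c("x", "y")) {
      ph <- if (dir == "x") acq$phase_x[, , f] else acq$phase_y[, , f]
      unw <- unwrap_phase(ph, comp, seed_point = seed_pt)
      u2d <- phase_to_displacement(unw, acq$k)
      u <- u2d[pts]
      if (!is.null(W)) u <- as.numeric(W %*% u)
      if (dir == "x") ux[f, ] <- u else uy[f, ] <- u
    }
  }
  times <- acq$frame_times
  ux <- temporal_fit(ux, times, params$fit_order)
  uy <- temporal_fit(uy, times, params$fit_order)
  g <- nrow(mask)
  coord <- (seq_len(g) - 1 - (g - 1) / 2) * acq$pixel_spacing
  structure(list(
    x0 = coord[cols], y0 = coord[rows],
    ux = ux, uy = uy,
    frame_times = times,
    mask = comp,
    pixel_spacing = acq$pixel_spacing,
    plane_position = acq$plane_position,
    slice_label = acq$slice_label,
    acquisition_index = acq$acquisition_index,
    subject_id = acq$subject_id
  ), class = "displacement_trajectories")
}

#' @export
print.displacement_trajectories <- function(x, ...) {
  cat(sprintf("<displacement_trajectories> %s slice, %d points x %d frames, plane %.1f mm\n",
              x$slice_label, length(x$x0), nrow(x$ux), x$plane_position))
  invisible(x)
}
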