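#' Find strong pixels
#'
#' Scans an image stack for pixels recording strictly more than `threshold`
#' photons.  These are candidate Bragg-peak pixels used to fit the
#' ellipsoidal peak shape; masked pixels are excluded.
#'
#' @param images 3D array of counts, dimensions (frame, slow, fast).
#' @param threshold Count threshold (> 0); pixels with counts strictly
#'   greater are returned.
#' @param mask Optional logical array, TRUE for masked pixels.
#' @return data.frame with columns `frame`, `x` (slow), `y` (fast), `count`.
#' @export
find_strong_pixels <- function(images, threshold, mask = NULL) {
  if (threshold <= 0) stop("threshold must be > 0")
  images <- as.array(images)
  sel <- images > threshold
  if (!is.null(mask)) sel <- sel & !as.logical(mask)
  w <- which(sel, arr.ind = TRUE)
  out <- data.frame(frame = w[, 1], x = w[, 2], y = w[, 3],
                    count = images[w])
  rownames(out) <- NULL
  out
}

#' Wrap fractional Miller offsets
#'
#' Offset of fractional Miller indices from the nearest integer triple,
#' with each component wrapped into `[-0.5, 0.5)` so that peaks near cell
#' boundaries are handled.
#'
#' @param hkl Fractional Miller indices (vector or n x 3 matrix).
#' @return n x 3 matrix of wrapped offsets.
#' @export
wrap_delta_hkl <- function(hkl) {
  h <- as_hkl_matrix(hkl)
  h - floor(h + 0.5)
}

#' Fit the ellipsoidal Gaussian peak shape
#'
#' Fits a single trivariate Gaussian (mean and sample covariance) to the
#' point cloud of wrapped fractional offsets of strong pixels from their
#' nearest Bragg node.  One global shape is fitted per sweep.
#'
#' @param delta_hkl n x 3 matrix of fractional offsets; components are
#'   wrapped into `[-0.5, 0.5)` before fitting.
#' @param min_points Minimum number of points required (default 10).
#' @return Object of class `peak_shape` with fields `mean`, `covariance`,
#'   `n_points`.
#' @export
fit_peak_shape <- function(delta_hkl, min_points = 10) {
  d <- wrap_delta_hkl(delta_hkl)
  if (nrow(d) < min_points)
    stop("need at least ", min_points, " strong pixels to fit the peak shape")
  mu <- colMeans(d)
  S <- stats::cov(d)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12 || min(ev) <= 0)
    stop("peak-shape covariance is rank deficient; point cloud is degenerate")
  structure(list(mean = mu, covariance = S, n_points = nrow(d)),
            class = "peak_shape")
}

#' @export
print.peak_shape <- function(x, ...) {
  cat(sprintf("peak_shape fitted to %d points; sd per axis: %s (fractional hkl)\n",
              x$n_points,
              paste(signif(sqrt(diag(x$covariance)), 3), collapse = ", ")))
  invisible(x)
}

#' Build the Bragg-peak ellipsoid mask
#'
#' Thresholds the fitted Gaussian at `n_sigma` standard deviations: a
#' location with wrapped offset `delta` from its nearest integer node is
#' masked iff its Mahalanobis distance from the fitted mean is `<= n_sigma`.
#' The mask applies at every predicted Bragg node regardless of intensity.
#'
#' @param shape A [fit_peak_shape()] result.
#' @param n_sigma Cutoff in standard deviations (> 0, default 3).
#' @return Object of class `peak_mask` with predicate functions
#'   `is_masked(hkl)` (per pixel, takes fractional hkl) and
#'   `voxel_masked(v, grid)` (per voxel index).
#' @export
build_peak_mask <- function(shape, n_sigma = 3) {
  if (n_sigma <= 0) stop("n_sigma must be > 0")
  Sinv <- solve(shape$covariance)
  mu <- shape$mean
  lim <- n_sigma^2
  is_masked <- function(hkl) {
    d <- wrap_delta_hkl(hkl)
    stats::mahalanobis(d, mu, Sinv, inverted = TRUE) <= lim
  }
  voxel_masked <- function(v, grid) is_masked(voxel_center(v, grid))
  structure(list(shape = shape, n_sigma = n_sigma, is_masked = is_masked,
                 voxel_masked = voxel_masked), class = "peak_mask")
}

#' Flag strong pixels not explained by any Bragg ellipsoid
#'
#' Strong pixels lying outside every peak ellipsoid cannot be Bragg
#' diffraction (they may be broken pixels or salt-crystal spots) and are
#' flagged as outliers to be excluded from integration.
#'
#' @param hkl Fractional Miller indices of the strong pixels (n x 3).
#' @param mask A [build_peak_mask()] result.
#' @return Logical vector, TRUE for outliers.
#' @export
flag_outliers <- function(hkl, mask) {
  if (length(hkl) == 0 || (is.matrix(hkl) && nrow(hkl) == 0))
    return(logical(0))
  !mask$is_masked(hkl)
}
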