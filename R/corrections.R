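#' Bin a background image stack into a coarse rate map
#'
#' Background measurements (crystal translated out of the beam) are noisy
#' per pixel; binning down in frames and pixels reduces the Poisson noise
#' before the rates are interpolated during corrections.  Bins are formed by
#' ceiling division, so partial bins at the array edges are retained: a
#' 2463 x 2527 pixel detector binned by 20 gives 124 x 127 pixel bins.
#' Each cell holds the mean rate (photons per pixel per second) over the
#' unmasked pixel-frame samples it covers; cells with no unmasked samples
#' are marked invalid.
#'
#' @param counts 3D array of photon counts, dimensions (frame, slow pixel,
#'   fast pixel).
#' @param exposure Exposure time per frame in seconds.
#' @param frame_bin Number of frames per bin (>= 1).
#' @param pixel_bin Pixels per bin; scalar or length 2 (slow, fast).
#' @param mask Optional logical array of the same shape; TRUE marks masked
#'   (excluded) samples.
#' @return An object of class `background_map` with fields `rate` (3D
#'   array), `valid`, `bin_size`, `centers` (bin-center coordinates per axis
#'   in frame/pixel units, 1-based) and `exposure`.
#' @export
bin_image_stack <- function(counts, exposure, frame_bin = 1, pixel_bin = 1,
                            mask = NULL) {
  counts <- as.array(counts)
  if (length(dim(counts)) != 3) stop("counts must be a 3D array (frame, slow, fast)")
  if (exposure <= 0) stop("exposure must be > 0")
  pixel_bin <- rep_len(pixel_bin, 2)
  bs <- as.integer(c(frame_bin, pixel_bin))
  if (any(bs < 1)) stop("bin sizes must be >= 1")
  dims <- dim(counts)
  nb <- as.integer(ceiling(dims / bs))
  bin_idx <- lapply(1:3, function(ax) (seq_len(dims[ax]) - 1L) %/% bs[ax] + 1L)
  id <- bin_idx[[1]][slice.index(counts, 1)] +
    nb[1] * (bin_idx[[2]][slice.index(counts, 2)] - 1L) +
    nb[1] * nb[2] * (bin_idx[[3]][slice.index(counts, 3)] - 1L)
  keep <- if (is.null(mask)) rep(TRUE, length(counts)) else !as.logical(mask)
  if (!any(keep)) stop("every bin has zero unmasked pixels")
  n_cells <- prod(nb)
  tot <- numeric(n_cells)
  cnt <- numeric(n_cells)
  sums <- rowsum(cbind(as.numeric(counts[keep]), 1), id[keep])
  cells <- as.integer(rownames(sums))
  tot[cells] <- sums[, 1]
  cnt[cells] <- sums[, 2]
  if (all(cnt == 0)) stop("every bin has zero unmasked pixels")
  rate <- ifelse(cnt > 0, tot / (cnt * exposure), NA_real_)
  centers <- lapply(1:3, function(ax) {
    lo <- (seq_len(nb[ax]) - 1L) * bs[ax] + 1L
    hi <- pmin(seq_len(nb[ax]) * bs[ax], dims[ax])
    (lo + hi) / 2
  })
  structure(list(rate = array(rate, nb), valid = array(cnt > 0, nb),
                 bin_size = bs, centers = centers, exposure = exposure),
            class = "background_map")
}

#' @export
print.background_map <- function(x, ...) {
  cat(sprintf("background_map: %s bins (frame x slow x fast), %d invalid cells\n",
              paste(dim(x$rate), collapse = " x "), sum(!x$valid)))
  invisible(x)
}

#' Interpolate a background rate map
#'
#' Multilinear interpolation of the binned background rate between bin
#' centers.  Queries outside the center lattice clamp to the edge values
#' (background varies slowly; extrapolation could produce negative rates).
#' Invalid cells are excluded by renormalizing the interpolation weights;
#' where every neighboring cell is invalid the result is `NA`, flagging the
#' observation.
#'
#' @param map A [bin_image_stack()] result.
#' @param frame,x,y Query coordinates (frame number, slow and fast pixel),
#'   vectors of equal length.
#' @return Numeric vector of rates (photons per pixel per second), `NA`
#'   where no valid neighbor exists.
#' @export
background_rate <- function(map, frame, x, y) {
  q <- cbind(frame, x, y)
  n <- nrow(q)
  lo <- matrix(1L, n, 3)
  tt <- matrix(0, n, 3)
  for (ax in 1:3) {
    cen <- map$centers[[ax]]
    m <- length(cen)
    if (m == 1) next
    xq <- pmin(pmax(q[, ax], cen[1]), cen[m])
    i0 <- findInterval(xq, cen, rightmost.closed = TRUE)
    i0 <- pmin(pmax(i0, 1L), m - 1L)
    lo[, ax] <- i0
    tt[, ax] <- (xq - cen[i0]) / (cen[i0 + 1] - cen[i0])
  }
  nb <- dim(map$rate)
  num <- numeric(n)
  den <- numeric(n)
  num_eq <- numeric(n)   # equal-weight fallback over valid cube corners,
  den_eq <- numeric(n)   # used when all interpolation weight is invalid
  for (corner in 0:7) {
    off <- c(bitwAnd(corner, 1L), bitwAnd(corner, 2L) %/% 2L,
             bitwAnd(corner, 4L) %/% 4L)
    w <- rep(1, n)
    idx <- matrix(0L, n, 3)
    skip <- FALSE
    for (ax in 1:3) {
      if (dim(map$rate)[ax] == 1 && off[ax] == 1L) { skip <- TRUE; break }
      idx[, ax] <- lo[, ax] + off[ax]
      w <- w * if (off[ax] == 1L) tt[, ax] else 1 - tt[, ax]
    }
    if (skip) next
    flat <- idx[, 1] + nb[1] * (idx[, 2] - 1L) + nb[1] * nb[2] * (idx[, 3] - 1L)
    v <- map$rate[flat]
    ok <- map$valid[flat]
    num <- num + ifelse(ok, w * v, 0)
    den <- den + ifelse(ok, w, 0)
    num_eq <- num_eq + ifelse(ok, v, 0)
    den_eq <- den_eq + as.numeric(ok)
  }
  ifelse(den > 0, num / den,
         ifelse(den_eq > 0, num_eq / den_eq, NA_real_))
}

#' Per-observation geometric correction factors
#'
#' Bundles the solid angle per pixel, detector quantum efficiency, air
#' transmission and polarization factor for each observation, and their
#' product, which divides both the intensity and its uncertainty.
#'
#' @param solid_angle Solid angle per pixel (steradian), > 0.
#' @param efficiency Detector quantum efficiency in (0, 1].
#' @param transmission Transmission factor of air in the diffracted beam
#'   path, in (0, 1].
#' @param polarization Polarization factor, > 0.
#' @return A data.frame with the four factors and their `product`.
#' @export
correction_factors <- function(solid_angle = 1, efficiency = 1,
                               transmission = 1, polarization = 1) {
  f <- data.frame(solid_angle, efficiency, transmission, polarization)
  if (any(!is.finite(as.matrix(f))) || any(as.matrix(f) <= 0))
    stop("all correction factors must be finite and > 0")
  f$product <- f$solid_angle * f$efficiency * f$transmission * f$polarization
  f
}

#' Correct integrated observations
#'
#' Converts accumulated photon counts into background-subtracted, corrected
#' intensities with Poisson standard errors:
#' `I = (n/dt - r_bg) / (dOmega E A P)` and
#' `sigma = sqrt(n)/dt / (dOmega E A P)`.
#' The Poisson error of the background itself is reduced by binning and is
#' neglected.  Zero-count observations get `sigma = 0` and are flagged
#' unusable for inverse-variance weighting (no artificial sigma floor).
#'
#' @param n Accumulated photon counts (non-negative integers).
#' @param dt Cumulative exposure per voxel in seconds (number of pixels
#'   times exposure per image), > 0.
#' @param r_bg Background rate at the observation (photons per pixel per
#'   second scaled to the voxel, i.e. same units as `n/dt`).
#' @param factors A [correction_factors()] data.frame, or a numeric vector
#'   giving the product of the four factors directly.
#' @return data.frame with columns `I`, `sigma` and `usable`.
#' @export
correct_observation <- function(n, dt, r_bg = 0, factors = 1) {
  if (any(n < 0)) stop("photon counts must be >= 0")
  if (any(!is.finite(dt)) || any(dt <= 0)) stop("dt must be finite and > 0")
  f <- if (is.data.frame(factors)) factors$product else as.numeric(factors)
  if (any(!is.finite(f)) || any(f <= 0)) stop("correction factors must be > 0")
  I <- (n / dt - r_bg) / f
  sigma <- sqrt(n) / dt / f
  data.frame(I = I, sigma = sigma, usable = n > 0)
}
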