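#' Integrate a pixel stream onto the voxel grid
#'
#' Accumulates masked photon counts into the oversampled reciprocal-space
#' grid.  Each pixel carries fractional Miller indices (computed upstream by
#' the geometry model or by the simulator) and is assigned to the nearest
#' voxel.  For every (voxel, sweep) pair the table records the accumulated
#' counts, the number of contributing pixels and the unweighted mean scan
#' coordinates (rotation angle and detector position) -- the coordinates
#' describe where the voxel was sampled, not where photons landed, so they
#' are not intensity weighted.  The accumulation is an associative,
#' commutative merge over chunks, so the result is independent of how the
#' stream is partitioned; `nproc` distributes chunks over processes without
#' changing the result.
#'
#' @param pixels data.frame with columns `phi` (degrees), `x`, `y` (detector
#'   pixels), `count` (photons, >= 0), `h`, `k`, `l` (fractional Miller
#'   indices) and optionally `batch` (sweep id, default 1).
#' @param grid A [miller_grid()].
#' @param exposure Exposure time per image in seconds; the cumulative
#'   exposure per voxel is `n_pixels * exposure`.
#' @param mask Optional [build_peak_mask()] result; pixels inside a Bragg
#'   ellipsoid contribute nothing.
#' @param exclude Optional logical vector flagging additional pixels to
#'   drop (e.g. strong-pixel outliers from [flag_outliers()]).
#' @param chunks Number of chunks to partition the stream into (>= 1).
#' @param nproc Number of worker processes for chunk accumulation.
#' @return An observation table (data.frame): `batch`, voxel indices
#'   `i, j, k`, asymmetric-unit indices `asu_i, asu_j, asu_k`, `op`,
#'   `friedel`, counts `n`, `n_pixels`, mean `phi`, `x`, `y`, scattering
#'   vector `s` (1/angstrom, at the voxel center) and `dt` (seconds).
#' @export
integrate_counts <- function(pixels, grid, exposure, mask = NULL,
                             exclude = NULL, chunks = 1L, nproc = 1L) {
  stopifnot(is.data.frame(pixels))
  need <- c("phi", "x", "y", "count", "h", "k", "l")
  missing_cols <- setdiff(need, names(pixels))
  if (length(missing_cols))
    stop("pixel stream lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(pixels$count < 0)) stop("pixel with negative count")
  if (exposure <= 0) stop("exposure must be > 0")
  keep <- rep(TRUE, nrow(pixels))
  if (!is.null(exclude)) keep <- keep & !exclude
  if (!is.null(mask)) keep <- keep & !mask$is_masked(as.matrix(pixels[, c("h", "k", "l")]))
  px <- pixels[keep, , drop = FALSE]
  if (is.null(px$batch)) px$batch <- 1L
  if (nrow(px) == 0) return(empty_observation_table())

  v <- voxel_of(as.matrix(px[, c("h", "k", "l")]), grid)
  dt_px <- data.table::data.table(
    batch = px$batch, i = v[, 1], j = v[, 2], k = v[, 3],
    count = as.numeric(px$count), phi = px$phi, x = px$x, y = px$y)

  chunks <- max(1L, as.integer(chunks), as.integer(nproc))
  part <- rep(seq_len(chunks), length.out = nrow(dt_px))
  pieces <- split(seq_len(nrow(dt_px)), part)
  accumulate <- function(rows) {
    sub <- dt_px[rows]
    sub[, list(n = sum(count), n_pixels = .N, phi_sum = sum(phi),
               x_sum = sum(x), y_sum = sum(y)),
        by = c("batch", "i", "j", "k")]
  }
  partials <- if (nproc > 1L) {
    parallel::mclapply(pieces, accumulate, mc.cores = nproc)
  } else {
    lapply(pieces, accumulate)
  }
  acc <- data.table::rbindlist(partials)
  acc <- acc[, list(n = sum(n), n_pixels = sum(n_pixels),
                    phi_sum = sum(phi_sum), x_sum = sum(x_sum),
                    y_sum = sum(y_sum)),
             by = c("batch", "i", "j", "k")]
  data.table::setorderv(acc, c("batch", "i", "j", "k"))

  vox <- as.matrix(acc[, c("i", "j", "k")])
  asu <- map_to_asu(vox, grid)
  out <- data.frame(
    batch = acc$batch, i = acc$i, j = acc$j, k = acc$k,
    asu_i = asu$asu[, 1], asu_j = asu$asu[, 2], asu_k = asu$asu[, 3],
    op = asu$op, friedel = asu$friedel,
    n = acc$n, n_pixels = acc$n_pixels,
    phi = acc$phi_sum / acc$n_pixels,
    x = acc$x_sum / acc$n_pixels,
    y = acc$y_sum / acc$n_pixels,
    s = s_magnitude(voxel_center(vox, grid), grid$cell),
    dt = acc$n_pixels * exposure)
  out
}

empty_observation_table <- function() {
  data.frame(batch = integer(0), i = integer(0), j = integer(0),
             k = integer(0), asu_i = integer(0), asu_j = integer(0),
             asu_k = integer(0), op = integer(0), friedel = logical(0),
             n = numeric(0), n_pixels = integer(0), phi = numeric(0),
             x = numeric(0), y = numeric(0), s = numeric(0), dt = numeric(0))
}
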