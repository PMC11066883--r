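#' Symmetry-expand a merged table into a 3D reciprocal-space map
#'
#' Every voxel in the requested bounds whose asymmetric-unit representative
#' is present in the merged table receives that voxel's merged intensity;
#' all other voxels are marked missing (`NA`, never zero, so plots can
#' distinguish unobserved from zero intensity).  Symmetry-equivalent filled
#' voxels carry equal values by construction.
#'
#' @param merged Merged table with `asu_i`, `asu_j`, `asu_k` and `I`.
#' @param grid A [miller_grid()].
#' @param bounds List with integer ranges `i`, `j`, `k` (each `c(lo, hi)`)
#'   in subdivided voxel units.
#' @return Object of class `reciprocal_map`: 3D `values` array, axis index
#'   vectors `i`, `j`, `k`, and the grid.
#' @export
expand_map <- function(merged, grid, bounds) {
  ax <- lapply(c("i", "j", "k"), function(nm) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2 || b[2] < b[1])
      stop("bounds$", nm, " must be c(lo, hi)")
    seq(as.integer(b[1]), as.integer(b[2]))
  })
  names(ax) <- c("i", "j", "k")
  vox <- as.matrix(expand.grid(i = ax$i, j = ax$j, k = ax$k))
  values <- rep(NA_real_, nrow(vox))
  if (nrow(merged) > 0) {
    asu <- map_to_asu(vox, grid)$asu
    idx <- match(paste(asu[, 1], asu[, 2], asu[, 3]), merged_key(merged))
    hit <- !is.na(idx)
    values[hit] <- merged$I[idx[hit]]
  }
  structure(list(values = array(values, lengths(ax)),
                 i = ax$i, j = ax$j, k = ax$k, grid = grid),
            class = "reciprocal_map")
}

#' @export
print.reciprocal_map <- function(x, ...) {
  cat(sprintf("reciprocal_map: %s voxels, %.1f%% filled\n",
              paste(dim(x$values), collapse = " x "),
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Reduce a reciprocal-space map back to asymmetric-unit values
#'
#' Averages the filled voxels of each symmetry orbit; the inverse of
#' [expand_map()] on its own output (exactly, since orbit members carry
#' equal values).
#'
#' @param map A [expand_map()] result.
#' @return data.frame with `asu_i`, `asu_j`, `asu_k`, `I`.
#' @export
reduce_map <- function(map) {
  vox <- as.matrix(expand.grid(i = map$i, j = map$j, k = map$k))
  val <- as.vector(map$values)
  keep <- !is.na(val)
  asu <- map_to_asu(vox[keep, , drop = FALSE], map$grid)$asu
  dt <- data.table::data.table(asu_i = asu[, 1], asu_j = asu[, 2],
                               asu_k = asu[, 3], I = val[keep])
  out <- dt[, list(I = mean(I)), by = c("asu_i", "asu_j", "asu_k")]
  data.table::setorderv(out, c("asu_i", "asu_j", "asu_k"))
  as.data.frame(out)
}

#' Isotropic intensity curve from shell means
#'
#' Mean non-halo intensity per resolution shell, interpolated linearly
#' between shell centers and clamped at the ends; used as the isotropic
#' component of the scattering.
#'
#' @param I Intensities per voxel.
#' @param s |s| per voxel.
#' @param scheme A [shell_scheme()].
#' @param use Logical selector of voxels contributing to the shell means
#'   (e.g. the non-halo partition); defaults to all.
#' @return Function mapping |s| values to interpolated isotropic intensity.
#' @export
isotropic_curve <- function(I, s, scheme, use = NULL) {
  if (is.null(use)) use <- rep(TRUE, length(I))
  if (!any(use)) stop("no voxels selected for the isotropic curve")
  sh <- shell_of(s[use], scheme)
  means <- tapply(I[use], sh, mean)
  cx <- scheme$centers[as.integer(names(means))]
  cy <- as.numeric(means)
  if (length(cx) == 1) return(function(sq) rep(cy, length(sq)))
  function(sq) stats::approx(cx, cy, xout = sq, rule = 2)$y
}

#' Subtract the isotropic component
#'
#' Subtracts, from each voxel, the shell-mean curve evaluated at the
#' voxel's |s| (linear interpolation between shell centers, clamped).
#' Shell means are computed from non-halo voxels only, since halo voxels
#' would bias the mean upward.
#'
#' @param I Intensities per voxel.
#' @param s |s| per voxel.
#' @param scheme A [shell_scheme()].
#' @param partition Optional factor from [halo_partition()]; when given,
#'   only `"non-halo"` voxels feed the isotropic curve.
#' @return List with `residual` (variational intensities) and `isotropic`
#'   (the subtracted values).
#' @export
subtract_isotropic <- function(I, s, scheme, partition = NULL) {
  use <- if (is.null(partition)) NULL else partition == "non-halo"
  fn <- isotropic_curve(I, s, scheme, use = use)
  iso <- fn(s)
  list(residual = I - iso, isotropic = iso)
}
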