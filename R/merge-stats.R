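#' Resolution-shell scheme
#'
#' Bins scattering-vector magnitudes into shells of constant s.  Default:
#' 20 equal-width shells over the observed range.  Intervals are half-open
#' `[edge_i, edge_{i+1})` with the last edge inclusive.
#'
#' @param s Numeric vector of |s| values (1/angstrom) defining the range,
#'   or a length-2 range.
#' @param n_shells Number of shells.
#' @param method `"width"` for equal-width shells or `"count"` for
#'   (approximately) equal-count shells.
#' @return Object of class `shell_scheme` with `edges` and `centers`.
#' @export
shell_scheme <- function(s, n_shells = 20, method = c("width", "count")) {
  method <- match.arg(method)
  s <- s[is.finite(s)]
  if (!length(s)) stop("no finite s values")
  edges <- if (method == "width") {
    seq(min(s), max(s), length.out = n_shells + 1)
  } else {
    unique(stats::quantile(s, probs = seq(0, 1, length.out = n_shells + 1),
                           names = FALSE, type = 7))
  }
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("shell edges must be strictly increasing; s range too narrow")
  structure(list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2),
            class = "shell_scheme")
}

#' Shell membership
#'
#' @param s Numeric |s| values.
#' @param scheme A [shell_scheme()].
#' @return Integer shell index per value (`NA` outside the edge range).
#' @export
shell_of <- function(s, scheme) {
  e <- scheme$edges
  idx <- findInterval(s, e, rightmost.closed = TRUE)
  idx[idx < 1 | idx > length(e) - 1] <- NA_integer_
  idx
}

#' Split observations into half data sets
#'
#' `randomHalf`: within each asymmetric-unit voxel, the voxel's
#' observations are shuffled with the seeded generator and assigned
#' alternately to the two halves, starting with a half chosen by a
#' per-voxel fair coin (so odd counts do not systematically favour one
#' half).  Per-voxel imbalance is at most 1.  `Friedel`: observations
#' whose symmetry operator to the asymmetric unit is improper (contains
#' the inversion) go to half 2, the rest to half 1.
#'
#' @param obs Observation table with `asu_i`, `asu_j`, `asu_k` and (for
#'   the Friedel split) a logical `friedel` column.
#' @param mode `"randomHalf"` or `"Friedel"`.
#' @param seed Integer seed for the random split.
#' @return Integer vector of half assignments (1 or 2) per observation.
#' @export
split_observations <- function(obs, mode = c("randomHalf", "Friedel"),
                               seed = 1) {
  mode <- match.arg(mode)
  if (mode == "Friedel") {
    if (is.null(obs$friedel)) stop("Friedel split requires a friedel column")
    return(ifelse(obs$friedel, 2L, 1L))
  }
  key <- paste(obs$asu_i, obs$asu_j, obs$asu_k)
  half <- integer(nrow(obs))
  groups <- split(seq_len(nrow(obs)), key)
  groups <- groups[order(names(groups))]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (g in groups) {
    perm <- if (length(g) > 1) g[sample.int(length(g))] else g
    first <- sample.int(2L, 1L)
    half[perm] <- rep(c(first, 3L - first), length.out = length(perm))
  }
  half
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

merged_key <- function(merged) paste(merged$asu_i, merged$asu_j, merged$asu_k)

#' Correlation between two merged half data sets by resolution shell
#'
#' Pearson correlation of the merged intensities over asymmetric-unit
#' voxels present in both halves, per shell.  With random halves this is
#' CC1/2; with a Friedel split it is CC_Friedel.  Shells with fewer than 3
#' common voxels return `NA`.
#'
#' @param merged1,merged2 Merged tables (see [merge_scaled()]) on the same
#'   grid, including an `s` column or fractional `h,k,l` from which s can
#'   be computed via `grid`.
#' @param scheme A [shell_scheme()].
#' @param s Optional per-voxel |s| for `merged1`'s voxels; if missing, an
#'   `s` column is required.
#' @return data.frame: shell index, s bounds, number of common voxels, cc.
#' @export
cc_by_shell <- function(merged1, merged2, scheme, s = NULL) {
  k1 <- merged_key(merged1); k2 <- merged_key(merged2)
  i2 <- match(k1, k2)
  common <- which(!is.na(i2))
  if (is.null(s)) s <- merged1$s
  if (is.null(s)) stop("supply s per voxel or an s column in merged1")
  sh <- shell_of(s[common], scheme)
  x <- merged1$I[common]
  y <- merged2$I[i2[common]]
  n_sh <- length(scheme$centers)
  cc <- rep(NA_real_, n_sh)
  nvox <- integer(n_sh)
  for (b in seq_len(n_sh)) {
    sel <- which(sh == b)
    nvox[b] <- length(sel)
    if (length(sel) >= 3 && stats::sd(x[sel]) > 0 && stats::sd(y[sel]) > 0)
      cc[b] <- stats::cor(x[sel], y[sel])
  }
  data.frame(shell = seq_len(n_sh), s_min = scheme$edges[-(n_sh + 1)],
             s_max = scheme$edges[-1], n_vox = nvox, cc = cc)
}

#' Reproducibility correlation between independent data sets
#'
#' CC_Rep: the per-shell Pearson correlation between intensities merged
#' from disjoint groups of sweeps (e.g. two crystals) that were scaled and
#' merged independently.
#'
#' @param merged1,merged2 Independently scaled-and-merged tables.  If both
#'   carry a `batches` attribute the groups are checked for overlap.
#' @param scheme A [shell_scheme()].
#' @param s Optional |s| per voxel of `merged1` (else its `s` column).
#' @return As [cc_by_shell()].
#' @export
cc_rep <- function(merged1, merged2, scheme, s = NULL) {
  b1 <- attr(merged1, "batches"); b2 <- attr(merged2, "batches")
  if (!is.null(b1) && !is.null(b2) && length(intersect(b1, b2)))
    stop("CC_Rep requires disjoint batch groups; found overlap: ",
         paste(intersect(b1, b2), collapse = ", "))
  cc_by_shell(merged1, merged2, scheme, s = s)
}

#' Halo / non-halo voxel partition
#'
#' A merged voxel belongs to the halo part iff its center lies on an
#' integer Miller-index node that passes the centering reflection
#' condition, i.e. the voxel surrounds an allowed Bragg peak (whose own
#' pixels were removed by the peak mask).  All other voxels, including
#' integer nodes forbidden by the centering, are non-halo.
#'
#' @param merged Merged table with `asu_i`, `asu_j`, `asu_k`.
#' @param grid A [miller_grid()].
#' @return Factor with levels `halo`, `non-halo`, one per merged voxel.
#' @export
halo_partition <- function(merged, grid) {
  v <- as.matrix(merged[, c("asu_i", "asu_j", "asu_k")])
  factor(ifelse(is_bragg_voxel(v, grid), "halo", "non-halo"),
         levels = c("halo", "non-halo"))
}

#' Shell intensity statistics by partition
#'
#' Mean and standard deviation of merged intensity per resolution shell
#' and partition label, normalized by a single constant: the maximum over
#' shells of the non-halo mean, which becomes 1.  Empty cells are `NA`.
#'
#' @param merged Merged table with intensity column `I`.
#' @param scheme A [shell_scheme()].
#' @param partition Factor per voxel (e.g. from [halo_partition()]).
#' @param s Optional |s| per voxel (else `merged$s`).
#' @return data.frame: shell, s_center, partition, n_vox, mean, sd
#'   (normalized).
#' @export
shell_statistics <- function(merged, scheme, partition, s = NULL) {
  if (is.null(s)) s <- merged$s
  if (is.null(s)) stop("supply s per voxel or an s column in merged")
  sh <- shell_of(s, scheme)
  parts <- levels(factor(partition))
  n_sh <- length(scheme$centers)
  out <- expand.grid(shell = seq_len(n_sh), partition = parts,
                     stringsAsFactors = FALSE)
  out$s_center <- scheme$centers[out$shell]
  out$n_vox <- 0L
  out$mean <- NA_real_
  out$sd <- NA_real_
  for (r in seq_len(nrow(out))) {
    sel <- which(sh == out$shell[r] & partition == out$partition[r])
    out$n_vox[r] <- length(sel)
    if (length(sel) >= 1) out$mean[r] <- mean(merged$I[sel])
    if (length(sel) >= 2) out$sd[r] <- stats::sd(merged$I[sel])
  }
  norm <- suppressWarnings(max(out$mean[out$partition == "non-halo"], na.rm = TRUE))
  if (is.finite(norm) && norm > 0) {
    out$mean <- out$mean / norm
    out$sd <- out$sd / norm
  }
  attr(out, "normalization") <- norm
  out[, c("shell", "s_center", "partition", "n_vox", "mean", "sd")]
}
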