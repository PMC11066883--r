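#' Laue-group operator presets
#'
#' Returns the list of 3x3 integer matrices for a named Laue group.  The
#' preset `"m-3"` (as for space group I213, label accepted as `"I213"`) is
#' generated from the rotations of point group 23 closed under inversion,
#' giving 24 operators.  `"-1"` gives the minimal centrosymmetric group
#' {identity, inversion}.  Laue groups always contain the inversion, so for
#' every operator R the list also contains -R.
#'
#' @param name One of `"m-3"`, `"I213"` (alias for `"m-3"`), `"-1"`.
#' @return List of 3x3 integer matrices, proper rotations first.
#' @export
laue_group_ops <- function(name = "m-3") {
  name <- as.character(name)
  if (name %in% c("m-3", "I213", "m-3bar", "23")) {
    gens <- list(
      matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3),   # threefold about [111]
      diag(c(-1, -1, 1))                            # twofold about z
    )
    props <- close_group(gens)
  } else if (name == "-1") {
    props <- list(diag(3))
  } else {
    stop("unknown Laue group preset: ", name)
  }
  # proper rotations first (identity leads), then their inversion images
  dets <- vapply(props, function(m) round(det(m)), numeric(1))
  props <- props[order(-dets, vapply(props, function(m) -sum(diag(m)), numeric(1)))]
  c(props, lapply(props, function(m) -m))
}

# closure of a generator set under matrix multiplication
close_group <- function(gens) {
  key <- function(m) paste(as.integer(m), collapse = ",")
  ops <- list(diag(3))
  names(ops) <- key(diag(3))
  repeat {
    added <- FALSE
    for (g in gens) for (o in ops) {
      p <- g %*% o
      k <- key(p)
      if (is.null(ops[[k]])) {
        ops[[k]] <- p
        added <- TRUE
      }
    }
    if (!added) break
  }
  unname(ops)
}

#' Reciprocal-space voxel grid
#'
#' Defines the oversampled grid used to accumulate diffuse scattering: the
#' reciprocal unit cell is subdivided by an integer factor per axis, so that
#' voxel centers lie at fractional Miller indices `(i/n_h, j/n_k, k/n_l)`.
#' The grid also carries the lattice centering (reflection condition) and
#' the Laue-group operators used for mapping to the asymmetric unit.
#'
#' @param cell A [unit_cell()].
#' @param subdivision Integer subdivision per axis; scalar or length 3.
#' @param centering One of `"P"`, `"I"`, `"F"`, `"C"`.
#' @param laue_ops List of 3x3 integer matrices, or a preset name accepted
#'   by [laue_group_ops()].
#' @return An object of class `miller_grid`.
#' @export
miller_grid <- function(cell, subdivision = 3, centering = c("P", "I", "F", "C"),
                        laue_ops = "m-3") {
  centering <- match.arg(centering)
  subdivision <- as.integer(rep_len(subdivision, 3))
  if (any(subdivision < 1)) stop("subdivision must be a positive integer per axis")
  if (is.character(laue_ops)) laue_ops <- laue_group_ops(laue_ops)
  laue_ops <- lapply(laue_ops, function(m) {
    m <- round(as.matrix(m))
    if (!all(dim(m) == c(3, 3))) stop("Laue operators must be 3x3 matrices")
    storage.mode(m) <- "double"
    m
  })
  check_laue_group(laue_ops)
  structure(list(cell = cell, subdivision = subdivision,
                 centering = centering, laue_ops = laue_ops),
            class = "miller_grid")
}

check_laue_group <- function(ops) {
  key <- function(m) paste(as.integer(m), collapse = ",")
  keys <- vapply(ops, key, character(1))
  if (anyDuplicated(keys)) stop("duplicate Laue operators")
  if (!(key(diag(3)) %in% keys)) stop("Laue operators must contain the identity")
  for (a in ops) {
    if (!(key(-a) %in% keys))
      stop("Laue group must be centrosymmetric (-R missing for some R)")
    for (b in ops) {
      if (!(key(a %*% b) %in% keys))
        stop("Laue operators are not closed under composition")
    }
  }
  invisible(TRUE)
}

#' @export
print.miller_grid <- function(x, ...) {
  cat(sprintf("miller_grid: subdivision %s, centering %s, %d Laue operators\n",
              paste(x$subdivision, collapse = "x"), x$centering,
              length(x$laue_ops)))
  print(x$cell)
  invisible(x)
}

#' Nearest voxel for fractional Miller indices
#'
#' Assigns each fractional hkl triple to the nearest voxel center of the
#' grid.  Exact half-way ties are broken by round-half-to-even on each axis
#' independently, which is deterministic and unbiased.
#'
#' @param hkl_frac Length-3 vector or n x 3 matrix of fractional Miller
#'   indices.
#' @param grid A [miller_grid()].
#' @return Integer n x 3 matrix of voxel indices in subdivided units.
#' @export
voxel_of <- function(hkl_frac, grid) {
  h <- as_hkl_matrix(hkl_frac)
  if (!all(is.finite(h))) stop("hkl coordinates must be finite")
  n <- grid$subdivision
  v <- cbind(round(h[, 1] * n[1]), round(h[, 2] * n[2]), round(h[, 3] * n[3]))
  storage.mode(v) <- "integer"
  dimnames(v) <- list(NULL, c("i", "j", "k"))
  v
}

#' Voxel center in fractional Miller indices
#'
#' @param v Integer length-3 vector or n x 3 matrix of voxel indices.
#' @param grid A [miller_grid()].
#' @return n x 3 numeric matrix of fractional hkl at the voxel centers.
#' @export
voxel_center <- function(v, grid) {
  v <- as_hkl_matrix(v)
  n <- grid$subdivision
  cbind(h = v[, 1] / n[1], k = v[, 2] / n[2], l = v[, 3] / n[3])
}

#' Lattice-centering reflection condition
#'
#' @param hkl Integer Miller-index matrix (n x 3).
#' @param centering One of `"P"`, `"I"`, `"F"`, `"C"`.
#' @return Logical vector: TRUE where the centering allows a reflection.
#' @export
centering_allowed <- function(hkl, centering) {
  hkl <- as_hkl_matrix(hkl)
  h <- hkl[, 1]; k <- hkl[, 2]; l <- hkl[, 3]
  switch(centering,
         P = rep(TRUE, nrow(hkl)),
         I = (h + k + l) %% 2 == 0,
         F = (h %% 2 == k %% 2) & (k %% 2 == l %% 2),
         C = (h + k) %% 2 == 0,
         stop("unknown centering: ", centering))
}

#' Does a voxel contain a Bragg peak?
#'
#' TRUE iff the voxel center is at integer Miller indices (all indices are
#' multiples of the subdivision) and the centering reflection condition
#' holds (e.g. h+k+l = 2n for I-centering).
#'
#' @param v Integer voxel-index vector or n x 3 matrix (subdivided units).
#' @param grid A [miller_grid()].
#' @return Logical vector.
#' @export
is_bragg_voxel <- function(v, grid) {
  v <- as_hkl_matrix(v)
  n <- grid$subdivision
  integer_node <- (v[, 1] %% n[1] == 0) & (v[, 2] %% n[2] == 0) &
    (v[, 3] %% n[3] == 0)
  out <- integer_node
  if (any(integer_node)) {
    hkl <- cbind(v[integer_node, 1] / n[1], v[integer_node, 2] / n[2],
                 v[integer_node, 3] / n[3])
    out[integer_node] <- centering_allowed(hkl, grid$centering)
  }
  out
}

#' Diffuse voxels per Bragg peak
#'
#' Counts, by exhaustive enumeration over one centering period of the
#' reciprocal lattice, how many voxels of the subdivided grid do not contain
#' a Bragg peak, per allowed Bragg node.
#'
#' @param subdivision Integer subdivision per axis (scalar, >= 1).
#' @param centering One of `"P"`, `"I"`, `"F"`, `"C"`.
#' @return Integer count of diffuse (non-Bragg) voxels per Bragg peak.
#' @export
count_diffuse_voxels <- function(subdivision, centering = "P") {
  subdivision <- as.integer(subdivision)
  if (length(subdivision) != 1 || subdivision < 1)
    stop("subdivision must be a single integer >= 1")
  if (!centering %in% c("P", "I", "F", "C"))
    stop("unknown centering: ", centering)
  period <- if (centering == "P") 1L else 2L
  grid <- miller_grid(cubic_cell(1), subdivision, centering, laue_ops = "-1")
  idx <- seq_len(period * subdivision) - 1L
  v <- as.matrix(expand.grid(i = idx, j = idx, k = idx))
  bragg <- is_bragg_voxel(v, grid)
  n_bragg <- sum(bragg)
  as.integer((nrow(v) - n_bragg) / n_bragg)
}

#' Map voxels to the asymmetric unit
#'
#' Applies every Laue operator to each voxel and takes the lexicographically
#' greatest image as the canonical asymmetric-unit representative.  The
#' chosen operator index is reported, and `friedel` is TRUE iff that
#' operator is improper (determinant -1), i.e. the observation is related
#' to its representative through a center of inversion.  Ties (special
#' positions fixed by several operators) resolve to the first operator in
#' the grid's list, so proper operators win over improper ones in the
#' shipped presets.
#'
#' @param v Integer voxel-index vector or n x 3 matrix.
#' @param grid A [miller_grid()] with non-empty `laue_ops`.
#' @return A list with elements `asu` (n x 3 integer matrix), `op` (integer
#'   vector of operator indices) and `friedel` (logical vector).
#' @export
map_to_asu <- function(v, grid) {
  v <- as_hkl_matrix(v)
  ops <- grid$laue_ops
  if (length(ops) == 0) stop("grid has no Laue operators")
  base <- 2 * max(abs(v), 1) + 1
  best_key <- rep(-Inf, nrow(v))
  best_op <- integer(nrow(v))
  best_img <- v
  for (oi in seq_along(ops)) {
    img <- v %*% t(ops[[oi]])
    key <- (img[, 1] * base + img[, 2]) * base + img[, 3]
    better <- key > best_key
    if (any(better)) {
      best_key[better] <- key[better]
      best_op[better] <- oi
      best_img[better, ] <- img[better, , drop = FALSE]
    }
  }
  dets <- vapply(ops, function(m) round(det(m)), numeric(1))
  asu <- best_img
  storage.mode(asu) <- "integer"
  dimnames(asu) <- list(NULL, c("i", "j", "k"))
  list(asu = asu, op = best_op, friedel = dets[best_op] < 0)
}
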