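#' Parameter grid
#'
#' Control points of one scaling-model parameter, stored on a 1-3
#' dimensional grid of scan coordinates.  Values at observation coordinates
#' are computed by multilinear interpolation (see [interp_operator()]).
#' The grid is vectorized with the first axis fastest, matching R's native
#' array layout.
#'
#' @param axes List of sorted numeric axis coordinates (or a single numeric
#'   vector for 1D).
#' @param values Array of control-point values with `dim` equal to the axis
#'   lengths; defaults to `fill` everywhere.
#' @param fill Default fill value (1 for scale factors, 0 for offsets).
#' @return Object of class `param_grid`.
#' @export
param_grid <- function(axes, values = NULL, fill = 1) {
  if (is.numeric(axes)) axes <- list(axes)
  if (length(axes) < 1 || length(axes) > 3)
    stop("param_grid supports 1-3 dimensions")
  for (ax in axes) {
    if (length(ax) < 1 || is.unsorted(ax, strictly = TRUE))
      stop("axis coordinates must be strictly increasing and non-empty")
  }
  nd <- vapply(axes, length, integer(1))
  if (is.null(values)) values <- array(fill, dim = nd)
  values <- array(as.numeric(values), dim = nd)
  if (any(!is.finite(values))) stop("control-point values must be finite")
  structure(list(axes = axes, values = values), class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat(sprintf("param_grid: %s control points over %d axis/axes\n",
              paste(dim(x$values), collapse = " x "), length(x$axes)))
  invisible(x)
}

#' Sparse multilinear interpolation operator
#'
#' Builds the sparse matrix `M` such that `M %*% as.vector(values)` gives
#' the interpolated parameter value at each query point.  Row i carries the
#' multilinear weights of query i over its `2^dim` surrounding control
#' points; rows sum to 1 and all entries are non-negative.  Queries outside
#' an axis range are clamped to the range.
#'
#' @param coords Query coordinates: numeric vector (1D) or n x dim matrix.
#' @param axes List of axis coordinate vectors (or single numeric vector).
#' @return A sparse `dgCMatrix` of dimension n x prod(axis lengths).
#' @export
interp_operator <- function(coords, axes) {
  if (is.numeric(axes)) axes <- list(axes)
  d <- length(axes)
  if (d < 1 || d > 3) stop("interp_operator supports 1-3 dimensions")
  if (any(vapply(axes, length, integer(1)) == 0)) stop("empty grid axis")
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = d)
  coords <- as.matrix(coords)
  if (ncol(coords) != d) stop("coords must have one column per axis")
  n <- nrow(coords)
  nd <- vapply(axes, length, integer(1))
  lo <- matrix(1L, n, d)
  tt <- matrix(0, n, d)
  for (ax in seq_len(d)) {
    cen <- axes[[ax]]
    m <- length(cen)
    if (m == 1) next
    xq <- pmin(pmax(coords[, ax], cen[1]), cen[m])
    i0 <- pmin(pmax(findInterval(xq, cen, rightmost.closed = TRUE), 1L), m - 1L)
    lo[, ax] <- i0
    tt[, ax] <- (xq - cen[i0]) / (cen[i0 + 1] - cen[i0])
  }
  stride <- cumprod(c(1, nd[-d]))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (corner in seq_len(2^d) - 1L) {
    off <- as.integer(bitwAnd(corner, 2^(seq_len(d) - 1L)) > 0)
    w <- rep(1, n)
    col <- rep(1, n)
    skip <- FALSE
    for (ax in seq_len(d)) {
      if (nd[ax] == 1 && off[ax] == 1L) { skip <- TRUE; break }
      w <- w * if (off[ax] == 1L) tt[, ax] else 1 - tt[, ax]
      col <- col + (lo[, ax] + off[ax] - 1L) * stride[ax]
    }
    if (skip) next
    ii <- c(ii, seq_len(n)); jj <- c(jj, col); xx <- c(xx, w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, prod(nd)))
}

#' Discrete second-derivative operator
#'
#' Rows of `(1, -2, 1)` acting on a vector of `n` control points; it
#' annihilates affine sequences.  For `n < 3` the operator is empty (zero
#' rows) and contributes no penalty.
#'
#' @param n Number of control points.
#' @return Sparse (n-2) x n matrix (0 x n if `n < 3`).
#' @export
second_derivative_operator <- function(n) {
  n <- as.integer(n)
  if (n < 3) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(0L, max(n, 0L))))
  r <- seq_len(n - 2L)
  Matrix::sparseMatrix(i = rep(r, 3), j = c(r, r + 1L, r + 2L),
                       x = rep(c(1, -2, 1), each = n - 2L), dims = c(n - 2L, n))
}

#' Discrete 2D Laplacian operator
#'
#' Five-point stencil (-4 center, +1 for each neighbor) applied at the
#' interior points of an `nx` x `ny` grid vectorized with the x axis
#' fastest.  Annihilates planes `alpha*x + beta*y + gamma`.  If the grid
#' has no interior points the operator is empty.
#'
#' @param nx,ny Grid dimensions.
#' @return Sparse matrix with one row per interior point and `nx*ny`
#'   columns.
#' @export
laplacian_operator <- function(nx, ny) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 3 || ny < 3)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0L, nx * ny)))
  ix <- rep(2:(nx - 1L), times = ny - 2L)
  iy <- rep(2:(ny - 1L), each = nx - 2L)
  ctr <- ix + nx * (iy - 1L)
  r <- seq_along(ctr)
  Matrix::sparseMatrix(
    i = rep(r, 5),
    j = c(ctr, ctr - 1L, ctr + 1L, ctr - nx, ctr + nx),
    x = rep(c(-4, 1, 1, 1, 1), each = length(ctr)),
    dims = c(length(ctr), nx * ny))
}

#' Identity regularization operator
#'
#' Penalizes the magnitude of the parameter vector itself; used to keep the
#' background offset as small as the data allow.
#'
#' @param n Number of control points.
#' @return Sparse n x n identity matrix.
#' @export
identity_operator <- function(n) Matrix::Diagonal(as.integer(n), x = rep(1, n))

#' Re-normalize a regularization parameter
#'
#' Converts the user-facing regularization parameter `alpha` into the
#' pre-factor `lambda` of the penalty `lambda * ||B x||^2` via the ratio of
#' squared Frobenius norms, `lambda = alpha * ||A||_F^2 / ||B||_F^2`.  With
#' this convention a given `alpha` behaves similarly across grid spacings,
#' data-set sizes and noise levels: `alpha << 1` favors the data misfit and
#' `alpha >> 1` favors the regularizer.
#'
#' @param alpha User regularization parameter (>= 0).
#' @param A Design matrix of the least-squares problem.
#' @param B Regularization operator.
#' @return The pre-factor `lambda` (0 when `||B|| = 0`).
#' @export
renormalize_alpha <- function(alpha, A, B) {
  frob2 <- function(M) sum(Matrix::rowSums(M * M))
  nb <- frob2(B)
  if (nb == 0 || nrow(B) == 0) return(0)
  alpha * frob2(A) / nb
}

#' Solve a regularized least-squares problem
#'
#' Minimizes `||A x - b||^2 + sum_k lambda_k ||B_k x||^2` through the
#' normal equations, solved by sparse Cholesky factorization.
#'
#' @param problem List with `A` (sparse design matrix), `b` (target
#'   vector) and `regs`, a list of `list(B = operator, lambda = weight)`.
#' @return Numeric solution vector of control-point values.
#' @export
fit_parameter <- function(problem) {
  A <- problem$A
  N <- Matrix::crossprod(A)
  for (rg in problem$regs) {
    if (rg$lambda > 0 && nrow(rg$B) > 0)
      N <- N + rg$lambda * Matrix::crossprod(rg$B)
  }
  rhs <- Matrix::crossprod(A, problem$b)
  x <- tryCatch(suppressWarnings(Matrix::solve(N, rhs)),
                error = function(e)
                  stop("normal matrix is singular or ill-conditioned; ",
                       "try a larger regularization alpha (", conditionMessage(e),
                       ")", call. = FALSE))
  as.numeric(x)
}

#' Restrain the background-offset parameter
#'
#' The offset correction must be positive, and to remove the degeneracy
#' with the merged intensity it is anchored at zero: negative control
#' points are clipped to zero, and if all points are positive a constant is
#' subtracted so at least one value equals zero.
#'
#' @param values Numeric vector of offset control points.
#' @return Restrained values (all `>= 0`, with `min = 0`).
#' @export
restrain_offset <- function(values) {
  values[values < 0] <- 0
  if (length(values) && min(values) > 0) values <- values - min(values)
  values
}
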