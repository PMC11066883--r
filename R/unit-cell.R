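#' Unit cell
#'
#' Construct a crystallographic unit cell from edge lengths (angstrom) and
#' angles (degrees).  The reciprocal metric tensor is precomputed so that
#' scattering-vector magnitudes can be evaluated for arbitrary (possibly
#' fractional) Miller indices.
#'
#' @param a,b,c Cell edge lengths in angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees (0 < angle < 180).
#' @return An object of class `unit_cell`.
#' @seealso [cubic_cell()] for the common cubic special case.
#' @export
unit_cell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90) {
  lengths <- c(a = a, b = b, c = c)
  angles <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (!all(is.finite(lengths)) || any(lengths <= 0))
    stop("cell edge lengths must be finite and > 0")
  if (!all(is.finite(angles)) || any(angles <= 0) || any(angles >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  # direct metric tensor G; reciprocal metric is its inverse
  G <- matrix(c(a * a, a * b * cg, a * c * cb,
                a * b * cg, b * b, b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 metric = G, reciprocal_metric = solve(G)),
            class = "unit_cell")
}

#' Cubic unit cell
#'
#' @param a Cell edge in angstrom; all three edges are set equal with
#'   90 degree angles.
#' @return A `unit_cell`.
#' @export
cubic_cell <- function(a) unit_cell(a)

is_cubic <- function(cell) {
  isTRUE(all.equal(c(cell$a, cell$b), c(cell$c, cell$c))) &&
    isTRUE(all.equal(c(cell$alpha, cell$beta, cell$gamma), c(90, 90, 90)))
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4g b=%.4g c=%.4g A, angles %.4g/%.4g/%.4g deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Scattering-vector magnitude
#'
#' Magnitude of the scattering vector s (in inverse angstrom) for fractional
#' Miller indices, using the reciprocal metric of the cell.  The resolution
#' is `1/s`.  For a cubic cell this reduces to `sqrt(h^2+k^2+l^2)/a`.
#'
#' @param hkl Numeric length-3 vector or n x 3 matrix of (fractional)
#'   Miller indices.
#' @param cell A [unit_cell()].
#' @return Numeric vector of |s| values in 1/angstrom.
#' @export
s_magnitude <- function(hkl, cell) {
  h <- as_hkl_matrix(hkl)
  q <- h %*% cell$reciprocal_metric
  sqrt(pmax(rowSums(q * h), 0))
}

as_hkl_matrix <- function(hkl) {
  if (is.null(dim(hkl))) {
    if (length(hkl) != 3) stop("hkl must have 3 components")
    hkl <- matrix(hkl, 1, 3)
  }
  hkl <- as.matrix(hkl)
  if (ncol(hkl) != 3) stop("hkl must have 3 columns")
  storage.mode(hkl) <- "double"
  hkl
}

#' Real-space wavelength of a lattice modulation
#'
#' Wave-like displacements of the crystal lattice with (fractional)
#' reciprocal-space offset `q_frac` from a Bragg node correspond to
#' real-space modulation waves of wavelength `a / q_frac` in a cubic cell.
#'
#' @param q_frac Magnitude of the fractional reciprocal-space offset (> 0),
#'   dimensionless.
#' @param cell A cubic [unit_cell()].
#' @return Wavelength in angstrom.
#' @export
modulation_wavelength <- function(q_frac, cell) {
  if (!is_cubic(cell)) stop("modulation_wavelength requires a cubic cell")
  if (any(!is.finite(q_frac)) || any(q_frac <= 0))
    stop("q_frac must be finite and > 0")
  cell$a / q_frac
}

#' Distance from a Bragg node to the corner of its voxel
#'
#' For a grid that subdivides the reciprocal cell by an integer factor `n`
#' per axis, voxels are cubes of fractional side `1/n`; the farthest point of
#' the node-centred voxel from the node is the half body diagonal,
#' `sqrt(3)/(2n)` in fractional units (e.g. 0.289 for `n = 3`).
#'
#' @param subdivision Integer subdivision per axis (>= 1).
#' @return Fractional distance (dimensionless).
#' @export
voxel_corner_distance <- function(subdivision) {
  if (any(subdivision < 1)) stop("subdivision must be >= 1")
  sqrt(3) / (2 * subdivision)
}
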