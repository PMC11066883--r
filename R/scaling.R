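#' Scaling configuration
#'
#' Settings for scaling-model refinement.  By default only the overall
#' scale factor `b(phi)` (illuminated volume) is refined; `full_model =
#' TRUE` enables all four physically motivated terms: absorption
#' `a(x, y, phi)`, illuminated volume `b(phi)`, background offset
#' `c(s, phi)` and detector flat field `d(x, y)` (fitted globally across
#' sweeps), so each observation is modelled as
#' `I_pred = m * I0 + o` with `m = a*b*d` and `o = a*c*d`.
#'
#' @param full_model Enable all four model terms.
#' @param enabled Optional named logical vector over `c("a","b","c","d")`
#'   overriding `full_model`.
#' @param alphas Named regularization parameters: smoothness weights for
#'   each term plus `c_magnitude` for the identity penalty that keeps the
#'   offset as small as the data allow.
#' @param b_phi_step Spacing of `b` control points in degrees of phi.
#' @param c_s_points Number of `c` control points along s.
#' @param c_phi_step Spacing of `c` control points in degrees.
#' @param a_xy_points Control points per detector axis for `a`.
#' @param a_phi_step Spacing of `a` control points in degrees.
#' @param d_xy_points Control points per detector axis for `d`.
#' @param max_cycles Maximum refinement cycles.
#' @param tol Relative chi-square change below which refinement halts.
#' @param outlier_sigma Rejection threshold in standard errors, applied
#'   between cycles (after the first); `Inf` disables rejection.
#' @return A list of class `scale_config`.
#' @export
scale_config <- function(full_model = FALSE, enabled = NULL, alphas = NULL,
                         b_phi_step = 2.5, c_s_points = 15, c_phi_step = 5,
                         a_xy_points = 5, a_phi_step = 10, d_xy_points = 200,
                         max_cycles = 20, tol = 1e-4, outlier_sigma = 5) {
  en <- if (full_model) c(a = TRUE, b = TRUE, c = TRUE, d = TRUE)
        else c(a = FALSE, b = TRUE, c = FALSE, d = FALSE)
  if (!is.null(enabled)) en[names(enabled)] <- enabled
  al <- c(a = 1, b = 1, c = 1, d = 1, c_magnitude = 0.01)
  if (!is.null(alphas)) al[names(alphas)] <- alphas
  structure(list(enabled = en, alphas = al, b_phi_step = b_phi_step,
                 c_s_points = c_s_points, c_phi_step = c_phi_step,
                 a_xy_points = a_xy_points, a_phi_step = a_phi_step,
                 d_xy_points = d_xy_points, max_cycles = max_cycles,
                 tol = tol, outlier_sigma = outlier_sigma),
            class = "scale_config")
}

axis_over <- function(lo, hi, n = NULL, step = NULL) {
  if (hi <= lo) return(lo)
  if (is.null(n)) n <- max(2L, as.integer(ceiling((hi - lo) / step)) + 1L)
  seq(lo, hi, length.out = n)
}

#' Build an initialized scaling model for an observation table
#'
#' Creates neutral parameter grids (scales 1, offset 0) with axes spanning
#' the observed coordinate ranges; `a`, `b` and `c` grids are per sweep,
#' `d` is global.
#'
#' @param obs Observation table with columns `batch`, `phi`, `x`, `y`, `s`.
#' @param config A [scale_config()].
#' @return Object of class `scaling_model`.
#' @export
build_scaling_model <- function(obs, config = scale_config()) {
  en <- config$enabled
  batches <- sort(unique(obs$batch))
  xr <- range(obs$x); yr <- range(obs$y); sr <- range(obs$s)
  x_ax_a <- axis_over(xr[1], xr[2], n = config$a_xy_points)
  y_ax_a <- axis_over(yr[1], yr[2], n = config$a_xy_points)
  x_ax_d <- axis_over(xr[1], xr[2], n = config$d_xy_points)
  y_ax_d <- axis_over(yr[1], yr[2], n = config$d_xy_points)
  s_ax <- axis_over(sr[1], sr[2], n = config$c_s_points)
  sweeps <- lapply(batches, function(bt) {
    pr <- range(obs$phi[obs$batch == bt])
    list(
      a = if (en["a"]) param_grid(list(x_ax_a, y_ax_a,
            axis_over(pr[1], pr[2], step = config$a_phi_step)), fill = 1),
      b = if (en["b"]) param_grid(list(
            axis_over(pr[1], pr[2], step = config$b_phi_step)), fill = 1),
      c = if (en["c"]) param_grid(list(s_ax,
            axis_over(pr[1], pr[2], step = config$c_phi_step)), fill = 0))
  })
  names(sweeps) <- as.character(batches)
  d <- if (en["d"]) param_grid(list(x_ax_d, y_ax_d), fill = 1)
  structure(list(enabled = en, batches = batches, sweeps = sweeps, d = d),
            class = "scaling_model")
}

#' @export
print.scaling_model <- function(x, ...) {
  on <- names(x$enabled)[x$enabled]
  cat(sprintf("scaling_model: %d sweep(s); enabled terms: %s\n",
              length(x$batches),
              if (length(on)) paste(on, collapse = ", ") else "none"))
  invisible(x)
}

param_coords <- function(kind, obs) {
  switch(kind,
         a = cbind(obs$x, obs$y, obs$phi),
         b = matrix(obs$phi, ncol = 1),
         c = cbind(obs$s, obs$phi),
         d = cbind(obs$x, obs$y))
}

#' Evaluate a scaling model at observation coordinates
#'
#' @param model A [build_scaling_model()] result (possibly refined).
#' @param obs Observation table with columns `batch`, `phi`, `x`, `y`, `s`.
#' @return data.frame with per-observation `a`, `b`, `c`, `d`, the scale
#'   `m = a*b*d` and offset `o = a*c*d`.
#' @export
evaluate_model <- function(model, obs) {
  n <- nrow(obs)
  av <- rep(1, n); bv <- rep(1, n); cv <- rep(0, n); dv <- rep(1, n)
  for (bt in model$batches) {
    rows <- which(obs$batch == bt)
    if (!length(rows)) next
    sw <- model$sweeps[[as.character(bt)]]
    sub <- obs[rows, , drop = FALSE]
    for (kind in c("a", "b", "c")) {
      pg <- sw[[kind]]
      if (is.null(pg)) next
      M <- interp_operator(param_coords(kind, sub), pg$axes)
      val <- as.numeric(M %*% as.vector(pg$values))
      if (kind == "a") av[rows] <- val
      if (kind == "b") bv[rows] <- val
      if (kind == "c") cv[rows] <- val
    }
  }
  if (!is.null(model$d)) {
    M <- interp_operator(param_coords("d", obs), model$d$axes)
    dv <- as.numeric(M %*% as.vector(model$d$values))
  }
  data.frame(a = av, b = bv, c = cv, d = dv, m = av * bv * dv,
             o = av * cv * dv)
}

#' Merge scaled observations by inverse-variance weighting
#'
#' Applies the current scaling model, `I_scaled = (I - o)/m`,
#' `sigma_scaled = sigma/m`, and merges all equivalent observations of each
#' asymmetric-unit voxel with weights `w = sigma_scaled^-2`:
#' `I0 = sum(w I_scaled)/sum(w)`, `sigma0 = sum(w)^-1/2`.  Observations
#' with non-positive sigma (zero counts) are excluded; voxels with no
#' usable observation are absent from the output.
#'
#' @param obs Observation table with columns `I`, `sigma`, `asu_i`,
#'   `asu_j`, `asu_k`.
#' @param model Optional [scaling_model()]; if supplied, `m` and `o` are
#'   evaluated from it.
#' @param m,o Per-observation scale and offset (defaults 1 and 0).
#' @param grid Optional [miller_grid()]; if given, fractional `h`, `k`,
#'   `l` columns for the asymmetric-unit voxel centers are included.
#' @param keep Optional logical vector of observations to include.
#' @return Merged table: `asu_i`, `asu_j`, `asu_k`, optional `h,k,l`,
#'   merged intensity `I`, standard error `sigma`, `n_obs`.
#' @export
merge_scaled <- function(obs, model = NULL, m = NULL, o = NULL, grid = NULL,
                         keep = NULL) {
  n <- nrow(obs)
  if (!is.null(model)) {
    ev <- evaluate_model(model, obs)
    m <- ev$m; o <- ev$o
  }
  if (is.null(m)) m <- rep(1, n)
  if (is.null(o)) o <- rep(0, n)
  m <- rep_len(m, n); o <- rep_len(o, n)
  ok <- is.finite(obs$I) & is.finite(obs$sigma) & obs$sigma > 0 & m > 0
  if (!is.null(keep)) ok <- ok & keep
  dt <- data.table::data.table(
    asu_i = obs$asu_i, asu_j = obs$asu_j, asu_k = obs$asu_k,
    iscl = (obs$I - o) / m, w = (m / obs$sigma)^2)[ok]
  if (nrow(dt) == 0)
    stop("no usable observations to merge (all sigma <= 0 or excluded)")
  mrg <- dt[, list(I = sum(w * iscl) / sum(w), sigma = 1 / sqrt(sum(w)),
                   n_obs = .N), by = c("asu_i", "asu_j", "asu_k")]
  data.table::setorderv(mrg, c("asu_i", "asu_j", "asu_k"))
  out <- as.data.frame(mrg)
  if (!is.null(grid)) {
    hkl <- voxel_center(as.matrix(out[, c("asu_i", "asu_j", "asu_k")]), grid)
    out <- cbind(out[, 1:3], h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                 out[, c("I", "sigma", "n_obs")])
  }
  out
}

#' Assemble the least-squares problem for one scaling parameter
#'
#' With all other parameters held fixed, each scaling term satisfies a
#' linear least-squares problem `||A x - b||^2` in its control points `x`,
#' where `A` is a diagonal matrix of partner factors over sigma times the
#' interpolation operator `M`:
#' \describe{
#'   \item{a}{`A = diag[d(b I0 + c)/sigma] M`, `b = I/sigma`}
#'   \item{b}{`A = diag(d a I0/sigma) M`, `b = (I - a c d)/sigma`}
#'   \item{c}{`A = diag(d a/sigma) M`, `b = (I - a b d I0)/sigma`}
#'   \item{d}{`A = diag[a(b I0 + c)/sigma] M`, `b = I/sigma`}
#' }
#' Regularization operators are attached with weights computed by
#' [renormalize_alpha()].
#'
#' @param kind One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param M Interpolation operator for this parameter at the observation
#'   coordinates.
#' @param I,sigma Corrected intensities and uncertainties.
#' @param I0 Current merged intensity per observation.
#' @param a,b,c,d Current per-observation values of the partner parameters.
#' @param reg_ops List of regularization operators (B matrices).
#' @param reg_alphas Numeric vector of alphas, one per operator.
#' @return A problem list for [fit_parameter()].
#' @export
assemble_problem <- function(kind, M, I, sigma, I0, a = 1, b = 1, c = 0,
                             d = 1, reg_ops = list(), reg_alphas = numeric(0)) {
  n <- length(I)
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  d <- rep_len(d, n)
  coefs <- switch(kind,
                  a = d * (b * I0 + c) / sigma,
                  b = d * a * I0 / sigma,
                  c = d * a / sigma,
                  d = a * (b * I0 + c) / sigma,
                  stop("unknown parameter kind: ", kind))
  rhs <- switch(kind,
                a = I / sigma,
                b = (I - a * c * d) / sigma,
                c = (I - a * b * d * I0) / sigma,
                d = I / sigma)
  A <- Matrix::Diagonal(n, x = coefs) %*% M
  regs <- Map(function(B, alpha)
    list(B = B, lambda = renormalize_alpha(alpha, A, B)),
    reg_ops, as.list(rep_len(reg_alphas, length(reg_ops))))
  list(A = A, b = rhs, regs = regs)
}

# regularization operators for one parameter grid, per Table-1-style rules:
# second derivative along phi and s axes, Laplacian over (x, y), and an
# identity magnitude penalty for the offset
regularizers_for <- function(kind, pg, alphas) {
  nd <- dim(pg$values)
  eye <- function(n) Matrix::Diagonal(n, x = rep(1, n))
  if (kind == "b") {
    list(ops = list(second_derivative_operator(nd[1])),
         alphas = alphas[["b"]])
  } else if (kind == "c") {
    ns <- nd[1]; np <- nd[2]
    list(ops = list(kronecker(eye(np), second_derivative_operator(ns)),
                    kronecker(second_derivative_operator(np), eye(ns)),
                    identity_operator(ns * np)),
         alphas = c(alphas[["c"]], alphas[["c"]], alphas[["c_magnitude"]]))
  } else if (kind == "a") {
    nx <- nd[1]; ny <- nd[2]; np <- nd[3]
    list(ops = list(kronecker(eye(np), laplacian_operator(nx, ny)),
                    kronecker(second_derivative_operator(np), eye(nx * ny))),
         alphas = c(alphas[["a"]], alphas[["a"]]))
  } else if (kind == "d") {
    list(ops = list(laplacian_operator(nd[1], nd[2])),
         alphas = alphas[["d"]])
  } else stop("unknown parameter kind: ", kind)
}

#' Refine the scaling model by regularized alternating least squares
#'
#' Alternates between inverse-variance merging (with the model held fixed)
#' and regularized least-squares refits of each enabled parameter in the
#' order b, c, a, d (with the merged intensity and partner parameters held
#' fixed).  The offset positivity restraint is applied after each `c` fit.
#' After every cycle the overall-scale gauge is fixed by normalizing the
#' mean of `b` over all sweeps to 1 (the compensating factor folds into the
#' merged intensity at the next merge).  Observations deviating from the
#' merged value by more than `outlier_sigma` standard errors are rejected
#' between cycles.  Refinement halts when the relative chi-square change
#' drops below `tol` or after `max_cycles`; three consecutive chi-square
#' increases abort with diagnostics.
#'
#' @param obs Observation table with columns `batch`, `asu_i`, `asu_j`,
#'   `asu_k`, `I`, `sigma`, `phi`, `x`, `y`, `s`.
#' @param config A [scale_config()].
#' @param grid Optional [miller_grid()] used to add fractional `h,k,l` to
#'   the merged output.
#' @return Object of class `scaling_fit`: `model`, `merged`, per-observation
#'   `scale` data.frame (a, b, c, d, m, o), logical `active` (FALSE for
#'   rejected outliers/unusable rows) and `diagnostics` (chi-square trace,
#'   cycles, convergence flag, rejected count).
#' @export
refine_scaling <- function(obs, config = scale_config(), grid = NULL) {
  n <- nrow(obs)
  usable <- is.finite(obs$I) & is.finite(obs$sigma) & obs$sigma > 0
  key <- paste(obs$asu_i, obs$asu_j, obs$asu_k)
  uk <- unique(key)
  vox_id <- match(key, uk)
  if (max(tabulate(vox_id[usable])) < 2)
    stop("scaling requires at least one asymmetric-unit voxel with >= 2 usable observations")
  model <- build_scaling_model(obs, config)
  en <- model$enabled
  alphas <- config$alphas
  batches <- model$batches

  rows_by_batch <- lapply(batches, function(bt) which(obs$batch == bt))
  names(rows_by_batch) <- as.character(batches)
  # interpolation operators over all rows; subset rows during fitting
  Mops <- list(a = list(), b = list(), c = list())
  for (bt in batches) {
    sw <- model$sweeps[[as.character(bt)]]
    rows <- rows_by_batch[[as.character(bt)]]
    sub <- obs[rows, , drop = FALSE]
    for (kind in c("a", "b", "c")) {
      if (!is.null(sw[[kind]]))
        Mops[[kind]][[as.character(bt)]] <-
          interp_operator(param_coords(kind, sub), sw[[kind]]$axes)
    }
  }
  Md <- if (en["d"]) interp_operator(param_coords("d", obs), model$d$axes)

  av <- rep(1, n); bv <- rep(1, n); cv <- rep(0, n); dv <- rep(1, n)
  eval_kind <- function(kind) {
    out <- rep(if (kind == "c") 0 else 1, n)
    for (bt in batches) {
      rows <- rows_by_batch[[as.character(bt)]]
      pg <- model$sweeps[[as.character(bt)]][[kind]]
      out[rows] <- as.numeric(Mops[[kind]][[as.character(bt)]] %*%
                                as.vector(pg$values))
    }
    out
  }

  active <- usable
  chi2_trace <- numeric(0)
  inc_streak <- 0L
  converged <- FALSE

  for (cycle in seq_len(config$max_cycles)) {
    mv <- av * bv * dv; ov <- av * cv * dv
    mrg <- merge_by_id(obs$I, obs$sigma, vox_id, length(uk), mv, ov, active)
    I0_obs <- mrg$I0[vox_id]
    fit_ok <- active & !is.na(I0_obs) & mv > 0
    chi2 <- sum(((obs$I - (mv * I0_obs + ov)) / obs$sigma)[fit_ok]^2)
    prev <- if (length(chi2_trace)) chi2_trace[length(chi2_trace)] else NA
    chi2_trace <- c(chi2_trace, chi2)
    if (!is.na(prev)) {
      if (chi2 > prev * (1 + 1e-12)) inc_streak <- inc_streak + 1L
      else inc_streak <- 0L
      if (inc_streak >= 3L)
        stop("scaling refinement diverged: chi-square increased for 3 ",
             "consecutive cycles (trace: ",
             paste(signif(chi2_trace, 6), collapse = ", "), ")")
      if (abs(chi2 - prev) < config$tol * prev) { converged <- TRUE; break }
    }

    for (kind in c("b", "c", "a", "d")) {
      if (!en[kind]) next
      if (kind == "d") {
        rows <- which(fit_ok)
        rg <- regularizers_for("d", model$d, alphas)
        prob <- assemble_problem("d", Md[rows, , drop = FALSE],
                                 obs$I[rows], obs$sigma[rows], I0_obs[rows],
                                 a = av[rows], b = bv[rows], c = cv[rows],
                                 reg_ops = rg$ops, reg_alphas = rg$alphas)
        model$d$values[] <- fit_parameter(prob)
        dv <- as.numeric(Md %*% as.vector(model$d$values))
      } else {
        for (bt in batches) {
          btc <- as.character(bt)
          rows_all <- rows_by_batch[[btc]]
          rows <- rows_all[fit_ok[rows_all]]
          if (length(rows) < 2) next
          pg <- model$sweeps[[btc]][[kind]]
          local_idx <- match(rows, rows_all)
          Msub <- Mops[[kind]][[btc]][local_idx, , drop = FALSE]
          rg <- regularizers_for(kind, pg, alphas)
          prob <- assemble_problem(kind, Msub, obs$I[rows], obs$sigma[rows],
                                   I0_obs[rows], a = av[rows], b = bv[rows],
                                   c = cv[rows], d = dv[rows],
                                   reg_ops = rg$ops, reg_alphas = rg$alphas)
          x <- fit_parameter(prob)
          if (kind == "c") x <- restrain_offset(x)
          model$sweeps[[btc]][[kind]]$values[] <- x
        }
        if (kind == "a") av <- eval_kind("a")
        if (kind == "b") bv <- eval_kind("b")
        if (kind == "c") cv <- eval_kind("c")
      }
    }

    if (en["b"]) {
      g <- mean(unlist(lapply(model$sweeps, function(sw) as.vector(sw$b$values))))
      if (is.finite(g) && g > 0) {
        for (btc in names(model$sweeps))
          model$sweeps[[btc]]$b$values <- model$sweeps[[btc]]$b$values / g
        bv <- bv / g
      }
    }

    if (is.finite(config$outlier_sigma)) {
      mv <- av * bv * dv; ov <- av * cv * dv
      iscl <- (obs$I - ov) / mv
      sscl <- obs$sigma / mv
      bad <- active & !is.na(I0_obs) & mv > 0 &
        abs(iscl - I0_obs) > config$outlier_sigma * sscl
      active[bad] <- FALSE
    }
  }

  mv <- av * bv * dv; ov <- av * cv * dv
  merged <- merge_scaled(obs, m = mv, o = ov, grid = grid, keep = active)
  structure(list(
    model = model, merged = merged,
    scale = data.frame(a = av, b = bv, c = cv, d = dv, m = mv, o = ov),
    active = active,
    diagnostics = list(chi2 = chi2_trace, cycles = length(chi2_trace),
                       converged = converged,
                       n_rejected = sum(usable & !active))),
    class = "scaling_fit")
}

merge_by_id <- function(I, sigma, vox_id, n_vox, m, o, active) {
  ok <- active & sigma > 0 & m > 0
  iscl <- (I[ok] - o[ok]) / m[ok]
  w <- (m[ok] / sigma[ok])^2
  sw <- rowsum(cbind(w, w * iscl), vox_id[ok])
  ids <- as.integer(rownames(sw))
  I0 <- rep(NA_real_, n_vox)
  sig0 <- rep(NA_real_, n_vox)
  I0[ids] <- sw[, 2] / sw[, 1]
  sig0[ids] <- 1 / sqrt(sw[, 1])
  list(I0 = I0, sigma0 = sig0)
}

#' @export
print.scaling_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "scaling_fit: %d cycle(s), chi2 %.6g -> %.6g, %s, %d outlier(s) rejected\n",
    d$cycles, d$chi2[1], d$chi2[length(d$chi2)],
    if (d$converged) "converged" else "cycle limit reached", d$n_rejected))
  invisible(x)
}
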