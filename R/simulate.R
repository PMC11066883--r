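#' Synthetic-experiment configuration
#'
#' Parameters of the bundled rotation-series simulator.  Defaults emulate a
#' fine phi-sliced room-temperature experiment on a cubic I-centered
#' crystal (cell edge 79.48 A, 50 degree sweeps of 0.1 degree frames at
#' 1 degree per second), with smooth isotropic diffuse intensity peaking
#' near 3 A resolution (s ~ 0.33 1/A), a band-limited variational
#' component symmetrized over the Laue group, halo intensity decaying as
#' the inverse square of the distance from allowed reciprocal-lattice
#' nodes, and the four multiplicative/additive artifact fields of the
#' scaling model.
#'
#' @param cell_a Cubic cell edge (angstrom).
#' @param subdivision Grid oversampling factor per axis.
#' @param centering Lattice centering (reflection condition).
#' @param laue Laue-group preset name.
#' @param n_sweeps Number of rotation sweeps.
#' @param phi_range Rotation range per sweep (degrees).
#' @param phi_step Rotation per image (degrees).
#' @param exposure Exposure per image (seconds).
#' @param detector_nx,detector_ny Detector size in pixels.
#' @param pixels_per_obs Pixels contributing per observation
#'   (observation-level mode); cumulative exposure is
#'   `pixels_per_obs * exposure / phi_step * phi_step` = pixels x exposure.
#' @param obs_per_sweep Observations generated per sweep.
#' @param n_voxels Number of distinct asymmetric-unit voxels sampled.
#' @param s_min,s_max Scattering-vector range sampled (1/angstrom).
#' @param iso_low,iso_peak,iso_base Isotropic profile: low-angle term,
#'   3 A-peak term and constant floor (photons/pixel/s).
#' @param variational_amplitude Amplitude of the band-limited variational
#'   field (photons/pixel/s).
#' @param halo_amplitude,halo_epsilon Halo term `A/(dq^2 + eps)` with
#'   `dq` the fractional distance from the nearest allowed node; `eps`
#'   defaults to the square of a typical peak-mask radius (0.102).
#' @param amp_a,amp_b,amp_c Artifact amplitudes for absorption, illuminated
#'   volume and background offset (set 0 to disable an artifact).
#' @param chip_drop,edge_drop Detector flat-field preset: relative response
#'   loss of one low-response chip rectangle and of panel edges (up to 20%).
#' @param background_rate Background rate (photons/pixel/s).
#' @param bragg_spike_rate Bragg-peak rate at allowed nodes in image mode
#'   (photons/pixel/s at the peak center).
#' @param seed Base seed; per-sweep sub-streams are derived from it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(cell_a = 79.48, subdivision = 3,
                              centering = "I", laue = "m-3",
                              n_sweeps = 4, phi_range = 50, phi_step = 0.1,
                              exposure = 0.1,
                              detector_nx = 100, detector_ny = 100,
                              pixels_per_obs = 100, obs_per_sweep = 25000,
                              n_voxels = 2000, s_min = 0.02, s_max = 0.4,
                              iso_low = 30, iso_peak = 40, iso_base = 5,
                              variational_amplitude = 2,
                              halo_amplitude = 0.3, halo_epsilon = 0.102^2,
                              amp_a = 0.1, amp_b = 0.3, amp_c = 2,
                              chip_drop = 0.1, edge_drop = 0.2,
                              background_rate = 2, bragg_spike_rate = 2000,
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$phi_range > 0, cfg$phi_step > 0, cfg$exposure > 0,
            cfg$background_rate >= 0, cfg$halo_amplitude >= 0,
            cfg$amp_a >= 0, cfg$amp_b >= 0, cfg$amp_c >= 0)
  structure(cfg, class = "simulation_config")
}

sim_grid <- function(config) {
  miller_grid(cubic_cell(config$cell_a), config$subdivision,
              config$centering, config$laue)
}

# squared fractional distance from each hkl to the nearest centering-allowed
# integer node (searching the 27 surrounding nodes)
nearest_allowed_dist2 <- function(hkl, centering) {
  hkl <- as_hkl_matrix(hkl)
  n <- nrow(hkl)
  best <- rep(Inf, n)
  for (dh in -1:1) for (dk in -1:1) for (dl in -1:1) {
    node <- cbind(round(hkl[, 1]) + dh, round(hkl[, 2]) + dk,
                  round(hkl[, 3]) + dl)
    ok <- centering_allowed(node, centering)
    d2 <- rowSums((hkl - node)^2)
    upd <- ok & d2 < best
    best[upd] <- d2[upd]
  }
  best
}

#' Simulate the ground-truth diffuse intensity field
#'
#' Builds the true intensity per asymmetric-unit voxel:
#' isotropic(s) + variational + halo.  The variational term is a
#' band-limited random field (a fixed set of random cosine waves)
#' symmetrized by averaging over the Laue-group orbit of each voxel.  The
#' halo term is `A_h * g(node) / (dq^2 + eps)` where `dq` is the
#' fractional distance to the nearest allowed node and `g` modulates the
#' halo strength smoothly from node to node.
#'
#' @param config A [simulation_config()].
#' @return Object of class `ground_truth`: the sampled voxel `table`
#'   (asu indices, fractional hkl, s, I0), the evaluator `I0_of(vox)`,
#'   per-sweep artifact field functions `a_fun`, `b_fun`, `c_fun`, global
#'   `d_fun`, and the `grid`.
#' @export
simulate_truth <- function(config) {
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  grid <- sim_grid(config)
  ops <- grid$laue_ops

  # band-limited random fields: fixed cosine waves in fractional hkl
  n_wave <- 6L
  u_var <- matrix(stats::runif(3 * n_wave, -0.5, 0.5), n_wave, 3)
  ph_var <- stats::runif(n_wave, 0, 2 * pi)
  u_halo <- matrix(stats::runif(3 * n_wave, -0.25, 0.25), n_wave, 3)
  ph_halo <- stats::runif(n_wave, 0, 2 * pi)
  wave_field <- function(hkl, u, ph) {
    acc <- 0
    for (w in seq_len(nrow(u)))
      acc <- acc + cos(2 * pi * (hkl %*% u[w, ]) + ph[w])
    as.numeric(acc) / sqrt(nrow(u))
  }
  iso <- function(s) {
    config$iso_low * exp(-(s / 0.08)^2) +
      config$iso_peak * exp(-((s - 0.33) / 0.10)^2) + config$iso_base
  }
  I0_of <- function(vox) {
    vox <- as_hkl_matrix(vox)
    hkl <- voxel_center(vox, grid)
    s <- s_magnitude(hkl, grid$cell)
    # symmetrize the variational field over the Laue orbit; orbit averaging
    # of incoherent waves damps the amplitude ~ 1/sqrt(n_ops), so restore it
    varv <- 0
    for (R in ops) varv <- varv + wave_field(hkl %*% t(R), u_var, ph_var)
    varv <- config$variational_amplitude * varv / sqrt(length(ops))
    halo <- 0
    if (config$halo_amplitude > 0) {
      d2 <- nearest_allowed_dist2(hkl, config$centering)
      gsym <- 0
      for (R in ops) {
        node <- round(hkl %*% t(R))
        gsym <- gsym + wave_field(node, u_halo, ph_halo)
      }
      g <- 1 + 0.3 * gsym / length(ops) * sqrt(length(ops))
      halo <- config$halo_amplitude * pmax(g, 0.2) / (d2 + config$halo_epsilon)
    }
    pmax(iso(s) + varv + halo, 0.05)
  }

  # sample distinct asymmetric-unit voxels within the s range
  hmax <- ceiling(config$s_max * config$cell_a)
  n_sub <- grid$subdivision[1]
  found <- matrix(integer(0), 0, 3)
  while (nrow(found) < config$n_voxels) {
    cand <- matrix(sample.int(2L * hmax * n_sub + 1L,
                              3L * 2L * config$n_voxels, replace = TRUE) -
                     (hmax * n_sub + 1L), ncol = 3)
    s <- s_magnitude(voxel_center(cand, grid), grid$cell)
    cand <- cand[s >= config$s_min & s <= config$s_max, , drop = FALSE]
    if (!nrow(cand)) next
    asu <- map_to_asu(cand, grid)$asu
    found <- unique(rbind(found, asu))
  }
  vox <- found[seq_len(config$n_voxels), , drop = FALSE]
  hkl <- voxel_center(vox, grid)
  tab <- data.frame(asu_i = vox[, 1], asu_j = vox[, 2], asu_k = vox[, 3],
                    h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    s = s_magnitude(hkl, grid$cell), I0 = I0_of(vox))

  # artifact fields; per-sweep random phases
  nx <- config$detector_nx; ny <- config$detector_ny
  ph_sweep <- stats::runif(config$n_sweeps, 0, 2 * pi)
  ph_sweep2 <- stats::runif(config$n_sweeps, 0, 2 * pi)
  b_fun <- lapply(seq_len(config$n_sweeps), function(sw) {
    ph <- ph_sweep[sw]
    function(phi) 1 + config$amp_b * sin(2 * pi * phi / config$phi_range + ph)
  })
  a_fun <- lapply(seq_len(config$n_sweeps), function(sw) {
    ph <- ph_sweep2[sw]
    function(x, y, phi) {
      1 + config$amp_a * sin(pi * x / nx) * sin(pi * y / ny) *
        (0.6 + 0.4 * cos(2 * pi * phi / config$phi_range + ph))
    }
  })
  # excess background enters the beam during part of the scan only (e.g.
  # the loop or excess solvent); the offset is exactly zero elsewhere
  c_fun <- lapply(seq_len(config$n_sweeps), function(sw) {
    amp <- config$amp_c * (0.5 + 0.5 * (sw %% 2))
    function(s, phi) {
      amp * exp(-((s - 0.12) / 0.10)^2) *
        pmax(0, sin(2 * pi * phi / config$phi_range))
    }
  })
  chip <- c(0.55, 0.75, 0.70, 0.85) * c(nx, nx, ny, ny)
  d_fun <- function(x, y) {
    ex <- pmin(x, nx - x, abs(x - nx / 2))
    ey <- pmin(y, ny - y, abs(y - ny / 2))
    edge <- pmax(0, 1 - pmin(ex, ey) / 6)
    in_chip <- x >= chip[1] & x <= chip[2] & y >= chip[3] & y <= chip[4]
    (1 - config$edge_drop * edge) * (1 - config$chip_drop * in_chip)
  }

  structure(list(table = tab, I0_of = I0_of, iso = iso,
                 a_fun = a_fun, b_fun = b_fun, c_fun = c_fun, d_fun = d_fun,
                 grid = grid, config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d asymmetric-unit voxels, s in [%.3g, %.3g] 1/A\n",
              nrow(x$table), min(x$table$s), max(x$table$s)))
  invisible(x)
}

#' Simulate one rotation sweep (observation-level records)
#'
#' Generates Poisson-count observations of the sampled voxels: expected
#' counts are `dt * ((m I0 + o) f + r_bg)` with `m = a b d`, `o = a c d`
#' evaluated from the configured artifact fields and `f` the product of
#' geometric correction factors, which are emitted alongside so the
#' corrections can be inverted downstream.
#'
#' @param truth A [simulate_truth()] result.
#' @param sweep Sweep index (1-based).
#' @param seed Seed for this sweep's sub-stream.
#' @param n_obs Number of observations (default from the config).
#' @param noise Draw Poisson counts (TRUE) or report the expected counts
#'   unrounded in `n` (FALSE, for linearity checks).
#' @return Observation table with simulator truth columns `true_m`,
#'   `true_o`, `true_I0` and correction inputs `r_bg`, `f_product`.
#' @export
simulate_sweep <- function(truth, sweep, seed, n_obs = NULL, noise = TRUE) {
  config <- truth$config
  grid <- truth$grid
  if (is.null(n_obs)) n_obs <- config$obs_per_sweep
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  tab <- truth$table
  idx <- sample.int(nrow(tab), n_obs, replace = TRUE)
  asu <- as.matrix(tab[idx, c("asu_i", "asu_j", "asu_k")])
  ops <- grid$laue_ops
  op_pick <- sample.int(length(ops), n_obs, replace = TRUE)
  vox <- asu
  for (oi in seq_along(ops)) {
    rows <- which(op_pick == oi)
    if (length(rows))
      vox[rows, ] <- asu[rows, , drop = FALSE] %*% t(ops[[oi]])
  }
  canon <- map_to_asu(vox, grid)

  phi <- stats::runif(n_obs, 0, config$phi_range)
  x <- stats::runif(n_obs, 0, config$detector_nx)
  y <- stats::runif(n_obs, 0, config$detector_ny)
  s <- tab$s[idx]
  I0 <- tab$I0[idx]

  av <- truth$a_fun[[sweep]](x, y, phi)
  bv <- truth$b_fun[[sweep]](phi)
  cv <- truth$c_fun[[sweep]](s, phi)
  dv <- truth$d_fun(x, y)
  m <- av * bv * dv
  o <- av * cv * dv

  f <- correction_factors(
    solid_angle = 1, efficiency = 0.95, transmission = 0.98,
    polarization = 1 - 0.05 * ((y / config$detector_ny) - 0.5)^2)
  dt <- config$pixels_per_obs * config$exposure
  rate <- dt * ((m * I0 + o) * f$product + config$background_rate)
  n <- if (noise) stats::rpois(n_obs, rate) else rate

  data.frame(batch = sweep, i = vox[, 1], j = vox[, 2], k = vox[, 3],
             asu_i = canon$asu[, 1], asu_j = canon$asu[, 2],
             asu_k = canon$asu[, 3], op = canon$op, friedel = canon$friedel,
             n = n, n_pixels = config$pixels_per_obs, phi = phi, x = x,
             y = y, s = s, dt = dt, r_bg = config$background_rate,
             f_product = f$product, rate = rate,
             true_m = m, true_o = o, true_I0 = I0)
}

#' Simulate a complete synthetic experiment
#'
#' Ground truth plus all sweeps, with corrected intensities attached via
#' [correct_observation()].  All randomness derives from the config seed;
#' per-sweep sub-streams are drawn deterministically from it, so a fixed
#' seed reproduces the tables exactly.
#'
#' @param config A [simulation_config()].
#' @return List: `obs` (observation table with `I`, `sigma`), `truth`,
#'   `grid`, `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  truth <- simulate_truth(config)
  old <- local_seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_sweeps)
  restore_seed(old)
  obs <- do.call(rbind, lapply(seq_len(config$n_sweeps), function(sw)
    simulate_sweep(truth, sw, seed = sub_seeds[sw])))
  cor <- correct_observation(obs$n, obs$dt, obs$r_bg, obs$f_product)
  obs$I <- cor$I
  obs$sigma <- cor$sigma
  list(obs = obs, truth = truth, grid = truth$grid, config = config)
}

#' Rasterize a sweep into a per-pixel image stack
#'
#' Image mode for exercising peak masking, background binning and
#' integration: a small detector is mapped smoothly into reciprocal space
#' (rotating with phi), per-pixel rates include the diffuse truth, the
#' artifact fields, a spatially varying background and optional Bragg
#' spikes at allowed nodes, and counts are drawn Poisson.  Full
#' ray-tracing of diffraction geometry is deliberately not attempted.
#'
#' @param truth A [simulate_truth()] result.
#' @param sweep Sweep index.
#' @param seed Seed for this sweep.
#' @param n_frames Number of frames to rasterize.
#' @param nx,ny Detector size for image mode (small by default).
#' @param span Extent of reciprocal space covered across the detector, in
#'   Miller-index units.
#' @param bragg Include Bragg spikes at allowed nodes.
#' @return List: `images` (frames x nx x ny count array), `pixels` (pixel
#'   stream data.frame for [integrate_counts()]), `phi` per frame, and
#'   `bg_rate(x, y)` the true background field.
#' @export
simulate_images <- function(truth, sweep = 1, seed = 1, n_frames = 40,
                            nx = 48, ny = 48, span = 4, bragg = TRUE) {
  config <- truth$config
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  phi_frames <- (seq_len(n_frames) - 0.5) * config$phi_step
  px <- expand.grid(x = seq_len(nx) - 0.5, y = seq_len(ny) - 0.5)
  bg_rate <- function(x, y)
    config$background_rate * (1 + 0.2 * cos(pi * (x - nx / 2) / nx))

  frames <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    phi <- phi_frames[fi]
    ang <- phi * pi / 180 * 6   # exaggerated sweep so frames revisit voxels
    qx <- (px$x / nx - 0.5) * span
    qy <- (px$y / ny - 0.5) * span
    qz <- 0.35 * span * sin(pi * px$x / nx) * sin(pi * px$y / ny)
    h <- cos(ang) * qx - sin(ang) * qy
    k <- sin(ang) * qx + cos(ang) * qy
    l <- qz
    hkl <- cbind(h, k, l)
    vox <- voxel_of(hkl, truth$grid)
    I0 <- truth$I0_of(vox)
    s <- s_magnitude(voxel_center(vox, truth$grid), truth$grid$cell)
    av <- truth$a_fun[[sweep]](px$x, px$y, phi)
    bv <- truth$b_fun[[sweep]](phi)
    cv <- truth$c_fun[[sweep]](s, phi)
    dv <- truth$d_fun(px$x, px$y)
    rate <- ((av * bv * dv) * I0 + av * cv * dv + bg_rate(px$x, px$y)) *
      config$exposure
    if (bragg) {
      delta <- wrap_delta_hkl(hkl)
      r <- sqrt(rowSums(delta^2))
      node <- hkl - delta
      spike <- centering_allowed(round(node), config$centering) & r < 0.08
      rate <- rate + ifelse(spike,
                            config$bragg_spike_rate * config$exposure *
                              (1 - r / 0.08), 0)
    }
    counts <- stats::rpois(length(rate), rate)
    frames[[fi]] <- data.frame(frame = fi, phi = phi, x = px$x, y = px$y,
                               count = counts, h = h, k = k, l = l,
                               batch = sweep)
  }
  pixels <- do.call(rbind, frames)
  images <- array(0, c(n_frames, nx, ny))
  images[cbind(pixels$frame, ceiling(pixels$x), ceiling(pixels$y))] <- pixels$count
  list(images = images, pixels = pixels, phi = phi_frames, bg_rate = bg_rate,
       nx = nx, ny = ny)
}

#' Simulate a background image stack
#'
#' Frames of pure background scattering (crystal out of the beam), Poisson
#' distributed around a smooth spatial field, for [bin_image_stack()].
#'
#' @param config A [simulation_config()].
#' @param n_frames Number of background frames.
#' @param nx,ny Detector size.
#' @param exposure Exposure per background frame (seconds).
#' @param seed Seed.
#' @return List with `counts` (frames x nx x ny), `exposure` and the true
#'   `rate(x, y)` field.
#' @export
simulate_background_stack <- function(config, n_frames = 20, nx = 48,
                                      ny = 48, exposure = 1, seed = 1) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  px <- expand.grid(x = seq_len(nx) - 0.5, y = seq_len(ny) - 0.5)
  rate <- function(x, y)
    config$background_rate * (1 + 0.2 * cos(pi * (x - nx / 2) / nx))
  r <- rate(px$x, px$y) * exposure
  counts <- array(0, c(n_frames, nx, ny))
  for (fi in seq_len(n_frames)) {
    counts[fi, , ] <- matrix(stats::rpois(length(r), r), nx, ny)
  }
  list(counts = counts, exposure = exposure, rate = rate)
}
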