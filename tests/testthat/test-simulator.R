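test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 5, n_sweeps = 1, obs_per_sweep = 500,
                           n_voxels = 100)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$obs, s2$obs)
  s3 <- simulate_experiment(simulation_config(seed = 6, n_sweeps = 1,
                                              obs_per_sweep = 500,
                                              n_voxels = 100))
  expect_false(identical(s1$obs$n, s3$obs$n))
})

test_that("the truth field is symmetric over Laue orbits", {
  cfg <- simulation_config(seed = 13, n_voxels = 100)
  truth <- simulate_truth(cfg)
  g <- truth$grid
  set.seed(1)
  for (r in 1:4) {
    v <- matrix(sample(-20:20, 3), 1)
    imgs <- t(sapply(g$laue_ops, function(R) as.vector(R %*% t(v))))
    vals <- truth$I0_of(imgs)
    expect_lt(diff(range(vals)), 1e-9 * max(abs(vals)))
  }
})

test_that("halo voxels are brighter on average when halos are enabled", {
  cfg <- simulation_config(seed = 13, n_voxels = 1500)
  truth <- simulate_truth(cfg)
  tab <- truth$table
  halo <- is_bragg_voxel(as.matrix(tab[, c("asu_i", "asu_j", "asu_k")]),
                         truth$grid)
  expect_gt(sum(halo), 3)
  expect_gt(mean(tab$I0[halo]), mean(tab$I0[!halo]))
  # with the halo disabled the intensity is isotropic + variational only
  cfg0 <- simulation_config(seed = 13, n_voxels = 300, halo_amplitude = 0,
                            variational_amplitude = 0)
  truth0 <- simulate_truth(cfg0)
  iso_only <- truth0$iso(truth0$table$s)
  expect_equal(truth0$table$I0, pmax(iso_only, 0.05), tolerance = 1e-12)
})

test_that("expected counts are linear in the volume scale factor", {
  cfg <- sim_config_quiet(seed = 21, n_sweeps = 1, obs_per_sweep = 400,
                          n_voxels = 100)
  truth <- simulate_truth(cfg)
  base <- simulate_sweep(truth, 1, seed = 77, noise = FALSE)
  truth$b_fun[[1]] <- function(phi) rep(2, length(phi))
  doubled <- simulate_sweep(truth, 1, seed = 77, noise = FALSE)
  # before noise: doubling b doubles the diffuse part of the expected counts
  diffuse_base <- base$rate - base$dt * cfg$background_rate
  diffuse_doubled <- doubled$rate - doubled$dt * cfg$background_rate
  expect_equal(diffuse_doubled, 2 * diffuse_base, tolerance = 1e-12)
})

test_that("corrected, merged intensities converge to the truth at high dose", {
  cfg <- sim_config_quiet(seed = 25, n_sweeps = 1, obs_per_sweep = 6000,
                          n_voxels = 300, pixels_per_obs = 10000)
  sim <- simulate_experiment(cfg)
  merged <- merge_scaled(sim$obs)
  tk <- paste(sim$truth$table$asu_i, sim$truth$table$asu_j,
              sim$truth$table$asu_k)
  idx <- match(paste(merged$asu_i, merged$asu_j, merged$asu_k), tk)
  rel <- (merged$I - sim$truth$table$I0[idx]) / sim$truth$table$I0[idx]
  expect_lt(sqrt(mean(rel^2)), 0.01)
})

test_that("image mode produces consistent stacks, spikes and background", {
  cfg <- sim_config_quiet(seed = 29, n_sweeps = 1, detector_nx = 40,
                          detector_ny = 40)
  truth <- simulate_truth(cfg)
  sim <- simulate_images(truth, sweep = 1, seed = 31, n_frames = 10,
                         nx = 40, ny = 40)
  expect_equal(dim(sim$images), c(10, 40, 40))
  expect_equal(sum(sim$images), sum(sim$pixels$count))
  # Bragg spikes create strong pixels near allowed nodes
  strong <- sim$pixels[sim$pixels$count > 20, ]
  expect_gt(nrow(strong), 10)
  d <- wrap_delta_hkl(as.matrix(strong[, c("h", "k", "l")]))
  expect_lt(stats::median(sqrt(rowSums(d^2))), 0.08)
  # background stack reproduces its generating field after binning
  bg <- simulate_background_stack(cfg, n_frames = 30, nx = 40, ny = 40,
                                  seed = 33)
  bm <- bin_image_stack(bg$counts, exposure = bg$exposure, frame_bin = 30,
                        pixel_bin = 10)
  centers_x <- bm$centers[[2]]
  got <- bm$rate[1, , 3]
  want <- bg$rate(centers_x, bm$centers[[3]][3])
  expect_lt(max(abs(got - want) / want), 0.1)
})
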