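make_split_fixture <- function(counts, seed = 1) {
  # observations grouped into voxels with the requested multiplicities
  obs <- do.call(rbind, lapply(seq_along(counts), function(i)
    data.frame(asu_i = i, asu_j = 0, asu_k = 0, I = rnorm(counts[i], 10),
               sigma = 1, friedel = rep_len(c(FALSE, TRUE), counts[i]))))
  obs
}

test_that("random-half splits balance every voxel to within one observation", {
  set.seed(19)
  obs <- make_split_fixture(c(4, 5, 1, 2, 7, 9, 3))
  half <- split_observations(obs, "randomHalf", seed = 5)
  expect_true(all(half %in% 1:2))
  tab <- table(obs$asu_i, half)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))
  expect_equal(unname(tab["1", 1]), 2)      # 4 equivalents -> 2 and 2
  expect_true(all(tab["2", ] %in% c(2, 3))) # 5 -> 3/2 or 2/3, never 4/1
  # deterministic under the same seed, different under another
  expect_identical(half, split_observations(obs, "randomHalf", seed = 5))
  expect_false(identical(half, split_observations(obs, "randomHalf", seed = 6)))
  expect_error(split_observations(obs, "quarters"), "arg")
})

test_that("Friedel splits assign by the inversion flag", {
  obs <- make_split_fixture(c(3, 3))
  half <- split_observations(obs, "Friedel")
  expect_equal(half, ifelse(obs$friedel, 2L, 1L))
  expect_error(split_observations(obs[, -6], "Friedel"), "friedel")
})

test_that("per-shell correlations behave at the fixed points", {
  set.seed(23)
  n <- 600
  merged <- data.frame(asu_i = 1:n, asu_j = 0, asu_k = 0,
                       I = rnorm(n, 5), s = runif(n, 0.1, 0.5))
  scheme <- shell_scheme(merged$s, n_shells = 4)
  # identical halves: 1 everywhere
  cc <- cc_by_shell(merged, merged, scheme)
  expect_equal(cc$cc, rep(1, 4), tolerance = 1e-12)
  # anti-correlated halves: -1
  neg <- merged
  neg$I <- -merged$I
  expect_equal(cc_by_shell(merged, neg, scheme)$cc, rep(-1, 4),
               tolerance = 1e-12)
  # affine rescaling leaves CC unchanged
  aff <- merged
  aff$I <- 3 * merged$I + 7
  expect_equal(cc_by_shell(merged, aff, scheme)$cc, rep(1, 4),
               tolerance = 1e-12)
  # independent pure noise: |CC| small with 1000 voxels per shell
  big <- data.frame(asu_i = 1:4000, asu_j = 0, asu_k = 0,
                    I = rnorm(4000), s = runif(4000, 0.1, 0.5))
  other <- big
  other$I <- rnorm(4000)
  cc0 <- cc_by_shell(big, other, shell_scheme(big$s, 4))
  expect_true(all(abs(cc0$cc) < 0.1))
  # sparse shells are undefined, never zero
  tiny <- merged[1:2, ]
  expect_true(is.na(cc_by_shell(tiny, tiny, scheme)$cc[1]))
})

test_that("reproducibility correlation requires disjoint groups", {
  m <- data.frame(asu_i = 1:50, asu_j = 0, asu_k = 0, I = rnorm(50, 5),
                  s = runif(50, 0.1, 0.5))
  scheme <- shell_scheme(m$s, 2)
  attr(m, "batches") <- c(1, 2)
  m2 <- m
  attr(m2, "batches") <- c(3, 4)
  expect_equal(cc_rep(m, m2, scheme)$cc, rep(1, 2), tolerance = 1e-12)
  attr(m2, "batches") <- c(2, 3)
  expect_error(cc_rep(m, m2, scheme), "disjoint")
})

test_that("halo partition selects allowed integer nodes only", {
  g <- insulin_like_grid(3)
  merged <- data.frame(asu_i = c(0, 3, 1, 6), asu_j = c(0, 3, 0, 0),
                       asu_k = c(0, 3, 0, 0))
  part <- halo_partition(merged, g)
  # (0,0,0) allowed; (1,1,1) violates h+k+l=2n; (1/3,0,0) fractional;
  # (2,0,0) allowed
  expect_equal(as.character(part), c("halo", "non-halo", "non-halo", "halo"))
})

test_that("shell statistics normalize to 1 at the non-halo maximum", {
  g <- insulin_like_grid(3)
  set.seed(29)
  vox <- as.matrix(expand.grid(i = 0:8, j = 0:8, k = 0:8))
  merged <- data.frame(asu_i = vox[, 1], asu_j = vox[, 2], asu_k = vox[, 3])
  merged$s <- s_magnitude(voxel_center(vox, g), g$cell)
  merged <- merged[merged$s > 0, ]
  part <- halo_partition(merged, g)
  scheme <- shell_scheme(merged$s, 5)
  # constant intensity: sd 0, normalized mean 1 everywhere it is defined
  merged$I <- 4
  st <- shell_statistics(merged, scheme, part)
  expect_true(all(st$sd[st$n_vox >= 2] == 0))
  expect_true(all(abs(st$mean[st$n_vox >= 1] - 1) < 1e-12))
  # generic intensities: the max over shells of the non-halo mean is 1
  merged$I <- rexp(nrow(merged), 1 / 10)
  st2 <- shell_statistics(merged, scheme, part)
  expect_equal(max(st2$mean[st2$partition == "non-halo"], na.rm = TRUE), 1)
  expect_true(all(is.na(st2$mean[st2$n_vox == 0])))
})

test_that("merging the two random halves reproduces the full merge", {
  cfg <- sim_config_quiet(seed = 47, n_sweeps = 2, obs_per_sweep = 4000,
                          n_voxels = 300)
  sim <- simulate_experiment(cfg)
  obs <- sim$obs
  half <- split_observations(obs, "randomHalf", seed = 9)
  full <- merge_scaled(obs)
  m1 <- merge_scaled(obs, keep = half == 1)
  m2 <- merge_scaled(obs, keep = half == 2)
  k <- paste(full$asu_i, full$asu_j, full$asu_k)
  i1 <- match(k, paste(m1$asu_i, m1$asu_j, m1$asu_k))
  i2 <- match(k, paste(m2$asu_i, m2$asu_j, m2$asu_k))
  w1 <- ifelse(is.na(i1), 0, 1 / m1$sigma[i1]^2)
  w2 <- ifelse(is.na(i2), 0, 1 / m2$sigma[i2]^2)
  I1 <- ifelse(is.na(i1), 0, m1$I[i1])
  I2 <- ifelse(is.na(i2), 0, m2$I[i2])
  recombined <- (w1 * I1 + w2 * I2) / (w1 + w2)
  expect_equal(recombined, full$I, tolerance = 1e-10)
})
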