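test_that("interpolation operators are stochastic (rows sum to 1, entries >= 0)", {
  ax1 <- seq(0, 10, by = 2)
  M <- interp_operator(c(0, 4, 10), ax1)
  expect_equal(as.numeric(M[1, ]), c(1, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(interp_operator(3, ax1) %*% seq_along(ax1)), 2.5)
  # 1D midpoint
  expect_equal(sort(interp_operator(1, ax1)@x), c(0.5, 0.5))
  # 3D cell center: eight weights of 1/8
  ax3 <- list(0:1, 0:1, 0:1)
  M3 <- interp_operator(matrix(0.5, 1, 3), ax3)
  expect_equal(sort(as.numeric(M3)), rep(0.125, 8))
  # random queries, including outside the range (clamped)
  set.seed(3)
  q <- cbind(runif(50, -2, 14), runif(50, -1, 6), runif(50, 0, 1))
  Mq <- interp_operator(q, list(ax1, 0:5, c(0, 0.5, 1)))
  expect_equal(Matrix::rowSums(Mq), rep(1, 50), ignore_attr = TRUE)
  expect_true(all(Mq@x >= 0))
  expect_error(interp_operator(1, numeric(0)), "empty")
})

test_that("regularization operators annihilate their null spaces", {
  D <- second_derivative_operator(7)
  expect_equal(dim(D), c(5, 7))
  phi <- seq_len(7)
  expect_equal(as.numeric(D %*% (3 + 2 * phi)), rep(0, 5))
  expect_equal(as.numeric(D %*% phi^2), rep(2, 5))
  expect_equal(nrow(second_derivative_operator(2)), 0)
  L <- laplacian_operator(5, 4)
  expect_equal(dim(L), c(6, 20))
  xy <- expand.grid(x = 1:5, y = 1:4)
  expect_equal(as.numeric(L %*% (2 * xy$x - 3 * xy$y + 1)), rep(0, 6))
  expect_equal(as.numeric(L %*% (xy$x^2 + xy$y^2)), rep(4, 6))
  expect_equal(nrow(laplacian_operator(2, 2)), 0)
})

test_that("merging matches the inverse-variance closed form", {
  one <- data.frame(asu_i = 1, asu_j = 0, asu_k = 0, I = 5, sigma = 2)
  expect_equal(merge_scaled(one)[, c("I", "sigma", "n_obs")],
               data.frame(I = 5, sigma = 2, n_obs = 1L))
  two <- data.frame(asu_i = 1, asu_j = 0, asu_k = 0, I = c(2, 4),
                    sigma = c(3, 3))
  m2 <- merge_scaled(two)
  expect_equal(m2$I, 3)
  expect_equal(m2$sigma, 3 / sqrt(2))
  # weighted-mean arithmetic oracle: (1, s=1) and (3, s=2) -> 1.4, 0.8944
  mix <- data.frame(asu_i = 0, asu_j = 1, asu_k = 0, I = c(1, 3),
                    sigma = c(1, 2))
  m3 <- merge_scaled(mix)
  expect_equal(m3$I, 1.4)
  expect_equal(m3$sigma, 0.8944, tolerance = 1e-4)
  # random orbits against the brute-force oracle
  set.seed(7)
  obs <- data.frame(asu_i = sample(1:6, 80, TRUE), asu_j = sample(0:2, 80, TRUE),
                    asu_k = 0, I = rnorm(80, 10), sigma = runif(80, 0.5, 2))
  m <- runif(80, 0.5, 2); o <- runif(80, 0, 1)
  got <- merge_scaled(obs, m = m, o = o)
  ora <- oracle_merge(obs, m, o)
  ora <- ora[match(paste(got$asu_i, got$asu_j, got$asu_k), ora$key), ]
  expect_equal(got$I, ora$I, tolerance = 1e-12)
  expect_equal(got$sigma, ora$sigma, tolerance = 1e-12)
  # zero-count observations (sigma 0) drop out rather than gaining weight
  obs$sigma[1] <- 0
  expect_equal(nrow(merge_scaled(obs)), nrow(ora))
})

test_that("least-squares problems reduce correctly when partners are neutral", {
  set.seed(9)
  n <- 40
  ax <- seq(0, 10, length.out = 5)
  M <- interp_operator(runif(n, 0, 10), ax)
  I <- runif(n, 5, 10); sigma <- runif(n, 0.5, 1); I0 <- runif(n, 4, 9)
  pb <- assemble_problem("b", M, I, sigma, I0)
  expect_equal(as.matrix(pb$A), as.matrix(Matrix::Diagonal(n, I0 / sigma) %*% M))
  expect_equal(pb$b, I / sigma)
  pc <- assemble_problem("c", M, I, sigma, I0)
  expect_equal(as.matrix(pc$A), as.matrix(Matrix::Diagonal(n, 1 / sigma) %*% M))
  expect_equal(pc$b, (I - I0) / sigma)
  # exact synthetic data: residual of the true parameter vector is zero
  x_true <- c(1, 1.5, 0.8, 1.2, 1)
  bvals <- as.numeric(M %*% x_true)
  pb2 <- assemble_problem("b", M, bvals * I0, sigma, I0)
  expect_lt(sqrt(sum((pb2$A %*% x_true - pb2$b)^2)), 1e-10)
})

test_that("alpha re-normalization scales as a Frobenius-norm ratio", {
  set.seed(2)
  A <- Matrix::rsparsematrix(30, 8, 0.3)
  B <- second_derivative_operator(8)
  expect_equal(renormalize_alpha(1, A, A), 1)
  expect_equal(renormalize_alpha(2, 2 * A, B), 4 * renormalize_alpha(2, A, B))
  expect_equal(renormalize_alpha(0, A, B), 0)
  empty <- second_derivative_operator(2)
  expect_equal(renormalize_alpha(5, A, empty), 0)
})

test_that("regularized solver recovers exact data and obeys the smooth limit", {
  set.seed(15)
  ax <- seq(0, 50, by = 5)
  phi <- runif(300, 0, 50)
  M <- interp_operator(phi, ax)
  x_true <- 1 + 0.3 * sin(seq_along(ax))
  y <- as.numeric(M %*% x_true)
  # lambda = 0, noiseless: exact recovery
  x <- fit_parameter(list(A = M, b = y, regs = list()))
  expect_equal(x, x_true, tolerance = 1e-10)
  # A = identity: solution is b
  x2 <- fit_parameter(list(A = identity_operator(4), b = c(1, 2, 3, 4),
                           regs = list()))
  expect_equal(x2, c(1, 2, 3, 4))
  # huge second-derivative penalty drives the solution to the best affine fit
  D <- second_derivative_operator(length(ax))
  x3 <- fit_parameter(list(A = M, b = y, regs = list(list(B = D, lambda = 1e10))))
  basis <- cbind(1, ax)
  affine <- basis %*% qr.solve(crossprod(as.matrix(M %*% basis)),
                               crossprod(as.matrix(M %*% basis), y))
  expect_equal(x3, as.numeric(affine), tolerance = 1e-4)
  # underdetermined problem without regularization errors out
  Mu <- interp_operator(c(1, 2), seq(0, 50, by = 5))
  expect_error(fit_parameter(list(A = Mu, b = c(1, 2), regs = list())),
               "singular|alpha")
})

test_that("offset restraint clips, anchors and preserves valid input", {
  expect_equal(restrain_offset(c(-0.2, 0.5, 1.0)), c(0, 0.5, 1.0))
  expect_equal(restrain_offset(c(0.3, 0.5)), c(0, 0.2))
  expect_equal(restrain_offset(c(0, 0.7)), c(0, 0.7))
  out <- restrain_offset(rnorm(50))
  expect_true(all(out >= 0))
  expect_equal(min(out), 0)
})

test_that("flat data yield a neutral model and the raw weighted mean", {
  set.seed(33)
  cfg <- sim_config_quiet(seed = 33, n_sweeps = 2, obs_per_sweep = 3000,
                          n_voxels = 200)
  sim <- simulate_experiment(cfg)
  fit <- refine_scaling(sim$obs, scale_config(), grid = sim$grid)
  expect_lt(max(abs(fit$scale$b - 1)), 0.02)
  raw <- merge_scaled(sim$obs)
  expect_equal(fit$merged$I, raw$I, tolerance = 0.02)
  expect_true(fit$diagnostics$converged)
})

test_that("two sweeps differing by a factor two give a 2:1 scale ratio", {
  cfg <- sim_config_quiet(seed = 41, n_sweeps = 2, obs_per_sweep = 4000,
                          n_voxels = 250)
  truth <- simulate_truth(cfg)
  truth$b_fun[[2]] <- function(phi) rep(2, length(phi))
  o1 <- simulate_sweep(truth, 1, seed = 101)
  o2 <- simulate_sweep(truth, 2, seed = 102)
  obs <- rbind(o1, o2)
  cor_ <- correct_observation(obs$n, obs$dt, obs$r_bg, obs$f_product)
  obs$I <- cor_$I; obs$sigma <- cor_$sigma
  fit <- refine_scaling(obs, scale_config(), grid = truth$grid)
  b1 <- mean(fit$scale$b[obs$batch == 1])
  b2 <- mean(fit$scale$b[obs$batch == 2])
  expect_equal(b2 / b1, 2, tolerance = 0.02)
  # gauge fixing: mean of b over all sweeps is 1
  bvals <- unlist(lapply(fit$model$sweeps, function(sw) as.vector(sw$b$values)))
  expect_equal(mean(bvals), 1, tolerance = 1e-10)
})

test_that("scaling is gauge invariant up to the fixed normalization", {
  cfg <- sim_config_quiet(seed = 55, n_sweeps = 2, obs_per_sweep = 3000,
                          n_voxels = 200, amp_b = 0.3)
  sim <- simulate_experiment(cfg)
  fit1 <- refine_scaling(sim$obs, scale_config(), grid = sim$grid)
  obs2 <- sim$obs
  obs2$I <- obs2$I * 3          # overall scale k folds entirely into I0
  obs2$sigma <- obs2$sigma * 3
  fit2 <- refine_scaling(obs2, scale_config(), grid = sim$grid)
  expect_equal(fit2$scale$b, fit1$scale$b, tolerance = 1e-6)
  expect_equal(fit2$merged$I, 3 * fit1$merged$I, tolerance = 1e-6)
})

test_that("chi-square does not increase across cycles without restraints", {
  cfg <- sim_config_quiet(seed = 61, n_sweeps = 2, obs_per_sweep = 4000,
                          n_voxels = 250, amp_b = 0.3)
  sim <- simulate_experiment(cfg)
  fit <- refine_scaling(sim$obs, scale_config(outlier_sigma = Inf,
                                              tol = 1e-12, max_cycles = 8),
                        grid = sim$grid)
  tr <- fit$diagnostics$chi2
  expect_true(all(diff(tr) <= abs(tr[-length(tr)]) * 1e-8))
})

test_that("scaling requires redundant observations", {
  obs <- data.frame(batch = 1, asu_i = 1:5, asu_j = 0, asu_k = 0,
                    I = rnorm(5, 10), sigma = 1, phi = 1:5, x = 1, y = 1,
                    s = 0.1)
  expect_error(refine_scaling(obs, scale_config()), ">= 2")
})
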