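test_that("Laue presets form closed centrosymmetric groups", {
  ops <- laue_group_ops("m-3")
  expect_length(ops, 24)
  keys <- vapply(ops, function(m) paste(as.integer(m), collapse = ","),
                 character(1))
  expect_true(paste(as.integer(diag(3)), collapse = ",") %in% keys)
  for (R in ops) {
    expect_true(paste(as.integer(-R), collapse = ",") %in% keys)
    expect_true(abs(abs(det(R)) - 1) < 1e-12)
  }
  expect_length(laue_group_ops("I213"), 24)  # space-group label alias
  expect_length(laue_group_ops("-1"), 2)
  expect_error(laue_group_ops("p6"), "unknown")
  # non-closed user operator lists are rejected
  expect_error(miller_grid(cubic_cell(10), 2, "P",
                           laue_ops = list(diag(3), diag(c(-1, 1, 1)))),
               "centrosymmetric|closed")
})

test_that("voxel assignment picks the nearest center with half-even ties", {
  g <- insulin_like_grid(3)
  expect_equal(as.vector(voxel_of(c(0, 0, 0), g)), c(0, 0, 0))
  # independent nearest-center search over neighboring candidates
  hkl <- c(0.16, -0.17, 0.34)
  cand <- as.matrix(expand.grid(i = -2:2, j = -2:2, k = 0:3))
  d <- rowSums((voxel_center(cand, g) -
                  matrix(hkl, nrow(cand), 3, byrow = TRUE))^2)
  expect_equal(as.vector(voxel_of(hkl, g)), as.vector(cand[which.min(d), ]))
  # exact half-way tie rounds to even on each axis independently
  expect_equal(as.vector(voxel_of(c(1 / 6, 0, 0), g)), c(0, 0, 0))
  expect_equal(as.vector(voxel_of(c(0.5, 0, 0), g)), c(2, 0, 0))
  expect_error(voxel_of(c(NA, 0, 0), g), "finite")
})

test_that("voxel_of inverts voxel_center on every voxel", {
  g <- insulin_like_grid(3)
  set.seed(4)
  v <- matrix(sample(-30:30, 300, replace = TRUE), ncol = 3)
  round_trip <- voxel_of(voxel_center(v, g), g)
  expect_equal(unname(round_trip), unname(v), ignore_attr = TRUE)
})

test_that("Bragg voxels satisfy integer indices plus the centering rule", {
  g <- insulin_like_grid(3)
  expect_true(is_bragg_voxel(c(0, 0, 0), g))
  expect_false(is_bragg_voxel(c(3, 3, 3), g))   # hkl (1,1,1), h+k+l odd
  expect_false(is_bragg_voxel(c(1, 0, 0), g))   # fractional index
  expect_true(is_bragg_voxel(c(3, 3, 0), g))    # hkl (1,1,0), sum even
  gF <- miller_grid(cubic_cell(10), 2, "F", "-1")
  expect_true(is_bragg_voxel(c(2, 2, 2), gF))    # (1,1,1) all odd
  expect_false(is_bragg_voxel(c(2, 2, 0), gF))   # (1,1,0) mixed parity
  gC <- miller_grid(cubic_cell(10), 2, "C", "-1")
  expect_true(is_bragg_voxel(c(2, 2, 2), gC))    # h+k even
  expect_false(is_bragg_voxel(c(2, 0, 0), gC))   # h+k odd
})

test_that("diffuse-voxel counts match exhaustive enumeration", {
  expect_identical(count_diffuse_voxels(1, "P"), 0L)
  expect_identical(count_diffuse_voxels(2, "P"), 7L)
  for (sub in 1:4) for (cen in c("P", "I", "F", "C")) {
    expect_equal(count_diffuse_voxels(sub, cen),
                 oracle_diffuse_count(sub, cen),
                 info = paste(sub, cen))
  }
  # the oversampled-by-three I-centered grid: enumeration gives 53 diffuse
  # voxels per Bragg peak (2 * 3^3 - 1)
  expect_identical(count_diffuse_voxels(3, "I"), 53L)
  expect_error(count_diffuse_voxels(3, "Q"), "centering")
})

test_that("asymmetric-unit mapping is constant on orbits with correct Friedel flags", {
  g <- insulin_like_grid(3)
  set.seed(11)
  for (rep in 1:5) {
    v <- matrix(sample(-12:12, 3), 1)
    imgs <- unique(t(sapply(g$laue_ops, function(R) as.vector(R %*% t(v)))))
    res <- map_to_asu(imgs, g)
    expect_equal(nrow(unique(res$asu)), 1)
  }
  # inversion-related pair of a general position maps to the same
  # representative with opposite Friedel flags
  gen <- matrix(c(5, 2, 1), 1)
  pair <- map_to_asu(rbind(gen, -gen), g)
  expect_equal(pair$asu[1, ], pair$asu[2, ])
  expect_true(xor(pair$friedel[1], pair$friedel[2]))
  idm <- map_to_asu(map_to_asu(matrix(c(5, 2, 1), 1), g)$asu, g)
  expect_equal(idm$op, 1)            # representative maps to itself via identity
  expect_false(idm$friedel)
})

test_that("orbit sizes from the asu mapping partition a test grid", {
  g <- insulin_like_grid(1)
  v <- as.matrix(expand.grid(i = -2:2, j = -2:2, k = -2:2))
  res <- map_to_asu(v, g)
  key <- paste(res$asu[, 1], res$asu[, 2], res$asu[, 3])
  # brute-force orbit of each representative must equal its member count
  for (k in unique(key)) {
    members <- v[key == k, , drop = FALSE]
    rep_vox <- res$asu[key == k, , drop = FALSE][1, ]
    orbit <- unique(t(sapply(g$laue_ops, function(R) as.vector(R %*% rep_vox))))
    in_box <- orbit[apply(abs(orbit) <= 2, 1, all), , drop = FALSE]
    expect_equal(nrow(members), nrow(in_box), info = k)
  }
  expect_equal(sum(table(key)), nrow(v))
})

test_that("scattering-vector magnitudes follow the reciprocal metric", {
  cell <- cubic_cell(79.48)
  expect_equal(s_magnitude(c(1, 0, 0), cell), 1 / 79.48, tolerance = 1e-12)
  expect_equal(s_magnitude(c(0, 0, 0), cell), 0)
  expect_equal(s_magnitude(c(1, 1, 0), cell),
               sqrt(2) * s_magnitude(c(1, 0, 0), cell))
  # oracle: explicit reciprocal basis vectors for a monoclinic cell
  mono <- unit_cell(10, 12, 15, beta = 105)
  a <- c(10, 0, 0)
  b <- c(0, 12, 0)
  cc <- 15 * c(cos(105 * pi / 180), 0, sin(105 * pi / 180))
  V <- abs(det(rbind(a, b, cc)))
  astar <- cross3(b, cc) / V
  bstar <- cross3(cc, a) / V
  cstar <- cross3(a, b) / V
  hkl <- c(2, -1, 3)
  svec <- hkl[1] * astar + hkl[2] * bstar + hkl[3] * cstar
  expect_equal(s_magnitude(hkl, mono), sqrt(sum(svec^2)), tolerance = 1e-10)
})

test_that("lattice-modulation wavelengths reproduce the printed geometry", {
  cell <- cubic_cell(79.48)
  expect_equal(round(modulation_wavelength(sqrt(3) / 6, cell)), 275)
  expect_equal(round(modulation_wavelength(0.102, cell), -1), 780)
  expect_equal(modulation_wavelength(1, cell), 79.48)
  expect_error(modulation_wavelength(0, cell), "> 0")
  expect_equal(voxel_corner_distance(3), sqrt(3) / 6)
})
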