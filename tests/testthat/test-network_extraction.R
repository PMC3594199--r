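test_that("a fully masked 9x9x9 volume tiles into 27 cubes", {
  vol <- toy_volume(c(9, 9, 9), seed = 1)
  cubes <- extract_cubes(vol)
  expect_equal(cubes$n_nodes, 27)
  expect_equal(dim(cubes$values), c(27, 27))
  # cube values must match direct array slicing at the stored corner
  for (i in c(1, 14, 27)) {
    cr <- cubes$corners[i, ] + 1
    expect_equal(cubes$values[i, ],
                 as.vector(vol$data[cr[1]:(cr[1] + 2), cr[2]:(cr[2] + 2),
                                    cr[3]:(cr[3] + 2)]))
  }
})

test_that("partial cubes at far faces are discarded", {
  vol9 <- toy_volume(c(9, 9, 9), seed = 2)
  vol10 <- gm_volume(array(0.5, c(10, 10, 10)))
  vol10$data[1:9, 1:9, 1:9] <- vol9$data
  vol10 <- gm_volume(vol10$data)
  c9 <- extract_cubes(vol9)
  c10 <- extract_cubes(vol10)
  expect_equal(c10$n_nodes, c9$n_nodes)
  expect_equal(c10$corners, c9$corners, ignore_attr = TRUE)
})

test_that("zero-variance cubes are excluded", {
  vol <- toy_volume(c(9, 9, 9), seed = 3)
  vol$data[4:6, 4:6, 4:6] <- 0.7      # one constant cube
  vol <- gm_volume(vol$data)
  cubes <- extract_cubes(vol)
  expect_equal(cubes$n_nodes, 26)
  expect_equal(unname(cubes$dropped[["zero_variance"]]), 1)
})

test_that("cube extraction errors on degenerate inputs", {
  expect_error(extract_cubes(gm_volume(array(1, c(2, 9, 9)))), "3 voxels")
  z <- gm_volume(array(0, c(9, 9, 9)))
  expect_error(extract_cubes(z), "empty mask")
  vol <- toy_volume(c(9, 9, 9))
  expect_error(extract_cubes(vol, offset = c(3, 0, 0)), "0..2")
})

test_that("cube correlation matches the textbook Pearson formula", {
  set.seed(42)
  v1 <- rnorm(27)
  v2 <- rnorm(27)
  expect_equal(cube_correlation(v1, v1), 1.0)
  expect_equal(cube_correlation(v1, 2 * mean(v1) - v1), -1.0)
  expect_equal(cube_correlation(v1, v2), oracle_pearson(v1, v2))
  expect_error(cube_correlation(rep(1, 27), v2), "zero-variance")
})

test_that("rotation-maximized correlation recovers rotated copies", {
  rots <- rotation_set()
  set.seed(7)
  v <- rnorm(27)
  for (p in rots[c(2, 10, 24)]) {
    expect_equal(max_rotation_correlation(v[p], v, rots), 1.0,
                 tolerance = 1e-12)
  }
})

test_that("spherically symmetric cubes are rotation-invariant", {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  v <- exp(-rowSums(off^2))           # function of distance from center
  set.seed(8)
  w <- rnorm(27)
  rots <- rotation_set()
  vals <- vapply(rots, function(p) cube_correlation(v[p], w), numeric(1))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)
})

test_that("max rotation correlation is symmetric and >= plain correlation", {
  rots <- rotation_set()
  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(27)
    b <- rnorm(27)
    m <- max_rotation_correlation(a, b, rots)
    expect_equal(m, max_rotation_correlation(b, a, rots), tolerance = 1e-10)
    expect_gte(m, cube_correlation(a, b) - 1e-12)
    expect_equal(m, oracle_max_rot(a, b, rots), tolerance = 1e-10)
  }
})

test_that("the similarity matrix matches the pairwise brute-force loop", {
  vol <- toy_volume(c(9, 9, 6), seed = 5)
  cubes <- extract_cubes(vol)
  rots <- rotation_set()
  S <- similarity_matrix(cubes, rots)
  expect_identical(S, t(S))
  expect_true(all(is.na(diag(S))))
  expect_true(all(abs(S[upper.tri(S)]) <= 1 + 1e-12))
  sub <- cubes$values[1:5, ]
  S5 <- similarity_matrix(sub, rots)
  for (j in 1:4) {
    for (m in (j + 1):5) {
      expect_equal(S5[j, m], oracle_max_rot(sub[j, ], sub[m, ], rots),
                   tolerance = 1e-10)
    }
  }
})

test_that("three identical cubes are perfectly similar", {
  v <- matrix(rep(rnorm(27), 3), nrow = 3, byrow = TRUE)
  S <- similarity_matrix(v)
  expect_equal(S[upper.tri(S)], rep(1, 3), tolerance = 1e-12)
})

test_that("separated real and null distributions give a zero-spurious threshold", {
  # cubes built from 3 strong shared patterns: real similarities cluster
  # high, value-permuted nulls sit far below
  set.seed(21)
  pats <- matrix(rnorm(3 * 27), 3)
  vals <- pats[sample.int(3, 60, replace = TRUE), ] +
    matrix(rnorm(60 * 27, sd = 0.05), 60)
  rots <- rotation_set()
  S <- similarity_matrix(vals, rots)
  th <- permutation_threshold(vals, rots, S = S, n_null_pairs = 5000,
                              seed = 1)
  expect_identical(th$status, "ok")
  real <- S[upper.tri(S)]
  null <- real[real < 0.9]            # the non-matching pairs
  expect_lt(th$threshold, min(real[real > 0.9]))
  expect_gt(th$threshold, max(null))
  expect_equal(th$achieved_spurious, 0)
})

test_that("pure noise volumes are flagged as no-signal with an empty graph", {
  vol <- toy_volume(c(12, 12, 9), seed = 31)
  cubes <- extract_cubes(vol)
  expect_warning(
    th <- permutation_threshold(cubes, n_null_pairs = 5000, seed = 2),
    "no threshold")
  expect_identical(th$status, "no_signal")
  S <- similarity_matrix(cubes)
  g <- binarize(S, th$threshold)
  expect_equal(igraph::ecount(g$graph), 0)
})

test_that("the sampled-null threshold agrees with an oversampled scan", {
  # planted signal with a continuum of strengths, so real similarities
  # cover a dense grid of candidate thresholds
  set.seed(41)
  pat <- rnorm(27)
  alpha <- runif(150, 0, 1.5)
  vals <- outer(alpha, pat) + matrix(rnorm(150 * 27, sd = 0.6), 150)
  rots <- rotation_set()
  S <- similarity_matrix(vals, rots)
  th_small <- permutation_threshold(vals, rots, S = S,
                                    n_null_pairs = 20000, seed = 3)
  th_big <- permutation_threshold(vals, rots, S = S,
                                  n_null_pairs = 400000, seed = 4)
  expect_identical(th_small$status, "ok")
  expect_identical(th_big$status, "ok")
  expect_equal(th_small$threshold, th_big$threshold, tolerance = 0.02)
  expect_lte(th_small$achieved_spurious, 0.05)
  expect_lte(th_big$achieved_spurious, 0.05)
})

test_that("binarization follows the positive strict-threshold rule", {
  set.seed(51)
  S <- matrix(runif(15 * 15, -1, 1), 15)
  S <- (S + t(S)) / 2
  diag(S) <- NA
  g <- binarize(S, 0.5)
  a <- adj_of(g)
  for (i in 1:14) {
    for (j in (i + 1):15) {
      expect_equal(a[i, j] == 1, S[i, j] > 0.5)
    }
  }
  # a negative threshold behaves exactly like zero (positivity rule)
  expect_equal(adj_of(binarize(S, -0.7)), adj_of(binarize(S, 0)))
  # threshold above the maximum kills every edge
  expect_equal(igraph::ecount(binarize(S, max(S, na.rm = TRUE))$graph), 0)
  expect_error(binarize(S, NA), "finite")
})

test_that("extracted networks always have symmetric, loop-free adjacency", {
  spec <- synthetic_spec(shape = c(21L, 21L, 12L))
  for (seed in 1:3) {
    v <- generate_volume(spec, "control", seed = seed)$volume
    g <- extract_network(v, n_null_pairs = 3000, seed = seed)
    a <- adj_of(g)
    expect_identical(a, t(a))
    expect_true(all(diag(a) == 0))
    cubes <- extract_cubes(v)
    expect_true(all(apply(cubes$values, 1, stats::var) > 0))
  }
})
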