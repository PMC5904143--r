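test_that("preconditioning maps the point cloud's central ellipsoid to a ball", {
  # +/- unit basis vectors: already spherical, transform changes nothing
  # up to rotation; check the MVE of the result is still the unit ball
  d <- 4
  P <- cbind(diag(d), -diag(d))
  pre <- precondition_profiles(P, r = d)
  mve <- actionsc:::mve_origin(pre$Yp, tol = 1e-4)
  ax <- sqrt(1 / eigen(mve$E, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(max(ax) / min(ax), 1.05)
  # strongly anisotropic cloud becomes near-spherical
  set.seed(11)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  pts <- Q %*% (c(10, rep(1, 5)) * matrix(rnorm(6 * 200), 6, 200))
  pre2 <- precondition_profiles(pts, r = 6)
  mve2 <- actionsc:::mve_origin(pre2$Yp, tol = 1e-4)
  ax2 <- sqrt(1 / eigen(mve2$E, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(max(ax2) / min(ax2), 1.05)
})

test_that("preconditioning preserves the planted separable support", {
  sim <- simulate_separable_instance(m = 20, k = 4, n = 40, noise_eps = 0,
                                     seed = 21)
  pre <- precondition_profiles(sim$Y, r = 4)
  expect_setequal(spa_select(pre$Yp, 4), sim$true_indices)
})

test_that("SPA picks dominant corners greedily", {
  e1 <- c(1, 0); e2 <- c(0, 1)
  Y <- cbind(3 * e1, e2, 0.5 * (e1 + e2))
  expect_equal(spa_select(Y, 2), c(1, 2))
  expect_equal(spa_select(Y, 1), 1)
  # tie on norms -> lowest index
  expect_equal(spa_select(cbind(e1, e1, e2), 1), 1)
})

test_that("SPA recovers planted pure columns on noiseless separable data", {
  for (seed in 1:20) {
    sim <- simulate_separable_instance(m = 30, k = 4, n = 60,
                                       noise_eps = 0, seed = seed)
    expect_setequal(spa_select(sim$Y, 4), sim$true_indices)
  }
})

test_that("SPA warns and returns fewer picks when the residual vanishes", {
  Y <- cbind(c(1, 0), c(2, 0), c(3, 0))   # rank 1
  expect_warning(sel <- spa_select(Y, 2), "residual")
  expect_equal(length(sel), 1)
})

test_that("oversampling detection flags duplicates, not separated candidates", {
  # 4 mutually orthogonal profiles: no edges, no flag
  Y <- diag(4) * 5
  K <- crossprod(Y)
  det <- detect_oversampling(K, 1:4)
  expect_false(det$flagged)
  expect_equal(igraph::ecount(det$graph), 0)
  # a duplicated candidate among well-separated others is flagged
  set.seed(31)
  B <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:5] * 4
  Y2 <- cbind(B, B[, 3] + rnorm(6, sd = 1e-3))
  K2 <- crossprod(Y2)
  det2 <- detect_oversampling(K2, 1:6)
  expect_true(det2$flagged)
  zm <- which.max(det2$z)
  pairs <- which(upper.tri(matrix(0, 6, 6)), arr.ind = TRUE)
  expect_equal(sort(unname(pairs[zm, ])), c(3, 6))
  # equal similarities: zero variance -> all z = 0, no flag
  K3 <- matrix(1, 5, 5) + diag(5)
  det3 <- detect_oversampling(K3, 1:5)
  expect_false(det3$flagged)
  expect_true(all(det3$z == 0))
  # below 4 candidates the test is skipped
  expect_false(detect_oversampling(K2, 1:3)$flagged)
})

test_that("automatic k selection recovers the planted number of types", {
  hits <- 0
  for (seed in 1:10) {
    ds <- small_dataset(seed = seed)
    kern <- suppressWarnings(action_kernel(ds$X))
    sel <- suppressWarnings(select_num_archetypes(kern$Y, K = kern$K))
    expect_gte(sel$k_star, 2)
    if (sel$k_star == 5) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("k selection returns k_max with a warning when nothing is flagged", {
  sim <- simulate_separable_instance(m = 10, k = 3, n = 12, noise_eps = 0,
                                     seed = 3)
  expect_warning(
    sel <- select_num_archetypes(sim$Y, k_min = 2, k_max = 3),
    "k_max")
  expect_equal(sel$k_star, 3)
})

test_that("PCHA objective is monotone and factors are column-stochastic", {
  set.seed(41)
  for (rep in 1:5) {
    Y <- matrix(rnorm(15 * 40), 15, 40)
    fit <- pcha_fit(Y, init = sample(40, 3), k = 3)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-12))
    expect_true(all(abs(colSums(fit$C) - 1) <= 1e-9))
    expect_true(all(abs(colSums(fit$H) - 1) <= 1e-9))
    expect_true(all(fit$C >= 0) && all(fit$H >= 0))
    # bounded below by the best rank-k approximation error
    sv <- svd(Y, nu = 0, nv = 0)$d
    expect_gte(tail(tr, 1) + 1e-8, sqrt(sum(sv[-(1:3)]^2)))
  }
})

test_that("PCHA with k = n and indicator C starts at objective zero", {
  set.seed(42)
  Y <- matrix(rnorm(8 * 6), 8, 6)
  fit <- pcha_fit(Y, init = 1:6, k = 6)
  expect_lt(fit$objective_trace[1], 1e-8 * sqrt(sum(Y^2)))
})

test_that("PCHA recovers planted simplex archetypes", {
  # true archetypes = scaled basis vectors; cells strictly interior
  set.seed(43)
  k <- 4; m <- 12; n <- 80
  W <- diag(m)[, 1:k] * 5
  H <- matrix(rexp(k * (n - k)), k)
  H <- sweep(H, 2, colSums(H), "/")
  Y <- cbind(W, W %*% H)   # include the pure corners themselves
  fit <- pcha_fit(Y, init = spa_select(Y, k), k = k)
  # Hungarian-style matching via greedy on the small k x k error matrix
  err <- outer(1:k, 1:k, Vectorize(function(i, j)
    sqrt(sum((fit$A[, i] - W[, j])^2))))
  perm <- clue_like_match(err)
  tot <- sqrt(sum((fit$A[, perm$row] - W[, perm$col])^2))
  expect_lt(tot / sqrt(sum(W^2)), 0.05)
})

test_that("dominant archetype assignment follows argmax with low-index ties", {
  H <- cbind(c(0, 1, 0), c(0.5, 0.5, 0), c(0.2, 0.3, 0.5))
  expect_equal(assign_dominant_archetype(H), c(2, 1, 3))
})

test_that("cell permutation permutes decomposition labels consistently", {
  ds <- small_dataset(seed = 6, n_types = 3, cells_per_type = 30,
                      m_genes = 300)
  dec <- suppressWarnings(action_decompose(ds$X, k = 3))
  set.seed(60)
  perm <- sample(ncol(ds$X))
  dec2 <- suppressWarnings(action_decompose(unclass(ds$X)[, perm], k = 3))
  # same partition structure up to archetype relabeling
  sc <- clustering_scores(dec2$labels, dec$labels[perm])
  expect_equal(sc$ari, 1, tolerance = 1e-8)
})

test_that("reconstruction stays in the convex hull of archetypes", {
  set.seed(44)
  Y <- matrix(rnorm(10 * 30), 10, 30)
  fit <- pcha_fit(Y, init = spa_select(Y, 3), k = 3)
  expect_true(all(fit$H >= -1e-12))
  expect_true(all(abs(colSums(fit$H) - 1) <= 1e-9))
})
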