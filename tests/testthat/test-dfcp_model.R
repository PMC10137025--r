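make_blobs <- function(n_per = 30, N = 8, centers = 3, sep = 10,
                       sigma = 1, seed = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(centers * N), centers)
  mu <- mu / sqrt(rowSums(mu^2)) * sep * (1:centers)
  X <- do.call(rbind, lapply(seq_len(centers), function(k)
    matrix(rnorm(n_per * N, sd = sigma), n_per) +
      matrix(mu[k, ], n_per, N, byrow = TRUE)))
  list(X = X, labels = rep(seq_len(centers), each = n_per))
}

test_that("twice-clustering recovers well-separated planted clusters", {
  b <- make_blobs(sep = 10, sigma = 1, seed = 2)
  m <- dfcp_model(b$X, k_candidates = 2:8, seed = 1)
  expect_equal(m$K, 3L)
  expect_equal(ari(predict(m, b$X), b$labels), 1)
  # centroids are member means
  for (k in 1:3) {
    members <- b$X[predict(m, b$X) == k, , drop = FALSE]
    expect_equal(m$centroids[, k], colMeans(members), tolerance = 1e-10)
  }
})

test_that("identical WQCPs collapse to the smallest candidate K", {
  X <- matrix(rep(c(1, 2, 3, 4), 20), 20, 4, byrow = TRUE)
  m <- dfcp_model(X, k_candidates = 2:6, seed = 1)
  expect_equal(m$K, 2L)
  expect_equal(m$centroids[, 1], c(1, 2, 3, 4))
  expect_equal(m$centroids[, 2], c(1, 2, 3, 4))
})

test_that("input order does not change the fitted centroid set", {
  b <- make_blobs(sep = 8, seed = 3)
  m1 <- dfcp_model(b$X, k_candidates = 2:6, seed = 9)
  set.seed(123)
  perm <- sample(nrow(b$X))
  m2 <- dfcp_model(b$X[perm, ], k_candidates = 2:6, seed = 9)
  expect_equal(m1$K, m2$K)
  sort_cols <- function(M) M[, order(M[1, ])]
  expect_equal(sort_cols(m1$centroids), sort_cols(m2$centroids),
               tolerance = 1e-8)
})

test_that("elbow rule picks the maximum-knee point, ties to smaller K", {
  expect_equal(elbow_select(c(100, 20, 18, 17, 16), 1:5), 2L)
  expect_equal(elbow_select(seq(100, 20, length.out = 6), 1:6), 1L)
  expect_equal(elbow_select(c(50, 10), 4:5), 5L)  # < 3 points: argmin
})

test_that("ratio features count assignments and sum to one", {
  expect_equal(ratio_features(rep(1, 5), 4), c(1, 0, 0, 0))
  expect_equal(ratio_features(c(1, 1, 2, 3), 3), c(0.5, 0.25, 0.25))
  for (s in 1:10) {
    set.seed(s)
    a <- sample(1:4, sample(1:30, 1), replace = TRUE)
    expect_equal(sum(ratio_features(a, 4)), 1)
  }
  expect_warning(z <- ratio_features(integer(0), 3),
                 class = "dfcp_warning")
  expect_equal(as.numeric(z), c(0, 0, 0))
  expect_true(attr(z, "flagged"))
})

test_that("beta regression matches the normal equations and reconstructs in-span points", {
  b <- make_blobs(sep = 6, centers = 4, seed = 4)
  m <- dfcp_model(b$X, k_candidates = 2:6, seed = 2)
  R <- m$centroids

  expect_equal(beta_regress(R[, 1], m),
               c(1, rep(0, m$K - 1)), tolerance = 1e-8)
  mix <- 0.5 * R[, 1] + 0.5 * R[, 2]
  expect_equal(beta_regress(mix, m),
               c(0.5, 0.5, rep(0, m$K - 2)), tolerance = 1e-8)

  set.seed(5)
  for (i in 1:10) {
    y <- rnorm(nrow(R))
    beta <- beta_regress(y, m)
    brute <- solve(crossprod(R), crossprod(R, y))
    expect_equal(beta, as.numeric(brute), tolerance = 1e-10)
    # residual orthogonal to the centroid span
    expect_lt(max(abs(crossprod(R, y - R %*% beta))), 1e-8)
  }

  # in-span reconstruction is exact
  set.seed(6)
  w <- as.numeric(R %*% rnorm(m$K))
  expect_lt(sqrt(sum((R %*% beta_regress(w, m) - w)^2)), 1e-8)
})

test_that("rank-deficient centroids give the minimum-norm coefficients", {
  R <- cbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))  # duplicate pattern
  m <- structure(list(centroids = R, K = 3L), class = "dfcp_model")
  beta <- beta_regress(c(2, 3, 0), m)
  expect_equal(R %*% beta, cbind(c(2, 3, 0)), tolerance = 1e-10)
  expect_equal(beta[1], beta[2], tolerance = 1e-10)  # weight split evenly
})

test_that("mean beta averages elementwise", {
  expect_equal(mean_beta(list(c(1, 0))), c(1, 0))
  expect_equal(mean_beta(list(c(1, 0), c(0, 1))), c(0.5, 0.5))
  set.seed(7)
  bs <- lapply(1:10, function(i) rnorm(4))
  expect_equal(mean_beta(bs), colMeans(do.call(rbind, bs)),
               tolerance = 1e-12)
})

test_that("nearest-centroid assignment matches brute force with low-index ties", {
  b <- make_blobs(centers = 5, sep = 7, seed = 8)
  m <- dfcp_model(b$X, k_candidates = 2:7, kmeans_k0 = 20, seed = 3)
  expect_equal(assign_pattern(m$centroids[, 3], m), 3L)
  # every training centroid maps to itself
  for (k in seq_len(m$K))
    expect_equal(assign_pattern(m$centroids[, k], m), k)

  set.seed(9)
  for (i in 1:20) {
    y <- rnorm(nrow(m$centroids), sd = 5)
    brute <- which.min(sapply(seq_len(m$K), function(k)
      sum((y - m$centroids[, k])^2)))
    expect_equal(assign_pattern(y, m), brute)
  }

  # equidistant case resolves to the lowest index
  m2 <- structure(list(centroids = cbind(c(1, 0), c(-1, 0)), K = 2L),
                  class = "dfcp_model")
  expect_equal(assign_pattern(c(0, 5), m2), 1L)
})

test_that("subject feature vectors concatenate ratios and mean betas", {
  b <- make_blobs(centers = 2, sep = 8, seed = 10)
  m <- dfcp_model(b$X, k_candidates = 2:5, seed = 4)
  K <- m$K
  # subject whose WQCPs all equal pattern 2's centroid
  sub <- matrix(rep(m$centroids[, 2], 3), 3, byrow = TRUE)
  f <- dfcp_features(sub, m, subject_id = "s", group = "case")
  expect_equal(f$ratios, c(0, 1, rep(0, K - 2)))
  expect_equal(f$mean_betas, c(0, 1, rep(0, K - 2)), tolerance = 1e-8)
  expect_length(c(f$ratios, f$mean_betas), 2 * K)
})

test_that("planted occupancy is recovered in the ratio features", {
  # two separated states; 50 WQCPs at 0.7/0.3 occupancy
  set.seed(11)
  c1 <- rnorm(10); c2 <- c1 + rnorm(10, sd = 1) + 5
  X <- rbind(matrix(rep(c1, 35), 35, byrow = TRUE) + rnorm(350, sd = .3),
             matrix(rep(c2, 15), 15, byrow = TRUE) + rnorm(150, sd = .3))
  m <- dfcp_model(X, k_candidates = 1:6, seed = 5)
  f <- dfcp_features(X, m, subject_id = "s", group = "case")
  expect_equal(m$K, 2L)
  expect_lt(abs(max(f$ratios) - 0.7), 0.1)
})

test_that("kmeans_k0 larger than the WQCP count is lowered with a warning", {
  X <- matrix(rnorm(5 * 4), 5)
  expect_warning(m <- dfcp_model(X, k_candidates = 2:3, kmeans_k0 = 50,
                                 seed = 1),
                 class = "dfcp_warning")
  expect_lte(m$kmeans_k0, 5L)
})
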