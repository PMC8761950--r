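blob_data <- function(n_per = 10, sep = 10, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(n_per * 2), n_per, 2),
        matrix(rnorm(n_per * 2, mean = sep), n_per, 2))
}

test_that("genotype means aggregate over blocks correctly", {
  set.seed(41)
  cfg <- sim_config(6, 3, c("a", "b"), c(10, 20), diag(c(4, 1)),
                    c(0.5, 0.5), seed = 41)
  tr <- simulate_rcbd(cfg)
  m <- genotype_means(tr)
  expect_equal(dim(m), c(6L, 2L))
  g1a <- mean(tr$value[tr$genotype == "G1" & tr$trait == "a"])
  expect_equal(m["G1", "a"], g1a)

  ms <- genotype_means(tr, standardize = TRUE)
  expect_equal(unname(colMeans(ms)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(ms, 2, sd)), c(1, 1), tolerance = 1e-9)
})

test_that("single-block table returns raw values as means", {
  tab <- data.frame(genotype = c("g1", "g2"), block = "b1",
                    trait = "y", value = c(1.5, 2.5))
  m <- genotype_means(tab)
  expect_equal(unname(m[, "y"]), c(1.5, 2.5))
})

test_that("standardizing a zero-variance trait is rejected by name", {
  tab <- data.frame(genotype = rep(c("g1", "g2"), 2),
                    block = rep(c("b1", "b2"), each = 2),
                    trait = "flat", value = 3)
  expect_error(genotype_means(tab, standardize = TRUE), "flat")
})

test_that("two-variable PCA matches the closed form 1 +/- rho", {
  set.seed(42)
  for (rho in c(-0.6, 0, 0.3, 0.9)) {
    S <- matrix(c(1, rho, rho, 1), 2, 2)
    X <- matrix(rnorm(400), 200, 2) %*% chol(S)
    p <- trait_pca(X)
    emp_rho <- cor(X)[1, 2]
    expect_equal(p$eigenvalues, c(1 + abs(emp_rho), 1 - abs(emp_rho)),
                 tolerance = 1e-9)
  }
  # perfectly correlated pair: rank-1 limit
  x <- rnorm(50)
  p <- trait_pca(cbind(a = x, b = 2 * x + 1))
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-9)
})

test_that("PCA eigen structure satisfies its conservation laws", {
  cfg <- carrot_panel_config(seed = 5)
  m <- genotype_means(simulate_rcbd(cfg), standardize = TRUE)
  p <- trait_pca(m)
  expect_equal(sum(p$eigenvalues), ncol(m), tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_true(all(diff(p$cumulative_percent) >= -1e-12))
  expect_equal(p$cumulative_percent[length(p$cumulative_percent)], 100,
               tolerance = 1e-9)
  # scores covariance is diagonal with the eigenvalues
  SC <- cov(p$scores)
  expect_equal(unname(diag(SC)), p$eigenvalues, tolerance = 1e-9)
  expect_lt(max(abs(SC[upper.tri(SC)])), 1e-9)
  # sign convention: dominant loading of each component is positive
  doms <- apply(p$loadings, 2, function(v) v[which.max(abs(v))])
  expect_true(all(doms > 0))
})

test_that("k-means degenerate cases behave as defined", {
  m <- blob_data(6, seed = 2)
  km1 <- kmeans_lloyd(m, k = 1, seed = 1)
  expect_equal(km1$centroids[1, ], colMeans(m), tolerance = 1e-12)
  expect_equal(km1$objective_j, sum(scale(m, scale = FALSE)^2),
               tolerance = 1e-9)
  kmn <- kmeans_lloyd(m, k = nrow(m), seed = 1)
  expect_equal(kmn$objective_j, 0, tolerance = 1e-12)
})

test_that("well-separated blobs are always recovered exactly", {
  m <- blob_data(10, sep = 10, seed = 3)
  truth <- rep(1:2, each = 10)
  for (s in 1:50) {
    km <- kmeans_lloyd(m, k = 2, seed = s, n_restarts = 2)
    agreement <- max(mean(km$assignments == truth),
                     mean(km$assignments == 3 - truth))
    expect_equal(agreement, 1)
  }
})

test_that("objective trace is monotone and matches stats::kmeans quality", {
  m <- blob_data(15, sep = 3, seed = 4)
  km <- kmeans_lloyd(m, k = 3, seed = 9, n_restarts = 10)
  expect_true(all(diff(km$objective_trace) <= 1e-8))
  ref <- stats::kmeans(m, centers = 3, nstart = 20)
  expect_lte(km$objective_j, ref$tot.withinss * (1 + 1e-6))
  km2 <- kmeans_lloyd(m, k = 3, seed = 9, n_restarts = 10)
  expect_identical(km$assignments, km2$assignments)
})

test_that("silhouette widths match hand arithmetic and the reference", {
  m <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  sw <- silhouette_widths(m, c(1, 1, 2, 2))
  b <- mean(c(10, sqrt(101)))
  expect_equal(sw$silhouette, rep((b - 1) / b, 4), tolerance = 1e-12)
  expect_equal(sw$silhouette[1], 0.9003, tolerance = 1e-4)

  set.seed(10)
  md <- matrix(rnorm(60), 20, 3)
  cl <- rep(1:4, each = 5)
  sw2 <- silhouette_widths(md, cl)
  ref <- cluster::silhouette(cl, dist(md))
  expect_equal(sw2$silhouette, unname(ref[, "sil_width"]),
               tolerance = 1e-12)
})

test_that("silhouette conventions: bounds, ties, singletons", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(rnorm(40), 20, 2)
    km <- kmeans_lloyd(m, k = sample(2:5, 1), seed = i)
    expect_true(all(km$silhouette >= -1 & km$silhouette <= 1))
  }
  # equidistant point: a = b so S = 0
  m <- rbind(c(-1, 0), c(1, 0), c(0, 0))
  sw <- silhouette_widths(m, c(1, 2, 1))
  expect_equal(sw$silhouette[3], 0)
  # singleton cluster gets 0 by convention
  sw2 <- silhouette_widths(rbind(c(0, 0), c(0, 1), c(9, 9)), c(1, 1, 2))
  expect_equal(sw2$silhouette[3], 0)
  expect_error(silhouette_widths(m, c(1, 1, 1)), "single cluster")
})
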