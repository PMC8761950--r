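random_corr_system <- function(p) {
  # random PSD correlation matrix + coherent response correlations
  A <- matrix(rnorm(p * (p + 2)), p + 2, p)
  R <- cor(A)
  beta <- rnorm(p, sd = 0.3)
  r <- as.numeric(R %*% beta)
  scale <- max(1, max(abs(r)) / 0.9)
  list(R = R, r = r / scale, beta = beta / scale)
}

test_that("orthogonal predictors give direct effects equal to r", {
  r <- c(0.7, -0.2, 0.4)
  pr <- path_coefficients(diag(3), r)
  expect_equal(unname(pr$direct), r)
  expect_true(all(pr$indirect[upper.tri(pr$indirect)] == 0))
  expect_equal(pr$residual_effect, sqrt(1 - sum(r^2)))
})

test_that("two-predictor system matches the hand-inverted closed form", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  pr <- path_coefficients(R, c(0.7, 0.1))
  expect_equal(unname(pr$direct),
               c((0.7 - 0.5 * 0.1) / 0.75, (0.1 - 0.5 * 0.7) / 0.75),
               tolerance = 1e-12)
  expect_equal(unname(pr$direct), c(0.8667, -0.3333), tolerance = 1e-4)
  expect_equal(unname(pr$indirect[1, 2]), 0.5 * pr$direct[[2]])
})

test_that("row reconstruction identity holds on random systems", {
  set.seed(21)
  for (i in 1:50) {
    p <- sample(2:8, 1)
    sys <- random_corr_system(p)
    pr <- path_coefficients(sys$R, sys$r)
    expect_lt(pr$reconstruction_error, 1e-10)
    expect_equal(unname(rowSums(pr$indirect)), unname(pr$r_with_response),
                 tolerance = 1e-10)
  }
})

test_that("direct effects are linear in the response correlations", {
  set.seed(22)
  sys <- random_corr_system(4)
  p1 <- path_coefficients(sys$R, sys$r)
  p2 <- path_coefficients(sys$R, 0.5 * sys$r)
  expect_equal(unname(p2$direct), unname(0.5 * p1$direct),
               tolerance = 1e-12)
})

test_that("residual effect is 0 when predictors fully determine response", {
  R <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  # choose r so that sum(P * r) = 1 exactly: r = R %*% beta with
  # t(beta) %*% R %*% beta = 1
  beta <- c(1, 1)
  beta <- beta / sqrt(drop(t(beta) %*% R %*% beta))
  r <- drop(R %*% beta)
  pr <- path_coefficients(R, r)
  expect_equal(pr$residual_effect, 0, tolerance = 1e-7)
})

test_that("singular systems are rejected with the null direction named", {
  R <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_error(path_coefficients(R, c(0.5, 0.5), predictors = c("a", "b")),
               "non-identifiable")
  expect_error(path_coefficients(diag(3), c(0.1, 0.2)), "match")
  expect_error(path_coefficients(matrix(c(1, 0.2, 0.4, 1), 2, 2),
                                 c(0.1, 0.2)), "symmetric")
  expect_error(path_coefficients(matrix(c(2, 0, 0, 2), 2, 2), c(0.1, 0.2)),
               "unit diagonal")
})

test_that("near-collinear systems surface huge direct effects and W-COLLIN", {
  # moisture / carbohydrates / calories-like trio at the clamp boundary
  R <- matrix(c(1, -0.99, -0.99,
                -0.99, 1, 0.9999,
                -0.99, 0.9999, 1), 3, 3)
  r <- c(0.05, -0.05, -0.04)
  expect_warning(
    pr <- path_coefficients(R, r, predictors = c("moisture", "carb", "cal")),
    class = "qgpanel_collinearity_warning")
  expect_gt(pr$condition_number, 1e3)
  expect_gt(max(abs(pr$direct)), 1)
  expect_lt(pr$reconstruction_error, 1e-10)
})

test_that("path analysis from a simulated trial recovers the true effects", {
  R_true <- matrix(c(1, 0.3, 0.1,
                     0.3, 1, 0.2,
                     0.1, 0.2, 1), 3, 3)
  beta <- c(0.5, -0.3, 0.2)
  r_true <- drop(R_true %*% beta)
  traits <- c("p1", "p2", "p3", "resp")
  Rfull <- rbind(cbind(R_true, r_true), c(r_true, 1))
  sds <- c(2, 3, 1, 4)
  Sg <- Rfull * outer(sds, sds)
  est <- sapply(1:60, function(s) {
    cfg <- sim_config(64, 3, traits, rep(50, 4), Sg,
                      rep(0.5, 4), seed = 3000 + s)
    pr <- path_from_trial(simulate_rcbd(cfg), traits[1:3], "resp")
    pr$direct
  })
  bias <- abs(rowMeans(est) - beta)
  expect_true(all(bias < 0.1))
})

test_that("single-predictor path degenerates to the correlation", {
  tr <- simulate_rcbd(two_trait_config(0.6, seed = 31))
  pr <- path_from_trial(tr, "x", "y")
  expect_equal(unname(pr$direct), unname(pr$r_with_response))
  expect_equal(dim(pr$indirect), c(1L, 1L))
  expect_equal(pr$residual_effect, sqrt(1 - pr$direct[[1]]^2),
               tolerance = 1e-12)
})

test_that("missing traits abort naming the path stage", {
  tr <- simulate_rcbd(two_trait_config(0, seed = 1))
  expect_error(path_from_trial(tr, c("x", "ghost"), "y"),
               "path_analysis")
  expect_error(path_from_trial(tr, "x", "x"), "must not be among")
})
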