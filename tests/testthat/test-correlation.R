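test_that("self-covariance reduces to the genotypic variance", {
  set.seed(3)
  tab <- random_trial(6, 3)
  a <- rcbd_anova(tab, "y")
  vc <- extract_components(a, 3)
  cc <- cross_product_components(tab, "y", "y")
  expect_equal(cc$cov_g, vc$sigma2_g_raw, tolerance = 1e-12)
  expect_equal(cc$cov_e, vc$sigma2_e, tolerance = 1e-12)
})

test_that("an affine duplicate trait has unit genotypic correlation", {
  set.seed(4)
  tab <- random_trial(8, 3)
  dup <- tab
  dup$trait <- "z"
  dup$value <- 2 * tab$value + 3
  both <- rbind(tab, dup)
  cs <- correlation_matrices(both, c("y", "z"))
  expect_equal(cs$rg["y", "z"], 1, tolerance = 1e-9)
  expect_equal(cs$rp["y", "z"], 1, tolerance = 1e-9)
  expect_equal(cs$cov_g["y", "z"], 2 * cs$cov_g["y", "y"],
               tolerance = 1e-9)
})

test_that("components match the brute-force double-loop oracle", {
  set.seed(5)
  for (i in 1:10) {
    G <- sample(3:5, 1)
    r <- sample(2:3, 1)
    tab <- random_trial(G, r)
    tab2 <- tab
    tab2$trait <- "z"
    tab2$value <- rnorm(nrow(tab), 5, 3)
    both <- rbind(tab, tab2)
    cc <- cross_product_components(both, "y", "z")
    o <- oracle_cross_components(tab$value, tab2$value,
                                 tab$genotype, tab$block)
    expect_equal(cc$cov_g, o$cov_g, tolerance = 1e-9)
    expect_equal(cc$cov_e, o$cov_e, tolerance = 1e-9)
    expect_equal(cc$cov_p, o$cov_p, tolerance = 1e-9)
  }
})

test_that("independent traits show near-zero mean genotypic correlation", {
  rgs <- vapply(1:100, function(s) {
    tr <- simulate_rcbd(two_trait_config(0, seed = s))
    correlation_matrices(tr, c("x", "y"))$rg["x", "y"]
  }, 0)
  expect_lt(abs(mean(rgs)), 0.03)
})

test_that("a known genotypic correlation is recovered on average", {
  rgs <- vapply(1:100, function(s) {
    tr <- simulate_rcbd(two_trait_config(0.59, seed = 1000 + s))
    correlation_matrices(tr, c("x", "y"))$rg["x", "y"]
  }, 0)
  expect_lt(abs(mean(rgs) - 0.59), 0.03)
  # single-trial sampling error at G = 64 keeps most draws within 0.15
  expect_gt(mean(abs(rgs - 0.59) < 0.15), 0.7)
})

test_that("rg tracks rp when heritability is near 1", {
  cfg <- two_trait_config(0.5, s2g = c(4, 4), s2e = c(0.005, 0.005),
                          seed = 7)
  tr <- simulate_rcbd(cfg)
  cs <- correlation_matrices(tr, c("x", "y"))
  h2 <- vapply(c("x", "y"), function(t) {
    vc <- extract_components(rcbd_anova(tr, t), 3)
    vc$sigma2_g / vc$sigma2_p
  }, 0)
  expect_true(all(h2 > 0.99))
  expect_lt(max(abs(cs$rg - cs$rp)), 0.02)
})

test_that("out-of-range estimates are clamped, flagged, sign-preserved", {
  # high true correlation + tiny genotypic signal in few genotypes makes
  # |rg| > 1 estimates likely; hunt a seed that produces one
  found <- FALSE
  for (s in 1:60) {
    cfg <- sim_config(4, 2, c("x", "y"),
                      c(0, 0), matrix(c(0.05, 0.049, 0.049, 0.05), 2),
                      c(1, 1), seed = s)
    tr <- simulate_rcbd(cfg)
    cs <- withCallingHandlers(
      tryCatch(suppressWarnings(correlation_matrices(tr, c("x", "y"))),
               error = function(e) NULL),
      qgpanel_clamp_warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(cs) || anyNA(cs$rg_raw)) next
    if (abs(cs$rg_raw["x", "y"]) > 1) {
      found <- TRUE
      expect_true(cs$clamped_flags["x", "y"])
      expect_equal(abs(cs$rg["x", "y"]), 1)
      expect_equal(sign(cs$rg["x", "y"]), sign(cs$rg_raw["x", "y"]))
      break
    }
  }
  expect_true(found)
})

test_that("zero genotypic variance yields NA rg rows with a diagnostic", {
  set.seed(12)
  tab <- random_trial(3, 3)
  # Latin-square layout: every genotype sees the same three values, so
  # genotype means are identical and the genotypic component truncates to 0
  flat <- data.frame(
    genotype = rep(c("g1", "g2", "g3"), times = 3),
    block = rep(c("b1", "b2", "b3"), each = 3),
    trait = "z",
    value = c(1, 2, 3, 2, 3, 1, 3, 1, 2),
    stringsAsFactors = FALSE)
  both <- rbind(tab, flat)
  vc <- suppressWarnings(extract_components(rcbd_anova(both, "z"), 3))
  expect_equal(vc$sigma2_g, 0)
  expect_warning(cs <- correlation_matrices(both, c("y", "z")),
                 class = "qgpanel_negvar_warning")
  expect_true(all(is.na(cs$rg["z", ])))
  expect_false(anyNA(cs$rp))
})

test_that("phenotypic correlation significance uses G - 2 df", {
  set.seed(6)
  tr <- simulate_rcbd(two_trait_config(0.9, seed = 2))
  cs <- correlation_matrices(tr, c("x", "y"))
  p <- rp_significance(cs, 64)
  r <- cs$rp["x", "y"]
  tt <- abs(r) * sqrt(62 / (1 - r^2))
  expect_equal(p["x", "y"], 2 * pt(tt, 62, lower.tail = FALSE),
               tolerance = 1e-12)
})
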