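# Independent brute-force oracles: plain double-loop sums of squares and
# cross-products, written against the textbook definitions and kept free
# of any package code path they are used to check.

oracle_rcbd_ss <- function(values, genotype, block) {
  gens <- unique(genotype)
  blks <- unique(block)
  grand <- mean(values)
  r <- length(blks)
  G <- length(gens)
  ss_g <- 0
  for (g in gens) {
    m_g <- mean(values[genotype == g])
    ss_g <- ss_g + r * (m_g - grand)^2
  }
  ss_b <- 0
  for (b in blks) {
    m_b <- mean(values[block == b])
    ss_b <- ss_b + G * (m_b - grand)^2
  }
  ss_t <- sum((values - grand)^2)
  list(ss_genotype = ss_g, ss_block = ss_b, ss_error = ss_t - ss_g - ss_b,
       ss_total = ss_t)
}

# component covariances from the definition: genotype-stratum mean
# cross-product and residual cross-product, double loops throughout
oracle_cross_components <- function(x, y, genotype, block) {
  gens <- unique(genotype)
  blks <- unique(block)
  G <- length(gens)
  r <- length(blks)
  xbar <- mean(x); ybar <- mean(y)
  scp_g <- 0
  for (g in gens) {
    scp_g <- scp_g + r * (mean(x[genotype == g]) - xbar) *
      (mean(y[genotype == g]) - ybar)
  }
  scp_e <- 0
  for (g in gens) for (b in blks) {
    i <- which(genotype == g & block == b)
    rx <- x[i] - mean(x[genotype == g]) - mean(x[block == b]) + xbar
    ry <- y[i] - mean(y[genotype == g]) - mean(y[block == b]) + ybar
    scp_e <- scp_e + rx * ry
  }
  mcp_g <- scp_g / (G - 1)
  mcp_e <- scp_e / ((G - 1) * (r - 1))
  cov_g <- (mcp_g - mcp_e) / r
  list(cov_g = cov_g, cov_e = mcp_e, cov_p = cov_g + mcp_e)
}

# small random balanced trial in long form, one trait, with genuine
# genotype and block strata
random_trial <- function(G, r, mu = 10, sd = 2, g_sd = 3, b_sd = 1) {
  geno <- rnorm(G, sd = g_sd)
  blk <- rnorm(r, sd = b_sd)
  data.frame(
    genotype = rep(sprintf("g%d", seq_len(G)), times = r),
    block = rep(sprintf("b%d", seq_len(r)), each = G),
    trait = "y",
    value = mu + rep(geno, times = r) + rep(blk, each = G) +
      rnorm(G * r, sd = sd),
    stringsAsFactors = FALSE)
}

# variance-component stub for operations that only need the components
make_vc <- function(sigma2_g, sigma2_e, trait = "t", n_blocks = 3L) {
  structure(list(trait = trait, sigma2_e = sigma2_e, sigma2_g = sigma2_g,
                 sigma2_g_raw = sigma2_g, sigma2_p = sigma2_g + sigma2_e,
                 n_blocks = n_blocks),
            class = "variance_components")
}

# two-trait simulation config with given genotypic correlation
two_trait_config <- function(rg, s2g = c(4, 4), s2e = c(0.04, 0.04),
                             seed = 1L) {
  Sg <- matrix(c(s2g[1], rg * sqrt(prod(s2g)),
                 rg * sqrt(prod(s2g)), s2g[2]), 2, 2)
  sim_config(64L, 3L, c("x", "y"), c(20, 20), Sg, s2e,
             block_variance = 0.1, seed = seed)
}
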