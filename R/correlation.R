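#' Genotypic, phenotypic and error covariance components for a trait pair
#'
#' Analysis-of-covariance estimator via the sum-trait identity: the mean
#' cross-product of traits x and y in a stratum is
#' `MCP(x, y) = (MS(x + y) - MS(x) - MS(y)) / 2`, computed for the
#' genotype and error strata of the RCBD. Components then follow the
#' same algebra as the variances: `cov_g = (MCP_G - MCP_E) / r`,
#' `cov_e = MCP_E`, `cov_p = cov_g + cov_e`. On the diagonal (y = x)
#' this reduces exactly to [extract_components()].
#'
#' @param table long trial table, balanced for both traits on the same
#'   genotypes and blocks.
#' @param x,y trait identifiers.
#' @return list with `cov_g`, `cov_p`, `cov_e`.
#' @export
cross_product_components <- function(table, x, y) {
  ax <- rcbd_anova(table, x)
  if (identical(x, y)) {
    vc <- suppressWarnings(extract_components(ax, ax$n_blocks))
    return(list(cov_g = vc$sigma2_g_raw, cov_p = vc$sigma2_g_raw + vc$sigma2_e,
                cov_e = vc$sigma2_e))
  }
  ay <- rcbd_anova(table, y)
  if (ax$n_genotypes != ay$n_genotypes || ax$n_blocks != ay$n_blocks)
    stop("traits '", x, "' and '", y, "' are not on the same design")

  tx <- table[table$trait == x, c("genotype", "block", "value")]
  ty <- table[table$trait == y, c("genotype", "block", "value")]
  m <- merge(tx, ty, by = c("genotype", "block"), suffixes = c("_x", "_y"))
  if (nrow(m) != nrow(tx))
    stop("traits '", x, "' and '", y, "' are misaligned: ",
         nrow(tx) - nrow(m), " plots without a matching pair")
  sum_tab <- data.frame(genotype = m$genotype, block = m$block,
                        trait = "x_plus_y", value = m$value_x + m$value_y,
                        stringsAsFactors = FALSE)
  as_ <- rcbd_anova(sum_tab, "x_plus_y")

  mcp_g <- (as_$ms_genotype - ax$ms_genotype - ay$ms_genotype) / 2
  mcp_e <- (as_$ms_error - ax$ms_error - ay$ms_error) / 2
  cov_g <- (mcp_g - mcp_e) / ax$n_blocks
  list(cov_g = cov_g, cov_p = cov_g + mcp_e, cov_e = mcp_e)
}

#' Genotypic and phenotypic correlation matrices
#'
#' Correlations between trait pairs at the level of variance and
#' covariance components rather than raw phenotypes:
#' `rg(x, y) = cov_g / sqrt(sigma2_g(x) * sigma2_g(y))` and analogously
#' for `rp` with phenotypic components. Because the components are
#' method-of-moments estimates, a ratio can fall outside `[-1, 1]`;
#' such entries are clamped to the boundary (sign preserved) and
#' flagged, with the pre-clamp values retained. A trait with zero
#' genotypic variance has no defined genotypic correlation: its `rg`
#' row/column is reported as `NA` with a diagnostic.
#'
#' @param table long trial table.
#' @param traits ordered trait identifiers (at least 2).
#' @return An object of class `correlation_set`: list with `traits`,
#'   matrices `rg`, `rp`, `cov_g`, `cov_p`, logical `clamped_flags`,
#'   and pre-clamp `rg_raw`, `rp_raw`.
#' @export
correlation_matrices <- function(table, traits) {
  traits <- as.character(traits)
  p <- length(traits)
  if (p < 2L) stop("need at least 2 traits")

  vcs <- lapply(traits, function(tr) {
    a <- rcbd_anova(table, tr)
    suppressWarnings(extract_components(a, a$n_blocks))
  })
  # raw (untruncated) components keep the estimator coherent across the
  # diagonal and off-diagonal: the raw phenotypic variance
  # (MS_G + (r-1) MS_E) / r is always positive, and an affine duplicate
  # trait then yields exactly rg = rp = 1
  s2g <- vapply(vcs, `[[`, 0, "sigma2_g_raw")
  s2p <- s2g + vapply(vcs, `[[`, 0, "sigma2_e")
  zero_g <- s2g <= 0
  if (any(zero_g))
    qg_warn("W-NEGVAR",
            paste("zero genotypic variance for:",
                  paste(traits[zero_g], collapse = ", "),
                  "- genotypic correlations reported as NA"),
            class = "qgpanel_negvar_warning")

  cg <- cp <- matrix(NA_real_, p, p, dimnames = list(traits, traits))
  for (i in seq_len(p)) {
    cg[i, i] <- s2g[i]
    cp[i, i] <- s2p[i]
    for (j in seq_len(p)[-seq_len(i)]) {
      cc <- cross_product_components(table, traits[i], traits[j])
      cg[i, j] <- cg[j, i] <- cc$cov_g
      cp[i, j] <- cp[j, i] <- cc$cov_p
    }
  }

  rg_raw <- cg / sqrt(outer(pmax(s2g, 0), pmax(s2g, 0)))
  rg_raw[zero_g, ] <- NA_real_
  rg_raw[, zero_g] <- NA_real_
  diag(rg_raw)[!zero_g] <- 1
  rp_raw <- cp / sqrt(outer(s2p, s2p))
  diag(rp_raw) <- 1

  clamp <- function(m) {
    m[which(m > 1)] <- 1
    m[which(m < -1)] <- -1
    m
  }
  rg <- clamp(rg_raw)
  rp <- clamp(rp_raw)
  # overshoot at floating-point noise level is not a clamp worth flagging
  flags <- (abs(rg_raw) > 1 + 1e-12 & !is.na(rg_raw)) |
    (abs(rp_raw) > 1 + 1e-12 & !is.na(rp_raw))
  if (any(flags))
    qg_warn("W-CLAMP",
            sprintf("%d correlation estimate(s) outside [-1, 1] clamped to the boundary",
                    sum(flags[upper.tri(flags)])),
            class = "qgpanel_clamp_warning")

  structure(
    list(traits = traits, rg = rg, rp = rp, cov_g = cg, cov_p = cp,
         clamped_flags = flags, rg_raw = rg_raw, rp_raw = rp_raw),
    class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, digits = 3, ...) {
  cat("Component correlations over", length(x$traits), "traits\n")
  cat("Genotypic (rg):\n")
  print(round(x$rg, digits))
  if (any(x$clamped_flags, na.rm = TRUE))
    cat("Note:", sum(x$clamped_flags[upper.tri(x$clamped_flags)],
                     na.rm = TRUE),
        "entries clamped to [-1, 1]\n")
  invisible(x)
}

#' Significance of phenotypic correlations
#'
#' Two-sided t-approximation with G - 2 degrees of freedom applied to
#' the phenotypic correlations only. No small-sample distribution is in
#' general use for component-level genotypic correlations, so none is
#' computed for `rg`.
#'
#' @param cs a [correlation_matrices()] result.
#' @param n_genotypes number of genotypes underlying the estimates.
#' @return matrix of p-values matching `cs$rp`.
#' @export
rp_significance <- function(cs, n_genotypes) {
  stopifnot(inherits(cs, "correlation_set"), n_genotypes > 2)
  r <- cs$rp
  df <- n_genotypes - 2
  tt <- abs(r) * sqrt(df / pmax(1e-12, 1 - r^2))
  p <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  diag(p) <- NA_real_
  p
}
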