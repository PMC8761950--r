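#' Per-trait randomized complete block ANOVA
#'
#' Fits the classical two-way fixed-layout RCBD analysis of variance
#' (genotype and block strata, no interaction) for one trait of a
#' balanced plot-level table and returns the quantities downstream
#' genetic-parameter work needs: stratum degrees of freedom, mean
#' squares, the genotype F test, and the standard error of a genotype
#' mean, `sqrt(MS_error / r)`.
#'
#' @param table long trial table with columns `genotype`, `block`,
#'   `trait`, `value` (see [simulate_rcbd()]).
#' @param trait trait identifier to analyse.
#' @return An object of class `rcbd_anova`: a list with `trait`,
#'   `n_genotypes`, `n_blocks`, `df_genotype`, `df_block`, `df_error`,
#'   `ms_genotype`, `ms_block`, `ms_error`, `ss_genotype`, `ss_block`,
#'   `ss_error`, `grand_mean`, `f_statistic`, `p_value`, `stars`,
#'   `se_mean`.
#' @details Missing cells are an error, not imputed: the estimator's
#'   expected-mean-squares algebra assumes balance. When the response is
#'   constant every mean square is 0 and the F statistic is defined as 0
#'   by convention.
#' @export
rcbd_anova <- function(table, trait) {
  sub <- table[table$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop("trait '", trait, "' not found in table")
  if (any(!is.finite(sub$value)))
    stop("non-finite values for trait '", trait, "'")

  gen <- factor(sub$genotype)
  blk <- factor(sub$block)
  G <- nlevels(gen)
  r <- nlevels(blk)
  if (G < 2L) stop("need at least 2 genotypes")
  if (r < 2L) stop("need at least 2 blocks; zero error df otherwise")
  counts <- table(gen, blk)
  if (any(counts != 1L)) {
    bad <- which(counts == 0L, arr.ind = TRUE)
    miss <- if (nrow(bad)) paste(levels(gen)[bad[, 1]], levels(blk)[bad[, 2]],
                                 sep = ":", collapse = ", ")
            else "duplicated cells present"
    stop("table is not balanced for trait '", trait,
         "'; missing cells: ", miss)
  }

  fit <- stats::aov(value ~ genotype + block,
                    data = data.frame(value = sub$value, genotype = gen,
                                      block = blk))
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ss <- an[["Sum Sq"]]
  names(ss) <- rownames(an)

  # constant response: snap numerically-zero strata to exact zeros
  total_ss <- sum(ss)
  scale2 <- (abs(mean(sub$value)) + 1)^2
  if (total_ss <= 1e-20 * scale2 * nrow(sub)) ss[] <- 0

  df_g <- G - 1L
  df_b <- r - 1L
  df_e <- (G - 1L) * (r - 1L)
  ms_g <- ss[["genotype"]] / df_g
  ms_b <- ss[["block"]] / df_b
  ms_e <- ss[["Residuals"]] / df_e

  if (ms_e > 0) {
    f <- ms_g / ms_e
    p <- stats::pf(f, df_g, df_e, lower.tail = FALSE)
  } else if (ms_g > 0) {
    f <- Inf
    p <- 0
  } else {
    f <- 0
    p <- 1
  }

  structure(
    list(trait = trait, n_genotypes = G, n_blocks = r,
         df_genotype = df_g, df_block = df_b, df_error = df_e,
         ms_genotype = ms_g, ms_block = ms_b, ms_error = ms_e,
         ss_genotype = ss[["genotype"]], ss_block = ss[["block"]],
         ss_error = ss[["Residuals"]],
         grand_mean = mean(sub$value),
         f_statistic = f, p_value = p,
         stars = significance_stars(p),
         se_mean = sqrt(ms_e / r)),
    class = "rcbd_anova")
}

#' @export
print.rcbd_anova <- function(x, ...) {
  cat("RCBD ANOVA for", x$trait, "(", x$n_genotypes, "genotypes x",
      x$n_blocks, "blocks )\n")
  tab <- data.frame(
    Df = c(x$df_genotype, x$df_block, x$df_error),
    `Mean Sq` = c(x$ms_genotype, x$ms_block, x$ms_error),
    row.names = c("genotype", "block", "residual"), check.names = FALSE)
  print(tab)
  cat("F =", format(x$f_statistic, digits = 5),
      " p =", format.pval(x$p_value), x$stars, "\n")
  invisible(x)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#'
#' @param p numeric vector of p-values.
#' @return character vector: `"***"`, `"**"`, `"*"`, or `"ns"`.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Variance components from an RCBD mean-square decomposition
#'
#' Method-of-moments extraction under the RCBD expected mean squares
#' \eqn{E[MS_G] = \sigma^2_e + r\,\sigma^2_g}: the error component is
#' the residual mean square, the genotypic component is
#' `(ms_genotype - ms_error) / n_blocks`, and the phenotypic component
#' is their sum. A negative genotypic estimate (possible by sampling
#' noise when the genotype signal is weak) is truncated to 0 for
#' downstream parameters but kept raw in `sigma2_g_raw`; truncation
#' emits a `W-NEGVAR` warning.
#'
#' @param anova an [rcbd_anova()] result, or any list with
#'   `ms_genotype` and `ms_error` fields and a `trait` name.
#' @param n_blocks number of blocks used in the fit (>= 2).
#' @return An object of class `variance_components` with fields `trait`,
#'   `sigma2_e`, `sigma2_g`, `sigma2_g_raw`, `sigma2_p`, `n_blocks`.
#'   `sigma2_p == sigma2_g + sigma2_e` holds exactly.
#' @export
extract_components <- function(anova, n_blocks) {
  if (n_blocks < 2L) stop("n_blocks must be >= 2")
  if (!is.null(anova$n_blocks) && anova$n_blocks != n_blocks)
    stop("n_blocks (", n_blocks, ") does not match the fitted design (",
         anova$n_blocks, ")")
  s2e <- anova$ms_error
  raw <- (anova$ms_genotype - anova$ms_error) / n_blocks
  s2g <- max(0, raw)
  if (raw < 0)
    qg_warn("W-NEGVAR",
            sprintf("negative genotypic variance estimate %.6g for '%s' truncated to 0",
                    raw, anova$trait %||% "?"),
            class = "qgpanel_negvar_warning")
  structure(
    list(trait = anova$trait %||% NA_character_,
         sigma2_e = s2e, sigma2_g = s2g, sigma2_g_raw = raw,
         sigma2_p = s2g + s2e, n_blocks = as.integer(n_blocks)),
    class = "variance_components")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components for", x$trait, "\n")
  cat(sprintf("  sigma2_e = %.6g  sigma2_g = %.6g  sigma2_p = %.6g\n",
              x$sigma2_e, x$sigma2_g, x$sigma2_p))
  if (x$sigma2_g_raw < 0)
    cat(sprintf("  (raw sigma2_g %.6g truncated to 0)\n", x$sigma2_g_raw))
  invisible(x)
}

#' ANOVA and variance components for every trait of a trial
#'
#' Convenience loop over [rcbd_anova()] + [extract_components()].
#'
#' @param table long trial table.
#' @param traits traits to analyse; default all present.
#' @return A list with `anovas` and `components` (named lists) and a
#'   per-trait summary `data.frame` `summary`.
#' @export
variance_components_table <- function(table, traits = unique(table$trait)) {
  anovas <- lapply(traits, function(tr) rcbd_anova(table, tr))
  names(anovas) <- traits
  comps <- lapply(anovas, function(a) extract_components(a, a$n_blocks))
  summary <- data.frame(
    trait = traits,
    df = vapply(anovas, `[[`, 0, "df_genotype"),
    mean_square = vapply(anovas, `[[`, 0, "ms_genotype"),
    sum_square = vapply(anovas, `[[`, 0, "ss_genotype"),
    se_mean = vapply(anovas, `[[`, 0, "se_mean"),
    f_statistic = vapply(anovas, `[[`, 0, "f_statistic"),
    p_value = vapply(anovas, `[[`, 0, "p_value"),
    stars = vapply(anovas, `[[`, "", "stars"),
    mean = vapply(anovas, `[[`, 0, "grand_mean"),
    sigma2_e = vapply(comps, `[[`, 0, "sigma2_e"),
    sigma2_g = vapply(comps, `[[`, 0, "sigma2_g"),
    sigma2_p = vapply(comps, `[[`, 0, "sigma2_p"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(anovas = anovas, components = comps, summary = summary)
}
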