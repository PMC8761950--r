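#' Genotypic and phenotypic coefficients of variation
#'
#' Component standard deviations expressed as a percentage of the trait
#' mean: `GCV = 100 * sigma_g / mean`, `PCV = 100 * sigma_p / mean`.
#' Because `sigma2_p >= sigma2_g`, GCV never exceeds PCV, and
#' `(GCV/PCV)^2` equals the broad-sense heritability computed from the
#' same components.
#'
#' @param vc a [extract_components()] result (or list with `sigma2_g`,
#'   `sigma2_p`).
#' @param mean trait mean, must be positive (the coefficient is
#'   undefined otherwise).
#' @return list with `gcv_percent` and `pcv_percent`.
#' @export
coefficients_of_variation <- function(vc, mean) {
  if (!is.finite(mean) || mean <= 0)
    stop("coefficient of variation undefined for mean <= 0")
  list(gcv_percent = 100 * sqrt(vc$sigma2_g) / mean,
       pcv_percent = 100 * sqrt(vc$sigma2_p) / mean)
}

#' Broad-sense heritability with class
#'
#' `h2b = sigma2_g / sigma2_p`, the fraction of phenotypic variance
#' attributable to genotypic effects, classified low (< 0.50),
#' medium (0.50 to 0.80, boundaries inclusive) or high (> 0.80).
#'
#' @param vc variance components with positive `sigma2_p`.
#' @return list with `h2b` and `h2b_class`.
#' @export
heritability <- function(vc) {
  if (vc$sigma2_p <= 0) {
    warning("sigma2_p is 0 for '", vc$trait %||% "?",
            "'; heritability undefined, reported as NA")
    return(list(h2b = NA_real_, h2b_class = NA_character_))
  }
  h2b <- vc$sigma2_g / vc$sigma2_p
  cls <- if (h2b < 0.50) "low" else if (h2b <= 0.80) "medium" else "high"
  list(h2b = h2b, h2b_class = cls)
}

#' Genetic advance under truncation selection
#'
#' Expected gain from selecting the best fraction of genotypes:
#' `GA = K * h2b * sigma_p`, with K the standardized selection
#' differential (2.06 at 5 percent selection intensity). Heritability is
#' used unrounded; rounding it first does not reproduce standard
#' published values. When a trait mean is supplied the gain is also
#' expressed as a percentage of that mean.
#'
#' @param vc variance components (for `sigma2_p`).
#' @param h2b broad-sense heritability in `[0, 1]`, unrounded.
#' @param k standardized selection differential, > 0; default 2.06.
#' @param mean optional positive trait mean for `ga_percent_of_mean`.
#' @return list with `genetic_advance` and (if `mean` given)
#'   `ga_percent_of_mean`.
#' @export
genetic_advance <- function(vc, h2b, k = 2.06, mean = NULL) {
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  if (!is.finite(h2b) || h2b < 0 || h2b > 1)
    stop("h2b must lie in [0, 1]")
  ga <- k * h2b * sqrt(vc$sigma2_p)
  out <- list(genetic_advance = ga)
  if (!is.null(mean)) {
    if (mean <= 0) stop("mean must be positive for GA percent of mean")
    out$ga_percent_of_mean <- 100 * ga / mean
  }
  out
}

#' Genetic parameters for every trait of a trial
#'
#' Runs the RCBD decomposition per trait and derives GCV, PCV,
#' broad-sense heritability (with class), genetic advance and GA as a
#' percentage of the trait mean. Trait means come from the data, never
#' from external tables.
#'
#' @param table long trial table.
#' @param traits traits to analyse; default all present.
#' @param k standardized selection differential; default 2.06 (5
#'   percent selection intensity).
#' @return A `data.frame`, one row per trait, with the ANOVA summary
#'   columns of [variance_components_table()] plus `gcv_percent`,
#'   `pcv_percent`, `h2b`, `h2b_class`, `genetic_advance`,
#'   `ga_percent_of_mean`.
#' @export
genetic_parameters <- function(table, traits = unique(table$trait),
                               k = 2.06) {
  vt <- variance_components_table(table, traits)
  res <- vt$summary
  n <- nrow(res)
  res$gcv_percent <- res$pcv_percent <- res$h2b <- rep(NA_real_, n)
  res$h2b_class <- rep(NA_character_, n)
  res$genetic_advance <- res$ga_percent_of_mean <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    vc <- vt$components[[i]]
    cv <- coefficients_of_variation(vc, res$mean[i])
    h <- heritability(vc)
    res$gcv_percent[i] <- cv$gcv_percent
    res$pcv_percent[i] <- cv$pcv_percent
    res$h2b[i] <- h$h2b
    res$h2b_class[i] <- h$h2b_class
    if (is.finite(h$h2b)) {
      ga <- genetic_advance(vc, h$h2b, k = k, mean = res$mean[i])
      res$genetic_advance[i] <- ga$genetic_advance
      res$ga_percent_of_mean[i] <- ga$ga_percent_of_mean
    }
  }
  attr(res, "selection_constant") <- k
  res
}
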