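#' Carbohydrates by difference
#'
#' Proximate analysis reports carbohydrates as whatever of the sample is
#' not moisture, ash, fat, fiber or protein:
#' `100 - (ash + moisture + fat + fiber + protein)`, all in percent of
#' fresh weight. Inconsistent inputs (components summing past 100) give
#' a negative result, which is flagged with a `W-QC` warning rather
#' than rejected so batch processing of noisy panels can proceed.
#'
#' @param ash,moisture,fat,fiber,protein component percentages, each in
#'   `[0, 100]` (vectorized).
#' @return carbohydrate percentage(s).
#' @export
percent_carbohydrates <- function(ash, moisture, fat, fiber, protein) {
  comp <- cbind(ash, moisture, fat, fiber, protein)
  if (any(comp < 0 | comp > 100))
    stop("proximate components must lie in [0, 100]")
  out <- 100 - rowSums(comp)
  if (any(out < 0))
    qg_warn("W-QC", sprintf(
      "%d sample(s) with components summing past 100 (negative carbohydrates)",
      sum(out < 0)), class = "qgpanel_qc_warning")
  unname(out)
}

#' Caloric value from Atwater factors
#'
#' `4 * protein + 9 * fat + 4 * carbohydrates`, kcal per 100 g when the
#' inputs are percentages of fresh weight.
#'
#' @param protein,fat,carbohydrates non-negative percentages
#'   (vectorized).
#' @return kcal per 100 g.
#' @export
atwater_calories <- function(protein, fat, carbohydrates) {
  if (any(c(protein, fat, carbohydrates) < 0))
    stop("inputs must be non-negative")
  4 * protein + 9 * fat + 4 * carbohydrates
}

#' Crude protein from Kjeldahl nitrogen
#'
#' Conversion `protein = N * 6.25`; results at or above 100 percent are
#' physically implausible and flagged with `W-QC`.
#'
#' @param nitrogen_percent Kjeldahl nitrogen, percent, >= 0
#'   (vectorized).
#' @return crude protein percentage(s).
#' @export
protein_from_nitrogen <- function(nitrogen_percent) {
  if (any(nitrogen_percent < 0)) stop("nitrogen must be non-negative")
  out <- nitrogen_percent * 6.25
  if (any(out >= 100))
    qg_warn("W-QC", sprintf(
      "%d sample(s) with derived protein at or above 100%% (implausible nitrogen)",
      sum(out >= 100)), class = "qgpanel_qc_warning")
  out
}

#' CIELAB colour reading
#'
#' @param L_star lightness, in `[0, 100]`.
#' @param a_star red-green axis.
#' @param b_star yellow-blue axis.
#' @return class `color_reading`.
#' @export
color_reading <- function(L_star, a_star, b_star) {
  if (L_star < 0 || L_star > 100) stop("L* must lie in [0, 100]")
  structure(list(L_star = L_star, a_star = a_star, b_star = b_star),
            class = "color_reading")
}

#' Colour difference Delta E*ab
#'
#' Euclidean distance between two readings in CIE 1976 L*a*b* space:
#' `sqrt((dL)^2 + (da)^2 + (db)^2)`.
#'
#' @param sample,reference [color_reading()] objects (or lists with
#'   `L_star`, `a_star`, `b_star`).
#' @return non-negative colour difference.
#' @export
delta_e <- function(sample, reference) {
  sqrt((sample$L_star - reference$L_star)^2 +
         (sample$a_star - reference$a_star)^2 +
         (sample$b_star - reference$b_star)^2)
}

#' DPPH radical-scavenging inhibition
#'
#' Percent drop in 517 nm absorbance of the DPPH radical over the
#' incubation: `100 * (abs_t0 - abs_t30) / abs_t0`. An end-point
#' absorbance above the start (pro-oxidant artifact) yields a negative
#' inhibition, returned with a `W-QC` flag rather than an error.
#'
#' @param abs_t0 absorbance at 0 min, > 0 (vectorized).
#' @param abs_t30 absorbance at the end of incubation, >= 0.
#' @return inhibition percentage(s).
#' @export
dpph_inhibition <- function(abs_t0, abs_t30) {
  if (any(abs_t0 <= 0)) stop("abs_t0 must be positive")
  if (any(abs_t30 < 0)) stop("abs_t30 must be non-negative")
  out <- 100 * (abs_t0 - abs_t30) / abs_t0
  if (any(out < 0))
    qg_warn("W-QC", sprintf(
      "%d sample(s) with absorbance gain over incubation (negative inhibition)",
      sum(out < 0)), class = "qgpanel_qc_warning")
  out
}

#' Batch derivation of proximate panel traits
#'
#' Takes one sample per row with columns `ash`, `moisture`, `fat`,
#' `fiber`, `protein` (optionally `nitrogen` in place of `protein`) and
#' appends derived `carbohydrates` and `calories` columns plus a
#' logical `qc_flag` marking rows whose derived carbohydrates fall
#' outside `[0, 100]`.
#'
#' @param df data.frame of proximate measurements (percent).
#' @return `df` with `carbohydrates`, `calories`, `qc_flag` appended.
#' @export
derive_proximate_panel <- function(df) {
  if (!"protein" %in% names(df)) {
    if (!"nitrogen" %in% names(df))
      stop("need a 'protein' or 'nitrogen' column")
    df$protein <- suppressWarnings(protein_from_nitrogen(df$nitrogen))
  }
  need <- c("ash", "moisture", "fat", "fiber", "protein")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$carbohydrates <- suppressWarnings(
    percent_carbohydrates(df$ash, df$moisture, df$fat, df$fiber,
                          df$protein))
  df$calories <- atwater_calories(df$protein, df$fat,
                                  pmax(0, df$carbohydrates))
  df$qc_flag <- df$carbohydrates < 0 | df$carbohydrates > 100
  df
}
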