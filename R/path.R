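#' Path-coefficient decomposition of correlations with a response trait
#'
#' Splits each predictor's correlation with the response into a direct
#' effect and indirect effects routed through the other predictors.
#' Direct effects P solve the linear system `R P = r`, where R is the
#' predictor correlation matrix and r the vector of predictor-response
#' correlations; the indirect effect of predictor i via predictor j is
#' `R[i, j] * P[j]`. By construction each row satisfies
#' `P[i] + sum_j R[i, j] P[j] = r[i]` to solver precision. The residual
#' effect is `sqrt(1 - sum(P * r))`, the response variation left
#' unexplained in the correlation metric.
#'
#' The system is solved exactly, with no ridge or pseudo-inverse
#' damping: with nearly collinear predictors the direct effects can be
#' legitimately enormous and opposite-signed, and damping would hide
#' that structure. Instead the condition number of R is reported and a
#' `W-COLLIN` warning raised when it exceeds 1e4.
#'
#' @param rg_predictors symmetric predictor correlation matrix with
#'   unit diagonal.
#' @param r_response vector of predictor-response correlations, same
#'   order and length as the matrix.
#' @param predictors,response optional identifiers for labelling.
#' @return An object of class `path_result`: `predictors`, `response`,
#'   `direct` (P), `indirect` (matrix, direct effects on the diagonal),
#'   `r_with_response`, `residual_effect`, `residual_raw`
#'   (`1 - sum(P*r)`, which ill-conditioning can push below 0; the
#'   reported residual is then 0 with `residual_clipped = TRUE`),
#'   `condition_number`, `reconstruction_error`.
#' @export
path_coefficients <- function(rg_predictors, r_response,
                              predictors = NULL, response = "response") {
  R <- as.matrix(rg_predictors)
  r <- as.numeric(r_response)
  p <- length(r)
  if (!all(dim(R) == p))
    stop("rg_predictors must be ", p, " x ", p,
         " to match r_response")
  if (!isSymmetric(unname(R), tol = 1e-8))
    stop("rg_predictors must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-8))
    stop("rg_predictors must have unit diagonal")
  if (anyNA(R) || anyNA(r))
    stop("correlations contain NA; cannot solve for direct effects")
  if (is.null(predictors))
    predictors <- colnames(R) %||% paste0("x", seq_len(p))

  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(abs(e$values)) / max(abs(e$values)) < 1e-12) {
    null_dir <- e$vectors[, which.min(abs(e$values))]
    stop("predictor correlation matrix is singular; direct effects are ",
         "non-identifiable along the direction (",
         paste(sprintf("%s: %.3f", predictors, null_dir), collapse = ", "),
         ")")
  }
  cond <- max(abs(e$values)) / min(abs(e$values))
  if (cond > 1e4)
    qg_warn("W-COLLIN",
            sprintf("predictor correlation matrix is ill-conditioned (condition number %.3g); direct effects are unstable",
                    cond),
            class = "qgpanel_collinearity_warning")

  P <- solve(R, r)
  indirect <- R * matrix(P, p, p, byrow = TRUE)  # [i, j] = R[i,j] * P[j]
  diag(indirect) <- P
  dimnames(indirect) <- list(predictors, predictors)

  residual_raw <- 1 - sum(P * r)
  clipped <- residual_raw < 0
  residual <- sqrt(max(0, residual_raw))

  structure(
    list(predictors = predictors, response = response,
         direct = stats::setNames(P, predictors),
         indirect = indirect,
         r_with_response = stats::setNames(r, predictors),
         residual_effect = residual, residual_raw = residual_raw,
         residual_clipped = clipped,
         condition_number = cond,
         reconstruction_error = max(abs(R %*% P - r))),
    class = "path_result")
}

#' @export
print.path_result <- function(x, digits = 3, ...) {
  cat("Path analysis of", x$response, "on", length(x$predictors),
      "predictors\n")
  cat("Direct effects:\n")
  print(round(x$direct, digits))
  cat(sprintf("Residual effect R = %.4f%s   condition number = %.3g\n",
              x$residual_effect,
              if (x$residual_clipped) " (clipped at 0)" else "",
              x$condition_number))
  invisible(x)
}

#' Path analysis straight from a trial table
#'
#' Estimates genotypic correlations among the predictors and with the
#' response via [correlation_matrices()], then decomposes them with
#' [path_coefficients()]. Clamp flags from the correlation stage are
#' carried along in `clamped_flags`.
#'
#' @param table long trial table.
#' @param predictors ordered predictor trait identifiers.
#' @param response response trait identifier (not among the predictors).
#' @return A `path_result` with an extra `clamped_flags` element.
#' @export
path_from_trial <- function(table, predictors, response) {
  if (response %in% predictors)
    stop("response trait must not be among the predictors")
  traits <- c(predictors, response)
  missing <- setdiff(traits, unique(table$trait))
  if (length(missing))
    qg_stop("path_analysis",
            paste("trait(s) not present in data:",
                  paste(missing, collapse = ", ")))

  if (length(predictors) == 1L) {
    cs <- correlation_matrices(table, traits)
    r <- cs$rg[predictors, response]
    res <- structure(
      list(predictors = predictors, response = response,
           direct = stats::setNames(r, predictors),
           indirect = matrix(r, 1, 1,
                             dimnames = list(predictors, predictors)),
           r_with_response = stats::setNames(r, predictors),
           residual_effect = sqrt(max(0, 1 - r^2)),
           residual_raw = 1 - r^2, residual_clipped = FALSE,
           condition_number = 1, reconstruction_error = 0),
      class = "path_result")
    res$clamped_flags <- cs$clamped_flags
    return(res)
  }

  cs <- correlation_matrices(table, traits)
  if (anyNA(cs$rg))
    qg_stop("path_analysis",
            "genotypic correlations undefined (zero genotypic variance)")
  R <- cs$rg[predictors, predictors]
  r <- cs$rg[predictors, response]
  res <- path_coefficients(R, r, predictors = predictors,
                           response = response)
  res$clamped_flags <- cs$clamped_flags
  res
}
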