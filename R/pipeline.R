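#' Run the full diversity-panel analysis pipeline
#'
#' Composes every stage — simulate (or read) a trial, per-trait RCBD
#' ANOVA with variance components and genetic parameters, genotypic and
#' phenotypic correlation matrices, path-coefficient decomposition of
#' the response trait, and multivariate structure (PCA, k-means,
#' silhouettes) — and writes the standard CSV reports plus a JSON
#' manifest recording the seed, input hash, package version and every
#' warning code emitted. Any stage failure aborts with the stage named
#' and removes the partial outputs of this run.
#'
#' Files written to `output_dir`:
#' \itemize{
#'   \item `trial.csv` — the analysed plot-level table.
#'   \item `genetic_parameters.csv` — one column per trait; rows DF,
#'     mean square, sum square, SE of mean, variance components, mean,
#'     GCV, PCV, h2b (+class), GA, GA percent of mean.
#'   \item `correlations_genotypic.csv` / `correlations_phenotypic.csv`
#'     and `correlation_clamp_flags.csv`.
#'   \item `path_effects.csv` — predictors x predictors with direct
#'     effects on the diagonal, plus the response-correlation column;
#'     `path_summary.json` with residual effect and condition number.
#'   \item `pca_summary.csv`, `clusters.csv`, `manifest.json`.
#' }
#'
#' @param config a [sim_config()] to simulate from, or `NULL` when
#'   `input_path` is given.
#' @param input_path CSV of an existing trial (see [read_trial_csv()]).
#' @param output_dir directory for reports (created if needed).
#' @param response response trait for the path analysis.
#' @param predictors ordered predictor traits; default the eight
#'   nutritional predictors conventionally regressed on beta-carotene.
#' @param k_clusters number of k-means clusters (default 8).
#' @param seed seed for the clustering restarts (and the simulation if
#'   `config` carries none).
#' @param n_restarts k-means restarts.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = NULL, input_path = NULL,
                         output_dir = "qgpanel_run",
                         response = "beta_carotene",
                         predictors = c("TSS", "vitamin_c", "moisture",
                                        "crude_fat", "crude_protein",
                                        "crude_fiber", "carbohydrates",
                                        "calories"),
                         k_clusters = 8L, seed = 1L, n_restarts = 10L) {
  if (is.null(config) && is.null(input_path))
    stop("provide a simulation config or an input CSV")
  if (response %in% predictors)
    stop("response trait must not be among the predictors")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  written <- character(0)
  codes <- character(0)
  collect <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        unlink(written)
        stop("stage ", stage, " failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      qgpanel_warning = function(w) {
        codes <<- c(codes, w$code)
        invokeRestart("muffleWarning")
      })
  }
  emit <- function(name) {
    path <- file.path(output_dir, name)
    written <<- c(written, path)
    path
  }

  # --- input stage -----------------------------------------------------
  trial <- collect({
    if (!is.null(config)) simulate_rcbd(config) else read_trial_csv(input_path)
  }, "input")
  write_trial_csv(trial, emit("trial.csv"))
  traits <- unique(trial$trait)

  # --- genetic parameters ---------------------------------------------
  gp <- collect(genetic_parameters(trial), "genetic_parameters")
  wide <- t(as.matrix(gp[, c("df", "mean_square", "sum_square", "se_mean",
                             "sigma2_e", "sigma2_g", "sigma2_p", "mean",
                             "gcv_percent", "pcv_percent", "h2b",
                             "genetic_advance", "ga_percent_of_mean")]))
  colnames(wide) <- gp$trait
  utils::write.csv(data.frame(parameter = rownames(wide), wide,
                              check.names = FALSE),
                   emit("genetic_parameters.csv"), row.names = FALSE)

  # --- correlations -----------------------------------------------------
  cs <- collect(correlation_matrices(trial, traits), "correlation")
  utils::write.csv(as.data.frame(cs$rg), emit("correlations_genotypic.csv"))
  utils::write.csv(as.data.frame(cs$rp), emit("correlations_phenotypic.csv"))
  utils::write.csv(as.data.frame(cs$clamped_flags),
                   emit("correlation_clamp_flags.csv"))

  # --- path analysis ----------------------------------------------------
  pr <- collect({
    missing <- setdiff(c(predictors, response), traits)
    if (length(missing))
      stop("trait(s) not present in data: ", paste(missing, collapse = ", "))
    path_from_trial(trial, predictors, response)
  }, "path_analysis")
  path_tab <- cbind(as.data.frame(pr$indirect),
                    response = pr$r_with_response)
  names(path_tab)[ncol(path_tab)] <- response
  utils::write.csv(path_tab, emit("path_effects.csv"))
  jsonlite::write_json(
    list(residual_effect = pr$residual_effect,
         residual_raw = pr$residual_raw,
         residual_clipped = pr$residual_clipped,
         condition_number = pr$condition_number,
         reconstruction_error = pr$reconstruction_error),
    emit("path_summary.json"), auto_unbox = TRUE, digits = NA)

  # --- multivariate -----------------------------------------------------
  mv <- collect({
    m <- genotype_means(trial, standardize = TRUE)
    pca <- trait_pca(m)
    km <- kmeans_lloyd(m, k = k_clusters, seed = seed,
                       n_restarts = n_restarts)
    list(means = m, pca = pca, clusters = km)
  }, "multivariate")
  pca_tab <- data.frame(
    component = paste0("PC", seq_along(mv$pca$eigenvalues)),
    eigenvalue = mv$pca$eigenvalues,
    variance_percent = mv$pca$variance_percent,
    cumulative_percent = mv$pca$cumulative_percent)
  utils::write.csv(pca_tab, emit("pca_summary.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(genotype = rownames(mv$means),
               cluster = unname(mv$clusters$assignments),
               silhouette = mv$clusters$silhouette),
    emit("clusters.csv"), row.names = FALSE)

  # --- manifest ----------------------------------------------------------
  manifest <- list(
    package = "qgpanel",
    version = as.character(utils::packageVersion("qgpanel")),
    seed = seed,
    simulated = !is.null(config),
    config_seed = if (!is.null(config)) config$seed else NULL,
    input_md5 = unname(tools::md5sum(file.path(output_dir, "trial.csv"))),
    n_genotypes = length(unique(trial$genotype)),
    n_blocks = length(unique(trial$block)),
    traits = traits,
    response = response,
    predictors = predictors,
    k_clusters = k_clusters,
    warning_codes = unique(codes))
  jsonlite::write_json(manifest, emit("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(trial = trial, genetic_parameters = gp,
                 correlations = cs, path = pr, multivariate = mv,
                 manifest = manifest, warning_codes = codes))
}
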