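#' Genotype-by-trait matrix of means over blocks
#'
#' Aggregates a long trial table to one row per genotype (mean over
#' blocks per trait), optionally standardizing each trait column to
#' mean 0 and unit variance (n - 1 divisor) — the form the PCA and
#' clustering stages expect.
#'
#' @param table long trial table.
#' @param traits trait columns to keep; default all present.
#' @param standardize standardize columns? A zero-variance trait makes
#'   standardization undefined and is an error naming the trait.
#' @return numeric matrix (genotypes x traits) with attribute
#'   `standardized`.
#' @export
genotype_means <- function(table, traits = NULL, standardize = FALSE) {
  if (is.null(traits)) traits <- unique(table$trait)
  sub <- table[table$trait %in% traits, , drop = FALSE]
  agg <- stats::aggregate(value ~ genotype + trait, data = sub, FUN = mean)
  wide <- stats::reshape(agg, idvar = "genotype", timevar = "trait",
                         direction = "wide")
  rn <- wide$genotype
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^value\\.", "", colnames(m))
  m <- m[, traits, drop = FALSE]
  rownames(m) <- rn
  m <- m[order(rownames(m)), , drop = FALSE]
  if (anyNA(m)) stop("missing genotype x trait cells in means matrix")
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0))
      stop("cannot standardize zero-variance trait(s): ",
           paste(colnames(m)[sds == 0], collapse = ", "))
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  attr(m, "standardized") <- standardize
  m
}

#' PCA of standardized genotype means
#'
#' Eigen-decomposition of the trait correlation matrix (standardized
#' variables), so eigenvalues sum to the number of traits. Loadings are
#' sign-fixed so each component's largest-magnitude loading is
#' positive; scores are the standardized means projected onto the
#' loadings.
#'
#' @param m genotype-means matrix from [genotype_means()]; standardized
#'   internally if it is not already.
#' @return class `trait_pca`: `eigenvalues` (non-increasing),
#'   `variance_percent`, `cumulative_percent`, `loadings`, `scores`.
#' @export
trait_pca <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 genotypes for PCA")
  C <- stats::cor(m)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(m), paste0("PC", seq_along(vals)))
  scores <- scale(m) %*% vecs
  structure(
    list(eigenvalues = vals,
         variance_percent = 100 * vals / sum(vals),
         cumulative_percent = cumsum(100 * vals / sum(vals)),
         loadings = vecs, scores = scores),
    class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, digits = 3, ...) {
  k <- min(4L, length(x$eigenvalues))
  tab <- rbind(eigenvalue = x$eigenvalues[1:k],
               `variance %` = x$variance_percent[1:k],
               `cumulative %` = x$cumulative_percent[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, digits))
  invisible(x)
}

# squared Euclidean distance from each row of m to each centroid row
dist2_to_centroids <- function(m, centroids) {
  d2 <- outer(rowSums(m^2), rowSums(centroids^2), `+`) -
    2 * m %*% t(centroids)
  pmax(d2, 0)
}

kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  idx <- sample.int(n, 1L)
  for (j in seq_len(k - 1L)) {
    d2 <- dist2_to_centroids(m, m[idx, , drop = FALSE])
    mind2 <- apply(d2, 1, min)
    mind2[idx] <- 0
    if (sum(mind2) == 0) {
      pool <- setdiff(seq_len(n), idx)
      idx <- c(idx, pool[sample.int(length(pool), 1L)])
    } else {
      idx <- c(idx, sample.int(n, 1L, prob = mind2 / sum(mind2)))
    }
  }
  m[idx, , drop = FALSE]
}

#' K-means clustering of genotype means (Lloyd + k-means++)
#'
#' Minimizes the objective `J = sum_i || x_i - c_{a(i)} ||^2` (sum of
#' squared Euclidean distances to the assigned centroid) by Lloyd
#' iterations from k-means++ starts, keeping the best of `n_restarts`
#' runs. J is checked to be non-increasing at every iteration. A
#' cluster emptied by reassignment is repaired by re-seeding its
#' centroid at the point farthest from its current centroid.
#'
#' @param m genotype-means matrix (standardize first for trait
#'   comparability).
#' @param k number of clusters, `2 <= k <= nrow(m)` (k = 1 allowed for
#'   the degenerate single-cluster case).
#' @param seed integer seed; results are deterministic given it.
#' @param n_restarts independent k-means++ starts; default 10.
#' @param max_iter Lloyd iteration cap per start.
#' @return class `cluster_result`: `k`, `assignments` (named integer
#'   vector), `centroids`, `objective_j`, `objective_trace` (per
#'   iteration of the winning start), `silhouette`,
#'   `cluster_mean_silhouette` (both NULL when k = 1).
#' @export
kmeans_lloyd <- function(m, k, seed = 1L, n_restarts = 10L,
                         max_iter = 100L) {
  n <- nrow(m)
  if (k < 1L || k > n) stop("k must be in [1, number of genotypes]")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  best <- NULL
  for (run in seq_len(n_restarts)) {
    centroids <- kmeanspp_init(m, k)
    trace <- numeric(0)
    prev_j <- Inf
    assign_vec <- rep(1L, n)
    for (it in seq_len(max_iter)) {
      d2 <- dist2_to_centroids(m, centroids)
      assign_vec <- max.col(-d2, ties.method = "first")
      # empty-cluster repair: re-seed at the globally farthest point
      repaired <- FALSE
      for (cl in seq_len(k)) {
        if (!any(assign_vec == cl)) {
          far <- which.max(apply(d2, 1, min))
          centroids[cl, ] <- m[far, ]
          assign_vec[far] <- cl
          repaired <- TRUE
        }
      }
      if (repaired) d2 <- dist2_to_centroids(m, centroids)
      j_now <- sum(d2[cbind(seq_len(n), assign_vec)])
      if (j_now > prev_j + 1e-8 * (1 + prev_j))
        stop("internal error: k-means objective increased")
      trace <- c(trace, j_now)
      for (cl in seq_len(k))
        centroids[cl, ] <- colMeans(m[assign_vec == cl, , drop = FALSE])
      if (is.finite(prev_j) && prev_j - j_now <= 1e-12 * (1 + prev_j)) break
      prev_j <- j_now
    }
    d2 <- dist2_to_centroids(m, centroids)
    j_final <- sum(d2[cbind(seq_len(n), assign_vec)])
    trace <- c(trace, j_final)
    if (is.null(best) || j_final < best$objective_j)
      best <- list(assignments = assign_vec, centroids = centroids,
                   objective_j = j_final, objective_trace = trace)
  }

  sil <- NULL
  cms <- NULL
  if (k >= 2L) {
    sw <- silhouette_widths(m, best$assignments)
    sil <- sw$silhouette
    cms <- sw$cluster_mean_silhouette
  }
  structure(
    list(k = as.integer(k),
         assignments = stats::setNames(best$assignments, rownames(m)),
         centroids = best$centroids,
         objective_j = best$objective_j,
         objective_trace = best$objective_trace,
         silhouette = sil, cluster_mean_silhouette = cms),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("k-means:", x$k, "clusters, objective J =",
      format(x$objective_j, digits = 6), "\n")
  print(table(cluster = x$assignments))
  if (!is.null(x$cluster_mean_silhouette)) {
    cat("Mean silhouette per cluster:\n")
    print(round(x$cluster_mean_silhouette, 3))
  }
  invisible(x)
}

#' Silhouette widths for a clustering
#'
#' For each observation, `a_i` is the mean Euclidean distance to the
#' other members of its own cluster and `b_i` the smallest mean
#' distance to any other cluster; the silhouette width is
#' `S_i = (b_i - a_i) / max(a_i, b_i)`, bounded in `[-1, 1]`.
#' Observations in singleton clusters get `S_i = 0` by convention.
#'
#' @param m data matrix (rows = observations).
#' @param assignments integer/factor cluster labels, >= 2 non-empty
#'   clusters.
#' @return list with `silhouette` (per observation) and
#'   `cluster_mean_silhouette` (named by cluster).
#' @export
silhouette_widths <- function(m, assignments) {
  cl <- as.integer(factor(assignments))
  ks <- sort(unique(cl))
  if (length(ks) < 2L)
    stop("silhouette undefined for a single cluster")
  n <- nrow(m)
  D <- as.matrix(stats::dist(m))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1L) {
      s[i] <- 0
      next
    }
    a_i <- mean(D[i, setdiff(own, i)])
    b_i <- min(vapply(setdiff(ks, cl[i]),
                      function(kk) mean(D[i, cl == kk]), 0))
    s[i] <- if (max(a_i, b_i) == 0) 0 else (b_i - a_i) / max(a_i, b_i)
  }
  cms <- tapply(s, cl, mean)
  names(cms) <- paste0("cluster", names(cms))
  list(silhouette = s, cluster_mean_silhouette = cms)
}
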