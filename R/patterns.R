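#' Centered-Pearson correlation distance matrix
#'
#' `d(i, j) = 1 - r(x_i, x_j)` with Pearson's r, so d ranges over
#' `[0, 2]`: 0 for identical shapes, 2 for perfectly anti-correlated ones.
#' This is the classic expression-clustering metric.
#'
#' @param x An [expression_matrix] (or numeric matrix).
#' @param by `"feature"` (default) clusters rows; `"sample"` clusters
#'   columns.
#' @param standardize_features For sample clustering, z-score each
#'   feature across samples first (default), so that between-sample
#'   correlations reflect relative expression changes rather than the
#'   spread of feature baseline intensities. Ignored for `by =
#'   "feature"`, where Pearson's r already centers and scales each
#'   feature.
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
correlation_distance_matrix <- function(x, by = c("feature", "sample"),
                                        standardize_features =
                                          (by[1] == "sample")) {
  by <- match.arg(by)
  m <- if (by == "feature") t(unclass(x)) else unclass(x)
  if (by == "sample" && standardize_features) {
    rsd <- apply(m, 1, stats::sd)
    if (any(rsd == 0 | is.na(rsd)))
      stop("zero-variance feature: ",
           paste(rownames(m)[rsd == 0 | is.na(rsd)], collapse = ", "))
    m <- (m - rowMeans(m)) / rsd
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | is.na(sds)))
    stop("zero-variance ", by, ": ",
         paste(colnames(m)[sds == 0 | is.na(sds)], collapse = ", "))
  d <- 1 - stats::cor(m)
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering with a flat cut
#'
#' Standard average- (or complete-) linkage agglomeration on a
#' precomputed distance matrix, mirroring the defaults of the classic
#' expression-clustering tools. Deterministic: [stats::hclust()] merges
#' are reproducible and tied merges resolve to the smaller index.
#'
#' @param dist Symmetric distance matrix (e.g. from
#'   [correlation_distance_matrix]) or a `dist` object.
#' @param linkage `"average"` (default) or `"complete"`.
#' @param k Optional number of flat clusters to cut the tree into.
#' @return List with `tree` (an `hclust`) and, when `k` is given,
#'   `clusters` (named integer vector).
#' @export
hierarchical_cluster <- function(dist, linkage = c("average", "complete"),
                                 k = NULL) {
  linkage <- match.arg(linkage)
  d <- if (inherits(dist, "dist")) dist else stats::as.dist(dist)
  n <- attr(d, "Size")
  tree <- stats::hclust(d, method = linkage)
  out <- list(tree = tree)
  if (!is.null(k)) {
    if (k > n) stop("requested ", k, " clusters from ", n, " items")
    out$clusters <- stats::cutree(tree, k = k)
  }
  out
}

#' Export a dendrogram in Newick format
#' @param tree An `hclust` object.
#' @param path Output file path.
#' @export
export_dendrogram_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export needs the ape package")
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Stage-mean trajectories of features
#'
#' @param x An [expression_matrix].
#' @param design A [stage_design]; stage means are ordered by its stage
#'   order.
#' @return data.frame with `feature_id` and one `mean_<stage>` column per
#'   stage.
#' @export
stage_trajectories <- function(x, design) {
  xs <- x[, names(design$samples), drop = FALSE]
  g <- design_factor(design, colnames(xs))
  gm <- sapply(levels(g), function(lev)
    rowMeans(xs[, g == lev, drop = FALSE]))
  if (is.null(dim(gm)))
    gm <- matrix(gm, nrow = 1, dimnames = list(rownames(xs), levels(g)))
  out <- data.frame(feature_id = rownames(xs), gm, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[-1] <- paste0("mean_", levels(g))
  rownames(out) <- NULL
  out
}

# sign of successive stage differences under a flatness tolerance
trend_vector <- function(stage_means, eps) {
  d <- diff(stage_means)
  ifelse(abs(d) <= eps, 0L, ifelse(d > 0, 1L, -1L))
}

#' Classify a stage trajectory into one of six dynamic patterns
#'
#' The trajectory of stage means (reference first, metastasis last) is
#' reduced to a trend vector: the sign of each successive difference, with
#' differences of magnitude at most `eps` treated as flat. Patterns:
#'
#' * **1** gradual decrease across the series (non-increasing, still
#'   falling at the last transition);
#' * **2** early decrease then plateau (non-increasing, flat tail);
#' * **3** non-monotone down-then-up;
#' * **4** non-monotone up-then-down;
#' * **5** gradual increase (non-decreasing, at least one rise);
#' * **6** flat through the primary stages, then a jump of at least
#'   `delta` at the metastasis transition (takes precedence over 5).
#'
#' Only patterns 1, 5 and 6 are described verbally in the source study;
#' 2-4 complete the taxonomy symmetrically and can be disabled with
#' `mode = "basic"`, in which case pattern 1/5 use their broad
#' definitions (any non-increasing / non-decreasing non-flat trajectory)
#' and everything else is unclassified.
#'
#' @param stage_means Numeric vector of the five stage means in stage
#'   order (reference first, metastasis last).
#' @param eps Flatness tolerance in log2 units (default 0.25).
#' @param delta Minimum metastasis jump for pattern 6 (default 1.0).
#' @param mode `"full"` (six patterns) or `"basic"` (1/5/6 only).
#' @return Integer pattern id in `1:6`, or `NA_integer_` for
#'   unclassified trajectories.
#' @examples
#' classify_pattern(c(5, 4, 3, 2, 1))            # 1
#' classify_pattern(c(1, 2, 3, 4, 5))            # 5
#' classify_pattern(c(3, 3, 3, 3, 6))            # 6
#' @export
classify_pattern <- function(stage_means, eps = 0.25, delta = 1.0,
                             mode = c("full", "basic")) {
  mode <- match.arg(mode)
  if (length(stage_means) != 5L)
    stop("trajectory needs 5 stage means, got ", length(stage_means))
  tr <- trend_vector(stage_means, eps)
  m <- length(tr)
  last_jump <- stage_means[m + 1L] - stage_means[m]
  # 6: flat through the primary stages, dramatic rise at metastasis
  if (all(tr[-m] == 0L) && tr[m] == 1L && last_jump >= delta)
    return(6L)
  down <- any(tr == -1L); up <- any(tr == 1L)
  if (mode == "basic") {
    if (!up && down) return(1L)
    if (!down && up) return(5L)
    return(NA_integer_)
  }
  if (!up && down) return(if (tr[m] == -1L) 1L else 2L)
  if (!down && up) return(5L)
  if (up && down) {
    first_sign <- tr[tr != 0L][1L]
    return(if (first_sign == -1L) 3L else 4L)
  }
  NA_integer_
}

#' Classify every feature's trajectory
#'
#' @param traj A trajectory table from [stage_trajectories].
#' @inheritParams classify_pattern
#' @return data.frame `feature_id`, `pattern` (integer or NA).
#' @export
classify_patterns <- function(traj, eps = 0.25, delta = 1.0,
                              mode = c("full", "basic")) {
  mode <- match.arg(mode)
  means <- as.matrix(traj[, grep("^mean_", colnames(traj)), drop = FALSE])
  data.frame(feature_id = traj$feature_id,
             pattern = apply(means, 1, classify_pattern, eps = eps,
                             delta = delta, mode = mode),
             stringsAsFactors = FALSE)
}
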