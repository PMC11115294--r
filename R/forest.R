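#' Random-forest configuration for unsupervised clustering
#'
#' @param n_trees number of trees T.
#' @param mtry features sampled per split; default `ceiling(sqrt(k))` for k
#'   features.
#' @param max_depth optional maximum tree depth (translated to a terminal
#'   node cap of `2^max_depth`).
#' @param min_leaf minimum terminal-node size.
#' @param seed integer seed making the forest deterministic.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 500, mtry = NULL, max_depth = NULL,
                          min_leaf = 5, seed = NULL) {
  if (n_trees < 1)
    hr_stop("`n_trees` must be >= 1", "headreach_invalid_argument")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 max_depth = max_depth, min_leaf = min_leaf, seed = seed),
            class = "forest_config")
}

#' Unsupervised random forest and proximity matrix
#'
#' Clusters unlabeled motion data with the synthetic-contrast random-forest
#' construction: a contrast class is built by independently permuting each
#' (z-scored) feature column, destroying the joint structure while keeping
#' the marginals; trees are then grown to separate real from permuted
#' observations, choosing at each node the largest-information-gain (Gini)
#' split among `mtry` randomly sampled features. Pairs of real observations
#' that often end in the same terminal leaf are similar under the forest's
#' metric; the proximity matrix collects these co-occurrence frequencies
#' over the real observations only.
#'
#' @param features numeric matrix or data.frame of observations x features.
#' @param config a [forest_config()].
#' @return List with `forest` (the fitted randomForest object),
#'   `proximity` (n x n symmetric matrix, unit diagonal, entries in
#'   `[0, 1]`), and `scaled` (the z-scored feature matrix).
#' @export
fit_unsupervised_forest <- function(features, config = forest_config()) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x); k <- ncol(x)
  if (n < 2)
    hr_stop("need at least two observations", "headreach_invalid_argument")
  sds <- apply(x, 2, sd)
  if (all(sds == 0))
    hr_stop("constant feature table: forest is degenerate",
            "headreach_degenerate_forest")
  keep <- sds > 0
  z <- scale(x[, keep, drop = FALSE])
  mtry <- if (is.null(config$mtry)) ceiling(sqrt(ncol(z))) else
    min(config$mtry, ncol(z))
  maxnodes <- if (is.null(config$max_depth)) NULL else
    as.integer(2^config$max_depth)
  with_seed(config$seed, {
    synth <- apply(z, 2, sample)
    xx <- rbind(z, synth)
    yy <- factor(rep(c("observed", "synthetic"), each = n))
    rf <- randomForest::randomForest(
      x = xx, y = yy, ntree = config$n_trees, mtry = mtry,
      nodesize = config$min_leaf, maxnodes = maxnodes,
      proximity = TRUE, keep.forest = TRUE)
    prox <- rf$proximity[seq_len(n), seq_len(n), drop = FALSE]
    diag(prox) <- 1
    prox <- (prox + t(prox)) / 2
    list(forest = rf, proximity = prox, scaled = z)
  })
}
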