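#' Partition observations from a proximity matrix
#'
#' k-medoids clustering on the canonical proximity-to-distance mapping
#' `d = sqrt(1 - proximity)`. The default deterministic build+swap solution
#' is supplemented with seeded random restarts, keeping the partition with
#' the smallest total dissimilarity to the medoids.
#'
#' @param prox symmetric proximity matrix (unit diagonal, entries in
#'   `[0, 1]`).
#' @param k number of clusters, `2 <= k < n`.
#' @param nstart number of additional random medoid initializations.
#' @param seed integer seed for the restarts.
#' @return Integer vector of cluster assignments (1..k), with attributes
#'   `medoids` (indices) and `objective` (total dissimilarity).
#' @export
cluster_from_proximity <- function(prox, k, nstart = 5, seed = NULL) {
  n <- nrow(prox)
  if (k < 2 || k >= n)
    hr_stop("`k` must satisfy 2 <= k < n", "headreach_invalid_argument")
  d <- sqrt(pmax(1 - prox, 0))   # pmax keeps the dims of its first argument
  diss <- as.dist(d)
  best <- cluster::pam(diss, k, diss = TRUE)
  best_obj <- sum(vapply(seq_len(n), function(i)
    d[i, best$id.med[best$clustering[i]]], numeric(1)))
  with_seed(seed, {
    for (s in seq_len(nstart)) {
      init <- sample.int(n, k)
      cand <- tryCatch(cluster::pam(diss, k, diss = TRUE, medoids = init),
                       error = function(e) NULL)
      if (is.null(cand)) next
      obj <- sum(vapply(seq_len(n), function(i)
        d[i, cand$id.med[cand$clustering[i]]], numeric(1)))
      if (obj < best_obj - 1e-12) {
        best <- cand; best_obj <- obj
      }
    }
  })
  structure(as.integer(best$clustering), medoids = best$id.med,
            objective = best_obj)
}

#' Elbow-method selection of the cluster count
#'
#' For each candidate k the observations are partitioned from the proximity
#' matrix ([cluster_from_proximity()]; k = 1 puts everything in one
#' cluster) and the within-cluster sum of squares (WSS) is computed in the
#' z-scored feature space. The knee is chosen automatically as the k
#' maximizing the second forward difference of the WSS curve (the sharp
#' decrease point); the full curve is returned for manual override.
#' AIC = WSS + 2 k p and BIC = WSS + ln(n) k p (p = number of features) are
#' reported alongside. When the strongest curvature is not well separated
#' from the rest of the curve (no sharp knee, e.g. a single homogeneous
#' cloud), the result is flagged low-confidence.
#'
#' @param features observations x features matrix (z-scored internally).
#' @param prox proximity matrix over the same observations.
#' @param k_max largest candidate k (>= 2, < n).
#' @param nstart,seed passed to [cluster_from_proximity()].
#' @return List of class `elbow_result`: `k`, `wss_by_k`, `aic_by_k`,
#'   `bic_by_k`, `assignments_by_k`, `low_confidence`.
#' @export
elbow_select_k <- function(features, prox, k_max = 8, nstart = 5,
                           seed = NULL) {
  z <- scale(as.matrix(features))
  z[is.nan(z)] <- 0
  n <- nrow(z); p <- ncol(z)
  if (k_max < 2)
    hr_stop("`k_max` must be >= 2", "headreach_invalid_argument")
  if (k_max >= n)
    hr_stop("`k_max` must be below the number of observations",
            "headreach_invalid_argument")
  ks <- 1:k_max
  assignments <- vector("list", k_max)
  wss <- numeric(k_max)
  for (k in ks) {
    cl <- if (k == 1) rep(1L, n) else
      as.integer(cluster_from_proximity(prox, k, nstart = nstart,
                                        seed = if (is.null(seed)) NULL
                                               else seed + k))
    w <- within_ss(z, cl)
    if (k > 1 && w > wss[k - 1]) {
      # k-medoids on proximity need not decrease the feature-space WSS;
      # fall back to splitting the heaviest cluster of the k-1 solution,
      # which can only decrease it
      alt <- split_heaviest_cluster(z, assignments[[k - 1]], prox,
                                    nstart = nstart, seed = seed)
      w_alt <- within_ss(z, alt)
      if (w_alt < w) {
        cl <- alt
        w <- w_alt
      }
    }
    assignments[[k]] <- cl
    wss[k] <- w
  }
  aic <- wss + 2 * ks * p
  bic <- wss + log(n) * ks * p
  if (k_max >= 3) {
    d2 <- wss[1:(k_max - 2)] - 2 * wss[2:(k_max - 1)] + wss[3:k_max]
    k_hat <- which.max(d2) + 1L
    # a sharp knee drops WSS by at least half going into k_hat
    low_conf <- max(d2) <= 0 || wss[k_hat] >= 0.5 * wss[k_hat - 1]
  } else {
    k_hat <- 2L
    low_conf <- TRUE
  }
  structure(list(k = k_hat, wss_by_k = wss, aic_by_k = aic, bic_by_k = bic,
                 assignments_by_k = assignments,
                 assignments = assignments[[k_hat]],
                 low_confidence = low_conf),
            class = "elbow_result")
}

# split the cluster with the largest within-SS contribution into two
split_heaviest_cluster <- function(z, cl, prox, nstart, seed) {
  per <- vapply(sort(unique(cl)), function(g) {
    idx <- cl == g
    if (sum(idx) < 2) return(-Inf)
    sum(scale(z[idx, , drop = FALSE], scale = FALSE)^2)
  }, numeric(1))
  g <- sort(unique(cl))[which.max(per)]
  idx <- which(cl == g)
  sub_cl <- if (length(idx) == 2) c(1L, 2L) else
    as.integer(cluster_from_proximity(prox[idx, idx, drop = FALSE], 2,
                                      nstart = nstart, seed = seed))
  out <- cl
  out[idx[sub_cl == 2]] <- max(cl) + 1L
  as.integer(factor(out))
}

within_ss <- function(z, cl) {
  sum(vapply(split(seq_len(nrow(z)), cl), function(idx) {
    m <- z[idx, , drop = FALSE]
    sum(scale(m, scale = FALSE)^2)
  }, numeric(1)))
}

#' @export
print.elbow_result <- function(x, ...) {
  cat(sprintf("elbow selection: k = %d%s\n", x$k,
              if (x$low_confidence) " (low confidence: no sharp knee)" else ""))
  curve <- data.frame(k = seq_along(x$wss_by_k), wss = x$wss_by_k,
                      aic = x$aic_by_k, bic = x$bic_by_k)
  print(curve, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Per-cluster z-value profiles
#'
#' Standardizes each variable over all observations and summarizes each
#' cluster by the mean and spread of the z-values per variable, the layout
#' used to read motion patterns off a cluster solution (e.g. "cluster 4:
#' long motor time, large shoulder excursion"). Also reports
#' `R2 = 1 - WSS/TSS` of the partition in z-space.
#'
#' @param features observations x features matrix or data.frame.
#' @param assignments integer cluster labels, one per observation.
#' @return List of class `cluster_profiles`: `profiles` (data.frame with
#'   cluster, variable, n, mean_z, sd_z), `r_squared`, `k`, `sizes`.
#' @export
cluster_profiles <- function(features, assignments) {
  x <- as.matrix(features)
  if (nrow(x) != length(assignments))
    hr_stop("one assignment per observation required",
            "headreach_invalid_argument")
  tab <- table(assignments)
  if (any(tab == 0))
    hr_stop("empty cluster in assignments", "headreach_invalid_argument")
  z <- scale(x)
  z[is.nan(z)] <- 0
  vars <- colnames(x)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(x)))
  rows <- list()
  for (cl in sort(unique(assignments))) {
    idx <- assignments == cl
    for (j in seq_along(vars)) {
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, variable = vars[j], n = sum(idx),
        mean_z = mean(z[idx, j]), sd_z = if (sum(idx) > 1) sd(z[idx, j]) else 0)
    }
  }
  tss <- sum(z^2)
  wss <- within_ss(z, assignments)
  r2 <- if (tss > 0) 1 - wss / tss else 0
  structure(list(profiles = do.call(rbind, rows), r_squared = r2,
                 k = length(tab), sizes = as.integer(tab)),
            class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat(sprintf("cluster profiles: k = %d, R2 = %.2f, sizes = %s\n",
              x$k, x$r_squared, paste(x$sizes, collapse = "/")))
  print(x$profiles, digits = 3, row.names = FALSE)
  invisible(x)
}
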