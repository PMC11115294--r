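#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two scores measured on the same
#' trials, using the placement-value (structural component) covariance
#' estimator. Both AUCs are computed in the fixed direction "higher score
#' predicts paralyzed" (no orientation flipping), consistent with
#' [roc_analysis()]. The test statistic is a two-sided z for the AUC
#' difference.
#'
#' @param scores_a,scores_b paired numeric scores on identical trials.
#' @param labels class labels.
#' @param positive label of the positive (paralyzed) class.
#' @return List with `auc_a`, `auc_b`, `var_diff`, `z`, `p`, plus the
#'   variance of each AUC (`var_a`, `var_b`) and their covariance.
#' @export
delong_auc_test <- function(scores_a, scores_b, labels,
                            positive = "paralyzed") {
  stopifnot(length(scores_a) == length(scores_b),
            length(labels) == length(scores_a))
  pos <- labels == positive
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0)
    hr_stop("both classes must be present", "headreach_invalid_argument")
  if (m < 2 || n < 2)
    hr_stop("need at least two observations per class for the variance",
            "headreach_undefined_test")

  placements <- function(s) {
    x <- s[pos]; y <- s[!pos]
    # V10[i]: fraction of negatives below positive i (ties half credit)
    v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
                  numeric(1))
    v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                  numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(var_diff))
    hr_stop("degenerate placement variance", "headreach_undefined_test")
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
    if (abs(d) > .Machine$double.eps^0.5)
      hr_stop("zero variance with non-zero AUC difference",
              "headreach_undefined_test")
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc,
       var_a = S[1, 1], var_b = S[2, 2], cov_ab = S[1, 2],
       var_diff = var_diff, z = z, p = p)
}
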