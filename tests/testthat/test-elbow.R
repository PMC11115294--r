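test_that("the elbow method recovers planted blob counts", {
  set.seed(81)
  for (k_true in c(3, 4)) {
    blobs <- simplex_blobs(k_true, 25, p = 4, sep = 15)
    # terminal-node size near the cluster scale keeps within-cluster
    # proximity from being diluted by leaf granularity
    fit <- fit_unsupervised_forest(blobs$x,
                                   forest_config(n_trees = 250, min_leaf = 20,
                                                 seed = k_true))
    eb <- elbow_select_k(blobs$x, fit$proximity, k_max = 8, seed = 17)
    expect_equal(eb$k, k_true)
    expect_false(eb$low_confidence)
    # recovered partition agrees with the planted one up to labels
    tab <- table(eb$assignments, blobs$labels)
    expect_gt(sum(apply(tab, 2, max)) / nrow(blobs$x), 0.85)
  }
})

test_that("the WSS curve is non-increasing on returned solutions", {
  set.seed(82)
  blobs <- simplex_blobs(3, 15, p = 4, sep = 8)
  fit <- fit_unsupervised_forest(blobs$x, forest_config(n_trees = 120,
                                                        seed = 3))
  eb <- elbow_select_k(blobs$x, fit$proximity, k_max = 6, seed = 5)
  expect_true(all(diff(eb$wss_by_k) <= 1e-8))
  expect_equal(eb$aic_by_k, eb$wss_by_k + 2 * (1:6) * 4, tolerance = 1e-12)
  expect_equal(eb$bic_by_k, eb$wss_by_k + log(45) * (1:6) * 4,
               tolerance = 1e-12)
})

test_that("a single homogeneous cloud is flagged low-confidence", {
  set.seed(83)
  x <- matrix(rnorm(50 * 4), 50, 4)
  fit <- fit_unsupervised_forest(x, forest_config(n_trees = 120, seed = 9))
  eb <- elbow_select_k(x, fit$proximity, k_max = 6, seed = 7)
  expect_true(eb$low_confidence)
})

test_that("invalid k_max is rejected", {
  x <- matrix(rnorm(20), 10, 2)
  pr <- diag(10)
  expect_error(elbow_select_k(x, pr, k_max = 1),
               class = "headreach_invalid_argument")
  expect_error(elbow_select_k(x, pr, k_max = 10),
               class = "headreach_invalid_argument")
})
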