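test_that("proximity matrix invariants hold across seeds", {
  set.seed(61)
  x <- matrix(rnorm(30 * 3), 30, 3)
  for (s in c(1, 2, 3)) {
    fit <- fit_unsupervised_forest(x, forest_config(n_trees = 60, seed = s))
    pr <- fit$proximity
    expect_equal(pr, t(pr))
    expect_equal(unname(diag(pr)), rep(1, 30))
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("well-separated blobs are closer within than between", {
  set.seed(62)
  blobs <- simplex_blobs(2, 20, p = 3, sep = 12)
  fit <- fit_unsupervised_forest(blobs$x, forest_config(n_trees = 150,
                                                        seed = 7))
  pr <- fit$proximity
  same <- outer(blobs$labels, blobs$labels, "==")
  diag(same) <- NA
  expect_gt(mean(pr[which(same)]), mean(pr[which(!same)]))
})

test_that("a single depth-one tree gives binary proximities", {
  set.seed(63)
  x <- matrix(rnorm(40), 20, 2)
  fit <- fit_unsupervised_forest(x, forest_config(n_trees = 1, max_depth = 1,
                                                  seed = 5))
  expect_true(all(fit$proximity %in% c(0, 1)))
})

test_that("duplicated observations have proximity one", {
  set.seed(64)
  x <- matrix(rnorm(36), 18, 2)
  x[18, ] <- x[1, ]
  fit <- fit_unsupervised_forest(x, forest_config(n_trees = 40, seed = 2))
  expect_equal(fit$proximity[1, 18], 1)
})

test_that("the forest is deterministic under its seed", {
  x <- matrix(rnorm(60), 20, 3)
  f1 <- fit_unsupervised_forest(x, forest_config(n_trees = 30, seed = 11))
  f2 <- fit_unsupervised_forest(x, forest_config(n_trees = 30, seed = 11))
  expect_identical(f1$proximity, f2$proximity)
})

test_that("a constant feature table is degenerate", {
  expect_error(fit_unsupervised_forest(matrix(1, 10, 3), forest_config()),
               class = "headreach_degenerate_forest")
})
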