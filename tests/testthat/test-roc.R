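test_that("Youden's index matches the published operating points", {
  ref <- reference_operating_points()
  j <- youden_index(ref$sensitivity_pct / 100, ref$specificity_pct / 100)
  expect_equal(round(j, 2), ref$youden)
})

test_that("perfectly separated scores give J 1 and AUC 1", {
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12),
                    rep(c("non_paralyzed", "paralyzed"), each = 3))
  expect_equal(r$j_at_cutoff, 1)
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff, 10)
})

test_that("AUC equals the Mann-Whitney statistic with half-credit ties", {
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(4:12, 1); n0 <- sample(4:12, 1)
    scores <- c(sample(1:8, n1, TRUE), sample(1:8, n0, TRUE))  # many ties
    labels <- rep(c("paralyzed", "non_paralyzed"), c(n1, n0))
    r <- roc_analysis(scores, labels)
    sp <- scores[labels == "paralyzed"]
    sn <- scores[labels == "non_paralyzed"]
    u <- sum(outer(sp, sn, ">")) + 0.5 * sum(outer(sp, sn, "=="))
    expect_equal(r$auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(32)
  scores <- rnorm(40)
  labels <- rep(c("paralyzed", "non_paralyzed"), 20)
  a0 <- roc_analysis(scores, labels)$auc
  expect_equal(roc_analysis(exp(scores), labels)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_analysis(qnorm(plogis(scores)), labels)$auc, a0,
               tolerance = 1e-9)
})

test_that("the cutoff attains the maximal J, ties broken low", {
  set.seed(33)
  scores <- sample(1:6, 30, TRUE)
  labels <- rep(c("paralyzed", "non_paralyzed"), 15)
  r <- roc_analysis(scores, labels)
  expect_true(all(r$j_at_cutoff >= r$youden_j - 1e-12))
  winners <- r$thresholds[r$youden_j == r$j_at_cutoff]
  expect_equal(r$cutoff, min(winners))
})

test_that("features lower on the paralyzed side report AUC below 0.5 as-is", {
  r <- roc_analysis(c(10, 11, 12, 1, 2, 3),
                    rep(c("non_paralyzed", "paralyzed"), each = 3))
  expect_equal(r$auc, 0)
})

test_that("single-class input is rejected", {
  expect_error(roc_analysis(1:5, rep("paralyzed", 5)),
               class = "headreach_invalid_argument")
})
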