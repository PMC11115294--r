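test_that("identical score pairs give z 0 and p 1", {
  set.seed(41)
  s <- rnorm(30)
  labels <- rep(c("paralyzed", "non_paralyzed"), 15)
  res <- delong_auc_test(s, s, labels)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  expect_equal(res$auc_a, res$auc_b)
})

test_that("labels independent of both scores give AUCs near one half", {
  set.seed(42)
  n <- 400
  labels <- rep(c("paralyzed", "non_paralyzed"), n / 2)
  res <- delong_auc_test(rnorm(n), rnorm(n), labels)
  expect_lt(abs(res$auc_a - 0.5), 0.08)
  expect_lt(abs(res$auc_b - 0.5), 0.08)
  expect_gt(res$p, 0.001)
})

test_that("statistic agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (i in 1:5) {
    n <- 60
    labels <- rep(c("paralyzed", "non_paralyzed"), n / 2)
    y <- as.integer(labels == "paralyzed")
    a <- rnorm(n) + 0.8 * y
    b <- rnorm(n) + 0.4 * y + 0.3 * a
    res <- delong_auc_test(a, b, labels)
    r1 <- pROC::roc(y, a, direction = "<", levels = c(0, 1), quiet = TRUE)
    r2 <- pROC::roc(y, b, direction = "<", levels = c(0, 1), quiet = TRUE)
    ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
    expect_equal(res$auc_a, as.numeric(r1$auc), tolerance = 1e-12)
    expect_equal(res$auc_b, as.numeric(r2$auc), tolerance = 1e-12)
    expect_equal(unname(res$z), unname(ref$statistic), tolerance = 1e-8)
    expect_equal(res$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("placement variance of one AUC tracks the bootstrap variance", {
  set.seed(44)
  n <- 50
  labels <- rep(c("paralyzed", "non_paralyzed"), n / 2)
  y <- as.integer(labels == "paralyzed")
  s <- rnorm(n) + y
  res <- delong_auc_test(s, s, labels)
  auc_of <- function(idx) {
    sp <- s[idx][y[idx] == 1]; sn <- s[idx][y[idx] == 0]
    (sum(outer(sp, sn, ">")) + 0.5 * sum(outer(sp, sn, "=="))) /
      (length(sp) * length(sn))
  }
  boots <- replicate(800, {
    idx <- c(sample(which(y == 1), replace = TRUE),
             sample(which(y == 0), replace = TRUE))
    auc_of(idx)
  })
  expect_lt(abs(res$var_a - var(boots)) / var(boots), 0.2)
})

test_that("degenerate inputs are rejected", {
  expect_error(delong_auc_test(1:4, 1:4, rep("paralyzed", 4)),
               class = "headreach_invalid_argument")
  # zero placement variance but different AUCs cannot be tested
  labels <- rep(c("paralyzed", "non_paralyzed"), each = 3)
  expect_error(delong_auc_test(c(2, 2, 2, 1, 1, 1), c(1, 1, 1, 2, 2, 2),
                               labels),
               class = "headreach_undefined_test")
})
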