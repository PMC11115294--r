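test_that("mirror-image groups give Wilks lambda 1 and F 0", {
  base <- matrix(rnorm(40, sd = 2), 20, 2)
  d <- data.frame(y1 = c(base[, 1], base[, 1]),
                  y2 = c(base[, 2], base[, 2]),
                  g = rep(c("a", "b"), each = 20))
  res <- manova_rm(d, dvs = c("y1", "y2"), factor = "g")
  expect_equal(res$wilks_lambda, 1, tolerance = 1e-9)
  expect_equal(res$F, 0, tolerance = 1e-9)
})

test_that("single DV without covariates reduces to one-way ANOVA", {
  set.seed(12)
  d <- data.frame(y = c(rnorm(15), rnorm(15, 1)),
                  g = rep(c("a", "b"), each = 15))
  res <- manova_rm(d, dvs = "y", factor = "g")
  a <- anova(lm(y ~ g, d))
  expect_equal(res$F, a[["F value"]][1], tolerance = 1e-9)
  expect_equal(res$p, a[["Pr(>F)"]][1], tolerance = 1e-9)
  expect_equal(res$univariate$eta_squared,
               a[["Sum Sq"]][1] / sum(a[["Sum Sq"]]), tolerance = 1e-9)
})

test_that("two-group two-DV Wilks matches the Hotelling T-squared form", {
  set.seed(13)
  n1 <- 12; n2 <- 14; n <- n1 + n2
  x1 <- matrix(rnorm(2 * n1), n1, 2)
  x2 <- matrix(rnorm(2 * n2, mean = 0.8), n2, 2)
  d <- data.frame(y1 = c(x1[, 1], x2[, 1]), y2 = c(x1[, 2], x2[, 2]),
                  g = rep(c("a", "b"), c(n1, n2)))
  S <- ((n1 - 1) * cov(x1) + (n2 - 1) * cov(x2)) / (n - 2)
  dm <- colMeans(x1) - colMeans(x2)
  T2 <- (n1 * n2 / n) * drop(t(dm) %*% solve(S) %*% dm)
  lambda_oracle <- 1 / (1 + T2 / (n - 2))
  res <- manova_rm(d, dvs = c("y1", "y2"), factor = "g")
  expect_equal(res$wilks_lambda, lambda_oracle, tolerance = 1e-9)
})

test_that("result is invariant to observation order", {
  set.seed(14)
  d <- data.frame(y1 = rnorm(40), y2 = rnorm(40),
                  g = rep(c("a", "b"), 20), cv = rnorm(40))
  r1 <- manova_rm(d, dvs = c("y1", "y2"), factor = "g", covariates = "cv")
  r2 <- manova_rm(d[sample(40), ], dvs = c("y1", "y2"), factor = "g",
                  covariates = "cv")
  expect_equal(r1$wilks_lambda, r2$wilks_lambda, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("degenerate designs are rejected", {
  d <- data.frame(y1 = rnorm(10), g = rep(c("a", "b"), 5))
  d$y2 <- d$y1                       # perfectly collinear DVs
  expect_error(manova_rm(d, dvs = c("y1", "y2"), factor = "g"),
               class = "headreach_error")
  expect_error(manova_rm(d[d$g == "a", ], dvs = "y1", factor = "g"),
               class = "headreach_invalid_argument")
})

test_that("normality and rank tests match their reference behaviour", {
  set.seed(15)
  x <- rnorm(50)
  sw <- shapiro_wilk(x)
  ref <- shapiro.test(x)
  expect_equal(sw$W, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(sw$p, ref$p.value, tolerance = 1e-3)
  expect_error(shapiro_wilk(rep(1, 10)),
               class = "headreach_undefined_statistic")

  # hand enumeration of rank sums for {1,2,3} vs {4,5,6}:
  # R1 = 6, R2 = 15, H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-9)

  same <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$H, 0, tolerance = 1e-9)
})
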