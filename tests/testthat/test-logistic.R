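test_that("balanced intercept-only model has null deviance 2n log 2", {
  d <- data.frame(side = rep(c("paralyzed", "non_paralyzed"), each = 10),
                  x = rep(0:1, 10))
  fit <- logistic_fit(d, "side", "x")
  expect_equal(fit$null_deviance, 2 * 20 * log(2), tolerance = 1e-9)
})

test_that("IRLS coefficients match a from-scratch Newton oracle", {
  set.seed(22)
  n <- 20
  d <- data.frame(x = rnorm(n), cv = rnorm(n))
  eta <- 0.8 * d$x - 0.3 * d$cv
  d$side <- ifelse(runif(n) < plogis(eta), "paralyzed", "non_paralyzed")
  fit <- logistic_fit(d, "side", "x", covariates = "cv")

  X <- cbind(1, d$x, d$cv)
  y <- as.integer(d$side == "paralyzed")
  beta <- rep(0, 3)
  for (i in 1:100) {
    p <- plogis(drop(X %*% beta))
    W <- p * (1 - p)
    step <- solve(t(X) %*% (X * W), t(X) %*% (y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-13) break
  }
  expect_equal(fit$coefficients$estimate, beta, tolerance = 1e-8)
})

test_that("a predictor independent of the response fits a null model", {
  set.seed(23)
  d <- data.frame(side = rep(c("paralyzed", "non_paralyzed"), 30),
                  x = rnorm(60))
  fit <- logistic_fit(d, "side", "x")
  expect_lt(fit$chisq, qchisq(0.99, 1))
  expect_lt(fit$mcfadden_r2, 0.1)
  expect_equal(fit$aic, fit$deviance + 2 * 2, tolerance = 1e-9)
})

test_that("adding a covariate never increases the deviance", {
  set.seed(24)
  d <- data.frame(x = rnorm(50), cv1 = rnorm(50), cv2 = rnorm(50))
  d$side <- ifelse(runif(50) < plogis(d$x), "paralyzed", "non_paralyzed")
  base <- logistic_fit(d, "side", "x")
  for (cvs in list("cv1", c("cv1", "cv2"))) {
    bigger <- logistic_fit(d, "side", "x", covariates = cvs)
    expect_lte(bigger$deviance, base$deviance + 1e-8)
  }
})

test_that("perfect separation triggers a diverging-coefficient warning", {
  d <- data.frame(x = c(1:10, 21:30),
                  side = rep(c("non_paralyzed", "paralyzed"), each = 10))
  expect_warning(fit <- logistic_fit(d, "side", "x"),
                 regexp = "separation")
  expect_true(fit$separation)
})

test_that("degenerate responses and collinear designs are rejected", {
  d <- data.frame(side = rep("paralyzed", 10), x = rnorm(10))
  expect_error(logistic_fit(d, "side", "x"),
               class = "headreach_invalid_argument")
})
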