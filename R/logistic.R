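#' Binomial logistic discrimination of the paralyzed side
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) of the side label on one kinematic feature plus the covariates,
#' reporting the model fit layout used for the clinical task: residual
#' deviance, AIC, McFadden's pseudo-R-squared (1 - logLik/logLik_null), the
#' overall model chi-square (null deviance - residual deviance, df = number
#' of non-intercept terms) and per-term Wald statistics.
#'
#' @param table data.frame holding response, predictor and covariates.
#' @param response name of the binary response column; the `positive` level
#'   is coded 1.
#' @param predictor name of the kinematic feature column.
#' @param covariates character vector of covariate column names.
#' @param positive response level coded as 1 (default `"paralyzed"`).
#' @return An object of class `logistic_fit`: `coefficients` table
#'   (estimate, se, z, p per term), `deviance`, `null_deviance`, `aic`,
#'   `mcfadden_r2`, `chisq`, `df`, `p`, `converged`, `separation`.
#' @export
logistic_fit <- function(table, response, predictor,
                         covariates = character(),
                         positive = "paralyzed") {
  stopifnot(all(c(response, predictor, covariates) %in% names(table)))
  y <- as.integer(table[[response]] == positive)
  if (length(unique(y)) < 2)
    hr_stop("response is degenerate (single class)",
            "headreach_invalid_argument")
  rhs <- c(predictor, covariates)
  dat <- table[, rhs, drop = FALSE]
  dat$.y <- y
  fml <- stats::reformulate(rhs, response = ".y")
  fit <- withCallingHandlers(
    glm(fml, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X))
    hr_stop("collinear design matrix", "headreach_rank_deficiency")
  separation <- any(abs(coef(fit)) > 15) || !fit$converged
  if (separation)
    warning("possible complete separation: coefficients diverging",
            call. = FALSE)
  co <- summary(fit)$coefficients
  ll <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(glm(.y ~ 1, data = dat, family = binomial())))
  chisq <- fit$null.deviance - fit$deviance
  df <- length(coef(fit)) - 1L
  structure(list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], z = co[, 3], p = co[, 4],
                              row.names = NULL),
    deviance = fit$deviance, null_deviance = fit$null.deviance,
    aic = fit$aic, mcfadden_r2 = 1 - ll / ll0,
    chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE),
    converged = fit$converged, separation = separation,
    fitted = fitted(fit), model = fit),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "logistic fit: deviance %.1f, AIC %.1f, McFadden R2 %.2f, X2(%d) = %.1f, p %s\n",
    x$deviance, x$aic, x$mcfadden_r2, x$df, x$chisq,
    format.pval(x$p, digits = 3)))
  print(x$coefficients, digits = 3)
  invisible(x)
}
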