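#' Covariate-adjusted multivariate comparison of sides
#'
#' Multivariate analysis of covariance of a set of kinematic dependent
#' variables on the measured side, with trial-level observations pooled
#' across participants (trials treated as observations, matching the
#' reported error degrees of freedom of the clinical analysis). The
#' multivariate test is Wilks' lambda with Rao's F approximation, computed
#' from a joint multivariate linear model with the covariates entered before
#' the side factor. Univariate ANCOVA F tests and eta-squared effect sizes
#' (effect SS / total SS) are returned per dependent variable.
#'
#' @param table data.frame with the dependent variables, the grouping factor
#'   and the covariates.
#' @param dvs character vector of dependent-variable column names.
#' @param factor name of the grouping column (two or more levels).
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return An object of class `manova_result`: `wilks_lambda`, `F`, `df1`,
#'   `df2`, `p`, and `univariate` (per-DV F, p, eta_squared).
#' @examples
#' d <- data.frame(y1 = rnorm(40), y2 = rnorm(40),
#'                 g = rep(c("a", "b"), 20))
#' manova_rm(d, dvs = c("y1", "y2"), factor = "g")
#' @export
manova_rm <- function(table, dvs, factor = "side", covariates = character()) {
  stopifnot(all(c(dvs, factor, covariates) %in% names(table)))
  table <- table[complete.cases(table[, c(dvs, factor, covariates)]), ]
  g <- as.factor(table[[factor]])
  if (nlevels(g) < 2 || any(tabulate(g) < 2))
    hr_stop("need at least two observations per group level",
            "headreach_invalid_argument")
  Y <- as.matrix(table[, dvs, drop = FALSE])
  n <- nrow(Y); p <- length(dvs)
  rhs <- c(covariates, factor)
  fml <- stats::reformulate(rhs, response = quote(Y))
  env <- list2env(c(list(Y = Y), as.list(table[, rhs, drop = FALSE])))
  environment(fml) <- env
  fit <- lm(fml)
  if (p >= fit$df.residual)
    hr_stop("more dependent variables than residual degrees of freedom",
            "headreach_invalid_argument")
  if (p == 1) {
    # one DV: Wilks reduces to SSE/(SSH+SSE) and Rao's F to the ANCOVA F
    a1 <- anova(fit)
    arow <- which(rownames(a1) == factor)
    ssh <- a1[arow, "Sum Sq"]; sse <- a1["Residuals", "Sum Sq"]
    mv <- data.frame(Wilks = sse / (ssh + sse),
                     `approx F` = a1[arow, "F value"],
                     `num Df` = a1[arow, "Df"],
                     `den Df` = a1["Residuals", "Df"],
                     `Pr(>F)` = a1[arow, "Pr(>F)"],
                     row.names = factor, check.names = FALSE)
  } else {
    mv <- tryCatch(anova(fit, test = "Wilks"),
                   error = function(e)
                     hr_stop(paste("rank-deficient multivariate model:",
                                   conditionMessage(e)),
                             "headreach_rank_deficiency"))
  }
  row <- which(rownames(mv) == factor)
  wilks <- mv[row, "Wilks"]
  if (length(wilks) != 1 || !is.finite(wilks))
    hr_stop("singular within-group covariance", "headreach_rank_deficiency")

  uni <- do.call(rbind, lapply(dvs, function(dv) {
    y <- table[[dv]]
    f1 <- stats::reformulate(rhs, response = quote(y))
    env1 <- list2env(c(list(y = y), as.list(table[, rhs, drop = FALSE])))
    environment(f1) <- env1
    a <- anova(lm(f1))
    arow <- which(rownames(a) == factor)
    data.frame(dv = dv, F = a[arow, "F value"], p = a[arow, "Pr(>F)"],
               eta_squared = a[arow, "Sum Sq"] / sum(a[, "Sum Sq"]))
  }))
  rownames(uni) <- NULL
  structure(list(wilks_lambda = wilks,
                 F = mv[row, "approx F"],
                 df1 = mv[row, "num Df"], df2 = mv[row, "den Df"],
                 p = mv[row, "Pr(>F)"],
                 univariate = uni, n = n, dvs = dvs, factor = factor,
                 covariates = covariates),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf(
    "Wilks' lambda = %.3f, F[%d, %d] = %.1f, p %s (n = %d)\n",
    x$wilks_lambda, x$df1, x$df2, x$F,
    format.pval(x$p, digits = 3), x$n))
  print(x$univariate, digits = 3)
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Shapiro-Wilk test, returning the
#' statistic and p-value used by the pipeline's normality gate (variables
#' with p < 0.05 are routed to the rank-based comparison).
#'
#' @param sample numeric vector (n >= 3, non-constant).
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(sample) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 3)
    hr_stop("Shapiro-Wilk needs at least 3 observations",
            "headreach_invalid_argument")
  if (length(unique(sample)) == 1)
    hr_stop("constant sample: statistic undefined",
            "headreach_undefined_statistic")
  if (length(sample) > 5000) sample <- sample[seq_len(5000)]
  ans <- shapiro.test(sample)
  list(W = unname(ans$statistic), p = ans$p.value)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis comparison used for dependent variables that
#' fail the normality gate.
#'
#' @param values numeric vector of observations.
#' @param groups grouping vector of the same length (>= 2 levels).
#' @return List with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    hr_stop("Kruskal-Wallis needs at least two groups",
            "headreach_invalid_argument")
  if (length(unique(values)) == 1)
    hr_stop("constant sample: statistic undefined",
            "headreach_undefined_statistic")
  ans <- kruskal.test(values, groups)
  list(H = unname(ans$statistic), df = unname(ans$parameter), p = ans$p.value)
}
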