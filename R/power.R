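#' Exact binomial sample-size search
#'
#' Minimum sample size for a one-sample exact binomial test of a constant
#' proportion `p0` against the alternative `p1 = p0 + g`: for each n in
#' ascending order, the smallest critical count c with exact one-sided size
#' at most `alpha` under `p0` is found, and the first n whose exact power
#' under `p1` reaches the target is returned. A two-sided variant splits
#' `alpha` equally between the tails.
#'
#' @param p0 constant proportion under the null.
#' @param g effect size; the alternative proportion is `p0 + g` (must stay
#'   within (0, 1]).
#' @param alpha significance level.
#' @param power target power.
#' @param sided `"one"` (default) or `"two"`.
#' @param n_max search cap.
#' @return List with `n`, `critical_value`, `achieved_power`, `size`.
#' @examples
#' binomial_min_n(p0 = 0.5, g = 0.4)  # n = 8 for the default design
#' @export
binomial_min_n <- function(p0 = 0.5, g = 0.4, alpha = 0.05, power = 0.8,
                           sided = c("one", "two"), n_max = 10000) {
  sided <- match.arg(sided)
  if (p0 <= 0 || p0 >= 1 || alpha <= 0 || alpha >= 1 ||
      power <= 0 || power >= 1)
    hr_stop("`p0`, `alpha`, `power` must lie in (0, 1)",
            "headreach_invalid_argument")
  p1 <- p0 + g
  if (g <= 0 || p1 > 1)
    hr_stop("effect size must be positive with p0 + g <= 1",
            "headreach_no_solution")
  a <- if (sided == "one") alpha else alpha / 2
  for (n in 1:n_max) {
    # smallest c with P(X >= c | p0) <= a
    sizes <- pbinom((0:n) - 1, n, p0, lower.tail = FALSE)
    ok <- which(sizes <= a)
    if (length(ok) == 0) next
    cc <- ok[1] - 1L                   # counts are 0-based
    pw <- pbinom(cc - 1, n, p1, lower.tail = FALSE)
    if (pw >= power)
      return(list(n = n, critical_value = cc, achieved_power = pw,
                  size = sizes[ok[1]]))
  }
  hr_stop("no sample size up to n_max reaches the target power",
          "headreach_no_solution")
}
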