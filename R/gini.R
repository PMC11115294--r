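#' Gini impurity
#'
#' `I = 1 - sum(p_c^2)` over the class proportions of a label multiset; the
#' impurity measure underlying the forest's split selection.
#'
#' @param labels non-empty vector of class labels.
#' @return Impurity in `[0, 1)`.
#' @examples
#' gini_impurity(c(1, 1, 1, 0))  # 0.375
#' @export
gini_impurity <- function(labels) {
  if (length(labels) == 0)
    hr_stop("`labels` must be non-empty", "headreach_invalid_argument")
  p <- tabulate(as.integer(factor(labels)))
  p <- p / sum(p)
  1 - sum(p^2)
}

#' Information gain of a binary split
#'
#' Impurity of the parent node minus the size-weighted impurities of the two
#' child nodes: `IG = I(Dp) - (Nl/Np) I(Dl) - (Nr/Np) I(Dr)`. The split with
#' the largest information gain among the candidate features is the one a
#' decision tree selects; for Gini impurity IG is always non-negative and is
#' zero exactly when both children have the parent's class proportions.
#'
#' @param parent_labels,left_labels,right_labels label vectors; the children
#'   must partition the parent (one child may be empty).
#' @return Information gain (>= 0 for Gini impurity).
#' @examples
#' information_gain(rep(0:1, each = 4), c(0, 0, 0, 1), c(1, 1, 1, 0))  # 0.125
#' @export
information_gain <- function(parent_labels, left_labels, right_labels) {
  np <- length(parent_labels)
  nl <- length(left_labels); nr <- length(right_labels)
  if (nl + nr != np)
    hr_stop("children must partition the parent node",
            "headreach_invalid_argument")
  both <- sort(as.character(c(left_labels, right_labels)))
  if (!identical(both, sort(as.character(parent_labels))))
    hr_stop("children must partition the parent node",
            "headreach_invalid_argument")
  ig <- gini_impurity(parent_labels)
  if (nl > 0) ig <- ig - nl / np * gini_impurity(left_labels)
  if (nr > 0) ig <- ig - nr / np * gini_impurity(right_labels)
  ig
}
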