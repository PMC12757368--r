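#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney U statistic via mid-ranks:
#' `AUC = U / (n_pos * n_neg)`, so tied scores count one half. Equivalent
#' to the probability that a random case scores above a random control.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Logical/character/factor labels; `TRUE` or `"case"` marks
#'   the positive class.
#' @return The AUC, a number in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "case"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value by enumeration when the combined sample size is at most 12
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param a,b Numeric vectors (the two groups).
#' @return A one-row tibble with `u_stat` (U of `a`), `p_value` and
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(a, b) {
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  tibble::tibble(u_stat = unname(ht$statistic), p_value = min(ht$p.value, 1),
                 method = if (exact) "exact" else "normal")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks; the two-sided p-value uses
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A one-row tibble with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input; Spearman correlation undefined.")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up procedure with monotonicity enforcement; the output is
#' in the input order and satisfies `q >= p` elementwise.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value sums hypergeometric probabilities of tables at
#' most as probable as the observed one.
#'
#' @param table A 2x2 matrix of non-negative counts.
#' @return The p-value (in (0, 1\]).
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  fisher.test(table, alternative = "two.sided")$p.value
}
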