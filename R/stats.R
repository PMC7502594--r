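#' Stomatal index
#'
#' Percentage of stomata among all epidermal cells:
#' `100 * stomata / (stomata + non_stomatal)`.
#'
#' @param stomata,non_stomatal Non-negative counts; total must be > 0.
#' @return Percentage in `[0, 100]`.
#' @export
stomatal_index <- function(stomata, non_stomatal) {
  if (any(c(stomata, non_stomatal) < 0)) stop("counts must be non-negative")
  total <- stomata + non_stomatal
  if (any(total <= 0)) stop("total cell count must be > 0")
  100 * stomata / total
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Test of independence between group and stoma/non-stoma status, without
#' continuity correction (df = 1). Used to compare stomatal index between
#' sector types.
#'
#' @param table 2x2 matrix of counts: rows are groups, columns are
#'   (stomata, non-stomatal cells).
#' @return List with `statistic` and `p.value`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("expected a 2x2 table")
  if (any(table < 0) || any(table != round(table))) stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("undefined test: a table margin is zero")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two density samples. The exact null
#' distribution is enumerated when the combined sample size is at most 20
#' (and no ties are present); otherwise the normal approximation with tie
#' correction is used, without continuity correction.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `U` (for the first sample) and `p.value`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  exact <- (length(a) + length(b)) <= 20 && !any(duplicated(c(a, b)))
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  list(U = unname(ht$statistic), p.value = ht$p.value)
}

#' Kruskal-Wallis rank test across groups
#'
#' Non-parametric one-way comparison of stomatal density across regions or
#' genotypes, with tie correction and the chi-squared approximation on
#' `k - 1` degrees of freedom. If all observations are identical the
#' statistic is 0 and p = 1.
#'
#' @param groups List of >= 2 non-empty numeric samples.
#' @return List with `H`, `df` and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) == 0)) stop("groups must be non-empty")
  x <- unlist(groups)
  if (length(unique(x)) == 1)
    return(list(H = 0, df = length(groups) - 1L, p.value = 1))
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  ht <- stats::kruskal.test(x, g)
  list(H = unname(ht$statistic), df = unname(ht$parameter), p.value = ht$p.value)
}
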