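# Rank-based two- and k-group comparisons with FDR control.
#
# These wrap the standard R tests; the value added is a uniform result
# record (statistic, raw p, group sizes) that the diversity, biochemistry
# and taxon screens all share, plus an explicit exactness rule for the
# rank-sum test.

test_result <- function(statistic, p_value, groups, n_per_group,
                        method, q_value = NA_real_) {
  assert_that(p_value >= 0 && p_value <= 1, "p-value outside [0, 1]")
  data.frame(method = method, statistic = statistic, p_value = p_value,
             q_value = q_value,
             groups = paste(groups, collapse = "|"),
             n = paste(n_per_group, collapse = "|"),
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided by default.  The exact null distribution is enumerated when the
#' pooled sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie correction is used (mid-ranks).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param groups optional labels for reporting.
#' @return one-row data.frame (statistic W, p_value, group sizes).
#' @export
wilcoxon_rank_sum <- function(x, y, groups = c("x", "y")) {
  assert_that(length(x) >= 2 && length(y) >= 2,
              "each group needs at least 2 observations")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  w <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact,
                                    alternative = "two.sided"))
  test_result(unname(w$statistic), w$p.value, groups,
              c(length(x), length(y)), "wilcoxon_rank_sum")
}

#' Kruskal-Wallis test
#'
#' H statistic with tie correction and a chi-square p-value on k - 1 degrees
#' of freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return one-row data.frame (statistic H, p_value, group sizes).
#' @export
kruskal_wallis <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2,
              "need at least 2 groups")
  assert_that(all(lengths(groups) >= 2),
              "every group needs at least 2 observations")
  labs <- names(groups) %||% paste0("g", seq_along(groups))
  k <- suppressWarnings(kruskal.test(groups))
  test_result(unname(k$statistic), k$p.value, labs, lengths(groups),
              "kruskal_wallis")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; the mapping back to input order is preserved and
#' q >= p always holds.
#'
#' @param pvals numeric vector of raw p-values in [0, 1] (NA allowed and
#'   propagated).
#' @return q-values in input order.
#' @export
benjamini_hochberg <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  assert_that(all(ok), "p-value outside [0, 1] at position ",
              which(!ok)[1L])
  p.adjust(pvals, method = "BH")
}

#' Feature-wise group screen with FDR control
#'
#' Applies the rank-sum (2 groups) or Kruskal-Wallis (>= 3 groups) test to
#' every row of a feature matrix and adjusts p-values across features.
#'
#' @param values features x samples numeric matrix.
#' @param group factor/character of group labels, one per sample.
#' @return data.frame with one row per feature: statistic, p_value, q_value.
#' @export
group_screen <- function(values, group) {
  assert_that(ncol(values) == length(group),
              "one group label per sample required")
  group <- as.factor(group)
  assert_that(nlevels(group) >= 2, "need at least 2 groups")
  res <- lapply(seq_len(nrow(values)), function(i) {
    sets <- split(values[i, ], group)
    if (nlevels(group) == 2)
      wilcoxon_rank_sum(sets[[1L]], sets[[2L]], groups = names(sets))
    else kruskal_wallis(sets)
  })
  out <- do.call(rbind, res)
  out <- cbind(feature = rownames(values) %||% seq_len(nrow(values)), out)
  out$q_value <- benjamini_hochberg(out$p_value)
  rownames(out) <- NULL
  out
}
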