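# Exact binomial over-representation test for a ZFP group among a tissue's
# enriched genes.

#' Exact binomial group-enrichment test
#'
#' One-sided upper-tail exact binomial test of whether a group is
#' over-represented: `p = P(X >= k)` for `X ~ Binomial(n, p0)`, with `k` the
#' observed number of group members among `n` tissue-enriched genes and `p0`
#' the group's background share of the full catalogue.
#'
#' @param k observed group members among the enriched genes (0 <= k <= n).
#' @param n number of enriched genes.
#' @param p0 background proportion of the group, in (0, 1).
#' @return list of class `zfp_enrichment` with `k`, `n`, `p0`, `expected`
#'   (`n * p0`) and `p_value`.
#' @export
binomial_enrichment <- function(k, n, p0) {
  if (length(k) != 1 || length(n) != 1 || length(p0) != 1 ||
      is.na(k) || is.na(n) || is.na(p0)) {
    stop_arg("k, n and p0 must be scalar and non-missing")
  }
  if (k < 0 || n < 0 || k > n || k != round(k) || n != round(n)) {
    stop_arg("need integer 0 <= k <= n")
  }
  if (p0 <= 0 || p0 >= 1) stop_arg("p0 must lie strictly between 0 and 1")
  p <- if (k == 0) 1 else stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  structure(list(k = as.integer(k), n = as.integer(n), p0 = p0,
                 expected = n * p0, p_value = p),
            class = "zfp_enrichment")
}

#' @export
print.zfp_enrichment <- function(x, ...) {
  cat(sprintf(
    "binomial enrichment: k = %d of n = %d (expected %.1f at p0 = %.3f), P(X >= k) = %.3g\n",
    x$k, x$n, x$expected, x$p0, x$p_value))
  invisible(x)
}

#' Group enrichment among a tissue's enriched genes
#'
#' Convenience wrapper assembling `k`, `n` and `p0` from tissue-specificity
#' calls and the annotated catalogue, then running [binomial_enrichment()].
#' `p0` is the group's share of the *full* catalogue, not of the tested
#' subset.
#'
#' @param calls data.frame from [tissue_specific()].
#' @param catalogue catalogue data.frame with `gene_id` and `group`.
#' @param tissue focal tissue label.
#' @param group focal ZFP group label.
#' @return a `zfp_enrichment` object with `tissue` and `group` fields added.
#' @export
group_enrichment <- function(calls, catalogue, tissue, group) {
  assert_df_cols(catalogue, c("gene_id", "group"), "catalogue")
  if (!tissue %in% calls$tissue) {
    stop_arg("tissue '", tissue, "' not present in the calls")
  }
  enr <- unique(calls$gene_id[calls$enriched & calls$tissue == tissue])
  enr <- enr[enr %in% catalogue$gene_id]
  n <- length(enr)
  if (n == 0) stop_arg("no catalogue genes enriched in tissue '", tissue, "'")
  k <- sum(catalogue$group[match(enr, catalogue$gene_id)] == group)
  p0 <- mean(catalogue$group == group)
  res <- binomial_enrichment(k, n, p0)
  res$tissue <- tissue
  res$group <- group
  res
}
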