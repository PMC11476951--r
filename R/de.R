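# One-vs-rest tissue-specificity calling with a negative-binomial Wald test.
#
# Counts are put on a common scale with TMM-adjusted effective library
# sizes; a per-gene dispersion is estimated by the method of moments from
# within-tissue replicate variability and shrunk toward a mean-dispersion
# trend; each tissue is then contrasted against all remaining samples.

# effective size factors: library size times TMM factor, geometric mean 1
effective_size_factors <- function(cm, low = 1, high = 10000) {
  x <- suppressMessages(filter_matrix(tpm(cm), low = low, high = high))
  f <- tmm_factors(x)
  s <- colSums(cm$counts) * f[colnames(cm$counts)]
  list(sf = s / geomean(s), keep = rownames(x$values))
}

# method-of-moments dispersion per gene, shrunk toward a trend on the mean.
# y: normalized count matrix; tissue: factor of tissue labels per column.
estimate_dispersion <- function(y, tissue, prior_df = 20) {
  tis <- split(seq_len(ncol(y)), tissue)
  tis <- tis[lengths(tis) >= 2]
  mu <- rowMeans(y)
  if (!length(tis)) {
    warning("no tissue has replicates; using a common dispersion of 0.1")
    return(rep(0.1, nrow(y)))
  }
  ss <- 0; df <- 0
  for (idx in tis) {
    sub <- y[, idx, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + (length(idx) - 1)
  }
  v <- ss / df
  phi_raw <- pmax((v - mu) / mu^2, 1e-6)
  # trend: lowess of log dispersion on log mean, evaluated per gene
  ok <- mu > 0
  lo <- stats::lowess(log(mu[ok]), log(phi_raw[ok]), f = 0.5)
  trend <- exp(stats::approx(lo$x, lo$y, xout = log(pmax(mu, min(mu[ok]))),
                             rule = 2)$y)
  phi <- exp((df * log(phi_raw) + prior_df * log(trend)) / (df + prior_df))
  pmax(phi, 1e-6)
}

nb_wald_two_group <- function(y, in_group, phi, pseudo = 0.5) {
  nA <- sum(in_group); nB <- sum(!in_group)
  mA <- rowMeans(y[, in_group, drop = FALSE])
  mB <- rowMeans(y[, !in_group, drop = FALSE])
  lfc <- log2((mA + pseudo) / (mB + pseudo))
  # delta method on the log of the group means; NB variance mu + phi mu^2
  varA <- (mA + phi * mA^2) / nA
  varB <- (mB + phi * mB^2) / nB
  se2 <- varA / (mA + pseudo)^2 + varB / (mB + pseudo)^2
  z <- (log(2) * lfc) / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(log2fc = lfc, p = p)
}

#' One-vs-rest tissue-specific expression calls
#'
#' For each tissue, every gene is tested for differential expression between
#' that tissue's samples and all remaining samples using a negative-binomial
#' Wald test on TMM-scaled counts, with Benjamini-Hochberg FDR control
#' across genes within each one-vs-rest comparison.  A gene is called
#' *enriched* in the tissue when `fdr < fdr_max` and `log2fc > lfc_min`
#' (up-regulated in the focal tissue).
#'
#' Genes failing the abundance filter (TPM below `low` everywhere or above
#' `high` anywhere) are excluded before testing.
#'
#' @param cm a [zfp_counts()] object with at least 2 tissues.
#' @param fdr_max FDR threshold (default 0.05).
#' @param lfc_min log2 fold-change threshold (default 1).
#' @param low,high TPM filter thresholds passed to [filter_matrix()].
#' @return data.frame with one row per gene x tissue: `gene_id`, `tissue`,
#'   `log2fc`, `p`, `fdr`, `enriched`.
#' @export
tissue_specific <- function(cm, fdr_max = 0.05, lfc_min = 1,
                            low = 1, high = 10000) {
  if (!inherits(cm, "zfp_counts")) stop_arg("cm must be a zfp_counts object")
  tissues <- unique(cm$tissue_of)
  if (length(tissues) < 2) stop_arg("need at least 2 tissues")
  if (any(table(cm$tissue_of) < 1)) stop_arg("every tissue needs >= 1 sample")
  es <- effective_size_factors(cm, low = low, high = high)
  y <- sweep(cm$counts[es$keep, , drop = FALSE], 2, es$sf, "/")
  phi <- estimate_dispersion(y, factor(cm$tissue_of))
  out <- lapply(tissues, function(t) {
    res <- nb_wald_two_group(y, cm$tissue_of == t, phi)
    fdr <- stats::p.adjust(res$p, method = "BH")
    data.frame(gene_id = rownames(y), tissue = t, log2fc = res$log2fc,
               p = res$p, fdr = fdr,
               enriched = fdr < fdr_max & res$log2fc > lfc_min,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize tissue-specificity calls
#'
#' @param calls data.frame from [tissue_specific()].
#' @param n_genes catalogue size used as the denominator of the
#'   tissue-specific percentage; defaults to the number of tested genes.
#' @return list with `per_tissue` (tissue, n_enriched, sorted decreasing),
#'   `n_specific` (genes enriched in >= 1 tissue) and `percent_specific`
#'   (half-up, one decimal).
#' @export
summarize_tissue_specificity <- function(calls, n_genes = NULL) {
  enr <- calls[calls$enriched, , drop = FALSE]
  per_tissue <- as.data.frame(table(tissue = factor(enr$tissue,
                                                    levels = unique(calls$tissue))),
                              stringsAsFactors = FALSE)
  names(per_tissue)[2] <- "n_enriched"
  per_tissue <- per_tissue[order(-per_tissue$n_enriched, per_tissue$tissue), ]
  rownames(per_tissue) <- NULL
  n_specific <- length(unique(enr$gene_id))
  n_genes <- n_genes %||% length(unique(calls$gene_id))
  list(per_tissue = per_tissue, n_specific = n_specific,
       percent_specific = round_half_up(100 * n_specific / n_genes, 1))
}

#' Expression summaries by ZFP group and by tissue
#'
#' Produces the tables behind the standard family-level views: per-gene mean
#' expression with group labels (group-level ranking), per-gene per-tissue
#' means (tissue-level distributions), and a row-z-scored gene x tissue
#' matrix for heat-mapping.  Rows with zero variance get z-scores of 0.
#'
#' @param x `zfp_expr` in state `"tmm_normalized"`.
#' @param catalogue catalogue data.frame with `gene_id` and `group`;
#'   catalogue genes absent from the matrix are excluded with a message.
#' @return list with `by_group` (gene_id, group, mean_expr), `group_stats`
#'   (group, n, mean, median — sorted by mean), `by_tissue` (gene_id,
#'   tissue, expr), and `heatmap` (z-scored matrix, genes x tissues).
#' @export
group_tissue_summary <- function(x, catalogue) {
  if (!inherits(x, "zfp_expr") || x$state != "tmm_normalized") {
    stop_arg("group_tissue_summary expects a zfp_expr in state 'tmm_normalized'")
  }
  assert_df_cols(catalogue, c("gene_id", "group"), "catalogue")
  present <- catalogue$gene_id %in% rownames(x$values)
  if (any(!present)) {
    message(sum(!present), " catalogue gene(s) absent from the expression matrix; excluded")
  }
  cat_df <- catalogue[present, , drop = FALSE]
  v <- x$values[cat_df$gene_id, , drop = FALSE]
  by_group <- data.frame(gene_id = cat_df$gene_id, group = cat_df$group,
                         mean_expr = rowMeans(v), row.names = NULL,
                         stringsAsFactors = FALSE)
  gs <- stats::aggregate(mean_expr ~ group, by_group,
                         function(z) c(n = length(z), mean = mean(z),
                                       median = stats::median(z)))
  group_stats <- data.frame(group = gs$group, n = as.integer(gs$mean_expr[, "n"]),
                            mean = gs$mean_expr[, "mean"],
                            median = gs$mean_expr[, "median"],
                            stringsAsFactors = FALSE)
  group_stats <- group_stats[order(group_stats$mean), ]
  rownames(group_stats) <- NULL
  tissues <- unique(x$tissue_of)
  tmat <- vapply(tissues, function(t) {
    rowMeans(v[, x$tissue_of == t, drop = FALSE])
  }, numeric(nrow(v)))
  if (is.null(dim(tmat))) tmat <- matrix(tmat, nrow = nrow(v),
                                         dimnames = list(rownames(v), tissues))
  by_tissue <- data.frame(
    gene_id = rep(rownames(tmat), times = ncol(tmat)),
    tissue = rep(colnames(tmat), each = nrow(tmat)),
    expr = as.vector(tmat), stringsAsFactors = FALSE
  )
  mu <- rowMeans(tmat)
  sdv <- apply(tmat, 1, stats::sd)
  z <- (tmat - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  list(by_group = by_group, group_stats = group_stats,
       by_tissue = by_tissue, heatmap = z)
}
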