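# Cross-tissue expression pipeline: count container, TPM, abundance
# filtering, TMM between-sample normalization, hierarchical sample
# clustering.

#' Count matrix container
#'
#' Bundles a gene-by-sample integer count matrix with the per-sample tissue
#' labels and per-gene effective lengths needed downstream.
#'
#' @param counts non-negative numeric matrix, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample ids).
#' @param tissues named character vector mapping every sample id to a tissue
#'   label, or an unnamed vector in column order.
#' @param lengths named numeric vector of effective gene lengths in bp
#'   (> 0), or an unnamed vector in row order.
#' @return object of class `zfp_counts`.
#' @export
zfp_counts <- function(counts, tissues, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_arg("counts must have gene rownames and sample colnames")
  }
  if (any(counts < 0)) stop_arg("counts must be non-negative")
  if (is.null(names(tissues))) {
    if (length(tissues) != ncol(counts)) stop_arg("one tissue label per sample required")
    names(tissues) <- colnames(counts)
  }
  miss <- setdiff(colnames(counts), names(tissues))
  if (length(miss)) stop_arg("samples without tissue label: ", paste(miss, collapse = ", "))
  tissues <- tissues[colnames(counts)]
  if (is.null(names(lengths))) {
    if (length(lengths) != nrow(counts)) stop_arg("one length per gene required")
    names(lengths) <- rownames(counts)
  }
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss)) stop_arg("genes without length: ", paste(miss, collapse = ", "))
  lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0)) stop_arg("gene lengths must be positive")
  structure(list(counts = counts, tissue_of = tissues, lengths = lengths),
            class = "zfp_counts")
}

#' @export
print.zfp_counts <- function(x, ...) {
  cat("zfp_counts:", nrow(x$counts), "genes x", ncol(x$counts), "samples,",
      length(unique(x$tissue_of)), "tissues\n")
  invisible(x)
}

new_expr <- function(values, tissue_of, lengths, state) {
  structure(list(values = values, tissue_of = tissue_of, lengths = lengths,
                 state = state), class = "zfp_expr")
}

#' @export
print.zfp_expr <- function(x, ...) {
  cat("zfp_expr [", x$state, "]: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Transcripts-per-million normalization
#'
#' Per sample: `rate_g = count_g / length_g`, `TPM_g = 1e6 * rate_g /
#' sum(rate)`; every column therefore sums to one million.
#'
#' @param cm a [zfp_counts()] object.
#' @return a `zfp_expr` object in state `"raw_tpm"`.
#' @export
tpm <- function(cm) {
  if (!inherits(cm, "zfp_counts")) stop_arg("cm must be a zfp_counts object")
  rate <- cm$counts / cm$lengths
  tot <- colSums(rate)
  if (any(tot <= 0)) {
    stop_arg("zero total read rate in sample(s): ",
             paste(colnames(cm$counts)[tot <= 0], collapse = ", "))
  }
  vals <- sweep(rate, 2, tot, "/") * 1e6
  new_expr(vals, cm$tissue_of, cm$lengths, "raw_tpm")
}

#' Abundance filtering of a TPM matrix
#'
#' Discards genes whose TPM is below `low` in *all* samples (never
#' expressed) or above `high` in *any* sample (implausibly abundant /
#' quantification artefacts).
#'
#' @param x `zfp_expr` in state `"raw_tpm"`.
#' @param low,high thresholds (defaults 1 and 10000).
#' @return `zfp_expr` in state `"filtered"`.
#' @export
filter_matrix <- function(x, low = 1, high = 10000) {
  if (!inherits(x, "zfp_expr") || x$state != "raw_tpm") {
    stop_arg("filter_matrix expects a zfp_expr in state 'raw_tpm'")
  }
  low_fail <- apply(x$values, 1, function(v) all(v < low))
  high_fail <- apply(x$values, 1, function(v) any(v > high))
  message("filter_matrix: dropped ", sum(low_fail), " gene(s) with TPM < ",
          low, " everywhere and ", sum(high_fail), " gene(s) with TPM > ",
          high, " somewhere")
  keep <- !(low_fail | high_fail)
  new_expr(x$values[keep, , drop = FALSE], x$tissue_of,
           x$lengths[keep], "filtered")
}

#' Trimmed-mean-of-M-values scale factors
#'
#' Standard TMM on an abundance matrix: against a reference column, per-gene
#' log2 ratios M and mean log2 abundances A are computed over genes positive
#' in both columns, the most extreme `trim_m` fraction of M and `trim_a`
#' fraction of A are discarded (split evenly over both tails), and the
#' sample's factor is `2^` the precision-weighted mean of the retained M
#' (weights `1 / (1/x_s + 1/x_r)`).  Factors are rescaled so their geometric
#' mean is 1.  M is taken on the matrix values directly, so rescaling one
#' column by `c` multiplies its factor by `c`.
#'
#' @param x `zfp_expr` in state `"filtered"`.
#' @param ref reference sample id; default: the sample whose 75th percentile
#'   of positive values is closest to the mean such percentile.
#' @param trim_m total fraction of M values trimmed (default 0.30).
#' @param trim_a total fraction of A values trimmed (default 0.05).
#' @return named vector of per-sample factors with geometric mean 1.
#' @export
tmm_factors <- function(x, ref = NULL, trim_m = 0.30, trim_a = 0.05) {
  if (!inherits(x, "zfp_expr") || x$state != "filtered") {
    stop_arg("tmm_factors expects a zfp_expr in state 'filtered'")
  }
  v <- x$values
  if (is.null(ref)) {
    q75 <- apply(v, 2, function(col) {
      pos <- col[col > 0]
      if (!length(pos)) 0 else stats::quantile(pos, 0.75, names = FALSE)
    })
    ref <- colnames(v)[which.min(abs(q75 - mean(q75)))]
  }
  if (!ref %in% colnames(v)) stop_arg("reference sample '", ref, "' not found")
  r <- v[, ref]
  f <- vapply(colnames(v), function(s) {
    if (s == ref) return(1)
    xs <- v[, s]
    ok <- xs > 0 & r > 0
    if (sum(ok) < 10) {
      warning("tmm_factors: fewer than 10 usable genes for sample ", s,
              "; factor set to 1")
      return(1)
    }
    M <- log2(xs[ok] / r[ok])
    A <- 0.5 * log2(xs[ok] * r[ok])
    w <- 1 / (1 / xs[ok] + 1 / r[ok])
    n <- length(M)
    loM <- floor(n * trim_m / 2) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a / 2) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (sum(keep) < 10) {
      warning("tmm_factors: fewer than 10 genes retained after trimming for sample ",
              s, "; factor set to 1")
      return(1)
    }
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, numeric(1))
  f / geomean(f)
}

#' Apply TMM factors to an expression matrix
#'
#' Divides each sample column by its factor, yielding the normalized matrix
#' used for all cross-tissue comparisons.
#'
#' @param x `zfp_expr` in state `"filtered"`.
#' @param factors named factor vector from [tmm_factors()]; computed when
#'   omitted.
#' @param ... passed on to [tmm_factors()].
#' @return `zfp_expr` in state `"tmm_normalized"` with the factors attached
#'   as attribute `"tmm_factors"`.
#' @export
tmm_normalize <- function(x, factors = NULL, ...) {
  if (is.null(factors)) factors <- tmm_factors(x, ...)
  vals <- sweep(x$values, 2, factors[colnames(x$values)], "/")
  out <- new_expr(vals, x$tissue_of, x$lengths, "tmm_normalized")
  attr(out, "tmm_factors") <- factors
  out
}

#' Hierarchical clustering of samples
#'
#' Distance is `1 - Pearson correlation` between samples on `log2(x + 1)`
#' of the normalized matrix; linkage is average (UPGMA).
#'
#' @param x `zfp_expr` in state `"tmm_normalized"` with at least 2 samples.
#' @return an [stats::hclust] tree with samples as leaves.
#' @export
cluster_samples <- function(x) {
  if (!inherits(x, "zfp_expr") || x$state != "tmm_normalized") {
    stop_arg("cluster_samples expects a zfp_expr in state 'tmm_normalized'")
  }
  if (ncol(x$values) < 2) stop_arg("need at least 2 samples to cluster")
  lv <- log2(x$values + 1)
  sds <- apply(lv, 2, stats::sd)
  if (any(sds == 0)) {
    stop_arg("constant sample column(s) ",
             paste(colnames(lv)[sds == 0], collapse = ", "),
             ": correlation distance undefined")
  }
  d <- stats::as.dist(1 - stats::cor(lv))
  stats::hclust(d, method = "average")
}

#' Export a sample tree in Newick format
#' @param hc an [stats::hclust] object from [cluster_samples()].
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
sample_tree_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Write an expression matrix as TSV
#' @param x `zfp_expr` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expr <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
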