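# Small in-code fixture builders shared across test files.

make_iso <- function(id, zf, len, eff = "", gene = "g1") {
  data.frame(isoform_id = id, gene_id = gene, length = len,
             zf_count = zf, effectors = eff, stringsAsFactors = FALSE)
}

# random single-gene isoform set with at least one ZF-bearing isoform
random_iso_set <- function(n = NULL) {
  n <- n %||% sample(1:6, 1)
  effs <- vapply(seq_len(n), function(i) {
    pick <- zfpkit:::GROUP_PRIORITY[runif(6) < 0.25]
    paste(pick, collapse = ",")
  }, character(1))
  iso <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_iso(sprintf("iso%02d", i), zf = sample(0:8, 1),
             len = sample(200:600, 1), eff = effs[i])
  }))
  if (!any(iso$zf_count >= 1)) iso$zf_count[sample(n, 1)] <- sample(1:8, 1)
  iso
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal catalogue data.frame from parallel vectors
make_catalogue <- function(gene_id, group, chrom = "1",
                           start = seq_along(gene_id) * 1e6,
                           end = start + 1e4) {
  data.frame(gene_id = gene_id, group = group, chrom = chrom,
             start = start, end = end, stringsAsFactors = FALSE)
}

# catalogue with n genes of which k are in `group`, rest ZF_ONLY
count_catalogue <- function(n, k, group = "KRAB") {
  make_catalogue(sprintf("g%03d", seq_len(n)),
                 c(rep(group, k), rep("ZF_ONLY", n - k)))
}

# orthologue table marking the first n_matched catalogue genes as matched
make_orth <- function(catalogue, species, n_matched) {
  data.frame(
    gene_id = catalogue$gene_id,
    target_species = species,
    orthologue_id = c(sprintf("ORTH%03d", seq_len(n_matched)),
                      rep("", nrow(catalogue) - n_matched)),
    stringsAsFactors = FALSE
  )
}

# random gene catalogue for cluster-oracle comparisons
random_catalogue <- function(n_genes, n_chroms = 3) {
  chrom <- sample(as.character(seq_len(n_chroms)), n_genes, replace = TRUE)
  start <- round(runif(n_genes, 0, 3e6))
  make_catalogue(sprintf("g%03d", seq_len(n_genes)),
                 sample(c("KRAB", "ZF_ONLY"), n_genes, replace = TRUE),
                 chrom = chrom, start = start,
                 end = start + round(runif(n_genes, 5e3, 3e4)))
}

# small count container: baseline vector, tissue design, optional planted
# effects as a gene x tissue log2 fold-change matrix
make_counts <- function(baseline, tissues, reps, lfc = NULL, dispersion = 0.1,
                        lengths = NULL, seed = 42) {
  set.seed(seed)
  G <- length(baseline)
  gene_ids <- names(baseline) %||% sprintf("g%04d", seq_len(G))
  names(baseline) <- gene_ids
  samples <- unlist(lapply(tissues, function(t) sprintf("%s_r%d", t, seq_len(reps))))
  tissue_of <- setNames(rep(tissues, each = reps), samples)
  mu <- outer(baseline, rep(1, length(samples)))
  colnames(mu) <- samples
  if (!is.null(lfc)) {
    for (t in colnames(lfc)) {
      sel <- tissue_of[samples] == t
      mu[, sel] <- mu[, sel] * 2^lfc[, t]
    }
  }
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
                   G, length(samples), dimnames = list(gene_ids, samples))
  lengths <- lengths %||% setNames(rep(1000, G), gene_ids)
  zfp_counts(counts, tissue_of, lengths)
}
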