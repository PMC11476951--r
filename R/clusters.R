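# Genomic ZFP gene clusters: transitive distance-based interval merging.

#' Detect genomic ZFP gene clusters
#'
#' Per chromosome (or scaffold), genes are merged transitively whenever the
#' boundary-to-boundary gap between a gene and the growing block is strictly
#' below `max_gap`; blocks with at least `min_genes` members are reported.
#' Strand is ignored.  Blocks are named `C<chrom>C<ordinal>` with ordinals
#' assigned left to right (a leading `"chr"` prefix is stripped from the
#' chromosome name).
#'
#' @param catalogue catalogue data.frame (see [build_catalogue()]) with
#'   `gene_id`, `group`, `chrom`, `start`, `end`.
#' @param max_gap maximum inter-gene gap in bp (default 250000); merging uses
#'   strict `< max_gap`.
#' @param min_genes minimum block size to report (default 3).
#' @return data.frame with one row per block: `cluster_id`, `chrom`, `start`,
#'   `end` (0-based half-open span), `n_total`, and list-columns `members`
#'   (gene ids sorted by start) and `member_groups`.
#' @export
detect_clusters <- function(catalogue, max_gap = 250000, min_genes = 3) {
  assert_df_cols(catalogue, c("gene_id", "chrom", "start", "end"), "catalogue")
  bad <- is.na(catalogue$chrom) | is.na(catalogue$start) | is.na(catalogue$end)
  if (any(bad)) {
    warning(sum(bad), " gene(s) without genomic coordinates excluded from clustering")
    catalogue <- catalogue[!bad, , drop = FALSE]
  }
  grp_col <- if ("group" %in% names(catalogue)) catalogue$group else
    rep(NA_character_, nrow(catalogue))
  out <- list()
  for (chr in unique(catalogue$chrom)) {
    g <- catalogue[catalogue$chrom == chr, , drop = FALSE]
    gg <- grp_col[catalogue$chrom == chr]
    o <- order(g$start, g$end, g$gene_id)
    g <- g[o, , drop = FALSE]; gg <- gg[o]
    # transitive merge on sorted intervals: gap to the running block end
    block <- integer(nrow(g))
    b <- 1L
    block[1] <- b
    run_end <- g$end[1]
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] - run_end < max_gap) {
        block[i] <- b
      } else {
        b <- b + 1L
        block[i] <- b
      }
      run_end <- max(run_end, g$end[i])
    }
    for (bi in unique(block)) {
      sel <- block == bi
      if (sum(sel) < min_genes) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = min(g$start[sel]), end = max(g$end[sel]),
        n_total = sum(sel), stringsAsFactors = FALSE,
        members = I(list(g$gene_id[sel])), member_groups = I(list(gg[sel]))
      )
    }
  }
  if (!length(out)) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_total = integer(),
                      members = I(list()), member_groups = I(list()),
                      stringsAsFactors = FALSE))
  }
  blocks <- do.call(rbind, out)
  blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
  ordinal <- stats::ave(seq_len(nrow(blocks)), blocks$chrom, FUN = seq_along)
  blocks <- data.frame(
    cluster_id = sprintf("C%sC%d", sub("^chr", "", blocks$chrom), ordinal),
    blocks, stringsAsFactors = FALSE
  )
  rownames(blocks) <- NULL
  blocks
}

#' Composition of detected clusters
#'
#' @param blocks data.frame from [detect_clusters()].
#' @return list with `per_block` (one row per block: `cluster_id`, `chrom`,
#'   `n_total`, one `n_<GROUP>` column per effector group) and `summary`
#'   (`n_blocks`, `n_genes`, `n_krab`).
#' @export
cluster_composition <- function(blocks) {
  if (!nrow(blocks)) {
    per_block <- data.frame(cluster_id = character(), chrom = character(),
                            n_total = integer(), stringsAsFactors = FALSE)
    return(list(per_block = per_block,
                summary = list(n_blocks = 0L, n_genes = 0L, n_krab = 0L)))
  }
  counts <- t(vapply(blocks$member_groups, function(gr) {
    table(factor(gr, levels = ZFP_GROUPS))
  }, integer(length(ZFP_GROUPS))))
  colnames(counts) <- paste0("n_", ZFP_GROUPS)
  per_block <- cbind(
    blocks[, c("cluster_id", "chrom", "n_total"), drop = FALSE],
    as.data.frame(counts)
  )
  rownames(per_block) <- NULL
  list(
    per_block = per_block,
    summary = list(
      n_blocks = nrow(blocks),
      n_genes = sum(blocks$n_total),
      n_krab = sum(per_block$n_KRAB)
    )
  )
}

#' Export cluster blocks as BED
#'
#' Standard 6-column BED (0-based half-open): chrom, start, end, name
#' (cluster id), score (member count), strand (`.`).
#'
#' @param blocks data.frame from [detect_clusters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
clusters_to_bed <- function(blocks, path) {
  bed <- data.frame(blocks$chrom, format(blocks$start, scientific = FALSE, trim = TRUE),
                    format(blocks$end, scientific = FALSE, trim = TRUE),
                    blocks$cluster_id, blocks$n_total, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
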