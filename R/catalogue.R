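# Building the annotated ZFP catalogue: per-isoform domain summaries,
# canonical-isoform selection, effector-group classification.

# priority used to collapse a multi-effector canonical isoform to one group
GROUP_PRIORITY <- c("KRAB", "SCAN", "BTB", "SET", "HOMEO", "PHD")
ZFP_GROUPS <- c(GROUP_PRIORITY, "ZF_ONLY")

#' Read an isoform coordinate table
#'
#' Expects a tab-separated file with header columns `gene_id`, `isoform_id`,
#' `chrom`, `start`, `end`, `strand`, `length` (protein length in residues).
#' Genomic `start`/`end` are interpreted as 1-based inclusive (the common
#' BioMart export convention) and normalized internally to 0-based half-open.
#'
#' @param path path to the TSV file.
#' @return data.frame with 0-based half-open `start`/`end`.
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop_arg("coordinate file not found: ", path)
  co <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_df_cols(co, c("gene_id", "isoform_id", "chrom", "start", "end",
                       "strand", "length"), "coordinate table")
  co$start <- as.numeric(co$start) - 1   # to 0-based half-open
  co$end <- as.numeric(co$end)
  co$chrom <- as.character(co$chrom)
  co
}

#' Summarize domain hits per isoform
#'
#' Collapses per-domain rows into one row per isoform: the number of C2H2
#' zinc-finger hits and the set of effector domains present.
#'
#' @param hits data.frame from [parse_domtblout()] (already E-value filtered).
#' @param coords data.frame from [read_coords()]; supplies `gene_id` and
#'   protein `length` per isoform.
#' @return data.frame with columns `isoform_id`, `gene_id`, `length`,
#'   `zf_count` and `effectors` (comma-separated, priority order; `""` when
#'   none).  Isoforms present in `coords` but absent from `hits` get
#'   `zf_count = 0`.
#' @export
annotate_isoforms <- function(hits, coords) {
  assert_df_cols(coords, c("gene_id", "isoform_id", "length"), "coords")
  iso <- unique(coords[, c("isoform_id", "gene_id", "length")])
  zf <- table(factor(hits$isoform_id[hits$profile == "ZF_C2H2"],
                     levels = iso$isoform_id))
  iso$zf_count <- as.integer(zf[iso$isoform_id])
  eff_hits <- hits[hits$profile %in% ZFP_EFFECTORS, , drop = FALSE]
  effs <- split(eff_hits$profile, eff_hits$isoform_id)
  iso$effectors <- vapply(iso$isoform_id, function(id) {
    e <- unique(effs[[id]])
    if (is.null(e)) "" else paste(GROUP_PRIORITY[GROUP_PRIORITY %in% e],
                                  collapse = ",")
  }, character(1))
  unknown <- setdiff(unique(hits$isoform_id), iso$isoform_id)
  if (length(unknown)) {
    message(length(unknown),
            " isoform(s) in the domain table have no coordinate entry and were dropped")
  }
  rownames(iso) <- NULL
  iso
}

has_effector <- function(iso) nzchar(iso$effectors)

#' Select the canonical isoform of a gene
#'
#' Applies, in order: (1) if an effector domain is present on some but not
#' all isoforms, restrict to the effector-bearing isoforms; (2) keep the
#' isoform(s) with the largest zinc-finger count; (3) on ties, keep the
#' longest; (4) remaining ties resolve to the lexicographically smallest
#' `isoform_id` so the choice is deterministic and order-independent.
#'
#' @param isoforms data.frame as produced by [annotate_isoforms()], all rows
#'   sharing one `gene_id`; at least one row must have `zf_count >= 1`.
#' @return the selected single-row data.frame.
#' @export
select_canonical <- function(isoforms) {
  if (!nrow(isoforms)) stop_arg("select_canonical: empty isoform list")
  if (!any(isoforms$zf_count >= 1)) {
    stop_arg("select_canonical: no isoform has a C2H2 zinc-finger hit")
  }
  cand <- isoforms
  eff <- has_effector(cand)
  if (any(eff) && !all(eff)) cand <- cand[eff, , drop = FALSE]
  cand <- cand[cand$zf_count == max(cand$zf_count), , drop = FALSE]
  cand <- cand[cand$length == max(cand$length), , drop = FALSE]
  cand[order(cand$isoform_id)[1], , drop = FALSE]
}

#' Classify one gene from its isoform annotations
#'
#' Returns `NULL` when no isoform carries a zinc-finger hit (the gene is not
#' a C2H2-ZFP).  Otherwise the canonical isoform is chosen with
#' [select_canonical()] and a single group label is assigned from its
#' effector set using the priority KRAB > SCAN > BTB > SET > HOMEO > PHD;
#' genes without any effector are labelled `ZF_ONLY`.  The full effector set
#' is retained in the `effectors` column for audit.
#'
#' @param isoforms data.frame of one gene's isoform annotations.
#' @return one-row data.frame (`gene_id`, `group`, `zf_count`, `effectors`,
#'   `canonical_isoform`, `length`) or `NULL`.
#' @export
classify_gene <- function(isoforms) {
  if (!nrow(isoforms)) stop_arg("classify_gene: empty isoform list")
  if (length(unique(isoforms$gene_id)) != 1L) {
    stop_arg("classify_gene: isoforms belong to more than one gene")
  }
  if (!any(isoforms$zf_count >= 1)) return(NULL)
  can <- select_canonical(isoforms)
  eff <- strsplit(can$effectors, ",", fixed = TRUE)[[1]]
  grp <- GROUP_PRIORITY[GROUP_PRIORITY %in% eff][1]
  if (is.na(grp)) grp <- "ZF_ONLY"
  data.frame(
    gene_id = can$gene_id, group = grp, zf_count = can$zf_count,
    effectors = can$effectors, canonical_isoform = can$isoform_id,
    length = can$length, stringsAsFactors = FALSE
  )
}

#' Build the annotated ZFP catalogue
#'
#' End-to-end annotation: per-isoform domain summaries, per-gene canonical
#' selection and group classification, and attachment of the canonical
#' isoform's genomic interval (0-based half-open).
#'
#' @param hits data.frame from [parse_domtblout()].
#' @param coords data.frame from [read_coords()].
#' @return catalogue data.frame, one row per C2H2-ZFP gene, with columns
#'   `gene_id`, `group`, `zf_count`, `effectors`, `canonical_isoform`,
#'   `chrom`, `start`, `end`, `strand`.
#' @export
build_catalogue <- function(hits, coords) {
  iso <- annotate_isoforms(hits, coords)
  per_gene <- split(iso, iso$gene_id)
  rows <- lapply(per_gene, classify_gene)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(gene_id = character(), group = character(),
                      zf_count = integer(), effectors = character(),
                      canonical_isoform = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  cat_df <- do.call(rbind, rows)
  key <- match(cat_df$canonical_isoform, coords$isoform_id)
  cat_df$chrom <- coords$chrom[key]
  cat_df$start <- coords$start[key]
  cat_df$end <- coords$end[key]
  cat_df$strand <- coords$strand[key]
  cat_df$length <- NULL
  cat_df <- cat_df[order(cat_df$gene_id), , drop = FALSE]
  rownames(cat_df) <- NULL
  cat_df
}

#' Tabulate catalogue composition by effector group
#'
#' @param catalogue data.frame with a `group` column (one row per gene).
#' @return data.frame with `group`, `n` and `percent` (share of the
#'   catalogue, half-up rounded to one decimal), sorted by decreasing count.
#'   Empty catalogue gives an empty table.
#' @export
summarize_groups <- function(catalogue) {
  if (!nrow(catalogue)) {
    return(data.frame(group = character(), n = integer(), percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(catalogue$group)
  out <- data.frame(group = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- round_half_up(100 * out$n / sum(out$n), 1)
  out <- out[order(-out$n, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read the catalogue as TSV
#' @param catalogue catalogue data.frame.
#' @param path file path.
#' @return `path` invisibly (write) or the catalogue data.frame (read).
#' @export
write_catalogue <- function(catalogue, path) {
  utils::write.table(catalogue, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(path) {
  if (!file.exists(path)) stop_arg("catalogue file not found: ", path)
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(effectors = "character"))
  out$chrom <- as.character(out$chrom)
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  out
}
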