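# Synthetic-data generators with recorded ground truth.  Every fixture used
# by the tests and the validation runs is produced here, at a miniature
# version of the study design: seven effector groups with KRAB at ~13% of
# genes, one large KRAB-rich gene cluster, partial orthologue tables, and
# negative-binomial count matrices with planted tissue-specific genes.

#' Simulation configuration
#'
#' Central parameter object for the three generators.  Defaults mirror the
#' annotated family's shape in miniature: group proportions follow the
#' 301-gene catalogue (KRAB 39, BTB 43, SET 14, HOMEO 4, PHD 2, SCAN 1,
#' rest ZF-only), one 21-gene cluster with 16 KRAB members, and a 6-tissue,
#' 3-replicate negative-binomial count design with dispersion 0.1 and
#' log-normal library-size factors (sdlog 0.3).
#'
#' @param seed integer RNG seed (default 1).
#' @param n_genes catalogue size for [simulate_catalogue()] (default 150).
#' @param group_proportions named numeric over the seven groups, summing
#'   to 1.
#' @param n_isoforms_range integer range of isoforms per gene.
#' @param cluster_spec list of planted clusters; each entry a list with
#'   `chrom`, `groups` (member group labels, in genomic order) and
#'   `gap_range` (bp between consecutive genes).
#' @param orthologue_match_rate list per species of named per-group match
#'   probabilities.
#' @param n_expr_genes,n_tissues,replicates_per_tissue count-matrix design
#'   (defaults 2000, 6, 3).
#' @param nb_dispersion negative-binomial dispersion (default 0.1).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean counts.
#' @param libsize_sdlog log-normal sd of library-size factors (default 0.3).
#' @param n_planted_per_tissue planted tissue-specific genes per tissue
#'   (default 10).
#' @param planted_lfc planted log2 fold-change (default 3).
#' @param planted_quantile planted genes are drawn from genes below this
#'   baseline quantile (default 0.6): tissue-specific transcription factors
#'   are typically low-to-moderately expressed, and this also keeps planted
#'   up-shifts inside the pipeline's abundance filter.
#' @param length_range effective gene-length range in bp.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 150,
                       group_proportions = c(
                         KRAB = 39, BTB = 43, SET = 14, HOMEO = 4,
                         PHD = 2, SCAN = 1, ZF_ONLY = 198) / 301,
                       n_isoforms_range = 1:3,
                       cluster_spec = list(list(
                         chrom = "29",
                         groups = c(rep("KRAB", 16), rep("ZF_ONLY", 5)),
                         gap_range = c(5e3, 2e5))),
                       orthologue_match_rate = list(
                         human = c(KRAB = 0.128, BTB = 0.953, SET = 0.929,
                                   HOMEO = 1, PHD = 1, SCAN = 0,
                                   ZF_ONLY = 0.843),
                         zebra_finch = c(KRAB = 0.128, BTB = 0.95, SET = 0.93,
                                         HOMEO = 1, PHD = 1, SCAN = 1,
                                         ZF_ONLY = 0.9)),
                       n_expr_genes = 2000,
                       n_tissues = 6,
                       replicates_per_tissue = 3,
                       nb_dispersion = 0.1,
                       baseline_meanlog = log(50),
                       baseline_sdlog = 1,
                       libsize_sdlog = 0.3,
                       n_planted_per_tissue = 10,
                       planted_lfc = 3,
                       planted_quantile = 0.6,
                       length_range = c(500, 3000)) {
  cfg <- list(
    seed = seed, n_genes = n_genes, group_proportions = group_proportions,
    n_isoforms_range = n_isoforms_range, cluster_spec = cluster_spec,
    orthologue_match_rate = orthologue_match_rate,
    n_expr_genes = n_expr_genes, n_tissues = n_tissues,
    replicates_per_tissue = replicates_per_tissue,
    nb_dispersion = nb_dispersion, baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog, libsize_sdlog = libsize_sdlog,
    n_planted_per_tissue = n_planted_per_tissue, planted_lfc = planted_lfc,
    planted_quantile = planted_quantile, length_range = length_range
  )
  if (abs(sum(cfg$group_proportions) - 1) > 1e-6) {
    stop_arg("group_proportions must sum to 1")
  }
  if (!all(names(cfg$group_proportions) %in% ZFP_GROUPS)) {
    stop_arg("unknown group in group_proportions")
  }
  if (cfg$nb_dispersion <= 0) stop_arg("nb_dispersion must be > 0")
  if (cfg$replicates_per_tissue < 1) stop_arg("replicates_per_tissue must be >= 1")
  n_clustered <- sum(vapply(cfg$cluster_spec, function(s) length(s$groups), integer(1)))
  if (n_clustered > cfg$n_genes) {
    stop_arg("cluster_spec places more genes (", n_clustered,
             ") than n_genes (", cfg$n_genes, ")")
  }
  for (s in cfg$cluster_spec) {
    span <- length(s$groups) * (30e3 + max(s$gap_range))
    if (span > 1e8) stop_arg("infeasible cluster_spec on chromosome ", s$chrom,
                             ": required span ", span, " bp exceeds 1e8")
    if (max(s$gap_range) >= 250e3) {
      stop_arg("cluster_spec gaps on chromosome ", s$chrom,
               " reach 250 kb; the planted cluster would not be contiguous")
    }
  }
  structure(cfg, class = "sim_config")
}

rand_id <- function(prefix, i) sprintf("%s%04d", prefix, i)

# one gene's isoform set, constructed so the intended canonical is known
# by design rather than re-derived through the selection rules:
# isoform 01 carries the effector (when the group has one), the maximal ZF
# count, the maximal length, and the smallest id.
simulate_gene_isoforms <- function(gene_id, group, n_iso) {
  zf_max <- sample(3:12, 1)
  len_max <- sample(350:700, 1)
  has_eff <- group != "ZF_ONLY"
  iso <- list()
  for (j in seq_len(n_iso)) {
    id <- sprintf("%s.t%02d", gene_id, j)
    if (j == 1L) {
      iso[[j]] <- list(id = id, zf = zf_max, len = len_max, eff = has_eff)
    } else {
      variant <- sample(c("no_eff", "fewer_zf", "shorter"), 1)
      if (!has_eff && variant == "no_eff") variant <- "fewer_zf"
      iso[[j]] <- switch(variant,
        no_eff = list(id = id, zf = zf_max + sample(0:2, 1),
                      len = len_max + sample(0:50, 1), eff = FALSE),
        fewer_zf = list(id = id, zf = max(1, zf_max - sample(1:2, 1)),
                        len = len_max, eff = has_eff),
        shorter = list(id = id, zf = zf_max,
                       len = len_max - sample(10:80, 1), eff = has_eff)
      )
    }
  }
  iso
}

domain_hits_for_isoform <- function(iso, group) {
  rows <- list()
  eff_len <- c(BTB = 111, HOMEO = 57, KRAB = 42, PHD = 53, SCAN = 84,
               SET = 154)
  if (iso$eff) {
    rows[[length(rows) + 1L]] <- data.frame(
      isoform_id = iso$id, profile = group,
      env_start = 10L, env_end = as.integer(10 + eff_len[[group]] - 1),
      i_evalue = signif(10^stats::runif(1, -12, -4), 3),
      score = round(stats::runif(1, 30, 90), 1),
      target_len = iso$len, stringsAsFactors = FALSE
    )
  }
  zf_start <- iso$len - 28L * iso$zf
  for (k in seq_len(iso$zf)) {
    s <- as.integer(zf_start + (k - 1L) * 28L)
    rows[[length(rows) + 1L]] <- data.frame(
      isoform_id = iso$id, profile = "ZF_C2H2",
      env_start = s, env_end = s + 22L,
      i_evalue = signif(10^stats::runif(1, -10, -3), 3),
      score = round(stats::runif(1, 15, 35), 1),
      target_len = iso$len, stringsAsFactors = FALSE
    )
  }
  # occasional sub-threshold decoy that the E-value filter must remove
  if (stats::runif(1) < 0.3) {
    rows[[length(rows) + 1L]] <- data.frame(
      isoform_id = iso$id, profile = sample(ZFP_EFFECTORS, 1),
      env_start = 5L, env_end = 60L,
      i_evalue = signif(10^stats::runif(1, -1.2, 0), 3),
      score = round(stats::runif(1, 2, 8), 1),
      target_len = iso$len, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Simulate a domain-annotated ZFP catalogue
#'
#' Writes a syntactically valid HMMER3 per-domain table, an isoform
#' coordinate TSV and a BioMart-style orthologue TSV for `cfg$n_genes`
#' genes, with group labels, intended canonical isoforms, cluster placement
#' and orthologue status all recorded in the returned ground-truth table.
#' Multi-isoform genes are constructed to exercise all canonical-selection
#' rules; ~30% of isoforms carry a decoy hit above the E-value threshold.
#' Cluster members are laid out with gaps drawn from the cluster's
#' `gap_range`; all remaining genes are spaced >= 400 kb apart so no
#' unplanned cluster can arise at the default 250-kb rule.
#'
#' @param cfg a [sim_config()] object.
#' @param out_dir directory for the three files (created if needed).
#' @return list with paths `domtbl`, `coords`, `orthologues` and the
#'   data.frame `truth` (`gene_id`, `group`, `canonical_isoform`,
#'   `cluster_id`, one `matched_<species>` column per species).
#' @export
simulate_catalogue <- function(cfg = sim_config(), out_dir = tempfile("simcat")) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  gene_ids <- rand_id("ZFPG", seq_len(cfg$n_genes))
  n_clustered <- sum(vapply(cfg$cluster_spec, function(s) length(s$groups), integer(1)))
  groups <- character(cfg$n_genes)
  cluster_id <- rep(NA_character_, cfg$n_genes)
  chrom <- character(cfg$n_genes)
  start <- numeric(cfg$n_genes)
  end <- numeric(cfg$n_genes)

  i <- 1L
  for (ci in seq_along(cfg$cluster_spec)) {
    s <- cfg$cluster_spec[[ci]]
    pos <- 1e6
    for (g in seq_along(s$groups)) {
      span <- sample(5e3:30e3, 1)
      groups[i] <- s$groups[g]
      cluster_id[i] <- sprintf("C%sC%d", s$chrom, 1L)  # one planted block per chrom
      chrom[i] <- s$chrom
      start[i] <- pos
      end[i] <- pos + span
      pos <- end[i] + round(stats::runif(1, s$gap_range[1], s$gap_range[2]))
      i <- i + 1L
    }
  }
  # remaining genes: proportions from the configured pie, far apart
  n_rest <- cfg$n_genes - n_clustered
  if (n_rest > 0) {
    rest_groups <- sample(names(cfg$group_proportions), n_rest, replace = TRUE,
                          prob = cfg$group_proportions)
    bg_chroms <- as.character(1:5)
    pos_of <- stats::setNames(rep(1e6, length(bg_chroms)), bg_chroms)
    for (g in seq_len(n_rest)) {
      ch <- sample(bg_chroms, 1)
      span <- sample(5e3:30e3, 1)
      groups[i] <- rest_groups[g]
      chrom[i] <- ch
      start[i] <- pos_of[[ch]]
      end[i] <- start[i] + span
      pos_of[[ch]] <- end[i] + round(stats::runif(1, 4e5, 1e6))
      i <- i + 1L
    }
  }

  hit_list <- list()
  coord_list <- list()
  canonical <- character(cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    n_iso <- sample(cfg$n_isoforms_range, 1)
    isos <- simulate_gene_isoforms(gene_ids[g], groups[g], n_iso)
    canonical[g] <- isos[[1]]$id
    for (iso in isos) {
      hit_list[[length(hit_list) + 1L]] <- domain_hits_for_isoform(iso, groups[g])
      coord_list[[length(coord_list) + 1L]] <- data.frame(
        gene_id = gene_ids[g], isoform_id = iso$id, chrom = chrom[g],
        start = start[g] + 1, end = end[g],   # written 1-based inclusive
        strand = sample(c("+", "-"), 1), length = iso$len,
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- do.call(rbind, hit_list)
  coords <- do.call(rbind, coord_list)

  species <- names(cfg$orthologue_match_rate)
  orth_rows <- list()
  truth <- data.frame(gene_id = gene_ids, group = groups,
                      canonical_isoform = canonical, cluster_id = cluster_id,
                      stringsAsFactors = FALSE)
  for (sp in species) {
    rate <- cfg$orthologue_match_rate[[sp]]
    matched <- stats::runif(cfg$n_genes) < rate[groups]
    truth[[paste0("matched_", sp)]] <- matched
    orth_rows[[sp]] <- data.frame(
      gene_id = gene_ids, target_species = sp,
      orthologue_id = ifelse(matched, paste0("ENS", toupper(substr(sp, 1, 3)),
                                             "G", sprintf("%07d", seq_len(cfg$n_genes))),
                             ""),
      stringsAsFactors = FALSE
    )
  }
  orth <- do.call(rbind, orth_rows)
  rownames(orth) <- NULL

  domtbl_path <- file.path(out_dir, "domains.domtblout")
  coords_path <- file.path(out_dir, "coords.tsv")
  orth_path <- file.path(out_dir, "orthologues.tsv")
  write_domtblout(hits, domtbl_path)
  utils::write.table(coords, coords_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(orth, orth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(domtbl = domtbl_path, coords = coords_path, orthologues = orth_path,
       truth = truth, hits = hits)
}

#' Simulate a cross-tissue negative-binomial count matrix
#'
#' Gene baselines are log-normal; per-sample library-size factors are
#' log-normal (sdlog `cfg$libsize_sdlog`); counts are negative-binomial with
#' mean `baseline * 2^lfc[tissue] * libfactor` and dispersion
#' `cfg$nb_dispersion`.  `cfg$n_planted_per_tissue` distinct genes per
#' tissue, drawn from below the `cfg$planted_quantile` baseline quantile,
#' receive a planted log2 fold-change of `cfg$planted_lfc`.
#'
#' @param cfg a [sim_config()] object.
#' @param out_dir optional directory; when given, counts/lengths/sample-sheet
#'   TSVs are written there.
#' @return list with `cm` (a [zfp_counts()] object), `truth` (data.frame
#'   `gene_id`, `tissue`, `log2fc` of planted effects), `baseline`,
#'   `lib_factors`, and file paths when `out_dir` was given.
#' @export
simulate_counts <- function(cfg = sim_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  G <- cfg$n_expr_genes
  tissue_names <- c("blastoderm", "brain", "liver", "muscle", "ovary",
                    "testis", "spleen", "kidney", "heart", "lung")
  if (cfg$n_tissues > length(tissue_names)) {
    tissue_names <- c(tissue_names,
                      sprintf("tissue%02d", seq_len(cfg$n_tissues - length(tissue_names))))
  }
  tissues <- tissue_names[seq_len(cfg$n_tissues)]
  samples <- unlist(lapply(tissues, function(t) {
    sprintf("%s_r%d", t, seq_len(cfg$replicates_per_tissue))
  }))
  tissue_of <- stats::setNames(rep(tissues, each = cfg$replicates_per_tissue),
                               samples)

  gene_ids <- rand_id("G", seq_len(G))
  baseline <- stats::setNames(
    stats::rlnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog), gene_ids)
  lengths <- stats::setNames(
    sample(cfg$length_range[1]:cfg$length_range[2], G, replace = TRUE),
    gene_ids)
  lib <- stats::setNames(stats::rlnorm(length(samples), 0, cfg$libsize_sdlog),
                         samples)

  n_planted <- cfg$n_planted_per_tissue * cfg$n_tissues
  eligible <- gene_ids[baseline <= stats::quantile(baseline, cfg$planted_quantile)]
  if (n_planted > length(eligible)) stop_arg("not enough low-baseline genes to plant")
  planted_genes <- sample(eligible, n_planted)
  truth <- data.frame(
    gene_id = planted_genes,
    tissue = rep(tissues, each = cfg$n_planted_per_tissue),
    log2fc = rep(cfg$planted_lfc, length.out = n_planted),
    stringsAsFactors = FALSE
  )

  lfc_mat <- matrix(0, G, cfg$n_tissues, dimnames = list(gene_ids, tissues))
  lfc_mat[cbind(truth$gene_id, truth$tissue)] <- truth$log2fc

  mu <- outer(baseline, rep(1, length(samples))) *
    2^lfc_mat[, tissue_of[samples], drop = FALSE] *
    matrix(lib, G, length(samples), byrow = TRUE)
  colnames(mu) <- samples
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$nb_dispersion),
    G, length(samples), dimnames = list(gene_ids, samples))

  cm <- zfp_counts(counts, tissue_of, lengths)
  out <- list(cm = cm, truth = truth, baseline = baseline, lib_factors = lib)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    counts_path <- file.path(out_dir, "counts.tsv")
    lengths_path <- file.path(out_dir, "lengths.tsv")
    samples_path <- file.path(out_dir, "samples.tsv")
    utils::write.table(
      data.frame(gene_id = gene_ids, counts, check.names = FALSE),
      counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = gene_ids, length = lengths),
      lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = samples, tissue = tissue_of[samples]),
      samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, list(counts = counts_path, lengths = lengths_path,
                       samples = samples_path))
  }
  out
}

#' Simulate a protein multiple alignment with planted conserved blocks
#'
#' A random reference sequence is copied into `n_seqs - 1` homologues; each
#' non-reference position is substituted with probability
#' `substitution_rate`, reduced to `conserved_rate` inside the planted
#' conserved blocks, and replaced by a gap with probability `gap_rate`.  The
#' reference row carries no gaps, so alignment columns map 1:1 to reference
#' positions.
#'
#' @param n_seqs number of sequences (default 11: a reference plus ten
#'   homologues).
#' @param length alignment length in residues (default 240).
#' @param conserved_blocks list of `c(start, end)` 1-based inclusive column
#'   ranges mutating at `conserved_rate`.
#' @param substitution_rate per-position substitution probability outside
#'   conserved blocks.
#' @param conserved_rate substitution probability inside conserved blocks.
#' @param gap_rate per-position gap probability in non-reference rows.
#' @param seed RNG seed.
#' @param out_fasta optional path; when given the alignment is written as
#'   aligned FASTA.
#' @return list with `aln` (a [zfp_alignment()]), `conserved` (logical per
#'   position) and `fasta` (path or `NULL`).
#' @export
simulate_alignment <- function(n_seqs = 11, length = 240,
                               conserved_blocks = list(c(31, 110), c(151, 230)),
                               substitution_rate = 0.5, conserved_rate = 0.05,
                               gap_rate = 0.02, seed = 1, out_fasta = NULL) {
  if (substitution_rate < 0 || substitution_rate > 1 ||
      conserved_rate < 0 || conserved_rate > 1 ||
      gap_rate < 0 || gap_rate > 1) {
    stop_arg("rates must lie in [0, 1]")
  }
  set.seed(seed)
  conserved <- rep(FALSE, length)
  for (b in conserved_blocks) {
    if (b[1] < 1 || b[2] > length || b[1] > b[2]) {
      stop_arg("conserved block [", b[1], ", ", b[2],
               "] outside the alignment length ", length)
    }
    conserved[b[1]:b[2]] <- TRUE
  }
  rate <- ifelse(conserved, conserved_rate, substitution_rate)
  ref <- sample(AA_ALPHABET20, length, replace = TRUE)
  seqs <- character(n_seqs)
  seqs[1] <- paste(ref, collapse = "")
  for (s in seq_len(n_seqs)[-1]) {
    row <- ref
    mut <- stats::runif(length) < rate
    row[mut] <- vapply(which(mut), function(i) {
      sample(setdiff(AA_ALPHABET20, ref[i]), 1)
    }, character(1))
    gap <- stats::runif(length) < gap_rate
    row[gap] <- "-"
    seqs[s] <- paste(row, collapse = "")
  }
  ids <- c("reference", sprintf("homolog%02d", seq_len(n_seqs - 1)))
  names(seqs) <- ids
  aln <- zfp_alignment(seqs, "reference")
  fasta <- NULL
  if (!is.null(out_fasta)) {
    writeLines(paste0(">", ids, "\n", seqs), out_fasta)
    fasta <- out_fasta
  }
  list(aln = aln, conserved = conserved, fasta = fasta)
}
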