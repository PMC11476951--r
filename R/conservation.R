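# Per-position conservation scoring of a protein multiple alignment with
# Jensen-Shannon divergence against a background amino-acid distribution.

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Uniform amino-acid background
#' @return named probability vector over the 20 standard amino acids.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
}

#' Read a 20-line background frequency TSV
#'
#' Two columns without header: amino-acid letter, frequency.  Frequencies are
#' renormalized to sum to 1 and must be strictly positive.
#'
#' @param path file path.
#' @return named probability vector over the 20 amino acids.
#' @export
read_background <- function(path) {
  bg <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  p <- stats::setNames(as.numeric(bg[[2]]), toupper(bg[[1]]))
  if (!setequal(names(p), AA_ALPHABET20)) {
    stop_arg("background must cover exactly the 20 standard amino acids")
  }
  p <- p[AA_ALPHABET20]
  if (any(p <= 0)) stop_arg("background frequencies must be strictly positive")
  p / sum(p)
}

# Shannon entropy in bits; 0 log 0 := 0
shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence of one alignment column
#'
#' Computes `JSD(P, Q) = H(lambda P + (1 - lambda) Q) - lambda H(P) -
#' (1 - lambda) H(Q)` in bits, with `P` the column's relative amino-acid
#' frequencies and `Q` the background, then normalizes by the upper bound
#' `Hb(lambda)` (the binary entropy of `lambda`; 1 bit at `lambda = 0.5`) so
#' the score lies in `[0, 1]`.
#'
#' @param counts named non-negative vector of residue counts (or
#'   frequencies) over the 20 amino acids; gaps must already be excluded and
#'   at least one count must be positive.
#' @param background strictly positive probability vector over the same
#'   alphabet (default uniform).
#' @param lambda mixture weight in (0, 1); default 0.5.
#' @return normalized divergence in `[0, 1]`.
#' @export
jsd_column <- function(counts, background = uniform_background(), lambda = 0.5) {
  if (lambda <= 0 || lambda >= 1) stop_arg("lambda must be in (0, 1)")
  if (anyNA(background) || abs(sum(background) - 1) > 1e-8 ||
      any(background <= 0)) {
    stop_arg("background must be strictly positive and sum to 1")
  }
  if (!is.null(names(counts)) && !is.null(names(background))) {
    counts <- counts[names(background)]
    counts[is.na(counts)] <- 0
  }
  tot <- sum(counts)
  if (tot <= 0) stop_arg("jsd_column: column has no non-gap residues")
  p <- counts / tot
  q <- background
  m <- lambda * p + (1 - lambda) * q
  jsd <- shannon_bits(m) - lambda * shannon_bits(p) - (1 - lambda) * shannon_bits(q)
  hb <- -(lambda * log2(lambda) + (1 - lambda) * log2(1 - lambda))
  # numerical noise can leave a tiny negative residue at P == Q
  min(max(jsd / hb, 0), 1)
}

#' Alignment container
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (residues plus `-` gaps).
#' @param reference_id id of the row whose ungapped positions define the
#'   reported coordinate system; default the first sequence.
#' @return object of class `zfp_alignment`.
#' @export
zfp_alignment <- function(seqs, reference_id = names(seqs)[1]) {
  if (!length(seqs)) stop_arg("alignment has no sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop_arg("alignment sequences must be named")
  }
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop_arg("alignment rows differ in length")
  if (!reference_id %in% names(seqs)) {
    stop_arg("reference_id '", reference_id, "' not found in the alignment")
  }
  structure(list(seqs = toupper(seqs), reference_id = reference_id),
            class = "zfp_alignment")
}

#' Read an aligned FASTA or Clustal file
#'
#' @param path alignment file.
#' @param format `"fasta"` (default) or `"clustal"`.
#' @param reference_id reference row id; default the first sequence.
#' @return a [zfp_alignment()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           reference_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_arg("alignment file not found: ", path)
  if (format == "fasta") {
    aa <- Biostrings::readAAStringSet(path)
    seqs <- stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  } else {
    ma <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    aa <- Biostrings::unmasked(ma)
    seqs <- stats::setNames(as.character(aa), names(aa))
  }
  zfp_alignment(seqs, reference_id %||% names(seqs)[1])
}

#' Per-position conservation profile
#'
#' For every alignment column where the reference row is not a gap, the
#' Jensen-Shannon score is computed over the column's non-gap residues and
#' (optionally) down-weighted by `(1 - gap_fraction)`.  Positions are
#' reported in 1-based ungapped reference coordinates.  An optional symmetric
#' sliding-window mean of half-width `window` smooths the profile (0 = off).
#'
#' @param aln a [zfp_alignment()] object.
#' @param background probability vector over the 20 amino acids.
#' @param gap_penalty multiply each score by the column's non-gap fraction
#'   (default `TRUE`).
#' @param lambda mixture weight passed to [jsd_column()].
#' @param window half-width of the optional smoothing window (default 0).
#' @return data.frame with `position`, `residue` (reference), `score`,
#'   `gap_fraction`.
#' @export
profile_conservation <- function(aln, background = uniform_background(),
                                 gap_penalty = TRUE, lambda = 0.5, window = 0) {
  if (!inherits(aln, "zfp_alignment")) stop_arg("aln must be a zfp_alignment")
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(mat) <- names(aln$seqs)
  ref <- mat[aln$reference_id, ]
  ref_cols <- which(ref != "-")
  if (!length(ref_cols)) stop_arg("reference row is all gaps")
  n <- nrow(mat)
  score <- gapf <- numeric(length(ref_cols))
  for (i in seq_along(ref_cols)) {
    col <- mat[, ref_cols[i]]
    res <- col[col != "-"]
    gapf[i] <- 1 - length(res) / n
    cnt <- table(factor(res, levels = names(background)))
    s <- jsd_column(stats::setNames(as.numeric(cnt), names(background)),
                    background, lambda)
    score[i] <- if (gap_penalty) s * (1 - gapf[i]) else s
  }
  if (window > 0) {
    sm <- score
    for (i in seq_along(score)) {
      lo <- max(1, i - window); hi <- min(length(score), i + window)
      sm[i] <- mean(score[lo:hi])
    }
    score <- sm
  }
  data.frame(position = seq_along(ref_cols), residue = ref[ref_cols],
             score = score, gap_fraction = gapf, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a conservation profile as TSV
#' @param profile data.frame from [profile_conservation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
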