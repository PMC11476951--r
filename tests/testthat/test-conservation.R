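test_that("column identical to the background scores zero", {
  bg <- uniform_background()
  expect_equal(jsd_column(bg, bg), 0)
  bg2 <- setNames(c(0.5, rep(0.5 / 19, 19)), names(bg))
  expect_equal(jsd_column(bg2 * 37, bg2), 0)  # scale-free in the counts
})

test_that("single-letter column against uniform background matches the closed form", {
  bg <- uniform_background()
  col <- setNames(c(12, rep(0, 19)), names(bg))
  # direct summation: M puts 0.5 + 1/40 on the observed letter, 1/40 elsewhere;
  # H(P) = 0, H(Q) = log2(20), normalizer = 1 bit at lambda = 0.5
  hM <- -(0.525 * log2(0.525) + 19 * 0.025 * log2(0.025))
  expected <- hM - 0.5 * log2(20)
  expect_equal(jsd_column(col, bg), expected, tolerance = 1e-12)
})

test_that("divergence is symmetric in column and background at lambda 0.5", {
  set.seed(4)
  for (i in 1:20) {
    p <- runif(20); p <- p / sum(p)
    q <- runif(20) + 0.01; q <- q / sum(q)
    names(p) <- names(q) <- names(uniform_background())
    expect_equal(jsd_column(p, q), jsd_column(q, p), tolerance = 1e-12)
  }
})

test_that("jsd matches the brute-force entropy oracle on random columns", {
  set.seed(17)
  bg <- uniform_background()
  for (i in 1:200) {
    counts <- setNames(rpois(20, lambda = 2), names(bg))
    if (sum(counts) == 0) counts[sample(20, 1)] <- 1
    lam <- sample(c(0.3, 0.5, 0.7), 1)
    expect_equal(jsd_column(counts, bg, lambda = lam),
                 oracle_jsd(counts, bg, lambda = lam), tolerance = 1e-10)
  }
})

test_that("invalid columns and parameters are rejected", {
  bg <- uniform_background()
  expect_error(jsd_column(setNames(rep(0, 20), names(bg)), bg), "no non-gap")
  expect_error(jsd_column(bg, bg, lambda = 1), "lambda")
  expect_error(jsd_column(bg, setNames(rep(0.05, 19), names(bg)[1:19])[names(bg)]),
               "background")
})

test_that("profiles of identical ungapped sequences are flat and maximal", {
  seqs <- setNames(rep("MKVLWAYT", 3), c("s1", "s2", "s3"))
  prof <- profile_conservation(zfp_alignment(seqs))
  expect_equal(nrow(prof), 8)
  expect_equal(length(unique(round(prof$score[prof$residue == "M"], 12))), 1)
  # every column is a point mass: all scores equal the point-mass value
  pm <- jsd_column(setNames(c(3, rep(0, 19)), names(uniform_background())),
                   uniform_background())
  expect_equal(prof$score, rep(pm, 8))
  expect_equal(prof$gap_fraction, rep(0, 8))
})

test_that("gap penalty halves the score of a half-gapped column", {
  seqs <- setNames(c("MA", "MA", "M-", "M-"), c("r", "a", "b", "c"))
  on_ <- profile_conservation(zfp_alignment(seqs, "r"), gap_penalty = TRUE)
  off <- profile_conservation(zfp_alignment(seqs, "r"), gap_penalty = FALSE)
  expect_equal(on_$score[2], off$score[2] / 2)
  expect_equal(on_$gap_fraction, c(0, 0.5))
})

test_that("a toy alignment matches the hand-rolled per-column oracle", {
  seqs <- setNames(c("MK-VA", "MR-V-", "MKAVA"), c("ref", "h1", "h2"))
  aln <- zfp_alignment(seqs, "ref")
  prof <- profile_conservation(aln, gap_penalty = TRUE)
  # reference has 4 ungapped positions (column 3 skipped)
  expect_equal(nrow(prof), 4)
  expect_equal(prof$residue, c("M", "K", "V", "A"))
  bg <- uniform_background()
  cols <- list(c("M", "M", "M"), c("K", "R", "K"), c("V", "V", "V"), c("A", "A"))
  for (i in seq_along(cols)) {
    counts <- table(factor(cols[[i]], levels = names(bg)))
    want <- oracle_jsd(setNames(as.numeric(counts), names(bg)), bg) *
      (length(cols[[i]]) / 3)
    expect_equal(prof$score[i], want, tolerance = 1e-12)
  }
})

test_that("row order does not change the profile; length equals ungapped reference", {
  sim <- simulate_alignment(seed = 23, gap_rate = 0.05)
  prof <- profile_conservation(sim$aln)
  perm <- sample(length(sim$aln$seqs))
  aln2 <- zfp_alignment(sim$aln$seqs[perm], "reference")
  expect_equal(profile_conservation(aln2), prof)
  expect_equal(nrow(prof),
               unname(nchar(gsub("-", "", sim$aln$seqs["reference"]))))
  expect_true(all(prof$score >= 0 & prof$score <= 1))
})

test_that("mutating a conserved column toward the background lowers its score", {
  bg <- uniform_background()
  pure <- setNames(c(10, rep(0, 19)), names(bg))
  mixed <- setNames(c(7, 1, 1, 1, rep(0, 16)), names(bg))
  near_bg <- setNames(rep(0.5, 20), names(bg))
  s <- c(jsd_column(pure, bg), jsd_column(mixed, bg), jsd_column(near_bg, bg))
  expect_true(all(diff(s) < 0))
})

test_that("aligned FASTA and Clustal inputs load into the same alignment", {
  sim <- simulate_alignment(n_seqs = 3, length = 30,
                            conserved_blocks = list(c(5, 15)), seed = 3,
                            out_fasta = withr::local_tempfile(fileext = ".fa"))
  aln <- read_alignment(sim$fasta, reference_id = "reference")
  expect_identical(aln$seqs, sim$aln$seqs)
  clu <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (2.1) multiple sequence alignment", "", "",
               paste("reference ", sim$aln$seqs[1]),
               paste("homolog01 ", sim$aln$seqs[2]),
               paste("homolog02 ", sim$aln$seqs[3]), ""), clu)
  aln2 <- read_alignment(clu, format = "clustal", reference_id = "reference")
  expect_identical(unname(aln2$seqs), unname(sim$aln$seqs))
})

test_that("background files are validated and renormalized", {
  f <- withr::local_tempfile()
  write.table(data.frame(names(uniform_background()), 1:20), f,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  bg <- read_background(f)
  expect_equal(sum(bg), 1)
  expect_equal(bg[["A"]], 1 / 210)
  bad <- withr::local_tempfile()
  write.table(data.frame(names(uniform_background())[1:5], 1:5), bad,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_error(read_background(bad), "20")
})
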