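test_that("TPM columns sum to one million and follow the rate formula", {
  counts <- matrix(c(5, 100, 100, 100), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cm <- zfp_counts(counts, c(s1 = "a", s2 = "b"), c(g1 = 1000, g2 = 2000))
  x <- tpm(cm)
  expect_equal(colSums(x$values), c(s1 = 1e6, s2 = 1e6))
  # equal counts, lengths L and 2L -> 2:1 split of the million
  expect_equal(x$values["g1", "s2"], 666666.7, tolerance = 1e-6)
  expect_equal(x$values["g2", "s2"], 333333.3, tolerance = 1e-6)
  # single expressed gene takes the whole million
  cm1 <- zfp_counts(matrix(3, 1, 1, dimnames = list("g1", "s1")),
                    c(s1 = "a"), c(g1 = 500))
  expect_equal(as.vector(tpm(cm1)$values), 1e6)
  expect_equal(x$state, "raw_tpm")
})

test_that("a sample with zero total rate is reported by name", {
  counts <- matrix(c(5, 3, 0, 0), 2, 2,
                   dimnames = list(c("g1", "g2"), c("ok", "empty")))
  cm <- zfp_counts(counts, c(ok = "a", empty = "b"), c(g1 = 100, g2 = 100))
  expect_error(tpm(cm), "empty")
})

test_that("abundance filter drops never-expressed and implausibly high genes", {
  v <- rbind(low = c(0.9, 0.5), high = c(50, 12000), keep = c(0.5, 3.0),
             edge = c(1.0, 0.2), cap = c(10000, 10000))
  colnames(v) <- c("s1", "s2")
  x <- zfpkit:::new_expr(v, c(s1 = "a", s2 = "b"),
                         setNames(rep(1e3, nrow(v)), rownames(v)), "raw_tpm")
  expect_message(xf <- filter_matrix(x), "dropped")
  # both bounds are strict: a gene touching 1.0 stays, one touching 10000 stays
  expect_setequal(rownames(xf$values), c("keep", "edge", "cap"))
  expect_equal(xf$state, "filtered")
  expect_error(filter_matrix(xf), "raw_tpm")
})

test_that("TMM factors are 1 for identical samples and track pure rescaling", {
  set.seed(2)
  v <- matrix(rlnorm(200, 4, 1), 100, 2,
              dimnames = list(sprintf("g%03d", 1:100), c("s1", "s2")))
  v[, 2] <- v[, 1]
  x <- zfpkit:::new_expr(v, c(s1 = "a", s2 = "b"),
                         setNames(rep(1e3, 100), rownames(v)), "filtered")
  expect_equal(tmm_factors(x), c(s1 = 1, s2 = 1))
  # doubling one column doubles its factor (before geometric-mean rescale)
  v2 <- v; v2[, 2] <- 2 * v[, 1]
  x2 <- zfpkit:::new_expr(v2, c(s1 = "a", s2 = "b"), x$lengths, "filtered")
  f <- tmm_factors(x2, ref = "s1")
  expect_equal(unname(f["s2"] / f["s1"]), 2)
  expect_equal(exp(mean(log(f))), 1)
})

test_that("TMM matches the naive oracle to 1e-8 on NB fixtures", {
  for (seed in c(3, 13)) {
    sim <- simulate_counts(sim_config(seed = seed, n_expr_genes = 400))
    xf <- suppressMessages(filter_matrix(tpm(sim$cm)))
    q75 <- apply(xf$values, 2, function(col) quantile(col[col > 0], 0.75, names = FALSE))
    ref <- colnames(xf$values)[which.min(abs(q75 - mean(q75)))]
    got <- tmm_factors(xf)
    expect_equal(got, oracle_tmm(xf$values, ref), tolerance = 1e-8)
    expect_equal(exp(mean(log(got))), 1, tolerance = 1e-12)
  }
})

test_that("TMM factors approximately agree with edgeR on a TPM matrix", {
  sim <- simulate_counts(sim_config(seed = 19, n_expr_genes = 500))
  xf <- suppressMessages(filter_matrix(tpm(sim$cm)))
  ours <- tmm_factors(xf)
  # edgeR computes M on library-size-scaled proportions; TPM columns have
  # (nearly) equal sums, so its factors should be close but not identical
  theirs <- edgeR::calcNormFactors(xf$values, method = "TMM")
  # different weighting and reference details: a coarse sanity band only;
  # the authoritative check is the 1e-8 naive-oracle comparison above
  expect_equal(unname(ours), unname(theirs), tolerance = 0.1)
})

test_that("scaling one sample's counts rescales only that sample's factor", {
  sim <- simulate_counts(sim_config(seed = 29, n_expr_genes = 300))
  xf <- suppressMessages(filter_matrix(tpm(sim$cm)))
  f0 <- tmm_factors(xf, ref = colnames(xf$values)[1])
  v2 <- xf$values
  v2[, 4] <- v2[, 4] * 3
  x2 <- zfpkit:::new_expr(v2, xf$tissue_of, xf$lengths, "filtered")
  f1 <- tmm_factors(x2, ref = colnames(xf$values)[1])
  # relative to the unscaled reference, only sample 4 moves, by ~3x (the
  # A-trim window and precision weights shift slightly under rescaling)
  r0 <- f0 / f0[1]; r1 <- f1 / f1[1]
  expect_equal(unname(r1[4] / r0[4]), 3, tolerance = 0.05)
  expect_equal(r1[-4], r0[-4], tolerance = 1e-9)
})

test_that("tmm_normalize divides by the factors and flags the state", {
  sim <- simulate_counts(sim_config(seed = 31, n_expr_genes = 200))
  xf <- suppressMessages(filter_matrix(tpm(sim$cm)))
  f <- tmm_factors(xf)
  xn <- tmm_normalize(xf, f)
  expect_equal(xn$state, "tmm_normalized")
  expect_equal(xn$values, sweep(xf$values, 2, f, "/"))
  expect_equal(attr(tmm_normalize(xf), "tmm_factors"), f)
})

test_that("duplicated samples merge first in the sample tree", {
  set.seed(41)
  counts <- matrix(rpois(300, 60), 100, 3,
                   dimnames = list(sprintf("g%03d", 1:100), c("s1", "s2", "s3")))
  counts[, 2] <- counts[, 1]
  counts[1:50, 3] <- counts[1:50, 3] + 200
  cm <- zfp_counts(counts, c(s1 = "a", s2 = "a", s3 = "b"),
                   setNames(rep(1e3, 100), rownames(counts)))
  xn <- suppressMessages(tmm_normalize(filter_matrix(tpm(cm))))
  hc <- cluster_samples(xn)
  expect_equal(sort(unname(cutree(hc, 2)[c("s1", "s2")])), c(1, 1))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
})

test_that("replicates of each tissue form their own clade", {
  # three tissue blocks with a strong shared expression program each
  set.seed(51)
  tissues <- c("brain", "liver", "ovary")
  baseline <- setNames(rlnorm(300, log(60), 0.6), sprintf("g%03d", 1:300))
  lfc <- matrix(0, 300, 3, dimnames = list(names(baseline), tissues))
  for (i in 1:3) lfc[((i - 1) * 50 + 1):(i * 50), i] <- 2
  cm <- make_counts(baseline, tissues, reps = 4, lfc = lfc, seed = 51)
  xn <- suppressMessages(tmm_normalize(filter_matrix(tpm(cm), high = Inf)))
  hc <- cluster_samples(xn)
  # each tissue is a clade: within-tissue cophenetic distances all smaller
  # than any distance to another tissue
  cp <- as.matrix(cophenetic(hc))
  for (t in tissues) {
    within <- cp[xn$tissue_of == t, xn$tissue_of == t]
    between <- cp[xn$tissue_of == t, xn$tissue_of != t]
    expect_lt(max(within), min(between))
  }
  # permuting sample order leaves the topology unchanged
  perm <- sample(ncol(xn$values))
  xp <- zfpkit:::new_expr(xn$values[, perm], xn$tissue_of[perm],
                          xn$lengths, "tmm_normalized")
  hc2 <- cluster_samples(xp)
  m1 <- as.matrix(cophenetic(hc))
  m2 <- as.matrix(cophenetic(hc2))
  expect_equal(m2[rownames(m1), colnames(m1)], m1)
  nwk <- sample_tree_newick(hc)
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("constant samples make the correlation distance fail loudly", {
  v <- matrix(5, 10, 3, dimnames = list(sprintf("g%d", 1:10),
                                        c("s1", "s2", "s3")))
  x <- zfpkit:::new_expr(v, setNames(c("a", "a", "b"), colnames(v)),
                         setNames(rep(1e3, 10), rownames(v)), "tmm_normalized")
  expect_error(cluster_samples(x), "constant")
})
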