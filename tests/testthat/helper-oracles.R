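# Independent brute-force oracles.  These deliberately re-derive each
# quantity through a different route than the package implementation.

# Jensen-Shannon divergence by explicit term-by-term entropy summation.
oracle_jsd <- function(counts, background, lambda = 0.5) {
  p <- counts / sum(counts)
  q <- background
  m <- lambda * p + (1 - lambda) * q
  ent <- function(v) {
    s <- 0
    for (x in v) if (x > 0) s <- s - x * log2(x)
    s
  }
  jsd <- ent(m) - lambda * ent(p) - (1 - lambda) * ent(q)
  hb <- -(lambda * log2(lambda) + (1 - lambda) * log2(1 - lambda))
  min(max(jsd / hb, 0), 1)
}

# Cluster detection by transitive closure of the pairwise-gap graph
# (breadth-first components on an explicit adjacency matrix).
oracle_clusters <- function(catalogue, max_gap = 250000, min_genes = 3) {
  out <- list()
  for (chr in unique(catalogue$chrom)) {
    g <- catalogue[catalogue$chrom == chr, , drop = FALSE]
    n <- nrow(g)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        gap <- max(g$start[i] - g$end[j], g$start[j] - g$end[i], 0)
        adj[i, j] <- gap < max_gap
      }
    }
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1L
      frontier <- i
      comp[i] <- cid
      while (length(frontier)) {
        nxt <- which(adj[frontier[1], ] & is.na(comp))
        comp[nxt] <- cid
        frontier <- c(frontier[-1], nxt)
      }
    }
    for (k in unique(comp)) {
      members <- g$gene_id[comp == k]
      if (length(members) >= min_genes) {
        out[[length(out) + 1L]] <- sort(members)
      }
    }
  }
  out[order(vapply(out, paste, character(1), collapse = ","))]
}

# Naive TMM: order-based trimming, explicit loops.
oracle_tmm <- function(v, ref, trim_m = 0.30, trim_a = 0.05) {
  r <- v[, ref]
  f <- rep(1, ncol(v))
  names(f) <- colnames(v)
  for (s in colnames(v)) {
    if (s == ref) next
    xs <- v[, s]
    ok <- which(xs > 0 & r > 0)
    M <- log2(xs[ok] / r[ok])
    A <- 0.5 * log2(xs[ok] * r[ok])
    w <- 1 / (1 / xs[ok] + 1 / r[ok])
    n <- length(M)
    km <- floor(n * trim_m / 2)
    ka <- floor(n * trim_a / 2)
    ordM <- order(M)
    ordA <- order(A)
    dropM <- c(head(ordM, km), tail(ordM, km))
    dropA <- c(head(ordA, ka), tail(ordA, ka))
    keep <- setdiff(seq_len(n), union(dropM, dropA))
    f[s] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f / exp(mean(log(f)))
}

# Upper binomial tail by log-space summation of individual terms.
oracle_binom_tail <- function(k, n, p) {
  if (k == 0) return(1)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log(1 - p)))
}
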