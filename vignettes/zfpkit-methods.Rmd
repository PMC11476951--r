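---
title: "Methods: annotating and profiling a C2H2 zinc-finger repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and profiling a C2H2 zinc-finger repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfpkit)
```

# Scope

C2H2 zinc-finger proteins (ZFPs) are the largest transcription-factor family
in vertebrate genomes. A repertoire survey typically proceeds in five
stages: domain-scan parsing and gene-level annotation, genomic cluster
detection, orthologue-conservation summaries, per-position alignment
conservation, and cross-tissue expression profiling with tissue-specificity
and group-enrichment calls. zfpkit implements each stage as a small set of
composable functions operating on plain tables, so the whole chain runs on
desk-scale inputs and on synthetic fixtures with known ground truth.

The upstream heavy lifting — hmmsearch against Pfam profiles, ClustalW
alignment, read alignment and quantification — is deliberately out of
scope; zfpkit consumes their standard text outputs.

# Annotation model

A gene qualifies as a C2H2-ZFP when at least one isoform carries at least
one zinc-finger (`zf-C2H2`) domain hit whose *independent* E-value passes
the scan threshold (default 0.05, matching the common
`-E 0.05 -incE 0.05` hmmsearch settings). The independent E-value is used
because it is the per-domain quantity hmmsearch itself uses for inclusion
decisions; envelope coordinates locate the domain.

When a gene has several isoforms, one canonical isoform is selected by
three ordered rules: (1) if an effector domain (KRAB, BTB/POZ, SCAN, SET,
Homeodomain, PHD) is present on some but not all isoforms, only
effector-bearing isoforms remain in contention; (2) the isoform with the
largest zinc-finger count wins; (3) ties go to the longest isoform. A
fourth, purely operational tie-break — the lexicographically smallest
isoform id — makes the choice deterministic and order-independent; it is
recorded here because the first three rules can genuinely tie on real
annotation sets.

Each gene receives a single group label from its canonical isoform's
effector set. Effectors can co-occur (for example SCAN together with KRAB
in mammals), and disjoint group counts require a precedence; zfpkit applies
KRAB > SCAN > BTB > SET > HOMEO > PHD, with genes lacking all effectors
labelled `ZF_ONLY`. The precedence is a documented package choice, not a
biological claim; the full effector set is always kept in the catalogue's
`effectors` column so multi-effector genes can be audited.

Genomic intervals are normalized internally to 0-based half-open
coordinates; input coordinate tables are read as 1-based inclusive, the
usual BioMart export convention.

# Cluster detection

ZFP gene clusters arise from local duplication, and the operational
definition used here mirrors interval-merge practice in BED tooling: on
each chromosome or scaffold, genes are merged transitively while the
boundary-to-boundary gap (next gene's start minus the running block end) is
strictly below `max_gap` (default 250 kb); merged blocks with at least
`min_genes` members (default 3) are reported, named `C<chrom>C<ordinal>`.
Whether published 250-kb rules measure start-to-start or
boundary-to-boundary distance is rarely stated; boundary-to-boundary is the
implemented choice, strand is ignored, and unplaced scaffolds are treated
as ordinary sequences so clusters can be called on them too. The merge is
validated against a brute-force transitive-closure oracle over the pairwise
gap graph in the test suite.

# Orthologue summaries

Orthologue pairing tables (gene id, target species, orthologue id — the
shape of a BioMart export) collapse to presence/absence: a gene is
"matched" in a species when at least one non-empty orthologue id exists.
One-to-many orthologies and duplicate rows therefore have no effect. Genes
absent from the table count as unmatched (with a logged count, since an
absent gene may also mean an id-mapping failure). Orthologue-confidence
flags present in some exports are ignored. Lineage-specific candidates are
genes unmatched in *every* species of a supplied list; an empty list yields
no calls, since absence has not been examined anywhere.

Percentages are rounded half-up to one decimal — the convention used when
such tables are reported — rather than with R's banker's rounding.

# Conservation scoring

Per-column conservation of an aligned protein family is scored with the
Jensen–Shannon divergence between the column's residue distribution
\(P\) and a background \(Q\):

\[ \mathrm{JSD}_\lambda(P, Q) \;=\; H(\lambda P + (1-\lambda) Q)
   \;-\; \lambda H(P) \;-\; (1-\lambda) H(Q), \]

with \(H\) the Shannon entropy in bits and \(\lambda = 0.5\) by default.
The score is normalized by its analytic upper bound, the binary entropy
\(H_b(\lambda)\) (1 bit at \(\lambda = 0.5\), attained only for disjoint
supports), so values lie in \([0, 1]\). Columns are scored only where the
designated reference row is ungapped, in 1-based ungapped reference
coordinates. Gaps are excluded from \(P\) rather than treated as a 21st
symbol; with `gap_penalty = TRUE` (default) the score is multiplied by the
column's non-gap fraction, so a half-gapped column scores half of its
residue-only value. Choices left open by common practice are exposed as
arguments with conservative defaults: uniform background over the 20
standard amino acids (a file-supplied background is accepted), no
pseudocounts (the strictly positive background keeps all entropies finite),
and no window smoothing (a symmetric window mean is available, off by
default).

# Expression pipeline

Counts enter as a gene-by-sample matrix with per-gene effective lengths and
a sample sheet mapping samples to tissues. The pipeline is:

1. **TPM.** Per sample, \(\mathrm{rate}_g = c_g / \ell_g\) and
   \(\mathrm{TPM}_g = 10^6 \cdot \mathrm{rate}_g / \sum_h \mathrm{rate}_h\);
   columns sum to \(10^6\) by construction.
2. **Abundance filter.** Genes with TPM below 1 in all samples (never
   expressed) or above 10,000 in any sample (implausible abundance or
   quantification artefacts) are discarded; both bounds are strict.
3. **TMM.** Between-sample scale factors by the trimmed mean of M-values:
   against a reference column (the sample whose 75th percentile of positive
   values is closest to the mean such percentile), per-gene
   \(M = \log_2 x_s / x_r\) and \(A = \tfrac12 \log_2 x_s x_r\) are computed
   over genes positive in both samples, the most extreme 30% of M and 5% of
   A are trimmed (split over both tails), and the factor is \(2\) raised to
   the precision-weighted mean of the retained M (weights
   \(1/(1/x_s + 1/x_r)\)); factors are rescaled to geometric mean 1.
   Because the pipeline applies TMM to an already length-normalized TPM
   matrix, M is taken on the matrix values directly rather than on
   library-size proportions; a column scaled by a constant \(c\) therefore
   gets its factor scaled by (approximately) \(c\). Samples with fewer than
   10 usable genes fall back to factor 1 with a warning.
4. **Sample clustering.** Average-linkage agglomeration on
   \(1 - \mathrm{Pearson}\) correlation between samples over
   \(\log_2(\mathrm{TPM} + 1)\) — the defaults of the heatmap tooling
   commonly used for such matrices. A constant sample column is an error,
   since correlation distance is undefined there. Trees export to Newick.
5. **Tissue specificity.** One tissue versus all remaining samples, per
   gene, repeated for every tissue. The test is a negative-binomial Wald
   test on TMM-scaled counts: normalized counts
   \(y = c / (\mathrm{libsize} \times \mathrm{TMM factor})\) (factors
   rescaled to geometric mean 1), group means compared on the log scale
   with the delta-method variance \((\mu + \phi\mu^2)/n\) per group and a
   pseudocount of 0.5 stabilizing low means. The per-gene dispersion
   \(\phi\) is a method-of-moments estimate from within-tissue replicate
   variance, shrunk (on the log scale, prior weight equivalent to 20
   degrees of freedom) toward a lowess mean–dispersion trend. P-values get
   Benjamini–Hochberg correction across genes within each one-vs-rest
   comparison; a gene is *enriched* in a tissue when FDR < 0.05 and
   log2 fold-change > 1, i.e. up-regulated in the focal tissue — the
   direction "enriched expression" implies.
6. **Group enrichment.** Whether a ZFP group is over-represented among a
   tissue's enriched genes is tested with a one-sided upper-tail exact
   binomial test, \(P(X \ge k)\) for \(X \sim \mathrm{Bin}(n, p_0)\), where
   \(n\) counts the tissue-enriched catalogue genes, \(k\) those in the
   focal group, and \(p_0\) is the group's share of the *full* catalogue.
   One-sided is the appropriate form for an over-representation question;
   no multiple-testing correction is applied across group-tissue
   combinations, as the intended use is a single focused test.

A dedicated differential-expression engine (DESeq2 and kin) is deliberately
not wrapped: the one-vs-rest scheme needs only a well-calibrated two-group
test, and an in-package test keeps the pipeline self-contained and
auditable. Its operating characteristics are validated directly — type-I
behaviour on null simulations and sensitivity on planted effects — rather
than by concordance with an external tool.

# Synthetic data: what it emulates, and what it does not

The generators produce every fixture the tests need, shaped like a miniature
avian ZFP survey:

* **Catalogue** (`simulate_catalogue`): default 150 genes with group
  proportions matching a 301-gene repertoire (KRAB 39/301 ≈ 13%, BTB
  43/301, SET 14, HOMEO 4, PHD 2, SCAN 1, the rest zinc-finger-only); one
  planted 21-gene cluster with 16 KRAB members on one chromosome (gaps
  5–200 kb), all other genes ≥ 400 kb apart; 1–3 isoforms per gene
  constructed so the intended canonical isoform is known *by design*
  (the designated canonical carries the effector, the maximal finger count,
  the maximal length and the smallest id, and alternative isoforms each
  violate exactly one selection rule); ~30% of isoforms carry a decoy
  domain hit above the E-value threshold. Orthologue tables are Bernoulli
  draws with per-group match rates defaulting to published per-group
  conservation shares (e.g. KRAB 0.128 vs BTB 0.953 against human).
* **Counts** (`simulate_counts`): default 2,000 genes, 6 tissues, 3
  replicates; log-normal baselines (meanlog \(\log 50\), sdlog 1),
  log-normal library-size factors (sdlog 0.3) to exercise TMM, and
  negative-binomial counts at dispersion 0.1 — a typical bulk RNA-seq
  value. Ten genes per tissue carry a planted log2 fold-change of 3.
  Planted genes are drawn from below the 60th baseline percentile:
  transcription factors, and KRAB-ZFPs especially, are low-to-moderately
  expressed, and this keeps an 8-fold up-shift inside the 10,000-TPM
  abundance filter that is part of the published filtering recipe.
* **Alignments** (`simulate_alignment`): a reference plus ten homologues
  (mirroring a one-gene, ten-species comparison), per-column substitution
  at 0.5 outside and 0.05 inside planted conserved blocks, optional gap
  injection in non-reference rows.

These fixtures validate bookkeeping, calibration and recovery — they do not
establish performance on real data. In particular, real repertoires have
correlated domain architectures and paralogue sequence similarity the
catalogue generator ignores; real expression data have batch effects,
GC/length biases and heavier-tailed dispersion than a single NB dispersion
value; and real alignments have indel structure richer than independent
per-column gaps. Passing tests therefore demonstrate that the
implementation does what the model says, not that the model captures every
property of real tissue atlases.

# Numerical choices and degenerate inputs

* Percentages round half-up to one decimal (`round_half_up`), matching
  reporting convention; R's default banker's rounding would turn 12.95 into
  12.9.
* The 250-kb merge rule is strict (`gap < max_gap`), as is the abundance
  filter on both bounds.
* TMM trimming is rank-based with stable tie resolution; identical columns
  yield factors of exactly 1.
* The JSD normalizer is the analytic bound \(H_b(\lambda)\); tiny negative
  residues from floating-point cancellation at \(P = Q\) are clamped to 0.
* All-gap columns cannot occur at reported positions (the reference row
  occupies them); an all-gap *input* column to `jsd_column` is an error.
* Dispersion estimates are floored at \(10^{-6}\); designs with no
  replicated tissue at all fall back to a common dispersion of 0.1 with a
  warning.
* Genes missing coordinates are excluded from clustering with a warning;
  catalogue genes absent from the expression matrix are excluded from
  summaries with a message.
* Every generator takes an explicit integer seed and is byte-reproducible
  at fixed configuration.

# Problem sizes

The shipped test suite and the validation script run the full chain at the
sizes above: 100 random catalogues of up to 50 genes for the cluster
oracle, 1,000 random columns for the JSD oracle, exact binomial tails for
all \(k \le n \le 200\), and ten independent seeds of the
2,000-gene × 6-tissue × 3-replicate design for sensitivity (planted
log2 fold-change 3) and null calibration. These sizes were chosen so a
complete validation runs in well under a minute on a single core while
keeping Monte-Carlo error small relative to the thresholds being checked
(≥ 90% sensitivity, ≤ 5% null call rate).

# Known limitations

* Group precedence for multi-effector genes is a convention; repertoires
  with many SCAN-KRAB genes would see their composition tables shift under
  a different precedence (the per-gene effector sets do not).
* The NB Wald test with few replicates (n = 3) relies on shrunk
  method-of-moments dispersions; it is calibrated in the simulated regime
  but is not a substitute for exact small-sample inference at marginal
  effect sizes.
* TMM on a TPM matrix measures composition shifts relative to
  length-normalized abundances; factors are not numerically identical to
  those computed from raw counts with library-size proportions.
* The conservation score treats columns independently; no phylogenetic
  weighting is applied, so dense sampling of close relatives inflates
  apparent conservation.
* Cluster naming by chromosome ordinal is stable only for a fixed
  catalogue; adding genes can renumber clusters on the same chromosome.
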