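---
title: "virolink: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{virolink: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`virolink` infers host–virus interactions from metagenome-derived sequence
data and analyses the covariation of paired viral and microbial
communities. This vignette is the package's own account of the models it
implements, the tunable parameters and why their defaults are what they
are, what the synthetic data generator does and does not emulate, and the
choices made where the design was genuinely open.

## 1. The analysis model

The pipeline assumes the standard viromics setting: viral scaffolds are
predicted upstream (with per-tool lysogeny/circularity calls supplied as a
sidecar table), microbial genomes arrive as binned MAG contigs, and raw
reads are available. Five stages follow.

**Viral populations.** Scaffolds of at least `min_scaffold_length` (default
10 000 nt — the catalogue targets complete-ish viral genomes, and 10 kb is
the conventional floor for soil virome population genomes) are clustered
greedily, longest first: a scaffold joins the first representative to which
its *global* identity reaches `derep_identity` (default 0.99), where
identity is matches over alignment length of a global alignment of the
shorter sequence onto the longer (computed with Biostrings, match +1 /
mismatch −2 / gap 10 + 0.5 per position; a 15-mer containment screen skips
hopeless pairs). This mirrors the greedy longest-first strategy of the
standard dereplication tools. Ties in length are broken by id order so the
clustering is reproducible. A population is lysogenic (or complete) if at
least one member was called so by at least one upstream tool — a logical OR
in both directions, deliberately permissive because upstream predictors
have complementary blind spots.

**Abundance.** Alignment records (tabular, or SAM/BAM where identity is
`(aligned columns − NM) / aligned columns` with soft clips excluded) are
filtered at `map_identity` ≥ 0.90, inclusive. Per-base depth comes from
interval stacking; *breadth* is the fraction of positions covered at ≥ 1×,
and a scaffold–sample combination is retained only when breadth ≥ 0.75
(inclusive — thresholds stated with "≥" are implemented with "≥"). Mean
depth is averaged over **all** positions of the scaffold, not only covered
ones: the breadth rule already guards against sparse spurious coverage, and
a full-length denominator keeps abundance proportional to recruited bases.
Normalized abundance is `mean_depth × 1e8 / library_read_count`; the
constant 10⁸ is arbitrary (any fixed constant preserves between-sample
ratios, which is all the downstream statistics use) and chosen to give
O(1)–O(100) values at typical library sizes.

**Spacer recovery.** Given per-MAG direct repeats, reads are scanned on
both strands for DR occurrences at Hamming distance ≤ `dr_max_mismatch`
(default 3). Substitution-only distance was chosen over edit distance
because read-level DR hits in short reads are overwhelmingly substitution
errors, and Hamming matching is deterministic and exhaustively testable
against a sliding-window oracle. Sequences between consecutive same-strand
hits of length 15–60 nt are emitted as spacers (the 60 nt ceiling is the
conventional upper bound for type I–III arrays; the 15 nt floor suppresses
degenerate inter-hit fragments, which real arrays do not produce).
Reverse-strand spacers are reported on the forward orientation of the
array, and dereplication at 100% identity canonicalizes each spacer to the
lexicographically smaller of itself and its reverse complement so a spacer
never counts twice across strands.

**Linkage.** Four independent evidence channels:

* *CRISPR (spacer → protospacer).* Spacers are aligned to viral genomes
  under the short-query scoring dialect (word size 7, match +1, mismatch
  −3, gap open 5, extend 2). The alignment itself is the exact optimal
  local alignment (computed with Biostrings) gated by a shared-7-mer word
  check — a seeded heuristic can only ever find alignments containing a
  word hit, and for 15–60 nt queries exact DP is cheap, so exactness costs
  nothing and makes the oracle-equivalence property testable. Evidence
  requires similarity = alignment length × identity / query length ≥ 0.80
  (inclusive). No PAM check is applied. Hits are searched on both strands.
* *ONF (d2\*).* Word counts at `k = 6` on the forward strand; expected
  counts from a Markov model of order `d2star_order` estimated from the
  same sequence by maximum likelihood; d2\* as in the README formula, with
  words of zero expected count in either profile skipped. All (host,
  virus) pairs with d2\* **strictly** below 0.2 are reported (the
  threshold is a published operating point, and all-pairs reporting rather
  than best-hit-only is deliberate: multiple hosts per virus are
  biologically expected; a `best_only` flag exists).
* *tRNA.* A link requires a viral tRNA exactly identical over its full
  length to a host tRNA, on either strand. All qualifying (host, virus)
  pairs are reported.
* *Homology.* Viral genomes are BLASTed (command-line BLAST+, task
  `blastn`) against MAG contigs; HSPs are aggregated per (virus, MAG) with
  overlapping query blocks merged before computing viral-contig coverage
  and length-weighted pooled identity. Evidence requires coverage ≥ 0.75,
  identity ≥ 0.70, bit score ≥ 50 and E ≤ 0.001. A virus that is itself a
  member contig of the MAG is excluded as a potential binning artifact
  unless flagged upstream as a defined prophage region inside a longer
  scaffold.

Interactions are unique at (host, virus, method) granularity: the same
pair supported by two channels counts twice, matching per-method totals
as they are conventionally reported; per-virus host counts are unique
(host, method) edges.

**Community statistics.** Shannon–Wiener diversity uses the natural log,
matching Pielou's evenness convention `J = H / ln S` (undefined at S = 1,
reported `NA`). Bray–Curtis, PCoA (eigendecomposition of the
double-centered Gower matrix; negative eigenvalues reported, axes only for
positive ones), one-way PERMANOVA by site (vegan's `adonis2`, seeded,
`p = (1 + #{F* ≥ F}) / (1 + 999)`), and BioENV (vegan, exhaustive subsets
of z-scored variables, Euclidean distances, Spearman correlation; refused
above 15 variables unless overridden). The BioENV method itself provides
no p-value, so significance of the best subset is fixed here as a seeded
Mantel test (Spearman, 999 permutations) — a concrete, reproducible
procedure standing in for the unspecified one.

**Symmetric CoCA** is authored in the package from its definition: both
matrices are converted to proportions and chi-square-transformed as in
correspondence analysis, using *common* site weights taken as the mean of
the two matrices' relative row totals (the pooled-versus-mean convention
is not fixed in the literature we follow; the mean is symmetric in the two
communities and is recorded in the output). The SVD of the cross-product
of the transformed matrices yields paired axes maximizing the covariance
of site scores; eigenvalues are squared singular values, "percent common
variance" is each eigenvalue over their total, and each community's
explained total inertia is the Frobenius mass of its transformed matrix
projected on the reported axes. Significance permutes the rows of the
second matrix and recomputes the sum of the leading `n_axes` eigenvalues,
with the add-one rule so p is never 0.

## 2. The synthetic community generator

The generator exists so that every stage can be tested against *planted,
machine-readable truth* without external data. It emulates:

* host genomes as order-1 Markov chains with per-host random transition
  matrices (symmetric Dirichlet, concentration 5) — enough compositional
  idiosyncrasy to give each host a distinguishable oligonucleotide
  signature, as real genomes have;
* CRISPR arrays serialized `DR, S1, DR, …, DR` (n spacers ⇒ n + 1 DR
  copies), DR length 29 nt and spacer lengths 25–45 nt (typical type I
  arrays), spliced into hosts; spacers are rejection-sampled so they never
  contain the DR on either strand;
* viral genomes carrying planted protospacers with an *exact*, seeded
  number of substitutions; shared tRNA genes planted verbatim; prophages
  embedded verbatim (no att-site duplication — homology linkage only needs
  sequence identity); composition-coupled viruses drawn from order-2
  models trained on their host;
* single-end shotgun reads with uniform starts, random strand and i.i.d.
  substitution errors, Poisson read counts proportional to
  abundance × genome length. The default read length is 200 nt (merged
  short-read pairs), long enough that a full DR–spacer–DR unit (≤ 103 nt
  at the default geometry) is spanned with generous margin, so planted
  spacer recall is limited by coverage, not read geometry, and at the
  default 20× the probability of missing any planted spacer is
  negligible;
* paired abundance matrices with site structure: per-site log-normal
  population profiles (between-site sd 1.5, within-site replicate sd 0.1 —
  strong site differentiation with tight replicates, the regime in which
  site-level ordination statistics are meaningful), a configurable linear
  microbial→viral coupling with optional log-normal noise, and
  environmental covariates of which temperature and sodium track the site
  means while pH and moisture are pure noise.

It deliberately does **not** emulate: indels or quality-score structure in
reads, paired-end geometry, strain variation, plasmids, att-site biology,
real taxonomic signal, or any generative claim about the real communities
the study design is modelled after — the site-effect and coupling models
are acceptance scaffolding. Consequently, passing the planted-truth tests
shows the *algorithms* are correct (exact channels attain precision =
recall = 1 on noiseless worlds by construction), not that the thresholds
are well-calibrated for any particular real dataset.

## 3. Numerical choices and degenerate inputs

* All generators are pure functions of their arguments including the seed;
  sub-streams are derived deterministically from a master seed.
* Thresholds written "≥" are inclusive (mapping identity, breadth,
  protospacer similarity, homology cutoffs); the d2\* threshold is strict
  ("< 0.2").
* d2\* of two all-zero centered profiles is undefined and returned as `NA`
  with a warning; words with zero expected count in either profile are
  skipped.
* `welch_compare` on two constant equal groups returns t = 0, p = 1.
* Zero-length alignments are dropped with a warning; all-zero abundance
  rows stay zero and are flagged; distances involving all-zero samples are
  `NA`.
* Alignment tie-breaks (equal score): lowest subject coordinate, then the
  + strand. Dereplication ties in length: lexicographically smaller id.
* Permutation p-values always use the add-one rule, so the smallest
  attainable p at 999 permutations is 0.001.

**The d2\* Markov order.** The function default is order 2, the
conventional operating point of alignment-free host matching at k = 6 on
real genomes. There is, however, a structural interaction with the
generator worth understanding: d2\* normalized at order *r* correlates
only the k-mer structure that order-*r* models do *not* capture. A
synthetic virus generated *from* a host-trained order-2 model has no
reproducible structure beyond order 2, so at normalization order 2 (or 1,
when hosts are order-1 chains) its centered residuals are pure sampling
noise and carry no host signal — the dissimilarity sits near 0.5 for every
host. At order 0 the shared di-/trinucleotide signature survives
normalization and the source host is recovered essentially always, with
true-pair d2\* well under the 0.2 threshold at realistic lengths. The
package therefore measures ONF discrimination (and runs the ONF channel on
synthetic worlds) at order 0, while keeping order 2 as the function
default for real data, where genomes carry structure far beyond any fitted
low-order chain. The order used is always recorded in the evidence detail
field.

## 4. Problem sizes used in the shipped analyses

The test suite and the acceptance analysis run, by choice, at desk scale:
a planted world of 20 hosts (20 kb) and 30 viruses (~10–15 kb) with 10
CRISPR, 5 tRNA, 3 prophage and 6 composition-coupled links under
error-free 20× reads; d2\* oracle agreement on 200 nt pairs at k = 3;
ONF discrimination with 10 hosts of 100 kb and 50 replicate 40 kb viruses;
PERMANOVA calibration over 200 null datasets of 12 samples × 15
populations at 999 permutations; CoCA constructions on 12 × 20 matrices.
These sizes make every property checkable in minutes while keeping each
statistic in its intended regime.

## 5. Known limitations

* Dereplication compares forward strands only; a population split across
  strands would not merge (synthetic and most assembler outputs are
  strand-consistent; flip candidates upstream if needed).
* The homology channel shells out to BLAST+; without `blastn` on the PATH
  it stops with an informative error rather than approximating.
* BioENV's exhaustive search is exponential in the number of variables and
  intentionally refuses > 15.
* Predictive-mode (cross-validated) CoCA is not implemented; only the
  symmetric mode with a permutation test is provided.
* The internal read simulator produces single-end, substitution-only
  reads; it is a test harness, not a sequencing-error model.
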