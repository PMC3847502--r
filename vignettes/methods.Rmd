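---
title: "Methods: transcript groups, enrichment, motif density and qPCR statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript groups, enrichment, motif density and qPCR statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawlac)
```

`strawlac` implements the statistical core of a three-condition
carbon-source transcriptome comparison for cellulolytic fungi: a glucose
reference and two inducing substrates (lactose and a lignocellulosic
material such as pretreated wheat straw). This vignette documents the
models, the tunable parameters, the numerical conventions, and the design
choices that were genuinely open — and what the synthetic-data tests do
and do not demonstrate about real data.

## Transcript-group classification

All expression values are log2 scale. For conditions X and Y with
replicate vectors per gene, the fold change is the difference of log2
condition means (a ratio of geometric means on the linear scale), and the
p-value comes from a per-gene two-sample test.

A gene is *upregulated* on substrate X versus glucose when

* fold change ≥ `fold_change_min` (default 2, i.e. log2 difference ≥ 1), and
* p < `p_max` (default 0.05, unadjusted).

The seven labels partition the gene universe: A (up on wheat straw only),
B (up on lactose only), C/D/E (up on both), CONSTITUTIVE, NONE.

Three conventions here were open and are settled as follows:

* **The C/D/E split.** "Stronger upregulated on one substrate" is not a
  quantitative criterion by itself. We apply the *same* rule to the direct
  wheat-straw-versus-lactose contrast: C when that contrast passes
  ≥ `wl_fold_min`-fold (default 2) at p < `p_max` in favour of wheat
  straw, D for lactose, E otherwise. This is symmetric with the primary
  criterion and needs no new thresholds.
* **The constitutive band.** "Comparable level on all three conditions"
  is implemented as: all three condition means above the expression
  floor, and *every pairwise* linear ratio of condition means inside
  [1/1.4, 1.4], boundary inclusive (a closed interval; a gene exactly at
  1.4-fold is constitutive). The band is applied to replicate means, not
  per-replicate values. Constitutive assignment takes precedence over
  A–E; since the band (1.4) is below the fold cutoff (2) no gene can
  satisfy both upregulation and the band anyway.
* **"Expressed".** Low-replicate array studies rarely state a detection
  cutoff. We use an explicit log2 floor, `expression_floor` (default
  1.0), configurable because it is a convention, not an estimate.

**Default test.** The per-gene test is the pooled-variance two-sample t
on log2 values, with Welch and label-permutation alternatives. With n = 2
replicates per condition the t-test has 2 degrees of freedom and little
power; the generator therefore supports 2–4 replicates and the
recovery benchmarks use n = 3. No multiple-testing correction is applied
by default — the raw p < 0.05 convention of the array era —, and the
enrichment screen offers an optional Benjamini–Hochberg column for users
who want it.

**Degenerate inputs.** When both groups have zero variance the t
statistic is undefined; we define p = 1 for equal means and p = 0
otherwise, so a noiseless 4-fold difference is called (this makes the
noiseless recovery benchmark exact) while identical vectors are not.

## Category enrichment

Each (category, group) pair is tested with a 2×2 Pearson chi-square test
(in group / not × in category / not), 1 df, against the background of
*all annotated genes* (overridable). Genes carrying several category
codes count once per code. The Yates correction is off by default; when
any expected cell is below 1 the result is flagged and a Fisher exact
p-value is attached. The implementation is the closed-form
N(ad−bc)²/(row·col products) identity; the test suite checks it against
the Σ(O−E)²/E definition over an exhaustive scan of small tables and
against `stats::chisq.test`.

## Hierarchical clustering and heat maps

Clustering operates on the gene × condition matrix of log2 means (what
the heat maps display), not on replicate-level values. Distances are
Euclidean; linkage defaults to average (UPGMA) and is configurable —
the original desktop tools of this field do not document their linkage,
so the choice is surfaced rather than hidden. Genes are sorted
lexicographically by id before clustering, which makes the tree invariant
to input row order and turns ties deterministic. Duplicate profiles are
legal and merge at height 0. Trees serialize to Newick (ultrametric;
leaf depth = half the root merge height). Heat maps use the 0–16 log2
colour scale (dark blue → dark red); values are clipped for display only,
and a companion TSV carries the unclipped values in leaf order so figure
content is testable without pixel comparison.

## Promoter motif density

Promoter windows are the L bases (default 1000) immediately 5′ of the
translation start, excluding the ATG; internally coordinates are 0-based
offsets from the window start, reported also as −L..−1 offsets. For
minus-strand genes the window is the reverse complement of the bases
immediately 3′ (genome-forward) of the start coordinate; truncation at
contig edges is recorded, not an error.

Scanning is greedy left-to-right with overlap prevention: a candidate
match (either strand; `+` wins coordinate ties) is accepted only if it
does not overlap a previously accepted match, across strands. A sequence
`N` matches only a motif `N`. Both-strand scanning is the default for
GGCW₄, a motif bound by a zinc binuclear cluster factor with no intrinsic
strand preference; single-strand scanning is available, and the
genome-wide reference census is taken as *input* so the null matches
whatever convention produced it.

**Density null.** The claim "one site about every 1595 bp genome-wide"
(33 Mbp / 20692 sites; ~1500 at the nearest-500 rounding) is
operationalized as a Poisson null for per-window counts with
λ = L / spacing (0.63 for L = 1000). The exact reference distribution of
the Anderson–Darling statistic against such a discrete null is not
available in closed form, so the test is Monte Carlo and exact by
exchangeability: draw `n_sim` replicate count sets from Poisson(λ),
compute the tie-adjusted (midrank) two-sample Anderson–Darling statistic
of each set — observed and simulated alike — against the pool of the
others, and report p = (1 + #(T_sim ≥ T_obs)) / (n_sim + 1). `n_sim` is
required ≥ 999 so the p floor is ≤ 0.001. The statistic itself is the
Scholz–Stephens tie-adjusted version, which the suite verifies against an
independent reference implementation on frozen fixtures; calibration
(type-I ≈ 0.05) is verified by simulation at 200 trials.

## qPCR statistics

Amplification efficiency comes from the dilution-series slope,
E = 10^(−1/slope) (E = 2 ⇔ slope −3.32); non-negative slopes are rejected
as invalid assays. Relative expression uses the efficiency-corrected
ratio normalized to a reference gene (default *tef1*) and a calibrator
sample (default a glucose 8 h culture), computed from replicate-mean Cts
with a bootstrap standard error over replicate combinations.

Significance of R ≠ 1 uses a fixed-reallocation randomization test:
replicate observations are reallocated between sample and calibrator
groups, target and normalizer Cts of the same reaction moving *together*
(they share a cDNA), and the two-sided p is the fraction of reallocations
at least as extreme on |log R|, with the (1+c)/(n+1) correction. A
consequence worth stating: with only 3+3 replicates there are
choose(6,3) = 20 distinct allocations and the attainable p floor is
2/20 = 0.1 — the test *cannot* reject at 0.05. The standard design of two
independent runs × three replicates (6 per group, 924 allocations) is
what the power guarantees refer to; the test suite asserts both the 3+3
floor and ≥95% power against an 8-fold change under the full design.

The Welch unequal-variance t-test is provided alongside (with the same
zero-variance conventions as the DE t-test), and biomass dry weight is
(protein − substrate control) / 0.35 g·g⁻¹, floored at zero, the
conversion constant being a configurable default rather than a hard-coded
fact.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions of the benchmarks: three conditions, 2 replicates
(3–4 available where test power needs them), baseline log2 level 6 ± 1
between genes, planted induction of 2 log2 units, constitutive jitter
uniform ±0.2 log2 (inside the ±0.485 band edge), i.i.d. Gaussian
replicate noise of sd 0.25 log2 units, NONE genes at half the expression
floor, qPCR Ct noise 0.15 cycles, and promoter site counts Poisson at the
1/1500 bp genome density unless planted explicitly. Promoter backgrounds
are drawn from a configurable base composition (uniform 25% by default)
with every motif-matching window rejected and resampled before exactly
the requested non-overlapping sites are inserted and verified by
re-scanning.

What it deliberately does **not** emulate: probe-level microarray
intensities, normalization artifacts, correlated noise between genes,
batch effects, annotation errors, or promoter sequence composition beyond
base frequencies. Passing the planted-truth benchmarks therefore shows
that the *statistical machinery* recovers what its model assumes — not
that the model captures every property of real arrays. In particular the
Gaussian log2 noise model was chosen because it is standard for
log-intensity data and sufficient for type-I/power testing, not because
real noise is exactly Gaussian.

**What the benchmarks compute** (all regenerated by the test suite and
`scripts/acceptance.R`, never stored): planted transcript-group recovery
at 1000 genes × 3 replicates (≥95% with noise 0.25; exactly 100%
noiseless — the residual confusions with noise are constitutive genes
whose jittered means cross the 1.4-fold band edge and fall to NONE);
type-I calibration of the chi-square and Anderson–Darling tests at 200
null trials against 99% binomial bounds of 0.05; randomization-test power
at 200 simulations; and oracle equivalence of the scanner (10⁴ random
sequences vs a brute-force sliding window), the chi-square (exhaustive
small tables), average linkage (O(n³) re-agglomeration, n ≤ 12) and the
Welch t (hand-computed case). These problem sizes were chosen to give
stable Monte-Carlo estimates at desk scale.

## Known limitations

* Headline gene counts of any real study depend on the upstream
  normalization of the deposited arrays, which is out of scope here; the
  package starts from an expression matrix.
* The classification inherits the weaknesses of unadjusted per-gene
  t-tests at n = 2; use n ≥ 3 and/or the permutation method when the
  design allows.
* FunCat parent-term propagation, GO term graphs and gene-set permutation
  methods (GSEA-style) are not implemented; enrichment is per flat code.
* The motif module scores exact IUPAC consensus matches only — no
  position weight matrices, no conservation filtering.
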