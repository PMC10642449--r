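---
title: "Methods: quantification, missingness and moderated testing for myelin LFQ proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, missingness and moderated testing for myelin LFQ proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelinlfq)
```

This vignette is the package's own account of the statistical machinery: the
models and their assumptions, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## iBAQ quantification

A protein's iBAQ value is its summed peptide intensity divided by the number
of theoretically observable tryptic peptides. The digest is fully tryptic
with zero missed cleavages: cleavage after every K or R unless the next
residue is P. "Observable" applies a length window, by default 7–30
residues. That window is the common convention for iBAQ; upstream search
engines do not publish theirs, so it is a configurable parameter
(`count_observable(min_len, max_len)`), not a claim about any particular
search. Relative abundance shares are iBAQ values expressed as a percentage
of the summed iBAQ over the reported universe; they are scale-invariant, and
in peripheral myelin the top three proteins (MPZ, MBP, periaxin) are
expected to hold roughly 60–75% of the total.

Protein-level input can be either precomputed per-sample iBAQ columns (the
usual path from a search-engine protein-groups table) or a peptide-intensity
table plus FASTA for self-computed iBAQ (`ibaq_from_peptides()`).

## Detection filter

Before any statistics, a protein must be detected — non-missing — in at
least `min_detected` (default 2) of the replicates of at least one group.
Requiring detection in *both* groups would delete exactly the one-group-only
proteins that are biologically interesting (proteins present only in young
or only in old nerves), so the universe is "detected in ≥ 1 group" and each
protein is labelled `both`, `<group>_only`, or `excluded`. This is an
interpretive choice and is surfaced as a label column rather than silently
applied.

## Missingness model

For each pairwise comparison, every protein's presence pattern is sorted
into one of four classes:

* **COMPLETE** — no missing values.
* **MNAR** — one group is depleted (≥ `mnar_min_missing` missing) while the
  other is fully observed (≥ `mnar_min_present_other`). Such one-sided
  patterns are treated as intensity-dependent left-censoring reflecting a
  real group difference, and are imputed by **MinDet**: the missing cell
  takes the minimum observed value of its own sample column.
* **MAR** — scattered dropout, at most `mar_max_missing` missing per group
  and not MNAR; imputed by **knn**: the mean of the k nearest protein rows'
  values in that column, with Euclidean distance over jointly observed
  columns rescaled by the overlap, neighbours required to be observed in the
  target column, and ties broken by row order for determinism. Default
  k = 10, the canonical knn-imputation default. If fewer than k candidates
  exist the available ones are used and a warning is emitted.
* **FILTERED** — fewer than 2 observed values in both groups, plus any
  remaining asymmetric pattern (e.g. 2 observed vs 1 observed) that supports
  neither a censoring interpretation nor a two-sample test. These rows are
  dropped and recorded in the audit table.

The published formulation of this rule is phrased for five replicates per
group; the experimental designs this package emulates have three. The rule
is therefore parameterized (`missingness_rule()`), and the shipped n = 3
default is the proportional transcription: MNAR = missing in ≥ 2/3 of one
group and present 3/3 in the other; MAR = ≤ 1 missing per group; FILTERED as
above. The classifier is tested against an exhaustive enumeration of all 2⁶
presence patterns, so the precedence order (COMPLETE, then the
both-groups-thin filter, then MNAR, then MAR, then the fallback filter) is
pinned down exactly; no pattern can receive two labels.

Imputation operates on log2-transformed intensities — the scale on which
left-censoring is approximately additive and on which the knn distances are
meaningful — and never alters an observed cell. Every imputed cell is logged
with its mechanism and value.

## Normalization and differential testing

Quantile normalization is applied after imputation (it requires a complete
matrix): each column's sorted values are replaced by the across-column mean
of sorted values; ties map to the average of the reference values at the
tied ranks. The implementation is checked against limma's
`normalizeQuantiles` in the tests.

The unpaired comparison uses an empirical-Bayes moderated t-test. Sample
variances are modelled as draws of $s_0^2 \cdot F(d_f, d_0)$; $(d_0, s_0^2)$
are estimated by matching the mean and variance of $\log s^2$ through
digamma/trigamma moments, inverting the trigamma numerically (Newton, the
estimate initialised at $0.5 + 1/y$). When the empirical spread of
$\log s^2$ does not exceed the sampling spread implied by $d_f$, $d_0$ is
reported infinite and every posterior variance equals $s_0^2$. The
moderated statistic uses the posterior variance
$s^2_{post} = (d_0 s_0^2 + d_f s^2)/(d_0 + d_f)$ and is referred to a t
distribution with $d_f + d_0$ (possibly fractional) degrees of freedom;
tail probabilities come from R's `pt`, i.e. the regularized incomplete
beta. At $d_0 = 0$ the statistic reduces exactly to the ordinary pooled t;
at $d_0 = \infty$ to a z-like statistic with common variance. Both limits
and the full path are verified against limma on shared data, and the test's
type-I error and realized FDR are checked by simulation.

The paired comparison (crush vs intact within mouse) is a one-sample t-test
on within-pair log2 differences with $d_f = n_{pairs} - 1$.

Conventions: fold changes are second group minus first (old − young,
crush − intact); tests are two-sided throughout, since both directions of
regulation are reported; zero-variance proteins are flagged `degenerate` and
given p = 1 rather than dropped or called significant — conservative and
auditable.

False-discovery control offers BH (default) and Storey q-values; Storey's
$\hat\pi_0$ comes from the $\lambda$-grid smoother (cubic smoothing spline,
3 df, evaluated at the largest $\lambda$, clipped to (0, 1]; for fewer than
100 p-values the smoother is replaced by the minimum of the grid estimates,
which is more stable there). The differential criterion reported by the
pipelines is q < 0.05. The original aging analysis used an empirical-null
local-FDR tool for this purpose; that decomposition is deliberately not
re-implemented, the q < 0.05 criterion stands in for it, and the deviation
is echoed in every report header — differential lists may differ marginally
at the margin of significance.

## Enrichment statistics

The **ground probability** is the fraction of the whole tested universe
meeting a regulation criterion (e.g. log₂FC < 0 and q < 0.05). The
**binomial subset test** then asks whether a named subset (the myelin
proteome after injury) meets the criterion more often than that ground
probability: a one-sided exact binomial tail $P(X \ge k)$, computed via the
log-scale tail of `pbinom` so that p-values of order 10⁻⁸⁰ remain
representable. One-sided "greater" is deliberate: the scientific claim is
"more regulated than the proteome at large". Because the ground probability
is estimated from a universe that contains the subset, the test is slightly
conservative when the subset is a large share of the universe; the null
calibration test uses a subset that is ~8% of the universe, where the effect
is negligible.

Fisher-exact over-representation intersects each gene set with a
user-supplied background (the proteome quantified in the experiment — not a
whole-genome background), tabulates the 2×2 table, and reports the
one-sided enrichment p unadjusted, mirroring the p ≤ 0.1 call criterion of
the pathway platforms this emulates, with a BH-adjusted column alongside.
Annotation content is a user input; no database is queried.

Cohen's d uses the pooled standard deviation. Accession normalization for
cross-dataset joins uppercases and strips isoform suffixes, with an
injectable mapping table, since silent join failures are the main hazard in
comparing two deposited proteomes.

## Image quantification

Three mask-based measures for two-channel (collagen / myelin)
immunofluorescence, all functions of mask membership only: integrated
density per positive pixel; coverage of the collagen mask by the myelin
mask (denominator = collagen-positive area, matching the "percentage of the
collagen-positive area overlapping myelin" reading; the myelin-area
denominator is available behind a flag); and the doubly-normalized overlap
intensity — integrated collagen density in the overlap ÷ coverage percent ÷
myelin-positive area, in that fixed order. The compound measure's units are
arbitrary; only ratios between groups are meaningful. Masks are inputs: a
fixed-threshold helper is provided, but the original segmentation macros are
unpublished, so absolute intensities from any particular study are not
reproducible and no adaptive thresholding is pretended.

## The synthetic-data generator

`simulate_lfq_experiment()` draws protein baseline abundances from a
log-normal (default meanlog = log 10⁶, sdlog = 1.5 — the heavy right skew
of iBAQ data), pins the leading proteins to expected shares of 40/17/6% of
total signal (the dominance structure of peripheral myelin), applies true
log2 fold changes to a `de_fraction` of non-dominant proteins, multiplies
in log-normal within-group noise (default CV 25% — within-group CVs are not
published for the real data; this default is a plausible LFQ value and is
documented as such, not as an estimate), and finally applies two dropout
mechanisms per cell: MNAR first, a Bernoulli with logistic probability
decreasing in log2 intensity (`mnar_midpoint` = 16, `mnar_steepness` = 1.2
per log2 unit, giving a few percent missingness concentrated at low
abundance), then MAR uniformly at `mar_rate` = 2% on the survivors. Every
missing cell carries exactly one mechanism label in the returned truth. All
randomness flows from one seed; identical configuration gives bit-identical
output.

`simulate_injury_experiment()` emulates the paired crush design: one intact
and one crushed sample per mouse, a shared per-mouse multiplicative effect
(sdlog 0.1) that makes pairing informative, and *per-protein Bernoulli*
downregulation at `down_fraction` inside a designated myelin block and
`down_fraction_other` outside it. Bernoulli rather than exact-count
assignment matters: it makes the regulated count in any subset binomial,
which is the sampling model the downstream enrichment test assumes, and it
is what lets the null calibration (equal rates inside and outside the
subset) produce approximately uniform binomial p-values.

`generate_image_fixture()` builds annular "myelin rings" and collagen
strands that are disjoint from, or strictly contained in, the ring mask, so
coverage is 0% or 100% by construction and truth masks are pixel-exact.

What the generator does **not** emulate: peptide-level variation and
peptide-to-protein roll-up, correlated protein co-regulation, batch or
run-order effects, non-log-normal contamination, or the spatial texture of
real micrographs. Passing tests therefore demonstrate that the pipeline
recovers truth under its own stated sampling model — calibration, recovery
and oracle-equivalence — not that any particular biological dataset would
yield particular numbers.

## Problem sizes and numerical choices

The test suite and the acceptance script use 400–5,000 proteins, 3 samples
per group (5 mice per arm for paired designs), and 5–100 simulation seeds
per property — sizes at which Monte-Carlo bands (e.g. type-I error within
0.05 ± 0.01, prior d₀ within ±25%) are comfortably discriminating while the
whole suite runs in minutes on one core. Tie-breaks (knn neighbours, rank
ties), degenerate inputs (zero variance, empty masks, all-missing columns)
and scale tags (raw/log2/normalized, enforced between stages) are all
handled explicitly and tested; errors name the offending protein, sample or
stage rather than failing silently.

## Known limitations

* The q < 0.05 criterion stands in for the original empirical-null local
  FDR; borderline differential calls can differ.
* The knn imputer is O(rows × targets) by brute force — fine for proteome
  scale (10³–10⁴ rows), not for much larger matrices.
* The binomial subset test inherits mild conservatism when the subset is a
  large fraction of the universe used for the ground probability.
* Spearman p-values use the t approximation, adequate for n in the tens to
  hundreds; no exact permutation p is computed at package level.
* The image module quantifies given masks; it does not segment.
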