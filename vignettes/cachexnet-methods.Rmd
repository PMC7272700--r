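---
title: "cachexnet: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cachexnet: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical machinery inside cachexnet — what
each stage assumes, which tunable parameters matter, how the synthetic
data generator works and what passing tests on it do and do not show, and
where the design was genuinely open and a choice had to be made.

## The setting

The package targets paired bulk mRNA and miRNA count matrices from a
small two-group design — typically a handful of control animals against a
slightly larger case group, as in rodent models of cancer cachexia where
skeletal muscle is profiled in tumor-bearing versus control animals. The
scientific questions are layered: differential expression; the
*stability* of each gene's response across heterogeneous case animals;
regulatory signal in promoters and gene sets; miRNA–target coupling
consistent with repression; and tissue-level disorganization in
histology.

## Normalization

Counts are made comparable with median-of-ratios size factors: for sample
$s$, $\hat{sf}_s = \mathrm{median}_g\, (k_{gs} / (\prod_{t} k_{gt})^{1/n})$
over features with nonzero counts in every sample, rescaled so the
factors' geometric mean is 1. The geometric-mean centering keeps the
normalized scale comparable across runs; it also means the normalized
scale inherits a global rescaling of the raw counts (relevant to the
pseudo-count below). Features detected in no or few samples carry no
information about library depth; if no feature is nonzero everywhere, the
function asks for a pre-filter rather than silently extrapolating.

Per-sample fold changes are ratios against the control-group mean with a
pseudo-count $\varepsilon$ added to both numerator and denominator.
$\varepsilon = 1$ normalized count by default: it bounds fold changes for
features touching zero and treats both orientations symmetrically. Since
the data's zero-handling convention is not otherwise pinned down, the
pseudo-count is exposed everywhere (`pseudo_count`); note that with
$\varepsilon > 0$ fold changes are *not* invariant to globally rescaling
the counts (pure ratios are).

CPM is $10^6 \cdot k_{gs} / \sum_g k_{gs}$; RPKM additionally divides by
the feature length in kb. The expressed-feature floor keeps features with
a raw count strictly above 32 in at least one sample. The same rule
serves two roles: the miRNA expression filter, and (applied to the mRNA
arm in the pipeline) the definition of the detected-gene universe —
analysis stages that are noise-limited by near-undetectable features
(clustering, enrichment backgrounds) operate on detected features only.
Abundance classes use type-7 (linear interpolation) quartiles, the most
common default; values below Q1 are `low`, above Q3 `high`.

## Differential expression

Each feature is modeled as negative binomial with variance
$\mu + \alpha\mu^2$. The test is a Wald test on
$\log_2(\bar{x}_{case}/\bar{x}_{ctrl})$ (pseudo-counted), with a
delta-method standard error that propagates
$\mathrm{Var}(x_{gs}) = \mu/sf_s + \alpha\mu^2$ through the group means,
and a two-sided normal reference.

The dispersion is the pooled within-group moment estimate
$\hat\alpha_g = \max\{(s^2_g - \bar\mu_g)/\bar\mu_g^2,\ 10^{-8}\}$,
**floored at the genome-wide median** of the per-feature estimates. The
floor is the load-bearing choice: with 4 + 6 samples the raw moment
estimate is so noisy that plugging it in makes the test anti-conservative
(about 8% of null features at p < 0.05 in our calibration runs), while
borrowing strength from the genome-wide ensemble — the same idea as the
"maximum" sharing mode of early NB differential-expression tools — brings
the type-I rate to the nominal 5%. The floor can be disabled
(`moderate_dispersion = FALSE`) for data with genuinely heterogeneous
dispersions and larger n. The $10^{-8}$ lower bound keeps Poisson-like
features numerically stable. This is intentionally *not* a re-implementation
of any specific published tool: no shrinkage of fold changes, no outlier
filtering — the downstream analyses need calibrated DE calls, not
bit-compatibility.

The DEG call combines an effect-size threshold with significance:
$\max(FC, 1/FC) \ge 1.5$ and BH $q \le 0.05$, both inclusive. Methods
sections and figure legends in this literature state the significance
field inconsistently (raw p vs FDR); both are supported
(`use_fdr = FALSE` switches to raw p) and the FDR form is the default as
the more conservative, multiplicity-aware reading. The BH step-up is
implemented in-package (`benjamini_hochberg()`) because it is part of the
method under test; the test suite cross-checks it against both a
brute-force transcription of the definition and `stats::p.adjust`.

## Stability, clustering, and the near-control subgroup

The stability measure is the percent coefficient of variation of a gene's
per-sample fold changes within the case group:
$\%CV_g = 100\,\widehat{\sigma}(FC_{g,\cdot})/\overline{FC}_{g,\cdot}$,
with the sample (n − 1) SD — at 6 case samples the variability estimate
should not be biased downward — while row z-scores for clustering use the
population SD, the usual standardization convention. Both are
configurable (`sd_type`).

Clustering standardizes $\log_2(\text{normalized} + 1)$ expression of the
DEGs (the heatmap convention; the log stabilizes the mean–variance
relationship so high-count genes do not dominate distances), then runs
k-means with Euclidean distance, many random restarts, and selection of
the restart with the lowest within-cluster sum of squares. The restart
count is exposed (`n_init`; the protocol this emulates used 10,000 —
defaults here are smaller because well-separated blocks converge long
before that, and the tests document the sizes they use). Cluster labels
are arbitrary in k-means, so they are renumbered by descending mean log2
fold change to make "cluster 1 = most up-regulated" stable across runs.

The near-control case subgroup is reconstructed as: average-linkage
hierarchical clustering of the case samples on Euclidean distance over
DEG z-scores, cut into two branches, taking the branch whose centroid is
closest to the control centroid. The source protocol names only
"Euclidean distances", so linkage and cut are genuinely open; average
linkage is robust for a handful of samples, and the two-branch cut
matches the near-control/far-from-control dichotomy the subgroup concept
implies. Re-running DE on controls plus that subgroup and intersecting
with the full DEG list yields the uniformly regulated reduced set
(`subgroup_degs()`).

## Promoter motif enrichment

Promoters are the −300..+50 window around the TSS, strand-aware with
half-open 0-based arithmetic; windows clipped by a contig edge are padded
with N and flagged. Motifs are position frequency matrices (JASPAR text
formats supported), converted to log-odds with a pseudocount of 0.1 per
cell — small enough to respect sharp columns, nonzero to keep zero counts
finite — against background base frequencies (uniform by default,
estimable from the pool). The score of a sequence is the best log-odds
placement over both strands and all offsets, min–max rescaled to [0, 1]
by the motif's worst/best attainable sums, so 1 means "contains the
consensus" for any motif; N positions contribute the column's background
expectation. The vectorized scanner is verified against an
exhaustive-placement oracle in the tests.

Enrichment compares the mean best-hit score of a foreground promoter set
against a CpG-matched background:
$z = (\bar{s}_{fg} - \bar{s}_{bg}) / (\hat\sigma_{bg}
\sqrt{1/n_{fg} + 1/n_{bg}})$, one-sided for over-representation. Promoter
scanners of this family classically use $\hat\sigma_{bg}/\sqrt{n_{fg}}$,
which is the limit of our form when the background is the whole promoter
repertoire ($n_{bg} \gg n_{fg}$); with matched backgrounds of comparable
size that limit form ignores the background mean's own sampling noise and
measurably inflates the type-I rate, so the two-sample denominator is
used. Calibration also depends on the foreground being large enough for
the CLT — with DEG promoter sets in the hundreds this holds; below a few
dozen sequences the right-skew of best-hit scores makes the one-sided
tail slightly anti-conservative. Occurrence fractions ("% of sequences
with at least one site") use a score cutoff of 0.8, configurable.

CpG matching samples, for each foreground promoter, a background promoter
whose CpG-dinucleotide fraction differs by at most ±0.02 (without
replacement, tightest-constrained first). The tolerance is tight enough
that CpG-island status cannot confound enrichment, loose enough that
pools a few times the foreground size can be matched.

## Gene-set over-representation

Standard upper-tail hypergeometric test per term with BH correction
across tested terms. The universe defaults to the genes detected in the
experiment, not the genome — an expression-aware background is the
accepted guard against detection bias; it is a parameter, because the
right universe is design-dependent. Terms smaller than 3 genes are
skipped as noise. Fold enrichment is $(k/n)/(K/N)$ and per-term up/down
fractions partition each term's DE hits by direction. Term grouping or
ontology-graph propagation is out of scope; terms are reported flat.

## miRNA–target integration

A candidate pair is any (miRNA, gene) reported by at least one prediction
source or a validated-target table (union-set rule); provenance lists
every supporting source and validated pairs are flagged (validated
evidence is treated as one more source in the union, and kept even when
also predicted). Identifiers are harmonized case-insensitively against
the expression namespaces, dropping and counting unmatched rows —
prediction databases and count matrices rarely share symbol versions.

"Inversely correlated" is implemented as *opposite DE direction*: keep
(m, g) iff both are DE and $\mathrm{sign}(\mathrm{lfc}_m) =
-\mathrm{sign}(\mathrm{lfc}_g)$. With 10 samples, a numeric
sample-level correlation threshold would be noisy and would re-test what
the DE stage already established; the sign rule is the operational
definition used in this literature. The network has miRNA degree = target
count and, for every miRNA pair with overlapping targets, an edge
weighted by the Jaccard coefficient of the two target sets; zero-overlap
edges are suppressed. Induced subnetworks can overlay user-supplied
protein-interaction edges, admitting non-DE interactors as neutral nodes.
GraphML and SIF exports make the graphs portable to standard viewers.

## Histology

Micrographs are reduced to a staining channel (red-dominance
$R - (G+B)/2$ for Picrosirius-like stains, rescaled to [0, 1]) and
thresholded with Otsu's method by default — the binarization protocol
being emulated is unspecified, so the threshold and method are recorded
in the result for provenance, and a fixed threshold is available for
synthetic fixtures. The stained-area score divides the foreground
fraction by an externally counted cell density, compensating fiber
atrophy; cell density is an input, not auto-detected.

The box-counting dimension overlays origin-anchored $s \times s$ grids
for a geometric ladder of sizes, counts occupied boxes $N(s)$, and takes
the least-squares slope of $\log N(s)$ vs $\log(1/s)$, with $R^2$
reported as a fit diagnostic. The default ladder uses powers of 2 up to
half the image side — or powers of 3 (from 1) when the image side is a
power of 3, which makes the estimator *exact* on aligned
Sierpinski-carpet fixtures ($D = \log 8/\log 3$). Grid offset averaging
is deliberately omitted: the estimator stays deterministic, matching the
behavior of the common interactive tool. Group comparisons use the
two-sample equal-variance t-test, two-tailed.

## The synthetic-data generator

`simulate_paired_counts()` draws
$k_{gs} \sim \mathrm{NB}(sf_s\,\beta_g\,2^{\mathrm{lfc}_{gs}}, \alpha)$
with log-uniform library sizes (default 0.5–2 million) so size-factor
estimation is genuinely exercised, log-normal baselines, and a single
dispersion $\alpha = 0.05$ — a typical within-group biological
variability for laboratory-animal bulk RNA-seq. Defaults mirror the
emulated design: 4 control vs 6 case samples, 10% DE features, mean
effect $\log_2 3$. DE features split into a *uniform* class (per-case-sample
lfc SD 0.15) and a *variable* class, in two modes:

* default: variable-class heterogeneity is independent per-sample noise
  (lfc SD 0.8) — the right null for testing that %CV separates the
  classes;
* `subgroup_mode = TRUE`: heterogeneity is *coherent* — variable-class
  effects are attenuated (×0.3) in the first three case samples, which
  therefore sit near the controls. This is the structure the emulated
  study actually describes (its variable clusters reflect a near-control
  case subgroup), and it is the mode under which the four
  direction × class blocks are recoverable by clustering and the
  subgroup detector has planted truth to find.

Planted miRNA–target pairs always couple features of opposite effect
sign; decoy pairs attach DE miRNAs to non-DE genes, so a correct
anti-correlation filter must remove all of them. Promoters are 350 nt
i.i.d. sequences (GC 0.4) with the motif consensus planted in foreground
genes at a configurable rate; `random_motif()` draws Dirichlet-graded
columns, like curated PWM libraries, rather than idealized
one-dominant-base columns whose lattice-like score distributions are not
representative. Fractal fixtures (filled square, Sierpinski carpet,
smoothed-field "fibers" at a known area fraction) have known geometry.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: gene–gene correlation and co-regulation
structure, GC/length biases, outlier samples and batch effects,
heavy-tailed dispersion across genes, sequence composition of real
promoters (repeats, CpG islands), miRNA seed-match biology, and the
optics of real histology. Results on synthetic data validate the
machinery, not the biology.

Determinism: one global seed feeds fixed per-generator child seeds, so
any module's inputs can be regenerated independently and every output —
including the full pipeline run — is byte-identical across runs with the
same seed (the manifest deliberately records no timestamps).

## Problem sizes and numerical notes

The test suite and acceptance script size their simulations to be
informative yet quick on a single CPU: 5,000 genes × 10 seeds for null
calibration, 2,000 genes for effect recovery, 800–1,200 genes for
stability/clustering over 10–20 seeds, 100 motifs × 50 independent
foreground/background draws (50/200 promoters) for motif calibration,
and depth-5 carpets (243×243) for the fractal estimator. Ties in
k-means restarts resolve by the first-best restart under the seeded RNG;
zero-variance rows z-score to zero with a warning; degenerate standard
errors yield p = 1 rather than NaN; all-zero features survive every stage
via the pseudo-count.

## Known limitations

The NB test's normal reference is asymptotic — at 2 + 2 samples it is
crude, and the dispersion floor can over-smooth genuinely low-dispersion
genes. The motif z-test assumes foreground sets of at least a few dozen
promoters. The subgroup reconstruction is one defensible reading of an
underspecified protocol. The box-counting estimator is grid-anchored;
dimensions of patterns without self-similar structure should be read as
descriptive indices, not physical dimensions. Multi-factor designs,
covariates, and fold-change shrinkage are out of scope.
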