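---
title: "toxflow: methods, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{toxflow: methods, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`toxflow` is a headless re-implementation of the analysis core of
interactive toxicogenomics environments built on large compound ×
dose × time expression archives. This vignette is the package's own
account of the statistics it computes, the conventions it fixes, and the
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## 1. Data model and fold-change conventions

A dataset is a probes × samples matrix of strictly positive normalized
intensities joined to per-sample metadata (compound, dose level,
exposure time, organ, species, platform, test type, and a
`control_group` key tying treated samples to their matched
vehicle-control samples for the same compound vehicle, organ and time).
Zero or negative intensities are rejected rather than imputed: every
downstream quantity passes through a logarithm, and silently repaired
values would corrupt fold changes invisibly.

Normalization divides each sample column by its own median, making the
column median exactly 1 (for an even number of probes the median is the
arithmetic mean of the two middle order statistics — the standard
convention). The same median-division underlies both display modes, so
users can reconstruct fold changes from "absolute" exports by hand.

The fold of a treated sample at a probe is its intensity divided by the
**arithmetic mean** of the matched control group's intensities. Folds
are kept on the ratio scale ("prior to log-2"), and a sample group's
displayed value is

```
value(p, g) = log2( mean_{s in g} fold(p, s) )
```

— the mean over the group's samples is taken first, the logarithm
applied last. This mean-then-log2 convention is what makes group values
stable when a user merges several doses, times or compounds into one
group: the merged value is the value of the merged sample set, not an
average of averages of logs. The price is a Jensen gap: the group value
is always ≥ the mean of per-sample log2 folds, with equality only when
all folds agree. A property test asserts exactly this dominance.

One modelling assumption is worth naming: control columns are
median-normalized with the same rule as treated columns before folds are
computed. Whether a legacy production database did precisely this is not
stated anywhere we could verify; uniform normalization is the only
self-consistent choice for user-uploaded data, so we fix it and say so.

## 2. Gene-set discovery: filters and test columns

Table columns accept four filter kinds — upper bound, upper bound on
absolute value, lower bound, lower bound on absolute value. All bounds
are **inclusive**: the workflow this package templates extracts genes
with log2 fold change "greater than or equal to 1.5", which fixes the
lower bound as ≥, and the other three mirror it for symmetry. Missing
values fail any active filter; inactive filters pass everything.

Multiple filters combine by conjunction (each filter constrains its own
column; a row must pass all of them). An explicit `combine = "or"`
option exists for one documented reason: dose/time-course workflows
often extract genes passing a threshold *at any time point* and pool
them before clustering. That is a union over per-column masks, not a
conjunction, and the pipeline template uses it for its fold-change
stage. The default remains AND.

Two test columns are available for comparing two sample groups probe by
probe, both two-sided (the direction of differential expression is not
known a priori, and two-sided testing is standard practice):

* **Welch's t** on per-sample log2 folds (or intensities): unequal
  variances, Welch–Satterthwaite degrees of freedom. Probes with fewer
  than two replicates after NA removal or zero variance in both groups
  are reported as `NA` with a warning rather than failing the whole
  column.
* **Mann–Whitney U**: exact two-sided p by the rank-sum counting
  recurrence when the pooled sample has ≤ 12 tie-free observations
  (`p = min(1, 2·min(P(U ≤ u), P(U ≥ u)))` under the permutation
  distribution); otherwise a normal approximation with tie-corrected
  variance and **no continuity correction** (validated against the
  reference implementation with matching settings).

p-values are deliberately **not** multiplicity-adjusted at the filtering
stage — the templated workflow thresholds raw p = 0.01 — and adjustment
lives in the enrichment module where a defined family of hypotheses
exists.

The consistent-regulation extractor implements the "half of or less
than control at all time points" rule: in down mode a probe passes iff
its group-level fold is ≤ `ratio` at **every** time point, boundary
inclusive (a fold of exactly 0.5 passes at ratio 0.5); up mode mirrors
with ≥ 1/ratio. Probes missing any time point are excluded and counted
in the resulting gene set's provenance.

## 3. Hierarchical clustering and the dendrogram cutoff

Gene (row) and group (column) dendrograms are built agglomeratively via
the Lance–Williams recurrence, in compiled code. Four linkages are
supported; `ward_d2` follows the Murtagh–Legendre definition (the
update operates on squared dissimilarities, merge heights are reported
on the original distance scale), and `average` is size-weighted UPGMA.
The default distance is Pearson correlation distance `d = 1 − r`
(range [0, 2]); profiles of fold changes over dose/time conditions are
compared by shape, which is why it is the workflow default together
with `ward_d2`. Euclidean distance is available for magnitude-sensitive
clustering. Rows with zero variance make correlation undefined and
raise an error naming the probe — constant rows are a modelling
problem, not something to paper over with a pseudo-distance.

Numerical choices:

* **Tie-break**: when two pairs attain the minimal distance, the pair
  with the lexicographically smallest position indices merges first.
  Reference implementations differ here; fixing the rule makes runs
  reproducible and row-permutation tests meaningful (partitions are
  compared up to relabeling).
* **Cut rule**: two leaves share a cluster iff their lowest common
  merge has height ≤ cutoff — boundary merges are joined, matching the
  common `cutree` convention. For the monotone linkages supported this
  equals union-find over all merges at height ≤ cutoff. Cluster count
  is non-increasing in the cutoff (property-tested over random
  dendrograms against a connected-components oracle).
* **Cluster numbering**: `cluster1..K` follow the dendrogram's leaf
  order, so the partition reads off a heatmap top to bottom.
* **Size limit**: clustering is restricted to 1000 gene rows
  (matching the behavioural constant of the environment this package
  mirrors); 1001 rows raise an explicit size-limit error.
* All four linkages are oracle-tested against `stats::hclust` (heights
  to 1e−8 and cophenetic equivalence) on random instances.

Dendrogram heights are serialized to the JSON sidecar with `%.17g`, so
a written partition reconstructs the dendrogram bit-exactly.

## 4. Enrichment

Over-representation of a query gene set in a category is scored with
the one-sided hypergeometric upper tail `P(X ≥ k)` (universe `N`,
category `K`, query `n`, overlap `k`), computed by summing the log-scale
probability mass — stable for universes well beyond 1e5. The full grid
`N ≤ 12` is tested against subset enumeration, and monotonicity in `k`
is property-tested. The remote enrichment service this replaces does
not publish its exact statistic; the hypergeometric over-representation
test is the de-facto standard for this service family and is our
explicit stand-in.

Choices: the default universe is all probes/genes of the platform in
use (caller-overridable, since a web application's implicit universe is
unknowable); the default adjustment is Benjamini–Hochberg across tested
categories; a probe→gene map, when supplied, collapses probes so one
gene counts once regardless of probe multiplicity. The per-cluster
quick summary reports, per cluster, the single category with minimal
**raw** p (ties: larger overlap, then lexicographic ID), mirroring the
popup used to tune a cutoff; clusters overlapping no category report
`"none"` — a zero-overlap category with p = 1 is not a meaningful "most
enriched feature".

## 5. Compound ranking

The source environment names a "total downregulation" ranking mode but
does not print its mathematics, so the scoring formula is this
package's own definition, kept deliberately simple and pluggable: the
score of a compound is the mean signed log2 fold over the query genes
and scoped conditions (negated for downregulation, so higher always
means a stronger match), averaged across time points — "total" read as
an aggregate over the whole course. Compounds lacking any query gene
are excluded and reported; ties order alphabetically. The scorer is an
injectable function precisely because per-time-point maxima or
correlation-to-reference-curve scores are defensible alternatives; the
monotonicity property (pointwise-lower folds never score lower in down
mode) is what any replacement should preserve. Dose scope defaults to
the Middle level, the templated workflow's choice.

## 6. Orthologous mode

Cross-species comparison collapses ortholog probe sets (supplied as
files; no sequence comparison is performed here) into single rows. The
cell for (set, group) is the **median** of the per-probe group averages
contributing to that group — "a median of averages", robust to a single
divergent probe (`median(1, 2, 9) = 2`, where a mean would give 4).
Even counts take the mean of the middle two, consistent with the
median convention elsewhere. Cells with no contributing probe are `NA`,
never 0 — absence of evidence must not masquerade as no regulation.
Values aggregated are log2 group values by default, matching the main
table's display mode; whether a production system medians over raw fold
averages instead is unstated, so the choice is flagged here. Group
columns sharing a name across platform tables pool their members into
one cross-species cell.

## 7. The synthetic world: what it emulates, what it does not

The generator emulates the *design* of a large toxicogenomics archive:
a compound panel × Control/Low/Middle/High × a 4 day–29 day repeat-dose
course × 3 replicates, with matched vehicle controls per compound and
time, emitted in the exact upload dialect the readers consume. The
signal model is log-normal: log2 intensity = probe baseline
(N(7, 1), typical of normalized microarray log intensities) + planted
condition effect + noise (Gaussian, sd 0.1 on the log2 scale by
default; a Student-t(3) option exists for robustness experiments).

Defaults are fixed once: 1000 probes, 10 compounds, 3 replicates. The
default effect model plants, for the first compound at the Middle dose,
three 60-probe blocks: early up (+2 at days 4/8), late up (+2 at days
15/29), and always down (−2/−1.5 alternating). One deliberate subtlety:
the down block's profile *varies* over time. A constant profile would
make Pearson correlation distance undefined for its rows; the
alternating −2/−1.5 profile keeps every fold ≤ 0.5 (so the
half-of-control rule still recovers the block exactly) while giving the
correlation a well-defined, well-separated shape. With these defaults
the same dataset exercises fold-change filtering, three-cluster
recovery at the recommended cutoff, consistent-down extraction and
compound ranking, and the planted truth is returned alongside the data.

Derived tolerances follow from the noise model: the group value of a
planted block has sd ≈ `noise_sd · sqrt(1/n_treated + 1/n_control)` ≈
0.082 at the defaults, so a ±0.2 band around a +2 effect is ~2.45σ
(nominal coverage ≈ 98.6%); the recovery test asserts ≥ 96% on a
500-probe block, a 4σ allowance for binomial sampling noise, plus a
direct check of the sd itself. The enrichment null-calibration world
was sized analytically *before* simulation: hypergeometric p-values are
discrete, so the attainable level below 0.05 depends on the category
and query sizes; with a universe of 5000, 50 categories of 200 and
queries of 500 the attainable level is ≈ 0.040, comfortably inside the
tested 0.05 ± 0.02 band, whereas small categories would fail that band
through discreteness alone.

What the generator does **not** emulate — hence what a green test does
not establish: probe-level array artifacts, batch and vehicle effects,
correlated noise between probes, dose–response monotonicity beyond the
planted patterns, many-to-one probe/gene structure, or pathology
endpoints. Recovery results on this world certify the *machinery*
(conventions, statistics, determinism), not performance on real
archives.

## 8. Determinism and reproducibility

Every source of randomness flows through an explicit integer seed: the
generators require one, draw baselines then noise in a fixed order
under it, and restore the caller's RNG state afterwards. The analysis
stages themselves draw no random numbers, so the declarative pipeline
is byte-identical across reruns on the same inputs — asserted by
hashing every artifact of a double run. Writers and readers round-trip
(expression pair, gene sets, GMT, ortholog maps, partitions), and the
individual-sample export (pre-log folds) re-aggregates to the grouped
export within 1e−12.

## 9. Known limitations

* The ranking formula is this package's definition (see §5); scores are
  comparable within a run, not across tools.
* Enrichment assumes exchangeable genes under the null; correlated
  co-expression inflates significance here as in any
  over-representation test.
* The clustering size limit is a hard error, not an automatic
  down-selection; choose the gene set first.
* MAS5/RMA normalization, CEL parsing, probe annotation retrieval and
  orthology computation are out of scope: normalized intensities and
  ortholog maps are inputs.
* The optional heatmap is a static rendering concern left to standard
  tools (`as.hclust()` converters are provided); no interactive widget
  is produced.
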