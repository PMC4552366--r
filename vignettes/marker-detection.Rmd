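---
title: "Detecting tissue marker genes from sorted expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tissue marker genes from sorted expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerseg)
```

## The problem and the method

A marker gene is a gene expressed predominantly in one tissue or cell
type, usable to establish the identity of a sample. Given a normalized
expression matrix (probes × samples, log2-scale intensities such as RMA
output) over several sample types with replicates, `markerseg` finds
marker probe sets by a ranking argument rather than by
differential-expression testing:

1. **Sorting.** Each probe's expression values are sorted in decreasing
   order, carrying the sample-type labels along.
2. **Cut-points.** A position `k` in the sorted profile is a *cut-point*
   when the `k` samples above it are exactly the union of complete
   replicate groups of the types seen there — the boundary segregates
   whole sample types at high expression from the rest. A profile can
   have several cut-points (one type on top, another at the bottom) or
   none (types interleaved).
3. **Scoring.** `n` cut-points split the profile into `n + 1` groups,
   each summarized by its mean. Cut-point `i` receives the *specificity
   score* `mean(group i+1) / mean(group i)`. Because the values are
   sorted decreasing, scores lie in (0, 1]; scores near 0 indicate a
   wide expression gap (high specificity), scores near 1 a negligible
   one.
4. **Selection.** A probe is called a *positive marker* for type `t`
   when its first cut-point isolates exactly `t`'s replicates at the top
   of the profile. The probe's score is the score of that first
   cut-point, i.e. the ratio of the second to the first entry of the
   group-mean vector. Calls are ranked per type by ascending score and
   filtered with `filter_markers()` at an inclusive cutoff
   (`score <= cutoff`; cutoff 1 retains everything).

```{r fixture}
fx <- fixture_profiles()$five_tissue
fit <- detect_markers(fx$expr, fx$groups)
marker_table(fit)
find_cut_points(sort_profile(fx$expr[1, ], fx$groups))
```

The fixture reproduces the canonical shape: a liver triplicate strictly
on top and a brain triplicate at the bottom of a 5-tissue × 3-replicate
profile gives two cut-points (positions 3 and 12), a positive marker
call for liver and — with `negative = TRUE` — a negative marker call for
brain. Negative markers and multi-type segregations are computable but
excluded from the default selection, which considers single-tissue
high-expression markers only.

## Assumptions and input contracts

* **Normalization is mandatory.** Values are used exactly as provided;
  the package validates finiteness and strict positivity (ratio scores
  need positive means) and performs no transformation, background
  correction or batch adjustment.
* **Replicates are required** for every sample type — the cut-point
  predicate is completeness of replicate groups — but the counts may
  differ between types. The default minimum is 2 per type;
  `min_replicates = 3` enforces a stricter triplicate design.
* **Ties.** Sorting is stable (ties keep input column order), so results
  are deterministic. Ties spanning a candidate cut-point do not
  invalidate it: group membership is decided by rank completeness, and a
  zero gap simply scores near 1, which the cutoff filter already
  penalizes. A fully constant probe carries no segregation information
  and yields no cut-points and no call.

## Design choices

* **The score's denominator group and numerator group.** The score is
  the ratio of the second to the first entry of the group-mean vector,
  so the numerator group is the segment between the first and second
  cut-points — not the pooled mean of all non-top samples. The pooled
  reading is available as `score_mode = "rest"` for comparison; on the
  fixture above it yields 0.591 instead of 0.707 because the bottom
  brain group drags the pooled mean down. The segment reading keeps the
  score local to the boundary it describes.
* **Inclusive cutoff.** `filter_markers()` keeps `score <= cutoff`, so
  cutoff 1 retains every call; equality at 1 occurs only under exact
  ties.
* **Gene identification.** `rollup_genes()` maps called probes to genes
  and keeps, per (type, gene), the minimum score over contributing
  probes. By default only probes annotated to exactly one gene count
  (the unambiguous-mapping identification rule); ambiguous probes can be
  admitted with `unambiguous_only = FALSE`, which is deliberately more
  permissive than the identification rule and meant for exploration.
  Gene identity is keyed by gene id; symbols are display metadata.
* **t-test baseline.** `ttest_markers()` uses Welch's unequal-variance
  statistic by default — with 3-vs-12 one-vs-rest splits the variance
  pooling assumption is fragile — and offers the pooled form via
  `var_equal = TRUE`. Benjamini–Hochberg adjustment is applied per
  one-vs-rest comparison (m = number of probes), matching the framing of
  one tissue compared against the rest; a probe is selected for a type
  when its adjusted p-value is at most `alpha` *and* its mean in the
  type exceeds the mean of the rest. Zero-variance degeneracies are
  defined, not errors: equal means give p = 1, unequal means give p = 0
  with a `degenerate` flag.
* **Precision at zero predictions** is undefined; such points are
  omitted from precision/recall curves by default
  (`zero_precision = "omit"`) or pinned to 1 (`"one"`).
* **Random baseline.** For a random selection of `s` genes from a
  universe of `N` containing `K` real markers the identified count is
  hypergeometric, so expected precision is `K/N` (constant) and expected
  recall `s/N`; `random_baseline()` returns these closed forms, with a
  seeded Monte-Carlo mode for empirical bands.

## The synthetic-data generator

`simulate_markers()` emulates the detector's intended input regime: a
log2-scale matrix over 5 tissues (brain, heart, kidney, liver, lung) × 3
replicates by default. Background probe `p` gets
`base_p + ε`, `base_p ~ N(7, 1)` drawn once per probe,
`ε ~ N(0, 0.25)` per cell; a planted marker for type `t` adds
`delta = 2` (log2 units, i.e. a 4-fold change) to `t`'s samples. The
defaults plant 20 markers per type over 2000 background probes, so the
shift is 8× the noise SD — a strong-marker regime in which the expected
score of a planted probe is `base_p / (base_p + delta)` (about 0.78 at
the default baseline) and recovery at cutoff 0.9 is essentially exact.
All draws come from a single seed in a fixed order (baselines, noise
matrix, ambiguous-probe choice), so the same seed reproduces the data
bit for bit; stray non-positive draws are truncated at a small positive
floor (with a message) rather than redrawn, preserving that
reproducibility.

A fraction of *background* probes (10% by default) is annotated to two
genes to exercise the ambiguity handling; planted probes stay
unambiguous so the gene-level ground truth is exact.

What the generator does **not** emulate: probe-level intensity
distributions of real arrays, correlated probe sets for one gene, batch
effects, and tissues with genuinely graded (rather than on/off)
expression. Passing the recovery tests therefore shows the selection
logic and scoring are correct under the stated model; it does not
certify performance on any particular real data set.

```{r sim}
sim <- simulate_markers(n_background = 300, n_markers_per_type = 10,
                        seed = 42)
fit <- filter_markers(detect_markers(sim$expr, sim$groups), 0.9)
summary(fit)
```

## Evaluation framework

Predictions are evaluated at gene level against a curated list of known
("real") markers, restricted to the genes present on the platform.
`precision_recall()` sweeps score cutoffs under two strategies:
*combined* pools all tissues' predicted genes against the pooled known
markers, *per-tissue* compares each tissue with its own known set.
Recall is identified/total known; precision is identified/predicted.
`overlap_counts()` reports the full Venn partition and pairwise Jaccard
similarities of predicted sets, e.g. between two data sets of the same
tissues.

The one-vs-rest t-test is the conventional comparator. Its
characteristic failure mode against the cut-point rule: a probe elevated
in *two* tissues still has a significant one-vs-rest test for each of
them, while its sorted profile has no single-type first cut-point. The
regression test and the acceptance script construct exactly this mixture
(planted single-tissue markers plus shared two-tissue probes) and verify
that the detector's combined-strategy precision at cutoff 0.9 is at
least the t-test's at alpha 0.05.

## Numerical and scale choices

Problem sizes in the test suite are chosen for exhaustive
cross-checking rather than realism: the brute-force oracle equivalence
runs on 500 random matrices of up to 200 probes and 6 types × 4
replicates, planted-marker recovery on ten 2,100-probe replicate data
sets, and all scores are compared to independently recomputed raw-mean
ratios at double precision (no tolerances beyond floating-point
equality where exactness is expected). File writers render floating
point with 6 significant digits and byte-stable ordering
(type, score, probe id), so identical inputs give identical outputs.

The command-line front end (`inst/cli/markerseg.R`) exposes `detect`,
`evaluate`, `ttest`, `simulate` and `overlap` subcommands over the same
functions; flags are the interface (no separate config-file layer).

## Limitations

* The method is rank-based and needs the *complete* replicate group of a
  type on top: a single outlying replicate demotes a true marker. This
  is by design (robustness of the call), but it makes the method
  sensitive to mislabeled samples.
* Scores compare adjacent group means on the input scale; on log2 data a
  score of 0.9 near baseline 7 corresponds to a ~0.7 log2-unit gap, so
  cutoffs are not fold-change thresholds and should be chosen by the
  marker-count sweep (`plot()` method) or the precision/recall curves.
* With only 2 replicates per type, chance segregation of a complete
  pair is more likely than with triplicates; prefer
  `min_replicates = 3` when the design allows.
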