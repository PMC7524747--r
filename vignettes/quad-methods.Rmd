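---
title: "Degradation kinetics from AHA pulse-chase ratio tables: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradation kinetics from AHA pulse-chase ratio tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadpipe)
```

## The measurement model

QUAD (Quantification of Azidohomoalanine Degradation) is a pulse-chase
design for measuring protein degradation in tissue. Animals are fed the
methionine surrogate azidohomoalanine (AHA) during a pulse window, so
that proteins synthesised in that window carry AHA; the animals then
return to a normal diet and the AHA-labelled pool is followed over chase
days 0, 3, 7 and 14. After click chemistry, each chase sample (tagged
with a heavy biotin-alkyne) is mixed 1:1 with a common Day0 internal
standard (tagged light), and mass spectrometry reports a heavy/light
(H/L) intensity ratio per AHA peptide. Because the light channel is a
fixed standard, the H/L ratio of a peptide tracks the fraction of its
parent protein's labelled pool remaining at that chase day.

For a protein degrading exponentially at rate $\lambda$ (per day), the
expected ratio at chase day $t$ is $e^{-\lambda t}$ (normalising the
ratio to 1 at day 0). The pipeline therefore:

1. filters peptide records on the quantification quality score
   (`apply_quality_filter()`, default cutoff 0.1, lower is better,
   boundary inclusive);
2. collapses proteins that cannot be distinguished by their peptide
   evidence and removes subset and no-unique-peptide proteins
   (`infer_protein_groups()`);
3. takes the **median** peptide H/L ratio per protein, replicate and
   chase day (`compute_protein_ratios()`; the median is robust to the
   occasional mis-quantified peptide, and even counts use the midpoint
   of the two central values);
4. builds the **protein stability trajectory** (PST): the natural log of
   the per-day ratios (`build_psts()`);
5. fits ordinary least squares $y = mx + b$ to each trajectory
   (`fit_kinetics()`): the slope $m$ (per day) is the stability readout,
   the degradation constant is $\lambda = -m$, and the half-life is
   $T_{1/2} = \ln(2)/\lambda$ days.

Two conventions deserve emphasis:

* **Averaging order.** In `averaged` mode the per-replicate median
  ratios are averaged arithmetically per chase day *first* and the mean
  is log-transformed afterwards. Mean-then-ln and ln-then-mean differ
  whenever replicates disagree (Jensen's inequality: mean-then-ln is
  always the larger), so the package treats the order as part of the
  definition and a test distinguishes the two.
* **Day-0 anchor.** The Day0/Day0 self-mix measures a ratio of 1 by
  construction, so the trajectory is pinned at $(0, 0)$ by default and
  completeness is required on the chase days only. `anchor_day0 = FALSE`
  switches to using only measured points, in which case a listed day 0
  must actually be quantified. The anchored fit is the default because
  the baseline is a designed property of the mix, not an observation
  with independent error.

Slopes of zero or above map to an infinite half-life sentinel and a
`stable` flag rather than a negative number of days; such proteins stay
in the clustering but are excluded from half-life correlations. Since
$T_{1/2} = \ln 2/(-m)$ is strictly monotone in $m$ on negative slopes,
the Spearman correlation between slope and half-life is exactly 1 there
— the two readouts order proteins identically, and the package tests
that structural fact rather than any empirical correlation value.

## Trajectory clustering and stability classes

`cluster_psts()` clusters trajectory vectors (one dimension per chase
day, ln scale, including the day-0 anchor when present) by agglomerative
hierarchical clustering under Ward's minimum-variance criterion with
Euclidean distances (`stats::hclust(method = "ward.D2")`), cut to
exactly `k` clusters. `k` is a required user input: cluster number is a
judgement call made on the dendrogram, average slope and trajectory
shape, so the package exports the full merge tree in Newick format
(`write_merge_tree()`) to support that inspection but never auto-selects
`k`. Clusters are relabelled `A`, `B`, ... by increasing mean member
slope, so `A` is always the steepest (least stable) cluster regardless
of input order.

Two quality gates follow:

* **Replicate concordance** (`concordance_filter()`): a protein is
  trusted only if the per-replicate trajectories of all its biological
  replicates land in the same cluster. Discordant proteins are dropped;
  proteins observed in a single replicate are kept but flagged
  `untested`. Dropping a protein never re-clusters the rest.
* **Stability classes** (`classify_stability()`): clusters whose mean
  slope is at or above a threshold are `stable`, the rest `unstable`,
  and proteins inherit their cluster's class. The default threshold of
  −0.10/day sits midway between typical brain (−0.11) and liver (−0.16)
  mean slopes; the boundary is inclusive toward stable. The published
  analyses drew this line by inspecting clusters; a numeric threshold
  makes the same call reproducible.

Joint-tissue clustering is the same operation run on a concatenated PST
set; no special casing.

## Comparative layers

All comparison statistics are thin, explicit wrappers over base R tests:

* `heavy_id_fraction()` — percentage of heavy identifications among all
  AHA identifications, the first-pass readout that labelled protein is
  disappearing over the chase.
* `compare_slope_sets()` — two-tailed t-test between tissue slope
  distributions. Welch (unequal variance) is the default since nothing
  guarantees equal spread between tissues; a pooled-variance Student
  option is exposed. Zero-variance inputs are flagged degenerate (p = 1
  when the constants agree, 0 otherwise) rather than erroring.
* `compare_ratio_groups()` — one-way ANOVA across tissues with either
  Bonferroni pairwise post-hoc tests or Tukey's HSD; both are offered
  because multi-tissue ratio analyses conventionally report one or the
  other, and the caller chooses per analysis.
* `age_volcano()` — per-protein log2 fold change (old/young) of
  replicate-mean ratios with a Welch p-value per protein; the
  significance line is drawn at raw p < 0.05 by default, with a
  Benjamini–Hochberg column available but off by default so the flag
  matches the conventional volcano-plot cut.
* `complex_homogeneity()` — fraction of protein complexes (CORUM-style
  membership lists) whose labelled subunits share one stability class;
  complexes with fewer than two labelled members leave the denominator
  and redundant complexes collapse to one. The fraction is invariant
  under a global stable/unstable swap, which is tested.
* `replicate_correlation_matrix()` and `property_correlation()` —
  pairwise-complete Pearson correlations between experiments and between
  slopes and an external per-protein property (disorder, molecular
  weight, abundance). Cells with fewer than 3 shared proteins are
  reported missing.

## Protein inference: rule precedence

The reporting rules are: merge proteins with identical peptide
evidence; do not report a protein whose evidence is a proper subset of
another's; require at least one unique quantified peptide. The package
applies redundancy merging and subset removal first and then iterates
the unique-peptide rule to a fixed point. The precedence matters: on a
covering design such as proteins {p1}, {p2}, {p1, p2}, checking
uniqueness before removing subsets would discard every protein, whereas
the standard reading (uniqueness is evaluated among *reportable*
proteins) keeps the covering protein. Merging and subset removal
commute, and the test suite checks the implementation against an
independent rule-application oracle with those two rules applied in
random order, plus input-order invariance.

## The synthetic generator

`generate_dataset()` exists so that every downstream stage has a known
ground truth. It emulates, per protein: a true slope drawn from
Normal(`slope_mean`, `slope_sd`) with tissue presets (brain −0.11/day,
liver −0.16/day) and $\lambda = \max(0, -\text{slope})$ — clamping at
zero because labelled protein cannot be gained during the chase — or,
alternatively, $\lambda$ drawn lognormally via
`lambda_meanlog`/`lambda_sdlog`; a peptide count of 1 + Poisson (mean
8.3 peptides per protein); a lognormal abundance; and optionally
biphasic decay (default 10% of proteins, one breakpoint at day 7, late
rate uniform between 0.1× and 0.5× of the early rate) since a minority
of trajectories in tissue data are non-exponential.

Per peptide observation the generator draws a multiplicative lognormal
ratio error (`ratio_noise_sd`, default 0.2 on the ln scale), computes
the light intensity from abundance × a lognormal peptide ionisation
factor × lognormal measurement noise, sets heavy = light × ratio, and
emits the row only if it passes a logistic detection model in log10
intensity — heavy channel for chase days, both channels at day 0. The
detection model is the mechanism that reproduces the observed decline of
heavy identifications with chase time: identification probability is
tied to abundance, and the heavy pool decays.

Unspecified-by-design magnitudes were fixed once at values a proteomics
practitioner would call realistic and are not tuned thereafter:
abundance lognormal with meanlog $\ln 10^6$ and sdlog 1.2 (≈ 2.5 decades
of dynamic range at 95%), ionisation sdlog 0.8, per-channel intensity
noise sdlog 0.1, detection midpoint at $10^4$ intensity units with
steepness 1.5 per decade (so a typical day-0 peptide is identified with
p ≈ 0.95 and identification erodes as the heavy pool shrinks), quality
scores Beta(1, 15) (about 20% of records fail the 0.1 cutoff).
`simulate_baseline_mix()` reuses the same machinery for the Day0
self-mix, sampling detection independently per channel, so its heavy
fraction is binomial around 50% for a true 1:1 mix.

What the generator deliberately does **not** emulate: spectrum-level
structure (m/z, charge, retention time), missed cleavages, shared
peptides between proteins (off by default), correlated peptide errors
within a protein, chromatographic batch effects, and ratio compression.
Passing tests therefore demonstrate that the estimators recover the
generating kinetics under idealised, independent noise — not that they
are robust to every pathology of real MS data.

## Numerical choices and degenerate inputs

* OLS is computed in closed form from centred sums; tests check it
  against `stats::lm` to 1e−10. With zero noise the fitted slope equals
  $-\lambda$ to 1e−10/day.
* $r^2$ is reported but never used as a filter; a zero-variance
  trajectory has undefined $r^2$ (reported `NA`) and slope 0.
* A trajectory with fewer than two distinct chase days is a degenerate
  design and errors; an empty required-day set is a configuration error.
* Ward merges are monotone (heights never decrease), and partitions are
  invariant to input order when pairwise distances are distinct; ties
  are broken by the agglomeration order of `hclust`, which is
  deterministic for a given input.
* All randomness flows from a single integer seed; identical config +
  seed reproduces byte-identical output tables.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to keep the full run
around half a minute while leaving no estimator untested: simulator
checks at 200–400 proteins, rate recovery at 50 (noise-free) and 200
(noisy) proteins with 3 replicates and days {0, 3, 7, 14}, the
brute-force Ward oracle at up to 8 trajectories across randomized
suites, parsimony against an exhaustive oracle on 100 random maps of up
to 10 proteins × 15 peptides, and the brain-vs-liver power property at
200 proteins per tissue over 20 seeds.

## Known limitations

* Biphasic proteins are *generated* but not *fitted* biphasically; the
  single-slope fit reports an average rate, which is exactly how such
  proteins appear in the published analyses. Nonlinear change-point
  fitting is out of scope.
* No error propagation from peptide to protein level: the median and
  the subsequent OLS treat each day's protein ratio as one observation.
* Synthesis is not modelled: the method reads pure degradation, which
  is its point, but also means it cannot separate slowed degradation
  from relabelling artefacts at very short chase times.
* The stability threshold and cluster count remain scientific choices;
  the package makes them explicit parameters rather than deciding.
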