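---
title: "Pattern-based signed co-expression networks: methods and design"
author: "gecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-based signed co-expression networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gecon)
```

## The model

Global proximity measures (Euclidean distance, Pearson correlation, mutual
information) can miss gene pairs whose expression profiles agree only
locally, or agree in shape but not in value (shifted and scaled patterns),
and they do not natively produce the *sign* of a co-regulation
relationship. `gecon` reconstructs a co-expression network from local
pattern agreement instead.

An expression profile over $M$ conditions is read as $M-1$ *edges*, the
segments between consecutive values. Each edge of gene $G_i$ is summarised
by two numbers:

* its **regulation sign** $G_i(r_k) \in \{+1, -1\}$, up or down
  ($+1$ when $O_{k-1} < O_k$, $-1$ when $O_{k-1} > O_k$); and
* its **degree of fluctuation** $G_i(a_k) \in [0, 180]$ degrees, computed
  from the two bounding values with the two-argument arctangent:
  $|\mathrm{atan2}(O_k, O_{k-1})|$ for an upward step and
  $180 - |\mathrm{atan2}(O_k, O_{k-1})|$ for a downward one.

The single profile $\{343, 314, 409\}$ becomes $\{138, -1;\ 52, +1\}$
after nearest-degree rounding — the package stores full precision and
rounds only for display.

Two genes' $k$-th edges are **positively similar** when they share the
regulation sign and their angles differ by less than a threshold $\tau$,
and **negatively similar** when their signs are opposite and the *sum* of
their angles is within $\tau$ of $180°$ (a perfect mirror pair $a$,
$180-a$ deviates by zero). The two conditions are mutually exclusive at
any single edge. The **positive/negative support** of a pair is the
fraction of its $M-1$ edges matching each way; a pair is **strongly
connected** when combined support strictly exceeds a threshold $\theta$,
and the edge sign is $+1$ or $-1$ according to which component exceeds
$\theta$ (with $\theta \ge 0.5$ at most one can). The signed network's
connected components are reported as co-expression **modules**.

Support counting uses a *correlogram*: a triangular $N(N-1)/2$ pair-count
structure filled in a single pass over the transposed edge table — each of
the $M-1$ edge columns is visited exactly once, and all pair counters for
that column are updated before moving on. Network construction afterwards
touches each unordered pair once, reading from the correlogram only.

## Parameters

* `tau` (degrees, default 20): angle tolerance for edge similarity. Values
  between 15 and 25 work well; smaller values demand closer local
  agreement, larger ones admit sloppier matches on both the positive and
  the negative route.
* `theta` (support fraction, default 0.5): minimum combined support,
  strict. At or above 0.5 a majority of edges must match and the edge-sign
  rule is unambiguous; below 0.5 a pair can connect on combined support
  with neither component dominant, in which case the larger component
  decides the sign (ties to +1).
* `beta` (default 0.5): F-score weight for evaluation, emphasising
  precision, the usual choice when false edges are costlier than missed
  ones.
* `minModuleSize` (default 2): a single gene is not a module.

## What the transform can and cannot see

Two geometric facts drive every design choice in the synthetic generator
and are worth stating plainly.

First, the angle of an edge depends only on the *ratio* of its two values
(with their signs). Profiles whose consecutive values are close — any
smooth profile at a roughly constant positive level — have all angles near
45° (up-steps) or 135° (down-steps). Two such profiles match at *every*
edge for any reasonable `tau`: same-sign steps agree on the positive
route, opposite-sign steps sum to ≈180° and agree on the negative route.
Smooth intensity-scale profiles are therefore mutually indistinguishable
to the method; specificity requires profiles whose value ratios vary
widely, which spreads the angle spectrum across $[0, 180]$.

Second, inversion — reflecting a profile about its mean, the natural model
of negative co-regulation — is visible to the negative similarity rule
only on *near-level* edges at *positive* levels. For an edge with values
far from the reflection centre (or at a negative level), the reflected
angle is approximately equal to, not complementary to, the original
(negating both arguments leaves `atan2`'s absolute angle unchanged), so
the sum test fails. In particular, profiles that swing through zero defeat
inverted-pattern detection even though they are ideal for specificity.

These two regimes pull in opposite directions, and that tension is a
property of the published transform, not of this implementation.

## The synthetic generator

`patternSpec()`/`generateDataset()` plant modules of known co-regulation
inside a background of unstructured genes. Defaults: 3 modules (shifted,
scaled, inverted) of 10 genes each, 15 conditions, 10 background genes,
noise sd 10 (expression units).

Guided by the geometry above, base profiles come in two styles:

* **Fluctuating** (shifted and scaled modules, background): a
  mean-reverting AR(1) walk around zero (autocorrelation 0.3, stationary
  sd 300), emulating log-ratio expression values. Angles spread broadly,
  so unrelated genes match only accidentally. Scaling by any positive
  factor leaves the representation exactly invariant; shifting by
  `alpha` (default within ±25, small against the ±300 swing) perturbs
  only the few edges whose values pass near zero.
* **Level** (inverted and mixed modules): a positive baseline drawn from
  \[200, 600\] drifting by ~5% per step, interrupted by extreme
  one-condition spikes (4–10 × baseline, at most one negative, at
  non-adjacent interior conditions). Near-level edges sit on the 45°/135°
  diagonal where reflection about the mean is visible; the spike count is
  chosen so these edges remain a strict majority of $M-1$, guaranteeing
  that reflected members stay strongly connected, while the random spike
  positions give each base a signature that keeps unrelated level-style
  genes (and distinct modules) apart.

In an inverted module, odd members follow the base and even members are
reflected, so the module plants both $+1$ and $-1$ edges; a pair's truth
sign is the product of its members' orientations. Mixed members reflect a
random contiguous window only. All randomness derives from the
spec's single seed through a splitting scheme, so datasets are exactly
reproducible and any one profile can be regenerated in isolation.

What the generator does *not* emulate: transcription kinetics (no ODE
dynamics as in DREAM-style simulators), condition-specific covariance,
heavy-tailed measurement error, or missing values. Passing recovery tests
on these data demonstrates that the implementation realises the method's
own model of co-regulation, not that the method succeeds on any
particular real dataset.

## Evaluation

Predictions are ranked by combined support (the only continuous score the
method produces; edge sign is ignored for ranking). Precision–recall and
ROC curves sweep the distinct score values in descending order, pairs
absent from the prediction ranking last at confidence 0; both areas use
trapezoidal integration. Directed gold standards in the DREAM edge-list
dialect are symmetrised (positive if either direction is). F-beta is
reported both as the maximum and the mean over the sweep, maximum first.
Reference values in the test-suite are fixed by hand-enumerated confusion
tables on a 6-pair toy, and the ROC area is cross-checked against an
independent implementation (pROC).

## Numerical choices and degenerate inputs

* Equal consecutive values take regulation +1; ties are measure-zero in
  continuous data and a fixed convention keeps determinism.
* A (0,0) edge gets angle 0 with a warning.
* Thresholds are strict (`< tau`, `> theta`) as defined.
* Angles are never rounded internally.
* The edge-sign fallback (combined support above `theta` but neither
  component alone) applies only when `theta < 0.5`; ties go to +1.
* Support storage is exact integer counting; supports are formed on read.

## Problem sizes

The bundled tests run the full pipeline on 40-gene × 15-condition planted
datasets (20 replicate seeds), on random matrices up to 50 × 20 against a
naive nested-loop oracle, and evaluation sweeps over a few hundred pairs
— sizes at which every check completes in seconds while still exercising
each code path; the algorithm itself is $O(NM + N^2M)$ in time and
$N(N-1)/2$ in pair memory and handles thousands of genes comfortably.

## Known limitations

* The negative-similarity geometry restricts detectable inversion to
  near-level positive profiles, as discussed; anticorrelated log-ratio
  profiles that cross zero will generally *not* be recovered as negative
  edges. This follows the published transform faithfully.
* Module extraction is plain connected components: one promiscuous gene
  can merge otherwise distinct modules. No overlapping or density-based
  module detection is attempted.
* The method is undirected; no causality or regulator/target orientation
  is inferred.
* Expression input is used as given: no normalisation, log-transform or
  imputation (profiles with missing values are rejected).
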