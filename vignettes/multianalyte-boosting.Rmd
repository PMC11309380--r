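---
title: "Multi-analyte pattern boosting: methods and design"
author: "metaboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-analyte pattern boosting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboost)
```

# The model

Each neem tree $i$ carries five metabolite concentrations
$c_{im}$, $m \in \{A, D, E, N, S\}$ (azadirachtin, desacetyl-salannin,
epoxy-azadiradione, nimbin, salannin). The true class of metabolite $m$
is
$$y_{im} = \mathbf{1}\{c_{im} > \bar c_m\} \in \{\text{low}, \text{high}\},$$
where $\bar c_m$ is the per-metabolite mean concentration (ties go to
*low*). Ten predictors — one per metabolite and organ, model ids
`A_f … S_f, A_l … S_l` — emit $\hat y^{(k)}_i \in \{\text{low},
\text{high}\}$.

A **pattern** $P = (S, a)$ is a non-empty subset
$S \subseteq \{1,\dots,10\}$ of models with a class assignment
$a : S \to \{\text{low},\text{high}\}$; there are $3^{10} - 1 = 59\,047$
of them (each model absent / low / high, minus the empty one). Sample $i$
*matches* $P$ iff $\hat y^{(k)}_i = a(k)$ for all $k \in S$.

Over $R$ test shuffles, pattern $P$ has **complete specificity** if, in
every shuffle where it matches at least one test sample, all matched
samples share one true fruit-A class, and **direction consistency** if
that class is the same across shuffles. Its **support** is the number of
shuffles with at least one match. `minePatterns(tabs, minSupport)`
returns every pattern satisfying all three conditions, tagged with its
implied class.

**Boosting**: a test sample matching at least one qualified low-implying
pattern and no high-implying pattern is called *low* (and vice versa);
samples matching neither kind *abstain*, samples matching both would
*conflict*. `decidePick()` maps the boosted call to the operational
"Pick" (high) / "Do not Pick" decision, falling back on the
single-analyte `A_f` prediction for abstentions.

On the shuffles used for mining, a conflict is impossible: if one sample
matched both a low- and a high-implying qualified pattern in some
shuffle, whichever true class the sample has would violate the complete
specificity of one of the two patterns. Hence every pattern-based call on
those *selection* shuffles is correct and the boosted per-class
specificity there is exactly 100 % — a structural property, not a tuned
number. For an honest generalisation estimate use
`experimentConfig(honest_eval = TRUE)`, which mines on the first
$R - 1$ shuffles and scores only the held-out last shuffle.

## Vectorised mining

Encode a pattern as the ternary integer
$\sum_{k \in S} a_k \, 3^{k-1}$ with $a_k \in \{1 = \text{low},
2 = \text{high}\}$. A sample with digit vector $d \in \{1,2\}^{10}$
matches exactly the $2^{10}$ patterns whose code is a subset sum of its
digit values. `sampleMatchCodes()` therefore computes one
$2^{10} \times 10$ binary matrix times the $10 \times n$ digit-value
matrix, and per-shuffle per-class match counts for all 59 047 patterns
follow from two `tabulate()` calls per shuffle. A full ten-shuffle,
$n = 1045$ experiment mines in a few seconds.

# The generator

## Concentrations

`simulateConcentrations()` draws each metabolite from a beta distribution
rescaled to its published concentration range with the published mean
(shape sum fixed at 4, a weakly informative choice that keeps densities
unimodal and positive across the range):

| metabolite | min | max | mean (mg/g) |
|---|---|---|---|
| A | 0.181 | 1.003 | 0.563 |
| D | 0.007 | 0.691 | 0.112 |
| E | 0.004 | 0.252 | 0.045 |
| N | 0.009 | 0.501 | 0.163 |
| S | 0.056 | 1.420 | 0.511 |

Dependence is a Gaussian copula, default exchangeable latent correlation
$\rho = 0.3$: the metabolites share a biosynthetic pathway and should be
positively associated, but no field estimate of the strength exists, so a
moderate value is used and is fully configurable (any PSD correlation
matrix). The induced Spearman correlation is
$(6/\pi)\arcsin(\rho/2)$, which the tests verify.

## Surrogate predictors

Each model predicts its own metabolite's true class correctly with a
per-class sensitivity (`predictorSpec()`), independently across models
given the truth. Defaults place `A_f` at 83.5 %/82.4 % (low/high) with the
other nine models spanning 60–98 %, mimicking a heterogeneous ensemble in
which fruit models outperform leaf models.

## Planted rules

`plantedRule(members, classes, implied_class, coverage, penetrance)`
embeds a ground-truth diagnostic pattern:

- exactly `round(coverage * n)` implied-class samples receive the full
  antecedent; chance matches on the remaining implied-class samples are
  always broken, so **coverage is the exact antecedent prevalence** in
  the implied class;
- chance matches on opposite-class samples are broken with probability
  `penetrance` by flipping one randomly chosen antecedent member (members
  that a conflicting rule pins for that sample's class are excluded from
  flipping, so rules never erode each other).

At `penetrance = 1` the antecedent is perfectly specific by construction,
which is what makes planted rules usable as recovery ground truth.
Rules implying different classes must conflict on at least one shared
member (`validateRules()`), otherwise one sample could be forced to carry
both antecedents.

# Cross-validation protocol

`makeSplits()` draws, per shuffle, a uniform permutation split with
`floor(n * ratio)` samples per subset and the remainder in train; at the
default 80/10/10 and $n = 1045$ that is 837/104/104. Metrics:

- per-class **sensitivity** = recall of that class; **specificity** =
  recall of the other class; precision/recall/**F1** per class plus their
  macro average; all shuffle-aggregated as mean ± SD (sample SD, $n-1$).
- **CV error** per class = $1 - \text{sensitivity}/100$, matching the
  interpretation of a per-class error rate under the shuffle protocol
  (the complement of the class recall; no other definition reproduces a
  pair of per-class errors).
- boosted metrics additionally report abstention and conflict rates and
  *pooled* per-class specificity (from the confusion counts pooled over
  all non-abstaining pattern decisions across shuffles).

`sensitivityCurve()` reports, per support threshold $m$ from $R$ down to
1, the number of qualifying low-/high-implying patterns and the per-class
**union coverage** — the percentage of a shuffle's true-class test
samples matched by *at least one* qualifying pattern — averaged across
shuffles with SD. Union coverage (rather than the mean of per-pattern
sensitivities) is the default because boosted sensitivities well above
any single pattern's coverage are only explicable by the union; the
per-pattern average is also available via
`sensitivityCurve(perPattern = TRUE)`.

## Statistical power of the support filter

Mining scans 59 047 patterns, so the support filter must control false
discoveries from multiple testing. A pattern that happens to contain
pinned members of a planted antecedent matches mostly covered samples of
one class; its expected opposite-class contamination per shuffle,
$\lambda_c$, can be well below 1 while its expected support matches,
$\lambda_s$, stay above 1. The probability such a pattern survives $R$
full-support shuffles is roughly
$(1 - e^{-\lambda_s})^R e^{-R\lambda_c}$, maximised near
$\lambda_s \approx 3$ at about $e^{-0.21 R}$ for the worst family. With
$R = 10$ and 200-sample test subsets hundreds of spurious patterns
survive; with $R = 30$ and 500-sample test subsets the expected count is
below one and their union-coverage contribution is negligible. The
recovery tests therefore use 30 shuffles — power analysis, not
tolerance adjustment.

# Detection plumbing

`letterbox(image, target = 640, fill = 114)` performs the aspect-fit
geometric stage only: scale by $s = \text{target}/\max(h, w)$ with
hand-rolled bilinear resampling (pixel-centre convention), centre on a
square canvas filled with gray value 114. It is idempotent on already
letterboxed images, and `unletterbox()` inverts the coordinate transform
to within 0.5 px. `toModelInput()` separately applies the tensor layout
change (transpose, BGR→RGB, scale to $[0,1]$), keeping the geometric
stage byte-exact and testable. `nms()` is greedy class-wise non-maximum
suppression: drop boxes below confidence 0.25, then keep boxes in
decreasing confidence order (input order breaks ties), suppressing
same-class boxes with IoU > 0.45.

# Numerical and reproducibility choices

- All randomness goes through `withr::with_seed()`; `deriveSeeds()`
  expands one experiment seed into per-stage seeds so stages stay
  reproducible independently.
- The copula factor uses the symmetric eigendecomposition square root
  (`chol()` would reject semi-definite inputs); eigenvalues are floored
  at 0 with a $-10^{-8}$ PSD tolerance.
- Class labels use a strict `>` threshold with ties to *low*, so a
  sample exactly at the mean is never double-counted.
- Percentages are reported on the 0–100 scale; CSV exports round to two
  decimals, JSON keeps full precision.

# Problem sizes exercised

Unit and acceptance tests run the full pipeline at $n = 1045$ with ten
shuffles (the study scale), recovery experiments at $n = 2000$ with 30
shuffles, exhaustive-mining equivalence against a brute-force oracle on
hundreds of random small instances (2–4 models), and NMS equivalence
against an $O(n^2)$ oracle on random box sets.

# Limitations

- The generator models predictor errors as independent across models
  given the truth; real image models share failure modes (lighting,
  occlusion), which would reduce the effective information in patterns.
- Complete specificity over finitely many shuffles is a noisy filter:
  patterns qualified on the selection shuffles are optimistically scored
  there (hence `honest_eval`), and union coverage on selection shuffles
  slightly overstates generalisable coverage.
- Concentration marginals are matched to range and mean only; skewness
  and tail behaviour of real cohorts are not calibrated.
- The letterbox/NMS module covers the geometric and post-processing
  contracts of the detection front end, not detection itself.
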