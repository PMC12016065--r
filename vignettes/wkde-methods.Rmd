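---
title: "Kernel density epigenetic clocks: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel density epigenetic clocks: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wkdeclock)
```

## The model

Aging leaves reproducible traces in DNA methylation: at certain CpG
sites the beta value (fraction of methylated alleles, here expressed as
a percentage) drifts with chronological age. Conventional epigenetic
clocks summarize this drift with linear regressions. `wkdeclock` instead
keeps, for every signature CpG $k$, the full empirical relationship
between age and methylation as a bivariate Gaussian kernel density
$K_{i,j,k}$ evaluated on a fixed grid — 101 age nodes ($i = 0, \dots,
100$ years) by 101 DNAm nodes ($j = 0, \dots, 100\%$). The density at a
grid node is the average of Gaussian bumps centered on the training
pairs:

$$K(g_{\text{age}}, g_{\text{dnam}}) \;=\; \frac{1}{n} \sum_{l=1}^{n}
\varphi_{s_a}\!\left(g_{\text{age}} - \text{age}_l\right)\,
\varphi_{s_d}\!\left(g_{\text{dnam}} - \text{DNAm}_l\right),$$

where $\varphi_s$ is the normal density with standard deviation $s$.
The axis bandwidths default to the normal-reference rule
$h = 4 \cdot 1.06 \cdot \min(\widehat{\sigma}, \text{IQR}/1.34)\,
n^{-1/5}$ (type-7 quartiles), and the working standard deviation is
$s = h/4$, the convention of the classical `kde2d` implementation this
reproduces. No per-kernel renormalization is applied after fitting:
prediction consumes the relative magnitudes across DNAm rows as they
are.

A new sample with methylation $\text{DNAm}(k)$ selects the density row
nearest to its DNAm value in each kernel (round-half-up to the unit
grid) and the clock aggregates rows across CpGs with weights $w_k \in
[-10, 10]$:

$$\widehat{\text{age}} = \arg\max_{i \in [0,100]}
\sum_k w_k \, K_{i,\,\text{DNAm}(k),\,k}.$$

Dividing the same weighted profile by its total turns it into a
probability distribution over ages. Two views of that distribution
matter:

* the **weighted** distribution drives the point prediction and is what
  the genetic algorithm optimizes;
* the **unweighted** distribution ($w_k \equiv 1$) feeds the *variation
  score* — the standard deviation of the age distribution after linear
  interpolation to 0.1-year resolution. It quantifies how much the
  signature CpGs disagree about the sample's age. The interval
  $\widehat{\text{age}} \pm \text{score}$ is reported alongside every
  prediction, and `coverage_fraction()` measures how often the
  chronological age falls inside it.

## Correcting for training-set age imbalance

Blood methylation cohorts over-represent middle-aged adults, which
biases the argmax toward over-represented ages. Two corrections are
implemented, as alternatives (they address the same problem and are not
combined):

1. **Uniform-age subsampling** (default): the training set is split
   into 5-year bins from 0 to 90 years plus one overflow bin for ages
   above 90, and 15 samples are drawn per bin — 285 when all 19 bins are
   full. Age exactly 90 belongs to the last regular bin, since the
   overflow bin is defined for ages strictly older than 90. Bins holding
   fewer than 15 samples contribute everything they have; this
   "take-all" policy is a package decision for cohorts whose extremes
   are sparse, and is logged when it triggers.
2. **Age-histogram normalization**: each age column of every kernel is
   divided by the count of training samples with that rounded age.
   Samples above 85 years are excluded from the counts, because their
   scarcity would otherwise explode the corrected densities; zero-count
   columns are zeroed, excluding those ages from the argmax.

## Weight optimization

The genetic algorithm minimizes the total absolute training error
$\sum_l |\text{age}_l - \widehat{\text{age}}_l(w)|$. Only four scalar
parameters of the recipe are fixed by convention — population 150, 100
generations, keep fraction 0.4, mutation rate 0.1 — so the concrete
operators are this package's own instantiation, chosen for bounded
real-valued genomes and strict determinism under a seed: truncation
selection (top 40% by rank survive), arithmetic crossover of two
distinct uniformly chosen survivors with a fresh uniform blend per gene,
uniform-reset mutation within $[-10, 10]$, and elitist tracking of the
best-ever individual. The unit vector $(1, \dots, 1)$ is always injected
into the initial population, which guarantees the optimized clock is
never worse than the unweighted clock on training data. Objective
evaluations run against a cached matrix of pre-looked-up density rows
(one 101-vector per sample × CpG); cache correctness against the direct
model traversal is itself a tested contract. The full recipe (150 × 100
evaluations, 27 CpGs, a few hundred cached samples) completes in a few
seconds on one CPU.

Negative weights are legitimate — a CpG can be informative through the
*low*-density ages it rules out. They can push parts of the weighted
profile below zero; the probability view floors negative entries at zero
before renormalizing (and flags that it did), while the argmax is taken
on the raw weighted sum so that flooring never changes the point
prediction.

## Numerical choices and degenerate inputs

* **Grid lookup.** DNAm values map to the nearest grid node with
  round-half-up; the training data's own convention for this is not
  observable, so the simplest deterministic rule was chosen.
* **Argmax ties** break toward the smallest age, making predictions
  deterministic (a flat profile predicts age 0).
* **Fine grid.** The 0.1-year interpolation uses 1001 points
  ($x = 0, \dots, 1000$, age $= x/10$), and the interpolated vector is
  renormalized to a proper probability mass function before moments are
  taken. An alternative "literal" mode applies fixed 0.1 prefactors to
  the unrenormalized vector instead; its mean and variance formulas are
  on mutually inconsistent scales unless the vector sums to one, so the
  renormalized form is the default and the literal form is retained
  only for comparison.
* **Interpolation smoothing.** A probability vector that is a unit
  point mass at an integer age becomes a triangular tent of half-width
  one year on the fine grid, so its variation score is
  $\sqrt{1/6} \approx 0.41$ years rather than exactly zero. This is an
  inherent property of interpolating before taking moments, and the
  tests treat it as the exact expected value. The uniform distribution
  keeps its closed form $0.1\sqrt{(1001^2 - 1)/12} \approx 28.90$.
* **Degenerate kernels.** A CpG with (near-)constant methylation has no
  usable bandwidth; kernel fitting refuses it with a pointer to remove
  the invariant CpG. Signature selection already flags zero-variance
  CpGs as undefined, so this arises only with hand-picked signatures.
* **Missing values** are never imputed. Selection uses
  pairwise-complete correlations and excludes CpGs with more than 20%
  missing values (a conservative, configurable default); prediction
  skips missing CpGs per sample and reports `n_cpgs_used`; the GA drops
  training samples with incomplete signatures; the multivariable
  baseline refuses samples with missing features while the averaged
  single-CpG baseline averages over what is available.

## The synthetic cohort generator

All tests and the acceptance analysis run on simulated cohorts, so the
generator is first-class, tested code. It emulates the features the
method actually relies on:

* **Trajectories.** Informative CpGs follow
  $\mu_k(\text{age}) = \beta_{0k} \pm \beta_{1k} \log(\text{age} + 1)$
  — the logarithmic shape that dominates strong age-associated blood
  CpGs, with fast drift in childhood and saturation late in life — with
  slopes $\beta_{1k} \in [9, 15]$% per log-year (a lifetime change of
  roughly 40–65%, the scale of the strongest clock CpGs) and baselines
  in $[5, 25]$% (mirrored at $100 - \beta_0$ for decreasing CpGs). A
  linear shape is available for oracle tests. Noise CpGs are flat.
* **Noise and saturation.** Gaussian noise with per-CpG sd drawn from
  $[2, 5]$%, then clipping to $[0, 100]$ — clipped rather than
  truncated-renormalized, which is sufficient to produce the saturation
  plateaus real CpGs show near 0 and 100% methylation.
* **Batch structure.** Each (study, CpG) pair receives an offset drawn
  from $N(0, \tau)$ with $\tau = 2$% by default, reproducing the
  between-study offsets at individual CpGs that degrade cross-study
  transfer of the raw (unweighted) kernel clock.
* **Ages.** The default "skewed" mixture (20% uniform 0–20 children,
  50% $N(50, 15)$, 30% $N(72, 9)$, truncated to $[0, 100]$) mimics the
  adult-heavy composition of public blood cohorts and is what makes the
  uniform-age subsampling step do real work.
* **Disease mode.** For a configured fraction of CpGs (default half),
  each diseased sample receives an independent per-CpG shift
  $\sim N(0, \sigma_d)$ before clipping. This decouples the affected
  CpGs' apparent ages from one another without touching chronological
  age — exactly the heterogeneity the variation score is designed to
  detect. With $\sigma_d = 0$ the diseased generator is bit-identical
  to the healthy one under the same seed.

The default scenario — 1000 samples, 30 CpGs (27 informative + 3
noise), 2 studies — mirrors the scale of a real multi-study training
set. On it, a clock trained on study 1 and validated on study 2 reaches
validation $r^2 \approx 0.94$, median absolute error of ~4–5 years and
~99% coverage of the $\pm$ variation-score interval, and a disease
cohort with $\sigma_d = 20$% shifts the median variation score clearly
above matched healthy controls.

What the generator does **not** emulate: cell-type composition and its
age trends, probe-level measurement artifacts, non-Gaussian outliers,
and realistic correlation structure *between* CpGs (CpGs are
conditionally independent given age). Passing tests therefore
demonstrate that the algorithms implement the intended mathematics and
that the pipeline behaves sensibly under the assumed generative model —
not that a clock trained here transfers to real arrays.

## Problem sizes used in tests and the acceptance analysis

Unit tests use cohorts of 50–600 samples and 2–12 CpGs; the acceptance
analysis uses the full default scenario (1000 samples, 27-CpG signature,
GA with population 150 for 100 generations). These sizes keep every
property checkable by brute force while exercising the same code paths
as a full-size run.

## Known limitations

* Predictions exist only inside the grid: ages above 100 cannot be
  predicted, and kernels say nothing about ages absent from the
  training range.
* The variation score's absolute scale depends on the kernel
  bandwidths; comparisons are meaningful within one model, not across
  models fitted with different bandwidth settings.
* The GA is a stochastic heuristic: different seeds give different
  (similarly performing) weight vectors, and nothing guarantees a
  global optimum — only that the result never falls behind the
  unweighted clock on training data.
* With large signatures the weight search can overfit; the
  27-CpG-scale signature is the intended operating point.
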