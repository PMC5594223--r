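---
title: "Methods: MVAR connectivity, SPECT perfusion, and nested-CV classification"
author: "eegspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MVAR connectivity, SPECT perfusion, and nested-CV classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegspect)
```

## The problem

Amnestic complaints in the elderly can stem from very different conditions —
subjective cognitive complaints (aSCC), amnestic mild cognitive impairment
(aMCI), Alzheimer's dementia (AD), or depression with cognitive impairment
(DCI) — whose differential diagnosis is clinically hard but decisive for
treatment. `eegspect` implements a quantitative pipeline that classifies these
groups pairwise from two cheap, widely available modalities: resting-state
EEG, summarized as directed spectral connectivity between 17 scalp
electrodes, and HMPAO-SPECT perfusion, summarized as 46 region-to-cerebellum
count ratios. Because no patient data are distributed with the package, a
synthetic cohort generator reproduces the statistical structure the analysis
assumes, so that every stage is testable end to end.

## EEG model and spectral connectivity

Each three-minute, artifact-free EEG segment (17 channels, 200 Hz) is modeled
as a multivariate autoregressive (MVAR) process

$$X(t) = \sum_{k=1}^{p} A_k X(t-k) + E(t), \qquad E(t) \sim (0, \Sigma).$$

`fitMVAR()` estimates $A_1,\dots,A_p$ and $\Sigma$ with a multichannel
Levinson-type partial-correlation recursion (Vieira–Morf): at every stage the
forward/backward prediction-error covariances and their cross-covariance are
estimated empirically with *unbiased* normalization (divisor $n-k$ at lag
$k$), the normalized partial-correlation matrix is formed through Cholesky
square roots, and the reflection coefficients update the coefficient stack by
the Levinson–Wiggins–Robinson recursion. The per-channel mean is removed
first; there is no detrending, filtering or variance normalization. The
production model order is $p = 100$ (half the sampling rate, so a full cycle
of a 2 Hz rhythm lies inside the model memory); correctness is
order-independent and the tests use small orders. On long stable simulations
the estimator agrees with an explicit least-squares lagged regression to
within $2\times10^{-2}$ entrywise (measured: about $2\times10^{-5}$ at
$n = 20{,}000$).

The fitted model is evaluated on the grid $f = 2, 3, \dots, 80$ Hz:

$$\bar A(f) = I - \sum_k A_k e^{-i 2\pi f k / f_s}, \qquad
  H(f) = \bar A(f)^{-1}, \qquad S(f) = H(f)\, \Sigma\, H(f)^*. $$

No $1/f_s$ scaling is applied to $S$; only relative values reach the
classifier. From these matrices the 14 interaction measures are derived, with
the orientation convention that entry $(i, j)$ is the influence of source $j$
on sink $i$:

* **Raw moduli** $|S_{ij}|$, $|H_{ij}|$ ("h"), $|\bar A_{ij}|$ ("Af"), with
  diagonals retained (autospectra are informative).
* **Coherency family**: $C_{ij} = S_{ij} / \sqrt{S_{ii} S_{jj}}$; COH is
  $|C_{ij}|$ (magnitude, not magnitude squared — a documented choice), iCOH
  is $\mathrm{Im}\,C_{ij}$, and pCOH is
  $|P_{ij}|/\sqrt{P_{ii}P_{jj}}$ with $P = S^{-1}$.
* **PDC family** (column-normalized outflow of $\bar A$): PDC, PDCF
  (normalized by $\bar a_j^* \Sigma^{-1} \bar a_j$), GPDC (residual-variance
  weighted).
* **DTF family** (row-normalized inflow of $H$): DTF, ffDTF (normalized over
  the whole grid), dDTF $=$ ffDTF $\times$ pCOH.
* **Granger family**: Geweke's spectral Granger causality
  $\mathrm{GGC}_{ij}(f) = \ln\!\big(S_{ii} / (S_{ii} - (\Sigma_{jj} -
  \Sigma_{ij}^2/\Sigma_{ii}) |H_{ij}|^2)\big)$, clipped below at zero, and DC,
  the direct causal gain $|\bar A_{ij}|$ off the diagonal. The GGC formula
  (with its conditional-variance correction) and the $|\bar A_{ij}|$ reading
  of DC are documented package choices.

All complex quantities are reduced to real values (modulus, except iCOH:
imaginary part) *before* band averaging, because the downstream t-tests and
SVM need real features. Band averages are arithmetic means over the integer
frequencies delta 2–4, theta 5–7, alpha 8–13, beta 14–30 and gamma 31–80 Hz.

Two structural identities are enforced at machine precision and tested on
every fitted model: $\sum_i \mathrm{PDC}_{ij}^2 = 1$ per source and
frequency, and $\sum_j \mathrm{DTF}_{ij}^2 = 1$ per sink and frequency.
A caveat worth stating explicitly: plain PDC and DTF are *not* invariant
under channel-wise rescaling of the signal (GPDC exists precisely to repair
this); the whole normalized family is invariant under *uniform* rescaling.
The tests assert both facts.

## Graph reduction

Each band-averaged $17\times17$ matrix can be reduced to five global graph
metrics. The matrix is made non-negative, the diagonal is zeroed, and weights
are rescaled to $[0,1]$ by the matrix maximum; fully weighted graphs are used
throughout (no binarization threshold — the analysis choice is documented, not
claimed to match any particular toolbox configuration):

* out–in degree-correlation **assortativity** (weighted Pearson correlation,
  over directed edges, of source out-strength vs target in-strength),
* **global efficiency** (mean inverse shortest-path length, edge length
  $1/w$, disconnected pairs contribute 0),
* mean directed weighted **clustering coefficient** (geometric-mean triangle
  form),
* **modularity** of a deterministic greedy agglomerative partition of the
  symmetrized graph (no stochastic community detection, so runs are exactly
  reproducible), floored at the trivial one-block partition's $Q = 0$,
* weighted **transitivity** (total triangle intensity over total triple
  count).

Degenerate graphs (fewer than two edges, zero degree variance) yield
flagged-missing values that are imputed to 0 with a log message when feature
vectors are assembled. Metrics are invariant to channel permutation and to
positive rescaling of the raw matrix.

## SPECT profile

The SPECT side is a fixed-length vector of 46 cerebellar perfusion ratios:
22 anatomical regions, left and right hemisphere interleaved per region,
plus pons+midbrain and a remaining-subcortical region. The left/right
interleaving is a package convention (the source material lists the regions
without printing an order). `normalizeCounts()` performs the cerebellar
count normalization for real data; the synthetic generator draws directly in
ratio space. Region names are a closed vocabulary and unknown names are
rejected at parse time.

## Feature scenarios

Seven feature-vector scenarios are assembled from a single per-cohort feature
table (a `SummarizedExperiment`, features × subjects, with full provenance in
`rowData`): one EEG measure alone ($17\cdot17\cdot5 = 1445$ features), SPECT
alone (46), their concatenation (1491), the deduplicated union of the
*optimized* per-measure selections ("EEG merged", with and without the
optimized SPECT selection), and the graph reduction ($14\cdot5\cdot5 = 350$
features, with and without SPECT). Duplicated features in merged vectors are
kept once (a documented choice). Diagonal electrode pairs are included, which
is why the per-measure count is exactly $17^2\cdot5$.

## Classifier and nested cross-validation

The classifier is a linear 2-norm soft-margin SVM: the exact convex primal
$\tfrac12\|w\|^2 + C\sum_i \max(0, 1 - y_i(w^\top x_i + b))^2$ is minimized
by a finite Newton iteration over active sets (the objective is piecewise
quadratic, so each step is one small ridge solve; a halving line search keeps
it monotone). Installed SVM implementations penalize the 1-norm of the slack,
so the 2-norm machine is authored here and cross-checked against `e1071` on
separable data, where both must classify identically. Features are
standardized to training-set mean and variance before every fit — applied
identically across scenarios; the default cost is $C = 1$.

Selection and evaluation follow a strict three-layer nested design:

1. **Outer layer**: one stratified 90/10 split. The 10% test set is touched
   exactly once, by the final model.
2. **Middle layer**: 10 stratified folds over the outer training set. Each
   fold ranks all features by a two-sample pooled-variance t-test computed
   *only on its own training subjects* (ascending p, ties by column index;
   zero-variance features get $p = 1$), then runs greedy forward selection.
3. **Inner layer**: each candidate vector is scored by 10-fold stratified
   cross-validated SVM accuracy. A candidate feature is kept only if
   (i) overall accuracy is at least the maximum of all previously obtained
   accuracies, (ii) while the best first-group accuracy is below 0.75, the
   new first-group accuracy is at least that maximum, and (iii) while the
   best second-group accuracy is below 0.5, the new second-group accuracy
   strictly exceeds that maximum. Search stops when features are exhausted,
   at 40 selected features, or after consecutive rejections exceeding 10% of
   the available features.

Per middle fold this yields one optimized feature list; features selected in
at least 3 of 10 folds survive (falling back to 2, then 1, if empty), capped
at the 41 most-voted (ties broken by better mean in-fold selection position,
then feature index). The growth cap 40 and final cap 41 belong to different
stages and are both honored. The final SVM is trained on the full outer
training set and evaluated once on the outer test set, reporting overall
accuracy, per-group accuracies (the per-group proportion of correct
predictions; the first-listed group plays the "sensitivity" role), and the
maximum-chance criterion $\max(n_1, n_2)/(n_1+n_2)$.

Numerical choices that matter: inner-CV accuracies are compared as exact
integer counts of correct predictions (every subject is predicted exactly
once per candidate), so criterion (i)'s tie-acceptance cannot be corrupted by
floating-point artifacts; "best so far" maxima are tracked over every
evaluated candidate, accepted or not, which is the stricter reading of the
procedure; the outer layer is a single split (a repeat-outer design would
change the reported quantity, not the procedure); middle-layer folds are
drawn independently per run. All randomness derives from one master seed, so
a full pipeline result is a pure function of (cohort, configuration, seed);
fold memberships are recorded in the result for audit, and a dedicated test
asserts that outer-test subjects never enter ranking or inner CV.

## Synthetic cohorts: what they emulate, and what they do not

The generator produces group-labelled subjects whose EEG is a realization of
a group-specific stable MVAR template and whose SPECT vector is drawn from
group-specific regional means. The generative model deliberately *is* the
analysis model, so parameter recovery is an exact oracle — structural zeros
in the template are preserved by the relative (magnitude-proportional)
per-subject coefficient jitter, and injected directed couplings reappear as
one-sided PDC.

Defaults mirror the study conditions: group sizes 41/71/39/69 (aSCC, aMCI,
AD, DCI), 17 channels at 200 Hz, 180 s per subject. The generator order is
$p_{\text{gen}} = 5$ (small and interpretable, independent of the analysis
order); burn-in is $\max(1000, 10p)$ samples; jittered models are
rejection-sampled for stability (at most 100 retries); SPECT draws are
truncated at zero by redraw, not clipping, keeping means unbiased for small
standard deviations. Because the source material reports no quantitative
effect sizes for group differences, those are free parameters chosen once: a
directed low-frequency coupling difference of 0.25 between the most separated
groups, an AD temporoparietal perfusion reduction of 0.15 ratio units
(3 standard deviations at the default regional SD of 0.05), and a
per-subject jitter of 0.05. What the generator does *not* emulate: EEG
artifacts, volume conduction, electrode geometry, non-stationarity, or any
claim that the synthetic effect sizes match patient data — so passing tests
demonstrate the correctness and calibration of the *pipeline*, not clinical
accuracy on real cohorts.

## Problem sizes used by the test and acceptance runs

The correctness of every stage is order- and size-independent, so the
automated runs use a reduced profile chosen for tight iteration: 4-channel
cohorts, generator and analysis order 5, 500–2000 samples per subject, and
SPECT-only or single-measure scenarios for the end-to-end properties
(estimator oracles use $n = 20{,}000$ samples; null calibration uses 20
cohorts of 20+20 subjects; the effect-detection run uses 60+60). The
production profile (17 channels, order 100, 36,000 samples) is exercised for
shape and contract correctness. Heavier profiles change runtime, not code
paths.

## Known limitations

* The exact formula behind the "direct causality" measure is not printed in
  the source material's main text; $|\bar A_{ij}(f)|$ off the diagonal is the
  documented stand-in, and COH is coherency magnitude rather than magnitude
  squared.
* The greedy, p-value-ordered search explores a tiny fraction of feature
  subsets; it is reproduced as specified, not improved.
* With a single stratified 90/10 outer split the reported accuracy rests on
  a small test set (8 of 80 subjects for the smallest pair), so single-run
  accuracies are coarse-grained by construction; calibration properties are
  therefore asserted over many seeds.
* Graph metric variants (weighted/directed choices) are documented package
  defaults; other toolbox configurations would give different feature values.
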