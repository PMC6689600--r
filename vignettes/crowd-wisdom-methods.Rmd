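---
title: "Crowd wisdom as one-dimensional dimension reduction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowd wisdom as one-dimensional dimension reduction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdwisdom)
```

## The problem and the model

A crowd of $k$ individuals — people, algorithms, or datasets — each answers
the same $n$ binary (yes/no) questions, either with a 0/1 vote or with a
continuous confidence score. The goal of crowd wisdom is a single consensus
ranking of the questions that is more accurate than most (ideally all)
individuals, without access to any ground truth.

The modelling idea this package is built around is that the quantity every
individual is actually estimating is not the binary answer but an
intermediate *class probability* $p_i = P(\text{yes} \mid \text{all relevant
data})$ for each question $i$. Individuals observe noisy, individually
biased versions of this one number. In the simplest linear form,

$$ r_{ji} \sim \mathcal{N}(\alpha_j \, p_i, \; 1), \qquad
   \alpha_j \sim \mathcal{N}(\bar\alpha, \sigma_\alpha^2), $$

where $r_{ji}$ is individual $j$'s response to question $i$ and $\alpha_j$
is the individual's skill: large positive $\alpha_j$ means strong signal,
$\alpha_j \approx 0$ means noise, and $\alpha_j < 0$ means a
*worse-than-random* individual whose answers anti-correlate with the truth.

Because every column of the $n \times k$ response matrix is parametrized by
the same latent scalar $p_i$, the questions lie — up to noise — on a
one-dimensional structure in $k$-dimensional response space. Recovering the
consensus is therefore a one-dimensional *unsupervised dimension reduction*
problem: the first (and only) embedding coordinate estimates the class
probability up to a monotone transformation and a global sign. This
reframing buys two things over classical binary-vote aggregators:

* continuous confidence information is used rather than thresholded away;
* individuals are weighted by estimated reliability, so an adversarial
  individual contributes *negative* weight instead of cancelling signal the
  way it does under a plain mean.

## Pipeline

`response_matrix()` holds questions in rows and individuals in columns,
everywhere. `normalize_responses()` makes individuals comparable:
continuous responses are rank-transformed per individual (ties averaged),
then every column is z-scored; binary votes are z-scored directly. Rank
conversion makes the pipeline invariant to any strictly increasing
per-individual recalibration of confidences.

`aggregate_crowd()` embeds the questions into one dimension:

| method | family | free parameter |
|---|---|---|
| `pca` | linear projection (leading right-singular direction) | — |
| `factor_analysis` | one-factor model, per-individual noise | — |
| `mds_classical` | Torgerson scaling of Euclidean distances | — |
| `lle`, `hessian_lle`, `ltsa` | local linear/tangent reconstructions | `n_neighbors` |
| `isomap` | geodesic distances + classical scaling | `n_neighbors` |
| `spectral` | normalized graph-Laplacian eigenmap | `n_neighbors` |
| `mean`, `median` | row statistics (baselines) | — |

For PCA the per-individual loadings are returned as `weights`; they are an
unsupervised estimate of each individual's accuracy. `sml()` provides the
classical binary-vote counterpart (spectral meta-learner): the leading
eigenvector of the inter-rater covariance with its unreliable diagonal
iteratively re-imputed from the current rank-one fit.

Sign indeterminacy is intrinsic to any 1-D embedding and is handled twice,
for two different purposes. During analysis, `align_sign()` orients the
consensus with the majority of the crowd (valid whenever more than half the
individuals are better than random). During evaluation,
`evaluate_oriented()` sidesteps the assumption entirely by scoring both the
output and its negative and reporting the better one; the same rule is
applied to the supervised baselines in `run_cv()` so no method gains an
orientation advantage.

## Simulator

`simulate_crowd()` draws a stream of pairs $(p \sim
\mathrm{Beta}(\beta,\beta),\; c \sim \mathrm{Bernoulli}(p))$ and keeps, in
draw order, the first $\mathrm{round}(n\,P(\text{yes}))$ yes questions and
the first $n - \mathrm{round}(n\,P(\text{yes}))$ no questions, then
shuffles. This rejection-stream construction fixes the class counts exactly
while preserving the joint distribution of $(p, c)$ conditional on the
class — resampling $c$ given a quota would not. Skills and responses then
follow the Gaussian model above, and the normalized matrix is attached.

Parameters, defaults, and what they mean:

| parameter | default | role |
|---|---|---|
| `n` | 1000 | questions |
| `k` | 10 | individuals |
| `p_yes` | 0.3 | positive-class frequency (count forced to `round(n*p_yes)`) |
| `beta` | 1 | question difficulty; 1 = uniform class probabilities, larger = harder |
| `alpha_mean` | 1 | mean skill |
| `alpha_sd` | 1 | skill spread; at 1 ≈ 16% of individuals are worse than random |
| `seed` | 1 | all randomness; sub-seeds per stage are derived deterministically |

The defaults are this package's reference condition, chosen to exercise a
mixed-quality crowd including adversarial members. They are a repository
convention, stated here once, and all replication experiments in the tests
and the acceptance script declare their parameters explicitly.

What the simulator deliberately does **not** emulate: correlated errors
between individuals (e.g. shared training data), question-dependent skill,
missing responses, and any nonlinearity between the class probability and
an individual's score beyond the monotone link. Passing tests on simulated
crowds therefore demonstrate correctness of the machinery and the
qualitative claims under conditional independence; they do not certify
performance on crowds with strongly correlated raters.

`perfect_binarize()` converts confidences to votes under the assumption
most favourable to binary aggregators: every individual knows the true
number of positives and marks exactly that many top-confidence questions
as yes (boundary ties drawn uniformly at random with an explicit seed).
Any sensitivity loss measured against this idealized binarization is a
lower bound on the loss under realistic thresholding.

## Numerical choices

* **Variance convention.** Normalization scales by the *population*
  standard deviation (divide by $n$), matching the standard-scaler
  convention; the `normalized` state is validated at $|\mu| < 10^{-9}$,
  $|\sigma^2 - 1| < 10^{-9}$.
* **Embedding sign.** Before semantic orientation, the raw eigen/SVD sign
  is fixed by making the entry of largest magnitude positive, so repeated
  runs are bit-identical.
* **Factor analysis.** One-factor EM with noise variances initialized at 1,
  loadings from the first principal direction, a floor of $10^{-8}$ on the
  noise variances, convergence on a per-question log-likelihood change
  below $10^{-6}$, and a 1000-iteration cap. Non-convergence returns the
  best iterate with a warning and is flagged in the result. Posterior
  factor scores are the consensus; the one-factor fit has no rotation
  ambiguity beyond sign.
* **Manifold embeddings.** The neighbour graph is built on Euclidean
  distances of normalized question rows, symmetrized by union, with
  distance ties broken by row index. Isomap computes geodesics with
  shortest paths and applies classical scaling; a disconnected graph is an
  error advising a larger `n_neighbors`. LLE uses the standard local Gram
  regularization ($10^{-3}\,\mathrm{tr}$); Hessian LLE with one target
  dimension needs `n_neighbors >= 3`; LTSA accumulates `I - G G'` over
  local tangent frames. All take the eigenvector of the smallest non-trivial
  eigenvalue.
* **SML.** Votes are recoded to ±1; the covariance diagonal starts at the
  mean off-diagonal magnitude and is re-imputed as $\lambda v^2$ until the
  maximum change is below $10^{-8}$ (cap 1000). A weighted vote sum of
  exactly 0 predicts yes; an all-equal prediction vector sets the
  `degenerate` flag, which replicate studies use as their exclusion rule.
* **ROC/PR.** One descending threshold sweep powers both curves, with tied
  scores entering as a group. AUROC is the rank-based Mann–Whitney
  statistic (ties half credit); AUPR is non-interpolated average precision
  — conventions differ between libraries, so this one is stated. The
  matched-FPR lookup evaluates the oriented ROC by linear interpolation
  between adjacent vertices, taking the upper point of a vertical segment.
* **Count-matched thresholding.** `threshold_match_positives()` breaks
  boundary ties by question index, deterministically — unlike the
  binarization step, replicate *comparisons* should not carry extra
  randomness.

## Design choices where the design was open

* **MDS variant.** Classical (Torgerson) scaling is included as the
  deterministic reading of "MDS"; non-metric MDS would introduce
  optimization randomness for no clear benefit in this setting (and on the
  complete neighbour graph Isomap already reduces to classical MDS, which
  the tests verify).
* **Factor-analysis consensus.** The posterior factor score is used as the
  consensus; any other monotone functional of the one-factor fit would give
  the same ranking-based metrics.
* **Normalization before SML.** Dimension-reduction methods consume the
  normalized matrix; SML consumes raw ±1-coded votes, as its covariance
  model is defined on votes. (For binary data the two differ only by a
  per-column affine map, which the covariance eigenvector is insensitive to
  up to scaling.)
* **Supervised roster.** Linear, lasso, elastic-net, logistic regression,
  LDA, random forest and kNN over the neighbour grid {5, 7, 10, 15, 25,
  40, 60, 90}. SVM is excluded from the default roster; the roster is a
  plain list of `fit`/`score` contracts, so adding one is a three-line
  user-side change.
* **Class-count rounding.** `round(n * p_yes)` positives, so arbitrary
  `(n, p_yes)` are usable; combinations rounding a class to zero are
  rejected.

## Problem sizes used by the tests

The unit suite runs on matrices between 2×2 and 1000×50 and completes in
well under a minute. The end-to-end claims are checked at a reference scale
chosen to keep the full suite fast while leaving each comparison's margin
far above its Monte-Carlo noise: 1000 questions throughout; 100 replicates
per crowd size for the SML→thresholded-PCA agreement study over
$k \in \{10, 50, 150\}$; 25 replicates per $k \in \{10, 50, 250\}$ for
class-probability recovery; 50 replicates for the adversarial-crowd
comparison ($\bar\alpha = 0.5, \sigma_\alpha = 1$, $k = 30$); 100
replicates for the binarization-loss measurement; and 50 stratified splits
at a 25% training fraction for the cross-validation benchmark. The
acceptance script (`scripts/acceptance.R`) recomputes the same quantities
from scratch at these scales.

## Known limitations

* Missing responses are rejected, not imputed; the model requires a
  complete matrix.
* Conditional independence between individuals is assumed everywhere; a
  block of highly correlated raters will be over-weighted.
* LLE-family embeddings are sensitive to noise and neighbourhood size and
  can be unreliable on noisy crowds; PCA, factor analysis and Isomap are
  the robust choices, with the mean/median baselines retained mainly as
  negative controls for the worse-than-random phenomenon.
* The CV harness evaluates on held-out questions within one dataset; it
  says nothing about transfer across datasets or time.
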