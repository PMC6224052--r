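---
title: "Clustering monthly service-utilization trajectories with mixtures of hidden Markov models"
author: "mhmmclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering monthly service-utilization trajectories with mixtures of hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhmmclust)
```

## The model

Claimants injured in transport accidents use compensable healthcare
services (here: psychology) at monthly counts that rise, persist and decay
on very different schedules. `mhmmclust` models one claimant's aligned
monthly count series $x_{1:T}$ (month 1 = first utilization, month $T$ =
last) with a hidden Markov model: a latent state $y_t \in \{1,\dots,N\}$
follows a Markov chain with initial distribution $\pi$ and transition
matrix $A$, and the observed count follows the state's categorical
emission row $B_{y_t}$ over the support $\{0,\dots,K-1\}$:

$$p(x_{1:T}, y_{1:T}) = p(y_1) \prod_{t=2}^{T} p(y_t \mid y_{t-1})
  \prod_{t=1}^{T} p(x_t \mid y_t).$$

Heterogeneity across claimants is captured by a finite mixture of $M$ such
HMMs: a cluster indicator $z$ with weights $w = p(z)$ selects which
component generated the whole series,

$$p(x_{1:T}, y_{1:T}, z) = p(z)\, p(y_1 \mid z)
  \prod_{t=2}^{T} p(y_t \mid y_{t-1}, z)
  \prod_{t=1}^{T} p(x_t \mid y_t, z),$$

so clustering whole trajectories and describing each cluster's utilization
regimes (states, dwell times, transitions) happen in one likelihood-based
fit. The assumptions to keep in mind: emissions are conditionally
independent given states; one shared $N$ across components; series length
$T$ is *not* modeled (two clusters that differ only in duration are
indistinguishable to the likelihood); and months are exchangeable across
claimants once aligned at first utilization.

## Fitting

`fit_mhmm()` runs EM (Baum-Welch) jointly over all series. The E-step
computes per-series cluster responsibilities and, inside each component,
state occupancies by the forward-backward recursions; the M-step
re-normalizes expected counts. Numerical choices:

* **Scaled recursions.** The mixture E-step uses the classical scaled
  (Rabiner) forward-backward in linear space, which avoids `exp`/`log` in
  the inner loops; the user-facing single-HMM functions (`hmm_loglik()`,
  `hmm_forward_backward()`, `hmm_viterbi()`) use log-space with
  log-sum-exp. Both routes agree to $10^{-8}$ and are tested against
  exhaustive path enumeration.
* **Emission floor.** During fitting every emission row receives a floor
  of $10^{-10}$ before renormalization so EM never produces a $-\infty$
  for an observed count. Models supplied by the user are scored exactly as
  given.
* **Boundary-truncated likelihood (default).** Aligned series start and
  end at a month with at least one visit *by construction of the data*:
  the series is trimmed to the first and last utilization month. The first
  and last emissions are therefore zero-truncated draws, and fitting the
  plain likelihood transfers probability mass away from count 0 in
  low-utilization states. With `boundary = TRUE` (default) the likelihood
  conditions the boundary emissions on positivity and the M-step augments
  the expected zero counts by $B_{s0}/(1-B_{s0})$ per truncated month —
  the standard truncated-count treatment, which keeps the M-step in closed
  form and the EM exactly monotone in the truncated likelihood. Set
  `boundary = FALSE` for the plain model.
* **Initialization and restarts.** Series are grouped by a one-dimensional
  k-means on a per-series summary (mean monthly count on odd restarts, the
  90th-percentile count on even restarts — the upper quantile isolates
  small clusters of short very-high bursts that the mean dilutes). Within
  a group, state $s$ is seeded on the $s$-th quantile band of the group's
  counts, highest band first, so the utilization ladder is represented
  from iteration one; jitter on all rows differentiates restarts. Default
  `restarts = 5`, `tol = 1e-6` (relative log-likelihood improvement),
  `max_iter = 500`. Purely random initialization was found to stall in
  poor optima often enough to corrupt model selection.
* **Label switching.** Clusters are reported in decreasing size order
  (cluster 1 is always the largest, the reference-cluster convention) and
  states within a cluster in decreasing expected-emission order; Viterbi
  ties break toward the lower state index. All outputs are deterministic
  given a seed.

`select_mhmm()` fits every pair on a grid (default $M \in \{2,3,4\}$,
$N \in \{2,3\}$) and selects by BIC, with AIC reported alongside. The free
parameter count is $(M-1) + M[(N-1) + N(N-1) + N(K-1)]$. The BIC sample
size is the total number of monthly observations $\sum_i T_i$ by default
(each month is a datum under the likelihood); `n_obs = "series"` switches
to the number of series, the convention that counts independent sampling
units. The paper-style grid bounds and the choice between these
conventions are left to the user because neither is canonical for
mixtures of sequences.

## The synthetic cohort

Real compensation claims are restricted, so `default_scenario()` encodes a
fully known generative truth that emulates their published descriptives:
788-claimant cohorts, three clusters with weights $(0.67, 0.27, 0.06)$,
monthly counts on $0,\dots,24$ ($K = 25$), series lengths 2-106 months
with mean about 29, and the three qualitative regimes — *brief* (a medium
state of about 4 visits/month decaying through low to a sticky zero
state), *intermediate* (starting high at about 8 visits/month, decaying
more slowly), *sustained* (very-high and high states held for most of a
long series). Design choices worth knowing:

* **Lengths** are cluster-specific shifted negative binomials
  ($T = 2 + \mathrm{NB}$, truncated at 106) with means (22, 40, 70) months
  and decreasing dispersion; `scenario_mean_length()` gives the analytic
  mean.
* **Emission shapes** mix three families deliberately: zero-truncated
  Poisson for the brief cluster's in-care states (an active treatment
  month has at least one visit, hurdle-style — this also makes the zero
  state own all zero months, which is what identifies it), plain Poisson
  for moderate regimes, and binomial rows for the sustained cluster's high
  regimes (visits capped by monthly appointment capacity, hence narrower
  than Poisson). The three clusters' state ladders are deliberately
  misaligned (e.g. medium means 4.0 vs 4.9) so that a smaller mixture
  cannot cheaply serve two clusters with shared states — separation that
  the published cluster descriptions imply but restricted data cannot
  confirm.
* **Boundary positivity** is enforced the way the data construction
  implies: the first and last emissions are resampled from the emission
  distribution conditioned on a positive count (a truncation, counted in
  the `truncated_draws` attribute), never by post-hoc editing.
* **Covariates** are drawn by rejection: a claimant's covariates are
  proposed from the published marginal frequencies (gender 52/48; age
  bands 35/22/21/13/9; roles 48/23/16/12/3; nine injury-flag rates;
  elapsed time from accident to first utilization
  $\sim \Gamma(1.2, 1.2)$ years) and accepted with probability
  $p(z_i \mid x)$ under a known multinomial-logit coefficient matrix
  (reference cluster 1). Among accepted draws the covariate law given the
  label is exactly Bayes-consistent with that logit, so every *slope* of
  the generating model is recoverable by multinomial logistic regression;
  intercepts shift by a computable constant, which is why recovery checks
  assert slopes only.

What the generator does **not** emulate: calendar seasonality, covariate
dependence of the series themselves (covariates influence only cluster
membership), payment fields, within-claimant service-type interactions,
and administrative truncation at the observation-window end. Passing
recovery tests therefore demonstrate correctness of the machinery under a
claims-like generative model, not performance on real claims.

## Summaries

`label_states()` names each state from its expected emission
$e_s = \sum_k k B_{sk}$: below 0.5 "zero", below 2 "low", below 5
"medium", below 10 "high", else "very high". The thresholds are a
reporting convention (configurable), chosen so that the default
scenario's nine states span all five labels. `stacked_counts()` /
`stacked_states()` produce the tidy tables behind stacked trajectory
plots (per month, how many active series show each count or decoded
state; tallies always sum to the number of series still active).
`state_diagram()` reports each state's emission pie with slices under
0.01 merged into "other", the expected dwell $1/(1 - A_{ss})$ months
(absorbing states flagged), and above-threshold transitions as edges.
`cluster_report()` gives sizes, shares, mean lengths, mean yearly
utilization and the fraction of active series at zero by month.

## Baseline comparison

`compare_clusterings()` re-runs the partition-based baselines on the same
data: PAM (build/swap k-medoids), CLARA (PAM on subsamples of 50, best
full-data cost of 5 draws) and fuzzy c-means (fuzzifier 2, hard labels by
maximum membership), plus silhouette summaries, the Dunn index and a
classical (Torgerson) 2-D MDS projection. Variable-length series are
right-padded with zeros to a common length and compared with Euclidean
distance — the vectorization is *our* assumption (none is canonical for
variable-length count series), the metric argument of `series_dist()` is
pluggable, and all baseline comparisons should be read structurally. One
honest consequence: silhouette and Dunn measure exactly the Euclidean
compactness that PAM/CLARA/FCM optimize, so under this vectorization the
likelihood-based MHMM partition does not generally win those indexes on
synthetic cohorts, even when it recovers the generative clusters almost
perfectly and the baselines do not. The published comparison used an
unstated vectorization; this package reports the indexes and lets them
speak.

## Membership regression

`model_suite()` explains hard cluster labels with four nested multinomial
logits (via `nnet::multinom`): demographics (gender, age group); plus
injury flags (brain head, soft tissue, non-limb fractures); plus elapsed
time in years from accident to first utilization; plus road-user role.
Reference choices follow the field convention: the largest cluster,
female, under-30, pedestrian. Standard errors come from the observed
information; p-values are two-sided Wald tests starred at 0.1 / 0.05 /
0.01 without multiplicity correction; rows with a missing modeled
covariate are dropped per model on the largest covariate set so the four
log-likelihoods are comparable. True perfect separation (the
response constant within a predictor level) and rank-deficient designs
are reported as errors rather than silently regularized; sparse-cell
quasi-separation — a small cluster unobserved at a rare covariate level,
routine at study scale — is instead warned about and kept, with the
inflated standard error speaking for itself.

## Problem sizes used by the tests

The test-suite experiments run at sizes chosen to exercise the claims
while staying quick: oracle equivalence on 200 random instances with
$T \le 6$, $N \le 3$, $K \le 5$ (exhaustive enumeration is exact there);
parameter recovery on one 800-claimant cohort (5 restarts); BIC
model-selection recovery on ten 400-claimant replicates; regression
calibration pooled over twelve 5000-claimant null replicates. The
acceptance script reproduces the headline quantities at the 788-claimant
study scale.

## Known limitations

Series length carries real information about utilization behavior but is
outside the likelihood; clusters differing mainly in duration separate
only through their emission/transition footprints. The shared-$N$
convention can over-parameterize simple clusters. BIC's sample-size
convention materially shifts the penalty (see above). The boundary
truncation treats first and last months symmetrically, while in real data
the last observed month may instead be censoring by the extraction
window. Soft (posterior-weighted) membership regression is not
implemented; hard labels feed the regression, matching the
assign-then-regress workflow.
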