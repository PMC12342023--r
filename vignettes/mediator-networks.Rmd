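---
title: "Dynamic network and Bayesian network analysis of mediator time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network and Bayesian network analysis of mediator time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynamed)
```

## The problem

Multiplexed immunoassay panels measure dozens of inflammatory mediators
(cytokines, chemokines, DAMPs such as HMGB1, stress factors such as GDF-15)
in the same serum or culture-supernatant samples over time. In small,
deeply-phenotyped cohorts — for instance pediatric acute liver failure
patients dichotomized into spontaneous survivors (S) and non-survivors
(NS), or hepatocyte cultures from wild-type versus HMGB1-knockout mice with
or without an acetaminophen insult — the scientific questions are less about
any single mediator than about the *organization* of the response: which
mediators move together, when, in which subgroup, and which mediators appear
to drive the others.

`dynamed` implements the two network views used for such data, the
univariate outcome statistics that accompany them, and a synthetic-data
generator with planted ground truth so that every inference stage can be
validated end to end without access to patient data.

## Dynamic network analysis (DyNA)

For each pair of adjacent sampling times $(t_k, t_{k+1})$ — e.g. d0–d1
through d6–d7 for a daily serum series, or 1–3, 3–6, 6–24, 24–48 h for a
culture time course — DyNA pools all subgroup samples at the two boundary
times and computes the Pearson correlation $r$ for every mediator pair. An
edge connects a pair when $|r| \ge \theta$, with the stringency $\theta$
defaulting to 0.85 and the threshold inclusive; the sign of $r$ is kept
(parallel vs anti-parallel movement). Per interval, the network complexity
is

$$\mathrm{complexity} = \frac{\sum_i N_i}{n - 1} = \frac{2E}{n-1},$$

where $N_i$ is the degree of mediator $i$, $E$ the number of edges, and $n$
the size of the analyzed panel. The total number of connections is the sum
of $E$ over all intervals; per-mediator connectivity sums a mediator's
degree over intervals.

Choices a user should know about:

* **Pooling mode.** The default `"levels"` mode treats each subject-by-time
  sample at the two boundary times as one observation. The alternative
  `"differences"` mode correlates per-subject changes across the interval
  (requiring both samples). Both are one switch apart
  (`buildNetworks(..., mode = )`) and the mode is recorded in the result,
  because the phrase "trajectories that move in parallel" genuinely admits
  both readings.
* **Pairwise deletion.** Each correlation uses the complete pairs for its
  two mediators; with few subjects this preserves the most data. A pair
  with fewer than `minPairs` (default 4) complete observations, or a
  mediator with zero variance in the window, is *undefined* — never an
  edge, but also never silently a zero. Excluded mediators still count in
  $n$ for the complexity denominator: they are part of the analyzed panel.
* **Tie at the threshold.** $|r| = \theta$ exactly is an edge (inclusive
  rule).

## Dynamic Bayesian network inference (DyBN)

DyNA is symmetric and interval-local. To ask which mediators *drive* which,
the package fits a first-order dynamic Bayesian network: each mediator at
time $t+1$ depends on a parent set of mediators (possibly including itself
— a self-loop) at time $t$. Because edges always point from $t$ to $t+1$,
no acyclicity constraint is needed and each child's family can be scored
independently.

Concentrations are log-transformed and z-scored per mediator within the
subgroup, then lag-1 transitions are pooled across subjects; a gap in a
subject's series breaks the chain (strict-consecutive policy) rather than
bridging over a missing day. Unequal grid spacing (e.g. the 6→24 h step) is
treated as a single transition and flagged in the result metadata.

**Scoring.** Families are scored with the Bayesian Gaussian equivalent
(BGe) marginal likelihood: under a Normal–Wishart prior, the marginal
likelihood of the data restricted to any variable subset is available in
closed form, and the family score is the marginal of
$\{\text{child}_{t+1}\} \cup \text{parents}_t$ minus the marginal of the
parents alone. Subsets of size $l$ are scored with Wishart degrees of
freedom $\alpha_w - d + l$ (the subset adjustment that makes
Markov-equivalent structures score identically — verified in the test suite
to $10^{-10}$, and against quadrature and importance-sampling integration
of the Normal–Wishart integral to $10^{-3}$ in log). Defaults, serialized
with every result: $\alpha_\mu = 1$, $\alpha_w = d + 2$,
$T_0 = 0.5\,I$ on z-scored data — conventional weak-prior choices.

**Changepoints.** Mediator dynamics need not be homogeneous over the
acute course, so each node may place changepoints on the time grid: the
Gaussian parameters of its family switch between segments while the
*structure is held fixed* across segments. The number of changepoints per
node carries a truncated Poisson($\lambda = 1$) prior with
`kMax` defaulting to 1 — series of 5–8 time points cannot support more
segments — and a minimum segment length of 2 transitions.

**Sampling.** A Metropolis–Hastings sampler mixes structure moves
(add/remove/swap one parent of a uniformly chosen node, fan-in limit 3) and
changepoint moves (birth/death/relocation), with proposal-count ratios
preserving detailed balance. Edge posteriors are inclusion frequencies over
retained samples; the sampler is deterministic given its seed, and with
`kMax = 0` it reduces exactly to the homogeneous model, where exhaustive
enumeration (`dybnExact`) is feasible for small panels and the test suite
requires agreement within 0.05. The consensus graph keeps directed edges
with posterior at or above a threshold (default 0.5; the consensus rule is
configurable because a single "final graph" admits several thresholds);
nodes whose self-loop passes are the self-feedback set, and self-feedback
nodes with at least one connection to another node are labelled central
(high-feedback) nodes. Arrows carry no sign.

## Outcome-biomarker statistics

* `mannWhitney`: U with midranks; exact two-sided p (null distribution of
  U) when the smaller group has at most 8 observations and no ties,
  otherwise the normal approximation with tie-corrected variance and
  continuity correction.
* `spearmanTest`: $\rho$ as Pearson on midranks; exact full-enumeration
  permutation p for $n \le 8$ ($8! = 40320$ arrangements), t-approximation
  with $n-2$ df above that — enumeration at $n = 9, 10$ costs seconds to
  minutes per call for negligible accuracy gain at those sizes.
* `rocAnalysis`: full ROC curve, trapezoid AUC (equal to
  $U/(n_1 n_2)$ with ties as one half — an identity the tests assert
  exactly), Youden-J optimal cutoff with ties broken toward the lowest
  cutoff, and automatic orientation (recorded) so AUC $\ge 0.5$ unless a
  positive group is named.
* `volcanoAnalysis`: fold change as the ratio of geometric means
  (concentrations are lognormal-like; the mean type is a package choice),
  p from the rank-sum test on all pooled time points, classification
  `up`/`down`/`not-significant` with inclusive fold-change threshold 2.0
  and $p < 0.05$, no multiple-testing correction. Pooling time points
  treats repeated measures as independent samples; the result carries a
  `pooled_time_points` flag because this is deliberate pseudo-replication,
  matching how such panels are usually screened.

## The synthetic-data generator

`generateDataset` simulates, per subject, a latent log-scale process

$$x_{t+1,i} = a_i(t)\, x_{t,i} + \textstyle\sum_j b_{ij}\, x_{t,j} +
\varepsilon_{t,i},$$

with stationary per-mediator standard deviation `latentLogSd`, node-specific
AR coefficients $a_i(t)$ that may switch at changepoints, and optional
cross couplings $b_{ij}$. Observed concentrations are
$\exp(\text{baseline} + \log \text{fold} + x + \text{noise})$, with
mediator baselines on realistic log-concentration scales, multiplicative
subgroup fold changes (aligning with the volcano's fold-change axis), and
missing-completely-at-random dropout.

Interval-local correlations are *planted* by replacing the boundary-time
values of the involved mediators with draws from a joint correlation
matrix. Because the correlation networks operate on raw concentrations,
the generator inverts the lognormal attenuation — a log-scale correlation
$\rho$ between variables with total log-variance $s^2$ yields linear-scale
Pearson $(e^{\rho s^2} - 1)/(e^{s^2} - 1)$ — so the *observed* correlation
hits the planted target (`latentCorrelationFor`). Two structural rules
follow from this design and are validated before any sampling: pairs
planted in the same window must form cliques or be node-disjoint (the
implied matrix must be positive semi-definite; a high-correlation star with
independent spokes is not a correlation matrix), and in the built-in
presets adjacent planted intervals use disjoint mediator sets, because a
boundary time shared by two planted windows is claimed by the earlier
window and would dilute the later one.

Two stylized presets encode the emulated study designs:

* `palfPreset()` — 28 human serum mediators, S $n = 14$ vs NS $n = 7$,
  daily samples d0–d7; GDF-15 elevated (fold 3) and MIG suppressed
  (fold 0.4) in NS, high HMGB1 in both, AR self-feedback on HMGB1 and
  GDF-15, a denser planted correlation structure in NS than in S (14 vs 5
  pair-windows at $r = 0.9$), and an S-only motif in which MIG bridges
  HMGB1 and GDF-15 (with the weaker implied HMGB1–GDF-15 correlation
  planted for positive semi-definiteness).
* `hepatocytePreset()` — 23 mouse mediators, four arms (WT/KO ×
  control/APAP) with 3–5 cultures per arm at 1, 3, 6, 24, 48 h; knockout
  arms have HMGB1 near zero and an attenuated GDF-15 response; planted
  correlations are denser in WT-APAP than in the knockout arms.

Effect sizes are stylized (`meta$stylized = TRUE`): the presets reproduce
the *shape* and the qualitative ground-truth structure of the emulated
studies, not fitted concentration ranges. What passing tests show is that
the inference machinery recovers known structure of the right kind at the
right sample sizes; they cannot show that real cohorts satisfy the
generator's assumptions. Features of real data the generator does not
emulate: persistent per-subject random effects (omitted because they would
masquerade as self-feedback and dilute planted cross-correlations),
informative dropout, detection-limit censoring beyond the ingestion
policy, and assay batch effects.

## Numerical choices and degenerate inputs

* Correlations: undefined (never zero) below `minPairs = 4` complete pairs
  or under zero variance; excluded mediators are reported with reasons.
* Volcano: the inclusive fold-change boundary uses a $10^{-9}$ relative
  guard so a fold change equal to the threshold up to floating error still
  classifies.
* BGe: determinants via Cholesky; a singular posterior scale matrix raises
  an error with its condition number. Empty segments and empty parent sets
  score exactly 0 and $\log p(\text{child columns})$ respectively.
* MCMC: proposals violating fan-in, `kMax` or minimum segment length are
  rejected; an acceptance rate below 1% during burn-in triggers a
  diagnostic warning; family scores are memoized.
* Seeds: everything stochastic is keyed by an explicit seed; pipeline
  stages derive per-stage seeds from the global one (kept below $2^{31}$).

## Problem sizes used in the validation suite

The shipped tests exercise: 100 random datasets (≤6 mediators, ≤3
intervals, 10–30 subjects) against a brute-force correlation/threshold
oracle; 1000 random graphs for the complexity identity; 100 generator
replicates for planted-correlation recovery (sensitivity ≥ 0.9, per-pair
false-positive rate ≤ 0.05 at threshold 0.85); BGe scores against
numerical-integration oracles at $N \le 5$ with up to 2 parents; MCMC vs
exact enumeration at 3 mediators and 50 000 iterations (within ±0.05);
self-feedback recovery with AR(1) = 0.8 on 2 of 5 mediators at the serum
study's shape (21 subjects × 8 times, ≥9/10 seeds); the AUC–U identity and
exact rank-test enumeration at all $n_1, n_2 \le 5$; a 1000-replicate null
calibration of the volcano significance gate; and the full pipeline on the
serum preset with the NS-vs-S density ordering over 10 seeds.

## Known limitations

* With 3–5 replicates per arm (the hepatocyte design), window correlations
  use 6–10 samples and a 0.85 threshold admits a non-trivial
  false-positive rate; the serum design (14–28 samples per window) is much
  better behaved. This mirrors the method itself, not an implementation
  artifact.
* Changepoint inference with `kMax = 1` on 5–8 time points is coarse by
  construction; the machinery supports larger `kMax` for longer series.
* The DyBN treats subjects as i.i.d. realizations of one process per
  subgroup; subject-level heterogeneity is not modelled.
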