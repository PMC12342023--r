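# dynamed

Dynamic network and dynamic Bayesian network analysis of longitudinal
inflammatory-mediator panels.

Multiplexed immunoassays measure dozens of mediators (cytokines,
chemokines, DAMPs such as HMGB1, stress factors such as GDF-15) in the same
samples over time — serum from patient subgroups with different outcomes,
or supernatants from hepatocyte cultures under genetic and pharmacological
perturbation. `dynamed` is for analysts of such panels who need to move
beyond per-mediator comparisons to the *organization* of the response:
which mediators move together in each time window, how network complexity
differs between subgroups, and which mediators the dynamics suggest are
drivers rather than passengers.

## What it computes

**DyNA — interval-wise correlation networks.** For each pair of adjacent
sampling times, mediator pairs are connected when their Pearson correlation
satisfies |r| ≥ θ (default stringency θ = 0.85, inclusive), with the sign
retained. Per interval, network complexity is

    complexity = (N₁ + N₂ + … + Nₙ) / (n − 1) = 2E / (n − 1)

for node degrees Nᵢ, edge count E and panel size n; the total number of
connections sums E over intervals, and per-mediator connectivity sums a
mediator's degree.

**DyBN — BGe-scored dynamic Bayesian networks.** A first-order model in
which each mediator at time t+1 depends on a parent set (possibly
including itself — a self-loop) at time t. Families are scored with the
closed-form Bayesian Gaussian equivalent (BGe) marginal likelihood under a
Normal–Wishart prior; node-specific changepoints let Gaussian parameters
switch along the time course while the structure stays fixed.
Metropolis–Hastings sampling over parent sets and changepoints yields
posterior edge probabilities, a thresholded consensus digraph, and the
self-feedback / central (high-feedback) node sets.

**Outcome statistics.** Mann–Whitney rank-sum (exact for small tie-free
samples), Spearman correlation against covariates such as age, ROC/AUC
with Youden-optimal cutoff (AUC ≡ U/(n₁n₂), asserted exactly in the
tests), and volcano classification at fold-change 2.0 and p < 0.05.

**Synthetic data with ground truth.** A generator plants subgroup fold
changes, interval-local correlations (hit on the observed concentration
scale by inverting the lognormal attenuation), AR(1) self-feedback,
cross-couplings and changepoints, with presets emulating a 28-mediator
serum study (14 vs 7 subjects, d0–d7) and a 23-mediator hepatocyte
experiment (4 arms, 1–48 h).

## Worked example

```r
library(dynamed)

g  <- generateDataset(palfPreset(), seed = 7)
ds <- g$dataset
ds
#> MediatorDataset
#>   4561 measurements | 28 mediators | 8 time points | subgroups: S, NS
#>   subjects: 21 | censored values: 0 | missing values: 0

nets <- buildNetworks(ds, "NS", threshold = 0.85)
nets
#> DynamicNetworkSet
#>   subgroup NS | 7 intervals | threshold 0.85 | mode levels
#>   edges per interval: 3, 0, 3, 2, 0, 0, 1 | total connections: 9

head(as.data.frame(volcanoAnalysis(ds, "S", "NS")), 3)
#>   mediator    log2fc fold_change      p.value class
#> 1   GDF-15  1.605798   3.0436398 2.791527e-22    up
#> 2      MIG -1.384351   0.3830619 1.762800e-19  down
#> 3     IL-6  1.086445   2.1235007 3.817264e-15    up

m  <- measurements(ds)
mm <- m[m$mediator == "GDF-15" & !is.na(m$value), ]
rocAnalysis(mm$value, mm$subgroup, positive = "NS")
#> ROC: AUC = 0.963 (positive = NS), optimal cutoff = 2505
```

The volcano table says that in this synthetic non-survivor subgroup GDF-15
is elevated about 3-fold (classified `up`) and MIG suppressed (`down`),
matching the planted ground truth; the ROC says pooled GDF-15
concentrations discriminate the subgroups almost perfectly (AUC 0.96).
The interval networks are denser in NS than in S (planted: 14 vs 5
pair-windows), which `compareSubgroups(runAll(runConfig("palf")), "S", "NS")`
summarizes side by side.

For the driver analysis:

```r
tt   <- buildTransitions(ds, "NS")       # z-scored lag-1 transitions
post <- dybnSample(tt, iterations = 20000, burnIn = 5000, seed = 1)
consensusGraph(post, threshold = 0.5)    # edges, self-feedback, central nodes
```

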