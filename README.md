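# radtempo

Comparative-phylogenetics tools for asking whether a clade — an island
radiation of frogs, say — diversified **early and fast**, in two currencies at
once: lineages and morphology. The package is aimed at systematists and
evolutionary ecologists who have a time-calibrated phylogeny (typically a
maximum clade credibility tree plus a Bayesian posterior sample), a
specimen-level morphometric table, and a habitat-ecotype classification, and
who want the classic tempo-and-mode battery run end to end with explicit
seeds and machine-readable output.

## What it computes

**Tempo of lineage accumulation.**

- The γ statistic of Pybus & Harvey. With internode intervals
  `g_k` (duration with exactly *k* reconstructed lineages) and total
  lineage-time `T = Σ k·g_k`,

      γ = [ (1/(n−2)) Σ_{i=2}^{n−1} Σ_{k=2}^{i} k·g_k − T/2 ] / [ T·√(1/(12(n−2))) ]

  γ is asymptotically N(0,1) under a constant-rate pure-birth process;
  γ < −1.645 (one-sided) indicates nodes concentrated toward the root — an
  early burst. Significance against exemplar-choice artifacts uses a
  random-pruning null: γ recomputed on replicate trees in which the full tree
  is randomly pruned to the same tip count.
- Maximum-likelihood fits and AICc/Akaike-weight ranking of three
  diversification models on the branching times: constant-rate pure birth
  (`lnL = ln((n−1)!) + (n−2)·ln λ − λT`), exponentially time-varying pure
  birth (`λ(t) = λ₀·e^{αt}`, *t* = age before present), and constant-rate
  birth–death (Nee et al. reconstructed-process likelihood). Fits are
  summarized across a posterior tree sample as best-fit frequencies and mean
  weights.

**Ecomorphology.**

- Specimen → species means on the natural-log scale, ordinary least-squares
  size correction against ln snout–vent length, covariance PCA with a
  ≥ 10 %-variance retention rule, and an ecotype MANOVA using Wilks Λ =
  det(E)/det(H+E) with Rao's F approximation.
- A simulation-based phylogenetic MANOVA: group labels held fixed, the null
  distribution of Wilks Λ built from multivariate Brownian datasets simulated
  on the tree with the rate matrix estimated from the data.

**Tempo of morphological diversification.**

- Phylogenetic size correction (GLS under the tree covariance C), the
  evolutionary rate matrix `R = (X−1a)ᵀC⁻¹(X−1a)/(n−1)`, and phylogenetic PCA
  (eigenanalysis of R, scores about the phylogenetic mean).
- Disparity-through-time: mean relative subclade disparity (average pairwise
  Euclidean distance, subclade over whole clade) at each node time, compared
  with a Brownian-motion simulation band; the morphological disparity index
  (MDI) is the signed area between the observed curve and the simulation
  median, and its posterior distribution is computed across tree samples.
- Brownian-motion vs single-optimum Ornstein–Uhlenbeck fits per PC axis,
  ranked by AICc weights.

**Synthetic data.** Every input can be simulated: constant-rate, early-burst
(decaying-speciation) and birth–death trees; posterior-like ensembles with
jittered node ages; clade-structured ecotype regimes; species trait means
with allometry and ecotype optima under OU; and specimen tables with 3–10
male specimens per species. `sim_radiation()` bundles a complete study
fixture in one call.

## Worked example

```r
library(radtempo)

sim <- sim_radiation(n_posterior = 20, seed = 1)      # early-burst scenario
report <- run_radiation(
  sim$tree, sim$specimens, sim$ecotypes, posterior = sim$posterior,
  nsim = list(gamma_null = 1000, manova = 1000, dtt = 2000, dtt_tree = 300),
  seed = 2)
report
```

```
== Radiation tempo report ==
Constant-rates (gamma) test
  gamma = -2.818  (n = 18 tips)
  one-sided 5% critical value under pure birth: -1.645
Gamma over 20 posterior trees
  median = -2.769 ; 95% interval ( -3.942 , -1.139 )
Diversification model comparison (n = 18 tips, AICc sample size 16 )
  model lambda alpha        mu   lnL k   AICc delta  weight
 expvar 0.7549 4.887        NA 37.11 2 -69.30 0.000 0.92774
   yule 2.6344    NA        NA 33.00 1 -63.72 5.579 0.05701
     bd 2.6344    NA 1.707e-13 33.00 2 -61.08 8.217 0.01525
Diversification models across 20 posterior trees
  model best_freq second_freq mean_weight sd_weight
 expvar      0.65        0.35     0.68884   0.32785
   yule      0.35        0.65     0.24549   0.25866
     bd      0.00        0.00     0.06567   0.06919
PCA: 15 axes; 2 retained
variance fractions: 0.7506, 0.1017, 0.0355, 0.0339, 0.0207, 0.0156 ...
MANOVA (Wilks): 18 species, 2 variables, 3 groups
  lambda = 0.01861 ; F( 4 , 28 ) = 44.31 ; P = 1.014e-11
Phylogenetic PCA: 14 axes; 2 retained (variance fraction >= rule)
variance fractions: 0.6349, 0.1172, 0.0702, 0.0493, 0.0409 ...
Disparity-through-time vs 2000 BM simulations
  MDI = -0.08631
MDI over 20 posterior trees
  median = -0.07324 ; 95% interval ( -0.1382 , -0.01424 )
```

Reading the output: γ = −2.82 is far below the −1.645 one-sided threshold and
the posterior interval stays negative — lineage accumulation slowed sharply
after an early burst. The time-varying speciation model carries almost all
the AICc weight on this tree and wins on 65 % of the posterior. The ecotype
MANOVA (Wilks Λ = 0.019) says habitat classes occupy distinct regions of
morphospace. The MDI is negative with a 95 % posterior interval excluding
zero: subclades partition morphological disparity among themselves, as
expected when ecotype optima map onto clades. `write_report(report, "out/")`
emits the same numbers as CSV/JSON tables.

Real data enter through `read_trees()` (Newick or NEXUS with translate
tables), a specimen CSV (columns `specimen_id`, `species`, `sex`, and the 15
measurement columns named as in `radtempo:::.measurement_names`), and an
ecotype CSV (species, class).

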