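---
title: "Tempo of lineage and morphological diversification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tempo of lineage and morphological diversification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtempo)
```

This vignette is the package's own account of the statistics it implements,
the assumptions behind them, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical choices that a
maintainer would otherwise have to reverse-engineer from the code.

## The two questions

An adaptive radiation makes two linked predictions. First, lineages should
accumulate fastest early, when ecological opportunity is greatest, and slow
down as niches fill. Second, morphological disparity should be structured by
that history: habitat specialists (here, ground, shrub and tree-hole
ecotypes) occupy distinct regions of morphospace, and the partitioning of
disparity among subclades through time departs from a simple random walk.
The package tests both, on a time-calibrated species tree plus a posterior
tree sample, species-mean morphometrics, and an ecotype map.

## Lineage tempo

### The γ statistic

All information about tempo under a pure-birth model is in the internode
intervals $g_k$ (the time during which exactly $k$ reconstructed lineages
existed, $k = 2..n$). With $T = \sum_k k\,g_k$,

$$\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1}\left(\sum_{k=2}^{i} k\,g_k\right) - T/2}
               {T\sqrt{1/(12(n-2))}}.$$

Under a constant-rate pure-birth process the normalized node heights are
uniform, making γ asymptotically standard normal; the package's own
generator reproduces the one-sided 5% critical value −1.645 by simulation
(the acceptance script recomputes it). γ is scale-free: rescaling all branch
lengths leaves it unchanged.

Two sources of uncertainty are propagated. *Exemplar choice*: when the
analysis tree is one exemplar per lineage pruned from a larger tree, a null
distribution is built by randomly pruning the full tree to the same size
(`gamma_prune_test()`), with a lower-tail $p = (\#\{\gamma_{null} \le
\gamma_{obs}\}+1)/(\text{reps}+1)$; the +1 correction avoids zero p-values,
and 1000 replicates is the conventional size. *Phylogenetic uncertainty*: γ
is recomputed on every posterior tree and summarized by the median and an
equal-tail 95% percentile interval (`gamma_posterior()`). Percentile rather
than HPD intervals are used throughout: the distributions involved are
unimodal and the choice is then immaterial at these sample sizes, and
percentiles are reproducible without a density estimator.

### Diversification models

Three models are fitted to the branching times by maximum likelihood
(`fit_diversification()`), all conditioned on the crown event and assuming
complete sampling:

* **Pure birth** (`yule`): $\ln L = \ln((n-1)!) + (n-2)\ln\lambda - \lambda T$,
  with the closed-form maximum $\hat\lambda = (n-2)/T$.
* **Time-varying pure birth** (`expvar`): $\lambda(t) = \lambda_0 e^{\alpha t}$
  with $t$ age before present, so $\alpha > 0$ means faster speciation deeper
  in the past. The log-likelihood sums event terms $\ln((i-1)\lambda(x_i))$
  and subtracts $\int k(t)\lambda(t)\,dt$ with $k(t)$ the piecewise-constant
  lineage count; the per-interval integrals are closed-form, computed with an
  `expm1`-based kernel stable through $\alpha \to 0$.
* **Constant-rate birth–death** (`bd`): the reconstructed-process likelihood
  in terms of $r = \lambda - \mu$ and $a = \mu/\lambda$.

The combinatorial constant $\ln((n-1)!)$ is included in all three so that the
reductions `expvar(α=0)` ≡ `yule` and `bd(μ=0)` ≡ `yule` are exact equalities
(tests assert them at 1e−10); it cancels in AICc differences. Saturated-
diversity and extinction-bearing time-varying variants of the wider
coalescent model family are out of scope; the table machinery is
model-agnostic so they can be added.

Ranking uses small-sample AICc, $-2\ln L + 2k + 2k(k+1)/(n_{obs}-k-1)$, and
Akaike weights. The AICc sample size defaults to $n-2$, the number of
informative internode waiting times (the crown age is conditioned on, and
the final interval is fixed by the present); `n_obs = "tips"` is available
since conventions differ. Optimization is multi-start Nelder–Mead on
transformed parameters — $\ln\lambda_0$, free $\alpha$, logit of $a$ — from
the conventional starting point ($\lambda = 0.05$, $\alpha = 10^{-5}$), the
pure-birth MLE, and four random starts; the pure-birth fit itself is a
bracketed 1-d optimization polished by a root-find on the finite-difference
score, so it matches the closed form to ~1e−10. Across a posterior sample,
`posterior_models()` tallies best-fit and second-best frequencies and the
mean and SD of each model's weight.

## Ecomorphology

Measurements are natural-log transformed *before* specimen averaging, so a
species value is the log geometric mean and the size regression is an
allometric power law; a `log = FALSE` switch gives raw-scale means. The
non-phylogenetic size correction is ordinary least squares of each character
on ln snout–vent length — deliberately ignoring phylogeny, because the
question at this stage is whether ecotype and form covary in the observed
species, not whether they would after phylogenetic correction. PCA is on the
covariance matrix of SVL plus the 14 residuals (centered, unscaled;
correlation PCA by flag), retaining axes whose variance fraction is ≥ 0.10.
Whether to ln-transform SVL before the PCA is a genuine convention choice;
the package uses the ln scale end to end for consistency.

The ecotype MANOVA reports Wilks $\Lambda = \det(E)/\det(H+E)$ with Rao's F
approximation. The phylogenetic variant (`phylo_manova()`) keeps the
observed group labels fixed and simulates multivariate Brownian datasets on
the tree — rate matrix estimated from the data — recomputing Λ each time;
the phylogenetic p is the lower-tail simulation quantile with the +1
correction, 1000 simulations by default. Because the simulated statistic is
Λ on all characters jointly, this is a MANOVA-style generalization of the
simulation-based phylogenetic ANOVA. On a star tree it agrees with the
classical test up to Monte-Carlo error (tested). Ecotype maps may use any
labels and any number of classes ≥ 2; intermediate classifications (e.g. a
fourth "ground-tree" class) are simply additional labels.

## Phylogenetic trait machinery

With tree covariance $C$ (shared root-to-MRCA path lengths), the package
implements the GLS phylogenetic mean $a = (1^TC^{-1}1)^{-1}1^TC^{-1}X$,
GLS size-correction residuals, the evolutionary rate matrix
$R = (X-1a)^TC^{-1}(X-1a)/(n-1)$ (ML divisor $n$ by flag), and phylogenetic
PCA: eigenvectors of $R$, scores $(X-1a)V$, variance fractions from the
eigenvalues, with the same ≥ 0.10 retention rule. All linear algebra goes
through Cholesky factors of $C$. When a pruned tree retains a stem below the
original root, `prune_to_taxa()` stores it as `root.edge` and `tree_vcv()`
adds it to the whole matrix, so pruning preserves both tip depths and
pairwise MRCA depths exactly.

Eigenvector signs are fixed by making each axis's largest-magnitude loading
positive, so outputs are deterministic across platforms. Loadings are
unit-norm eigenvectors by default; a `"correlation"` mode scales them by the
square roots of the eigenvalues for readers who expect loadings comparable
to correlations.

BM and OU log-likelihoods are exact Gaussian densities. For the
single-optimum OU on an ultrametric tree of depth $T$ the tip covariance is
$\frac{\sigma^2}{2\alpha}e^{-\alpha d_{ij}}(1-e^{-2\alpha t_{ij}})$ with
$t_{ij}$ the MRCA depth and $d_{ij} = 2(T-t_{ij})$. The root state is fixed
at the optimum (non-stationary start); a stationary-start variant is
available by flag, since single-optimum fits are sometimes parameterized
that way and the data cannot distinguish the conventions strongly at these
sample sizes. `fit_evo_models()` profiles $z_0$ and $\sigma^2$ in closed
form and optimizes only $\ln(\alpha T)$ on $[-6, \ln 50]$ by grid plus
golden-section refinement; BM is the $\alpha \to 0$ boundary, so the OU
log-likelihood is kept ≥ the BM one by construction and fits that reach the
boundary are reported as BM-degenerate (the OU weight then equals the pure
AICc-penalty value). AICc here uses sample size $n$ (species), $k = 2$ for
BM and 3 for OU.

Simulators: `simulate_bm()` accumulates branch-wise Gaussian increments with
covariance $R \cdot$ branch length (replicate sweeps share one precomputed
root-path matrix, which is what makes the 10⁴-replicate DTT nulls cheap);
`simulate_ou()` uses exact per-branch OU transitions with per-regime optima
and reduces to BM at $\alpha = 0$.

## Disparity through time

Disparity is the average pairwise Euclidean distance in morphospace (squared
distances by flag); relative subclade disparity divides by the whole-clade
disparity. The DTT curve is evaluated on the tree's own node-time grid,
rescaled to $[0,1]$ from root to present: the value at 0 is 1 by convention
(the clade relative to itself); at each subsequent divergence the lineages
present *just after* that node contribute the relative disparities of their
descendant tip sets (singletons contribute 0); the terminal point $(1, 0)$
is appended. MDI is the left-step integral of (observed − null median) over
that grid — step rather than trapezoid integration, matching the curve's
event-step semantics, and integrating to the present rather than stopping at
the last node. Both conventions exist in the literature; the tests pin this
one against a brute-force time-slice oracle.

The null band simulates Brownian datasets on the PC-score matrix directly
(rate matrix estimated from the scores), mirroring the pipeline order PCA →
DTT, with pointwise equal-tail 95% bands (simultaneous bands are not
attempted). 10 000 simulations is the headline default; per-posterior-tree
sweeps use 1000. `posterior_mdi()` redoes the whole chain per posterior tree
— that tree's $C$, GLS size correction, phylogenetic PCA, requested axes,
DTT, MDI — and summarizes the per-tree MDI list by median and percentile
interval.

## The synthetic-data generator

The generator produces inputs with the statistical structure the analyses
assume, sized like the motivating study system: an 18-species ultrametric
tree, a posterior-like ensemble, three ecotypes painted onto clades, 15
log-linear measurements with allometry on snout–vent length, and 3–10 male
specimens per species with an across-species median of 8 (discrete
triangular specimen-count distribution peaked at 8, since only the range and
median are constrained by the protocol being emulated).

**Trees.** `sim_yule_tree()` draws internode intervals exactly as
independent $\text{Exp}(k\lambda)$ (the present is set just before the
$(n{+}1)$-th split), which *is* the γ null. `sim_slowdown_tree()` simulates
an inhomogeneous pure-birth process whose forward-time rate is
$\lambda_0 e^{-\text{decay}\cdot s}$, via the operational-time transform of
a unit-rate Yule draw; conditional on the realized height this is exactly
the exponential age-form model the likelihood fits, so model recovery is
well-posed. Draws whose operational span exceeds the integrated-rate budget
$\lambda_0/\text{decay}$ are rejected. `sim_bd_tree()` is a forward
birth–death simulation with reject-and-retry, cut just before the event
after $n$ lineages first coexist and pruned of extinct tips; at $\mu = 0$ it
delegates to the Yule generator, making the reduction exact.

**Defaults as emulation targets.** The radiation scenario uses
$\lambda_0 = 10$, decay $= 4.5$, chosen once so that the median γ at
$n = 18$ is ≈ −2.8, the strongly-negative regime the analyses are designed
to detect; ecotype optima separate by 0.5 ln-units along a
climbing-vs-digging contrast (digit-tip widths and webbing against
metatarsal tubercle lengths) with OU pull $\alpha T = 5$ and stationary SD
0.12; intraspecific measurement noise is lognormal with SD 0.08, typical of
repeated linear measurements. The posterior emulator multiplies node ages
by independent lognormal factors with log-SD 0.3 (≈ ×/÷1.8 at 95%),
emulating wide Bayesian divergence-time uncertainty, clipping children below
parents to stay ultrametric.

**What the generator does not emulate — and what that means for the tests.**
Topological uncertainty in the posterior (only ages are jittered);
correlation structure of real Bayesian posteriors; measurement covariance
beyond allometry; and strong convergent reuse of ecotypes across distant
clades. The last point has a visible consequence: with optima mapped onto
clades, disparity is partitioned *among* subclades, so the fixture's MDI on
the optimum-aligned axis is consistently **negative** — the classic
early-burst DTT signature — rather than positive as convergence-dominated
empirical systems can show. The end-to-end checks therefore test that the
MDI credible interval excludes zero under the radiation scenario and covers
zero under the constant-rate/Brownian scenario, without asserting a sign.
Passing tests show the pipeline detects the structure the generator encodes;
they do not certify behavior on data features the generator lacks.

## Numerical choices and degenerate inputs

* Ultrametricity is enforced within a relative tolerance (default 1e−6,
  configurable) and tip depths are symmetrized to their mean before ages are
  taken, absorbing the rounding jitter of exported chronograms.
* Polytomies are rejected by default, resolvable to zero-length binary
  splits by flag; negative branch lengths (possible in MCC trees) are
  rejected or clamped to zero with a warning.
* Ages are measured backward from the present (present = 0); DTT relative
  time runs forward from the root on $[0,1]$. These conventions are used
  everywhere.
* All simulation p-values carry the +1 correction; all intervals are
  equal-tail percentiles.
* Optimizer settings: Nelder–Mead relative tolerance 1e−12 with up to 2000
  iterations, five additional random starts; non-converging models are
  flagged, warned about, and excluded from the weight normalization.
* Wilks Λ requires $n \ge p + g$ (within-group cross-products of full rank);
  the error message suggests reducing dimensions (e.g. using retained PC
  scores).
* Singular tree covariances (duplicate zero-length tips) and zero-variance
  size characters produce immediate errors naming the offending input.

## Problem sizes in the test suite

The statistical tests run at sizes chosen to give stable Monte-Carlo
behavior at desk scale: 5000 pure-birth trees for the γ null distribution;
150 Brownian datasets × 400 simulations for MDI calibration; 400 replicates
at 199 simulations for phylogenetic-MANOVA p uniformity; 100–200 replicates
at $n = 100$ for parameter recovery; and 50 seeds per scenario (16 posterior
trees × 150 simulations each) for the end-to-end contrast. The full suite
runs in roughly three minutes on one core.

## Known limitations

* Extinction-bearing time-varying and saturated-diversity models are not
  implemented; with them absent, support for "slowdown" cannot be separated
  from some extinction scenarios — γ is therefore interpreted jointly with
  the fitted model set, never alone.
* No incomplete-sampling corrections (complete sampling is assumed), no
  rate-shift detection, no clade-specific rates.
* OU fitting is single-optimum; multi-optimum processes appear only in the
  simulator. Fitting a single-optimum OU to multi-optimum data often
  collapses to the BM boundary.
* μ̂ from reconstructed trees is weakly identified; only the net rate
  $r = \lambda - \mu$ is treated as recoverable.
* The phylogenetic MANOVA assumes Brownian motion under the null; heavy-
  tailed or strongly OU-like null processes would change its calibration.
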