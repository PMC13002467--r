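---
title: "A joint latent-space model for brain connectivity and behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A joint latent-space model for brain connectivity and behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilatnet)
```

## The model

`bilatnet` fits a generative Bayesian model that couples two data sources
per participant $i = 1, \dots, N$: a symmetric region-by-region brain
connectivity matrix and a vector of behavioral outcome items.

**Connectivity component.** Each region $u = 1,\dots,V$ carries a
unidimensional latent position $z_{u,i}$, and the observed edge between
regions $u < v$ is

$$x_{u,v,i} = w_i^\top \beta + a_i + z_{u,i}\, z_{v,i} + e_{u,v,i},
  \qquad e_{u,v,i} \sim N(0, \sigma^2),$$

where $w_i$ are participant covariates (first element 1), $a_i$ is a
participant intercept and the bilinear product $z_u z_v$ drives the tie.
Unlike additive node effects, the bilinear effect captures third-order
structure — transitivity, balance, clusterability — that distributed
functional systems induce in connectomes. Self-edges are never modeled;
all sums run over $u < v$. When each edge is standardized across
participants (`standardize_edges()`), node-level additive effects are
unnecessary.

**Behavior component.** Outcomes follow a Rasch-type item model with a
flexible continuous link: item $p$ for participant $i$ is

$$y_{i,p} = h_i^\top \gamma + b_p + \theta_i + \epsilon_{i,p},
  \qquad \epsilon_{i,p} \sim N(0, \tau^2),$$

with item intercepts $b_p$ (fixed, standard-normal prior) and a
per-person latent trait $\theta_i$ (random). Item loadings are fixed at
unity.

**The joint component — where the inference lives.** The two latent
blocks are coupled through a joint multivariate normal prior,

$$(z_{1,i}, \dots, z_{V,i}, \theta_i)^\top \sim
  \mathrm{MVN}(0, \Sigma), \qquad
  \Sigma = \begin{pmatrix} \Lambda_z & \Lambda_{z\theta} \\
  \Lambda_{z\theta}^\top & \Lambda_\theta \end{pmatrix},$$

so the $V$ entries of the cross-covariance block $\Lambda_{z\theta}$
measure, region by region, how latent connectivity co-varies with the
behavioral trait across participants. A region whose 95% credible
interval for its cross-covariance excludes zero is flagged as a
biomarker (`summarize_covariances()`). Priors: $\beta, \gamma \sim
\mathrm{MVN}(0, I)$; $a_i, b_p \sim N(0,1)$; $\sigma^{-2}, \tau^{-2}
\sim \mathrm{gamma}(1/2, 1/2)$; $\Sigma \sim
\mathrm{IW}(I_{V+1},\, V + 3)$, the smallest integer degrees of freedom
with a defined prior mean.

## Estimation

`run_chain()` iterates a fully conjugate six-step Gibbs cycle:
$(\beta, a) \to \sigma^2 \to (\gamma, b) \to \tau^2 \to \{Z, \theta\}
\to \Sigma$. The latent scan updates each participant's regions in index
order and then the trait; participants are conditionally independent and
are drawn as vectorized blocks (the scan itself is compiled code). The
$\Sigma$ step draws from
$\mathrm{IW}(I + F'^\top F',\, N + V + 3)$ with $F'$ the
$N \times (V{+}1)$ matrix of latent rows, so its posterior mean is a
weighted average of the prior scale and the latent sample covariance and
approaches the sample covariance as $N$ grows.

### Reflection indeterminacy

The bilinear likelihood is invariant under negating a whole latent row,
$z_i \mapsto -z_i$, so each participant's sign is identified only softly,
through the prior cross term with $\theta_i$. Three design choices deal
with this; all three were driven by reproducible failure modes observed
on synthetic data:

1. **A reflection Metropolis move.** Single-site scans essentially never
   traverse the reflection modes (flipping a row one region at a time
   passes through astronomically unlikely states), so with scans alone
   the initial random signs freeze and the estimated cross-covariance
   collapses to zero. Each latent scan therefore begins with a
   per-participant Metropolis proposal $z_i \to -z_i$. The likelihood
   cancels under the flip, the acceptance ratio involves only the prior
   cross term ($\log r = 2\,\theta_i\, Q_{\theta z} z_i$ with
   $Q = \Sigma^{-1}$), and the move leaves the posterior exactly
   invariant — it is purely a mixing device, and it is what lets the
   sign field and the cross-covariance order jointly during burn-in.

2. **Alignment of stored draws, not of the chain.** After burn-in the
   first draw of $Z$ is recorded as a reference; every retained draw is
   sign-aligned to it row by row (`align_reflection()`) *as it is
   stored*. Feeding the alignment back into the evolving chain state is
   tempting (it mimics "fixing the signs") but creates a feedback
   pathology: rows forced against their preferred mode fight the prior
   cross term, and the trait variance $\Lambda_\theta$ collapses toward
   zero. Aligning only the stored copies preserves the chain's exact
   stationary distribution while making the latent running means
   sign-coherent.

3. **A global orientation convention.** The two global modes — all rows
   negated, cross-covariance column mirrored — are *exactly*
   equiprobable in the posterior; no data can distinguish them. Draws
   are therefore reported in the orientation whose net cross-covariance
   is positive. Because this is a single whole-sample mirror, it can
   never change which intervals exclude zero; it only fixes the reported
   sign, the way factor-analysis software fixes a loading's sign.

### Mixing, defaults, and multi-start

Defaults are 3000 iterations with 1000 burn-in and no thinning, which is
ample for the signal scenarios used in the package's tests. Null data
(no true cross-covariance) is the hard case: the sign field and the
cross-covariance column form a near-critical system whose joint
fluctuations decorrelate slowly (integrated autocorrelation times of
order $10^2$ iterations), and calibrated credible intervals there need
chains of roughly five thousand iterations at $N = 500$, $V = 20$
or longer. This is why
the hot loops are compiled. `multi_start_fit()` implements the
ten-random-initializations protocol, scoring each start by held-out
behavior imputation and refitting the winner on the full data; see the
caveat below on what that score can and cannot measure on synthetic
data.

The latent scan's prior term uses the exact full conditional derived
from the complete joint precision $\Sigma^{-1}$. A
`region_marginal_prior` switch reproduces instead the variant in which
the prior contribution comes only from the $2 \times 2$
(region, trait) submatrix of $\Sigma$; the exact form is the default
because it preserves the stationary distribution for a general
$\Sigma$.

## The synthetic-data generator

`simulate_dataset()` emulates the simulation design the package is
tested against: latent rows drawn $\mathrm{MVN}(0, \Sigma)$ with unit
variances, where a random subset of $\mathrm{round}(\pi V)$ regions
($\pi$ = signal proportion, grid values 0.1 and 0.3) receives
cross-covariance 0.9 — and the same value within the signal block of
$\Lambda_z$, which keeps $\Sigma$ positive definite; edges add
$N(0, 1/\mathrm{SNR})$ noise (SNR grid 0.5 and 1, latent variance held
at 1 — the simplest monotone reading of "noise controlled by the error
variance at constant signal variance"); a single behavior item adds
$N(0, 0.5)$ noise; intercepts and covariate effects are zero.
`scenario_grid()` enumerates the full
$\{500, 1000, 2000\} \times \{20, 70\} \times \{0.5, 1\} \times
\{0.1, 0.3\}$ factorial of 24 scenarios.

What the generator does **not** emulate: spatial structure, small-world
or modular topologies beyond the planted equicorrelated block,
non-Gaussian edge distributions, site or motion artifacts, and
missing-data mechanisms other than missing-completely-at-random masks.
Passing tests on this design therefore demonstrates correctness of the
inference machinery under the model's own assumptions, not robustness to
real fMRI preprocessing.

## What out-of-sample behavior prediction can and cannot do

This is the package's most important caveat. Under the generative design
above, the latent rows have mean zero, so for any regions $u, v$,
$\mathrm{cov}(z_u z_v,\, \theta) = 0$ exactly (an odd Gaussian moment),
and the bilinear likelihood is invariant to $z_i \to -z_i$. For a test
participant with **no observed behavior**, the posterior of
$(z_i, \theta_i)$ is therefore exactly symmetric under joint negation,
and the model-optimal point prediction of their outcome is a constant.
No clean-holdout method — including edge-wise regression baselines,
whose edge–outcome correlations are identically zero under this design
— can predict the *direction* of an unlabeled participant's trait from
bilinear connectivity alone; only magnitude information survives, and
magnitude carries no linear correlation with the outcome.

`predict_behavior_theta()` and `predict_behavior_z()` are nevertheless
implemented exactly per their contracts (test participants enter the
chain with outcomes masked; imputations are drawn in the sign-aligned
mode so they reflect within-mode uncertainty rather than averaging to
zero across modes), and the package enforces strict train/test hygiene:
masked outcomes provably never influence any training-phase quantity.
Their measured held-out correlations on the synthetic design sit inside
the permutation-null band, as the symmetry argument requires.

The reverse direction is different: `predict_connectivity()` conditions
on *observed* behavior, which pins the trait's sign; the test latent row
is drawn from its conditional given $\theta_i$, and the predicted edge
$E[z_u z_v \mid \theta]$ is a sign-immune quadratic. This direction
genuinely beats the entry-wise training-mean baseline on the planted
signal subgraph, and the package's tests verify it.

## Numerical choices

- Precision partitioning (`partition_precision()`) refuses indefinite
  input with a condition-number diagnostic; reassembly round-trips to
  $10^{-8}$ relative error.
- $\Sigma$ draws are symmetrized after inversion; every stored draw is
  checked positive definite in tests.
- Edge standardization uses the $n - 1$ sample standard deviation and
  errors (listing the offending pairs) on zero-variance edges rather
  than silently dropping them.
- Credible intervals use `stats::quantile` type 7 (inclusive linear
  interpolation); no multiplicity correction across regions is applied,
  matching the per-region reporting convention.
- Zero inner products during sign alignment keep the current sign; a
  zero net cross-covariance keeps the current global orientation.
- Degenerate inputs fail loudly: non-positive-definite $\Sigma$,
  zero-variance outcomes in the correlation metric (NA with a warning,
  never silent 0), empty edge sets for a test participant.

## Problem sizes used by the test suite

The packaged tests run the conjugacy oracles at $N \le 5$, $V \le 3$
with 10,000 draws each; the stationarity oracle compares 200,000 latent
sweeps on a $V = 2$, $P = 1$, $N = 1$ instance against 101-point 3-D
grid quadrature; parameter recovery uses 3 replicates of the
$N = 2000$, $V = 20$, SNR 1, signal-proportion 0.1 scenario; null
calibration uses 20 replicates at $N = 500$ with 5000-iteration chains;
prediction uses 2 repeats of the 100-test-participant protocol at
$N = 500$. These sizes are scaled down from a 100-replicate design; the
replication counts are the package's choice of a test envelope, and all
thresholds are stated in the tests themselves.

## Known limitations

- The behavior latent dimension is fixed at $D = 1$; multi-dimensional
  traits are out of scope.
- One shared covariate effect $\beta$ for all edges; per-edge covariate
  effects are not supported.
- Sign-direction prediction of behavior for fully unlabeled participants
  is impossible under the model (see above); reported behavior-prediction
  correlations on synthetic data are null-level by construction.
- The credible-interval machinery assumes the chain has mixed; on null
  data short chains *will* over-flag. Use the defaults or longer.
- The generator's SNR convention ($\sigma^2 = 1/\mathrm{SNR}$) is one of
  several consistent readings of "controlled by the error variance".
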