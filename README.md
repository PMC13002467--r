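# bilatnet — joint latent-space modeling of brain connectivity and behavior

`bilatnet` is for researchers who ask which brain regions' connectivity
patterns track a behavioral outcome across participants — imaging
biomarker detection — and who want that question answered by a single
generative model with calibrated uncertainty rather than by mass
univariate edge screening.

## The model

For participant *i*, regions *u* < *v* carry symmetric connectivity

> x₍u,v,i₎ = wᵢᵀβ + aᵢ + z₍u,i₎·z₍v,i₎ + e,  e ~ N(0, σ²)

where z₍u,i₎ is a unidimensional latent position per region — the
bilinear product z_u z_v captures the triangular, clustered dependence
structure of connectomes. Behavior items follow a Rasch-type model

> y₍i,p₎ = hᵢᵀγ + b_p + θᵢ + ε,  ε ~ N(0, τ²)

with a per-person latent trait θᵢ. The two latent blocks are coupled by
a joint prior (zᵢ, θᵢ) ~ MVN(0, Σ): the V-vector cross-covariance block
Λ_zθ of Σ is the inferential target, and a region is reported as a
biomarker when the 95% credible interval of its cross-covariance
excludes zero. Estimation is a fully conjugate Gibbs sampler
(inverse-Wishart update for Σ) with explicit handling of the bilinear
term's reflection indeterminacy: a posterior-invariant sign-flip
Metropolis move for mixing, sign alignment of stored draws against a
post-burn-in reference, and a net-positive global orientation
convention. The package also ships the simulation-study generator (24
scenarios: N ∈ {500, 1000, 2000}, V ∈ {20, 70}, SNR ∈ {0.5, 1}, signal
proportion ∈ {0.1, 0.3}), CPM / lasso / CCA comparators, dual-direction
out-of-sample prediction, and weighted-graph topology statistics
(strength, shifted closeness, betweenness). See the methods vignette
(`vignettes/joint-latent-model.Rmd`) for the estimation details and the
package's identifiability caveats.

## Worked example

Simulate the core study scenario — 500 participants, 20 regions, SNR 1,
10% signal regions with true cross-covariance 0.9 — fit the model, and
read off the biomarker report:

```r
library(bilatnet)

cfg <- simulation_config(n_participants = 500, n_regions = 20, snr = 1,
                         signal_proportion = 0.1, seed = 42)
sim <- simulate_dataset(cfg)
sim$truth$signal_regions
#> [1]  5 17

fit <- run_chain(sim$connectivity, sim$behavior, prior_spec(20),
                 sampler_config(n_iterations = 3000, burn_in = 1000, seed = 1))
report <- summarize_covariances(fit)
report[report$significant, ]
#>    region posterior_mean    ci_low  ci_high significant
#> 5       5      0.8949540 0.7481869 1.059376        TRUE
#> 17      17      0.9172191 0.7717256 1.084187        TRUE

power_specificity(report, sim$truth)
#>       power specificity
#>           1           1
```

The two planted signal regions (5 and 17) are recovered exactly — their
posterior means sit at the true value 0.9 with intervals excluding zero
— and none of the 18 null regions is flagged. The same fitted object
feeds prediction (`predict_connectivity()`, `predict_behavior_theta()`)
and the latent-network topology statistics
(`latent_network()`, `node_strength()`, `shifted_closeness()`,
`betweenness()`).

A thin command-line wrapper covering simulate / fit / report / predict /
netstats / benchmark is installed at `inst/scripts/bilatnet`.

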