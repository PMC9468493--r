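# calcikin

Bayesian inference of molecular calcium kinetics from fluorescence imaging
traces.

Spontaneous calcium activity in astrocytes is shaped by a small set of
molecular rates: the SERCA pump refilling the endoplasmic reticulum (ER),
the IP3 receptor releasing ER calcium into the cytosol, a ligand-independent
ER leak, and the production and turnover of IP3 itself. Changes in the
expression of these proteins — for instance downstream of a genetic deletion
— change these rates, but the rates are not directly observable: what a
microscope records is the saturating fluorescence of an indicator such as
GCaMP6m, one trace per active region (ROI). `calcikin` inverts that mapping.
Given per-ROI fluorescence time series (typically 180 frames at 1 Hz, as
produced by an upstream ROI-extraction stage such as MIN1PIPE), it infers a
posterior distribution over the kinetic rates of each ROI, then treats the
per-ROI posterior means as individual measurements for classical group
statistics.

## The model

Hidden state `x = (C_CS, q, p)`: cytosolic calcium (µM), the IP3-receptor
recovery variable, and IP3 (µM), evolving as

    dC_CS/dt = J_c − J_s + J_l
    dq/dt    = a2 d2 (p + d1)/(p + d2) (1 − q) − a2 C_CS q
    dp/dt    = −(p − p0)/τ + v_p (C_CS + 0.2 k_p)/(C_CS + k_p)

with ER calcium eliminated through conservation of total cell calcium,
`C_ER = [C0 (1 + c1) − C_CS]/c1`, and fluxes

    J_c = v1 [p/(p+d1)]^3 [C_CS/(C_CS+d5)]^3 q^3 (C_ER − C_CS)   (IP3 receptor)
    J_s = v_s C_CS^2/(C_CS^2 + k_s^2)                            (SERCA)
    J_l = v2 (C_ER − C_CS)                                       (ER leak)

Observation function (GCaMP6m, dissociation constant K_d = 167 nM):

    y_t = κ_F · C_CS/(C_CS + K_d) + d_F + ε_t,   ε_t ~ N(0, σ⁻¹)

The state evolves with additive noise `η_t ~ N(0, α⁻¹ I)` at frame
resolution; the dynamics are integrated on a finer "microtime" grid (0.1 s
explicit Euler sub-steps per 1 s frame). Six extensive parameters are free
in the inversion — `v_s, v1, v2, τ, v_p, k_s` — each represented as its
literature prior mean times `exp(ξ)` with a Gaussian prior on the exponent
(mean 0, variance 2), which enforces positivity. Inference is variational
Bayes with a Laplace (Gaussian) approximation for states and parameters and
gamma marginals for the precisions α and σ, iterated by Gauss–Newton steps
with step-halving until the free-energy increment falls below 0.02 nats or
100 iterations are reached. Runs returning a positive state-noise precision
are accepted; the rejection rate on well-posed cohorts stays below 5%.

## Worked example

Generate a two-group synthetic cohort (8 ROIs per group; the second group
carries a 15% reduction of SERCA V_max and ER leak, the direction of the
22q11.2-deletion phenotype), invert every trace, and summarise:

```r
library(calcikin)
coh <- generate_cohort(8, list(wt = c(), del = c(vs = 0.85, v2 = 0.85)),
                       seed = 11)
res <- run_batch(coh)
tab <- results_table(res)
wt  <- tab[grepl("^wt",  tab$roi_id), ]
del <- tab[grepl("^del", tab$roi_id), ]
summarize_group(wt)
#> Group summary: 8/8 runs accepted (rejection rate 0.0%)
#>  parameter      mean           se n
#>         vs 1.0606979 0.0792372249 8
#>         v1 9.5582870 1.4982468586 8
#>         v2 0.1158845 0.0073533632 8
#>        tau 5.9144922 0.4232524458 8
#>         vp 0.1036338 0.0057339494 8
#>         ks 0.1018600 0.0007802743 8
compare_groups(wt, del)
#>   parameter statistic   p_value
#> 1        vs     0.375 0.6271671
#> 2        v1     0.375 0.6271671
#> 3        v2     0.375 0.6271671
#> 4       tau     0.375 0.6271671
#> 5        vp     0.500 0.2699997
#> 6        ks     0.375 0.6271671
```

The group summary lists, per free parameter, the across-ROI mean and
standard error of the per-ROI posterior means (units: `vs` µM/s, `v1` 1/s,
`v2` 1/s, `tau` s, `vp` µM/s, `ks` µM), together with the rejection rate.
`compare_groups` reports the two-sample Kolmogorov–Smirnov statistic and
asymptotic p-value per parameter; with only 8 ROIs per group a 15% shift is
not expected to reach significance — detecting shifts of that size takes
cohorts of dozens to hundreds of ROIs, which is what real recordings
provide.

A single fit exposes the full posterior:

```r
fit <- res[["wt_01"]]
fit
#> Posterior summary for ROI wt_01
#>   accepted: TRUE | iterations: 20 | R^2: 0.9877 | alpha-hat: 46.3
#>     posterior_mean posterior_sd
#> vs      1.19054571   1.53136961
#> v1     14.86782977  14.67167790
#> ...
```

A command-line wrapper over the same functions is installed with the
package (`system.file("cli", "calcikin.R", package = "calcikin")`) with
subcommands `simulate`, `synth`, `invert`, and `summarize`, all seedable;
every output is accompanied by a YAML run log recording the seed and
settings.

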