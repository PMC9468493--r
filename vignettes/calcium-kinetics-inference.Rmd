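---
title: "Inferring calcium kinetics from fluorescence traces: model, inversion, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring calcium kinetics from fluorescence traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcikin)
```

This vignette is the package's own account of its model and numerical
choices: what is assumed, which knobs matter, what the synthetic-data
generator does and does not emulate, and where the design was genuinely
open and a choice had to be made.

## The generative model

The hidden state of one region of interest (ROI) is the triple
$x = (C_{CS}, q, p)$: cytosolic calcium (µM), the IP3-receptor recovery
variable ($q \in [0,1]$), and IP3 concentration (µM). The dynamics are the
classical reduced model of IP3-receptor-mediated calcium exchange between
cytosol and endoplasmic reticulum (ER), extended with calcium-dependent IP3
production and first-order IP3 decay. ER calcium is not a state variable:
total cell calcium is conserved, so
$C_{ER} = [C_0(1+c_1) - C_{CS}]/c_1$, with $c_1$ the ER/cytosol volume
ratio. Three fluxes move calcium: the IP3-receptor channel (gated by IP3,
calcium, and $q^3$), the SERCA pump (Hill coefficient 2), and a
ligand-independent leak proportional to the ER-cytosol concentration
difference.

The measurement is the saturating fluorescence of a single-site calcium
indicator (GCaMP6m),
$g(C_{CS}) = \kappa_F\, C_{CS}/(C_{CS} + K_d) + d_F$, with the dissociation
constant fixed at $K_d = 167$ nM. $\kappa_F$ (gain) and $d_F$ (background)
are recording-specific and inferred per trace. Fluorescence is treated as
an instantaneous function of calcium; the finite decay time of the
indicator is deliberately not modelled, which restricts the method to
kinetics on the multi-second scale. State noise enters additively at frame
resolution with precision $\alpha$, measurement noise with precision
$\sigma$, both gamma-distributed in the posterior approximation.

Twelve of the kinetic constants are held at their literature values
(`kinetic_params()` defaults). The six *extensive* rates — those
proportional to the expression level of the corresponding protein — are
free in the inversion: SERCA $V_{max}$ (`vs`) and $K_m$ (`ks`), the
IP3-receptor rate (`v1`), the ER leak rate (`v2`), the IP3 lifetime
(`tau`), and the IP3 production rate (`vp`). Each free parameter is
parameterised as (prior mean) × $e^{\xi}$ with $\xi \sim N(0, 2)$, which
enforces positivity; the value 2 is a variance on the dimensionless
exponent. Initial states carry identity-scale Gaussian priors
(calcium 0.1 µM, variance 0.05; $q$ 0.5, variance 0.2; IP3 0.5 µM,
variance 0.2).

## Integration: microtime stepping

Frames arrive at 1 Hz; the dynamics are moderately stiff at that step, so
each frame transition is integrated by explicit Euler sub-steps on a finer
"microtime" grid, by default ten 0.1 s sub-steps per frame. Against a
classical 4th-order Runge–Kutta reference at a 1 ms step, the default
stepping stays within 1% per state component over 10 s (this is enforced in
the test suite). After every sub-step the state is safeguarded into its
physical domain — calcium inside the conservation bounds
$(0, C_0(1+c_1))$, $q$ in $[0,1]$, IP3 positive, with $\varepsilon =
10^{-9}$ µM margins — and the number of safeguard activations is counted.
Without safeguarding, a coarse explicit step can push calcium outside the
conservation range during sharp transients, which is also the mechanism
behind occasional divergent inversion runs.

## The variational scheme

The approximate posterior factorises over five blocks — states, kinetic
exponents $\theta$, observation parameters $\phi = (\kappa_F, d_F)$, and
the two precisions — Gaussian for the first three, gamma for the
precisions. One iteration updates:

1. **States**: an extended Kalman filter over frames (transition Jacobians
   by central finite differences of the one-frame map), followed by a
   fixed-lag smoothing pass in which each state estimate uses a limited
   window of subsequent observations (default 2 frames). Smoothed means are
   safeguarded into the physical domain.
2. **Measurement precision** $\sigma$: conjugate gamma update from the
   squared residuals about the smoothed path, plus the state-covariance
   correction propagated through the observation gradient.
3. **Kinetics and observation parameters**: a *joint* Gauss–Newton step on
   the observation residuals of the deterministic trajectory integrated
   from the inferred initial state. Kinetic sensitivities are central
   finite differences (relative step $10^{-4}$) of the predicted trace;
   the $\kappa_F, d_F$ columns are analytic. The Gaussian priors enter as
   ridge terms; the posterior covariance is the inverse Gauss–Newton
   Hessian.
4. **State-noise precision** $\alpha$: conjugate gamma update from the
   transition residuals of the smoothed path under the updated kinetics,
   plus covariance trace corrections using the lag-one smoothed
   cross-covariances.

The free energy — expected log-joint at the posterior means with
second-order covariance corrections, plus Gaussian entropies, minus the
Gaussian and gamma KL terms — is evaluated after each candidate step. Steps
that would lower it below the last retained value are halved up to 8 times;
if no admissible fraction is found, the iteration is not retained (the
working iterate may still move, which lets the scheme escape shallow
plateaus, but the reported free-energy sequence contains only retained
iterations and is therefore non-decreasing by construction). The returned
posterior is the last retained iterate, i.e. the free-energy maximum over
the run. Iteration stops at a retained increment below 0.02 nats, after
three consecutive non-retained iterations, or at 100 iterations.

Why a joint Gauss–Newton on the *predicted-trajectory* residuals rather
than on the state-transition residuals that $\theta$ formally enters in the
factorised objective? Both were implemented. The transition-residual route
is unidentifiable in practice: the data-assimilated state path can absorb
parameter error, and the coupled updates stall at a biased self-consistent
point (the SERCA rate drifting to half its true value on noiseless data).
Differentiating the full trajectory ties the parameters directly to the
observable and, on noiseless synthetic traces generated at the prior means,
recovers all six free parameters to within ~1%. The transition residuals
still do what they must: they determine $\alpha$, whose positivity is the
acceptance criterion, and they enter the free energy.

Divergences (non-finite states, filter failure, non-positive-definite
covariances) never raise out of a batch: the run is returned flagged
`diverged`, counted as rejected, and excluded from group statistics.

## Observation-parameter priors

$\kappa_F$ and $d_F$ have no literature values — they depend on the camera,
illumination, and expression level — so their priors are scaled from the
data. The naive centering ($\kappa_F$ at the trace range, $d_F$ at the
trace minimum) is biased by a factor of ~2: the indicator's bound fraction
$C/(C + K_d)$ spans only about half of $[0,1]$ between resting calcium and
a physiological transient peak, so a gain equal to the fluorescence range
forces the inferred calcium path to stretch unphysically, and the kinetic
rates compensate. The package instead centres the gain at
range$/(s_{peak} - s_{rest})$, where $s_{rest}$ is the bound fraction at
the resting-calcium prior mean (0.1 µM) and $s_{peak}$ at a nominal 1 µM
transient peak, and the background at $\min(y) - \kappa_F^{(0)} s_{rest}$.
Both priors keep variance range², wide enough for the data to move them.
For a constant (zero-range) trace the scale falls back to 1% of the mean
level so the inversion still terminates; such traces carry essentially no
kinetic information and the posteriors remain at the priors, which the test
suite checks.

## Precision hyperpriors, lag, and other defaults

| Setting | Default | Why |
|---|---|---|
| `frame_dt` | 1 s | 1 Hz acquisition |
| `micro_dt` | 0.1 s | stability of the explicit step (see above) |
| `max_iterations` | 100 | iteration cap of the inversion |
| `min_free_energy_increment` | 0.02 nats | convergence threshold |
| α, σ hyperpriors | gamma(1, 1) | weakly informative, scale-free |
| `lag` | 2 frames | smallest smoothing window using future data; cost linear in trace length |
| `k_d` | 0.167 µM | GCaMP6m; the command line takes it in nM (`--kd-nm`) and converts, avoiding silent 1000× unit errors |

The gamma(1, 1) hyperpriors and the 2-frame lag are genuine defaults of
this implementation, not literature values; both are exposed in
`inversion_config()`. The lag barely affects the results in practice
(lag 2 versus full-trace smoothing was compared during development and
changed the recovered parameters by far less than their posterior spread),
because most of the parameter information flows through the
trajectory-sensitivity step.

Posterior summaries report, on the physical scale, the prior mean times
$e^{\mu}$ (the posterior median of the implied log-normal) and
delta-method variances. The median is preferred over the log-normal mean
because weakly identified parameters with near-prior exponent variance
would otherwise be inflated by $e^{\sigma^2/2}$ even when the data say
nothing.

## The synthetic-data generator

`generate_trace()` and `generate_cohort()` emulate the tabular traces the
pipeline consumes: deterministic (optionally state-noisy) dynamics from the
standard initial state, mapped through the observation function, with
i.i.d. Gaussian observation noise. The defaults encode the acquisition
protocol the pipeline targets — 180 frames at 1 Hz (3 min) — with
observation noise at 2% of each trace's range and per-ROI log-normal
parameter jitter with sd 0.1, which produces across-ROI spread comparable
in kind (not in value) to real cohorts. State noise is off by default: the
generator's role is to provide ground truth under the inversion's own
model assumptions.

What the generator does *not* emulate, and what passing tests therefore do
not establish about real data: photobleaching and baseline drift,
indicator decay kinetics, ROI-extraction artefacts (the upstream
computer-vision stage is consumed as input, not simulated), non-Gaussian
or correlated noise, and cell-to-cell variation in the *fixed* kinetic
constants. Real recordings also sit at unknown distances from the model
class; the recovery results here quantify algorithmic correctness, not
biological validity.

With default geometry the model relaxes from the standard initial state
through a single calcium transient onto a stable plateau; this transient
is what identifies the rates. Five of the six free parameters are strongly
identified by such a trace; SERCA $K_m$ (`ks`) is nearly flat in the
likelihood and is effectively reported at its prior unless the data are
unusually informative — visible in the worked examples as posterior means
within a percent of 0.1 µM.

## Problem sizes used in the checks

The standard cohort used by the fit-quality, rejection-rate, and
free-energy checks is 20 traces of 180 frames (one inversion each, about
a second per trace); parameter-recovery checks use single 180-frame
traces and 10 seeded replicates of the shifted-SERCA contrast; the
group-comparison calibration uses 250–400 replicated null cohorts of
direct parameter draws, which exercises the statistics layer without
re-running inversions. These sizes were chosen so the whole suite
completes in well under a minute while leaving the Monte-Carlo tolerances
meaningful.

## Known limitations

- The free energy is a Laplace-style approximation evaluated at posterior
  means with second-order corrections; it is a consistent objective for
  step control and convergence, not a calibrated model-evidence estimate.
- $K_d$ is fixed, not inferred; misspecifying it rescales the inferred
  calcium concentrations and, through them, the concentration-dimensioned
  rates.
- The scheme assumes uniformly sampled traces and a single kinetic regime
  per trace; traces with strong drift or multiple behavioural regimes
  violate the model and typically surface as low $R^2$ rather than as
  rejections.
- Group comparisons use the asymptotic two-sample Kolmogorov–Smirnov test
  per parameter without multiple-testing correction (a Bonferroni flag is
  available); with six parameters, isolated p-values near 0.05 should be
  read accordingly.
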