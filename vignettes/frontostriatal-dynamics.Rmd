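---
title: "Modelling stochastic frontostriatal dynamics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stochastic frontostriatal dynamics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`fsdyn` simulates resting-state activity of the ventral (nucleus
accumbens–orbitofrontal cortex) and dorsal (putamen–lateral prefrontal
cortex) frontostriatal circuits with a reduced Wong–Wang population model.
Each region $i$ is summarised by its average synaptic gating
$S_i \in [0, 1]$:

$$\dot S_i = -\frac{S_i}{\tau_S} + (1 - S_i)\,\gamma\, H(x_i) + v_i,
\qquad
H(x) = \frac{a x - b}{1 - \exp(-d\,(a x - b))},$$

$$x_i = w J_N S_i + G J_N \sum_j \tilde C_{ij} S_j + I_0,$$

with gating relaxation $\tau_S = 0.1$ s, kinetic constant
$\gamma = 0.641\ \mathrm{s^{-1}}$ (coupling timescale $1/\gamma \approx
1.56$ s), local recurrence $w = 0.9$, global coupling scale $G = 2.5$,
synaptic factor $J_N = 0.2609$ nA, and white node noise $v_i$ of amplitude
$\sigma = 0.1\ \mathrm{s^{-1}}$ (variance $0.01\ \mathrm{s^{-2}}$). The
transfer-function constants $a = 270\ \mathrm{nC^{-1}}$, $b = 108$ Hz,
$d = 0.154$ s and the background current $I_0 = 0.3$ nA are the canonical
values of this model family; they are stated assumptions here (fixed
biophysics, not fitted) and remain configurable in `model_parameters()`.
The singularity of $H$ at $a x = b$ is removable and is evaluated by a
second-order series; `transfer_function()` is exactly continuous there.

Striato-cortical projections abstract the direct/indirect basal-ganglia
pathways: their momentary sign decides net excitation versus inhibition.
They are therefore modelled as mean-reverting (Ornstein–Uhlenbeck)
couplings

$$\dot{\tilde C}_{ij} = -\eta_{ij}\,(\tilde C_{ij} - C_{ij}) + v_{ij},$$

where $C_{ij}$ is the set point, $\eta_{ij}$ the drift (relaxation rate
towards the mean) and $v_{ij}$ white noise of amplitude $\sigma_{ij}$
(volatility). All other projections (cortico-striatal, cortico-cortical,
striato-striatal) are static couplings.

### Noise discretisation

"White noise of variance $\sigma^2$" is read as a white-noise *intensity*:
the Euler–Maruyama update adds $\sigma\sqrt{dt}\,\xi$ per step, which is
the standard discretisation of the SDE and makes the simulated statistics
step-size invariant (the test suite checks that halving $dt$ under a shared
Brownian path changes time-averaged gating by less than 1%). Gating is
clipped to $[0, 1]$ after each step — it is a channel fraction — and clip
events are counted in the returned `trajectory_set`. Initial conditions are
$S_i(0) = 0.1$ and $\tilde C_{ij}(0) = C_{ij}$; a burn-in (default 60 s of
a 13-min run) removes any dependence on them.

The nominal integration step is the very fine $dt = 0.01$ ms
(`simulation_config()` default). Desk-scale analyses in this package — the
test suite, the fitting experiments, the virtual-intervention runs — use
$dt = 1$ ms, justified by the step-size convergence property above; the
Rcpp core integrates a 13-minute four-region session in tens of
milliseconds at that step.

## Hemodynamics

Neural activity is converted to BOLD with the Balloon–Windkessel model
(four states per region: vasodilatory signal, inflow, venous volume,
deoxyhemoglobin), with the classical parameter set
($\kappa = 0.65$, $\gamma_h = 0.41\ \mathrm{s^{-1}}$, $\tau_h = 0.98$ s,
$\alpha = 0.32$, $\rho = 0.34$, $V_0 = 0.02$) and BOLD read-out
$V_0\,(7\rho(1-q) + 2(1-q/v) + (2\rho - 0.2)(1-v))$. The model is driven by
the synaptic gating $S$ by default; whether the original analyses drove it
with gating or firing rates is ambiguous in the source material, so
`fc_model_runner(drive = "rate")` offers the alternative (the firing-rate
drive reconstructs the input currents with the recorded dynamic couplings).
The hemodynamic system is integrated at the neural recording resolution
(10 ms by default; a downsampling-consistency test guards this) and sampled
at the fMRI TR of 0.81 s; the first 20 s of BOLD are discarded as the
filter's transient.

## Deterministic skeleton analysis

Freezing the dynamic couplings at their means and removing noise leaves a
smooth vector field whose equilibria `find_equilibria()` locates by dense
multi-start Newton iteration (grid spacing 0.02 per gating dimension up to
three regions, 0.1 for four — the four-region grid would otherwise need
6.8 million starts; the batched Newton uses the analytic Jacobian).
Duplicates are merged at $10^{-4}$ and every reported point satisfies
$\max_i |\dot S_i| < 10^{-8}\ \mathrm{s^{-1}}$. Stability is the sign of
the largest real part of the Jacobian eigenvalues.

The two-region circuit reproduces the three regimes of the single-circuit
analysis: monostable low activity for mutually inhibitory (or mixed)
couplings, monostable high activity for strong mutual excitation, and a
bistable window in between — for symmetric couplings the window sits at
$C \approx 0.12$–$0.39$, and the package's canonical bistable configuration
is $C_{12} = C_{21} = 0.25$. `bifurcation_scan()` tracks equilibria along a
coupling grid and localises the two saddle-node folds delimiting the window
by bisection on the equilibrium count. `transition_rate()` counts zero
crossings of a coupling series per minute; exact zeros inherit the previous
sign so only genuine reversals count. Note that an Ornstein–Uhlenbeck path
is not differentiable, so this count grows with the sampling rate; rates are
comparable only at a fixed recording resolution (10 ms throughout).

## Functional connectivity and distances

FC is the vector of pairwise Pearson correlations between regional BOLD
series in one fixed edge order — NAcc–OFC, NAcc–LPFC, NAcc–dPut, OFC–LPFC,
OFC–dPut, LPFC–dPut — recorded in every file header, because no module may
disagree on edge identity. Correlations are used raw (no Fisher
transformation). Cohorts of FC vectors are compared with the sum over edges
of 1-Wasserstein distances between the per-edge empirical distributions;
the quantile-function form supports unequal cohort sizes (the empirical
groups are 45 and 52 subjects). Subject-to-simulation pairing uses the
Euclidean distance between FC vectors.

## Group fitting by ABC-SMC

Model parameters are fitted to a group's FC summary statistics (per-edge
mean and population variance; 12 numbers for four regions) by approximate
Bayesian computation with a sequential Monte Carlo scheme. Priors are
uniform: excitatory couplings in $[0, 0.5]$, sign-free couplings in
$[-0.5, 0.5]$, drift in $[0, 0.1]\ \mathrm{s^{-1}}$, volatility in
$[0.1, 0.4]\ \mathrm{s^{-1}}$, node noise in $[0.05, 0.1]\ \mathrm{s^{-1}}$.
Design choices where the source material is silent:

* **Threshold schedule**: keep the best half of the pooled particles per
  generation (elitist), so the acceptance threshold is non-increasing by
  construction; stop at the target RMSE $\epsilon = 0.01$ or a generation
  cap.
* **Perturbation kernel**: component-wise Gaussian with variance twice the
  survivors' empirical variance, reflected at the prior bounds — a standard
  adaptive ABC-SMC choice; reflection keeps every particle inside the prior
  box.
* **Density estimate**: Gaussian KDE with Silverman bandwidths per
  marginal; sampling picks a stored particle (preserving the joint
  structure) and jitters each component, reflected at the bounds.
* **Group comparison**: two-sided Mann–Whitney U per parameter, Bonferroni
  family-wise correction (configurable), Cohen's *d* with pooled SD,
  labels `medium` above 0.5 and `strong` above 0.8.

### The recovery experiment

`abc_recovery_experiment()` checks the machinery end to end: a synthetic
group target (40 repetitions) is simulated from known parameters on the
two-region circuit and refitted with a reduced budget (200 particles,
8 generations). Identifiability dictated its design, in three steps.
First, the single-edge summary carries two numbers (mean and variance of
FC), so at most two parameters can be identified; the volatility and drift
of the stochastic coupling are practically unidentifiable here — when the
coupling wanders slowly (drift 0.04–0.05 s⁻¹ means a 20–25 s correlation
time), single-session FC is nearly bimodal, as episodes of strong
transient coupling saturate the correlation towards 1. Second, even for
static couplings, the mean FC *aliases*: a moderately negative
striato-cortical coupling and a strongly excitatory one parked on a
bistable branch produce the same session correlation, and the reciprocal
pair $(C_{12}, C_{21})$ trades off along a ridge, so two-coupling fits
place posterior mass in the aliased region on some noise realisations.
Third, near the bistable folds, noise-induced state switching makes the
across-repetition FC variance very large, and an elitist SMC (which never
re-evaluates survivors) then accumulates particles whose recorded fitness
is optimistic noise. The experiment therefore fits the striato-cortical
coupling $C_{12}$ over its full prior $[-0.5, 0.5]$, with ground truth
$-0.45$ — the strongly negative regime is the one FC signature that
aliases with nothing else — the cortico-striatal coupling fixed and known
at $0.34$ (the fitted group median) and node noise at its prior floor
(0.05 s⁻¹), which suppresses stochastic switching across the prior range.
Under this design the posterior median recovers the coupling within a few
percent of the prior width across seeds.

## Virtual interventions

`enumerate_interventions()` lists all non-empty parameter subsets up to six
targets (1485 subsets for 11 parameters). For each intervention, virtual
subjects are drawn with the targeted parameters sampled from the control
posterior and the rest from the patient posterior, simulated, and split
into cohorts (nominally 20 cohorts of 50 from 1000 subjects, mirroring the
empirical group sizes). The outcome statistic compares the 400
cohort-pair distances d(post, control baseline) against
d(patient baseline, control baseline) with a one-sided Mann–Whitney U test;
$\mathrm{AUC} = U/(n_1 n_2)$ (ties half) is the probability that the
intervention moved the cohorts closer to the controls. Significance is
Bonferroni-corrected across the intervention family by default. Null
statistics repeat the comparison with independent control and patient
replicate cohort sets.

Contribution scores attribute improvements to parameters: within every
significant intervention, cohort-mean parameter values (z-scored against
the patient baseline) are differenced across all 20×20 pre/post cohort
pairings and dotted with the pairing's FC improvement (mean baseline
distance to controls minus mean post distance); scores accumulate over the
interventions that target the parameter, and the sign is oriented so that
positive means "increasing this parameter accompanies FC normalisation".
Parameters never targeted score exactly zero.

## Digital twins

Subjects are paired to the simulation with the nearest FC vector
(exact search, lowest index on ties). Parameter changes between the
baseline and follow-up twins are tested per parameter with a two-sided
paired Wilcoxon signed-rank test (Bonferroni-corrected), and related to
symptom changes through an *uncentred* dot product of z-scored parameter
changes with symptom-score changes — uncentred so the sign keeps its
meaning (increase vs decrease, improvement vs worsening). The scalar
"FC change" correlated with symptom change is not operationally defined in
the source material; the package's default is the baseline-minus-follow-up
change in Euclidean distance between the subject's FC vector and the
control-group mean FC (positive = normalisation), computed by
`fc_change_towards_controls()`. Pearson correlations come with a seeded
1000-resample bootstrap percentile CI. Desk-scale analyses use simulation
libraries of 10⁴ or fewer entries rather than the millions a production
fit would accumulate; pairing cost is linear in library size.

## The synthetic study generator

`make_group_spec()` encodes two ground-truth populations as truncated
normals inside the prior box, located at the fitted group posterior
medians: the patient-like group has elevated bidirectional ventral coupling
(C_OA 0.36, C_AO 0.34 versus −0.03, 0.11), weakened dorsal coupling
(C_LP 0.05, C_PL 0.10 versus 0.21, 0.34), weaker cortico-cortical coupling
(C_OL 0.22 vs 0.30), loss of striato-striatal inhibition (C_AP 0.02 vs
−0.26), lower drift (0.04 vs 0.05 s⁻¹) and higher volatility (0.27/0.26 vs
0.24 s⁻¹). Spreads default to 10% of each prior width — only medians and
effect-size labels are reported for the originals, and this spread produces
effect sizes of the observed order for the well-separated parameters.
Parameters without a reported group difference (C_LO, C_PA, global noise)
sit at mid-prior in both groups.

`generate_fc_dataset()` maps hidden per-subject parameters to FC either
through the full simulator or through a labelled analytic surrogate — the
stationary correlation of the drift field linearised at its low-activity
equilibrium (a Lyapunov-equation solve), which ignores coupling volatility
and is used only in unit tests, never in acceptance-level analyses.
Measurement noise (SD 0.05) is added and values are clipped to $[-1, 1]$.
The longitudinal generator plants an exact in-sample Pearson correlation
(default 0.35) between a per-subject FC-normalisation scalar and symptom
changes with requested moments (default mean −4.7, SD 5.0, matching a
moderate four-week clinical improvement on a 0–40 symptom scale): a noise
vector is orthogonalised against the standardised FC change and the two are
mixed with weights $r$ and $\sqrt{1-r^2}$. Exact planting makes the
generator's contract sharp; the bootstrap-coverage tests then check the
*estimator*, not the generator.

What the generator does **not** emulate: scanner artefacts, motion,
preprocessing effects, site differences, or any heavy-tailed structure of
empirical FC. Passing tests show the pipeline's statistics behave correctly
on data generated by the model family itself, not that the model fits any
particular empirical dataset.

## Problem sizes used by the checks

The test suite and the acceptance script run everything at desk scale,
chosen so the full battery completes comfortably on one CPU: two-region
fits use 140–200 s sessions at $dt = 1$ ms with 8 repetitions per particle
and a 200-particle, 8-generation budget; the end-to-end intervention check
uses 20 cohorts of 25 subjects per condition with 170-s sessions (1500
four-region simulations); Ornstein–Uhlenbeck moment checks pool 8–16
chains of 2000–4000 s at $dt = 10$ ms. These sizes are stated here as the
package's own reproducibility choices.

## Known limitations

* **Volatility–FC direction.** With the adopted noise discretisation, high
  coupling volatility produces large, correlated excursions of both
  regions and BOLD FC saturates towards 1, so the regime maps show FC
  *rising* with volatility. The motivating intuition for the
  drift–volatility parameterisation runs the other way — a coupling held
  constant at its set point was expected to give the highest FC — and the
  grid, mean coupling and realisation counts under which that direction
  holds are not pinned down, so the package does not assert it; the map
  machinery is exercised by implementation-true properties instead (zero
  transition rate at zero volatility, transition rate increasing with
  drift and volatility jointly).
* **Zero-crossing counts are resolution-bound** (see above).
* **Identifiability.** One edge's FC summary cannot constrain the full
  five-parameter two-region circuit; group-level fits of the four-region
  circuit (12 summary numbers) are correspondingly better conditioned but
  still exhibit ridges between reciprocal couplings.
* The contribution-score pairing scheme (which pre-cohort pairs with which
  post-cohort) is a package convention — all 400 pairings with mean
  distances as the improvement scalar — since no finer operational
  definition is available.
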