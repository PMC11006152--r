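---
title: "Modelling public-goods cooperation and cheating in a chemostat"
author: "chemocoop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling public-goods cooperation and cheating in a chemostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemocoop)
```

## The biological system and the model

*Pseudomonas aeruginosa* growing on a protein substrate (gelatin) cannot
take the substrate up directly: it must first secrete extracellular
proteases that cleave the protein into utilizable products. The protease
is a *public good* — once secreted, its products benefit every cell in
the vessel, including quorum-sensing-deficient *lasR* mutants that never
pay the metabolic cost of producing it. In a continuous culture
(chemostat) this sets up the classic tragedy-of-the-commons dynamic:
cheaters enrich, enzyme supply collapses, and with it the whole
population.

The package implements a deterministic, mechanistic description of this
system with five state variables: substrate $S$ (mmol/l), cleavage
product $P$ (mmol/l), enzyme $E$ (mmol/l), cooperator biomass $X_1$ and
cheater biomass $X_2$ (both g dry weight/l):

$$
\begin{aligned}
\dot S &= D\,(S^0 - S) - G(S, E) \\
\dot P &= \sigma\, G(S, E) - \tfrac{1}{\gamma}(X_1 + X_2)\,F(P) - D P \\
\dot E &= \eta\, Q(X_1)\, X_1\, F(P) - D E \\
\dot X_1 &= X_1\left[(1 - Q(X_1))\,F(P) - D\right] \\
\dot X_2 &= X_2\left[F(P) - D\right]
\end{aligned}
$$

with three auxiliary functions:

* **Monod growth** $F(P) = \mu_{\max} P / (K_S + P)$ — saturating
  per-capita growth on the cleavage product;
* **Michaelis–Menten proteolysis** $G(S, E) = k_{cat} E S / (K_M + S)$ —
  linear in enzyme, saturating in substrate;
* **quorum-sensing burden**
  $Q(X_1) = q\, X_1^n / (X_1^n + QS_{\min}^n)$ — the fraction of the
  cooperator's metabolic budget diverted to enzyme production. The Hill
  form captures the switch-like, density-dependent activation of
  quorum-controlled genes; $Q(0) = 0$ and $Q \to q$ at high cooperator
  density.

The cooperator grows at the discounted rate $(1 - Q)F$ while the cheater
enjoys the full rate $F$; the per-capita growth gap is exactly
$Q(X_1)F(P) \ge 0$, which is why the cheater frequency
$R = X_2/(X_1 + X_2)$ can never decrease in this base model.

Enzyme synthesis is coupled to the cooperator's growth flux:
$\eta\,Q(X_1)\,X_1\,F(P)$, where $\eta$ (mmol enzyme per g biomass) is
the amount of enzyme produced per unit of gross biomass production and
$Q$ the fraction of that flux diverted. This coupling is the
dimensionally consistent reading of "enzyme produced per biomass" — a
cell that is not growing has no anabolic flux to divert — and it means
enzyme output shuts down both below the quorum threshold *and* under
starvation.

### Parameters

| Parameter | Units | Meaning | Default |
|---|---|---|---|
| $S^0$ | mmol/l | substrate in the inflow (also initial $S$) | 0.210 |
| $D$ | 1/h | dilution rate (flow / volume) | 0.121 |
| $\mu_{\max}$ | 1/h | maximal growth rate | 1.38 |
| $k_{cat}$ | 1/h | enzyme turnover number | 480 |
| $K_S$ | mmol/l | product at half-maximal growth | 0.840 |
| $K_M$ | mmol/l | substrate at half-maximal cleavage | 0.068 |
| $\eta$ | mmol/g | enzyme per unit biomass produced | 6.2e-4 |
| $\gamma$ | g/mmol | biomass yield per product | 0.0423 |
| $\sigma$ | – | cleavage products per substrate molecule | 40 |
| $q$ | – | maximal metabolic burden (0–1) | 0.610 |
| $QS_{\min}$ | g/l | cooperator density at QS half-activation | 0.045 |
| $n$ | – | Hill coefficient | 2 |

The defaults are the best-fit values of a calibration against chemostat
time series (see below). `parameter_ranges()` records the biologically
estimated intervals for the parameters known only to a range; the others
are single point estimates. $D$ and $n$ are never sampled: the dilution
rate is set by the experimental hardware, and Hill coefficients above 2
change the dynamics negligibly.

Biomass converts to optical density at 0.48 g dry weight/l per OD600
unit (`biomass_to_od()`), the factor implied by the system's paired
calibration values (0.0240 g/l at OD 0.05, and the QS threshold 0.045
g/l at OD 0.094).

### Culture protocol

Experiments grow the culture in **batch** (no flow) until it nears
saturation, then switch on the pump. `culture_schedule()` mirrors this:
the model runs with $D = 0$ for `batch_hours`, then with the configured
$D$ for `chemostat_hours`. Time zero is the start of flow, so batch
times are negative — the axis used by all outputs. Defaults: 32 h batch
for WT-only cultures, 55 h for cocultures, 192 h (8 days) of chemostat
mode. Initial states: total OD 0.05, entirely cooperators (WT-only,
$X_1(0) = 0.0240$ g/l) or with a 10 % cheater fraction (coculture,
$X_1(0) = 0.0216$, $X_2(0) = 0.00240$); $P(0) = 0$,
$E(0) = 3\times 10^{-6}$ mmol/l.

```{r basic}
p <- model_parameters()
wt <- simulate_chemostat(p, culture_schedule(32, 192))
tail(od600_total(wt), 1)          # WT-only settles near OD 0.24

co <- simulate_chemostat(p, culture_schedule(55, 192),
                         initial_state("coculture", p),
                         scenario = "coculture")
tail(od600_total(co), 1)          # coculture washes out
tail(cheater_frequency(co)$value, 1)  # cheaters plateau near 65 %
```

Three qualitative regimes emerge. A cooperator-only culture is stable
whenever the burden is large enough to sustain enzyme supply and the
dilution rate is below the achievable growth rate. A coculture under any
positive dilution collapses — cheaters erode the enzyme supply and the
whole population washes out — while with $D = 0$ the culture merely
saturates. And even as the population collapses, the cheater frequency
does **not** go to fixation: once the cooperator density falls below
$QS_{\min}$ the burden $Q$ vanishes, the growth gap closes, and
$R(t)$ freezes at a density-dependent limit. The closed form

$$
R(t) = \frac{R(0)\,e^{\int_0^t A}}{1 - R(0) + R(0)\,e^{\int_0^t A}},
\qquad A(t) = Q(X_1(t))\,F(P(t))
$$

is implemented in `saturation_prediction()` and agrees pointwise with
the directly computed frequency; the integral is evaluated by the
trapezoid rule on the trajectory's own grid, so its accuracy is
controlled by the sampling density you choose.

## Evolved-mutant variants

Long cultivations select for faster-growing mutants. Three six-state
variants add a mutant class $X_3$ fed from its parent at rate $\alpha$
and growing with an elevated $\mu_{\max,2}$ (`evolved_parameters()`,
`simulate_evolved()`):

1. **cheater from the marked cheater** — $X_3$ is protease-deficient and
   carries the resistance marker;
2. **cheater from the WT** — $X_3$ is protease-deficient but unmarked,
   so the protease-deficiency and antibiotic-resistance assays diverge;
3. **cooperator from the WT** — $X_3$ produces enzyme; the QS burden is
   evaluated on the combined producer density $Q(X_1 + X_3)$.

`phenotype_frequencies()` maps the three biomass classes onto the two
plate assays accordingly. With $\alpha = 0$ and $X_3(0) = 0$ every
variant reduces exactly to the base model, and in all variants the
mutational outflow and inflow cancel in the parent-plus-mutant biomass
sum, so "mutation" is a pure relabeling of growth. A faster-growing
protease-deficient mutant arising from the WT would strictly require two
mutations; it is modelled as a single event, since single regulatory
mutations can produce both phenotypes at once.

## Calibration pipeline

`fit_pipeline()` reproduces a random-screening calibration:

1. **Sampling** (`sampling_scheme()`, `sample_parameters()`): ranged
   parameters and $E(0)$ are drawn uniformly from their estimated
   intervals; point-estimated parameters are either jittered with a
   normal of 10 % relative spread (round 1) or held fixed (round 2).
   Round 2 raises the lower bounds of $k_{cat}$ to 150 and $\eta$ to
   $4\times10^{-4}$, the smallest values a first broad screen found
   compatible with the data's qualitative dynamics.
2. **Success filter** (`success_criteria()`, `evaluate_success()`): a
   draw is kept when (i) the WT-only culture retains more than 0.01 g/l
   of cooperators at the final time (no washout), (ii) the coculture
   batch phase peaks below OD 0.58 (no runaway growth), and (iii) the
   final cheater frequency reaches at least 30 %. The frequency is
   evaluated at the final chemostat time point; because the base-model
   frequency is monotone, this equals its maximum over the run.
3. **Scoring** (`rmse()`, `combine_scores()`): per-replicate RMSEs
   against the WT-only density, coculture density and protease-deficient
   frequency series, averaged within each data type, max–min normalized
   across the successful ensemble, and combined with weights 0.4 / 0.6 /
   0.2. The coculture weight is highest because parameter sets that
   inflate the cheater frequency also overshoot coculture batch growth;
   normalization is computed across the full successful ensemble.
4. **Selection** (`select_candidates()`): the lowest-scoring 10 % are
   kept, then candidates whose end-of-batch (t = 0) coculture density
   falls outside the observed range, or whose t = 0 cheater frequency is
   below 30 %, are dropped. Where a human would compare the survivors
   visually, the pipeline deterministically takes the lowest combined
   score.
5. **Refinement** (`refine()`): greedy multiplicative perturbations
   (±1 %, ±5 %) of single parameters and of parameter pairs, accepting
   only moves that lower the raw weighted RMSE, until no move improves
   it or the step budget is spent. This is a deterministic stand-in for
   manual polish; the objective is non-increasing by construction.

`success_yield()` runs stage 1–2 alone, which is how the fraction of
parameter space compatible with the qualitative dynamics is measured.

## Sensitivity analysis

`parameter_sweep()` varies one parameter (five values is the customary
panel) with everything else at the best fit; `pairwise_rmse_map()`
evaluates the fit over a two-parameter grid (41 × 41 equidistant values
by default) with extended ranges — $\sigma \in [30, 70]$, $q \in [0,1]$,
$\gamma \in [0.03, 0.07]$, $QS_{\min} \in [0, 0.2]$ being the classic
panels — recording each cell's RMSE and whether the simulation on
average overshoots (+1) or undershoots (−1) the data. The sign is the
sign of the mean residual pooled over replicates, the simplest estimator
consistent with "on average over or under". Undershoot bands in the
WT-only map flag washout regions: a minimum burden of roughly
$q \gtrsim 0.25$ is needed for cooperator stability.

## Synthetic data

Because the measured series exist only as published figures, the package
generates its own pseudo-experimental data (`synthetic_config()`,
`generate_dataset()`), emulating the measurement process:

* OD600 readings at the batch start, batch end and every 24 h of
  chemostat mode, with mean-one multiplicative lognormal noise (default
  CV 5 %, matching typical replicate scatter) and a detection limit of
  OD 0.001 below which values read 0;
* phenotype frequencies estimated by patching up to `n_colonies`
  (default 100) random colonies per sample — a single binomial draw per
  phenotype, so observed frequencies are exact multiples of
  $100/n_{\text{colonies}}$. The experimental two-stage bookkeeping
  (size-class counting, then patching within classes) is methodological
  rather than statistical and is collapsed into that single draw;
* optional per-replicate mutation injections reproducing the divergent
  replicate phenotypes of the evolved variants.

What the generator does *not* emulate: irregular per-replicate batch
durations (each scenario uses one configurable duration), plating
dilution series, instrument drift, or any genetic drift at low density
— the truth is always a deterministic trajectory. Tests that pass
against synthetic data therefore validate the pipeline's statistical
machinery and identifiability, not the adequacy of the deterministic
model for any particular real culture.

`make_benchmark_suite()` freezes three fixtures: a noiseless best-fit
dataset (used for parameter recovery: a 200-draw screen plus greedy
refinement recovers $q$ and $QS_{\min}$ to well within 25 %), a noisy
four-replicate set with two injected mutants, and a three-time-point toy
set for exact unit tests.

## Numerical choices

* **Integrator**: `lsoda` (stiff-capable, switching) with relative
  tolerance $10^{-8}$ and absolute tolerance $10^{-10}$. Collapse
  trajectories approach machine zero, which is why a stiff-capable
  method and a tight absolute tolerance matter.
* **Positivity**: the right-hand sides floor each state at zero when
  computing rates, so solver undershoots cannot inject negative biomass
  into the dynamics; sampled states within $10^{-8}$ below zero are
  clipped to zero, anything lower is treated as an integration failure.
  Failed integrations raise an error that carries the offending
  parameter set (during ensemble screening they are counted as
  "numerical" failures rather than aborting the run).
* **Phase handling**: each phase is integrated densely by the solver's
  own adaptive stepping and reported on the requested grid; the state is
  continuous across the batch-to-chemostat switch.
* **Frequency floor**: when total biomass falls below $10^{-12}$ g/l a
  frequency is reported missing (`NA`) instead of risking 0/0.
* **Quadrature**: the saturation integral uses the trapezoid rule on the
  trajectory grid. On a grid refined near the flow switch (where $A(t)$
  changes fastest) the closed form matches the direct frequency to
  better than $10^{-6}$ relative.
* **Interpolation onto observation times** is linear; observation
  cadence (~24 h) is coarse relative to the near-steady dynamics, so
  higher-order schemes buy nothing.
* **Problem sizes**: the test suite screens ensembles of $10^4$ draws
  for the yield check, 100 draws for trajectory-level property checks,
  and 200 draws plus a 25-move refinement budget for parameter
  recovery — sizes at which the stochastic checks are stable from seed
  to seed while the whole suite stays quick.

## Known limitations

* The model is deterministic: it cannot represent drift, founder
  effects, or the timing randomness of real mutational events — the
  evolved variants model a *flux* of mutants, not discrete events.
* All proteolysis is collapsed into a single enzyme species; real
  systems secrete several proteases with different kinetics.
* The vessel is assumed perfectly mixed: no wall growth, aggregation or
  spatial refuges, which in reality can shelter cooperation.
* The OD–biomass conversion is a single fixed factor; it is not re-fit
  from calibration curves.
* At the default best fit the simulated WT-only steady state sits near
  OD 0.24 — the algebraic fixed point of the equations, reproduced
  independently by root-finding in the test suite. Replicate cultures
  can stabilize somewhat above this; the gap is within the spread the
  sensitivity maps show for in-range parameter choices (e.g. higher
  $\sigma$ or $\gamma$ raise the plateau).
* Calibration is a random screen plus greedy polish; it finds a good
  basin, not a posterior. No gradient-based or Bayesian machinery is
  included, and none is warranted by figure-resolution data.
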