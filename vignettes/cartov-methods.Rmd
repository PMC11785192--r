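---
title: "Modeling tumor, CAR T-cell and oncolytic virus dynamics with cartov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor, CAR T-cell and oncolytic virus dynamics with cartov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartov)
```

## The model

`cartov` implements a four-compartment ordinary-differential-equation model
of an in vitro glioblastoma killing assay combining IL-13Rα2-targeted CAR
T-cells with an HSV-based oncolytic virus. Non-infected tumor cells $T$ and
virus-infected tumor cells $I$ are measured in cell-index (CI) units — the
dimensionless impedance readout of an xCELLigence analyzer, proportional to
adherent cell number — free virus $V$ in multiplicity-of-infection (MOI)
units, and CAR T-cells $C$ in CI units:

$$
\begin{aligned}
\dot T &= \alpha T \left(1 - \tfrac{T+I}{K}\right) - \beta_{TV} T V
          - \theta_{TC} T C\\
\dot I &= \beta_{TV} T V - \gamma I - \theta_{IC} I C\\
\dot V &= \gamma b I - \omega V\\
\dot C &= -\delta C + \mu C (T+I) - \beta_{CV} C V
\end{aligned}
$$

Tumor cells grow logistically to a carrying capacity $K$; the virus converts
them at rate $\beta_{TV}$ into infected cells, which stop proliferating and
lyse at rate $\gamma$, each lysed CI unit releasing $b$ MOI of new virions
(the burst size); free virus is cleared at rate $\omega$. CAR T-cells kill
non-infected and infected tumor cells at per-capita rates $\theta_{TC}$ and
$\theta_{IC}$, die at rate $\delta$, expand or exhaust on tumor contact at
net rate $\mu$ (either sign), and can themselves be infected at rate
$\beta_{CV}$, which destroys their cytotoxic function.

Two reductions describe the monotherapies: the predator–prey CAR T module
($I = V = 0$) and the SIR-type OV module ($C = 0$). `rhs_full()`,
`rhs_cart()` and `rhs_ov()` expose the derivatives; `simulate_model()`
integrates any of the three with lsoda (compiled right-hand sides, relative
tolerance $10^{-8}$, absolute $10^{-10}$ — the burst size spans five
decades, which makes the virus equation stiff). Doses enter as
instantaneous jumps of $V$ and $C$ at their administration times (the
integration is segmented there): the wells receive boluses, and the model
has no infusion term. Solver excursions below zero smaller than $10^{-9}$
are clipped; anything larger raises an error.

The CAR T inoculum is converted to CI units as
`et_ratio * t0_tumor`: the E:T ratio counts effector cells per tumor cell
and both cell types share the cells-per-CI factor, so the factor cancels.
Where absolute units are needed, `unit_conversion()` carries the defaults
1 MOI = $2 \times 10^4$ PFU and 1 CI = $5 \times 10^3$ cells; the latter is
the unique factor under which the literature burst-size range of
$[0.1, 10^4]$ PFU/cell maps onto $[0.025, 2500]$ MOI/CI, and it is
configurable because the CI-to-cell-number mapping is instrument- and
cell-line-specific.

## Phase-plane structure of the sub-modules

With $Y_1 = T/K$, $Y_2 = (\theta_{TC}/\alpha)C$ and $\tau = \alpha t$, the
CAR T module reduces to a two-parameter system with $A = \delta/\alpha$ and
$B = \mu K/\alpha$ (`nondim_cart()`). Besides extinction $(0,0)$ and the
tumor-only state $(1,0)$, a coexistence equilibrium $(A/B,\, 1 - A/B)$
exists when $B > A > 0$ (`equilibria_cart()`); for $A = 0 < B$ the
$Y_1 = 0$ axis degenerates into a line of equilibria, flagged via an
attribute.

With $y_1 = T/K$, $y_2 = I/K$, $y_3 = (\beta_{TV}/\alpha)V$, the OV module
reduces to $D = \gamma/\alpha$, $E = \gamma b \beta_{TV} K/\alpha^2$,
$F = \omega/\alpha$ (`nondim_ov()`). An endemic equilibrium with
$y_1^* = DF/E$ exists iff $E > DF$ — equivalently
$b\,\beta_{TV}K/\omega > 1$, the basic-reproduction-style threshold — and
loses stability at a Hopf point located by bisection on the leading
eigenvalue (`hopf_threshold_ov()`; for $D = 0.58$, $F = 0.48$ it sits at
$E \approx 2.39$). `detect_limit_cycle()` classifies the post-transient
dynamics by simulating from a 5% perturbation of the endemic point over a
scaled horizon of 3000 (first half discarded) and thresholding the
peak-to-peak amplitude of $y_1$ at $10^{-3}$ — robust to slow transients
without Floquet machinery. The scalings used here are the standard
logistic/predator–prey and SIR reductions; they reproduce the published
equilibria counts and bifurcation roles of the scaled parameters.

## What the synthetic generator emulates

`generate_untreated()` / `generate_treatment_panel()` emulate the
impedance assay layout end to end: 15-minute sampling over 96 h; a linear
24 h attachment ramp from 0 to the trigger burden (masked from fitting —
the exclusion logic is exercised, never fitted); treatment at the first
time the clean trace reaches `t0_tumor = 0.95` CI, the midpoint of the
protocol's 0.9–1 trigger band; the observable $T + I$ (impedance cannot
distinguish infected from non-infected adherent cells, and CAR T-cells do
not adhere); and multiplicative log-normal noise, mean-corrected so it is
unbiased, with default `sigma_rel = 0.05` — the instrument's true noise
magnitude is not published, so this is a free knob. Replicate streams are
seeded deterministically from the `noise_spec()` seed.
`generate_infected_fraction_assay()` likewise produces duplicate
infected-fraction readings $I/(T+I)$ at 24 h and 48 h across the dose grid
$\{5\times10^{-4}, 10^{-3}, 10^{-2}, 0.1, 1\}$ MOI with additive truncated-
Gaussian noise.

The generating truth (`default_truth_params()`) fixes $K = 5.2246$ CI,
$b = 25$ MOI/CI and $\omega = 0.05\,h^{-1}$ at their reference calibration
values and sets the remaining rates — $\alpha = 0.08$, $\beta_{TV} = 0.02$,
$\gamma = 0.05$, $\theta_{TC} = 0.4$, $\theta_{IC} = 1$,
$\beta_{CV} = 0.003$, $\delta = 0.01$, $\mu = 0.02$ — so that the panel
reproduces the assay's qualitative regime at its deliberately sub-optimal
doses: untreated wells plateau near $K$ by 96 h; each monotherapy
suppresses partially and dose-dependently; infected cells are killed
faster than non-infected ones ($\theta_{IC} > \theta_{TC}$); every tested
combination outperforms both of its matched monotherapies; and scheduling
outcomes are dominated by the CAR T administration time. One documented
tension: the data-derived observation that $\delta$ exceeds $\mu$ at low
E:T ratios cannot be combined with this scheduling phenomenology in a
single constant parameter set, and the scheduling behaviour was given
priority.

What passing tests on these synthetics do **not** show: recovery from real
impedance traces, whose noise is autocorrelated and heteroscedastic in
ways a log-normal i.i.d. model does not capture; plate-position (edge)
effects; or any spatial structure — the model is well mixed by assumption.

## Staged calibration

`fit_carrying_capacity()` → `fit_cart_module()` → `fit_ov_module()` →
`fit_full_model()` mirror the staged protocol: (1) logistic
$(\alpha, K, T_0)$ on untreated wells; (2) $(\theta_{TC}, \delta, \mu)$ on
CAR T monotherapy wells with $(\alpha, K)$ fixed; (3) the OV module in two
steps across a log-spaced burst-size grid — $b$ is not identifiable from
impedance data alone, so it is scanned over $[0.025, 2500]$ MOI/CI, with
$(\alpha, \beta_{TV}, \gamma)$ fit at each $b$, then $\alpha, \gamma$
frozen at their across-grid medians and $\beta_{TV}$ refit per $b$; (4)
$(\theta_{IC}, \beta_{CV}, \beta_{TV}, \theta_{TC})$ on combination wells
with everything else inherited from the earlier stages. Every stage fits
each replicate separately over the unmasked 24–96 h window, minimizing the
sum of squared errors between the observed CI and the model's tumor signal
($T$ for the CAR T module, $T+I$ otherwise; predictions on a 0.5 h grid,
interpolated linearly to the observation times — a 4× coarser grid changes
the objective by under 0.5%), with the initial tumor burden taken from the
first unmasked observation rather than fitted. Replicate means ± standard
deviations are the reported estimates.

Numerical choices that matter:

* **Search scale.** All positive rates are optimized in $\log_{10}$ space
  (their bounds span up to nine decades); $\mu$ stays linear because it
  may change sign. Bounds (`default_fit_bounds()`) bracket the scales
  implied by the units, with small positive floors standing in for zero on
  the log scale.
* **Optimizer.** Global-best PSO (`pso_minimize()`; inertia 0.7, cognitive
  and social weights 1.5, reflective bounds, early stop after 30
  stagnant iterations at relative tolerance $10^{-8}$) followed by
  restarted Nelder–Mead descent from the best few mutually distant
  particles: the SSE valleys are narrow and curved, where swarms converge
  slowly. Non-finite objective values become $+\infty$, never crashes.
  Every run is a pure function of its configuration seed.
* **Basin structure of the combination fit.** The combination SSE surface
  is bimodal in $(\theta_{IC}, \beta_{CV})$: a deep basin at the
  generating values and a shallow one (three orders of magnitude higher
  SSE, yet an RMS misfit of only $\sim 2\times10^{-3}$ CI) that trades
  slower infected-cell killing against less CAR T infection. Because the
  shallow basin's attraction region dominates, `fit_full_model()` runs a
  deterministic profile of $\theta_{IC}$ over a decade grid spanning its
  bounds, re-descending the other parameters at each value from the swarm
  solution and polishing the two best profile points. This recovers the
  generating parameters to better than 1% on noiseless data across all
  tested optimizer seeds.
* **Identifiability limits.** At the assay's sub-optimal doses the CAR T
  burden is only 0.02–0.04 CI, so the $\theta_{IC} I C$ and
  $\beta_{CV} C V$ terms perturb the observable by less than 5%
  measurement noise: under realistic noise these two parameters are not
  recoverable to better than a factor of a few (their SSE profile is flat
  over an order of magnitude), and $\delta = 0.01\,h^{-1}$ is small enough
  that its absolute uncertainty dominates its value. The package reports
  replicate spreads rather than hiding this.

## Burst-size analysis

Evaluating the OV module at the moment of infection yields
$\beta_{TV} = (b I'(0) + V'(0) + \omega V_0)/(b\,T_0 V_0)$
(`beta_from_initial_rates()`), hence with $I'(0) = 0$ the exact log-log
relation $\log \beta_{TV} = -\log b + \mathrm{const}$: the fitted infection
rate is inversely proportional to the assumed burst size. The
package treats this identity and the pipeline sweep separately, on
purpose. `beta_from_initial_rates()` inverts the model to machine
precision on consistent states. The two-step *fitted* sweep
(`fit_ov_module()` + `loglog_relation_check()`) reproduces a strongly
decreasing, near-linear log-log relation, but with a slope of about
$-0.83$ rather than exactly $-1$: a whole-window least-squares refit does
not inherit the initial-rate identity, because rescaling
$(\beta_{TV}, b) \to (c\beta_{TV}, b/c)$ — which would leave trajectories
invariant — also rescales the fixed initial dose, so the fit compromises
between infection-wave timing (set by the product $b\,\beta_{TV}$) and
seeding amplitude (set by $\beta_{TV} V_0$). We verified across generator
regimes that no parameterization brings the fitted slope into
$-1 \pm 0.05$; the corresponding acceptance check is therefore expected
to fail, and the slope is reported as computed.

`infected_fraction_surface()` maps $I/(T+I)$ over a $(b, \omega)$ grid at
the assay read times, optionally overlaying an experimental mean ± sd
band, and `interp_fraction_vs_dose()` interpolates assay fractions to new
doses with a shape-preserving monotone (Fritsch–Carlson) cubic in
$\log_{10}$ dose — doses span more than three decades, and an
unconstrained cubic could overshoot the $[0,1]$ range that fractions must
respect. No extrapolation outside the measured dose range is allowed.

## Treatment outcomes and scheduling

Outcomes are the tumor AUC (trapezoidal integral of $T+I$, or of the
measured CI for data) and the final burden $T(\bar t) + I(\bar t)$ at
$\bar t = 72$ h (`auc_ci()`, `final_burden()`, `predict_outcome()`). The
outcome clock starts at the no-delay administration reference and is not
shifted by delays, so delayed schedules compete on the same horizon; the
default AUC window $[0, 72]$ h post-treatment is exposed, since a
post-seeding window is equally defensible. `delay_scan()` sweeps both
administration delays over $[0, 40]$ h (1 h grid by default; the
acceptance analyses use 2–4 h grids, which resolve the same structure at
a fraction of the cost), breaking argmin ties toward the earliest
schedule; `delay_scan_mono()` produces the per-dose monotherapy delay
curves. `interpolate_params_vs_dose()` predicts parameter sets for
untested virus doses through the unique interpolating polynomial per
parameter (linear for two source doses), carrying $\delta$ and $\mu$ over
unchanged — virus dose does not affect CAR T intrinsic rates — and
clamping negative extrapolations at zero with a warning.
`compare_mono_combo()` assembles the monotherapy-versus-combination
parameter and AUC table.

## Reproducibility and problem sizes

Every stochastic step — noise generation, swarm initialization — is an
explicit function of an integer seed, and the generators and optimizers
save and restore the global RNG state. The test suite and the acceptance
script run the full pipeline at desk scale: single conditions and one to
three replicates per fit, an 11-point burst grid, 2–4 h delay grids, and
ten noise seeds for the recovery study. These sizes are the package's
choice of a representative, quickly reproducible experiment; all of them
are arguments, and production-scale runs only change the numbers passed
in.

## Known limitations

* Deterministic ODEs only: at very low MOI the infection process is
  stochastic, and a branching-process treatment would be more faithful.
* No spatial or plate-layout effects; compartments are well mixed.
* The CI↔cell-number and MOI↔PFU conversions are configurable constants,
  not estimated quantities.
* $\theta_{IC}$, $\beta_{CV}$ and (at its small default value) $\delta$
  are weakly identified at realistic noise; treat their point estimates
  with the reported spreads.
* Single administration per agent; fractionated regimens are out of
  scope.
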