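---
title: "Mechanistic modelling of GAL pathway induction under mixed sugars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic modelling of GAL pathway induction under mixed sugars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Budding yeast decides whether to induce its galactose-utilization (GAL)
genes by weighing galactose against glucose. `galswitch` implements a
deterministic ODE model of this decision with twelve dynamic species:
Gal1p (the fluorescent-reporter proxy and readout), Gal2p (galactose
permease), Gal3p and its galactose-activated form Gal3p\*, Gal80p, Gal4p,
the Gal3p\*–Gal80p and Gal4p–Gal80p complexes, an aggregate hexose
transporter HXT, a total catabolite-repressor pool (Mig1p-like), and
intracellular glucose and galactose. The glucose-bound active repressor
$R_s$ is algebraic:
$R_s = \frac{\mathrm{gluc_{in}}^{n_{Rs}}}{\mathrm{gluc_{in}}^{n_{Rs}} +
K_{Rs}^{n_{Rs}}} \cdot R_{tot}$,
and represses transcription of *GAL1*, *GAL3* and *GAL4*.

Three structural choices matter:

* **Shared transporters.** Both Gal2p and HXT carry both sugars with
  competitive Michaelis kinetics. For Gal2p the glucose flux is
  $k_{G2}\,G2\,\frac{\mathrm{gluc_{ex}}}{\mathrm{gal_{ex}}/r_{G2} +
  \mathrm{gluc_{ex}} + K_{Ggluc}}$ and the galactose flux has the mirrored
  form with relative affinity $r_{G2}$; HXT uses $r_{HXT}$ and catalytic
  scaling $r_{cat} k_{G2}$. Competition makes intracellular sugar levels
  track the external *ratio*, which is what produces a straight decision
  front in log–log space.
* **Sequestration switch.** Gal80p is held in stoichiometric excess over
  Gal4p with tight binding; induction requires galactose-activated Gal3p\*
  to titrate Gal80p away. Positive feedback through *GAL3* and *GAL2*
  makes the switch bistable, and the bistable region is read out as the
  bimodal region of a cell population.
* **Intracellular galactose as the Gal3p ligand.** The sensor binds
  `gal_in`, not external galactose, so sensing happens downstream of
  transport competition.

External sugars are % w/v and are held constant during any one
integration (fixed nutrient conditions per grid cell). The right-hand
side is compiled (C, via deSolve) for speed; an interpreted `gal_rhs()`
is exported and the test suite holds a second, independent literal
transcription of the equations against which both are checked to
relative 1e-12.

## Reference parameters

The packaged `reference_parameters()` are literature-scale placeholders,
not a fit to any experimental table. They were designed once so that the
simulated default grid reproduces the canonical phenomenology:

* all three response classes (unimodal OFF, bimodal, unimodal ON) on the
  96-condition grid, with a broad bimodal band;
* a half-maximum decision front that is straight in log–log space
  ($R^2 > 0.9$);
* monotone repression by glucose at fixed galactose;
* *gal80Δ*: galactose-insensitive rows (glucose-threshold sensing);
* *mig1Δ*: induction at least the wild type's everywhere, clearly higher
  at high glucose;
* bidirectional bimodal-range control by the sensor branch (kf3, kf83,
  dsugar and partners) and inducible-only behavior of the Gal2p group
  (a2, ag2, KG2, rG2);
* leftward front shifts (toward higher glucose/galactose induction
  ratios) when rHXT decreases or kf83 / kf3 increase.

One design insight is worth recording. If the regulatory proteins run at
high copy number, the boundary of the bistable region is set by the
*turnover flux* of the Gal3p\*–Gal80p complex (each degraded complex
carries one galactose molecule away, so sustaining sequestration costs
$d \cdot C83$ galactose per unit time), and binding-rate parameters
barely move it. The reference set therefore runs the
Gal3p/Gal80p/Gal4p core at low copy number with tight binding
($k_{f83}, k_{f84} \gg k_{r83}, k_{r84}$), which puts the boundary in an
equilibrium-limited regime where sensor kinetics have real leverage —
matching the observation that Gal3p/Gal80p-related parameters are strong
bidirectional controllers of the bimodal range.

Time is in model time units with dilution `d = 0.05` per unit; a
protein half-life is therefore ~14 time units and grid steady states are
typically reached within a few hundred units.

## Steady states, modality, and the decision front

For every sugar condition the system is equilibrated twice: from an OFF
state (pre-equilibrated without sugars) and from an ON state
(pre-equilibrated in 2% galactose, no glucose — the saturating top of the
measured ladder; configurable). Integration proceeds in windows of 100
time units until the largest relative change of any component across a
window falls below 1e-6, up to `t_max = 1e5`; non-convergence masks the
condition rather than failing the run. A titration mode (continuation
along the galactose ladder in both sweep directions) is available and
produces the same bimodal classification as the dual-init protocol on
the reference set.

A condition is *bimodal* when the high steady state is ≥5-fold above the
low one (boundary inclusive; the low state is floored at 1e-9 so a
true-zero OFF state with any induced ON state counts as bimodal).
Otherwise it is unimodal ON or OFF according to whether the high state
reaches half the profile maximum. Profiles are normalized to their own
maximum over unmasked cells, mirroring per-strain normalization of
reporter data. The four lowest-galactose cells of the zero-glucose row
are masked by default (no carbon source, no growth).

The decision front interpolates the 0.5 crossing of the normalized high
level log-linearly between adjacent nonzero ladder points, per glucose
row; the induction ratio is the median glucose/crossing ratio over rows,
reported raw and snapped to the nearest power of two.

## Calibration

The objective is the summed squared deviation of the simulated
normalized high/low levels from a table's ON/OFF peak positions over
valid, unmasked conditions. The posterior combines a Gaussian likelihood
on the stacked residuals, $-\mathrm{Obj}/\sigma^2$, with log-normal
priors evaluated in log10 parameter space, the likelihood entering as
the proportionality $\exp(-\mathrm{Obj}/\sigma^2)$ (no factor 2 in the
exponent). Defaults where the choice was open: $\sigma = 0.1$ on the normalized
scale (residuals live in [0, 1]); priors centered on the packaged
defaults with a 1-decade sd; random-walk Metropolis proposals of 0.1
decades per free parameter; chain length and burn-in are configuration.
Sampling in log10 space enforces positivity. The best-so-far state is
tracked by objective with ties keeping the earlier state. Proposals whose
simulation fails score $-\infty$ and are rejected. Multi-strain fits share
one parameter vector and apply each strain's knockouts (structural zeros)
before simulation, so knockout-synthesis rates are effectively not free
for those strains.

## Perturbation survey

Each of the 36 free (non-Hill) parameters is multiplied by each factor in
{0.01, 0.1, 0.5, 2, 10, 100} (216 perturbations). At each of the eight
glucose levels the galactose ladder is titrated in both directions and
three metrics are recorded: `delta_on` and `delta_full`, the log2 shifts
of the bimodality-emergence and full-induction boundaries, and
`delta_level`, the relative change of the un-normalized high-branch Gal1p
level at the highest ladder galactose. Perturbed systems are classified
against the *reference* half-maximum level so a collapsed (always
repressed) system reads as unimodal OFF, and degeneration is reported at
a sentinel one twofold step beyond the ladder maximum with an explicit
flag, so capping can never silently flip a classification. Rows are
grouped by the ≥8-fold rule: `more_inducible` when `delta_on ≤ -3` at two
or more glucose levels, `more_repressed` when `delta_on ≥ +3` at two or
more levels or any degeneration, `bimodality_insensitive` when all
boundary shifts are within one twofold step and `|delta_level| ≤ 0.1`.
The 2-D embedding of matrix rows uses classical multidimensional scaling
of Minkowski row distances (order 2 by default); it is deterministic and
serves visualization only — classification never consults it.

## Phenotype switching

`scan_parameter()` evaluates the objective at 48 multipliers evenly
log-spaced over $[10^{-3}, 10^{3}]$ (endpoints inclusive) plus the ×1
default as a 49th candidate, so the improvement
$\Delta\mathrm{Obj} = (\mathrm{Obj}_{start} - \mathrm{Obj}_{best}) /
\mathrm{Obj}_{start}$ is never negative; ties prefer the multiplier
closest to 1. `improvement_matrix()` runs the scan for every
(strain, parameter) pair and caches simulated profiles across strains,
since a perturbed profile does not depend on which table it is scored
against. Because several parameters act through the same mechanism
(e.g. kf83/kr83/a80/ag80 all set the effective Gal3p\*–Gal80p
sequestration strength), recovery is judged against mechanistic partner
sets, not single columns.

## Synthetic data

`generate_strain_table()` emulates summarized flow-cytometry output: per
condition, the ON-peak and OFF-peak positions are the simulated
normalized high/low levels plus Gaussian noise (default sd 0.05 on the
normalized scale, truncated at zero, OFF never above ON), re-normalized
to the table maximum, with non-convergent or no-growth cells marked
invalid. Tables are bit-reproducible from their spec (mandatory seed).
The default panel is the base strain, *mig1Δ*, *gal80Δ*, and three
single-mechanism variants (rHXT ÷ 10, kf83 × 10, kf3 × 10). What the
generator does *not* emulate: histogram shapes, cell-to-cell noise
mechanisms, growth-rate differences between conditions, or
strain-specific measurement artifacts — so green tests demonstrate
internal consistency of the pipeline, not fidelity to any particular
laboratory dataset.

## Numerical choices and problem sizes

* lsoda with `rtol = 1e-8`, `atol = 1e-10`; tiny negative undershoot is
  clamped to zero (mass-action systems are non-negative analytically);
  integrator give-ups (pathological perturbations such as ×1000
  multipliers) are masked, not fatal.
* Calibration-scale analyses (recovery sweeps, MCMC examples) run on a
  reduced 4 glucose × 6 galactose grid, and the structural 216-row survey
  on a 4-point galactose ladder — desk-scale choices that keep the full
  pipeline reproducible in minutes; all sizes are configuration, and the
  full 8 × 12 grid and 11-point ladder are the analysis defaults.
* Ties and degenerate inputs: an all-zero profile (e.g. a *GAL1*
  deletion) normalizes to zero with a warning; an empty free-parameter
  list returns the starting point after one objective evaluation;
  `improvement(0, 0)` is 0 by convention.

## Known limitations

Single-cell stochasticity (switching rates, mixed-population dynamics)
is out of scope — bimodality is inferred from deterministic bistability.
Gal4p/Gal80p dimerization, subcellular localization, per-isoform HXT
differences and sugar depletion during growth are not modelled. The
packaged parameter values are qualitative-phenomenology placeholders;
quantitative comparison to a particular strain requires calibrating
against that strain's tables with `fit_strains()`.
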