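---
title: "Methods: confidence-level response surfaces for dose combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confidence-level response surfaces for dose combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocomb)
```

## The model stack

`isocomb` answers one question: for which dose combinations `(AMT1, AMT2)`
does a combination therapy reach a prespecified efficacy target ŷ (a
population success rate, e.g. 95%), and with what confidence given
parameter uncertainty?

Three nested levels of description are involved.

**Individuals.** A PK/PD model maps a subject's parameters and a dose pair
to a binary outcome. In the malaria-like testbed each drug follows a
two-compartment disposition model with first-order absorption (parameters
`ka` 1/day, `CL` L/day, `Vc` L, `Q` L/day, `Vp` L per drug); the parasite
population grows exponentially at `kgrow` (1/day) and is killed at a
concentration-dependent rate. Per-drug kill follows a sigmoidal Emax model
`e_i = Emax_i c^h_i / (EC50_i^h_i + c^h_i)`, and the two drugs combine by a
Bliss-independence form normalized for unequal maximal effects,
`e1 + e2 - e1 e2 / max(Emax_1, Emax_2)`, so that saturating both drugs
yields the larger Emax rather than the sum, and a single drug reduces the
expression exactly to its own Hill effect. A subject is cured when the
parasite concentration is below the limit of quantification (10
parasites/ml) at day 28 after a single oral dose of each drug.

**Populations.** A population realization is one draw of population
parameters from the parameter-uncertainty distribution — interpreted as the
asymptotic sampling distribution of maximum-likelihood estimates, here
multivariate normal on the log scale for positive-constrained parameters.
Conditioned on that draw, `n_subj` subject parameter sets are drawn
log-normally with the population's IIV variances (diagonal by default, an
optional correlation matrix couples the random effects). The population's
output at a dose pair is the *success rate*: the fraction of its subjects
cured. Sampling is hierarchical and frozen up-front under a seed chain
(master seed → per-population seeds → per-subject seeds), so a population's
surface is deterministic (common random numbers across doses) and
independent of the order in which doses are evaluated.

**Ensemble.** Repeating over `n_pop` population draws gives the ensemble.
The ensemble-level summary is the *confidence level*: the fraction of
populations whose success rate meets ŷ at a dose pair.

## The fastIsoboles search

For a monotone success-rate surface, all information about a population is
contained in its *effective isobole* — the curve where the surface crosses
ŷ, separating non-efficacious from efficacious dose pairs. The search
generalizes bisection to curves:

1. evaluate the nine nodes of the 3×3 lattice over `[0, AMT1max] ×
   [0, AMT2max]` (level `j = 1`);
2. estimate the isobole by marching-squares contour extraction with linear
   interpolation (`grDevices::contourLines`), no smoothing;
3. double the resolution; evaluate a new node only if its distance to the
   current isobole estimate — Euclidean distance to the polyline's
   *segments*, in normalized dose units — is smaller than the
   pre-refinement grid spacing `2^-j`;
4. repeat until the discrete Fréchet distance between successive estimates
   drops below `tol`, or `max_iter` iterations are reached.

After `j` iterations the lattice has `2^j + 1` doses per drug. Nodes never
evaluated are filled by bilinear interpolation from the previous level
before contour extraction; they lie farther than one spacing from the
isobole, so their side of the level is already determined and the filled
values cannot move the contour. On the monotone fixtures in the test suite
the search needs at most 35% — typically around 10% — of the full 65×65
lattice at `j = 6`.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `target_rate` | 0.95 | efficacy target ŷ (fraction of subjects) |
| `bounds` | (800, 800) mg | maximum feasible dose per drug |
| `max_iter` | 6 | iterations; final resolution `2^j + 1` per axis |
| `tol` | `2^-7` | Fréchet convergence tolerance, normalized units (one cell at the practical maximum resolution of 129) |
| `n_pop`, `n_subj` | 750, 1500 | ensemble sizes of the reference study conditions |
| aggregation resolution | `2^(j+1) + 1` | twice the final search resolution |

All geometry (refinement distances, Fréchet steps) is computed in
normalized dose space — each axis divided by its maximum dose — so the
spacing-based thresholds remain meaningful when the two drugs have
different dose ranges.

## The aggregateIsoboles construction

Augmenting an isobole's ordered vertices with the stretch of the
dosing-space boundary that runs through the origin yields a simple polygon
enclosing the failure region. Each node of a fresh uniform lattice is
encoded 0 if it fails (strictly inside the polygon, or on its closure
segments along the boundary — the origin always fails) and 1 if it
succeeds (on the isobole itself, where the target is achieved exactly, or
outside). Averaging the binary fields over populations gives the
confidence-level response surface; its contours at e.g. 0.50 and 0.95 are
the confidence-level isoboles. Containment uses even-odd ray casting with
an explicit boundary test. Populations whose search classified the whole
space ("entire space efficacious"/"non-efficacious") contribute constant
all-1/all-0 fields.

## Numerical choices

- **Success-rate evaluation.** With linear PK the concentration profile is
  dose-proportional and available in closed form (tri-exponential), and the
  exponential-growth/kill PD integrates exactly to
  `log P(T) = log P0 + kgrow·T − ∫ kill(C1(t), C2(t)) dt`. The population
  objective therefore precomputes per-subject unit-dose concentration
  matrices once and evaluates the kill integral by trapezoidal quadrature
  on a grid quadratically clustered near `t = 0` (401 nodes by default,
  where absorption makes the kill rate change fastest). The single-subject
  trajectory path integrates the coupled ODE system with `deSolve::lsoda`
  at rtol `1e-8` / atol `1e-10` — tight because the cure decision compares
  a state against a small limit of quantification — and a test asserts the
  two routes agree on terminal log-parasitemia to `1e-4`.
- **Parasite positivity.** Reported trajectories floor parasitemia at
  `1e-3` parasites/ml; the closed-form route works in log space and cannot
  go negative.
- **Degenerate starts.** If all nine initial nodes fall on one side of ŷ,
  one full-lattice refinement to level 2 (25 nodes total) is performed
  before declaring the space unbracketed — the analogue of bisection's
  bracket check, so steep sub-cell isoboles are not overlooked.
- **Multiple contour components.** All components enter the refinement
  distance test, but the result's isobole is the longest component:
  spurious micro-components near the level must not derail refinement, and
  the monotonicity assumption implies a single true isobole.
- **Ties on a stepwise confidence surface.** Confidence isoboles are drawn
  by the same linear-interpolation contour routine; on a stepwise surface
  the contour falls within one cell of the step.
- **Discrete (not continuous) Fréchet distance** is used: an exact dynamic
  program, adequate because contours are dense relative to the tolerance.
  It is direction-sensitive, so comparisons against closed-form oracles
  densify the oracle (`densify_polyline()`) and minimize over the two
  traversal directions.
- **Convergence bound.** The Fréchet step between successive estimates
  scales with the grid spacing; the package asserts the conservative bound
  `sqrt(2)·2^-j` (normalized units) for the recovered isobole against
  closed-form oracles.

## The testbed parameterization

The malaria-like defaults (`malaria_default_params()`) are synthetic
plausible values, not estimates for any real drug pair: absorption 3–6
1/day, clearances 9–14 L/day, central volumes 45–60 L, maximal kill rates
6.5–7.5 1/day against a growth rate of `log(10)/2 ≈ 1.15` 1/day (a
ten-fold multiplication per 48-h cycle from a baseline of `1e7`
parasites/ml), EC50 1 mg/L. They were chosen once so that mono-dose cures
of the point-estimate population occur near 330 mg (drug 1) and 450 mg
(drug 2), leaving the population-level 95% isoboles — pushed outward by IIV
(log-variances 0.05 on clearances and EC50s, 0.02 on growth) and parameter
uncertainty (log-SDs 0.05 on PD parameters, 0.03 on clearances) — inside
the 800 mg maximum feasible dose per drug. Analytic fixture families
(`additive`, `bliss`, `probit_additive`, `nonmonotone_bump`) provide
closed-form surfaces and isoboles used as oracles.

## What the synthetic generator does and does not emulate

The generator reproduces the hierarchical structure of a clinical-trial
simulation: parameter uncertainty at the top, log-normal IIV below it,
binary endpoints per subject, and success-rate granularity of `1/n_subj`.
It does not emulate covariate effects, residual/observation error,
dropout, adherence, estimation error in the uncertainty distribution
itself, or model misspecification — passing tests demonstrate correctness
of the algorithms under the stated hierarchical model, not robustness of
any real drug-development decision.

## Problem sizes used in tests

The default study conditions (750 populations × 1500 subjects, `j = 6`)
describe a production run. The test suite and acceptance script exercise
the same code paths at reduced sizes chosen to keep the full suite fast on
one CPU while leaving every contract binding: end-to-end brute-force
comparison at 25 populations × 200 subjects on a 17×17 lattice (`j = 4`),
savings and oracle accuracy at `j = 6` on single populations of 100–200
subjects, CDF equivalence at 50 populations.

## Known limitations

- Monotone surfaces only: like bisection, the search can overlook isoboles
  of non-monotone surfaces (e.g. an Eagle-effect bump). Run
  `check_monotonicity_run()` on a few probe populations first; the
  `nonmonotone_bump` fixture demonstrates a detected violation.
- One isobole per population; multi-contour effect levels are out of scope.
- Two drugs; higher-dimensional combinations would need cross-sections.
- Fixed dosing schedules per run; schedule exploration requires one run per
  schedule.
- `rank_parameter_influence()` summarizes an isobole's location by its
  normalized failure-polygon area (Spearman correlation against the
  population draws). Other location summaries are conceivable; this one is
  scale-free and handles degenerate isoboles naturally (area 0 or 1).
- The achievable speedup over brute force depends on the isobole's shape:
  curves hugging the boundary save more, diagonal curves less. The manifest
  reports the achieved ratio for every run.
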