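---
title: "Modelling apoptosis execution: cooperative apoptosome recruitment, the caspase-9 molecular timer and XIAP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling apoptosis execution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoptimer)
```

## The biological problem

After mitochondrial outer membrane permeabilisation (MOMP), cytochrome c
(CytC) and SMAC enter the cytosol. CytC, APAF1 and ATP assemble the
apoptosome, the platform on which pro-caspase 9 (PC9) is activated to cleave
pro-caspase 3 (PC3); active caspase 3 (C3) then executes apoptosis, read out
here as cleavage of a DEVD-site reporter substrate. Two negative regulators
gate this cascade. XIAP inhibits cleaved caspase 9 (C9-35/12, via its BIR3
domain) and C3 (via BIR2), and is itself neutralised by SMAC. Independently,
autocatalytic cleavage of the apoptosome-bound PC9 homodimer produces
C9-35/12, which binds the apoptosome only weakly: platform activity therefore
shuts itself down over tens of minutes — the *molecular timer*. Because both
XIAP inhibition and the timer are triggered by the same autocleavage event,
their contributions cannot be separated experimentally; this package
separates them by simulation.

## The reaction network

The model is a mass-action ODE system in µM and minutes over 20 species.
Its reactions:

* **Platform formation.** `APAF1 + CytC → Apop` at rate
  `k_asm · [APAF1][CytC] · ATP/(ATP + K_ATP)`. The apoptosome is coarse-grained
  to one PC9-recruitment unit per activated APAF1; ATP enters as a saturating
  modifier (`K_ATP` = 100 µM, so both cellular 920 µM and reconstituted 1 mM
  ATP are non-limiting). CytC is consumed stoichiometrically, which is what
  makes minority MOMP (5% release) assemble platforms more slowly and less
  completely.
* **Cooperative PC9 recruitment.** A first PC9 binds weakly and reversibly
  (`kon_primary`, `koff_primary`); a second PC9 is then captured directly
  into a homodimer with much higher association and much lower dissociation
  (`kon_secondary`, `koff_secondary`). The bounds of the calibration force
  primary binding weaker, and secondary binding stronger, than the
  SPR-derived kinetics of the non-cleavable PC9 trace, because an SPR readout
  mixes the two binding modes.
* **Autocleavage and the timer.** The bound homodimer converts at `k_auto`;
  both protomers cleave, one C9 remaining platform-bound and one released.
  C9 rebinds only weakly (`kon_C9`, `koff_C9`; dissociation constant 100 µM
  against 2.5 nM for secondary PC9 binding), so platform activity decays once
  the PC9 pool is consumed.
* **Catalysis.** PC3 is cleaved by the PC9 heterodimer, the PC9 homodimer
  (both moieties counted) and platform-bound C9 (`k_PC9`, `k_C9`); C3 cleaves
  the reporter substrate (`k_cat_DEVD`).
* **Regulation.** XIAP binds C9 (free and platform-bound, same kinetics) and
  C3, one caspase per XIAP; SMAC sequesters free XIAP essentially
  irreversibly. The XIAP/SMAC affinities are the well-characterised
  nanomolar BIR-domain values.
* **Turnover.** First-order degradation and zeroth-order synthesis terms
  exist for the free proteins but default to zero, and the screening
  functions keep them off.

Model variants rewire this system: `no_timer` gives C9 the secondary-PC9
binding kinetics (stable binding, activity persists; XIAP inhibition of C9 is
retained, keeping the two regulators separable), `no_xiap` zeroes the XIAP
pool, `noncleavable` zeroes `k_auto` (no C9 is ever formed, so XIAP cannot
touch the apoptosome), and the joint removal combines the first two. The
timer is attributed solely to the poor affinity of C9-35/12 for the platform,
which is why "timer off" is implemented as an affinity change and not as a
frozen dissociation.

## Parameters and calibration

The defaults (all in µM, min; see `default_parameters()`) fall into three
groups.

* **Literature-anchored:** XIAP–C3 (K_D 1 nM), XIAP–C9 (10 nM), SMAC–XIAP
  (0.4 nM), CytC 10 µM and ATP 920 µM for a HeLa-like cell.
* **SPR-anchored bounds:** the shipped synthetic dissociation traces give the
  non-cleavable PC9 anchor (t½ = 40 s, K_D = 0.1 µM → k_off 1.04 min⁻¹, k_on
  10.4 µM⁻¹min⁻¹). `default_bounds()` places primary binding below and
  secondary binding above this anchor, and bounds C9 rebinding weaker in
  affinity than secondary binding (the timer precondition).
* **Calibrated:** the PC9/C9 recruitment and catalysis constants were fixed
  by requiring, inside those bounds, that (i) the simulated HeLa substrate
  cleavage follows a Boltzmann-shaped time course with half-time near 25 min;
  (ii) the reconstituted-apoptosome protocol (APAF1 0.3 µM, PC9 0.0125 µM,
  pre-incubation 5–30 min before PC3/substrate addition) shows the maximal
  cleavage rate declining several-fold across the pre-incubation window,
  while the timer-off variant stays flat within 5%; and (iii) increasing XIAP
  monotonically suppresses cleaved C3 in the HeLa setting.
  `estimate_parameters()` implements the same fitting machinery generically:
  multi-start (Latin hypercube) bounded least squares in log10 space, with
  each training set's residuals normalised by its dynamic range before the
  equal-weight sum — "equal weighting" is otherwise scale-ambiguous between a
  percentage curve and a rate curve.

Two calibration decisions deserve emphasis. The per-moiety catalytic rates
of PC9- and C9-apoptosome are set equal (`k_PC9 = k_C9 = 6 µM⁻¹min⁻¹`). The
zymogen and cleaved enzyme share the active site, and the ordering between
the non-cleavable and timer-off variants (a non-cleavable zymogen should be
at least as dangerous as merely removing the timer, since it also escapes
XIAP) holds only if the platform-bound zymogen is not intrinsically weaker.
The small integrated activity share of the PC9 species then emerges from
their short residence time, not from a weak rate constant. Second, the weak
C9 rebinding constant (K_D 100 µM) was chosen at the top of its bounded
range: with micromolar-range platforms, any substantially stronger rebinding
leaves a persistent activity plateau that erases the pre-incubation decline
the timer training data show.

## Numerical choices

* Stiff integration with `lsoda` (via deSolve) on a compiled C right-hand
  side; absolute tolerance 1e-19 µM, relative 1e-8. Halving both changes the
  240-min cleavage by well under 0.1% (tested).
* Dense output defaults to one point per 10 s (1441 points over 240 min),
  which stabilises the trapezoidal activity integrals; endpoint-only grids
  are used where only a final value is needed.
* Death events (substrate cleavage strictly exceeding 25%) are located by
  bisection on the interpolated dense output to 1e-6 min; grid-snapped death
  times would distort the survival curves. Trajectories at or below the
  threshold are censored at 240 min.
* The post-maximum decay of an IETDase activity trace is fitted with the
  shared one-phase-decay fitter, time re-zeroed at the maximum, `y0` fixed to
  the maximum and the plateau constrained non-negative; non-decaying traces
  (timer off) report an infinite half-life rather than a spurious fit.
* The one-phase-decay fitter starts from a deterministic heuristic (first
  value, last value, log-linear slope of the first third) and uses a bounded
  Levenberg–Marquardt step, so identical inputs give identical fits; flat
  traces are flagged unidentifiable instead of fitted.

## The population screens

`sample_cohort()` draws virtual cells uniformly and independently per protein
from ranges chosen once from reported expression levels across common cell
lines: APAF1 0.05–1, PC9 0.005–0.25, PC3 0.05–1, XIAP 0.01–0.6, SMAC
0.05–1.5 µM (log-uniform sampling is available as an option). CytC and ATP
are fixed at the HeLa-like 10 and 920 µM. `screen_report()` then runs the
whole pipeline: 60-min classification of apoptosis capability (normal
variant) and timer dependence (timer-off variant among resistant cells),
Mann–Whitney ROC AUCs of each input concentration and of the XIAP–SMAC
balance `log10(XIAP/SMAC)` (the log-ratio puts the equimolar separation
point at zero; an absolute difference is available for sensitivity
analysis), and a 240-min four-variant survival cohort for Kaplan–Meier
curves, logrank contrasts, timer-rescue fractions and Webb's
fractional-product synergy, with scores strictly below 0.9 called
synergistic. Default problem sizes are 5000 classification cells and 1000
survival cells, the sizes also used by `scripts/acceptance.R`.

Patient profiles are handled the same way at a 300-min horizon with full
MOMP, APAF1 defaulting to the colorectal tumour median 0.123 µM, and class
labels related to disease-free/overall survival through the product-limit
estimator and a two-group Cox model (both via the survival package).

## What the synthetic data emulate — and what they do not

The generators produce (a) one-phase-decay dissociation traces with seeded
Gaussian noise standing in for digitized SPR curves; (b) Boltzmann cleavage
curves and exponentially declining timer points standing in for the
published training data; and (c) patient cohorts with log-normal protein
concentrations parameterised by median and coefficient of variation (XIAP
100%, PC9 154%, PC3 144%, SMAC 135%, matching the dispersion reported for
the stage III colorectal cohort) and exponential class-dependent survival
with independent censoring. Passing tests on these fixtures demonstrates
internal consistency — parameter recovery, estimator correctness, invariant
preservation — not agreement with any real SPR instrument, FRET experiment
or patient outcome. In particular the synthetic patient cohort has, by
construction, a clean proportional-hazards structure that real cohorts lack,
and the shipped SPR fixtures are labelled synthetic because the original
figure-digitized values are not redistributable here.

## Known limitations

* The apoptosome is coarse-grained to independent recruitment units; the 7:7
  platform stoichiometry and intra-platform cooperativity beyond the
  two-step PC9 capture are not resolved.
* C3-mediated feedback cleavage of C9 (D330) and of XIAP is excluded by
  design, as are upstream Bcl-2 family dynamics (MOMP is an instantaneous
  pool transfer) and all synthesis/degradation during screens.
* The ordering "non-cleavable ≥ timer-off" holds cell-by-cell only where
  released SMAC covers XIAP. With XIAP in excess, the timer-off variant's C9
  pool can act as a XIAP decoy — sequestering XIAP away from C3 much like a
  SMAC mimetic — and occasionally out-kills the non-cleavable variant. The
  tests assert the ordering in its robust domain plus the XIAP-escape
  contrast on an XIAP-excess fixture.
* Quantities that depend on the exact literature parameterisation and
  sampling ranges (notably the XIAP ROC magnitudes and the minMOMP rescue
  fraction) are sensitive to choices this package had to make
  independently; the screen's orderings and the synergy direction are the
  robust outputs.
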