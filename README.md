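# apoptimer

Systems modelling of the apoptosis execution phase: cooperative recruitment
of pro-caspase 9 (PC9) to the apoptosome, the **molecular timer** created by
its autocleavage to weakly-binding caspase 9 (C9-35/12), and regulation by
XIAP and SMAC.

After mitochondrial outer membrane permeabilisation (MOMP), cytochrome c and
SMAC are released; the apoptosome assembles and activates caspase 9, which
cleaves pro-caspase 3, whose product executes apoptosis (read out as DEVD
substrate cleavage, with >25% cleavage defining a death event). XIAP inhibits
cleaved caspase 9 and caspase 3 and is neutralised by SMAC; independently,
autocleavage of the apoptosome-bound PC9 homodimer converts it to C9-35/12,
whose poor platform affinity shuts apoptosome activity down over tens of
minutes. Both brakes hang off the same cleavage event, so their separate
contributions are experimentally inaccessible — but trivially separable in a
model with independent switches. The package is aimed at systems biologists
studying apoptosis sensitivity and at anyone needing a fast, fully tested
virtual-cell screening pipeline on top of a stiff mass-action ODE core.

## The model in brief

A 20-species mass-action ODE system (µM, minutes), compiled in C and solved
with `lsoda` (atol 1e-19, rtol 1e-8):

* platform formation `APAF1 + CytC → Apop` (ATP a saturating modifier);
* cooperative recruitment `Apop + PC9 ⇌ Apop·PC9`,
  `Apop·PC9 + PC9 ⇌ Apop·PC9₂` with k_on(primary) < k_on(secondary) and
  k_off(primary) > k_off(secondary), anchored to SPR-derived bounds;
* autocleavage `Apop·PC9₂ → Apop·C9 + C9` and weak rebinding
  `Apop + C9 ⇌ Apop·C9` (K_D ≫ platform concentration — the timer);
* catalysis `PC3 → C3` by the active platform species (IETDase activity
  `k_PC9·[active PC9] + k_C9·[active C9]`) and `Sub → cSub` by C3;
* XIAP binding of C9 (BIR3) and C3 (BIR2); SMAC sequestration of XIAP
  (k_off = ln 2 / t½, k_on = k_off / K_D throughout).

Switchable variants — `normal`, `no_xiap`, `no_timer`, `no_xiap_no_timer`,
`noncleavable` — feed survival screens (Kaplan–Meier, logrank), ROC/AUC
classification screens (Mann–Whitney pair counting), Webb's
fractional-product synergy (`<0.9` = synergistic) and simulation-based
classification of patient tumour profiles (apoptosis capable vs resistant at
300 min, Cox hazard ratios for survival endpoints).

## Worked example

```r
library(apoptimer)
params <- default_parameters()
sys    <- build_network(params, model_variant())

# HeLa-like cell, complete MOMP, 4 h
traj <- simulate_network(sys, apply_momp(initial_state(), 1), t_end = 240)
print(traj)
#> Apoptosis-execution trajectory
#>   1441 time points over [0, 240] min, 20 species
#>   final C3-substrate cleavage: 100.0%
detect_death_event(traj)
#> death event at 12.278 min (cleavage > 25%)
round(100 * c3_substrate_cleavage(traj, c(10, 20, 30, 60)), 1)
#> [1] 19.0 42.7 59.9 87.0

# molecular timer: pre-incubating the apoptosome erodes its punch
rates <- sapply(c(5, 15, 30), function(d) timer_protocol_observable(params, d))
round(rates / rates[1], 3)
#> [1] 1.000 0.287 0.169

# population screen (scaled down; defaults are n = 5000 / 1000)
rep <- screen_report(n = 800, seed = 1, n_survival = 400)
print(rep)
#> Population screen (n = 800 classification, 400 survival, seed 1)
#>   resistant fraction: momp 0.06, minmomp 0.382
#>   resistance AUC after full MOMP:
#>     balance  0.932
#>     smac     0.906
#>     pc9      0.830
#>     pc3      0.690
#>     xiap     0.681
#>     apaf1    0.501
#>   timer rescue (momp): 9/393 = 0.023
#>   timer rescue (minmomp): 46/350 = 0.131
#>   median Webb score (minmomp): 0.000
#>   median Webb score (momp): 0.000
```

Reading the output: the HeLa-like cell dies ~12 min after MOMP with a
sigmoid cleavage time course. The timer protocol shows apoptosome activity
decaying several-fold across a 5–30 min pre-incubation window. In the
screen, the XIAP–SMAC balance (`log10(XIAP/SMAC)`, 0 at equimolarity) is the
strongest single predictor of apoptosis resistance after full MOMP; the
timer rescues a much larger share of would-be deaths after minority MOMP
(5% release) than after full MOMP; and Webb scores far below 0.9 mean XIAP
and the timer suppress apoptosis synergistically, not additively.

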