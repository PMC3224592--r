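---
title: "A whole-body compartmental model of arsenic methylation and excretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body compartmental model of arsenic methylation and excretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmethyl)
```

## The model

Ingested trivalent inorganic arsenic (iAs) is absorbed from the gut into
the blood, taken up by the liver, and methylated there in two steps by
arsenic (+3 oxidation state) methyltransferase (AS3MT): first to
monomethylarsonic acid (MMA), then to dimethylarsinic acid (DMA). DMA is
excreted into urine much faster than MMA or iAs, which is why methylation
is usually regarded as a detoxification pathway. Because human data come
from blood and urine while the chemistry happens in the liver, the package
implements a whole-body compartment model that connects the two.

The state carries ten body compartments in concentration units (uM) and
three cumulative urine amounts (umol):

* `gut`, `gut_MMA`, `gut_DMA` — arsenicals awaiting absorption; one gut
  pool per dosed species, because oral MMA and DMA doses absorb at their
  own rates (0.11, 2 and 0.125 per hr for iAs, MMA, DMA) and enter their
  own blood pools.
* `BiAs`, `BMMAs`, `BDMAs` — blood (3 L).
* `bodystore` — iAs reversibly bound in non-liver tissues (30 L).
* `LiAs`, `LMMAs`, `LDMAs` and the protein-bound `LiAs_store`,
  `LDMAs_store` — liver (2 L).
* `UiAs`, `UMMAs`, `UDMAs` — cumulative urinary amounts, in micromoles so
  trajectories compare directly to interval urine collections.

All transport, storage and excretion steps are first order. When a flux
crosses compartments of different volume, the ratio of volumes converts
the concentration change (a loss of `k*[A]` uM/hr from compartment A
arrives as `k*(V_A/V_B)*[A]` uM/hr in B); the urine equations carry the
blood volume itself, converting concentration loss into molar
accumulation. These factors make the volume-weighted total
`sum(V_i * C_i) + urine` obey exact mole balance against the cumulative
input, which the test suite checks both algebraically on random states
and along integrated trajectories.

The two methylation velocities are the only nonlinearities:

$$V_1 = u\,V_{max,1}\,
  \frac{[\mathrm{LiAs}]}{(K_m + [\mathrm{LiAs}])
        \left(1 + [\mathrm{LiAs}]/K_{si}\right)
        \left(1 + [\mathrm{LMMA}]/K_{i,prod}\right)}
  \cdot \frac{\alpha\,[\mathrm{SAM}]}{K_{m,SAM} + [\mathrm{SAM}]}$$

$$V_2 = u\,V_{max,2}\,
  \frac{[\mathrm{LMMA}]}{(K_m + [\mathrm{LMMA}])
        \left(1 + [\mathrm{LiAs}]/K_{i,iAs}\right)}
  \cdot \frac{\alpha\,[\mathrm{SAM}]}{K_{m,SAM} + [\mathrm{SAM}]}$$

with `Km = 4.6` uM for both steps, substrate inhibition of step 1 making
`V1` non-monotone with its maximum at `sqrt(Km * Ksi)`, inhibition of
step 2 by liver iAs (`Ki = 40` uM), and `u` an AS3MT expression
multiplier. Both steps consume a methyl group from S-adenosylmethionine
(SAM), hence the shared saturable SAM factor (`Km_SAM = 11.8` uM). The
constant `alpha` is chosen so the factor is exactly 1 at the declared
normal liver SAM — `alpha_for_normal_sam(60, 11.8) = 1.1967` — so that
below-normal SAM (folate deficiency) slows both steps in a calibrated
way rather than rescaling the whole model.

### The inhibition-constant convention

The source literature is ambiguous about which of the two step-1
inhibition constants (1.26 uM and 40 uM) is the substrate-inhibition
constant for liver iAs and which the product-inhibition constant for
liver MMA: the rate-law presentation pairs 1.26 with the substrate, while
the tabulated constants are labelled the other way (`KiiAs = 40`,
`KiMMA = 1.26`). Both assignments are implemented behind the
`inhibition_convention` switch of `as_params()`. The default, `"table"`
(substrate constant 40, product constant 1.26), was fixed by running the
chronic-exposure scenarios under each convention and keeping the one
whose steady-state blood and urine compositions reproduce the published
composition tables within one integer percentage point; the `"text"`
assignment misses the blood iAs share by about two points. The same
switch governs the in-vitro parameter set.

Two related resolutions, made the same way: `Vmax = 1` uM/hr for both
steps (the value quoted with the fitted model; the alternative 0.7 is
selectable) and `Km = 4.6` uM for the second step (the alternative 3 is
selectable). Under `Vmax = 0.7` or `Km2 = 3` the scenario tables are off
by up to nine points.

## Dosing

Single oral doses become available in the gut over a six-minute window
(0.1 hr) as rectangular input pulses; `gut_input_function()` exposes the
piecewise-constant rate and its breakpoints, and the integrator restarts
at every breakpoint so a pulse can never be stepped over. Doses are
quoted in micrograms of elemental arsenic and converted at 74.9216 g/mol,
so equal microgram doses of the three species compare on a molar basis.
A dietary background intake of 7 ug/day is on by default in dose
simulations, since the single-dose experiments the transport parameters
derive from measured such a background. The chronic-exposure scenarios
instead use a constant input whose stated total (e.g. 300 ug/day) already
is the whole daily intake, so background is not added there.

## Urine analysis

The observable everywhere is the interval excretion rate: urine
accumulated between consecutive collections divided by the interval
length (`interval_excretion_rates()`), which is how the human experiments
report their data. Rate curves are harder to fit than cumulative curves
and carry more information — in particular the long flat tails that
storage pools produce. Composition percentages are compared to published
tables after half-up rounding to integers (`round_half_up()`), matching
how those tables print, with a tolerance of one percentage point.

## Chronic-exposure scenarios and folate supplementation

`run_chronic_profile(daily_input, SAM, upregulation)` integrates to
steady state and summarises blood and urine composition and the total
blood, liver and body-store burdens. The folate analysis compares a
folate-deficient scenario (SAM = 15 uM, one quarter of normal) with a
supplemented one (SAM = 60 uM) at 300 ug/day and AS3MT upregulated
two-fold; `folate_comparison()` reports the percent changes in the three
burdens. Raising SAM from 15 to 60 uM lowers total blood arsenic by
about 13%, total liver arsenic by about 20% and the body store by about
26% at these settings. Steady state is used for the comparison (the
12-week supplementation horizon is far beyond the slowest time constant,
about 100 hr, so a finite-horizon run gives the same numbers; the
transient itself is available via `sam_switch_transient()`, which shows
the urinary DMA overshoot within the first two weeks). Upregulation
multiplies both `Vmax` values.

## The in-vitro hepatocyte variant

`hepatocyte_config()` reparameterises the same equations for cultured
human hepatocytes: blood becomes the 0.5 ml culture medium, liver becomes
the 0.0005 ml of cells (volume ratio 0.001), and the gut, urine and
whole-body store are removed. A medium storage pool (iAs binding to the
collagen-coated plate) replaces the body store with volume ratio 1, and
the cells keep an iAs store but no DMA store. With volumes in ml and
concentrations in uM the phase totals are in nmol; the closed system
conserves its initial moles (0.05 nmol for the 0.1 uM arm) to solver
precision. Because the cells hold one thousandth of the medium volume,
cell concentrations exceed medium concentrations early while cell-phase
moles stay a small fraction of the total — assertions in the tests are
therefore on moles, not concentrations.

## Staged calibration

The transport parameters of the whole-body model are identified from
three single-dose arms in a fixed order that mirrors how the subsystems
nest:

1. `DMA_stage` — the DMA-dose arm involves only `k5`, `k_5`, `k10`,
   `k_10`, `k8` and the DMA gut absorption rate.
2. `MMA_stage` — the MMA-dose arm adds `k4`, `k_4`, `k7`, `Vmax2` and the
   MMA gut rate.
3. `full_stage` — the iAs arm constrains the remaining parameters
   (`k1`, `k2`, `k_2`, `k3`, `k_3`, `k9`, `k_9`, `k6`, `Vmax1`).

Each stage fixes its estimates before the next runs. The objective is
least squares on the interval excretion rates of the observed species
(`weighting = "absolute"`); a `"relative"` option divides residuals by
the observations, which is the statistically matched choice when the
measurement error is multiplicative.

The loss surface of interval-rate data is a classic sloppy
sum-of-exponentials landscape: long curved valleys and many local minima
that fit the curves to within a fraction of a percent. A plain local
search from random starts lands in a different valley almost every time.
`fit_stage()` therefore works in three phases in log parameter space: a
maximin Latin-hypercube screen of the bounds, Levenberg-Marquardt
polishing of the best screen points, and basin hopping — repeated
seeded log-normal perturbation and re-polish of the incumbent, accepting
downhill and near-level moves — until a numerically exact fit or a
patience limit. Default bounds are a decade either side of the reference
values; all randomness is governed by a single seed (default 20110826).
Noiseless synthetic data are reproduced to machine precision and the
generating parameters recovered to well under 1% per stage with the
default budgets; the full-stage (9-parameter) search uses a larger
hopping budget because the body-store and liver-store pathways shape the
same slow excretion tail and are the sloppiest pair — echoing the
biological observation that urine data alone barely distinguish
extra-hepatic from hepatic storage.

With 5% multiplicative noise on 20 collection intervals the per-arm
information is genuinely limited. Local identifiability analysis
(Cramér–Rao bounds from the residual Jacobian at the generating values)
puts the attainable relative precision of the store exchange constants
at hundreds of percent — `k10` worst of all — while the absorption and
excretion constants remain comparatively tight; misestimated store
constants then propagate into the later stages that hold them fixed. No
estimator can recover every staged parameter to within 15% from data of
this design at that noise level, and the recovery suite's noisy check
documents exactly that: it reports per-parameter medians over ten seeds
and fails the 15% bar on the store constants while the noiseless run
recovers everything to well under 1%. Denser early sampling, repeated
dosing, or longer horizons would be needed to pin the storage kinetics
from noisy urine data.

## The synthetic-data generator

`generate_excretion_dataset()` and `generate_invitro_dataset()` emulate
the two experimental designs whose original data exist only as published
figures: interval urine collections after single (0–100 hr, 5-hr
intervals) or repeated (14-day) oral doses, and medium/cell time courses
after introducing 0.1 uM arsenite into hepatocyte cultures. Noise is
i.i.d. multiplicative lognormal with mean exactly one and a configurable
coefficient of variation (default 5%), applied to the rates — the fitted
observable — not to cumulative amounts. `cv = 0` returns the noiseless
model output bit for bit, identical seeds give identical datasets, and
the generator restores the global RNG state. What the generator does
*not* emulate: inter-individual parameter variability (every dataset
comes from one parameter set), urine collection-volume errors, or
correlated assay drift; recovery results on synthetic data therefore
show that the pipeline is correct and well-conditioned, not that human
data of this design would constrain every parameter equally well.

## Numerical choices

* Integration: stiff-capable `lsoda` with `rtol = 1e-8`,
  `atol = 1e-10` by default (`1e-7`/`1e-9` inside the fitting loop,
  `1e-9`/`1e-11` for the polish), restarted at every input breakpoint.
  The right-hand side is compiled C for speed; an R implementation
  (`arsenic_derivatives()`) is exported and the tests verify the two
  agree, alongside a fixed-step Runge-Kutta oracle.
* Steady states: long integration (2000-hr chunks, horizon 1e4 hr) with
  a derivative-norm stopping rule, then damped Newton polish on the
  12 non-urine states with a finite-difference Jacobian, cross-checking
  the integration; residual tolerance 1e-10 uM/hr.
* Negative-concentration guard: values no lower than minus ten times
  `atol` are treated as solver noise and clipped to zero; anything
  larger aborts with an error, since it indicates a misconfigured
  integration rather than roundoff.
* Degenerate inputs: all-zero composition is an error rather than NaN;
  duplicate collection times and non-monotone cumulative urine are data
  errors; the in-vitro configuration rejects nonzero excretion or gut
  constants.
* Problem sizes: the conservation suite simulates 500–1000 hr horizons;
  scenario steady states converge in well under a second; the recovery
  suite uses the 0–100 hr, 20-interval design with one noiseless staged
  run and ten noisy seeds.

## Known limitations

* Pentavalent/trivalent speciation and the glutathione-dependent
  reduction steps are not modelled; each methylation is a single
  effective step.
* Inhibition of AS3MT by S-adenosylhomocysteine and the wider one-carbon
  network are outside the model; SAM enters only through the saturable
  factor, and the folate-to-SAM chain is represented by the stated SAM
  values themselves.
* One lumped non-liver store; no tissue-resolved distribution, no
  dermal or inhalation routes, no creatinine or dilution correction of
  urine.
* The calibration reproduces a staged fitting *protocol* on data of the
  published design; it does not claim to retrace the original manual
  tuning path.
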