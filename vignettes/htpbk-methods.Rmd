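---
title: "Methods: a generic whole-body PBK engine for parameterisation benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a generic whole-body PBK engine for parameterisation benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Purpose and scope

`htpbk` implements a high-throughput physiologically based kinetic (PBK)
modelling pipeline: a generic whole-body simulator that is parameterised
per compound from pluggable, source-tagged property records, together with
the evaluation machinery needed to benchmark *parameterisation strategies*
(which tool's lipophilicity, which partitioning method, which clearance
source, ...) against observed concentration-time profiles. The object of
study is never one compound's model; it is the strategy, scored over a
dataset by median profile errors.

The package deliberately does not call any external property-prediction
tool: tool outputs are inputs here. It is also not a re-implementation of
any specific commercial simulator; the engine is a standard flow-limited
whole-body model whose mechanisms (partitioning, IVIVE clearance scaling,
dissolution-limited oral absorption) follow the published method families.

## The model

### Physiology

The body is 12 perfused tissues (lung, liver, kidney, gut, spleen, muscle,
adipose, skin, brain, heart, bone, rest-of-body) plus arterial and venous
blood. The lung sits between venous and arterial blood and carries the
cardiac output; gut and spleen drain through the portal vein into the
liver. Reference values describe a healthy 73 kg adult male with cardiac
output 390 L/h and GFR 7.2 L/h, compiled in the style of reference-man
tables; the exact defaults of any particular simulator are not public, so
this table is versioned package data
(`inst/extdata/reference_human_physiology.json`) and every number can be
inspected or replaced. The liver volume used by clearance scaling is the
1.8 L reference value (1800 g at 1.05 g/ml). When study demographics
provide a body weight, volumes scale linearly with weight and flows and
GFR with weight^0.75 (standard allometry); sex, age and height are
recorded but do not switch tables, because no alternative reference table
is shipped.

### Distribution

Each perfused organ is flow-limited:

    dA_i/dt = Q_i * (C_art - C_i / (Kp_i / BP))

with `Kp_i` the tissue:plasma partition coefficient and `BP` the
blood:plasma ratio (default 1, configurable scalar). Five published method
families compute `Kp` from the shipped tissue-composition table
(`tissue_composition()`), itself an implementer-compiled approximation of
the tables printed in the method literature:

* **Poulin & Theil**: octanol-based lipid/water partitioning with plasma-
  and tissue-protein binding (`fu_t` derived from plasma binding scaled by
  the tissue:plasma albumin ratio); adipose uses the distribution
  coefficient at pH 7.4 and no tissue binding.
* **Berezhkovskiy**: the same composition terms, but the protein
  association constant derived from measured plasma binding is corrected by
  subtracting the plasma-lipid partitioning contribution (clamped at zero).
* **Rodgers & Rowland**: ionisation-aware. Moderate-to-strong bases
  (basic pKa >= 7) bind acidic phospholipids with an association constant
  back-calculated from blood-cell partitioning at intracellular pH 7.0
  (red-cell pH 7.22, haematocrit 0.45); acids and neutrals bind albumin,
  weak bases lipoproteins.
* **Schmitt**: membrane-affinity driven, with ionised species attenuated
  20-fold in membranes and cations given enhanced acidic-phospholipid
  affinity.
* **PK-Sim-standard (published form)**: membrane affinity drives lipid
  partitioning directly, with the empirical protein affinity
  `0.163 + 0.0221 * K`.

Whatever lipophilicity subtype the strategy resolves (LogP, LogD, LogMA) is
fed to each method *as-is*; regression conversions to LogMA happen only
when the strategy configures one. This mirrors the benchmarking design
being emulated, where each tool's value was piped into each method.

Two behaviours matter for interpretation. First, a hypothetical organ with
plasma's composition has `Kp = 1` under Poulin–Theil for neutral compounds
(exact); under Berezhkovskiy the corrected binding term breaks the symmetry
by the small plasma-lipid contribution (~5% at fu near 1), which is the
correction working as intended, not an error. Second, because plasma lipid
appears in the composition denominators, Poulin–Theil and Berezhkovskiy
saturate at very high lipophilicity while the membrane-affinity families
keep growing ten-fold per log unit. That robustness difference — composition
methods are less damaged by wildly overpredicted LogP values — is encoded as
a regression test comparing Kp growth between LogP 5 and 6.

### Elimination

Two modes. In **plasma mode** a whole-body plasma clearance acts on the
venous plasma concentration; it already represents all systemic processes,
so passive renal clearance is never added on top (a strategy flag asking
for it is ignored with a warning). In **intrinsic mode** hepatocyte
intrinsic clearance (ul/min/10^6 cells) is scaled to the whole liver as

    CL_liver = CLint * hepatocellularity * liver_density * liver_volume

(1.1e8 cells/g, 1.05 g/ml, volume in ml; converted to L/h) and elimination
acts on the unbound liver concentration `fu * C_liver / Kp_liver`
(well-stirred simplification, plasma fu). Passive renal clearance
`GFR * fu` is added when the strategy requests it. Plasma-clearance inputs
may be declared per kilogram and are then scaled by the subject weight.
Plasma-mode elimination is applied to venous plasma, which makes
`AUC = Dose / CL` exact and testable.

### Oral absorption

A deliberately simple gastrointestinal model: the dose enters the stomach
(dissolved for solutions and suspensions, undissolved for capsules and
tablets), empties first-order at 2.8 1/h, and reaches a single well-mixed
gut lumen (fasted fluid volume 0.25 L, effective absorption area 6600 cm^2,
mean transit residence 3.5 h). Solid formulations dissolve along a
piecewise-linear profile reaching 80% at the formulation's `t80`
(defaults: 25 min capsules, 40 min tablets) and 100% at `1.25 * t80`. The
dissolved lumen concentration is capped at the compound's solubility; at
the cap, dissolution can only replace what absorption and transit remove,
and dissolved inflow beyond that precipitates into the undissolved pool
(precipitate is not re-dissolved). Absorption transfers
`P_eff * area * C_lumen` into the liver inflow (first pass); unabsorbed
material leaves with intestinal transit. Permeability can be used directly,
rescaled by a tool-specific factor (`caco2_scaling_factor()`, the geometric
mean of target/predicted ratios), or predicted from MW and LogMA by the
surrogate `a * 10^(b*logMA) * MW^c` — the published internal equation's
coefficients are not available, so the defaults (`a = 2.8e6`, `b = 1`,
`c = -4.5` cm/min) were calibrated once to give mid-range human effective
permeabilities at MW 300 / LogMA 2 and are fully configurable.

Collapsing the intestine to one compartment is known to overestimate the
velocity of oral absorption (early Tmax); that bias is accepted and matches
the behaviour of the workflow being emulated.

### Integration

The environment provides no ODE solver package, so the engine ships a
purpose-written adaptive Dormand–Prince 5(4) integrator (C++, relative
tolerance 1e-8, absolute 1e-10 mg, configurable), restarted at right-hand
side discontinuities (infusion end, dissolution kinks). Cumulative
elimination and the venous-plasma AUC are carried as extra states, so mass
balance and exposure are integrals of the same accuracy as the solution.
Validation is by closed forms: mass balance at ~1e-14, dose linearity to
1e-9, `AUC = Dose/CL` to 0.5%, and the one-compartment half-life limit.
The half-life identity `t1/2 = ln2 * V / CL` holds only in the limit
`CL << organ flows` (the deviation is first-order in CL/Q); the test uses
CL = 2 L/h, where agreement is ~1%.

## Metrics and aggregation

Profiles are scored at exactly the observed timepoints (the error metrics
are defined over observed datapoints; observations are never interpolated).
The **Relative Log2 Error** is the mean of `log2(pred/obs)` over a
profile's datapoints (bias); the **Absolute Log2 Error** is the mean of
`|log2(pred/obs)|` (closeness). Observed values at or below the limit of
quantification (default 0) are excluded with a reported count; non-positive
predictions at usable points are floored at 1e-12 mg/L with a warning, a
handling choice the source text does not specify. Summary parameters
(Cmax, first-occurrence Tmax, AUC to the last observation by the linear-up
/ log-down trapezoid) are compared as log2 ratios, and fold-range tables
report the percentage of compounds within 1.5/2/3/5/10-fold. Multiple
studies of one compound are reduced to the compound's median; strategies
are summarised by the median over compounds ("Median Log2 Error"); even
counts use the mean of the two central values. Failed simulations are
excluded from medians but always counted and listed.

Strategy grids (`run_grid()`) evaluate the cartesian product of per-slot
options and rank by median absolute Log2 error, with exact ties broken
lexicographically by strategy label for determinism. The three-step
workflow (`stepwise_workflow()`) fixes clearance and fraction unbound to
benchmark sources while choosing the physico-chemical slots on IV data,
then chooses Fu/clearance on the same IV data, then solubility and
permeability on PO data — first on the liquid-formulation subset (no
dissolution parameter needed), then on all PO studies.

## The synthetic generator

`generate_dataset()` stands in for a curated clinical dataset. Its world is
fixed: compounds with MW uniform on [150, 900] Da, LogD normal(2, 1.5)
truncated to [-3, 7], Fu log-uniform [0.01, 1], plasma clearance
log-uniform [0.5, 50] L/h, solubility log-uniform [1, 1e4] mg/L,
permeability log-uniform over three decades, 0–2 pKa sites; 1–6 studies per
compound across IV (bolus and 0.25–2 h infusions) and PO (all four
formulation labels), 8–14 log-spaced samples over 24 h (IV) or 36 h (PO),
doses log-uniform 10–500 mg. Observation error is multiplicative
log-normal with CV 25% (concentrations are positive and errors scale with
level); inter-study variability is a log-normal body-weight perturbation
(SD 0.1) applied through the demographic scaling path. Emulated prediction
tools perturb the truth on the scale natural to each property
(multiplicative log10 for clearance/solubility/permeability, additive for
lipophilicity and pKa, logit for Fu).

Because observations are produced by the same engine under the truth
parameters, a green closed-loop test establishes *internal consistency*
(resolution, simulation and scoring invert each other) and *ranking
recovery* (a low-noise emulated tool beats a high-noise one). It does not
establish agreement with clinical data, engine fidelity to any particular
commercial simulator, or realism of the marginal distributions — those
require the real curated dataset, which must be supplied by the user
through the loaders.

## Numerical and design choices

* Integrator tolerances 1e-8/1e-10; step-size controller clamped to
  [0.2, 5] per step; explicit restart at RHS kinks.
* Tmax ties break to the earliest time.
* Consensus lipophilicity is the arithmetic mean of the named sources'
  values (after any configured conversion); duplicate records from one
  source are averaged at load with a warning.
* A pKa source returning no sites is a neutral compound, not a missing
  slot; `pka_source = "none"` forces neutrality for every compound.
* The shipped LogMA regression coefficients are implementer transcriptions
  with citation labels; the cited originals are not reproducible offline
  and the "self-derived" LogD equation is a synthetic refit. Treat them as
  configuration, not ground truth.
* Blood:plasma ratio defaults to 1 (the source text is silent) and enters
  only as the scalar `Kp/BP`.
* Suspensions are treated as fully dissolved at administration.
* Fu is clamped to [1e-6, 1] inside the partitioning methods to keep the
  association constants finite.

## Known limitations

No transporters, gut-wall or extrahepatic metabolism, enterohepatic
recirculation, saturable kinetics, metabolite tracking, or population
variability beyond demographic scaling. The intestine is a single
compartment; Tmax is biased early. The composition table and the reference
physiology are approximations compiled from the literature, versioned as
data so they can be audited and replaced wholesale.
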