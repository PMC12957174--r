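---
title: "PBPK modelling of ayahuasca alkaloid / SSRI interactions: methods and design choices"
author: "ayapbpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PBPK modelling of ayahuasca alkaloid / SSRI interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ayapbpk)
```

# The problem

Ayahuasca combines N,N-dimethyltryptamine (DMT), a serotonin-receptor
agonist that is orally inactive on its own, with β-carbolines — chiefly
harmine (HRM) — that reversibly inhibit monoamine oxidase A (MAO-A), the
enzyme that otherwise destroys DMT in the gut wall and liver before it
reaches the circulation.  Harmine itself is cleared by several cytochrome
P450s, including CYP2D6.  The SSRIs fluoxetine (FL, with its long-lived
active metabolite norfluoxetine, NFL) and paroxetine (PR) are strong
CYP2D6 inhibitors.  Coadministration therefore sets off a chain:
CYP2D6 inhibition → higher harmine exposure → deeper MAO-A inhibition →
higher DMT exposure, on top of any direct inhibition of DMT's own
secondary CYP2D6 pathway.  The package quantifies this chain with a
whole-body physiologically based pharmacokinetic (PBPK) model and
classifies the predicted interactions on the regulatory
(EMA/ICH-M12-style) AUC-ratio scale.

# Model structure

`pbpk_model()` assembles, per compound, a perfusion-limited whole-body
model: stomach → gut lumen → gut wall → portal vein → liver, plus lung,
adipose, bone, brain, heart, kidney, muscle, skin and spleen, connected
through arterial and venous blood.  All amounts are integrated in µmol;
reported plasma concentrations are venous plasma in ng/mL.

* **Absorption.** First-order gastric emptying (default time constant
  0.25 h, a parameter flagged by the sensitivity analysis) followed by
  first-order uptake from the lumen into the gut wall with rate `ka` and
  fraction absorbed `fabs` (the complement is counted "unabsorbed" so the
  mass balance closes).  By default `ka` is derived from lipophilicity
  through the saturable correlation `ka_from_logP()`, so logP influences
  absorption the way permeability does in platform PBPK tools; a numeric
  `ka` overrides this for compounds with known absorption kinetics.
* **Distribution.** Perfusion-limited tissue exchange
  `Q_t (C_art − C_t·BP/Kp_t)`.  Tissue:plasma coefficients come from the
  Rodgers–Rowland tissue-composition equations (strong bases: DMT,
  harmine, paroxetine — the acidic-phospholipid affinity is
  back-calculated from blood-cell binding) or from a Schmitt-type
  membrane-composition model (the very lipophilic fluoxetine and
  norfluoxetine).  Both are pure functions of the shipped composition
  table (`inst/extdata/tissue_composition.tsv`) and are covered by
  hand-computed oracle values in the tests.
* **Metabolism.** Michaelis–Menten routes
  (`v = kcat·E·Cu/(Km_app + Cu)`) or unbound intrinsic clearances, sited
  in liver or gut wall and driven by the unbound venous-equilibrium
  concentration `Cu = fu·C_t/Kp_t`.  Routes are tagged with the enzyme
  that carries them (CYP2D6, MAO-A, a lumped "CYP_other") so perpetrators
  couple to victims through shared site-specific enzyme pools.
  Stoichiometric metabolite formation (FL → NFL) transfers the stated
  molar fraction of the flux into the metabolite's liver pool.
* **Inhibition.** Three mechanisms, exposed as pure functions and used
  identically inside the ODE right-hand side: competitive Km scaling
  `1 + ΣCu_I/Ki` (fluoxetine/norfluoxetine, which thereby also inhibit
  their own clearance, so nonlinear accumulation emerges without extra
  machinery), reversible MAO-A inhibition by unbound harmine applied in
  gut wall and liver (`maoa_coupling()`), and mechanism-based CYP2D6
  inactivation by paroxetine with enzyme turnover
  `dE/dt = kdeg(1−E) − kinact·Cu/(KI+Cu)·E` (default kdeg 0.0136 h⁻¹,
  the ~51 h CYP2D6 half-life).
* **Excretion.** Linear renal clearance referenced to kidney
  venous-equilibrium plasma.

The right-hand side conserves `dosed + formed = in body + eliminated +
unabsorbed` identically, so the integrator (lsoda, rtol 1e-8, atol 1e-10
µmol, dose events applied as state discontinuities) preserves mass
balance to round-off; `check_mass_balance()` verifies ~1e-15 in practice
and the suite enforces < 1e-6.

# Parameterization and calibration

Physicochemistry (MW, logP, pKa) comes from public compound databases;
plasma binding, blood:plasma ratios and the inhibition constants from the
DDI literature.  Values the literature does not pin down were calibrated
middle-out against the observed mean exposure after 1 mL/kg oral
ayahuasca (DMT 0.67 mg/kg, HRM 1.77 mg/kg; observed AUC₀₋₁₂ 49.16 and
38.49 ng·h/mL, Cmax 14.1 and 10.9 ng/mL for DMT and HRM), with the fold
error (predicted/observed) required to stay inside the accepted 0.5–2.0
qualification window:

* **Harmine CYP2D6 turnover.** The literature kcat of 29.7 min⁻¹ does
  not reproduce clinical exposure (a point platform-based studies of this
  system also make); the shipped value (55 min⁻¹ at 0.5 µM hepatic
  CYP2D6, Km 0.9 µM) was obtained by parameter identification and sits
  comfortably inside the 50–60-fold spread of CYP2D6 activity.
  `fit_parameters()` reproduces this identification and the tests verify
  it recovers a known kcat from synthetic data.
* **Fraction metabolized.** Harmine fm,CYP2D6 ≈ 0.2 (several CYPs share
  its O-demethylation), DMT hepatic clearance dominated by MAO-A with a
  secondary CYP2D6 route; both kept editable via `config_set()`.
* **Effective SSRI potency.** In-vitro CYP2D6 Ki values underestimate
  in-vivo potency for fluoxetine/norfluoxetine; the shipped unbound Ki
  (0.01 / 0.008 µM) are in-vivo-effective values chosen so that the
  steady-state CYP2D6 suppression matches the "strong inhibitor" class.
  Paroxetine uses published-range mechanism-based constants
  (KI 0.34 µM unbound, kinact 19 h⁻¹).

The DDI ratios themselves were *not* calibration targets; they emerge
from the baseline models plus the dosing protocols (perpetrator 20 mg
once daily for 5 or 14 days, ayahuasca co-administered with the final
dose, ratios computed by NCA over the 12 h after the substrate dose —
the same horizon to which the observed AUCs were extrapolated).

# Synthetic clinical trials

`generate_trial()` emulates the volunteer study that anchors the model:
6 subjects (4 M/2 F), age 32 ± 11 y and weight 75 ± 11 kg (truncated
normal), sampled pre-dose and at 20, 40, 60, 90, 120, 180 and 240 min.
Individual weight scales the mg/kg dose and the physiology (volumes
linear in weight, flows with weight^0.75); lognormal interindividual
variability (median 1) multiplies enzyme abundances — default CV 35% for
the CYPs, 20% for MAO-A here, reflecting reported variability without
asserting a measured distribution; residual error is proportional
(CV 20%, typical LC-MS/MS performance); values below the 0.1 ng/mL
quantification limit (the assay calibration floor) are censored, and
pre-dose samples are drug-free by design.  What the generator does *not*
emulate: absorption-time variability from the plant matrix, within-day
enzyme rhythms, correlated demographics, or dropout — so passing
recovery tests demonstrate estimator correctness under the stated noise
model, not robustness to every feature of real data.

Parameter identification (`fit_parameters()`) is bounded
Levenberg–Marquardt least squares on log-transformed parameters against
the mean profile, with a log-scale objective by default because the
concentrations span orders of magnitude.  With the clinical design and
20% residual error, the recovered harmine kcat is unbiased to a few
percent when averaged over 20 replicate trials; a single 6-subject trial
identifies it only to roughly ±30%, which is the realistic information
content of eight time points on a partially CYP2D6-cleared compound.

# Sensitivity analysis

`local_sensitivity()` perturbs one parameter at a time to p·(1 ± 0.5)
(the ±50% variation-range convention) and reports the central normalized
coefficient S = (ΔM/M)/(Δp/p).  Central differencing was chosen because
the convention does not fix sidedness; note that for a strictly
log-linear response such as AUC = Dose/CL the *finite* ±50% central
coefficient is −4/3, approaching the analytic −1 only as the variation
shrinks — the tests assert the finite-difference value.  Two analyses are
shipped: exposure determinants of DMT AUC under paroxetine (MAO-A
intrinsic clearance dominates, the inactivation constants are
intermediate, the reversible Ki is negligible) and the absorption
analysis on the ayahuasca-only model, whose perturbed set comprises the
absorption/transit parameters (logP, gastric emptying time, gut-wall
MAO-A clearance, renal clearance).  Protein binding is examined in the
exposure analysis rather than here because fu rescales clearance,
first-pass extraction and distribution simultaneously.

# Numerical choices and degenerate inputs

* lsoda with rtol 1e-8/atol 1e-10; event times are forced onto the
  output grid.  The state at an event time is recorded *before* the dose
  is applied; doses at t = 0 are folded into the initial condition.
* Setting the gastric emptying time to zero routes oral doses directly
  into the gut lumen — used by the verification tests that compare
  against the Bateman one-compartment solution on a collapsed anatomy
  (huge flows, uniform Kp = 1), where closed forms exist.
* Trapezoidal NCA with optional terminal log-linear extrapolation from
  the last three positive points.  After an IV bolus the venous mixing
  transient decays on the blood-turnover timescale; AUC checks against
  Dose/CL therefore use geometrically spaced early output times.
* Interaction classes default to none < 1.25 ≤ weak < 2 ≤ moderate < 5 ≤
  strong on the AUC ratio; the threshold vector is an argument because
  published reports sometimes label ratios just below 1.25 as weak.
* Kp prediction rejects non-positive results; tissues missing from the
  composition table raise configuration errors naming the tissue, and
  dangling metabolite/enzyme references are caught before integration.

# Problem sizes

The shipped analyses use: 12 h baseline simulations on a 0.05 h grid;
DDI scenarios of 108 h (5-day) and 324 h (14-day) with an hourly grid
densified to 0.05 h over the post-substrate window; 20 replicate trials
of 6 subjects for the recovery experiment; populations of up to 10⁴
individuals in the distributional tests.  A full DDI scenario pair
integrates ~60–80 ODE states and completes in seconds on one core.

# Known limitations

* Perfusion-limited distribution only: no transporters, no
  permeability-limited brain sub-model — central DMT exposure is out of
  scope, as is any pharmacodynamic (serotonin-syndrome) link.
* Absorption is first-order; dissolution/solubility limitation of the
  plant matrix is represented only through the absorption-rate
  correlation and gastric emptying time.
* Harmaline and tetrahydroharmine are omitted as MAO-A inhibitors (their
  plasma exposure or potency is several-fold below harmine's).
* The lumped "CYP_other" pathway cannot resolve per-isoform DDIs beyond
  CYP2D6.
* Ratios are point predictions on a reference 75 kg individual; the
  population machinery samples variability but no population DDI
  distribution is claimed.
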