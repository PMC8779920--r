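---
title: "Model and methods: whole-body PBPK with gut transit for levetiracetam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: whole-body PBPK with gut transit for levetiracetam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`levipbpk` couples a nine-compartment gut transit/dissolution/absorption
model to a whole-body perfusion-limited PBPK disposition model for
levetiracetam (LEV), and layers three applications on top: validation
against published adult pharmacokinetic parameters, virtual crossover
bioequivalence of rapidly dissolving tablet formulations, and pediatric
regimen design against the 5–19 µg/mL therapeutic window. This vignette
is the package's account of the underlying science: the model equations,
the parameters that matter, the design choices that were genuinely open,
and the limits of what the tests demonstrate.

## The compound

Levetiracetam is a BCS class I antiepileptic: freely soluble, highly
permeable, essentially un-ionized at physiological pH (pKa 16.1), with
negligible plasma protein binding (fup 0.97) and predominantly renal
elimination (66% of dose excreted unchanged). These properties make it
close to a best case for mechanistic PK modelling — linear kinetics,
no transporter or enzyme saturation, dissolution never rate-limiting —
and they dictate several simplifications below (neutral-species
partitioning only, no precipitation, no food effect).

The packaged profile (`lev_compound()`) carries molecular weight 170.21
g/mol, logP 0.8 (logD 0.9 available via a switch), blood:plasma ratio
1.11, in vitro permeability 9.6 × 10⁻⁶ cm/s, adult plasma clearance
0.063 L/h/kg and the 0.66 renal fraction. The published aqueous
solubility is printed with impossible units ("1.04 g/mol"); the profile
reads it as 1.04 g/mL. At that solubility the luminal saturation term
in the dissolution equation never engages at therapeutic doses, which
is the intended behaviour.

Two clearance values circulate for adults: 0.96 mL/min/kg
(0.0576 L/h/kg) from the literature summary, and 0.063 L/h/kg derived
from the IV 1500 mg cohort (dose / AUC0–∞ / weight =
1500/370.70/64.19). The package defaults to the IV-derived value, which
is the one the disposition data actually identify; the literature value
ships alongside as an attribute.

## Physiologies

`build_adult_physiology()` scales a packaged 70-kg reference table:
tissue volumes linearly with body weight, regional flows and cardiac
output (350 L/h at 70 kg) with weight^0.75, blood volume as 0.07 L/kg
(plasma fraction 0.55). The reference anthropometry is a lean-Asian
oriented composite of standard human tables: muscle 26 L, adipose
13.5 L, and a skeleton-dominated rest-of-body compartment (12.53 L,
water fraction 0.31) that closes the mass balance to a ~66.5 L total
body volume. Sex shifts only the muscle/adipose split by ±10%; LEV
disposition is insensitive to it.

`build_child_physiology()` derives height from weight and BMI
(h = √(w/BMI)), applies the same allometry, and additionally uplifts
tissue water fractions by the ratio of the age-interpolated body-water
fraction (0.75 at birth → 0.60 by age 12) to the adult value. For the
6-year-old reference child (22.26 kg, BMI 16.07) the uplift is 1.125.
Ages outside 0.5–15 y warn rather than fail (extrapolation).

`sample_population()` draws age, weight and BMI uniformly within the
published virtual-trial ranges (25–50 y, 54.33–67.91 kg, BMI
21.3–23.88, 50% male) — uniform because only ranges are reported — with
a seed contract (identical seeds give bitwise-identical populations)
and no perturbation of the caller's RNG stream.

## Tissue partitioning

`kp_berezhkovskiy()` implements the tissue-composition partitioning
equation for a neutral compound,

$$Kp_t \;=\; \frac{P\,(f_{nl,t} + 0.3 f_{ph,t}) + (f_{w,t} + 0.7 f_{ph,t})}
          {P\,(f_{nl,p} + 0.3 f_{ph,p}) + (f_{w,p} + 0.7 f_{ph,p})}
 \cdot \frac{fu_p}{fu_t},
 \qquad fu_t = \frac{1}{1 + 0.5\,(1-fu_p)/fu_p},$$

with the unbound-fraction correction in the Berezhkovskiy form (for
fup = 0.97 the correction is a 1.5% effect). The lipid-phase partition
coefficient `P` is, by default, the vegetable-oil:water coefficient
(log D_vo:w = 1.115 logP − 1.35 ≈ −0.46 for LEV) applied to **all**
tissues. For a hydrophilic compound this single-lipid-phase treatment
is the appropriate one: using octanol:water for lean tissues (available
as `lipid = "pow"`) inflates the lean-tissue lipid term roughly
twenty-fold and pushes the whole-body Vss above the 0.5–0.7 L/kg
literature bracket. Whether the upstream implementation used logP or
logD is unstated; logP is the default and `use_logd` the switch (the
difference is under 2% of Vss).

With the packaged composition table this yields lean-tissue Kp of
0.77–0.87, adipose 0.47, rest-of-body 0.38, and

$$V_{ss} = \frac{V_{plasma} + \sum_t Kp_t V_t}{BW}$$

of **0.606 L/kg** for the reference adult and **0.667 L/kg** for the
6-year-old (the pediatric body-water uplift raises Kp of every
water-rich tissue). Both sit inside the 0.5–0.7 L/kg bracket and
within 15% of the published model values (0.54 and 0.61 L/kg). The
residual gap is attributable to the proprietary composition tables of
the original software, which are not printed and cannot be reproduced
exactly.

## Gut transit and absorption

The gut is nine serial compartments (stomach; duodenum; jejunum 1–2;
ileum 1–3; caecum; colon) with fasted-state defaults: gastric transit
0.25 h, small-intestinal transit 3.3 h split in the conventional
proportions (0.26/0.95/0.76/0.59/0.43/0.31 h), caecum 4.5 h, colon
13 h; pH 1.3 in the stomach rising to 7.4 distally (pH is carried for
completeness; un-ionized LEV ignores it). Radii taper 1.6 → 0.85 cm
along the small intestine and scale with (BW/70)^{1/3}.

Each compartment holds an undissolved and a dissolved pool. Transit is
first-order (`kt = 1/T_n`); dissolution applies the Weibull release
hazard `h(t) = (b/t_d)(t/t_d)^{b-1}` (time since dose) to the
undissolved pool, damped by a luminal saturation factor
`1 − C_lumen/C_s` that is inert for LEV; absorption removes drug from
the dissolved pool at

$$k_{a,n} = \frac{2\,P_{eff}^{\text{vivo}}}{R_n} \cdot ASF_n,$$

the standard radial-flux law, into the portal stream. The stomach does
not absorb.

Two calibration constants convert the in vitro permeability to in vivo
behaviour, both fixed **once** in the packaged profile and never refit:

* a global scale (88.0) mapping 9.6 × 10⁻⁶ cm/s to an effective human
  permeability of 8.4 × 10⁻⁴ cm/s — squarely in the range of measured
  human jejunal Peff for highly permeable drugs; and
* segment absorption scale factors declining distally (duodenum 1.0,
  jejunum 0.67/0.36, ileum 0.087/0.050/0.029, caecum 0.012, colon
  0.006).

They were calibrated against the published adult 1500 mg reference
absorption pattern — 49.7% of dose absorbed in the duodenum, 36.2% and
7.8% in the jejunal segments, total Fa 96.7% — because a single global
factor cannot reproduce both the front-loaded segment distribution and
a total Fa below 100%. The packaged values give Fa 96.9% with segment
fractions 50.3/36.1/7.6. Mass balance (lumen + absorbed + exited =
dose) holds to floating-point precision at every output time, and the
linearity of the system makes the segment fractions independent of the
dissolution time-course, which is why an instant-release and a 1-minute
Weibull input give identical Fa.

## Whole-body disposition

Eleven perfusion-limited tissues (lung in series with the heart–lung
loop; liver receiving hepatic artery plus the portal drainage of gut
and spleen plus absorbed drug) plus arterial and venous blood:

$$V_t \frac{dC_t}{dt} = Q_t \left(C_{art} - \frac{C_t\,R_{bp}}{Kp_t}\right)$$

with amounts in mg, flows in L/h, and reported plasma concentration =
venous blood concentration / Rbp (1 mg/L ≡ 1 µg/mL). Renal elimination
applies the renal clearance to renal arterial plasma inflow
(filtration semantics); the 34% non-renal remainder acts on hepatic
inlet plasma. Both choices make the identity AUC0–∞ = Dose/CL exact in
the continuous model regardless of Kp values (verified to 0.5%
including integrator and NCA error), and imply a first-pass extraction
of ~2% — consistent with LEV's near-complete oral bioavailability.

Integration uses a stiff-capable variable-step solver (`deSolve::lsoda`,
rtol 1e-8, atol 1e-10 mg) with restarts at every dose event. IV doses
enter venous blood as boluses or constant-rate infusions; oral doses
enter the stomach. The IV validation regimen is modelled as a 0.75-h
infusion: the observed IV Tmax of 0.711 h identifies the infusion
duration, since concentrations under an infusion peak at its end.

Pediatric clearance is the one genuinely open disposition choice. The
printed pediatric per-kg clearance (0.88 mL/min/kg = 0.053 L/h/kg) is
irreconcilable with the published pediatric simulations themselves: at
0.053 L/h/kg a 222.6 mg q12h regimen in a 22.26-kg child would average
~15 µg/mL with troughs near 9, where the source reports a trough of
4.13 µg/mL. The package therefore defaults to allometric scaling
(exponent 0.75) of the adult IV-derived absolute clearance from its
64.19-kg reference subject — the standard choice for a renally cleared
drug beyond infancy — giving 0.085–0.087 L/h/kg at 17–22 kg, which
reproduces the published pediatric concentration ranges and matches
field estimates of pediatric LEV clearance. The printed value remains
available through the `cl_per_kg` override.

## Non-compartmental analysis

`run_nca()` follows the conventional industrial settings, which the
source does not specify: linear-up/log-down trapezoids for AUC and
AUMC; λz by log-linear regression over terminal windows of ≥3 points
excluding Tmax, selected by maximal adjusted R² with ties resolved
toward fewer points; AUC0–∞ = AUC0–t + C_last/λz; MRT_last =
AUMC0–t/AUC0–t. A baseline zero immediately preceding the first
positive sample is retained so the absorption-phase triangle is
counted; other non-positive values are dropped. Profiles with no
terminal decline return λz-dependent fields as `NA` rather than
failing. The prediction error statistic is absolute,
PE% = 100·|predicted − observed|/observed, and the model-acceptance
gate requires every Cmax and AUC PE ≤ 20%; Tmax is reported but not
gated (sampling-grid artifacts dominate it, and the source's own Tmax
errors run to 114%).

## Bioequivalence

`tost_be()` log-transforms each parameter and builds the 90% CI of the
test/reference geometric mean ratio: pooled-variance two-sample
interval for parallel designs; the period-difference method (half
within-subject period differences compared across sequences) for the
2×2 crossover, which removes period effects without fitting a mixed
model — the estimator choice was open, and the period-difference method
is the textbook closed form. Zero-variance (identical-arm) data yield
a degenerate CI at the exact ratio with a warning rather than an
error. The standard limits are 80–125%; the virtual-trial acceptance
band is 85–120%.

`virtual_be_trial()` simulates every subject under test and reference
dissolution with the same physiology (the crossover design), runs NCA,
and applies the crossover TOST. Between-subject variability comes
solely from the sampled physiologies; no residual error is added by
default (an optional lognormal CV exists for power studies). The
virtual-trial dose is 1000 mg — the published mean Cmax of ~25 µg/mL
identifies that strength, though it is never stated — and both arms
default to the packaged fast profile of the 1000 mg tablets (the
strength feeding the virtual trial was likewise unstated).

## Pediatric regimen design

`simulate_regimen()` runs a loading + maintenance q12h course (7 days
by default; steady state is reached within ~2 days given the ~5.6 h
pediatric half-life) and reports the final-interval trough/peak, the
fraction of the interval inside the 5–19 µg/mL window, and whole-course
extrema (the published concentration spans mix loading-transient and
steady-state intervals, so course extrema are the comparable summary).

`missed_dose_remediation()` operationalizes the published remediation
logic. Against the no-miss reference course, a candidate remedial dose
is acceptable when the profile (i) re-enters the reference steady-state
envelope [trough_ss, peak_ss] within one dosing interval, (ii) returns
to the concentrations of normal dosing — its remediation-interval peak
reaches the reference peak over the same interval — and (iii) never
exceeds the reference peak by more than 10% (the tolerance fixed at
design time). Among acceptable candidates the chosen dose minimizes
the integrated absolute deviation from the reference. For the
6-year-old scenario (miss at 60 h, remediation at 72 h) this rejects
275 mg as too low (peak ratio 0.98), rejects 350 mg as excessive
(+23%), and selects 300 mg (+6.4%), matching the published ranking.
Without criterion (ii), the minimal-deviation rule alone would prefer
275 mg in this model — the deviation integral does not encode the
clinical requirement of restoring therapeutic peaks, which is exactly
the argument the source makes against 275 mg.

`find_regimen()` is a deterministic grid search returning the smallest
(maintenance-first) loading/maintenance pair whose whole-course troughs
stay at or above the window floor and peaks at or below the ceiling;
infeasible grids return an explicit no-solution result carrying the
best candidate by time-in-window.

## Synthetic data

The generators exist so every stage can be exercised without any
external data.

* `gen_dissolution()` emulates the instant-dissolving tablets' pH 1.2
  profiles: Weibull td 0.9 min, ≥85% at 2.5 min, complete at 5 min,
  ≤2% multiplicative assay noise; points whose true release exceeds
  99.5% are reported as complete, as assays do. A `slowed` variant
  scales td (default ×50) to emulate a degraded product.
* `gen_dog_dataset()` draws per-animal one-compartment parameters
  lognormally (default CV 10%, n = 3 per group) around truths
  back-calculated from the published beagle group table: ke from the
  half-life, CL/F from dose/AUC0–∞, and ka solved so the closed-form
  Cmax matches the group Cmax (the printed Tmax values are used as a
  fallback only — several printed Tmax/Cmax/AUC combinations,
  notably the originator product's 0.28 h Tmax, are not jointly
  attainable by any one-compartment model, and Cmax/AUC are the
  quantities the bioequivalence statistics consume).
* `gen_clinical_profile()` produces the published adult profiles:
  mono-exponential for IV (C0 = observed Cmax, ke = Cmax/AUC0–∞) and
  Bateman curves for oral regimens with ke and V/F solved so the
  analytic Cmax and AUC0–∞ equal the observed values (ka fixed at
  3/h). NCA of the generated profiles recovers the observed
  parameters to within sampling-grid discretization.

All generators are seed-deterministic and restore the caller's RNG
state.

What the synthetic data do **not** emulate: assay error and BLQ
censoring, within-subject variability between periods, food effects,
circadian variation, and adherence patterns beyond a single missed
dose. Tests passing on these fixtures demonstrate internal consistency
of the computational pipeline and faithfulness to the published summary
statistics — not predictive performance on new clinical data.

## Numerical choices and degenerate inputs

Solver tolerances rtol 1e-8 / atol 1e-10 mg; dose events always split
the integration span; negative-state excursions beyond −1e-6 mg abort
with an error, smaller ones are clipped to zero. The Weibull release
hazard is capped at 1200/h (a 2-second half-time, never binding for
real profiles) to keep the system non-stiff, and dissolution fits fall
back from the full 3-parameter Weibull to fixed-fmax and fixed-shape
forms when saturated profiles leave too few informative points. λz
tie-breaks prefer fewer terminal points; windows never include Tmax.
Zero-variance BE datasets warn and report the degenerate CI. Grid
searches and candidate rankings are fully deterministic.

Default problem sizes: 0.05 h output resolution for single-profile
work, 0.1 h for population trials; 24 virtual subjects for the
bioequivalence trial (the published virtual-trial size is not stated;
24 is the conventional crossover enrolment and matches the IV cohort
size); 7-day pediatric courses.

## Known limitations

* The adult/pediatric Vss run ~12/9% above the published model values —
  the proprietary tissue-composition tables cannot be reproduced, only
  bracketed; both values remain inside the literature 0.5–0.7 L/kg.
* Simulated pediatric peaks run 15–30% above the published spans
  (faster absorption in this parameterization); troughs agree to a few
  percent. Comparisons against published spans are made within ±30%
  bands.
* The published 2.134 µg/mL concentration 12 h after a missed pediatric
  dose implies a ~12 h terminal half-life, inconsistent with the
  published clearance and volume (t½ ≈ 5–6 h) and with levetiracetam
  pharmacology; this model yields ~1.2 µg/mL and cannot reproduce that
  single value. The missed-dose *ranking* is insensitive to this.
* No ontogeny of metabolic enzymes (LEV is renally cleared), no
  pregnancy/geriatric physiologies, no nonlinear kinetics, no
  permeability-limited tissues, no bile-salt solubilization or fed
  state, no replicate/reference-scaled BE designs, and no
  pharmacodynamic (seizure) modelling.
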