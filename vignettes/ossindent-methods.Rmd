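---
title: "Methods: nanoindentation reduction, histomorphometry indices, and case-control statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoindentation reduction, histomorphometry indices, and case-control statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ossindent)
```

`ossindent` implements the analysis chain of a nested case-control biopsy
study of atypical femur fracture (AFF): reduction of Berkovich
nanoindentation force–depth curves to tissue nanomechanical properties,
derivation of ASBMR bone-histomorphometry indices on three envelopes, and
the case-control statistics that relate the two to AFF status. Because raw
patient data for such studies are not released, the package also contains a
first-class synthetic-data generator; this vignette explains the models,
the parameters that matter, the numerical choices, and precisely what the
synthetic validation does and does not establish.

## 1. The indentation forward model

The simulator (`simulate_curve()`) produces the four protocol phases of a
displacement-controlled indent: ramp at 0.25 mN/s to 500 nm, 60 s hold at
maximum load, unload at the same rate to 10 % of maximum load, and a 100 s
low-load hold for thermal drift. These constants (exposed in
`indentation_protocol()`) are the study's measurement protocol.

*Loading* follows the elastic–plastic series model for a conical indenter:
the depth at load $P$ is the sum of an elastic and a plastic contribution,

$$h(P) = \sqrt{P/C_e} + \sqrt{P/C_p}, \qquad
  C_e = \tfrac{2}{\pi} E_r \tan\psi, \qquad C_p = C_0\,H,$$

with $\psi = 70.3^\circ$ the effective cone half-angle and $C_0 = 24.5$
the ideal area-function constant ($C_0 = \pi\tan^2\psi$). Equivalently
$P = K h^2$ with $K^{-1/2} = C_e^{-1/2} + C_p^{-1/2}$. $H$ — the
resistance to plastic deformation — is therefore defined as the hardness a
purely plastic contact with the same area function would exhibit; it is
finite for real bone and $H \to \infty$ recovers a purely elastic Sneddon
cone.

*Hold*: depth grows logarithmically, $\Delta h = c\,\ln(1 + t/\tau)$ with
$\tau$ fixed at 10 s and the amplitude $c$ a material parameter
(`creep_amp_nm`). A single-amplitude logarithmic law is the standard shape
for short-hold bone creep; the protocol's 60 s hold exists precisely to
let this transient run out before unloading.

*Unloading* is a power law $P = B(h - h_f)^m$ with $m = 2$ (the exponent
of conical elastic recovery) whose tangent at maximum load equals the
elastic stiffness implied by the sample modulus and the contact area at
maximum load. These two requirements determine $(B, h_f)$ through the
self-consistent condition

$$S = 2 E_r \tan\psi \; h_c, \qquad h_c = h_{max} - \varepsilon_{cone} P_{max}/S,$$

i.e. the larger root of $S^2 - \pi C_e h_{max} S + \pi C_e
\varepsilon_{cone} P_{max} = 0$. In the purely elastic limit this reduces
exactly to the Sneddon cone stiffness $S = 2\sqrt{C_e P_{max}}$, so the
forward model degenerates correctly. (The naive series-model tangent
$2\sqrt{C_e P_{max}}$ applied to an elastic–plastic indent is *not*
consistent with the Oliver–Pharr contact area and is not used.)

All phases carry additive linear depth drift (`drift_rate_nm_s`) and
Gaussian depth noise (`noise_sd_nm`); load is treated as noise-free, as it
is the controlled quantity. Sampling rates default to 100 Hz on the ramps
and 10 Hz on the holds, typical acquisition rates for depth-sensing
indentation; they are configurable in `indentation_protocol()`.

## 2. The reduction

`extract_properties()` chains five steps, each available separately:

1. **Segmentation** (`segment_curve()`): phases are identified from the
   sign of the load rate, with a threshold of 20 % of the protocol loading
   rate (adapted downward for curves ramped more slowly) and runs shorter
   than 3 samples absorbed into their neighbours so isolated noise flips
   cannot split a phase. A curve that never unloads is an error; an empty
   hold or drift hold is allowed. Maximum load is the hold-plateau load;
   maximum depth is the depth at unloading onset, because creep keeps
   deepening the contact during the hold.
2. **Drift correction** (`correct_drift()`): depth is regressed on time
   over the drift hold, excluding its first 20 s (viscoelastic recovery),
   and `rate × t` is subtracted from all depths. If the hold is missing or
   shorter than the exclusion window the curve is returned uncorrected
   with a warning — never silently.
3. **Unloading fit** (`fit_unloading()`): nonlinear least squares of the
   power law over the top 80 % of the unloading load range. The fit is
   performed in the *depth* coordinate, $h = h_f + a P^{1/m}$
   ($a = B^{-1/m}$), because the noise model (and the instrument) put the
   measurement noise on depth; fitting $P(h)$ over the narrow
   elastic-recovery span is badly conditioned. Multistart over
   $m \in \{1.2, 1.5, 2.0\}$ with $m$ constrained to $[1, 2.5]$,
   tie-break by residual sum of squares; an exponent at a bound yields a
   warning. $h_{max}$ is evaluated from the fitted law at $P_{max}$ rather
   than from a single noisy sample.
4. **Oliver–Pharr** (`oliver_pharr()`) and **loading decomposition**
   (`decompose_loading()`): the formulas of the README, with the loading
   coefficient $K$ estimated by least squares of depth on $\sqrt{P}$
   through the origin. $h_c \le 0$ and a loading stiffer than the purely
   elastic bound ($K \ge C_e$ beyond a 2 % numerical slack) are errors; a
   decomposition implying $H$ above 100 GPa is reported as "no measurable
   plasticity" with `NA`, distinguishing an elastic contact from a failed
   fit.
5. **Energies** (`indentation_energies()`): trapezoidal integration, with
   the creep hold included in the total work (the indenter moves at
   $P_{max}$, so work is done; excluding it would let $U_e$ exceed the
   total for nearly elastic contacts). The unloading integral is prepended
   with the unloading-onset sample so that $U_e + U_p = U_{total}$ holds
   exactly by construction. Energies are reported in picojoules
   (1 mN·nm = 1 pJ); a ~2 mN, 500 nm indent stores a few hundred pJ, and
   the package does not rescale this to any other printed unit.

**The geometry factor ε.** The package default is $\varepsilon = 0.75$,
the standard Berkovich/paraboloid convention for instrument data. The
forward model, however, is an ideal cone, for which the correct factor is
$\varepsilon_{cone} = 2(\pi - 2)/\pi \approx 0.727$ (`cone_epsilon()`).
Round-trip validations therefore reduce simulated curves with
$\varepsilon_{cone}$; using 0.75 on a pure cone would build in a ~1.9 %
systematic error in $E_r$ that is geometry mismatch, not estimator error.
Real Berkovich data should keep 0.75 (and may supply `beta = 1.034` and
calibrated area coefficients).

**Aggregation** (`aggregate_sites()`): cortical sites are averaged
directly; cancellous sites hierarchically (sites → trabecula means →
specimen), so an unbalanced trabecula still contributes exactly one mean.
Failed sites are excluded and counted, and a specimen with no valid sites
is reported missing rather than imputed.

## 3. Histomorphometry indices

`structural_indices()`, `static_indices()`, and `dynamic_indices()`
implement the index definitions with these conventions:

* Mineralizing surface uses the ASBMR double-plus-half-single convention,
  $MS/BS = (dLS + sLS/2)/BS$.
* $BFR/BS = MAR \cdot (MS/BS) \cdot 365$ in µm³/µm²/**year** — the
  annualization factor is demanded by the unit even though the compact
  formula "MAR × MS/BS" omits it.
* Imputation: surfaces with only single labels receive the conventional
  MAR floor of 0.3 µm/day; surfaces with no label have MAR treated as
  *missing* while MS/BS, BFR/BS, and Ac.f are set to zero. Missingness is
  preserved through all serializations as empty fields, never as zeros, so
  a suppressed-turnover envelope is distinguishable from an unmeasured
  one.
* $Ac.f = (BFR/BS) / W.Th$, so the identity $Ac.f \cdot W.Th = BFR/BS$
  holds exactly for every labeled envelope — this is tested, not assumed.
* Tb.Th uses the plate model without obliquity correction,
  $Tb.Th = 2000\,A_{bone}/P_{bone}$ (µm from mm² and mm), and Tb.N is
  derived as $(BV/TV)/Tb.Th$ in 1/mm. Reports sometimes print Tb.N per
  mm²; the package reports the standard per-mm quantity.

## 4. The synthetic cohort

`cohort_spec()` fixes the study conditions: 16 subjects per arm, treatment
durations 7.5 ± 4.7 years (non-AFF) and 11.5 ± 4.9 years (AFF) truncated
at the 2-year entry criterion, 60 cortical sites and 5 × 12 cancellous
sites per specimen, and per-group mean ± SD targets for the
histomorphometry indices on all three envelopes (`histo_targets()`).
Nanomechanical targets (`mech_targets()`) use representative AFF/non-AFF
cortical values for E, H, and Hc; since site-to-site scatter is not
published, the SDs (3.0 GPa for E, 0.35 GPa for H, 0.2 GPa for Hc) were
chosen once as realistic bone-nanoindentation scatter.

Site values follow a subject random-intercept model whose variance split
achieves the requested intraclass correlation; the default `icc = 0.5` is
a guess (within-subject variance of these properties is not published) and
deliberately configurable.

**The AFF mechanism.** AFF status is linked to *subject-mean cortical
elastic modulus* through a logistic model with slope
$\log(\text{or\_per\_gpa})$, which keeps the generating odds ratio
interpretable per GPa. Consequently the association is encoded *only* by
`or_per_gpa`: subject-mean cortical E is always drawn from the pooled
centre of the two target entries, and `or_per_gpa = 1` is an exact null
(label independent of mechanics, balanced arms). Encoding the association
both through group-specific E means and through an OR would double-count
it and destroy the null.

Envelope primitives are generated at the measurement-table level (surface
lengths, thickness readings, label lengths, interlabel distances) by
drawing index targets per subject and inverting the index formulas, with
consistency constraints enforced (no surface length exceeds BS; labels fit
on the surface). A configurable fraction of subject-envelopes is made
single-label-only (15 %) or unlabeled (15 %) — plausible for a
suppressed-turnover cohort — to exercise the imputation rules.

**What the generator does *not* emulate**: spatial correlation of sites
within a trabecula, non-Gaussian site distributions, curve artefacts
(surface-find errors, pop-ins, tip blunting), inter-envelope correlation
of remodeling indices, and any image-level structure. Passing the
package's tests therefore establishes that the estimators are correct
*under the stated model*, not that the model captures every feature of
real biopsies.

## 5. Statistics

* `group_summary()` produces mean ± SD (n − 1 denominator) per group.
* `ttest_from_summary()` implements Student's pooled t test (Welch
  optional) directly from summary statistics, so published tables and raw
  vectors take the same code path; `two_group_ttest()` is the data-frame
  wrapper. The unpaired pooled test is the study's stated comparison.
* `gee_logit()` fits the marginal logistic model by GEE. The exchangeable
  working correlation is the primary choice, but when the outcome is
  constant within every cluster — exactly the case-control design, where
  case status is a subject attribute observed at many sites — the moment
  estimator drives the working correlation towards singularity and
  attenuates slopes; the fit then falls back to the independence working
  structure (with a message), which is the standard marginal model for
  cluster-constant outcomes. The default variance is the Mancl–DeRouen
  bias-corrected cluster-robust sandwich with a $t_{G-p}$ reference:
  with a few dozen clusters the plain sandwich is anti-conservative
  (simulated type-I error roughly 8–9 % at 32 subjects versus ~5 % with
  the correction). The plain sandwich (`cov_type = "robust"`) is retained
  for cross-checking against reference implementations.
* `fit_aff_or()` wraps the model AFF ~ duration + property. With
  `level = "subject"` the property is first collapsed to subject means,
  which removes the errors-in-variables attenuation that site-to-site
  scatter induces (at `icc = 0.5`, a site-level predictor attenuates the
  subject-level log-OR by roughly the ICC). For small cohorts the
  `estimator = "firth"` option fits bias-reduced (Jeffreys-penalized)
  logistic regression: at 32 subjects and 3 parameters the ordinary MLE
  overestimates the log-OR by on the order of 15–20 %, while the Firth
  estimate is unbiased to within simulation error and remains finite under
  complete separation. Apparent separation in the GEE path is flagged and
  the interval reported as (0, ∞) rather than a fabricated finite one.
  Whether the original analyses used site-level or subject-mean
  predictors is not documented; both are provided and neither is claimed
  to reproduce the published odds ratios.

## 6. Validation design and known limitations

The test suite validates each stage against independent oracles: the
closed-form Sneddon cone (reduction), exact triangle areas (energies),
hand arithmetic (histomorphometry), `t.test` and a permutation test
(t tests), a contingency-table cross-product (odds ratios), frozen
reference GEE values from an independent implementation, and Monte Carlo
recovery of generator truth for (E, H), drift, stiffness, ICC, and the OR.

Problem sizes were chosen to keep the full suite to a few minutes on one
CPU: 5 × 5 × 20 noisy curves for parameter recovery, 100 curves for
stiffness error, 2000 replicates for OR recovery and coverage (the
per-replicate log-OR SD is ≈0.2 at 32 subjects, so smaller designs leave
the mean-bias check dominated by simulation noise), 200 replicates for
null calibration.

Known limitations:

* The contact-stiffness estimate from a free-exponent power-law fit over
  the top 80 % of unloading has a median relative error of ≈4–5 % at 1 %
  depth noise — the parameters $(h_f, m)$ are weakly identified over the
  narrow elastic-recovery span of a stiff-tissue indent. Property
  recovery for E and H is materially better because errors partially
  cancel through the reduction.
* No tip-area calibration, continuous-stiffness measurement, or creep
  correction to S beyond the protocol hold is implemented; the area
  function accepts calibrated polynomial terms but defaults to ideal.
* The odds-ratio stage assumes the logistic mechanism of the generator;
  real AFF aetiology is certainly richer, and the printed odds ratios of
  any particular study derive from unreleased data that desk-scale
  simulation cannot reproduce.
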