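---
title: "A semi-mechanistic model linking CSF neurofilament light chain to the rate of brain atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semi-mechanistic model linking CSF neurofilament light chain to the rate of brain atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nflatrophy)
```

## The model

Neurofilament light chain (NfL) is a structural protein found only in
neurons. Adult CNS neurons neither proliferate nor regenerate, so NfL in
the cerebrospinal fluid (CSF) must come from axonal damage or neuronal
death. `nflatrophy` implements a mass-balance model that turns this
observation into a quantitative link between the CSF NfL concentration and
the rate of whole-brain atrophy.

Three ingredients:

1. **Volume trajectory.** Whole-brain volume follows a quadratic function
   of age, $V(t) = k_0 + k_1 t - k_2 t^2$, so the neurodegeneration rate
   $-dV/dt = -k_1 + 2 k_2 t$ rises linearly with age: atrophy
   accelerates. In Huntington's disease (HD) carriers the acceleration
   coefficient scales with CAG repeat length through a power law,
   $k_{2,i} = k_{2,pop}\,(CAG_i/42.5)^{\beta}$.
2. **NfL release.** The mass of NfL entering CSF per unit time equals the
   brain NfL concentration times the rate of volume loss:
   $c_{Brain} \cdot (-dV/dt)$, clamped at zero when the trajectory is
   still rising (neurons do not reabsorb NfL).
3. **CSF clearance.** NfL leaves the single CSF compartment by bulk CSF
   flow, $dc/dt = [c_{Brain}(-dV/dt) - CL \cdot c]/V_{CSF}$. CSF turns
   over in hours while neurodegeneration plays out over years, so the
   compartment sits at quasi-steady state (QSS):
   $c_{CSF}(t) = c_{Brain}\,(-dV/dt)\,/\,CL$.

The per-group clearances are fixed constants taken from MRI net
aqueduct-flow measurements — 303 µL/min in healthy controls (HC), 136 in
premanifest HD, 108 in manifest HD — and are never estimated; any
systematic error in them is absorbed by the estimate of $c_{Brain}$.
Clearance is held constant in age within a group.

```{r worked}
p <- structural_params()        # published population values
neurodegeneration_rate(50, p)   # 4.18 mL/yr in a 50-year-old control
cnfl_csf_qss(50, p, clearance_table(), "HC")   # ~419 pg/mL
```

Because the QSS concentration is proportional to $-dV/dt$, CSF NfL reads
out the *rate*, not the extent, of neurodegeneration; its linear rise with
age mirrors the acceleration $2k_2$, and the area under the NfL-time curve
is proportional to the volume lost.

### Parameters and units

| parameter | meaning | unit | default |
|---|---|---|---|
| `k0` | volume intercept at age 0 | mL | 1500 |
| `k1` | linear volume coefficient (shared across groups) | mL/yr | 4.84 |
| `k2` | acceleration, healthy controls | mL/yr² | 0.0902 |
| `k2_hd_pop` | acceleration, HD population at CAG 42.5 | mL/yr² | 0.125 |
| `beta_cag` | CAG power-law exponent | — | 2.74 |
| `cnfl_brain` | NfL concentration in brain tissue | µg/g | 15.5 |
| `density_brain` | tissue density for µg/g ↔ pg/mL | g/mL | 1.03 |
| `V_CSF` | CSF compartment volume (ODE only) | mL | 150 |

Internal canonical units are mL, years and pg/mL; conversions
(`convert_brain_conc()`, `convert_clearance()`, 365.25 days/yr) happen at
the boundary. `V_CSF` is a literature value — the QSS solution, which all
estimation uses, does not depend on it; only the full ODE
(`cnfl_csf_ode()`) does, and that exists mainly to verify the QSS
approximation (they agree within 1% over ages 30–77 for every group and
CAG 39–51).

## The synthetic cohort generator

`sample_subjects()` and `simulate_observations()` emulate the design of a
two-visit observational study: 20 HC (mean baseline age 50.7 yr), 20
premanifest HD (42.4 yr, mean CAG 42.0), 40 manifest HD (56.0 yr, mean CAG
42.75); visits at day 0 and 730; 10% of follow-ups missing. Ages are
truncated normal (SD 8 yr, range 26–77); CAG repeats are a shifted
binomial on 39–51 matched to the group means (the real CAG spectrum is not
published). A `replicate` knob scales every group size for recovery
studies.

Between-subject variability is an additive normal effect on $k_0$
(ω = 40 mL; residual head-size variation that survives intracranial-volume
adjustment) and a log-normal effect on $k_2$ (ω = 0.3, keeping
acceleration positive). Observation noise is additive on volume
(SD 11 mL) and proportional on NfL (coefficient 0.216), with concentrations
floored at 1 pg/mL so they stay physical.

What the generator does *not* emulate: assay batch effects, visit-time
irregularity, informative dropout, measurement-error correlation within a
visit, or any misspecification of the structural model itself. Passing
recovery tests therefore show that the estimator is consistent and
well-calibrated *under the model*, not that the model is right for any
particular real dataset.

## Estimation

`fit_nfl_model()` maximises the joint marginal likelihood of both
observation streams: volumes with additive-normal error, NfL with
proportional-normal error, sharing the per-subject parameters. Choices
that matter:

* **Intercept effect integrated analytically.** The additive $k_0$ effect
  enters only the volume stream, linearly, so it is marginalised in closed
  form (compound-symmetry covariance), leaving a single random effect to
  integrate numerically.
* **Acceleration effect by robust quadrature.** The log-normal $k_2$
  effect is integrated per subject on the union of nodes centred at the
  Newton mode of the joint density (found with analytic first and second
  derivatives) and a fixed grid spanning the prior, combined by a
  log-scale trapezoid rule. The union matters: the positive-part clamp on
  the rate can split a subject's conditional density into two bumps, and a
  quadrature tied to a single mode changes discontinuously when the mode
  flips, which defeats quasi-Newton optimizers. `n_nodes = 1` gives the
  plain Laplace approximation.
* **Floored observations are left-censored.** An NfL value at the 1 pg/mL
  reporting floor contributes $\Phi((1-g)/(\sigma_p g))$, the exact
  probability of a floored measurement, rather than a density at an
  astronomical standardized distance.
* **Smooth rate clamp.** Inside the likelihood, $\max(-dV/dt, 0)$ is
  replaced by a softplus with scale 0.01 mL/yr. The scale was sharpened
  until the maximum-likelihood estimates stopped moving; a wide smoothing
  (0.05) measurably tilts the nearly flat ridge between $k_1$ and $k_2$.
* **Centred, bounded, log-scale parameterisation.** Positive parameters
  are estimated on the log scale inside physiologically generous box
  bounds; the trajectory is estimated as its value and slope at age 50
  rather than at age 0, because the raw $(k_0, k_1, k_2)$ coordinates form
  a curved, nearly flat valley (the data sit decades from the intercept).
* **Starting values and basin search.** Data-driven moments (within-
  subject volume slopes regressed on mid-age, per-subject accelerations,
  QSS inversion for $c_{Brain}$, robust median-based scales) give the
  default start; a small set of candidate starts profiles the weakly
  identified curvature direction and the best-scoring candidates are
  refined before the full quasi-Newton pass (L-BFGS-B with a cached
  forward-difference gradient, then a Newton-type polish; relative
  function tolerance 1e-8, iteration cap 2000).

Standard errors come from the observed information with a delta-method map
back to the natural scale. `two_stage_fit()` is an intentionally simple
moment/least-squares estimator over the same equations — stage 1 fits the
slope equation $\Delta V/\Delta t = k_1 - 2 k_2(group, CAG)\,\bar t$ by
structured least squares over the within-subject changes (a plain
slope-on-midage regression is inconsistent when $k_2$ varies with CAG
inside a group), stage 2 solves each subject's trajectory given $k_1$ and
regresses $\log k_{2,i}$ on $\log(CAG/42.5)$, stage 3 inverts the QSS
relation on every NfL observation and takes the median implied brain
concentration. It is exact on clean data and is kept as an independent
consistency check, never the headline method. `compare_models()` ranks specifications by a small-sample
corrected BIC, $-2\ell + p\log(n)\,n/(n-p-1)$ (the analogue of the AICc
inflation applied to the BIC penalty; recorded in the fit metadata).

### Identifiability

Separating the basal rate $k_1$ from the accelerations is the model's
weakest direction: with two visits per subject, the within-subject slope
constrains $k_1 - 2k_2\,\bar t$, and disentangling the two leans on
cross-sectional curvature. Even with an 800-subject replicated design the
profile likelihood along this ridge is shallow (moving $\hat k_1$ by
~20% costs only a few log-likelihood units), so single-dataset estimates
of $k_1$ and $k_2$ carry sampling scatter of roughly 5–10% while their
identified combinations (the rate at typical ages, $\beta$, $c_{Brain}$,
the error magnitudes) are much tighter. The acceptance suite's recovery
test should be read with that in mind.

## Diagnostics

`prediction_band()` simulates virtual subjects (random effects plus
observational error) from fitted or assumed parameters and returns
pointwise quantiles over an age grid; the median curve is the
typical-subject trajectory (zero random effects, zero noise) — a fixed,
documented convention, negligibly different from the Monte-Carlo median at
the default ω. Bands include observational error, so they bound future
*observations* and their empirical coverage can be checked directly.
`cag_rate_sweep()` tabulates the neurodegeneration rate by age and CAG;
`residual_report()` returns individually weighted residuals for both
streams (volume standardized by σ_add, NfL by σ_prop·prediction). With few
visits per subject, empirical-Bayes shrinkage deflates the residual SD
below 1; the standardization diagnostic is most informative on designs
with several visits.

## Degenerate inputs and numerical edges

* Ages below the trajectory vertex ($t < k_1/2k_2$) predict zero NfL;
  the study's age range (26–77) sits above the vertex at the published
  values, so the clamp rarely binds on realistic cohorts.
* Subjects with a single visit contribute through the pooled stages and
  the marginal likelihood; they are skipped (with a warning) by
  per-subject stages of the two-stage estimator.
* `two_stage_fit()` refuses to estimate the CAG power law from fewer than
  two distinct CAG values.
* The ODE is stiff on the year timescale ($CL/V_{CSF} \approx 10^3$/yr)
  and is solved with `deSolve::lsoda` at tight tolerances.

## Problem sizes used by the test-suite

Unit tests run on the 80-subject study design or smaller; the recovery
check uses one ×10-replicated cohort (800 subjects), model selection uses
20 replicates of the 80-subject design, and band coverage uses ~5,000
fresh simulated observations — sizes at which each check's Monte-Carlo
error is well inside the asserted tolerance.

## Known limitations

* Clearances are fixed inputs; the model cannot separate a clearance error
  from $c_{Brain}$ (they enter the QSS prediction only as a ratio).
* $k_1$/$k_2$ separation is weakly identified on two-visit designs (see
  above).
* Plasma/serum NfL kinetics, microglial clearance and exosomal NfL release
  are outside the model's scope.
* The linear-volume alternative (`model_spec("linear")`) exists to be
  rejected: it predicts an NfL concentration constant in age and is
  retained only for the corrected-BIC comparison.
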