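---
title: "Emphysema-excluded dose-volume metrics and pneumonitis risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emphysema-excluded dose-volume metrics and pneumonitis risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EmphyDose)
```

## The scientific problem

Radiation pneumonitis (RP) is the dose-limiting lung toxicity of thoracic
radiotherapy. The classical dosimetric predictors — mean lung dose (MLD) and
the percentage of lung receiving at least 20 Gy (V20%) — treat every lung
voxel as equivalent. Emphysematous lung, however, is largely destroyed tissue:
its contribution to pneumonitis risk is plausibly different from that of
functional parenchyma. EmphyDose implements the analysis that follows from
this idea: quantify emphysema on CT as **low attenuation volume (LAV)**,
remove it from every dose-volume statistic, and ask whether the LAV-excluded
parameters predict symptomatic RP better than their traditional counterparts.

## The measurement model

**LAV segmentation.** A lung voxel is LAV when its HU lies at or below a
threshold: -856 HU on free-breathing CT (free breathing is close to
expiration) and -950 HU on full-inspiration CT — the standard quantitative-CT
conventions. Segmentation is a plain threshold on the supplied lung mask: no
smoothing, no connected-component cleanup, no airway exclusion. Smoothing
would silently change volumes; the threshold is configurable
(`lavConfig()`), and a voxel exactly at the threshold counts as LAV
(inclusive, the usual LAA% convention; also configurable). A free-breathing
vs inspiratory calibration check (`calibrateLav()`) reports the OLS slope,
intercept and Pearson/Spearman correlation between paired measurements.

**Dose-volume parameters.** The lung is partitioned into LAV and non-LAV
compartments. For each dose cutoff $x \in \{2, 5, 10, 20, 30\}$ Gy (the
conventional set; configurable) the package computes absolute volumes
$V_x$, $V_x - \mathrm{LAV}_x$, $\mathrm{LAV}_x$ (cc), percentages
$V_x\%$, and the compartment ratios $(V_x-\mathrm{LAV}_x)/\mathrm{TLV}$ and
$(V_x-\mathrm{LAV}_x)/(\mathrm{TLV}-\mathrm{LAV})$; plus TLV, LAV, LAV%,
TLV$-$LAV and the mean doses MLD (whole lung), MED (LAV compartment) and
MLWED (non-LAV compartment) — 36 parameters per patient. The boundary is
inclusive ($\geq x$ Gy) everywhere. Ratios are reported on the 0–1 scale and
$V_x\%$ on the 0–100 scale, matching how such tables are conventionally
printed.

Voxel bookkeeping is deliberately exact: a voxel belongs to a compartment or
not (centers only, no partial-volume weighting), absolute $V_x$ is stored as
$(V_x-\mathrm{LAV}_x) + \mathrm{LAV}_x$ so the partition identity holds to
the bit, and the volume-weighted decomposition
$\mathrm{MLD}\cdot\mathrm{TLV} = \mathrm{MED}\cdot\mathrm{LAV} +
\mathrm{MLWED}\cdot(\mathrm{TLV}-\mathrm{LAV})$ is an exact identity because
MED and MLWED average *all* compartment voxels, including unirradiated ones
("irradiated LAV" is read as the LAV inside the contoured lung). The
alternative reading — average only voxels with dose $> 0$ — is available via
`irradiatedOnly = TRUE` but breaks the identity. MED is undefined (NA) when
there is no LAV, and MLWED when LAV fills the lung; such patients are
excluded listwise from that parameter's model with a logged count.

**Grids.** Dose grids rarely share the CT lattice, so the dose is resampled
onto the CT geometry (LAV lives on CT voxels — resampling the CT onto the
coarser dose grid would destroy the segmentation) by trilinear interpolation
at voxel centers, with no extrapolation: target centers outside the dose grid
get 0 Gy. Whether a clinical planning system computes overlaps on the dose or
the image grid varies by vendor; fixing the CT grid makes the choice explicit
and testable. Contours are rasterized by the even-odd rule at voxel centers,
with points exactly on an edge counting as inside (a deterministic tie-break
the DICOM standard leaves open); a contour plane farther than half the slice
spacing from every slice is an error rather than a silent shift.

## The risk models and their comparison

The endpoint is binary: CTCAE RP grade $\geq 2$ (symptomatic, primary) or
$\geq 3$ (secondary). Clinical covariates are screened univariately —
Wilcoxon rank-sum for continuous variables (exact when both groups have
$\leq 20$ patients: by the exact distribution without ties, by full
permutation enumeration with ties when tractable; tie-corrected normal
approximation otherwise) and Fisher's exact test for categorical ones
(two-sided by the minimum-likelihood rule, which handles $r \times c$
tables).

Each dosimetric parameter is **divided by its sample SD** (n−1 denominator,
no centering — centering only moves the intercept and is available behind a
flag) and entered into a logistic model adjusted for chemotherapy and
interstitial lung disease, the two covariates that act as confounders in this
setting. Fits are maximum likelihood via IRLS; the per-SD odds ratio, Wald
95% CI and p-value are reported together with the exact identities
$\mathrm{AIC} = 2k - 2\ell$ and $\mathrm{BIC} = k\ln n - 2\ell$. Complete or
quasi-complete separation *of the dosimetric term* is a hard error with an
optional Jeffreys-prior (Firth) penalized refit behind a flag; a diverging
rare *adjuster* (e.g. ILD present in 6% of patients and perfectly aligned
with the outcome in a small cohort) leaves the dosimetric term estimable and
is tolerated with a warning.

Models are compared on five measures: rank-based (Mann–Whitney) AUC with
ties counting 1/2; AIC; BIC; integrated discrimination improvement (IDI, the
difference in discrimination slopes); and the **continuous** (category-free)
net reclassification improvement, range $[-2, 2]$, with exact ties
contributing 0. The categorical NRI is bounded by 2 only with extreme
categories; reported values above 1 on this kind of data are only
interpretable as the continuous form, which is what the package implements.
The IDI/NRI reference model is the MLD model *with the same adjusters*, so
the comparison isolates the dosimetric term; using bare MLD instead is a
flag. The ROC operating point of the best parameter maximizes Youden's
$J = \text{sens} + \text{spec} - 1$ over observed values under the rule
"score $\geq$ threshold is positive", breaking ties toward higher
specificity — the usual convention where the selection rule is not otherwise
stated. No multiple-testing correction is applied across the 36 parameters.

## The synthetic cohort

No patient imaging is distributed, so validation runs on a phantom cohort
(`simulateCohort()`) built to emulate the printed summary statistics of a
100-patient thoracic radiotherapy population:

* **Anatomy** — an ellipsoid lung pair on a 48×48×32 grid at 4 mm spacing,
  with a per-patient size factor (0.88–1.12) so TLV varies;
* **Emphysema** — a union of random spheres (radius 8–16 mm) inside the
  lung with HU $\sim N(-950, 30)$ against parenchyma $N(-750, 50)$, placed
  until the *measured* LAV fraction at -856 HU centers on 0.103 (the
  structural target is corrected downward for the ~1.7% parenchyma noise
  tail below the threshold);
* **Dose** — a cylindrical beam through the right lung (radius 10–18 mm,
  6 mm Gaussian penumbra, 0.3%/mm depth attenuation, prescribed dose
  uniform on 30–66 Gy, 8 mm positional jitter), calibrated once so cohort
  medians land near MLD ≈ 7 Gy and V20% ≈ 14;
* **Covariates** — chemotherapy at 40% and ILD at 6% prevalence, with age,
  sex, stage, histology, smoking and BMI drawn to resemble the cohort
  table;
* **Outcome** — $P(\mathrm{RP}) = \mathrm{logit}^{-1}(-1.5 + 1.2 z +
  1.0\,\mathrm{chemo} + 1.2\,\mathrm{ILD})$ where $z$ is the cohort z-score
  of $(V_{30}-\mathrm{LAV}_{30})/(\mathrm{TLV}-\mathrm{LAV})$, giving
  roughly a 30% event rate. The generator z-scores the driver (centers and
  scales) although the *analysis* standardization divides by the SD only:
  with division alone the event rate would track the driver's mean/SD ratio
  and could not stay near the printed 27%. Events receive grades 2:3:4:5 in
  proportion 12:13:1:1 and non-events 0:1 in proportion 49:24, so both
  endpoints are exercisable from one generator.

Per-patient seeds are counter-based hashes of the master seed, so cohorts
are bit-reproducible and stable under reordering, and the image/dose
generator never sees outcome labels (no leakage by construction). HU are
integers and doses are quantized to 0.001 Gy, which is what makes
DICOM/NIfTI fixture round trips exact.

What the phantoms do *not* emulate: airway/vessel anatomy, lobar structure,
realistic beam arrangements (multi-field, arcs), dose heterogeneity
corrections, respiratory motion, or any correlation between emphysema burden
and dose placement. Passing tests therefore demonstrate that the *pipeline*
recovers a known generative signal under realistic marginal statistics — not
that the clinical effect size is reproduced.

## Problem sizes and numerical choices

Single-cohort analyses use the default 48×48×32 phantom grid. The
replicate studies (200 cohorts for the direction-of-effect check, 1000 fits
for the null calibration) use a 24×24×16 grid at 8 mm spacing — the package's
chosen desk-scale size; the generative model, prevalences and LAV target are
identical at both sizes. The direction-of-effect check asks whether the
parameter that drives the outcome beats MLD by AUC in more than 70% of
replicates with a positive mean IDI — a reproduction of the *ordering*, not
of any clinical effect size. The null calibration draws outcomes
independently of all parameters and expects per-parameter Wald rejections at
5% ± 2%.

Other numerical choices: geometry orthonormality is enforced to 1e-6;
trilinear interpolation clamps to the source hull with no extrapolation;
GLM convergence uses IRLS with relative log-likelihood tolerance 1e-10 and
at most 100 iterations; separation is flagged when a fitted probability is
within 1e-8 of 0/1 and the reported coefficient exceeds 15 in absolute
value; the exact Wilcoxon permutation path is used when both groups have at
most 20 observations and the enumeration has at most 2e5 assignments.

## Worked example

```{r example, eval = FALSE}
sim <- simulateCohort(n = 100, masterSeed = 42)
cmp <- compareParameters(sim$profiles, sim$cohort,
                         endpoint = "grade2", reference = "MLD")
head(cmp[order(-cmp$auc), c("parameter", "auc", "aic", "bic", "idi", "nri")])

op <- rocOperatingPoint(sim$profiles$ratio_nonlav_30,
                        deriveEndpoint(records(sim$cohort)$rp_grade, 2))
op$threshold; op$sensitivity; op$specificity
```

`runStudy()` wraps the whole sequence (simulation or NIfTI fixtures →
profiles → univariate screen → model comparison → ROC operating point) into
a reproducible bundle of CSV/JSON files, and `renderReport()` formats the
bundle as Markdown without recomputing anything.

## Known limitations

* DICOM support is a minimal explicit-VR little-endian codec for CT series,
  RT Dose and RT Structure Set — sufficient for fixtures and for toolkit
  interoperability, not a general DICOM library (no implicit VR, no
  compressed transfer syntaxes).
* The lung mask is analyzed as supplied; no airway/trachea exclusion or
  planning-structure (GTV/PTV) subtraction is performed, although an
  exclusion list can be emulated by editing the mask before profiling.
* Physical dose only; no EQD2 or fractionation correction, and no DVH
  curves beyond the threshold queries the parameters need.
* Bootstrap confidence intervals for IDI/NRI and the categorical NRI are out
  of scope.
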