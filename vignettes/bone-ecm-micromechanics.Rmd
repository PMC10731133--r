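---
title: "Micromechanics of bone extracellular matrix: models, estimators and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micromechanics of bone extracellular matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomech)
```

## The scientific problem

Osteogenesis imperfecta (OI) is a genetic collagen-I disorder that makes
whole bones brittle, yet at the scale of the extracellular matrix (ECM) —
individual osteonal lamellae, micrometers across — compressive properties
of OI tissue are not inferior to healthy tissue. Whether the same holds in
*tension* is the question this package's pipeline is built around: it
implements, end to end, the quantitative analysis of a microtensile /
nanoindentation / polarized-Raman / micro-CT study of bone ECM from one
healthy and two OI (type I and type III) iliac crest biopsies, together
with a synthetic-data generator that reproduces the statistical structure
of such a cohort so that every stage is testable without access to raw
measurements.

The package estimates, per osteonal site:

* **Microtensile properties** — loading modulus $E_{loading}$ (the highest
  slope of the loading stress-strain curve, combining elastic and
  irreversible deformation), ultimate stress $\sigma_{ult}$, strain at
  ultimate stress $\varepsilon_{ult}$, strain at failure, and a
  brittle/ductile classification.
* **Fiber orientation and mineralization** — the out-of-plane angle
  $\theta_{MCF}$ of the mineralized collagen fibers and the degree of bone
  mineralization (DBM, the $\nu_1 PO_4$/amide I Raman area ratio), from
  polarization-resolved Raman line scans.
* **Indentation properties** — indentation modulus $E_{ind}$, hardness
  $H_{IT}$, elastic and total work, by Oliver-Pharr analysis.
* **Tissue mineral density** (TMD) from calibrated micro-CT.

and fits three models on top:

$$E_{loading} = \alpha_{FST} + \beta\,TMD + \epsilon, \qquad
  \sigma_{ult} = \alpha_{FST} + \beta\,TMD + \epsilon$$

with the fracture surface type (FST: axial / mixed / transversal) as a
categorical anisotropy factor, and the combined indentation model

$$E_{ind}(\theta, DBM) = \alpha + \beta\,DBM + \Delta E\, f(\theta),$$

where $f$ is the normalized shape function of the transverse isotropic
indentation tensor ($f(0°)=0$, $f(90°)=1$) and
$\Delta E = E_{33} - E_{11}$. Group differences are tested with a
random-intercept mixed model (`value ~ group + (1 | biopsy)`), a
likelihood-ratio test, and Dunn's rank-based post hoc comparisons with
Bonferroni-Holm adjustment.

## The anisotropic contact model

Bone ECM is transverse isotropic: five engineering constants
($E_{11}, E_{33}, \nu_{12}, \nu_{31}, G_{31}$) assemble into a 6x6
stiffness (`assemble_stiffness()`, positive definiteness checked on the
Kelvin form). The indentation modulus of the half-space for an arbitrary
indentation direction is computed by `indentation_modulus()` from the
Barnett-Lothe surface Green's function: for each in-plane direction $t$,
the 3x3 tensor

$$B(t) = \frac{1}{2\pi}\int_0^{2\pi}
  \left[(nn) - (nm)(mm)^{-1}(mn)\right]\,d\phi,
  \qquad (ab)_{jk} = a_i C_{ijkl} b_l,$$

with $(m, n)$ an orthonormal pair rotating in the plane perpendicular to
$t$, gives the surface displacement profile
$h(\gamma) \propto a\cdot B^{-1}(t(\gamma))\cdot a$ along the indentation
axis $a$, and the circular-contact polar average yields
$M = 2 / \langle a\cdot B^{-1} a\rangle_\gamma$. Both integrals use
trapezoidal quadrature on the (periodic, smooth) integrands with grid
doubling until the result changes by less than `tol` (default $10^{-3}$
relative); non-convergence is an error, not a silent fallback.

Two independent closed forms validate the solver: the isotropic limit
$M = E/(1-\nu^2)$ and, for indentation along the symmetry axis of a
transverse isotropic material,

$$M_3 = 2\sqrt{\left(C_{33}-\frac{C_{13}^2}{C_{11}}\right)
  \Big/ \left(\frac{1}{C_{44}} +
  \frac{2}{\sqrt{C_{11}C_{33}}+C_{13}}\right)},$$

implemented separately in `axial_indentation_modulus_closed_form()`. The
polar-average (circular contact) approximation is exact on the symmetry
axis and a standard approximation for tilted axes, where the true contact
patch is mildly elliptical; the rotation-consistency test bounds the
residual asymmetry effect at well under one percent for bone-like
constants.

**Angle convention.** $\theta_{MCF}$ is the angle between the fiber axis
and the specimen surface plane; indentation is along the surface normal,
so $\theta = 90°$ loads the fiber axially and $M(90°)$ is governed by
$E_{33}$. The literature is not unanimous here, and group-level data can
appear paradoxical under either convention (the most-aligned group can
show the *largest* indentation modulus through its higher mineralization,
i.e. the $\beta\,DBM$ term dominating). The convention is therefore kept
explicit and configurable rather than hard-wired into conclusions.

**Shape function class.** $f(\theta) = c_1\sin^2\theta +
(1-c_1)\sin^4\theta$ satisfies the endpoint normalization identically,
is monotone for $c_1 \in [0, 2]$, and fits the computed $M(\theta)$
profile of bone-like constants with residual RMS below 1% of
$M(90°)-M(0°)$. Default constants ($E_{11}=15$, $E_{33}=26$,
$\nu_{12}=0.32$, $\nu_{31}=0.25$, $G_{31}=7$ GPa) are bone-like values
for osteonal lamellar tissue and are configurable; all contact-module
tests are property-based rather than tied to these numbers.

## Raman estimation choices

* **Calibration function.** The published calibration mapping the
  polarization-aggregated amide I / amide III area ratio to
  $\theta_{MCF}$ is instrument-specific and not available in closed form;
  the package uses a monotone parametric stand-in
  $\theta = 90\,((r - r_{min})/(r_{max}-r_{min}))^{p}$ with
  $(r_{min}, r_{max}, p)$ in `raman_calibration()` and the synthetic
  generator using its exact inverse. Within the package, the calibration
  is therefore self-consistent by construction: estimator correctness is
  assessed as round-trip recovery, not as agreement with any external
  instrument.
* **Polarization aggregation.** The per-angle amide I / amide III ratios
  are aggregated by their arithmetic mean over the 13 polarization angles
  (0-180° in 15° steps); a max-minus-min modulation-depth option exists
  as a configuration alternative. DBM is the arithmetic mean of
  $\nu_1 PO_4$/amide I over the same angles, which cancels the
  polarization dependence of both bands.
* **Baseline.** Second-order polynomial fitted to rolling-window local
  minima with iterative one-sided trimming: peak-tail-contaminated
  anchors have strictly positive residuals and are discarded until the
  anchor set stabilizes. On noise-free spectra this recovers an exact
  quadratic baseline to machine precision.
* **Band model.** Lorentzian superpositions per window (amide I 1550-1750
  cm$^{-1}$ with sub-peaks at 1638/1670; amide III 1215-1300 with
  1242/1273; $\nu_1 PO_4$ 920-990 with 960), Levenberg-Marquardt least
  squares, analytic areas $\pi \cdot \text{amplitude} \cdot
  \text{half-width}$. The $\nu_2 PO_4$/amide III ratio is deliberately
  not implemented: at the spectral background levels this pipeline
  emulates, the second phosphate band is not reliably extractable.

## The synthetic cohort generator

`generate_cohort()` draws site-level ground truths from the configured
group distributions (truncated normal for bounded quantities) and builds
raw records that are, by construction, exact inverses of the analyzers at
zero noise. Design choices worth knowing:

* **Group parameters** default to the reference cohort summary
  (`reference_cohort_params()`): three groups (healthy, OI type I, OI
  type III) with one biopsy each and 8/7/8 osteonal sites, group means
  and SDs for all ten parameters, and fixed FST compositions (4/2/2,
  5/1/1, 0/6/2).
* **Coupling laws** are group-mean-centred, e.g. $E_{ind} = \mu_g +
  \beta_{dbm}(DBM - \mathbb{E}_g[DBM]) + \Delta E (f(\theta) -
  \mathbb{E}_g[f(\theta)]) + \epsilon$, with $\mathbb{E}_g[f(\theta)]$
  computed by quadrature under the truncated normal. This matches the
  configured group means in expectation while keeping the model structure
  recoverable; residual SDs are set so the total variance matches the
  configured SD (floored at 5% when the couplings alone would exceed it,
  in which case the realized SD is slightly larger than configured).
* **Tensile curves** rise linearly at the true modulus and bend over a
  quadratic cap to the peak; the strain at peak is clamped to the
  feasible band $(1.02, 1.98)\,\sigma/E$ that the "highest slope" +
  "stress maximum" contracts impose. Ductile specimens continue on the
  concave tail to $\varepsilon_{fail} = 1.2\,\varepsilon_{ult}$ by
  default (the observed range being roughly 12-31% excess strain).
* **Raman bands** are given smooth compact support (cosine taper outside
  each fit window). Real Lorentzian tails extend indefinitely; the taper
  is what makes baseline anchors outside the windows *exactly* quadratic
  and hence the zero-noise round trip exact, which is the well-posedness
  property the tests rely on. Passing tests therefore demonstrate
  estimator consistency within this generative family, not robustness to
  arbitrary real-world band shapes, fluorescence or cosmic spikes.
* **Indentation records** follow the trapezoidal protocol (load at 100
  mN/min to 1 um depth, 30 s hold, unload at 400 mN/min) with peak load,
  stiffness and residual depth solved so that Oliver-Pharr analysis
  returns exactly the requested $(E_{ind}, H_{IT})$. A consequence: the
  work quantities $W_{el}, W_{tot}$ of raw records are dictated by the
  contact law and come out below the configured cohort work truths,
  which are therefore used at truth level in the statistics while the
  raw pipeline reports the contact-law values.
* **Noise defaults** (chosen once as realistic orders of magnitude, both
  configurable): force 2 uN and displacement 2 nm on the tensile
  channels, spectral noise 1% of the amide I peak amplitude, 1 nm / 0.02
  mN on the indentation channels, 25 mgHA/cm3 density noise on micro-CT.
  The corresponding recovery accuracy is about 0.5° mean absolute error
  in $\theta_{MCF}$ and under 5% relative error in DBM.

## Statistics

The mixed model is fitted by maximum likelihood (not REML), so the
likelihoods of the nested fixed-effect structures are comparable and the
LRT against $\chi^2_{k-1}$ is valid. The reference design — one biopsy
per group — confounds the group effect with the biopsy random intercept;
`lrt_group_effect()` accepts it with a loud warning, and statistical
validation uses the `"wellposed"` preset instead. That preset uses 8
biopsies per group with 4 sites each: a simulation study of the null
distribution showed the $\chi^2$ reference to be visibly liberal at 4
biopsies per group (empirical size ~9% at the 5% level), marginal at 6
and adequate from 8, so 8 is the preset's value. Dunn's test uses the
normal approximation on joint ranks with tie correction; Holm adjustment
is step-down and never reduces a raw p-value.

## Numerical conventions and degenerate inputs

* Slope window for $E_{loading}$: 0.2% strain, at least 10 samples;
  failure is the first sample below 50% of the running stress maximum
  (brittle fracture is a near-vertical drop). A curve without such a drop
  yields a flagged result, not an error.
* Oliver-Pharr: power-law fit over the top 80% of the unload force range,
  $\varepsilon = 0.75$, ideal Berkovich area $24.5\,h_c^2$ (polynomial
  tip-defect terms optional), diamond constants 1141 GPa / 0.07. Negative
  stiffness or $h_c > h_{max}$ flag the indent invalid; aggregation over
  an osteon averages the valid indents and reports the invalid count.
* Report tables round half away from zero at one decimal.
* All generators are deterministic under a fixed seed; the pipeline fans
  a single run seed out to per-stage child seeds so stages can be rerun
  in isolation.

## Problem sizes

The test suite and the acceptance script use: 20 random materials for the
isotropic contact oracle; a 10-point angle grid (91-point grid for
monotonicity of the fitted $f$); 200 replicates of the n = 23
combined-model recovery at 1.5 GPa residual noise; a 0-90° angle grid in
15° steps with two replicates per point at the default spectral noise for
the Raman round trip; 500 null replicates of the well-posed design for
LRT calibration; and full reference cohorts (23 sites) for the
end-to-end run. These sizes were chosen so the complete suite documents
the statistical claims while remaining comfortable to run routinely.

## Known limitations

* The contact solution assumes a circular contact patch off-axis
  (polar-average approximation) and linear elasticity; no elastoplastic
  indentation or finite-element contact modelling.
* The Raman calibration is a self-consistent parametric stand-in, not an
  instrument calibration; absolute angle accuracy on real spectra is
  outside what the package can claim.
* The synthetic generator does not emulate thermal drift, frame
  compliance, fluorescence backgrounds, FIB damage layers, or spatial
  heterogeneity within a site beyond the per-position angle variation.
* With one biopsy per group, group-level inference is intrinsically
  confounded; the package surfaces this rather than hiding it.
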