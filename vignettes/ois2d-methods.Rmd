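---
title: "Methods: 2D optical imaging spectroscopy of cortical hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2D optical imaging spectroscopy of cortical hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ois2d)
```

## The measurement and the model

Two-dimensional optical imaging spectroscopy (2D-OIS) illuminates the
cortical surface through a cranial window with four wavelengths (495, 559,
575 and 587 nm) and collects the remitted light with a camera, giving an
effective per-wavelength frame rate of 8 Hz. Changes in the remitted
intensity at each pixel are driven mainly by changes in oxy- (Hbo) and
deoxyhemoglobin (Hbr) concentrations, which absorb very differently across
this band.

The conversion from intensities to concentrations is the modified
Beer–Lambert law. For each wavelength $\lambda$ and pixel,

$$\Delta A(\lambda, t) = -\ln \frac{I(\lambda, t)}{\bar I_0(\lambda)}
  \approx \ln 10 \, \big[\varepsilon_{Hbo}(\lambda)\, \Delta C_{Hbo}(t) +
  \varepsilon_{Hbr}(\lambda)\, \Delta C_{Hbr}(t)\big]\, L(\lambda),$$

where $\bar I_0$ is the temporal mean over a baseline window,
$\varepsilon$ are molar extinction coefficients (base-10 convention,
cm$^{-1}$M$^{-1}$), and $L(\lambda)$ is the mean path length travelled in
tissue by the photons that return to the detector. With four wavelengths
and two unknowns the system is overdetermined; `unmixPixel()` /
`unmixStack()` solve it by ordinary least squares, with no sign
constraint (Hbr washout *is* negative) and no weighting — the minimal
assumption, cross-checked in the tests against an explicit
normal-equations oracle. Total hemoglobin is defined as
$\Delta Hbt = \Delta Hbo + \Delta Hbr$, enforced by construction.

$L(\lambda)$ comes from Monte-Carlo photon transport
(`simulateRemittancePathlength()`): a pencil beam enters a semi-infinite
homogeneous slab at normal incidence; steps are sampled exponentially at
$\mu_t = \mu_a + \mu_s$; scattering follows Henyey–Greenstein with
anisotropy $g$; the photon weight is multiplied by the albedo
$\mu_s/\mu_t$ at each interaction (implicit capture) with Russian
roulette below weight $10^{-4}$ (survival 0.1); every photon re-crossing
the entry surface is detected regardless of angle, and Fresnel reflection
at the boundary is ignored. The reported path length is the
weight-weighted mean total geometric path of detected photons — the role
$L(\lambda)$ plays in the inversion above. The absorption
$\mu_a(\lambda)$ is derived from the assumed baseline state via
`absorptionCoefficient()`; $\mu_a$ for transport is in natural-log units
(hence the explicit $\ln 10$ on the base-10 extinction table, recorded as
a flag on the table so a natural-log compilation can be substituted).

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| baseline state (oxygen) | 100 µM Hbt, 70% SO₂ | – | standard assumption for the 100% oxygen condition |
| extinction table | bundled synthetic compilation | cm⁻¹M⁻¹ | see below |
| reduced scattering µs′ | 20 at 560 nm, $\propto \lambda^{-1}$ | cm⁻¹ | literature-typical cortical range |
| anisotropy g / index n | 0.9 / 1.4 | – | standard soft-tissue values |
| photons per wavelength | 10⁵ (tests use less) | – | SE well below 1% of the mean |
| ROI threshold k | 1.5 | prestim SD | the selection rule of the analysis |
| vessel quantile | 0.8 | – | upper-quantile cut on PCA loadings |
| Bonferroni family | α/m | – | e.g. 0.05/15 ≈ 0.003 |

The bundled extinction spectra
(`inst/extdata/hb_extinction_synthetic.tsv`) are a *synthetic*
compilation: cubic splines through hand-set anchors reproducing the
published band structure of hemoglobin (oxy double peak at 542/577 nm
with the 560 nm trough, the single broad deoxy band near 555 nm,
isosbestic crossings near 500/527/545/570/584 nm, and the red gap where
deoxyhemoglobin dominates). No single published table is copied; every
property the pipeline relies on (full-rank four-wavelength design, good
conditioning, smoothness for linear interpolation) is a property of this
band structure, not of any specific compilation, and all quantitative
validation is against the phantom's own forward model, which uses the
same table.

## The synthetic phantom

`makePhantom()` draws a circular cranial window containing a curved
artery and a curved vein (thick curves, disjoint, both guaranteed to
traverse a central "active" patch), with parenchyma elsewhere. The
forward model (`simulateSession()`) composes, per compartment:

* a baseline trajectory per breathing condition — constant under oxygen
  (100 µM / 70%) or air (95 µM / 62%), a first-order exponential ramp
  (10 s dead time, 20 s time constant) across gas switches, and a
  hypercapnia excursion (fractional Hbt gain 0.15, SO₂ gain 0.05, 15 s
  ramp). The first-order form keeps the pre-switch baseline window
  exactly flat, so window-mean estimates are unbiased;
* a spreading-depression multiplier for acute scenarios
  (`csdPerturbation()`): $1 - A e^{-t/\tau} \cos(2\pi t/P)$ with
  $\tau = 1200$ s and $P = 400$ s on the session clock — an alternating
  constriction/dilation recovering over the session. Defaults $A = 0.06$
  (wild-type-like) and $A = 0.12$ (Alzheimer-like) encode the scenario
  that the acute perturbation is larger in the disease-model group;
  chronic scenarios have $A = 0$;
* evoked responses (`evokedTimecourse()`): unit-area gamma kernels
  convolved with the stimulus boxcar; the artery leads the vein in
  latency, Hbr is negative-going with extra lag, and under the *air*
  condition a delayed negative lobe is added to Hbt (post-stimulus
  arterial undershoot) that is absent under oxygen. Acute scenarios scale
  amplitudes by 0.7 (wild-type-like) or 0.45 (Alzheimer-like); chronic
  scenarios are identical across groups — the generator encodes the
  qualitative structure of the study design, with amplitudes chosen once
  as plausible values (artery 6, vein 3, parenchyma 2 µM Hbt at plateau);
* the same Beer–Lambert forward relation as the inversion, rendered to
  camera counts $I = I_0 e^{-\Delta A}$ with $I_0 = 2000$ (mid-range of a
  12-bit sensor), signal-scaled Gaussian shot noise ($\sigma = \sqrt I$),
  a constant dark offset (100 counts, SD 2) emitted also as dark frames,
  and integer quantisation.

Every recording carries its injected compartment time courses
(`@truth`), so any stage can be scored against ground truth.

What the phantom does **not** emulate: spatially heterogeneous path
lengths (large vessels violate the homogeneous-tissue assumption more
than parenchyma), motion and physiological oscillations (heartbeat,
vasomotion), wavelength cross-talk from filter switching, and true
Poisson statistics (a Gaussian approximation is used). Passing tests
therefore demonstrate the correctness and calibration of the *analysis*,
not the realism of any particular biological effect size.

## Pipeline decisions

* **Rebaselining**: attenuation is computed per experiment against its
  own baseline window — the pre-stimulus interval of the first trial for
  stimulation records, the pre-switch interval for gas records. A
  consequence: slow baseline shifts (the spreading-depression recovery)
  appear as *within-record drift*, not as an offset of the first frames;
  the scenario checks measure them accordingly.
* **ROI**: always from the 16 s oxygen experiment (Exp7): pixels whose
  stimulus-window mean of the trial-averaged fractional Hbt exceeds the
  pre-stimulus mean by 1.5 pre-stimulus SDs. Zero-variance pixels are
  excluded with a log; an empty mask is an error, not an empty result.
* **Air baseline**: estimated per session from the ROI-mean
  concentration shift over a settle window (default: the last third of
  the oxygen-to-air record), then used as the fractional reference for
  the air-breathing experiments. Path lengths are kept fixed per
  breathing condition, not updated frame-by-frame.
* **PCA compartments**: per-pixel temporal mean removed, no variance
  scaling (loadings stay in response-amplitude units); first singular
  component; sign fixed so the temporal score covaries positively with
  the stimulus regressor. Arteries: upper-quantile (0.8) Hbt loadings in
  the ROI; veins: upper-quantile |Hbr| loadings minus artery pixels.
* **Statistics**: the mixed two-way repeated-measures ANOVA uses the
  classical error strata (group against subject-within-group; the
  within-subject factor and interaction against subject-by-level). No
  sphericity correction is applied. Degenerate all-equal tables report
  F = 0, p = 1 rather than 0/0. The equal-variance two-sample t-test
  reports an explicit infinite-t case for zero pooled variance with
  unequal means.
* **Calibration suites** (type-I rate, power) run at the
  response-magnitude level: `simulateCohortMagnitudes()` draws
  per-subject magnitudes around true per-experiment values (between-
  subject SD 0.002, residual SD 0.004), which is exactly the data level
  the ANOVA consumes. Rendering hundreds of full image sessions would
  test the same code path at far greater cost.
* **Monte-Carlo bookkeeping** is verified two ways: a pure-R per-photon
  walker consuming the identical random stream must agree with the
  compiled engine to 10 decimal digits, and the statistical properties
  (SE ∝ n^{-1/2}, monotonicity in µ_a) are checked independently.

## Problem sizes

Tests and the acceptance script run the full algorithms at desk scale:
64×64 or 48×48 grids with shortened protocols (2–3 trials per
stimulation experiment, 240–450 s gas records) for most checks, and the
full 184×184/full-length protocol remains available through the same
functions. Two checks deliberately use study-scale pieces: the ROI rule
is validated with the full 15 trials of Exp7 (the 1.5-SD rule needs the
study's trial averaging to lift the weakest responses above the noise
floor), and the spreading-depression envelope is evaluated on the full
6600 s session clock.

## Known limitations

* The semi-infinite homogeneous slab is the simplest defensible
  remittance geometry; layered or vessel-resolved media would change
  $L(\lambda)$ quantitatively.
* The fractional Hbt response retains a mild dependence on the assumed
  baseline through $B \cdot L(B)$; the robustness check quantifies the
  deviation across 80–120 µM rather than assuming exact invariance.
* Response magnitudes are defined relative to the experiment-level
  baseline (fractional − 1 over the stimulation window); in acute
  scenarios the spreading-depression drift biases them, which is
  faithful to the confound in real acute sessions.
* Serialisation uses R's native format behind
  `writeSessionResult()`; the event-log CSV is the plain-text
  interchange format.
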