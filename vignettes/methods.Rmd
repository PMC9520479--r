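---
title: "Methods: preprocessing, feature filtering and classification of tissue Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing, feature filtering and classification of tissue Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanbiopsy)
```

## The problem

Fiber-probe Raman spectra of brain tissue carry a composition
fingerprint — cholesterol and carotenoid bands fall as tissue turns
malignant, hemoglobin and water bands rise with the blood filling and
edema of the tumor core — but the Raman signal sits on a fluorescence
continuum one to two orders of magnitude more intense, on top of
ambient illumination and detector noise, and occasional frames
saturate the detector. This package implements the chain from raw
frames to a three-class tissue call (normal white matter / tumor
edge, i.e. infiltration zone / tumor center), and a binary
malignant-vs-normal summary of it.

## Preprocessing model

Each sample contributes five measurement frames (taken at varying
probe angles) and five ambient background frames. The chain, in
order:

1. **Saturation exclusion.** Any frame whose raw maximum exceeds 90%
   of the detector dynamic range is dropped. With the default
   simulated design (15/15/20 frames) this leaves the 14/15/19
   structure the rest of the defaults assume.
2. **Background subtraction.** The per-sample average of the ambient
   frames is subtracted pointwise. Negative residuals are noise and
   are deliberately preserved (an optional zero-clip exists but
   defaults off; clipping before normalization biases band areas).
3. **Savitzky–Golay smoothing** (window 15 points, order 3). Edges
   use truncated-window polynomial fits, so any polynomial of degree
   ≤ 3 passes through unchanged — that exactness is one of the test
   suite's contracts.
4. **Fluorescence removal.** The continuum is modeled as a sum of
   K = 4 real Morlet wavelets
   \[ B(\nu) = \sum_k a_k e^{-((\nu-c_k)/s_k)^2/2}
      \cos(\omega_0 (\nu-c_k)/s_k), \qquad \omega_0 = 5, \]
   fitted by bounded nonlinear least squares with an asymmetric loss
   that charges residuals where \(B > s\) a factor `asymmetry` more
   than residuals below the signal. This is the standard trick that
   keeps an estimated baseline under the peaks rather than through
   them.
5. **Crop** to the closed interval 900–1800 cm⁻¹, where the
   diagnostically useful bands live. On the even 2050-point grid of
   the simulated axis this keeps 683 points; a real instrument's
   pixel-to-wavenumber map will give a different count (646 on the
   instrument the defaults emulate), which is why the axis is always
   stored explicitly.
6. **Integral normalization**: division by the trapezoidal integral
   over the cropped axis. Output spectra integrate to 1 (±1e−9);
   normalization is idempotent and scale-invariant.

The whole chain is a pure function of its inputs and configuration —
there is no hidden randomness — and every step appends its parameters
to the provenance log of the returned object.

### Numerical choices in the baseline fit

The fit is the one genuinely delicate numerical step, and three
choices deserve a record:

* **Scale bounds (150–8000 cm⁻¹).** With carrier \(\omega_0 = 5\),
  the positive central lobe of a Morlet spans only about
  \(\pm 0.31\,s\) before the cosine turns it negative. Representing a
  continuum lobe of standard deviation \(\sigma\) therefore needs
  scales near \(3\text{–}4\sigma\). An upper bound of a few hundred
  cm⁻¹ would make the model family *incapable* of expressing a
  realistic continuum (we measured best-achievable R² < 0 against the
  true fluorescence with an upper bound of 1500); 8000 cm⁻¹ admits
  lobes wider than the whole axis. The lower bound of 150 cm⁻¹ keeps
  the baseline an order of magnitude smoother than any Raman line
  (FWHM ≈ 15–40 cm⁻¹), so it cannot chase peaks.
* **Asymmetry = 100.** Mild ratios (≈10) let the baseline ride a few
  percent into the peaks and absorb 10–20% of band area on noiseless
  fixtures; at 100 the band-area recovery error stays under 8%
  across spectra and seeds. Far larger ratios (≥300) destabilize the
  optimizer.
* **Deterministic multi-start + polish.** Six fixed start layouts
  (centers at axis quantiles, scales spanning 0.25–1.5 of the axis
  span, amplitudes read off the signal) are optimized with an
  analytic gradient; the best result is then polished with a
  finite-difference pass, which copes better with the kinks of the
  asymmetric loss. The procedure is a pure function of (spectrum,
  config).

## Fisher-criterion feature filtering

For every wavenumber the one-way ANOVA F statistic across the three
classes is compared with the F critical value at level α (default
0.05, df 2 and n−3); only exceeding wavenumbers are retained. No
multiple-testing correction is applied by default — the filter is a
screening device feeding a classifier, not an inference — but
Benjamini–Hochberg is available (`adjust = "BH"`). Retained
intensities are summed inside biochemical bands; each band then gets
a fresh one-way ANOVA on its sums, annotated `*` (p < 0.05) or `**`
(p < 0.001). Band-level tiers are recomputed rather than inherited
from pointwise tests because band sums, not single pixels, are what
an analyst reads. With three groups the ANOVA F is the standard
reading of a "Fisher criterion"; a Fisher-discriminant-ratio variant
(between-class scatter of class means over pooled within-class
variance) is available behind `criterion = "discriminant_ratio"` for
sensitivity analysis — it has no null distribution, so it keeps the
top `alpha` fraction of wavenumbers by ratio instead of thresholding
at a quantile of a reference distribution.

A note on replicate structure: the five replicates of one sample are
not independent, and a one-way F across all measurements is
anticonservative wherever sample-level variability dominates
replicate-level variability. The filter deliberately mirrors that
simple protocol; the synthetic generator (below) is the place where
the consequences can be studied with known truth.

## Classification

* **PCA** by covariance eigendecomposition, mean and loadings fitted
  on training rows only (a fit-on-all mode exists for score-plane
  figures, flagged as leaking test information into the projection).
  Loadings carry a sign convention (largest-magnitude entry
  positive) so results are platform-reproducible. Two components are
  the default projection.
* **RBF-SVM** (libsvm, one-vs-one) with C = 1 and
  γ = 1/(p · var(X)); no hyperparameter search, because the
  protocol being reproduced reports none. Features are z-scored with
  training statistics before the kernel (RBF kernels are
  scale-sensitive); toggleable.
* **Split rule:** per class, `max(round(0.30 · n), 5)` training
  spectra — 5/5/6 for class sizes 14/15/19. The default split
  ignores patient identity to mirror the original protocol; the
  grouped mode keeps whole patients on one side and should be
  preferred for any claim about new-patient performance.
* **Binary collapse:** positive = tumor edge ∪ center. An edge
  spectrum predicted center (or vice versa) still counts as a true
  positive: the binary question is malignancy, not subtype.
* **Repeated paired evaluation.** A single 30% split of ~48 spectra
  is extremely high-variance, so the default protocol re-splits
  (default 50×) with all variants sharing each split, and reports
  means ± sd. Single-split mode remains available.

## The synthetic generator

The generator emulates the acquisition the defaults assume: a
2050-point axis on 127–2830 cm⁻¹; 3/3/4 samples for normal / edge /
center with 5 measurement replicates and 5 background frames each; an
intense smooth continuum (3 broad Gaussian lobes, amplitude ~10–20×
the peaks); ambient level with slow drift; Gaussian peaks for 15
biochemical components; i.i.d. detector noise (sd 120 counts,
consistent with shot noise on a ~15k-count continuum); and
overexposure handling (a configurable fraction of replicates is
driven past the 16-bit ceiling, or exact per-class counts — the
study-design default saturates one normal and one center replicate so
exclusion leaves 14/15/19).

Class contrasts follow the tissue biochemistry: cholesterol and
carotenoids decrease toward the tumor center (with the edge elevated
near 960 and 1228 cm⁻¹), hemoglobin and water increase, and several
strong bands (phenylalanine 1003, CH₂ 1445, amides) carry no class
signal but large variability. Two nuisance sources are deliberate and
load on *replicates* rather than samples: a lognormal per-replicate
fluorescence amplitude jitter and a smooth per-replicate spectral
gain tilt (low-order Legendre, sd 5%) standing in for the varying
probe angle between exposures. Within-sample CVs (0.20–0.30) are set
at or above between-sample CVs (0.10–0.15): replicates probe
different spots of heterogeneous tissue. This balance matters — when
sample-level nuisance dominates, the pseudoreplicated F filter marks
most of the axis significant; with replicate-level variation
dominating, the retained set is sparse and concentrated in the truly
discriminative bands, the regime the filter-then-project comparison
assumes.

Randomness is split into named sub-streams (design, amplitudes,
fluorescence, ambient, noise, saturation, gain) derived
deterministically from the seed, so changing, say, the noise level
does not reshuffle the sampling design.

What the generator does **not** emulate: wavelength-dependent
instrument response, cosmic-ray spikes, non-Gaussian line shapes
(pseudo-Voigt tails), pixel-level calibration error, or real
biological covariance between components. Passing tests on synthetic
data therefore demonstrate the correctness and calibration of the
algorithms under the stated model, not clinical performance.

## What the comparison shows

On study-like synthetic cohorts, over paired splits pooled across
several simulated cohorts, the `combined` variant (filter → PCA →
SVM) achieves higher specificity than `pca_only` at essentially equal
accuracy, and `filtered_svm` sits between or above both — the
expected behavior when discriminative signal is sparse and dense
nuisance variance dominates the leading principal components of the
full spectrum. The acceptance script computes these quantities from
scratch at run time; no number in this vignette or the README is
asserted beyond what the tests and script compute.

With only 3–4 samples per class, a *single* simulated cohort's
variant comparison is dominated by cohort-level luck (which samples
happened to be drawn); the package therefore pools several cohorts
for the headline comparison, and the chance-level control uses the
99% binomial band at one test-set size (n = 32) around the majority
rate — the envelope of what any truth-independent classifier can
produce — rather than a band that presumes a specific prediction
marginal.

## Known limitations

* The Morlet-sum baseline is a model of *smooth* continua; steep
  fluorescence shoulders at the axis edge can leave a few-percent
  residual that integral normalization partially absorbs.
* The per-point F filter inherits the pseudoreplication of the
  protocol it mirrors (see above); with real data, a mixed-effects
  screen or patient-grouped permutation would be more conservative.
* The 26 retained features of the emulated instrument's protocol are
  not a target: retained counts on synthetic data depend on the
  configured contrasts and nuisance, and the tests only require the
  retained set to cover every truly discriminative band.
* SVM hyperparameters are fixed defaults; no claim of optimality.
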