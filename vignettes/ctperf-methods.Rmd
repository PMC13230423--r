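---
title: "CTP deconvolution and lesion volumetry: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CTP deconvolution and lesion volumetry: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctperf)
```

This vignette is the package's account of its science: the perfusion model
and its discretisation, the input-validation stage, the parameters that
matter and why they default to what they do, what the digital phantom does
and does not emulate, and the numerical corners we had to decide.

## The perfusion model

A dynamic CT acquisition measures, at every voxel, the attenuation added by
an iodine bolus as it transits the vasculature. The tissue enhancement
curve is the convolution of the arterial input function (AIF) with the
voxel's residue function $F_r(t)$ — the fraction of tracer still present
$t$ seconds after an idealised impulse input — scaled by the flow:

$$F_v(t) = \mathrm{CBF}\int_0^t \mathrm{AIF}(\mu)\,F_r(t-\mu)\,d\mu .$$

Sampled at the frame interval $\Delta t$ this becomes a rectangle-rule sum,
$F_v(t_j) = \Delta t \cdot \mathrm{CBF} \sum_{i\le j}
\mathrm{AIF}(t_i)F_r(t_j - t_i)$, i.e. a linear system $V = A r$ with $A$
the lower-triangular Toeplitz matrix of $\Delta t$-scaled AIF samples and
$r = \mathrm{CBF}\cdot F_r$ the unknown.

Deconvolution is ill-posed, so the system is solved by truncated SVD:
reciprocal singular values below a fraction of the largest are zeroed.
Two matrix forms are implemented:

* **sSVD** — the $N \times N$ Toeplitz system itself.
* **bcSVD** (default) — the AIF column is zero-padded to $2N$ and wrapped
  into a $2N \times 2N$ circulant matrix, $\bar a_{ij} = a_{(i-j) \bmod 2N,\,0}$.
  Circular convolution can represent a residue that is *shifted* relative
  to the AIF without violating causality constraints, which makes the
  solution insensitive to bolus-arrival delay; solution indices above $N$
  correspond to negative lags and are clamped to $T_{max}=0$ as
  non-physiological.

From the solution: $\mathrm{CBF} = \max r$ (the residue equals CBF at its
peak), $T_{max} = \Delta t \cdot \mathrm{argmax}\, r$,
$\mathrm{CBV} = \int F_v / \int \mathrm{AIF}$, and
$\mathrm{MTT} = \mathrm{CBV}/\mathrm{CBF}$ (central volume theorem).

### A quadrature correction for CBV and MTT

The discrete forward model is a left-endpoint (rectangle) quadrature, so
the ratio of curve sums recovers not MTT but
$\Delta t \sum_j e^{-j\Delta t/\mathrm{MTT}} =
\Delta t/(1 - e^{-\Delta t/\mathrm{MTT}}) \approx \mathrm{MTT} + \Delta t/2$:
at MTT 4 s and $\Delta t$ 1.5 s an unacceptable +19% bias. We therefore
compute

$$\mathrm{CBV} = \frac{\sum_j F_v(t_j)}{\sum_j \mathrm{AIF}(t_j)}
 - \frac{\Delta t}{2}\,\mathrm{CBF},$$

the trapezoid-consistent counterpart of the rectangle-rule model (it
removes the half-sample of the residue's initial value). With it, MTT
recovery error on the phantom drops to about 1%, and
$\mathrm{MTT}\cdot\mathrm{CBF} = \mathrm{CBV}$ holds exactly. An
uncorrected trapezoid on raw curves would also halve the area of an
impulse-like AIF — the correction is what makes the impulse sanity check
recover MTT at all.

### Truncation

The truncation fraction defaults to **0.10** of the largest singular value,
the customary operating point for circulant-SVD deconvolution. It is the
single most influential numerical parameter: at 0 the noiseless phantom is
recovered to machine precision; at 0.10 both modes acquire a CBF bias
(bcSVD's is uniform across delays, sSVD's grows with delay). Because the
deconvolution's flow units are arbitrary, all downstream decisions use
*relative* CBF, where a uniform bias cancels — this is precisely why
delay-insensitivity of bcSVD matters and why delay sensitivity of sSVD
corrupts lesion volumes: its bias varies voxel by voxel with arrival time.
The delay-robustness test measures exactly this, comparing
$|r\mathrm{CBF} - 1|$ per voxel for delays of 1–4 frames with each mode's
map normalised by its own non-delayed-tissue median; raw-unit CBF errors
would conflate the uniform truncation bias with the delay effect (and at
the 10% truncation the two modes' raw biases are of similar size).

## Input validation

Curves are summarised by: baseline (mean of the first 4 frames, about 6 s
pre-contrast), peak enhancement, time to peak, FWHM (linear interpolation
at half enhancement; an edge that never descends below half height extends
to the end of the acquisition, so cut-off boluses read as very wide),
number of peaks (local maxima with prominence at least 10% of the peak),
and the decay fraction shed within 15 s after the peak.

The rule set quantifies the qualitative published criteria. Only two
numbers are published — peak HU > 80 and a 3–12 s arteriovenous delay —
and we read "peak HU" as *enhancement above baseline* (raw HU depends on
the tissue baseline; an absolute mode is available). The remaining rules
needed defaults, chosen once from the physiology of a first-pass bolus:

| rule | default | rationale |
|---|---|---|
| peak rule | > 80 HU enhancement | published threshold |
| single peak | exactly 1, prominence ≥ 0.1 × peak | multi-peak ⇒ motion/recirculation |
| sharpness | FWHM ≤ 12 s (AIF), ≤ 20 s (VOF) | arterial bolus is narrow; veins disperse |
| decay | ≥ 40% of enhancement shed in 15 s | "fast attenuation after the peak" |
| early peak (AIF) | within 2/3 of the scan | artery must peak well before the end |
| pair delay | venous − arterial peak ∈ [3, 12] s | published window |

On top of the rules sit two learned models, trained on synthetic labelled
curves: kind-specific gradient-boosted validity classifiers (IV), and a
single-hidden-layer feed-forward venous-vs-arterial classifier (LV) whose
main features are peak timing and height. Arterial candidates must
classify as non-venous and vice versa; this operationalises the guard
against AIF-with-AIF or VOF-with-VOF pairs (two arterial-shaped curves can
each be individually plausible yet peak simultaneously). The published
tuned hyperparameters were fitted to private clinical data, so the
defaults here are the libraries' standards with fixed seeds; training is
made order-invariant by canonically sorting the feature rows and deriving
augmentation noise from curve content rather than list position. Decision
threshold 0.5 for both models.

Pair selection keeps candidates passing rules + IV + LV, requires the 3–12
s delay across the pair, ranks arterial candidates by earlier peak then
higher enhancement and venous by higher enhancement, and returns the top
pair — or the `"invalid curve"` warning state. A warning exits the CLI
with status 0: in a clinical pipeline a warning is a result.

## The phantom

The generator emulates a standard stroke protocol: 30 frames at 1.5 s,
4 mm slices, a gamma-variate arterial bolus (onset 6 s, peak 150 HU at
9 s), a venous curve delayed 4.5 s, dispersed ×1.3 and scaled ×1.5, and
tissue generated by the discrete forward model with a mono-exponential
residue (a box-car alternative exists behind a flag). Defaults plant a
core of 12.0 mL at 20% of normal flow and a penumbra of 40.0 mL arriving
7.5 s late; normal tissue has CBF 0.01 s⁻¹ and MTT 4 s — a 4% blood-volume
fraction, which puts tissue enhancement at a few HU against the ~150 HU
arterial peak, the ratio real scanners produce. Everything rides on a
40 HU baseline with additive Gaussian noise (2 HU for a clean
acquisition). Corruption modes (multi-peak, jagged, truncated bolus, flat)
reproduce the documented failure modes; `truncated_bolus` shifts the
bolus so it has not returned toward baseline by the last frame — bad bolus
timing — and trips the warning end to end.

What the phantom does **not** emulate: anatomy, partial-volume effects,
beam hardening and scanner physics, recirculation, dispersive transport
beyond the gamma-variate shape, and spatially correlated noise. Two
consequences matter for interpreting green tests. First, tissue curves at
a realistic 2 HU noise level have single-voxel SNR of 2–3; without the
spatial smoothing every commercial package applies (deliberately out of
scope here), voxelwise maps under noise are qualitative, so the
parameter-recovery guarantees are stated for the noiseless phantom.
Second, integer-frame delays and a shared discrete grid make the *absolute*
noiseless problem easier than reality — which is why the delay-robustness
comparison is run at the active 10% truncation on the rCBF scale, where
the effect the circulant method exists to fix actually shows.

## Other design choices

* **"Eight-voxel radius"** for ROI correction is read as a 3D Euclidean
  ball in voxel units (the correction demonstrably moves landmarks in both
  in-plane and slice directions); a Chebyshev box is available. Ties are
  broken by smaller displacement, then lexicographic index, so correction
  is deterministic and idempotent.
* **AUC for ROI correction** is computed on baseline-subtracted curves:
  raw-HU area is dominated by the tissue baseline and would defeat the
  purpose of selecting bolus-rich voxels.
* **Motion correction** is an exhaustive ±3-voxel integer-translation
  search maximising correlation with the first frame — deterministic,
  exact for the translations a phantom can plant, and replaceable by a
  full rigid registrar for clinical data. It is off by default in the
  pipeline configuration because the phantom is motion-free; enable it for
  scanner data.
* **rCBF reference**: the denominator of rCBF is not published. Default is
  the median CBF over masked voxels with Tmax ≤ 6 s (robust, anatomy-free);
  a contralateral-hemisphere mode is provided for anatomical data and an
  explicit constant for tests.
* **Thresholds are strict inequalities** (< 30%, > 6 s), and volumes are
  reported as integer mL (round half away from zero) with the exact value
  retained.
* **CCC** uses Lin's population (1/n) moments; the 1/(n−1) variant is a
  flag (they differ only when means differ). The bootstrap interval is the
  2.5/97.5 percentile over 1000 paired resamples — percentile, not BCa,
  matching the published description of the resampling.
* **Landmark distance** supports both the in-plane 2D form and a 3D form
  including the slice axis; 3D is the default for anisotropic voxels.
* **Localization** by CNN is out of scope (it requires private clinical
  data and GPUs); the package accepts external landmark JSON and provides
  a classical heuristic (AUC ranking split by time-to-peak) so the CLI
  runs fully automatically on the phantom.

## Problem sizes

The test suite exercises units on a 24 × 24 × 4 × 30 phantom and the
acceptance checks on the full default 64 × 64 × 8 × 30 grid (32,768
voxels per map, deconvolved through a single precomputed pseudo-inverse);
classifier checks use 400 labelled curves with a 25% held-out split. The
full suite runs in well under a minute on one CPU. Full clinical-size
(512 × 512 × 27) generation works through the same code path, just
larger.

## Known limitations

Voxelwise maps at realistic tissue SNR need spatial regularisation that is
intentionally not implemented; the oscillation-index adaptive truncation
family is likewise out of scope. The LV stage implements one feed-forward
architecture rather than a model zoo. DICOM ingestion, skull stripping and
infarct annotation from diffusion imaging are upstream concerns: the
package starts at a 4D NIfTI plus landmarks (or a brain mask) and ends at
maps, volumes and warnings.
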