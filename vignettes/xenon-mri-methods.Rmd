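---
title: "Quantitative hyperpolarized 129Xe lung MRI: models and methods"
author: "xepipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative hyperpolarized 129Xe lung MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xepipe)
```

Hyperpolarized xenon-129 is an inhaled MRI contrast gas. Its magnetization
is prepared outside the scanner and is *not* renewable: every RF pulse
consumes part of it, and what is inhaled must be imaged within one breath
hold. Xenon also dissolves into lung tissue, where it resonates roughly 198
ppm (membrane/interstitium) and 217 ppm (red blood cells, RBC) away from the
gas resonance. These properties enable three complementary exams —
ventilation, diffusion, and gas exchange — and this package implements the
quantitative analysis for all three, plus the calibration spectroscopy that
precedes them and synthetic phantoms that provide ground truth for every
stage.

## Calibration spectroscopy

The calibration scan acquires 500 free induction decays (FIDs) at the
dissolved-phase frequency followed by 20 at the gas frequency, with TR 15 ms.

**Flip angle.** Because hyperpolarized magnetization is non-renewable, the
k-zero magnitude of the gas FIDs follows

$$ S_i = S_0 \cos(\alpha)^{\,i-1} + C, $$

with $C$ absorbing the magnitude noise floor. `fit_flip_angle()` solves this
by nonlinear least squares and reports the scale factor
$\alpha_\mathrm{prescribed}/\alpha_\mathrm{fitted}$ used to rescale future
prescriptions. Long trains decay into the Rician noise floor, whose bias is
not additive; the fit therefore truncates the series where a running median
falls below three times the estimated floor (tail median). This keeps the
100-seed Monte-Carlo mean within 1% of truth at SNR 50 for flips from 5 to
45 degrees, which a naive full-series fit does not achieve.

**Spectral fits.** The gas frequency offset is fitted on the complex
spectrum with the exact finite-acquisition line shape (the geometric-sum DFT
of a decaying complex exponential), which resolves the centre far below the
FFT bin width even for truncated FIDs. The dissolved spectrum is fitted in
the time domain as a sum of three complex Lorentzians (RBC, membrane, gas;
amplitude, frequency, linewidth, phase each), initialized from local maxima
of a zero-padded magnitude spectrum. The first 100 dissolved FIDs are
discarded (early signal includes xenon in downstream vasculature during
inhalation) and the remainder averaged. Note that the full-width at half
maximum of a *magnitude* spectrum is $\sqrt 3$ times the Lorentzian
linewidth; all linewidths here are true Lorentzian widths, and
$T_2^* = 1000/(\pi\,\mathrm{FWHM})$ ms holds exactly for every fitted peak.

**TE90.** One-point Dixon separation requires RBC and membrane to be 90
degrees apart at k-zero:

$$ \mathrm{TE90} = \mathrm{TE} +
   \frac{90 - (\phi_\mathrm{RBC} - \phi_\mathrm{mem})}
        {360\,(f_\mathrm{RBC} - f_\mathrm{mem})}, $$

with phases wrapped to $(-180, 180]$ degrees first, so the result is
invariant under 360-degree wraps.

**Optimal flips.** For ventilation and diffusion the package maximizes the
mean train signal over flip angle: the discrete mean
$\sin\alpha\,(1-\cos^{N N_b}\alpha)/(N(1-\cos^{N_b}\alpha))$ for center-out
trajectories and its continuous-sum form
$\sin\alpha\,(\cos^{N_\mathrm{eff}}\alpha - 1)/\ln\cos\alpha$ for Cartesian
encoding ($N_\mathrm{eff} = N$ or $N N_b$). Gas exchange uses the fixed
consortium pair of 0.5 degrees (gas) and 20 degrees (dissolved). The
optimizer is checked against a dense 0.001-degree grid search in the tests.

## Segmentation

`otsu_lung_mask()` thresholds the pooled volume intensities by Otsu's
criterion (threshold and structuring-element size both adjustable; the
default element size of 1 voxel means no morphological smoothing, and
speckle removal comes from retaining the two largest connected components —
one component is accepted alone if it holds at least 60% of the foreground,
covering merged lungs). `remove_airways()` grows a bright connected tube
from a superior-central seed and relabels it 2; airway voxels are excluded
from every downstream lung statistic. The tube must be distinctly brighter
than parenchyma (threshold at 90% of the robust maximum, and at least 1.2
times the lung mean), otherwise the mask is returned unchanged — free gas in
the trachea is brighter than parenchymal signal on ventilation images.

## Ventilation quantification

**SNR.** The background of a magnitude image is Rayleigh distributed, so the
measured background SD underestimates the complex noise SD:
$\sigma_{BG}^2 = \sigma_M^2/(2 - \pi/2)$. SNR is
$S_\mathrm{lung}/\sigma_{BG}$, or
$(S_\mathrm{lung}-S_{BG})/\sigma_{BG}$ in the gas-exchange variant. A
consequence worth noting: a mask containing pure noise has SNR
$\sqrt{\pi/2} \approx 1.25$ under this correction (the Rayleigh mean over
the *corrected* SD), not the Rayleigh mean/SD ratio of 1.91.

**Threshold VDP.** Voxels below 60% of the whole-lung mean are defects;
VDP $= 100\,(1 - VV/TLV)$ equals the defect percentage. A slice-wise 3×3
median filter cleans the binary defect mask. The filter is *mask-aware*: the
majority is taken over the in-lung voxels of each window. A plain
zero-padded majority erodes the corners of genuine solid defects at the lung
border and can import background votes at the boundary; the mask-aware
filter preserves solid blocks, still removes isolated voxels, and its
reference implementation (explicit neighbourhood loops) is replicated
independently in the test suite.

**Linear binning.** Intensities are normalized by the 99th percentile of the
airway-excluded whole image, clipped to [0, 1], and classified into six bins
at healthy-reference thresholds $\mu \pm \sigma$, $\mu \pm 2\sigma$: defect
($<\mu-2\sigma$), low, two normal, two hyper bins. Defaults are
$\mu = 0.68$, $\sigma = 0.14$ (bias-corrected 2D images; 0.54/0.15 without
bias correction). VDP is the defect-bin percentage only; low ventilation is
reported separately.

**Hierarchical k-means.** Four 1D clusters on the in-lung intensities; the
lowest cluster is re-clustered into four; its lower two sub-clusters are
defect, the upper two hypointense. Initialization is deterministic (12.5,
37.5, 62.5, 87.5 intensity percentiles, Lloyd iterations), so results are
reproducible without a seed; degenerate empty clusters trigger up to ten
deterministic re-seeds on a shifted quantile grid.

**DDI.** The exact published formula for the defect distribution index is
not restated here; the package's documented stand-in assigns each defect
voxel $100\times$ the defect fraction of the lung voxels within a Chebyshev
neighbourhood (default radius 3 voxels; 2D restricts to the slice), averaged
over defect voxels. Compact defects score high, scattered ones low, and the
definition sits behind a small function so the published variant can be
swapped in.

**GLRLM texture.** In-mask intensities (normalized to [0, 1]) are quantized
to 32 gray levels; run-length matrices are accumulated along the in-slice
directions 0/45/90/135 degrees with runs truncated at the mask boundary, and
the standard eleven features (SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE,
SRHGE, LRLGE, LRHGE) are averaged over directions. On a checkerboard the
axis directions give SRE = 1; the diagonals of a checkerboard are
constant-valued, so diagonal runs are long — a property worth remembering
when interpreting direction-averaged features.

## Diffusion

With b-values in s/cm² (first always 0), the mono-exponential apparent
diffusion coefficient is the closed-form least-squares slope of $\ln S$ on
$b$ — implemented exactly in that form and verified against a generic linear
solver at 1e-10. Weighted least squares (weights $S_i^2$, the standard
log-transform noise weighting) and a grid-posterior Bayesian fit (Gaussian
likelihood, $S_0$ profiled, ADC grid 0–0.14 cm²/s at 5×10⁻⁴ resolution) are
alternatives; all three agree exactly in the two-point noiseless case.
Voxels with nonpositive signals or b0 signal below twice the noise floor are
invalidated individually, and ADC above 0.14 cm²/s (free diffusion of xenon
in air) is flagged invalid rather than reported.

The healthy reference is age-adjusted: $\mu = 0.0002\,\mathrm{age} + 0.029$
and $\sigma = 5\times10^{-5}\,\mathrm{age} + 0.0121$ cm²/s, both
user-overridable; binning reuses the six-bin ventilation code path verbatim.

Two morphometry models fit per voxel by bounded Levenberg–Marquardt:

- stretched exponential $S = S_0 e^{-(b\,\mathrm{DDC})^\alpha}$ with
  heterogeneity index $\alpha \in (0, 1]$; $\alpha = 1$ recovers the
  mono-exponential model exactly. The mean diffusive length scale uses the
  free-diffusion form $L_{mD} = \sqrt{2\,\mathrm{DDC}\,\Delta}$ (flagged on
  the result; the published empirical mapping can be supplied as a
  function).
- orientation-averaged cylinder model
  $S = S_0 e^{-b D_T}\sqrt{\pi/(4 b D_{AN})}\,\mathrm{erf}(\sqrt{b D_{AN}})$
  with $D_{AN} = D_L - D_T$; the $b D_{AN} \to 0$ singularity is removable
  ($1 - bD_{AN}/3$) so isotropic voxels fit without failure. Geometric
  outputs (duct radius, sleeve depth, mean linear intercept, S/V, alveolar
  density) require published empirical inversion coefficients that are not
  transcribed here; the `geometry_fn` hook accepts one and ships disabled.

## Gas exchange (1-point Dixon)

Interleaved 3D radial gas and dissolved acquisitions are reconstructed by
Kaiser–Bessel gridding (kernel width 4, oversampling 2, Beatty kernel
parameter) with Pipe-style iterative density compensation, FFT,
deapodization, and cropping; absolute intensity is anchored by matching the
image sum to the measured k-centre sample. Radial sampling covers the
inscribed k-space ball, not the full cube — a point source reconstructs with
peak amplitude $\pi/6$ of its DC sum, and the test oracle compares energies
against a ball-limited direct FFT of the truth image for that reason.

Separation proceeds in a fixed order: (1) the gas-image phase
(single resonance, hence a pure B0 map) is subtracted voxelwise from the
dissolved phase; (2) a global phase $\phi_0$ is found by 1D root bracketing
on $(-180, 180]$ so that the ratio of summed real to summed imaginary parts
over the lung matches the spectroscopic RBC:membrane ratio — sign changes
across the poles of the ratio function are rejected by a residual check, and
the root of smallest $|\phi_0|$ is taken; (3) RBC is the real part, membrane
the imaginary part; (4) residual negative signal is zeroed and its magnitude
reported. One subtlety: spectroscopy reports t = 0 amplitudes while the
image is acquired at TE90, so the matching target is decay-adjusted by
$e^{-\mathrm{TE90}/T_2^{*\mathrm{RBC}}}/e^{-\mathrm{TE90}/T_2^{*\mathrm{mem}}}$;
this makes noiseless phantom recovery exact.

Corrections then divide each channel by $e^{-\mathrm{TE90}/T_2^*}$, scale
the gas image by $\sin 20^\circ/\sin 0.5^\circ \approx 39$, form RBC:gas and
membrane:gas ratio maps, and normalize the gas image by its 99th percentile
for the ventilation channel. Binning uses six bins for gas, dissolved and
RBC and eight for membrane (extra bins at $\mu+3\sigma$, $\mu+4\sigma$ for
its elongated tail); the default healthy references are gas 0.51 ± 0.19,
dissolved 0.0075 ± 0.00125, membrane 0.0049 ± 0.0015, RBC 0.0026 ± 0.001,
RBC/membrane 0.53 ± 0.18, RBC oscillations 8.96 ± 10.56. RBC-oscillation
maps are not computed (no published method restated here), but imported
oscillation maps can be binned against their reference entry.

## Synthetic phantoms

Every stage is testable without data downloads:

- **Calibration FIDs** — gas block follows the cosine-depletion law exactly
  (that is the model the flip fit inverts); the dissolved block holds a
  steady amplitude with an early transient (decay constant 25 excitations)
  emulating downstream-vasculature signal, which is what the 100-FID discard
  removes. Dissolved magnetization is replenished from the alveolar gas
  reservoir each TR, so a cosine decay across 500 dissolved excitations
  would be unphysical and would bury the averaged signal under any noise.
- **Ventilation** — two ellipsoidal lungs with a mediastinal gap and a
  bright tracheal tube (1.6× parenchyma, exercising airway removal),
  spherical defects with exact voxel counts, an optional quadratic
  multiplicative bias field, and complex Gaussian noise scaled so the
  magnitude-image SNR hits a target (the background is then Rayleigh, making
  the SNR correction exercisable).
- **Diffusion** — mono- or stretched-exponential decay from a known ADC/DDC
  map over b-values {0, 7.5, 15, 22.5, 30} s/cm² (a configurable
  placeholder protocol; no canonical table is restated here).
- **Gas exchange** — complex gas and dissolved volumes composed from known
  RBC/membrane/gas maps with RBC on the real axis, membrane at 90 degrees,
  per-channel T2* decay at TE90, a shared B0 phase map, and optional complex
  noise; a forward projector samples the DFT along spherical-Fibonacci
  radial spokes to produce raw k-space for the reconstruction path.

Phantoms are bit-identical under a fixed seed. They emulate signal models
and noise statistics, not anatomy: no real airway trees, vascular
structures, partial-volume mixtures, coil-array sensitivities or motion.
Passing phantom tests therefore validates the estimators against their own
generative models and stated invariants; it does not certify accuracy on
in-vivo data.

## Numerical choices and problem sizes

Nonlinear fits use Levenberg–Marquardt with analytic-free residuals,
bounded where physical ($\alpha \le 1$, diffusivities in [0, 0.14] cm²/s),
tight tolerances (1e-15 on the dissolved fit, which operates near machine
precision on noiseless data), and data-driven starts (log-linear slopes,
spectral peak picking). The Dixon $\phi_0$ search brackets on a 0.5-degree
grid before root polishing; exact grid zeros are accepted directly. Test
problem sizes are kept small by design — 16³–32³ gas-exchange volumes with
700–1200 spokes, 24³–64³ ventilation/diffusion volumes, 100-seed
Monte-Carlo loops — chosen so the full suite completes in well under a
minute while still exercising every code path at meaningful SNR.

## Known limitations

- Registration to anatomical images is a hook (supply a pre-computed
  transform); no registration optimizer ships in the package.
- CNN segmentation, BM3D denoising and vendor-proprietary raw formats are
  out of scope; the latter attach through `register_raw_reader()`.
- The DDI formula and the membrane eight-bin edge placement are documented
  stand-ins behind swappable interfaces, as is the morphometry geometry
  extraction.
- The reconstruction normalization assumes center-out spokes (k = 0
  sampled); pure ring or shifted trajectories would need a different
  anchor.
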