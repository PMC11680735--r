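# xepipe

Quantitative analysis of hyperpolarized xenon-129 lung MRI in R.

Hyperpolarized ¹²⁹Xe is an inhaled contrast gas whose non-renewable
magnetization is consumed by every RF pulse, and which dissolves into lung
tissue with distinct chemical shifts for membrane (≈198 ppm) and red blood
cells (≈217 ppm). This enables three exams — **ventilation** (where does the
gas go), **diffusion** (how large are the airspaces) and **gas exchange**
(how well does xenon reach the blood) — each needing dedicated image
processing. `xepipe` implements the full chain for all three, for imaging
scientists and physicists who need scriptable, reproducible analysis:

- **Calibration spectroscopy** — flip-angle scale factor from the cosine
  depletion law `S_i = S0·cos(α)^(i−1) + C`, gas frequency offset,
  three-peak complex-Lorentzian dissolved fit (RBC:membrane ratio, T2* =
  1000/(π·FWHM) ms), the Dixon echo time
  `TE90 = TE + (90 − Δφ)/(360·Δf)`, and optimal flip angles per sequence.
- **Segmentation** — Otsu lung masks, airway removal, lung volumes.
- **Ventilation** — Rayleigh-corrected SNR (`σ_BG² = σ_M²/(2 − π/2)`),
  polynomial bias correction, three ventilation-defect-percentage (VDP)
  algorithms (60%-of-mean threshold with median-filter cleanup, six-bin
  linear binning against a healthy reference μ ± kσ, hierarchical k-means),
  defect distribution index (2D/3D) and gray-level run-length texture.
- **Diffusion** — ADC maps (closed-form log-linear, weighted, Bayesian),
  age-adjusted reference binning (μ = 0.0002·age + 0.029 cm²/s), and
  stretched-exponential / cylinder morphometry models.
- **Gas exchange** — 3D radial Kaiser–Bessel reconstruction, 1-point Dixon
  separation of RBC and membrane with B0 correction, T2* and
  flip-angle (sin 20°/sin 0.5° ≈ 39) corrections, generalized linear
  binning (six bins; eight for membrane).
- **Synthetic phantoms** for every stage, with exact ground truth — the
  entire pipeline is testable offline.

I/O covers NIfTI (via RNifti), DICOM series, an MRD-style HDF5 raw
container (via rhdf5), JSON/CSV metrics export, and a plugin hook for
vendor raw formats.

## Worked example

Calibrate from a synthetic FID train (true flip 20°, prescribed 25°, gas
offset 62 Hz, RBC:membrane 0.53), then quantify a ventilation phantom with a
257-voxel defect at SNR 30:

```r
library(xepipe)

cal_ph <- make_calibration_fids(true_flip_deg = 20, gas_freq_offset_hz = 62,
                                noise_sigma = 0.002, seed = 1)
cal <- run_calibration(cal_ph$raw, prescribed_flip_deg = 25)
print(cal)
#> <calibration_result>
#>   flip: 20.14 deg fitted / 25.00 prescribed (scale 1.2412)
#>   gas frequency offset: 62.01 Hz
#>   RBC:membrane = 0.530; TE90 = 0.643 ms (TE 0.450, TR 15.0)
#>   optimal flip [ventilation]: 7.96 deg
#>   optimal flip [gas_exchange]: 0.5/20 deg

vent <- make_ventilation_phantom(
  defect_spec = list(list(center = c(20, 35, 6), radius = 4,
                          intensity_frac = 0)),
  snr_target = 30, seed = 1)
res <- run_ventilation(vent$vol, vent$mask, seed = 1)
print(res)
#> <ventilation_result>
#>   VDP [threshold]: 2.48 %
#>   VDP [linbin]: 2.54 %
#>   VDP [kmeans]: 1.44 %
#>   TLV 1366.7 mL, VV 1332.9 mL, SNR 29.9
#>   DDI 2D 52.5 +/- 13.2, 3D 44.4 +/- 9.7
```

The fitted flip angle (20.14°) recovers the simulated 20° within noise; the
scale factor 25/20.14 = 1.24 is what would rescale future prescriptions.
TE90 = 0.643 ms is the echo time at which the RBC and membrane resonances
reach 90° phase separation, given the fitted phase difference (45°) and
frequency split (19 ppm). The three VDP values bracket the ground truth of
2.54% defect volume (257 of 10 124 lung voxels); the measured SNR of 29.9
confirms the phantom's target of 30; the high DDI marks the defect as one
compact cluster rather than scattered voxels.

Everything is also drivable from the shell via the thin CLI:

```sh
Rscript inst/cli/xepipe.R phantom --scenario ventilation --snr 30 --out ph
Rscript inst/cli/xepipe.R ventilation --image ph/ventilation.nii.gz \
    --mask ph/mask.nii.gz --ref 0.68,0.14 --out results
```

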