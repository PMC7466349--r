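---
title: "Quantifying total 5-alkylresorcinols in cereal products by 1H qNMR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying total 5-alkylresorcinols by 1H qNMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arsqnmr)
```

## The assay

5-Alkylresorcinols (ARS) are phenolic lipids of the bran of wheat and rye —
1,3-dihydroxy-5-*n*-alkylbenzenes with odd-numbered side chains, dominated by
the C19 and C21 homologs. They are a practical marker of whole-grain content:
abundant in whole-grain flours of old wheat varieties and rye, essentially
absent from refined white flour. In DMSO-d6 the three aromatic protons
(H-2,4,6) of the whole homolog family collapse into a single singlet at
6.00 ppm, in a region free of matrix signals, which makes a direct
internal-standard qNMR assay possible: extract ~330 mg of flour in 1 mL of
DMSO-d6 containing 0.5 mg of syringaldehyde, record a one-pulse 1H spectrum,
and compare the 6.00 ppm integral with the syringaldehyde aldehyde singlet
at 9.79 ppm, whose integral is set to 1.

The concentration follows from the molar ratio between analyte and internal
standard (IS):

$$C \;=\; \frac{(I_{ARS}/3)\; \cdot\; \mathrm{mmol}_{IS}}{M_{sample}}$$

with $I_{ARS}$ the normalized 3-proton integral, $\mathrm{mmol}_{IS} =
0.00270$ for 0.5 mg of syringaldehyde, and $M_{sample} = 330$ mg. The
division by 3 converts the 3-proton integral to a per-mole quantity against
the 1-proton aldehyde reference; this 1-proton reading of the IS integral is
what makes the formula dimensionally coherent, and is made explicit in
`concentration()`. Conversion to mass units uses the average molecular
weight of the dominant homologs, $MW_{avg} = (376 + 404)/2 = 390$ g/mol
(C19 and C21; the arithmetic mean is our reading of "average"). Reported
values are rounded to whole mg/Kg and two-decimal mmol/Kg.

Two constants deserve a note. The protocol constant 0.00270 mmol is used as
the default IS amount even though 0.5 mg / 182.17 g/mol = 0.002745 mmol; the
package reproduces the assay as printed, and `ars_constants(use_true_is_mw =
TRUE)` switches to the exact value (a uniform +1.7% rescaling of every
concentration). And of the published concentration table, two rows are
internally inconsistent with the MW-390 conversion (the *T. aestivum*
whole-grain flour row, and a rounding-direction edge on the *T. dicoccum*
grain row); `published_presets()` flags them via `conversion_exact` and they
are excluded from exact conversion checks rather than reconciled.

## What the simulator emulates

Because no spectra are deposited with the assay, the package ships a
generator (`synthesize_fid()`, `simulate_sample()`) that emulates the
measurement physically rather than statistically:

- **Lineshape.** Each resonance is a decaying complex exponential at the
  offset implied by its shift; its Fourier transform is a Lorentzian of
  natural width $1/(\pi T_2)$. Default $T_2 = 1/\pi$ s gives 1.0 Hz —
  a sharp singlet, matching the resolved aromatic singlet of the assay.
  J-coupling, 13C satellites and solvent suppression are deliberately out
  of scope: the DMSO singlet convention makes the ARS signal a singlet.
- **Saturation.** Amplitudes scale with $n_{protons} \times \mathrm{mmol}
  \times (1 - e^{-(d_1 + aq)/T_1})$. Default $T_1$ values are 1.2 s (ARS
  aromatic protons) and 2.5 s (aldehyde proton), chosen so the
  relaxation-delay ladder 1, 2, 5, 8, 10, 15, 20 s visibly converges at the
  protocol's 10 s: `delay_sweep()` reports 10 s as the first delay from
  which the ARS/IS ratio changes by less than the 0.5% tolerance (our
  quantitative reading of a ratio that "remains unchanged"; see
  `analysis/04_validate.R` for the computed ladder).
- **Scan accumulation.** Independent white Gaussian noise is added to both
  channels of each scan and the scans are summed, so spectral S/N grows as
  $\sqrt{n_{scans}}$. No $t_1$-noise, drift or lineshape error is modeled —
  the simplest model consistent with the validation statistics.
- **Extraction.** A single-pool model: cycle $k$ recovers
  $\eta(1-\eta)^{k-1}$ of the total, with per-cycle efficiency $\eta = 0.96$
  so that one ultrasonic DMSO extraction recovers >95% and further cycles
  add <5%, as the wet protocol reports.
- **Matrix.** Carbohydrate-envelope peaks confined to 3.0–5.5 ppm plus the
  residual DMSO line at 2.50 ppm (the calibration reference) encode the
  empirical cleanliness of the 6.00 ppm region in DMSO-d6 extracts; an
  optional adversarial peak at 6.3 ppm exercises integration-window
  discipline.

The acquisition defaults are the protocol's printed constants: 400 MHz,
5263.18 Hz sweep, 32 K real+imaginary points (so the complex FID holds
16384 points and $aq = td/(2 \cdot sw) = 3.11$ s, FID resolution
$1/aq = 0.32$ Hz), $d_1 = 10$ s, 16 scans, 298 K, 90° pulse. The printed
sweep of 5263.18 Hz is taken as authoritative and the ppm extent derived
from it (13 ppm × 400 MHz would give 5200 Hz); the carrier sits at 6.5 ppm
before calibration refines the axis.

**Noise level.** The per-scan noise sd (5.7e-4 amplitude units,
`default_noise_sigma()`) is calibrated once so that a 45 mg/Kg sample —
the assay's quantification limit — measures S/N ≈ 10 under the default
acquisition and the declared S/N convention. This couples the synthetic
noise floor to the assay's stated LOQ and is not adjusted per analysis.

What passing tests therefore show — and do not show: the pipeline recovers
known concentrations under ideal Lorentzian lineshapes, white noise and a
clean 6.00 ppm window. Real flour extracts add shimming imperfections,
baseline roll, temperature-dependent shifts and possible trace overlap that
the generator does not emulate, so the parameter-recovery results bound the
data-processing error of the method, not its full analytical error.

## Processing chain

`process_fid()` applies, in order, each step appending one provenance entry
to the processing log:

1. **Apodization**: exponential weighting $e^{-\pi \cdot lb \cdot t}$ with
   $lb = 0.3$ Hz, adding 0.3 Hz to each linewidth while preserving areas.
2. **Zero filling** (factor 2, power-of-two enforced): interpolation only.
3. **Fourier transform**, scaled by the dwell time with the first point
   halved, so window integrals approximate continuous-transform Lorentzian
   areas; axis in descending ppm.
4. **Phasing**: the protocol phases automatically, then manually. Both
   paths exist: exact manual angles via `phase_params()`, and an automatic
   mode minimizing squared negativity of the real trace plus a small
   (1e-4-weighted) entropy penalty on its derivative, by a 5° zero-order
   grid on a decimated trace followed by Nelder–Mead refinement of both
   orders. Non-convergence applies the best candidate and flags the log —
   never silent. Simulated FIDs emerge in absorption mode, so batch
   analyses default to the exact zero correction and the automatic phaser
   is exercised where a phase error actually exists.
5. **Baseline**: polynomial (default cubic) fitted on signal-free anchor
   windows and subtracted. The anchors default to four windows bracketing
   the analyte region (12.5–11.5, 9.3–8.3, 7.5–6.6, 2.0–0.5 ppm). Anchoring
   only the spectrum edges was rejected: a cubic interpolated across 10 ppm
   from edge anchors is ill-conditioned mid-spectrum and measurably
   amplified replicate scatter at the analyte windows about sevenfold.
   Anchors overlapping an integration window raise an error.
6. **Calibration**: the axis is shifted so the residual DMSO line sits at
   2.50 ppm; the reference peak must clear 5× the noise RMS and be a major
   line (>0.1% of the global maximum).

## Quantification and detection

Integration is a plain trapezoid on the real trace over (high, low) ppm
windows, centered at 6.00 and 9.79 ppm with 0.10 ppm half-width (the
protocol gives only the centers); both windows share the lineshape, so the
~1% Lorentzian tail outside each window cancels in the ratio. The IS
window must contain a usable reference — positive area, above 3× the
noise-equivalent area, and a peak height that is not mere tail leakage —
otherwise quantification aborts with a named error.

S/N is peak height over twice the noise RMS of a signal-free region
(11.4–10.4 ppm), the common instrument-software convention, configurable
via `rms_factor`. A noise region indistinguishable from zero (below 1e-5 of
the spectrum maximum, far beyond any real dynamic range) returns the `Inf`
sentinel. Detection calls use inclusive thresholds: S/N < 3 is ND,
3 ≤ S/N < 10 detected-but-below-LOQ, ≥ 10 quantified.

`lod_loq()` extrapolates detection limits by linear S/N scaling, so
LOQ/LOD = 10/3 pre-rounding by construction. Note that the assay's printed
absolute limits (15 μg and 10 μg per 330 mg portion, i.e. 45 and 30 mg/Kg)
have a 1.5 ratio and are therefore mutually inconsistent with linear S/N
scaling; the package reproduces the printed pair through the exact
μg ↔ mg/Kg conversions (`ug_to_mg_per_kg()`, `mg_per_kg_to_ug()`) and
reports S/N-scaled estimates separately, labeled as such.

## Validation studies

- `recovery_study()` quantifies each extraction cycle separately and
  normalizes by the summed concentration — the model-free estimate used
  when recovery is judged from successive extractions. Cumulative recovery
  is reported from the fitted first-cycle efficiency as
  $1-(1-\hat\eta)^{cycles}$.
- `precision_study()` runs `replicates × days` independent measurements;
  interday variation is a deterministic per-day multiplicative factor drawn
  uniformly from ±2% under the study seed (the protocol reports no
  day-effect model; the amplitude is configurable and logged). %RSD is
  100·sd/mean within day (averaged over days) and across all measurements.
  A sample below the LOQ raises an error: precision is undefined under the
  method.
- `delay_sweep()` runs noise-free, since it characterizes saturation, not
  noise.

## Numerical choices and degenerate inputs

Seeds are mandatory everywhere randomness exists (`sample_spec`,
`synthesize_fid`); there is no hidden global RNG state, and identical
config + seed yields byte-identical report files. Resonances outside the
sweep window are rejected rather than aliased. Zero-amount resonances are
dropped from synthesis; an all-zero FID transforms to an all-zero spectrum;
an empty FID is an error. Windows are always (high ppm, low ppm), matching
the descending display axis. Boundary S/N exactly at a threshold takes the
higher category. Negative integrals (pure-noise windows) are clamped to
zero before the concentration formula.

Problem sizes: the examples and tests run the full 32 K-point acquisition
for everything quantitative, and an 8 K-point variant inside Monte-Carlo
loops (20 seeds per property) where only relative behavior is measured.

## Known limitations

- No per-homolog resolution: the method measures total ARS and cannot
  determine side-chain length; the package inherits this deliberately.
- Near the quantification limit the replicate scatter of the ±0.10 ppm
  trapezoidal integral is large: at the calibrated noise floor a 63 mg/Kg
  sample (S/N ≈ 14) shows ~16% per-measurement RSD — apodization correlates
  neighboring frequency points, inflating integral noise ~3.7× over the
  white-noise estimate — so a 10-replicate mean still carries ~5% standard
  error. Concentration estimates within a few multiples of the LOQ should
  be read with that uncertainty in mind; well above the LOQ (≥ 120 mg/Kg)
  replicate RSD falls below ~8% and the pipeline recovers preset
  concentrations to within a few percent.
- The automatic phaser assumes a spectrum with dominant positive absorption
  peaks; spectra that are mostly baseline can converge to the flagged
  best-candidate path.
- JCAMP-DX support covers the package's own 1D NTUPLES/AFFN dialect (two
  pages, real and imaginary); compressed (DIFDUP/SQZ) vendor files are not
  parsed.
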