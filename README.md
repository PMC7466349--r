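# arsqnmr

Internal-standard ¹H qNMR quantification of total 5-alkylresorcinols (ARS)
in flour, grain and baked products — as a fully simulated, tested pipeline.

ARS are phenolic lipids of wheat and rye bran (1,3-dihydroxy-5-*n*-
alkylbenzenes, mainly C19/C21 side chains) used as whole-grain markers. In
DMSO-d6 extracts their three aromatic protons collapse into one singlet at
6.00 ppm in a matrix-free region, so total ARS can be measured in a single
one-pulse ¹H experiment against a syringaldehyde internal standard (IS,
aldehyde singlet at 9.79 ppm, integral set to 1):

    C = (I_ARS / 3) · mmol_IS / M_sample        [mmol per mg]

with mmol_IS = 0.00270 (0.5 mg syringaldehyde) and M_sample = 330 mg;
mass units via the average C19/C21 molecular weight, MW_avg = 390 g/mol.
Detection calls use S/N thresholds: ≥ 10 quantified, ≥ 3 detected (below
LOQ), otherwise ND.

The package provides:

- `spin_sim` layer — a physical simulator of the measurement
  (`sample_spec()`, `synthesize_fid()`, `simulate_sample()`): Lorentzian
  lines with T1 saturation and T2 decay, per-scan Gaussian noise summed
  over scans, a per-cycle extraction-efficiency model, and presets for the
  published flour/grain/product panel (`published_presets()`).
- processing — `apodize()`, `zero_fill()`, `fourier_transform()`,
  `phase()` (automatic negativity+entropy minimization or exact manual
  angles), `baseline_correct()`, `calibrate_ppm()`, chained by
  `process_fid()`, with a full provenance log on every spectrum.
- quantification — `integrate_spectrum()`, `concentration()`,
  `to_mg_per_kg()`, `snr()`, `detection_call()`, wrapped by
  `quantify_sample()` / `quantify_report()`.
- validation — `recovery_study()`, `precision_study()`, `lod_loq()`,
  `delay_sweep()`, aggregated by `validation_report()`.
- I/O — 1D JCAMP-DX read/write (`read_jcamp()`, `write_jcamp()`), flat
  key=value run configuration (`run_config()`), CSV reports with
  provenance headers.

## Worked example

```r
library(arsqnmr)

s <- preset_sample("t_monococcum_wholegrain", seed = 1)  # 638 mg/Kg einkorn flour
fid  <- simulate_sample(s)                    # 16384 complex points, 16 scans
spec <- process_fid(fid, phase_with = "auto") # 0.3 Hz LB, zf, FT, phase, baseline, calibrate
quantify_spectrum(spec)
#> total ARS: 653 mg/Kg (1.67 mmol/Kg)   [i_ars=0.6138, S/N=142.3, quantified]
```

The normalized 6.00 ppm integral (`i_ars` ≈ 0.61 for this sample) feeds the
formula above: 653 mg/Kg against the preset's 638 mg/Kg, within the
replicate scatter at this noise level (S/N ≈ 142). Noise-free, the pipeline
returns 641 mg/Kg (+0.5%, the residual IS saturation bias at d1 = 10 s).
An ARS-free white-flour sample comes back as ND:

```r
quantify_sample(preset_sample("t_aestivum_white", seed = 2))$status
#> [1] "nd"
```

## Analysis workflow

The `analysis/` scripts run the whole study over the simulated panel and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # FIDs as JCAMP-DX + sample manifest
Rscript analysis/02_process.R    # processing chain, logs serialized
Rscript analysis/03_quantify.R   # per-sample report CSV with ND flags
Rscript analysis/04_validate.R   # recovery, %RSD, LOD/LOQ, delay sweep
Rscript analysis/05_report.R     # published-table-style summary
```

`04_validate.R` prints, for a 638 mg/Kg whole-grain sample: recovery by
cycle 0.962 / 0.038 / 0.001, intraday %RSD 0.97, interday 1.99, and a
relaxation-delay sweep converging at 10 s. `05_report.R` reproduces every
quantifiable preset within 0.5% (noise-free) and calls both white-flour
matrices ND.

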