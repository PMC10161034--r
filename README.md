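# adipoCT

**How low can the radiation dose of an abdominal CT go before automated fat
quantification stops being trustworthy?**

adipoCT is an R package for radiology physics and body-composition
researchers. It implements, end to end, the procedure for determining the
lower dose limit of automated subcutaneous (SAT) and visceral (VAT) adipose
tissue measurement: a synthetic abdominal phantom cohort with ground-truth
fat masks and dose-dependent noise, SSDE dosimetry, a Hounsfield-window fat
segmenter with a classical denoiser, fat-volume statistics, and a native
Mann-Whitney testing ladder that derives an acceptable-accuracy threshold
and the dose limit per compartment.

## The model in brief

* Fat is quantified as the **fat volume per unit scan length**
  `Vu = mean(S_i)` (mean per-slice fat area, mm^3/mm), which is invariant to
  slice interval and scan-length differences; accuracy against ground truth
  is `(1 - |V_true - V_meas| / V_true) * 100%`.
* Dose is expressed as the **size-specific dose estimate**
  `SSDE = CTDIvol * f(AP + LAT)` (AAPM 204 convention, 32-cm phantom) and
  normalised across slice thicknesses as `SSDE_5.25 = SSDE * T / 5.25`,
  because image noise scales as `1 / sqrt(SSDE * T)`.
* The **acceptable accuracy** per compartment is the mean repeat-scan
  accuracy attainable under positioning differences alone (derived from
  ground-truth-vs-ground-truth comparisons after truncation/interval
  confounder screens and 3-sigma outlier exclusion).
* Automated measurements are binned on `SSDE_5.25` and tested one-sided
  (Mann-Whitney, inferiority alternative) against the acceptable-accuracy
  reference sample; the **lower dose limit** is the lowest dose above which
  no bin shows inferiority, with a coarse-thickness fallback level when no
  fine bin qualifies. The effective dose at the limit is
  `SSDE * scan_length * 0.015` mSv.

See `vignettes/dose-limit-methods.Rmd` for assumptions, parameter defaults
and limitations.

## Worked example

```r
library(adipoCT)

# dosimetry of a low-dose scan of a 250 x 400 mm abdomen
dose_record(ap = 250, lat = 400, thickness = 1.25, ctdivol = 1.7)
#> <dose_record> CTDIvol 1.7 mGy, AP 250 + LAT 400 mm -> SSDE 1.91 mGy;
#>               T 1.25 mm -> SSDE_5.25 0.455 mGy

# a compact simulated dose-limit study (6 subjects, 3 doses, 2 thicknesses)
cfg <- study_config(
  cohort = cohort_spec(n_subjects = 6, dose_grid = c(1.5, 1.9, 2.3),
                       thickness_grid = c(1.25, 5.25),
                       geometry = volume_geometry(n_pixels = 240,
                                                  pixel_spacing = 2,
                                                  n_slices = 2)),
  output_dir = "demo_out", master_seed = 2026)
report <- run_study(cfg)
#> [simulate] cohort of 6 subject(s), 3 dose(s) x 2 thickness
#> [noise] ROI sigma: pre 0.00 HU, post 37.98 HU, denoised 12.63 HU
#> [segment] building accuracy records (denoiser: bilateral)
#> [stats] testing 156 accuracy records
#> [report] combined limit 1.5 mGy; effective dose 0.0225 mSv

report$dose_limits
#>  SAT  VAT
#> 1.50 0.35
compute_effective_dose(report$combined_limit, 16.8, 0.015)
#> [1] 0.378
```

Reading the output: without noise reduction, low-dose SAT segmentation is
not acceptably accurate at fine slice thickness, so the SAT limit comes
from the 5.25-mm denoised fallback at `SSDE_5.25 = 1.5` mGy; VAT passes its
fine-thickness bins down to the lowest tested edge. At a 16.8-cm scan, the
combined limit corresponds to an effective dose of about **0.38 mSv** -
roughly a hundredth of a routine abdominal CT. Per-bin means, p-values and
the full confounder screens are in `report$stats` and in the `stats.json` /
`accuracy.csv` artifacts written to `output_dir`.

## Command line

```sh
Rscript exec/adipoct dose ssde --ctdivol 1.7 --ap 250 --lat 400
Rscript exec/adipoct run --config study.yaml --seed 1 --out results_dir
Rscript exec/adipoct stats --accuracy results_dir/accuracy.csv --config study.yaml
```

Exit codes: 0 success, 2 configuration error, 3 stage failure.

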