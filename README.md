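# thalscreen

Haemoglobin-chain quantification from linear-mode MALDI-TOF blood spectra
and machine-learning screening for thalassaemia.

## What it is for

Thalassaemia is deficient synthesis of the α- or β-globin chain of
haemoglobin; its molecular hallmark is chain imbalance. Linear-mode
MALDI-TOF MS measures the intact chains directly: a species of neutral
average mass *M* with charge *z* appears at `m/z = (M + z·1.00728)/z`, so
α-, β-, γ-globin and a spiked myoglobin internal standard (IS, 16,952 Da)
give peaks at 1+ and 2+ between m/z 2,000 and 20,000. This package is for
analysts building or evaluating MS-based thalassaemia screening: it
implements the complete chain from raw two-column ASCII spectra to a
compared panel of classifiers, and a synthetic-cohort generator so the
whole pipeline is testable without patient data.

The stages:

- **specproc** — smoothing, SNIP baseline removal, SNR-based peak picking,
  one-point m/z recalibration on the IS, 3000 ppm peak matching,
  IS normalisation;
- **globin_features** — the 10 screening features per sample: normalised
  α, β, γ intensities at 1+/2+, plus α/β and α−β at each charge state;
- **screenmodels** — single-feature Mann–Whitney AUC ranking (top-5 or
  AUC-threshold selection), stratified 2:1 split, eight classifier
  families (RF, LR, SVM, KNN, DT, NB, AdaBoost, ANN), evaluation with
  DeLong 95% CIs, sensitivity/specificity/accuracy/precision and the
  confusion matrix;
- **reportstats** — Spearman feature–covariate correlations, PCA overview,
  β- vs non-β / α- vs non-α task groupings, end-to-end orchestration;
- **synthcohort / spectra_io** — seeded forward model of acquisitions
  (Gaussian peaks, exponential baseline, truncated noise, ppm drift,
  linked clinical covariates) and all on-disk formats (ASCII spectra,
  CSV manifests/feature tables, JSON reports, YAML configs).

## Worked example

```r
library(thalscreen)

panel <- globin_panel()
acq <- acquisition_model(noise_sd = 0.002, calibration_shift_ppm = 400)
sim <- simulate_spectrum(panel, default_profiles()$beta_thal, acq, seed = 42)
sim$spectrum
#> Spectrum S1: 18001 points, m/z 2000.0-20000.0, max intensity 1.81

proc <- process_spectrum(sim$spectrum, panel)
round(compute_features(proc$assignments), 3)
#>    alpha_1p     beta_1p    gamma_1p    alpha_2p     beta_2p    gamma_2p
#>       1.212       0.455       0.418       1.214       0.453       0.416
#> ratio_ab_1p ratio_ab_2p  diff_ab_1p  diff_ab_2p
#>       2.665       2.678       0.757       0.760
sim$record$truth_ratio_ab
#> [1] 2.669
```

The processed `ratio_ab_1p` (2.665) recovers the simulated true α/β
(2.669) through baseline, noise and a 400 ppm calibration drift: the β
deficit of this simulated β-thalassaemia sample roughly halves β-chain
output, pushing α/β far above the balanced control value of 1.

A whole two-cohort study (simulate → process → select on cohort-1 training
data → fit → evaluate on test and independent cohort-2 validation):

```r
cfg <- default_pipeline_config(
  n_cohort1 = c(control = 30, beta_thal = 20, alpha_thal = 10),
  n_cohort2 = c(control = 30, beta_thal = 20, alpha_thal = 10),
  methods = c("LR", "RF", "NB"))
res <- run_pipeline(cfg, seed = 7)
res$suites$thal_vs_control
#> Model suite on features: gamma_1p, gamma_2p, diff_ab_1p, diff_ab_2p, ratio_ab_1p
#>   LR       validation AUC 0.984 (0.953-1.000)  sens 0.967  spec 1.000
#>   RF       validation AUC 1.000 (1.000-1.000)  sens 1.000  spec 0.967
#>   NB       validation AUC 1.000 (1.000-1.000)  sens 1.000  spec 0.967
#> Best by validation AUC: RF
```

Selection lands on the γ-chain and imbalance features (γ rises and α/β
shifts when β output drops), and every family separates the synthetic
cases from controls on the held-out validation cohort.

A command-line interface wraps the same stages
(`simulate` / `process` / `pipeline`):

```sh
Rscript inst/cli/thalscreen.R pipeline \
  --config inst/extdata/demo_config.yaml --out run1 --seed 1
```

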