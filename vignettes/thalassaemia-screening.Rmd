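---
title: "Haemoglobin-chain quantification and thalassaemia screening from linear-mode MALDI-TOF spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haemoglobin-chain quantification and thalassaemia screening from linear-mode MALDI-TOF spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalscreen)
```

## The screening problem

Thalassaemia is caused by deficient synthesis of the α- or β-globin chain of
haemoglobin, so its molecular hallmark is *chain imbalance*: the molar ratio
of intact α- to β-globin in blood departs from the balanced value of healthy
carriers of `HBA`/`HBB` wild-type alleles. Linear-mode MALDI-TOF mass
spectrometry sees the intact chains directly — a protein of neutral average
mass $M$ carrying $z$ protons appears at

$$ m/z = \frac{M + z \cdot 1.00728}{z}, $$

so α-, β- and γ-globin and a spiked myoglobin internal standard (IS,
16,952 Da) each give peaks at charge 1+ and 2+ inside a 2,000–20,000 Th
acquisition window. `thalscreen` implements the full analysis chain from raw
two-column ASCII spectra to a compared panel of binary screening classifiers,
plus a synthetic-cohort generator so every stage is testable without patient
data.

## The processing model

Per spectrum, in order:

1. **Smoothing** — moving average (default window 7 points) or
   Savitzky–Golay; the method is not dictated by the underlying assay, so
   both sit behind one interface.
2. **Baseline removal** — SNIP iterative clipping (default 60 iterations)
   with the usual log–log–square-root compression. SNIP was chosen because
   the dominant linear-mode artefact is a smooth decaying chemical baseline,
   and SNIP handles it with a single, interpretable parameter (the clipping
   half-window in grid points). The decomposition is exact:
   `corrected + baseline = input`, `0 <= baseline <= input`.
3. **Peak picking** — local maxima with signal-to-noise at least `snr_min`
   (default 3). The noise scale is 1.4826 × the median absolute deviation of
   the detail residual (input minus a 21-point moving average; wider than
   the smoothing window, so residual noise survives into the estimate). The
   height entering the SNR is the apex *prominence* above a 101-point
   running median rather than the raw height: baseline estimation can leave
   a small positive floor, and raw heights measured from zero would promote
   noise maxima riding on that floor. On noise-free input the scale
   degenerates; a floor of $10^{-6}\times$ the maximum intensity then
   rejects numerical ripple while genuine peaks keep effectively infinite
   SNR. Peaks closer than `min_spacing` (10 Th) merge, keeping the taller.
4. **One-point m/z recalibration** — the picked peak closest in ppm to the
   IS 1+ reference (16,953.007 Th) defines a single multiplicative
   correction `mz_ref / mz_obs` applied to all peaks. One reference peak
   supports exactly one degree of freedom, hence a multiplicative (not
   affine) model. A sample with no IS candidate within the search window is
   flagged `calibration_failed`, never silently passed.
5. **Peak matching** — every (species, charge) slot takes its nearest
   candidate within 3000 ppm, greedily by ascending |ppm error|, one slot
   per peak; `ppm = (obs − ref)/ref × 10⁶`, signed.
6. **IS normalisation** — each globin intensity is divided by the IS peak
   *of the same charge state*, falling back to IS 1+ when IS 2+ is
   unmatched (flag `is2_fallback`). The assay description mentions only
   "the internal standard peak", so which charge state the original
   software divided by is unknowable; same-charge division is the default
   because it cancels charge-dependent peak-width and detection effects
   exactly (both numerator and denominator carry the same width), and
   `is_norm = "one_plus"` is available as the alternative reading.

## The ten features

Per sample: six normalised intensities (`alpha_1p`, `beta_1p`, `gamma_1p`,
`alpha_2p`, `beta_2p`, `gamma_2p`), the ratios `ratio_ab_1p/2p = α/β` and
the differences `diff_ab_1p/2p = α − β` per charge state. Features are used
on their natural scale (no log), a ratio is masked when its denominator slot
is missing or zero, and nothing is imputed — samples failing QC are dropped
with a logged count (median imputation exists as a switch for robustness
experiments only).

## Modelling protocol

Features are ranked by single-feature rank-based (Mann–Whitney) AUC with
tie correction; selection is either the top-k rule (k = 5 for the screening
task) or an AUC threshold (`auc_min = 0.85` for the β-genotype task). The
construction cohort is split 2:1 per class (nearest-integer 2/3 allocation);
eight classifier families are fitted on the training part and evaluated on
the training, test and independent validation tables: random forest (500
trees, `mtry = ⌊√p⌋`), logistic regression (plain maximum likelihood,
optional ridge), RBF SVM (C = 1, `gamma = 1/p`), KNN (k = 7), CART-style
decision tree (Gini, depth 10), Gaussian naive Bayes, AdaBoost on 100
decision stumps, and a one-hidden-layer neural network (5 tanh units,
weight decay 10⁻³). The original study fixed none of these hyperparameters,
so they are fixed, documented defaults here; every fit is seeded.
Distance-based families (SVM, KNN, ANN) standardise features with training
statistics only — selection and scaling never see test or validation data.

Evaluation reports AUC with a DeLong 95% CI (normal-theory interval from
the placement-value variance estimate, truncated to [0, 1] — chosen to
match the behaviour of the standard ROC packages), sensitivity,
specificity, accuracy, precision and the confusion matrix. The decision
threshold is 0.5 on the probability-like score by default; nothing in the
assay description fixes how continuous scores became a confusion matrix, so
0.5 is the only assumption-free choice, with a training-ROC Youden-point
option (`threshold = "youden"`).

## The synthetic world

`simulate_spectrum()` is a forward model of one acquisition: Gaussian peaks
(σ = 8 Th at 1+, halved at 2+ — linear-mode peaks are broad and roughly
symmetric, and time-of-flight width shrinks with charge) at the protonated
m/z of each species, amplitude equal to the drawn abundance (times a 2+
fraction, default 0.25), a decaying exponential baseline
$A e^{-m/z/\tau}$ (τ = 3000 Th; A defaults to 5× the median peak amplitude
at the low edge), additive Gaussian noise truncated at zero after
summation, and a multiplicative calibration drift in ppm. Abundances are
lognormal around class means with a stated between-sample CV (default 15%;
the draws have exact mean and CV). The class worlds: controls have α/β
expectation 1 and near-zero γ; β-thalassaemia halves β and re-expresses γ
(0.4); α-thalassaemia reduces α to 0.55; the compound class perturbs both.
Clinical covariates are Gaussian around class baselines with linear links —
γ abundance raises Hb F, α+β raises blood Hb — so only the *signs* of the
feature–covariate correlations are contracted, not magnitudes.

What the generator does **not** emulate: isotope structure, adducts and
matrix clusters, detector saturation, transfused donor haemoglobin, the
δ-chain (Hb A₂) and variant haemoglobins (Hb E, Hb Lepore). A green
end-to-end test therefore establishes that the pipeline recovers what this
stated world contains — chain imbalance under baseline, noise and drift —
and nothing about vendor-software equivalence or clinical performance.

## Numerical and design choices

- **Globin masses** (α 15126.4, β 15867.2, γ 15995.3 Da) are canonical
  human globin-sequence constants, config-overridable; no acceptance
  quantity depends on them because every check compares against the
  generator's own truth.
- **Degenerate inputs**: all-zero spectra yield an empty peak list (not an
  error); duplicate m/z values are averaged at load time; negative
  intensities are clipped to zero with a warning; single-class label
  vectors are hard errors for every AUC-bearing function.
- **Tie-breaks**: feature ranking breaks AUC ties by the canonical column
  order; peak merging keeps the taller peak.
- **The α-task world**: the directional check that the β-task outperforms
  the α-task uses a *weak-α* simulation (α reduced to 0.8 rather than the
  default 0.55), because the common mild deletional α genotypes reduce
  α-chain output far less than β⁰/β⁺ alleles reduce β output — that is the
  physiological reason the α task is harder. Both tasks use the same
  matched protocol (same cohorts, same split, top-5 selection, LR) so the
  comparison isolates the biology, not the selection rule.
- **Permutation null**: class labels are shuffled independently in the
  training, test and validation tables under fixed seeds, and the whole
  protocol (selection included) reruns, so the null AUC reflects the full
  pipeline's selection optimism, not just the classifier's.

## Limitations

Charge states above 2+ and overlapping variant peaks are out of scope; the
ASCII export dialect (whitespace-delimited, `#` comments) is this package's
assertion, not the instrument's; and the published cohort results depend on
unreleased patient spectra, so the acceptance checks here are property-based
(split arithmetic, printed confusion-matrix arithmetic, oracle equivalence,
recovery and directionality on the synthetic world) rather than re-derivations
of the clinical AUCs.
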