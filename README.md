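# ecgddd

ECG-based drunk-driving detection with correlation-weighted composite
kernels.

Alcohol intake leaves a measurable signature on the electrocardiogram:
the P wave flattens (−11.21%) and its duration disperses (+23.77%),
the R and S peaks grow (+19.54%, +8.14%), the R-R interval shortens
(−8.43%), and the maximal P duration lengthens (+9.07%).  `ecgddd` is
an R package for researchers in biomedical signal processing that
implements, end to end, a classifier built on those effects:

* **Synthetic cohorts** — annotated two-class ECG records (sum-of-five-
  Gaussians beat templates, subject-level variability, configurable
  noise), standing in for a paired sober/intoxicated volunteer study.
* **Preprocessing** — the Pan-Tompkins chain (5–15 Hz band-pass,
  five-point derivative, squaring, 150 ms moving-window integration,
  adaptive thresholds) with beat segmentation and corrupted-beat
  rejection.
* **Delineation** — P/Q/R/S/T peaks, amplitudes against a local
  isoelectric baseline, and 10%-threshold P-wave durations corrected
  for the smoother's broadening.
* **Features** — per 10-beat window: means and population variances of
  the P, R, S amplitudes and R-R intervals, plus Pmax and Pd.
* **Weighted kernels and SVM** — linear, quadratic, cubic-polynomial
  and radial-basis kernels, both "prime" and as composite kernels
  `K_c(x, y) = Σ_p c_p K_p(x_p, y_p)` with weights `c_p ∝ |cor(feature_p,
  label)|`, `Σ c_p = 1`; a sequential-minimal-optimization dual solver
  over precomputed Gram matrices.
* **Evaluation** — stratified (optionally group-aware) 10-fold
  cross-validation reporting accuracy, sensitivity and specificity,
  and the 8-way kernel comparison (K1a…K4b).

See the vignette (`vignettes/ecgddd-methods.Rmd`) for the model,
every tunable default, and known limitations.

## Worked example

```r
library(ecgddd)

# a small cohort: 4 subjects, one normal + one drunk 2-min record each
cfg  <- cohort_config(n_subjects = 4, seed = 42)
recs <- generate_cohort(cfg)

# preprocessing + delineation + 10-beat window features
ds <- build_dataset(recs, W = 10, stride = 1)
ds
#> <ddd_dataset> 783 windows x 10 features (class 0: 374, class 1: 409)

# drunk-vs-normal percent change of two features
m0 <- colMeans(ds$X[ds$y == 0, ]); m1 <- colMeans(ds$X[ds$y == 1, ])
round(100 * (m1 - m0) / m0, 2)[c("mean_R_amp", "Pd")]
#> mean_R_amp         Pd
#>      19.00      25.93

# cross-validate a weighted third-order polynomial kernel classifier
cross_validate(ds, kernel_spec("poly3", weighted = TRUE), k = 10,
               seed = 1)
#> <cv_report> 10-fold, weighted poly3 kernel: Acc 1.0000  Se 1.0000  Sp 1.0000
```

The R-amplitude shift recovered from the raw signal (+19.00%) matches
the +19.54% injected by the generator, and the recovered P-wave
dispersion shift (+25.93%) brackets the injected +23.77% (at four
subjects these estimates are noisy; the study-scale run below is the
definitive check).  On such a clean, overlapping-window cohort the
classes separate perfectly; the interesting comparisons are between
kernels — `compare_kernels(ds)` returns the 8-row table with the
best-by-accuracy variant flagged.

A thin command-line front end over the same functions ships in
`inst/cli/ecgddd.R`:

```sh
Rscript inst/cli/ecgddd.R all --config run.yaml
```

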