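# pastage

Staging tumor progression from ex vivo photoacoustic time-domain spectra.

When pulsed laser light excites tissue, absorbed energy launches ultrasonic
pressure transients that a piezoelectric detector records as a 1-D
time-domain trace. As a tumor advances, its changing biochemistry alters
those traces, so the stage of progression (control day 0 and days 5, 10, 15,
20 after induction in a xenograft model) can be read off the spectra by a
classifier. `pastage` implements that analysis end to end, for signal
processing researchers who want a reproducible, testable reference pipeline:

1. **Pre-processing** — detrending, polynomial baseline correction, optional
   background subtraction, max-absolute normalization, then selection of the
   0.27–0.6 ms region of interest (ROI) where between-stage variation is
   largest (858 samples at the 2.6 MHz sampling rate).
2. **Augmentation** — label-preserving amplitude rescaling with factors
   0.5, 1.0, …, 4.5, a 10-fold expansion of the dataset.
3. **Feature extraction** — a level-2 wavelet packet decomposition (WPD)
   with the Daubechies-6 mother wavelet under a periodized, exactly
   orthonormal filter bank. The level-2 approximation node AA2 = (2,0)
   captures >99% of signal energy and its 215 coefficients are the raw
   features.
4. **Feature selection** — greedy minimal-redundancy maximal-relevance
   (mRMR) ranking of AA2 coefficients by mutual information,
   `score(x) = I(x; y) − mean_{s ∈ S} I(x; s)`, keeping the top 10.
5. **Classification** — one-vs-one multi-class SVMs (RBF, polynomial and
   linear kernels; decision function `f(x) = Σ_j α_j y_j G(x, x_j) + b`)
   under 80/20 stratified hold-out repeated 10 times, reporting per-class
   sensitivity, one-vs-rest specificity and overall accuracy.

Because raw recordings of this kind are rarely public, the package ships a
seeded hierarchical generator of synthetic spectra
(`generate_spectra()`) that emulates the acquisition design — 5 groups × 5
tissues × 4 positions × 5 replicates = 500 traces of 5200 samples — with
class-dependent damped-sinusoid transients inside the ROI, tissue/position
random effects, baseline drift and white noise. Every stage is exercised
and benchmarked against it.

## Worked example

```r
library(pastage)

spectra <- generate_spectra(study_design(), class_templates(), seed = 1)
roi     <- pa_preprocess(spectra, roi = roi_window(0.27e-3, 0.6e-3))
all10   <- pa_augment(roi, augment_plan())          # 5000 rows
feats   <- extract_aa2_features(all10, wavelet = "db6", level = 2)
rank10  <- mrmr_rank(feats, k = 10)
fm      <- build_feature_matrix(feats, rank10, k = 10)
ho      <- repeated_holdout(fm, n_repeats = 10, seed = 1)

head(rank10, 3)
#>    rank feature coefficient  score
#> 1     1 aa2_027          27  0.996
#> 2     2 aa2_022          22 -0.361
#> 3     3 aa2_134         134 -0.397

glance(ho)
#>   kernel     best_accuracy mean_accuracy n_repeats
#> 1 rbf                 97.5          96.6        10
#> 2 polynomial          98.4          98.0        10
#> 3 linear              97.9          97.4        10
```

The ranking lists AA2 coefficient indices by selection order: the first
score is the plain relevance `I(x; y)` in nats and later scores are the
redundancy-penalized criterion at selection (negative once redundancy
outweighs relevance). `glance()` summarizes the repeated hold-out: on the
default synthetic data the polynomial kernel classifies best, with best-run
test accuracy 98.4% over the five stages. Per-class detail comes from
`report_table(ho)`:

```r
head(report_table(ho), 5)
#>   class kernel specificity sensitivity accuracy
#> 1 day0  rbf           99.8       100       97.5
#> 2 day10 rbf           99.9        96       97.5
#> 3 day15 rbf           99.4        95.5     97.5
#> 4 day20 rbf           98.1        97.5     97.5
#> 5 day5  rbf           99.8        98.5     97.5
```

Subband energy accounting for a single trace shows why AA2 is the feature
source (fractions of total energy per level-2 node):

```r
energy_distribution(wpd_decompose(roi$samples[[1]]))
#>   node  fraction
#> 1 2.0   0.999
#> 2 2.1   0.000272
#> 3 2.2   0.000169
#> 4 2.3   0.000207
```

`run_pipeline(pa_config(...), output_dir = "run1")` executes all of the
above from one configuration object and writes the spectra/feature/ranking
CSVs, per-repeat evaluation reports and a JSON manifest of seeds and
versions. `autoplot()` methods cover rankings, confusion matrices and
hold-out summaries; `plot_spectra()` and `plot_energy_distribution()` cover
traces and subbands.

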