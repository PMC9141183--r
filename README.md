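# eegfusion

Cross-subject recognition of emotional valence from multi-channel EEG, built
around three ideas: a broad hand-crafted feature battery, two-stage feature
selection (mutual information + sequential forward floating selection), and
multi-classifier probability fusion. Evaluation is subject-disjoint
throughout — hold-out by subject and leave-one-subject-out (LOSO) — because
the question the package answers is whether a valence classifier transfers to
people it has never seen, not whether it can memorize one person's EEG.

The intended users are affective-computing and neurophysiology researchers
working with DEAP-shaped data (per subject: trials × channels × samples at
128 Hz plus continuous self-report ratings), or anyone who wants a fully
reproducible, dependency-light reference implementation of this family of
pipelines. A synthetic generator produces data of the same shape with
controllable class-conditional band-power structure, so everything here runs
and is tested without any external dataset.

## The method

**Preprocessing.** Keep the last 40 s of each trial, cut into non-overlapping
10 s windows (1280 samples), reduce to a 15-electrode montage (AF3/4, F3/4,
F7/8, FP1/2, P7/8, T7/8, O1/2, CZ). Valence ratings binarize at 5:
`y = 1` iff rating > 5. Features are z-scored with parameters fitted on
training subjects only: `z = (x − μ) / σ`, σ in the population form.

**Features (249 per window).** Per channel: mean, population SD, mean
absolute first difference, mean absolute lag-2 difference (4 × 15); band
energies of alpha (8–14 Hz), beta (14–30 Hz), gamma (30–47 Hz) after
zero-phase order-4 Butterworth filtering (3 × 15); plus beta/alpha ratios on
F3, F4, AF3, AF4 (4), rational asymmetry `RASM = P_left / P_right` for
(F3, F4) and (AF3, AF4) in alpha and beta (4), summed broadband power of the
7 non-frontal channels (1), and nine nonlinear descriptors per channel
(9 × 15): sample entropy `−ln(A^m(r) / B^m(r))` and approximate entropy
`Φ^m(r) − Φ^(m+1)(r)` (m = 2, r = 0.2·SD), differential entropy
`½ ln(2πeσ²)`, wavelet entropy `−Σ p_j ln p_j` over a 5-level db4
decomposition, largest Lyapunov exponent (Rosenstein), Higuchi fractal
dimension, R/S Hurst exponent, and Hjorth mobility
`sqrt(var(ẋ)/var(x))` and complexity.

**Selection.** A mutual-information filter,
`I(X;Y) = Σ p(x,y) ln[p(x,y) / (p(x)p(y))]` over 10-quantile bins, keeps half
the features (249 → 124); SFFS with a 5-fold cross-validated KNN evaluator
then searches down to 65, alternating greedy additions with floating
removals. SFS, SBS, a correlation filter and PCA are available as
alternatives.

**Multi-classifier fusion.** KNN (k = 41), RBF-SVM (C = 0.7, γ = 0.015) and a
100-tree random forest are trained on the selected features; the class
probabilities of a fused subset (KNN+RF, KNN+SVM, RF+SVM or all three) are
summed into two weight features, cross-fitted on the training side to avoid
leakage, concatenated with the full 249-feature block, re-standardized and
passed to a final classifier.

**Metrics.** Accuracy, precision, recall, F1 (class 1 positive), per fold and
macro-averaged.

## Worked example

```r
library(eegfusion)

# 4 synthetic subjects, 6 trials each, with a +60% frontal beta effect
cfg <- synthetic_config(n_subjects = 4, n_trials = 6, seed = 42)
ft  <- synthetic_feature_table(cfg)   # trim 40 s, 10 s windows, 249 features
ft
#> <feature_table> 96 windows x 249 features, 4 subject(s)

# leave-one-subject-out: MI filter to half, top-20 by MI, KNN+RF fusion vs none
fold <- fold_config(mi_fraction = 0.5, target_dim = 20, selector = "mi",
                    variants = list(none = character(0),
                                    knn_rf = c("knn", "rf")),
                    finals = "rf", seed = 1)
report <- loso_cv(ft, fold)
report
#> <evaluation_report> protocol=loso, 4 fold(s)
#>  variant final  accuracy precision  recall        f1
#>   knn_rf    rf 0.6770833 0.7188853 0.59375 0.5645349
#>     none    rf 0.6458333 0.4569444 0.50000 0.4767157
```

Each of the 4 folds trains on 3 subjects (72 windows) and tests on the
held-out subject's 96/4 = 24 windows; the table shows macro averages over
folds. `none` is the random forest on the 20 selected features alone;
`knn_rf` adds the summed KNN and RF class probabilities as weight features
next to the full 249-feature block before the final forest — here worth about
3 accuracy points. (A warning about a zero-denominator precision in one fold
is expected at this tiny scale: one test subject gets no positive
predictions; the metric guards return 0.) At this size the run takes under a
minute; the packaged benchmark in `benchmark_configs()` (8 subjects × 12
trials, full MI+SFFS selection per fold) is the scale used by the acceptance
checks.

Real DEAP data can be used by converting each subject's container to the
structure `list(data = [40 × 32 × 8064], labels = [40 × 4])` saved as `.rds`
(`read_deap_recording()`), or to the plain-text portable dialect
(`write_recording_portable()` / `read_recording_portable()`).

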