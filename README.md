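# mircos

Two-class authentication of powdered plant material from Fourier-transform
mid-infrared (FT-MIR) spectra. The motivating problem is telling wild from
cultivated medicinal plant material (e.g. *Gastrodia elata*): the two share
every absorption band and differ only in band intensities, so the question
is whether chemometrics — or an image classifier over correlation maps —
can decide provenance from a 4000–450 cm⁻¹ fingerprint.

The package implements the complete workflow:

* **Synthetic data** — a two-class FT-MIR generator (Gaussian bands at the
  characteristic positions of a dried tuber powder; per-band class
  multipliers; multiplicative scatter, linear baseline, replicate scans,
  measurement noise), so the whole pipeline is testable although real
  provenance-labelled spectra of this kind are confidential.
* **Preprocessing** — SNV, MSC (with a frozen training reference),
  Savitzky–Golay smoothing/derivatives, and the nine named chains
  (RAW … SG+2D).
* **Splitting** — stratified Kennard–Stone maxmin selection with floor
  rounding (109 + 63 samples at 70% → 76 + 44 train / 33 + 19 test).
* **Chemometrics** — PCA; NIPALS PLS-DA with R²Y/Q²/RMSEE/RMSECV/RMSEP,
  stratified k-fold CV and a 200-round permutation test; RBF-SVM grid
  search over base-2 (c, g) grids.
* **2D correlation spectroscopy** — synchronous Φ = SᵀS/(m−1),
  asynchronous Ψ = SᵀNS/(m−1) with the Hilbert–Noda matrix
  N_jk = 1/π(k−j), integrated I = Φ∘Ψ; per-sample maps from each sample's
  replicate scans.
* **Imaging + CNN** — maps rendered as 3-D surface images (deterministic
  PNG), partitioned 84/36/52 into train/test/external-validation, and
  classified by a compact residual network (im2col/GEMM convolutions in
  RcppArmadillo, batch norm, Adam) scored with accuracy, sensitivity,
  specificity and effectivity (= Sen × Spe).

See `vignettes/mircos-methods.Rmd` for the models, conventions and design
decisions.

## Worked example

```r
library(mircos)

spectra <- generate_spectra(synthetic_config(seed = 1))
spectra
#> SpectraSet: 516 records (172 samples x 3 scans), 1776 points [4000..450 cm^-1]
#> cultivated       wild
#>        109         63

avg   <- average_replicates(spectra)
split <- stratified_split(avg, fraction = 0.7)
split
#> split_result (kennard_stone): 120 train / 52 test
#>         cultivated wild
#> n_train         76   44
#> n_test          33   19

train <- subset_samples(avg, split$train_ids)
test  <- subset_samples(avg, split$test_ids)
fit <- plsda_fit(train$absorbance, train$labels, n_components = 2)
ev  <- plsda_evaluate(fit, test$absorbance, test$labels)
#> PLS-DA (RAW): acc_train 100.0%  acc_test 100.0%  R2Y 0.993  Q2 0.992
#>               RMSEE 0.0414  RMSECV 0.0426  RMSEP 0.0269
ev$metrics
#> acc 1.0000  sen 1.0000  spe 1.0000  eff 1.0000
```

The training and test accuracies are fractions of correctly classified
samples under the argmax rule; R²Y/Q² are fit/cross-validated variance
fractions on the class-indicator scale (close to 1 = strong, stable
model); the RMS errors are on the same indicator scale. `sen` is the
wild-detection rate, `spe` the cultivated-detection rate, and
`eff = sen × spe`.

The image branch of the workflow:

```r
maps <- per_sample_maps(spectra, downsample = 16)   # 111 x 111 maps
ds <- build_image_dataset(maps, "images",
                          counts = c(train = 84, test = 36, ev = 52),
                          seed = 1, config = render_config(image_size = 64),
                          categories = "synchronous")
model <- train_classifier(ds, epochs = 46, seed = 1,
                          arch = resnet_spec(c(8, 16), 1), early_stop = TRUE)
evaluate_classifier(model, ds, "ev")$metrics
#> acc 1.0000  sen 1.0000  spe 1.0000  eff 1.0000
```

A full experiment (all preprocessing chains, PLS-DA + SVM + CNN, CSV/JSON
report) runs behind one configuration object:

```r
report <- run_experiment(experiment_config("tiny", seed = 1))
# or, from a shell:
#   Rscript inst/scripts/mircos-run.R --preset tiny --seed 1 --out out/
```

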