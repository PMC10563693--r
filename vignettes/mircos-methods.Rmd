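---
title: "Methods: FT-MIR two-class authentication with correlation-map imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FT-MIR two-class authentication with correlation-map imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wild-grown medicinal plant material (the motivating case is *Gastrodia
elata*, "TianMa") commands a much higher price than its cultivated
counterpart, and the two are essentially indistinguishable by eye once dried
and powdered. Fourier-transform mid-infrared (FT-MIR) spectroscopy over
4000–450 cm⁻¹ fingerprints the bulk composition (carbohydrates, proteins,
lipids, nucleic acids) of such powders quickly and non-destructively. The
two provenance classes share every absorption band — the chemistry is the
same — and differ only in band *intensities*, i.e. in the relative amounts
of the constituents. `mircos` implements, end to end, a workflow for
deciding the class of a sample from its spectrum:

1. spectral preprocessing (SNV, MSC, Savitzky–Golay smoothing/derivatives)
   and classical chemometrics — PCA for exploration, PLS-DA and RBF-SVM for
   classification, with permutation diagnostics;
2. generalized two-dimensional correlation spectroscopy (2D-COS): each
   sample's replicate scans are turned into synchronous, asynchronous and
   integrated correlation maps over the wavenumber × wavenumber plane;
3. the maps are rendered as three-dimensional surface images and classified
   by a compact residual convolutional network, scored with
   accuracy/sensitivity/specificity/effectivity.

Because real provenance-labelled spectra of this kind are rarely
distributable, the package ships a synthetic-data generator that emulates
the statistical structure such data sets have; every stage is tested
against it.

## The synthetic two-class generator

A clean class spectrum is a sum of Gaussian bands
$A_k m_{k,c}\exp\{-(\nu-\mu_k)^2/2\sigma_k^2\}$ at the positions a dried
tuber powder absorbs: 1014 cm⁻¹ (carbohydrate C–O/C–C/C–O–H), 1220 and
1240 cm⁻¹ (phosphodiester), a 1300–1500 cm⁻¹ CH₂/CH₃ composite, 1635 cm⁻¹
(amide I), 2800–3000 cm⁻¹ aliphatic C–H (2921 cm⁻¹ CH₂), and the broad
3276 cm⁻¹ O–H/N–H stretch. The two classes share all positions and widths;
they differ only through per-band multipliers $m_{k,c}$ — a pure absorbance
effect, which is what distinguishes wild from cultivated material in
practice. The default contrast multiplies a subset of bands by 1.5 for the
wild class; `contrast = 1` is an exact null.

Each record (one scan) is

$$x(\nu) = g\,s_c(\nu) + (a + b\nu) + j + \varepsilon(\nu),$$

with a multiplicative gain $g\sim U(0.95, 1.05)$, an additive linear
baseline ($a \sim U(\pm 0.02)$, $b \sim U(\pm 5\times10^{-6})$ per cm⁻¹),
a per-scan constant offset $j \sim N(0, 0.002)$ emulating repositioning
drift, and iid Gaussian noise with $\sigma = 0.01$ absorbance units — 1% of
the tallest band. Every sample is scanned `replicates = 3` times with
independent draws of all four distortions. The magnitudes were fixed once,
on the physical argument that for ATR spectra of re-packed powders the
dominant scan-to-scan effect is the multiplicative contact/gain change,
with baseline drift an order of magnitude smaller; they are all
configurable. The default design is 109 + 63 samples (cultivated + wild),
the sample sizes of the authentication study this workflow emulates, on a
4000–450 cm⁻¹ grid digitized at 2 cm⁻¹ (1776 points; the optical resolution
of such instruments is 4 cm⁻¹, and acquisition software typically digitizes
at half that).

What the generator deliberately does **not** model: heteroscedastic
detector noise, water-vapour/CO₂ lines, ATR penetration-depth dispersion,
peak shifts or width changes between classes, and between-sample
biological covariance beyond the class effect. Passing tests on this
generator therefore demonstrate that the pipeline recovers a multiplicative
band-intensity contrast under scatter, baseline and noise — not that it
would survive every artefact of real instruments.

## Preprocessing

* **SNV** — each record to mean 0, unit standard deviation (the $n-1$
  sample convention, so tests can be exact).
* **MSC** — ordinary least squares of each record on a reference spectrum,
  then inversion $(x-a)/b$; the reference defaults to the *training-set*
  mean and must be frozen before transforming held-out records
  (`msc_reference()`), which the pipeline does to avoid leakage. MSC
  exactly inverts affine distortions of its reference.
* **Savitzky–Golay** — window 15 points, polynomial order 3 throughout;
  `1D`/`2D` chains are the first/second SG derivatives, `SG` alone is
  smoothing. Derivatives are divided by the signed grid step, giving
  physical d/dν units independent of grid direction. Edge points come from
  the filter's one-sided startup rows, so polynomials up to the filter
  order are reproduced exactly everywhere. The filtering itself is
  delegated to `signal::sgolayfilt()`.

The nine named chains exposed by the pipeline are RAW, 1D, 2D, SNV, MSC,
SG, SNV+2D, MSC+2D, SG+2D, applied left to right. "Window 15 / order 3" is
our reading of the conventional "third-order" SG description: a
third-*derivative* filter is used by no chain, while a third-order
polynomial underlies all of them.

## Kennard–Stone splitting

`kennard_stone_select()` is the classical maxmin algorithm: start from the
two most distant records, then repeatedly add the record whose minimum
distance to the selected set is largest. Ties break to the lowest index
after canonical ordering by sample id, so selection is deterministic and
invariant to record shuffling; a brute-force greedy oracle validates it on
small instances. `stratified_split()` runs the algorithm per class on the
replicate-averaged raw spectra and takes `floor(0.7 × class size)` per
class for training. With 109 + 63 samples this yields 76 + 44 = 120
training and 33 + 19 = 52 test samples; floor rounding (rather than
ceiling) is what reproduces those counts. Distances are computed on raw
spectra because splitting precedes the choice of a preprocessing chain.

## Correlation maps

For a perturbation series stored as rows of $S$ ($m \times n$), the package
computes

* synchronous $\Phi = S^{\top}S/(m-1)$,
* asynchronous $\Psi = S^{\top} N S/(m-1)$ with the Hilbert–Noda matrix
  $N_{jk} = 1/\pi(k-j)$ off-diagonal and 0 on it,
* integrated $I = \Phi \circ \Psi$ (elementwise; the defining expression is
  written pointwise in $(\nu_1,\nu_2)$, so the elementwise reading is the
  faithful one).

`dynamic_spectra()` subtracts a reference (by default the series mean, the
convention that makes $\Phi$ a covariance and its diagonal the
per-wavenumber variance); invariants — symmetry of $\Phi$, antisymmetry and
zero diagonal of $\Psi$, quadratic scaling — are enforced by tests, along
with hand-computed $m=3$ examples.

**Per-sample maps.** One image per sample is needed for the CNN, and the
natural series for a sample is its $r = 3$ replicate scans. Which reference
to subtract is the one genuinely open design point, and we settled it
empirically on the generator:

* *within-sample mean-centering* leaves only scan-to-scan deviations; their
  dominant term is $\widehat{\mathrm{var}}(g)\,s_c \otimes s_c$, and the
  sample variance of three gains is a scaled $\chi^2_2$ variable that
  collapses to noise level for a few percent of samples — those samples'
  maps carry no class information at all;
* *global-mean deviation* is sign-blind: both classes deviate from the
  pooled mean along the same spectral direction with opposite signs, and
  the outer product erases the sign, making the two classes' maps nearly
  identical;
* *no centering* (applying the defining equations directly to raw
  intensities) gives $\Phi \approx \frac{m}{m-1}\bar{s}\otimes\bar{s}$ — a
  stable, composition-driven pattern whose normalized shape differs clearly
  between classes, while $\Psi$ then depends only on the small scan-to-scan
  differences and is nearly uninformative.

`per_sample_maps()` therefore defaults to `center = "none"`. This choice
also reproduces the empirical quality ordering reported for this family of
workflows — synchronous-map classifiers excel while asynchronous-map
classifiers hover at the majority-class baseline — which is exactly what a
raw-intensity construction predicts. `center = "mean"` and a
`mode = "deviation"` fallback (global-mean reference; synchronous-only when
$r = 1$) remain available.

Maps are computed on a decimated grid (`downsample`, default 4). The test
and acceptance runs decimate by 32 (56 × 56 maps): when surfaces are
rendered at 64 px, keeping the facet count near the pixel resolution avoids
aliasing the surface into moiré-like artefacts that destabilize the image
classifier.

## Rendering and the image data set

`render_surface()` draws a map as a perspective surface (`graphics::persp`)
viewed from elevation 30°, azimuth −60°, facets coloured by height with a
perceptually uniform palette, no axes or box, intensity autoscaled to the
map's own range. Per-map autoscaling makes images invariant to the
quadratic amplitude factor, which would otherwise leak the absolute
absorbance scale to the classifier; a fixed `zlim` is available for
ablation. PNG is the default format because its output is byte-identical
for identical inputs, which makes rendering determinism testable; JPEG is
supported. `build_image_dataset()` renders all categories, draws one
stratified random train/test/external-validation assignment per seed —
largest-remainder allocation keeps each class's share of every role within
one sample of exact proportionality — and writes a manifest. The reference
design partitions 172 samples as 84/36/52, giving 516 images over the
three categories.

## Chemometrics

**PCA** is the mean-centered SVD (`stats::prcomp`), reported as
explained-variance fractions.

**PLS-DA** is NIPALS PLS2 on centered spectra against centered one-column-
per-class indicators, with the argmax decision rule (equivalent to a 0.5
threshold in two-class coding). Reported metrics, all on the indicator
scale: cumulative $R^2Y = 1-\mathrm{RSS}/\mathrm{TSS}$;
$\mathrm{RMSEE}=\sqrt{\mathrm{RSS}/nq}$ on training residuals; $Q^2 =
1-\mathrm{PRESS}/\mathrm{TSS}$ and RMSECV from stratified k-fold
cross-validation (default 7 folds, deterministic cyclic assignment within
class) with a full per-fold refit; RMSEP on the test set. With as many
components as the data support, PLS fitted values coincide with least
squares on the indicators — a small-case oracle in the tests; an
independent implementation (`mixOmics::plsda`) cross-checks class
predictions. The component count can be fixed or grown while each added
component improves $Q^2$.

**Permutation test** (default 200 rounds): labels are permuted, the model
refitted with the same configuration, and each round's $R^2Y$/$Q^2$ plotted
against the absolute Pearson correlation between permuted and original
indicators, with the unpermuted model at correlation 1. Straight-line fits
give the intercepts; the model is flagged as overfitted when the $Q^2$
intercept is nonnegative or any permutation reaches the original $R^2Y$ or
$Q^2$. A negative $Q^2$ intercept on real signal and a raised flag on pure
noise are both exercised in the acceptance tests.

**SVM**: radial-kernel `e1071::svm` on column-standardized features
(standardization frozen on the training set), grid-searched over base-2
grids (defaults $c \in 2^{-10..20}$, $g \in 2^{-20..4}$ — wide enough to
contain both the "reasonable region" $2^{-2}..2$ quoted for such problems
and the much larger optima that grid searches actually return on raw
spectra) by stratified k-fold CV accuracy (default 5 folds). Ties break
toward smaller $c$, then smaller $g$; the winner is refitted on the full
training set.

## The residual network

No deep-learning framework is assumed: convolutions are im2col/GEMM
kernels in RcppArmadillo and everything else (batch norm, ReLU, global
average pooling, softmax cross-entropy, Adam) is plain R, which keeps
training deterministic for a fixed seed and fast enough on one CPU at the
sizes involved. Analytic gradients are verified against finite differences
in the tests.

Architecture (`resnet_spec`): an entry 3×3 convolution, then one stage per
width entry, each stage `blocks` identity-shortcut residual blocks of two
3×3 conv+BN layers; stages after the first open with a stride-2
conv+BN transition; global average pooling feeds a linear two-way head.
The closing batch-norm scale of every residual branch starts at zero, so
each block is the identity at initialization — without this (and batch
norm generally) the loss surface of the class-imbalanced problem has a
majority-class plateau that small networks escape only erratically.
Optimization: Adam, learning rate 3 × 10⁻³, batch 16, no augmentation,
per-channel input normalization frozen on the training role. The default
budget is 46 epochs; optional early stopping ends training once test-role
accuracy has held at 100% for 5 consecutive epochs (off by default so that
histories are comparable across runs). The default architecture is
3 stages × 2 blocks at widths 16/32/64 for 224 px images; the test and
acceptance runs use the documented compact variant — 2 stages × 1 block,
widths 8/16, 64 px images — which trains in about a minute per run on one
CPU.

Evaluation treats `wild` as the positive class throughout (the economically
adulterated target): sensitivity is the wild-detection rate, specificity
the cultivated-detection rate, and effectivity their product — note the
product definition means a classifier with Sen = Spe = 0.635 has
Eff ≈ 0.40, not 0.635. A majority-class predictor on a 33/19 role scores
exactly 33/52 ≈ 63.46%, the baseline every trained model must beat.

## Reference design arithmetic

With the full-scale preset (`experiment_config("full")`): 172 samples split 120/52 by per-class
Kennard–Stone (76 + 44 / 33 + 19); 3 × 172 = 516 correlation-map images;
image roles 84/36/52 per category with the external-validation role
disjoint from train and test by sample id (leakage is checked at
evaluation time).

## Numerical choices and degenerate inputs

Grids must be strictly monotonic with a constant step (relative tolerance
10⁻⁹); spectra CSVs are written with 17 significant digits so read∘write is
the identity at double precision. Constant records are rejected by SNV, a
zero MSC slope and empty confusion-matrix denominators raise classed
errors naming the offender, and non-finite losses abort training with the
epoch index. The Kennard–Stone and SVM tie rules are fixed (lowest
canonical index; smallest $c$ then $g$). One master seed fans out to
per-stage seeds through a deterministic hash so any stage can be re-run in
isolation.

## Known limitations

* The generator's noise is iid Gaussian and its class effect purely
  multiplicative; conclusions about robustness to peak shifts, band
  broadening, or correlated instrument drift cannot be drawn from it.
* The per-sample map construction assumes replicate scans are available;
  with single scans only the sign-blind deviation fallback exists, and its
  discriminative power is intrinsically weaker.
* Real-data results of the motivating study (its preprocessing-by-model
  metric tables and PCA variance shares) are not reproducible here because
  those spectra are confidential; the acceptance suite checks the
  arithmetic, the metric layer, the method's invariants, and a scaled-down
  synthetic analog of the headline 100% external-validation result instead.
* The CNN consumes rendered surfaces, so its input distribution depends on
  the fixed rendering parameters (view angles, palette, autoscaling); these
  are deliberately frozen and recorded rather than learned.
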