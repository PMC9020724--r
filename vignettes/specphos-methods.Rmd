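---
title: "Models and methods behind specphos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind specphos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specphos)
```

specphos analyses leaf reflectance spectra of rice grown under graded
phosphate supply. This vignette explains the models the package implements,
the assumptions behind them, the defaults of the synthetic-data generator
and what passing tests on generated data do and do not demonstrate.

## The biological setting

Rice seedlings grown hydroponically under three phosphate supplies — P100
(320 µM, overly sufficient), P5 (16 µM, mildly deficient) and P0.25
(0.8 µM, severely deficient) — accumulate very different amounts of leaf
inorganic phosphate (Pi, measured per leaf area in nmol/mm²). Severe
deficiency changes the leaf optically: visible (VIS, 420–720 nm)
reflectance rises as chlorophyll declines, while near-infrared (NIR,
730–790 nm) reflectance falls with leaf structure. Mild deficiency barely
changes the spectrum at all, because surplus Pi above roughly
0.2 nmol/mm² sits in vacuolar storage and is spectrally invisible. Every
model in the package inherits this asymmetry: spectra are informative
about Pi only in the deficient range.

## Spectra preprocessing

Device exports arrive as wide CSVs on a 380–790 nm grid at 2 nm (206
channels). Preprocessing is deliberately minimal and order-insensitive:

* **Technical replicates** (two scans per leaf) are averaged channelwise
  (`average_replicates()`; idempotent).
* **The 380–410 nm edge is dropped** (`exclude_noisy_band()`): the device
  is unstable there, with adjacent channels barely correlated. All
  analyses run on 420–790 nm, 186 channels.
* **Standardization** (`standardize_spectra()`) centers and scales each
  channel with statistics computed on the training split only, which are
  then reused for validation and test data. Computing statistics per
  split would leak information into model selection.

Reflectance is stored as a fraction in [0, 1]; percent-scale input is
auto-detected (any value above 1.5) and rescaled with a warning.

## Ratio indices

Because VIS channels are strongly correlated among themselves, as are NIR
channels, while the two blocks are only weakly cross-correlated, one
NIR/VIS ratio summarises a spectrum well. The package screens all
`build_ratio_grid()` pairs — 7 NIR bands (730–790 nm) × 31 VIS bands
(420–720 nm) at 10 nm spacing, 217 ratios — against any trait by Spearman
correlation, computed on plants pooled from the two deficient treatments.
For association mapping, each accession's mean ratio under severe
deficiency is divided by its mean under control (`normalize_sr_traits()`),
yielding 217 "SR traits" per accession with 1 meaning "no change under
deficiency". Accession means use the mean-of-ratios convention (ratios per
plant first, then averaged) and pool plants across experiment blocks.

## The decay calibration

The relation between a reflectance characteristic $y$ (band or ratio) and
Pi is modelled as exponential decay,

$$y = a + b\,e^{-c\,\mathrm{Pi}},$$

because reflectance changes sharply below ~0.1 nmol/mm² and flattens above
~0.2. Constraints: $a \ge -1$ (responses derived from reflectance are
bounded) and $c \ge 0$ (decay); $b$ is free, with $b<0$ when the response
rises towards an upper asymptote. Points with Pi < 0.02 nmol/mm² are
trimmed before fitting; measurements that low are assay noise.

Numerics: the objective is non-convex, so `fit_decay()` multi-starts.
The offset starts at `min(y)` (or `max(y)` when the Pi–response rank
correlation is positive), the multiplier at the signed response range, and
the rate at `1/median(Pi)` scaled by 0.1, 1 and 10; each start runs
`nls(algorithm = "port")` under the box constraints with an
`optim(L-BFGS-B)` polish and fallback, and the lowest residual sum of
squares wins. The parameter covariance comes from the final Jacobian,
$\hat\sigma^2 (J^\top J)^{-1}$; `summary()` reports per-parameter CV% =
100·SE/|estimate|. R² is reported as computed and may be negative for
pathological fits. The test suite checks the fitted SS against a dense
grid-search oracle over $(a, b, c)$.

`fit_by_level()` fits either individual plants or accession×treatment cell
means (Pi and response averaged first). The two deficient treatments are
pooled into one regression; cell averaging removes plant-level scatter, so
accession fits are systematically tighter. One plant per accession makes
the two levels coincide, which the tests assert.

## The convolutional models

Both network variants consume a standardized 186-channel spectrum:

* **Encoder**: conv(16 filters, kernel 8) → batch norm → ReLU;
  conv(32, kernel 8) → batch norm → ReLU; average pooling (window 4,
  stride 3) → 61×32 → flatten (1952); dropout 0.2 → dense 64 → ReLU →
  dropout 0.2 → dense 3 (softmax over P100/P5/P0.25) or dense 1 (linear,
  log10 Pi).
* **Multi-task decoder** (optional): dense 1952 → reshape (61, 32) →
  [conv(32, k8) → BN → ReLU → 2× nearest upsampling] → [conv(16, k8) → BN
  → ReLU → 2× upsampling] → conv(1, k4). The decoder's dense width is
  derived from the encoder's actual pooled length at construction, and the
  upsampled length (244) is mapped back onto the 186-channel grid by a
  fixed linear interpolation — cropping would discard the band edges. The
  reconstruction target is the standardized input itself.

Losses: categorical cross-entropy (weight 1.0) and, for the multi-task
variant, the per-sample mean squared channel error summed over samples
(weight 0.5). Mean squared error drives the regression head. The training
objective normalises both terms by batch size, which leaves their relative
weight unchanged.

Training choices the architecture description leaves open are fixed as
package defaults and exposed as arguments: Adam (learning rate 1e-3),
batch size 64, up to 100 epochs with early stopping (patience 20) on
validation loss, best-epoch weights restored. Each training spectrum gets
one Gaussian-noise copy per epoch (SD 0.01 reflectance units, fresh draws
each epoch); augmented rows are flagged and never used for evaluation.
For the regression task all plants of an accession land in the same split
(`split_data(group_by_accession = TRUE)`), so test metrics measure
generalization to unseen accessions, and only deficient-treatment plants
are used — including P100 plants, whose vacuolar Pi is spectrally
invisible, degrades the regression. Non-positive Pi values would be
excluded with a message before the log10 transform.

The whole network stack — convolutions (im2col + BLAS), batch
normalization, dropout, Adam, backpropagation — is implemented in base R
inside the package; the backward pass is verified against central finite
differences to ~1e-8 relative error in the test suite. With
`recon_weight = 0` the multi-task model reproduces the single-task loss
trajectory exactly under the same seed, a regression test of the shared
encoder path.

**Grad-CAM** (`grad_cam()`): the gradient of the class score (or
regression output) with respect to the last convolutional block's
activations weights those activations element-wise, and the weighted
activations are summed over feature maps, rectified (only regions pushing
the score up are kept) and normalized to sum to one per sample. The
gradient weights are kept at full positional resolution rather than
averaged over positions first: position-averaged weights were evaluated
on fixtures with a planted discriminative band and smear attribution
across the spectrum when the informative region is narrow, while
positionwise weighting concentrates it correctly. Since the convolutions
preserve length, the map is already at input resolution. Dropout is
disabled, so maps are deterministic; an all-zero map falls back to
uniform with a message.

## Association post-processing

The package post-processes per-SNP association output (GEMMA-dialect
tables via `read_gemma_assoc()`, or the built-in `naive_assoc()`
per-SNP linear regression on synthetic fixtures — the mixed-model scan
itself is external and out of scope):

* MAF filter: drop MAF **<** 0.05 (boundary kept).
* Bonferroni threshold on the −log10 scale: with 113,114 SNPs at
  α = 0.05, −log10(0.05/113114) = 6.35.
* Significance: −log10(p) **≥** threshold (boundary significant).
* Locus grouping: the "approximately 300-kb region" rule is implemented
  as single-linkage chaining — consecutive position-sorted significant
  SNPs at most 300,000 bp apart join one locus. A span-based reading
  (total locus extent ≤ 300 kb) was the alternative; gap-based chaining
  was chosen because it is order-independent and matches how association
  peaks with LD shoulders behave, and the window is configurable. The
  grouping rule is recorded in the result's metadata. Lead SNP = minimum
  p, ties to the lower position; names follow `q<trait><chr>[-k]` ordered
  by position.
* LD candidate windows: SNPs within 100 kb of a lead (inclusive) with
  r² **>** 0.50 (strict, per the rule's wording); pairs missing from the
  LD table count as below threshold and are logged.
* `qq_data()` uses expected quantiles −log10(i/(n+1)); `manhattan_data()`
  lays chromosomes end to end.

Each boundary convention above follows the wording of the corresponding
rule; all thresholds are arguments with these defaults.

## The synthetic panel

`generate_panel()` emulates the study design so every stage is testable
without external data: 172 accessions × 3 treatments × 3 plants × 3
blocks, two technical scans per leaf.

* **Pi**: lognormal per treatment, moment-matched to accession-mean
  targets of 3.60 ± 1.74 (P100), 0.22 ± 0.07 (P5) and 0.07 ± 0.03
  (P0.25) nmol/mm². The across-accession log-variance splits into a
  shared accession effect (log-SD 0.20, carried across treatments) and an
  accession-by-treatment residual; plants scatter around their cell mean
  with log-SD 0.35, and blocks contribute a multiplicative log-SD 0.05.
* **Spectra**: a smooth healthy-leaf baseline (chlorophyll troughs, green
  bump, red edge, NIR plateau) plus a deficiency deviation profile
  (positive VIS, negative NIR) attenuated by $e^{-c\,\mathrm{Pi}}$ with
  c = 20 per nmol/mm², so mildly deficient leaves are spectrally almost
  indistinguishable from control while severely deficient leaves respond
  strongly. Baseline band ratios are anchored to the control-treatment
  ratio means (R740/R560 ≈ 2.95, R750/R700 = 2.53) and the deviation
  amplitudes are solved so that the expected attenuation of the P0.25 Pi
  distribution lands the two headline ratios on their severe-deficiency
  means (2.43, 2.12). The expectation is taken over the lognormal rather
  than at its mean because the attenuation is convex in Pi.
* **Variation**: accessions differ in deficiency-response strength
  (lognormal multiplier on the deviation term, log-SD 0.3), red-edge
  position (±1.2 nm) and overall amplitude (±0.012); plants add the same
  three components at (0.2, 1.0 nm, 0.010) plus i.i.d. per-channel scan
  noise of SD 0.01 — inflated 8× below 420 nm to emulate the device's
  noisy UV edge. These SDs were fixed by matching the generated
  per-treatment ratio dispersions and the pooled plant-level
  Spearman correlations (≈0.7) to their reference values; with them the
  generated panel reproduces the reference descriptive table closely.
* **Biomass and conversions**: biomass is lognormal per treatment
  (0.32/0.29/0.16 g means) sharing the accession Pi effect at half
  weight, which induces the observed positive Pi–biomass association;
  areal dry mass (mean 0.034 mg/mm²) supports the nmol/mm² → mg/g
  conversion (molecular weight of PO₄³⁻ taken as 94.97 g/mol) and makes
  the derived PUtE means land near their reference values.
* All randomness derives from one root seed through a fixed
  stream-splitting scheme; equal configurations generate byte-identical
  panels.

The GWAS fixture (`generate_gwas()`) draws Hardy–Weinberg genotypes at
independent background SNPs on a rice-like genome (12 × 30 Mb), plants
causal SNPs at configured positions with tightly linked neighbours
(genotype copies with a 3% flip rate within 50 kb), builds the trait as
planted additive effects plus Gaussian noise, and tabulates pairwise LD
r² within 100 kb.

**What generated data cannot show.** The generator reproduces the
statistical structure the analyses assume — not leaf biophysics. Real
spectra have wavelength-correlated instrument noise, senescence effects
in older leaves, and accession-specific spectral shapes that no smooth
baseline plus four noise components captures; real genotypes have
population structure and kinship, which is precisely why the real
analysis uses a mixed model. Passing tests here demonstrate that the
algorithms are implemented correctly and behave as designed under known
truth, not that the biological conclusions transfer. In particular, the
accession-level decay-calibration R² on generated panels (~0.59–0.66 for
the two headline ratios) brackets rather than matches the reference
values, because the two real ratios differ in fit quality in a way that
no printed summary of the data pins down.

## Problem sizes and determinism

The test suite and the acceptance script generate their data at the study
shape where the quantity depends on it (172 accessions for summary
statistics and calibration fits) and at reduced sizes for network
training (tens of accessions, 15–25 epochs, batch 120–128), which is
where the properties under test — separability, attribution placement,
the value of the reconstruction objective — are already expressed.
Training runs are seeded end to end (weights, splits, augmentation,
batch order, dropout), so every reported number is reproducible.

## Known limitations

* `naive_assoc()` is a per-SNP linear model for fixtures; it ignores
  relatedness and will be anticonservative on structured populations.
* The decay model's covariance is a local (Jacobian) approximation;
  near-boundary solutions (c ≈ 0) make it unreliable, and CVs should be
  read with that in mind.
* Grad-CAM attributes at the resolution of the last convolution block;
  with length-preserving convolutions this equals the input grid, but
  attribution sharpness is limited by the receptive field (~22 nm).
* The classifier cannot distinguish P100 from P5 when, as under the
  default generator (and in the motivating data), their spectra are
  essentially identical; accuracy well above 2/3 is only meaningful on
  panels whose treatments actually separate spectrally.
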