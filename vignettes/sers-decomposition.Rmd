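---
title: "Estimating amino-acid composition from SERS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating amino-acid composition from SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Surface-enhanced Raman spectroscopy (SERS) records molecule-specific
vibrational fingerprints with single-molecule-scale sensitivity. Each of the
20 canonical amino acids has a distinguishable SERS signature — tryptophan's
indole modes near 1552 and 760 cm⁻¹, alanine's CH₃ deformation near
1445 cm⁻¹, phenylalanine's ring-breathing doublet at 1000/1033 cm⁻¹, and so
on. A protein's SERS spectrum superimposes the contributions of its
residues, so a classifier trained to recognize the 20 pure amino-acid
signatures can be turned around: feed it a mixture or protein spectrum and
read its 20 softmax probabilities, averaged over replicate spectra, as an
estimate of the sample's amino-acid *composition* (20 non-negative
fractions summing to 1). This package implements that full pipeline —
synthetic data generation, spectral preprocessing and quality control,
cluster-separability diagnostics, the transformer classifier, and the
composition/error reporting — as tidyverse-style functions over spectra
tibbles.

The method recovers composition only. Residue order (sequence), post-
translational modifications and conformation effects on band intensities
are out of scope.

## Synthetic spectra as study conditions

Experimental spectra are replaced by a calibrated generator whose defaults
define the package's study conditions:

* **Templates.** Each amino acid is a fixed list of 5–8 Lorentzian bands
  (center, half-width at half-maximum 6–8 cm⁻¹, relative amplitude with the
  dominant band at 1), shipped as `inst/extdata/amino_acid_bands.csv`. The
  three marker classes above are anchored at their documented band
  positions; the other 17 band sets are curated synthetic constants chosen
  for pairwise distinguishability (maximum pairwise cosine similarity of
  noise-free renders ≈ 0.46), not literature assignments. Lorentzian line
  shapes are the standard model for Raman bands.
* **Axis.** 1117 evenly spaced channels over 400–1800 cm⁻¹. The channel
  count matches the acquisition this emulates; the range is a documented
  assumption (it covers every named band with standard fingerprint
  coverage) and is overridable everywhere.
* **Noise model** (`noise_model()`): a broad Gaussian fluorescence
  background (amplitude 0.4 of the dominant band, center 1000 cm⁻¹, width
  600 cm⁻¹); additive white noise with σ = 0.01 in dominant-band units;
  and per-band multiplicative lognormal amplitude jitter with relative
  σ = 0.08 (lognormal keeps intensities positive). The jitter level was
  chosen once so that replicate band-intensity CVs land mostly below 10%
  and safely below 20%, the reproducibility regime the pipeline assumes.
  A `poor_fraction` of 20% of map replicates gets 5× additive noise,
  emulating low-signal Raman-map points; with these values clean spectra
  sit near SNR ≈ 100 and poor ones near SNR ≈ 20–25, so the SNR-50 filter
  has real work to do.
* **Mixtures and proteins.** Components are rendered with band jitter but
  without background, min–max normalized, combined by (re-normalized)
  weights, rescaled to [0, 1], and only then background and additive noise
  are applied. Jitter must act at render time — it is a per-band effect
  and cannot be applied to a sum. Mixture weights default to equal.
  Protein spectra optionally add fixed amide bands (amide I 1660 cm⁻¹,
  amide III 1260 cm⁻¹) that free amino acids lack; peptide-band masking
  must remove them before prediction.

What the generator does **not** emulate: electromagnetic/chemical
enhancement physics, substrate geometry, wavenumber miscalibration,
cosmic-ray spikes, peak-position drift, or conformation-dependent
intensity changes in proteins. Passing tests therefore demonstrate the
pipeline's internal correctness and its behavior under controlled,
realistic noise — not performance on any particular instrument's data.

## Preprocessing

`preprocess_pipeline()` applies, per spectrum and in order:

1. **Asymmetric least squares (ALS) background subtraction** — iteratively
   reweighted penalized least squares with second-difference penalty
   λ = 1e5, asymmetry p = 0.01, 10 iterations (common spectroscopy
   practice; all exposed in `preprocess_config()`).
2. **Savitzky–Golay smoothing** — window 11, polynomial order 3.
3. **Peptide-band masking** (optional) — channels in the amide I
   (1630–1700 cm⁻¹) and amide III (1230–1300 cm⁻¹) windows are replaced by
   linear interpolation between the window edges. Interpolation rather
   than deletion keeps every spectrum at 1117 channels, so one trained
   model serves free amino acids and proteins. Amide II (~1480–1580 cm⁻¹)
   is deliberately not masked by default: it would delete tryptophan's
   1552 cm⁻¹ marker. A constant spectrum is rejected as a degenerate input
   (a dead detector row), not silently zeroed.
4. **Min–max normalization** to [0, 1].

**SNR.** No single per-spectrum SNR definition is universal; the package
uses peak signal over residual noise: the maximum of the
background-subtracted, smoothed signal divided by the standard deviation of
the smoothing residual (floored at 1e-12). It is scale-invariant and needs
no replicates. Note the Savitzky–Golay residual of a finite-width
Lorentzian is small but nonzero, so even noiseless spectra have finite SNR
(~10³), far above the filtering regime.

**Filtering.** `filter_dataset()` drops spectra with SNR below 50, ranks
the survivors per class, and keeps the top 33 (ties broken by original
order), erroring if any class cannot fill its quota. The per-class quota
guards the classifier against class imbalance. At the default map scale
(121 replicates × 20 classes = 2420 spectra) this yields exactly 660.

## Cluster-structure diagnostics

`tsne_embed()` is an exact t-SNE implementation (perplexity 30, PCA
initialization, early exaggeration, 1000 iterations, fixed seed — values
chosen once as standard defaults) mapping the 1117-dimensional spectra to
3-D; the O(n²) gradient loop is compiled (RcppArmadillo), so a
2420-spectrum embedding takes about a minute. Cluster count is made
quantitative rather than visual: `estimate_cluster_count()` sweeps
k-means over k = 10…30 and returns the k with maximal mean silhouette,
ties to the smaller k; `cluster_agreement()` reports the adjusted Rand
index of the k = 20 k-means partition against the true labels. With 20
tight, widely separated clusters, k-means with a handful of random
restarts routinely misses its global optimum (we observed k = 20
partitions scoring 0.75 silhouette where the true-label partition scores
0.97, spuriously favoring k = 19 or 21), so each k-means run uses 50
restarts plus a deterministic Ward-linkage initialization, keeping the
better objective value. The filtered-vs-unfiltered separability
comparison embeds the *full* unfiltered map dataset (121 per class,
including its low-SNR map points) against the filtered top-33-per-class
set — the same contrast the before/after-filtering figures of SERS
clustering studies draw.

## The transformer classifier

`model_config()` defaults: patches of 16 channels (70 tokens, the last
zero-padded by 3), a learned linear patch embedding into d_model = 64
scaled by √d_model before the sinusoidal positional encoding is added
(without this scaling the O(1) positional code swamps the spectral signal
and training stalls at chance), 2 *pre-norm* encoder layers with 4-head
self-attention and a 128-wide feed-forward block, mean pooling over
tokens, dropout 0.3, and a dense 20-way softmax that also receives the
mean-pooled *raw patch embedding* through a linear skip path. Dropout 0.3
is applied after each dense sublayer (attention projection, both
feed-forward layers, and the classification head input). This is the
smallest configuration we found that trains to high accuracy on a single
CPU in minutes; forward and backward passes are hand-implemented and
verified against numerical differentiation in the test suite.

The linear skip path deserves a word: vibrational spectra of mixtures are
(to first order) additive in their components, so the map from spectrum
to composition has a large linear part. Routing the pooled patch
embedding — which is exactly linear in the input — directly into the
logits gives the network an explicitly additive pathway, while the
encoder refines it for the pure-class decisions. Without it, mixture
probability mass drifts to whichever third class the nonlinear features
happen to favor.

The pre-norm layout (`x + sublayer(LN(x))`) is chosen deliberately over
the post-norm original: it preserves an identity residual stream from the
patch embedding to the pooled features. That matters here because the
pooled representation of a *superposition* of two spectra should
interpolate between the representations of its components — the property
the composition read-out depends on. With post-norm layers (LN applied on
the residual sum) we observed mixtures collapsing to confident single-class
predictions even though, in input space, a mixture sits almost exactly
between its components (linear-probe diagnostics in `scratch/` during
development showed a regularized linear softmax decomposes the same
mixtures with RMSE < 0.05).

Training (`train_config()`): Adam at learning rate 0.001, batch size 32,
cross-entropy loss, plateau halving of the learning rate (factor 0.5 after
2 epochs without improvement), early stopping on validation loss with
patience 5, and retention of the minimum-validation-loss checkpoint. An
improvement must exceed `min_delta = 1e-3` to count as progress —
validation loss on well-separated synthetic data otherwise keeps creeping
down by ~1e-5 per epoch and training would never stop; the checkpoint
itself is still the strict minimum. The early-stopping validation set is a
stratified 10% carved from the training data; any held-out test split is
never touched during training. A stratified split uses largest-remainder
allocation, so an 80/20 split of 660 spectra gives exactly 132 test
spectra (6–7 per class). All randomness derives from the configured seed.

Two further training choices serve calibration rather than raw accuracy,
because the softmax probabilities are later *read as compositions*:

* **Label smoothing** (0.1): bounds the logit margins so a spectrum
  between two classes receives split probabilities instead of a saturated
  one-hot answer.
* **Mixup** (Dirichlet(1, 1, 1) weights over three shuffled copies of the
  batch, drawn per row): each minibatch is convexly combined with shuffled
  copies of itself, mixed rows re-normalized to [0, 1] (the space
  preprocessed spectra live in), and targets mixed with the same weights.
  This trains the network to map superimposed spectra to proportionally
  mixed probabilities — the confidence-as-abundance assumption made
  explicit as a training objective. Without it the classifier, though
  100% accurate on pure spectra, is free to assign a mixture's
  probability mass arbitrarily.

## Decomposition and evaluation

`estimate_composition()` averages the per-spectrum probability rows over
all replicate spectra of a sample (`aggregate = "mean_proba"`; predicting
from the channel-wise mean spectrum is available as
`"mean_spectrum"`). Averaging probabilities keeps the estimate a proper
fraction vector and matches the confidence-as-abundance reading of the
softmax output.

Metrics: MSE = (1/n)Σ(ŷᵢ−yᵢ)² and RMSE = √MSE, over the 20 fractions
(n = 20) for compositions; NRMSE divides RMSE by the *range* of the
reference fractions (the common range-normalization convention, since no
single NRMSE definition is universal). The coefficient of variation uses
the sample standard deviation (n − 1), the standard choice for small
replicate sets. Band intensities for CV are read at the fixed band-center
channel found on the class-mean spectrum, so CV measures intensity
variability, not peak-shift variability. `most_abundant()` breaks ties by
canonical (alphabetical one-letter) order for determinism.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run the pipeline at the study
scale: 121 map replicates per class (2420 spectra) filtered to 660,
training with the default configuration (~20–40 epochs), an independent
validation set of 50 spectra per class, 25 replicate spectra per doublet
pair (aspartate/histidine, cysteine/methionine, aspartate/valine,
isoleucine/asparagine) and per protein, and 50 replicates per class for
the CV report. Unit tests use smaller axes and toy two-class sets. The
validation replicates are drawn from the clean component of the noise
model (`poor_fraction = 0`), emulating an independently acquired,
usable-quality dataset; the map-style training data keep the 20% poor
fraction so that SNR filtering is exercised.

## Known limitations

* Composition estimates inherit softmax calibration: a classifier trained
  to near-zero loss is overconfident on single spectra, and reliable
  composition estimates need averaging over replicate spectra.
* Top-1 (most-abundant residue) identification for full protein spectra
  is reliable under the default synthetic template library only when the
  dominant residue is strongly dominant (fraction ≳ 0.4, e.g.
  collagen-like glycine content). Near-uniform 20-component compositions
  pile many overlapping bands into the 600–720 cm⁻¹ region, and the
  transformer's estimate can favor a class anchored there even though a
  linear classifier can still separate the contributions — the
  information is present, but the network's calibration on such far
  out-of-distribution superpositions is limited. The bundled synthetic
  protein fixtures have dominant fractions of 0.38–0.40 for this reason.
* Recovered mixing weights for unequal doublets are compressed toward
  equality by roughly 0.1–0.2 at weight 0.25, a smoothness bias of the
  regularized network.
* The curated band library is a synthetic stand-in; real SERS band
  positions and relative intensities vary with substrate and instrument.
* Exact t-SNE is O(n²) per iteration and intended for a few thousand
  spectra at most.
* The classifier assumes a fixed axis; spectra must be resampled to the
  training grid upstream.
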