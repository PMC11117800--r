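# sersdecomp

Estimate the amino-acid composition of peptide and protein samples from
surface-enhanced Raman spectroscopy (SERS) spectra.

SERS records molecule-specific vibrational fingerprints; each of the 20
canonical amino acids has a distinguishable signature (tryptophan ~1552 and
760 cm⁻¹, alanine ~1445 cm⁻¹, phenylalanine ~1000/1033 cm⁻¹, ...). The idea
implemented here: train a 20-class transformer encoder on preprocessed
single-amino-acid spectra, then, for a mixture or protein sample, average
the model's softmax probabilities over replicate spectra and read the mean
probability vector **p̂ ∈ Δ¹⁹** as the sample's composition. Quality is
reported as MSE = (1/n)Σᵢ(ŷᵢ − yᵢ)², RMSE = √MSE, range-normalized RMSE,
and replicate reproducibility as CV = (σ/μ)·100%.

The package provides, as pipe-friendly functions over spectra tibbles
(rows = spectra, columns = metadata + one column per wavenumber):

* **Synthetic data** — a calibrated generator for all 20 amino acids
  (Lorentzian band templates, fluorescence background, additive noise,
  per-band lognormal jitter, Raman-map replicates, weighted mixtures and
  protein spectra with removable amide bands). Stands in for instrument
  data; band sets for the 17 classes without well-known anchors are
  synthetic curated constants.
* **Preprocessing** — asymmetric-least-squares background subtraction,
  Savitzky–Golay smoothing, peptide-band masking, min–max normalization,
  per-spectrum SNR estimation, and SNR-threshold + per-class top-k
  filtering (threshold 50, top 33 by default).
* **Cluster diagnostics** — exact 3-D t-SNE, silhouette-swept k-means
  cluster counting, adjusted-Rand agreement with labels.
* **Classifier** — a small pre-norm transformer encoder (70 patch tokens,
  d_model 64, 2 layers, 4 heads, dropout 0.3) written in plain R with
  hand-derived backpropagation, Adam, label smoothing, mixup augmentation,
  plateau LR schedule and early stopping. `tidy()`/`glance()` methods and
  training-curve plots included.
* **Decomposition & reports** — composition estimation, error metrics,
  most-abundant-residue identification, major-band detection and CV
  tables, FASTA/composition-table references.

## Worked example

```r
library(sersdecomp)

cfg  <- preprocess_config()                    # ALS, SG, SNR 50, top 33
raw  <- generate_dataset(121, noise_model(), seed = 42)   # 2420 spectra
filt <- filter_dataset(raw, cfg)               # 660 spectra, 33 per class
spec <- preprocess_pipeline(filt, cfg)         # [0, 1] normalized

fit <- train_classifier(spec, model_config(), train_config(seed = 7))
glance(fit)
#> # A tibble: 1 × 5
#>   epochs best_epoch best_val_loss val_accuracy n_classes
#>    <int>      <int>         <dbl>        <dbl>     <int>
#> 1     36         36         0.656            1        20

# decompose an equal-weight aspartate/histidine doublet from 25 replicates
mix <- lapply(1:25, function(i)
  simulate_mixture(c(D = 1, H = 1), noise_model(), seed = i)$spectrum)
mixp <- preprocess_pipeline(dplyr::bind_rows(mix), cfg)
est  <- estimate_composition(fit, mixp)
dplyr::filter(est, fraction > 0.05)
#> # A tibble: 4 × 2
#>   amino_acid fraction
#>   <chr>         <dbl>
#> 1 D            0.501
#> 2 H            0.225
#> 3 Q            0.0729
#> 4 Y            0.0821
rmse_composition(est, composition(c(D = 0.5, H = 0.5)))
#> [1] 0.06701948
```

The fitted model reaches 100% accuracy on its held-out validation split
(the residual validation loss of ~0.65 is the label-smoothing floor, not
misclassification); the doublet estimate concentrates on the two true
components with a composition RMSE well under 0.1 (exact numbers vary
with seeds). `evaluate_protein()` produces the same report for
protein spectra against a FASTA-derived reference, and
`plot_composition(est, ref)` draws the predicted-vs-reference double-bar
figure.

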