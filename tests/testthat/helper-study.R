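# Shared full-scale study objects for the acceptance-style tests.
# Built lazily once per test run (generation, SNR filtering, preprocessing
# and training take a few minutes) and reused across test files.

.study <- new.env(parent = emptyenv())

study_raw <- function() {
  if (is.null(.study$raw)) {
    .study$raw <- generate_dataset(121, noise_model(), seed = 42)
  }
  .study$raw
}

study_snr <- function() {
  if (is.null(.study$snr)) {
    .study$snr <- estimate_snr(study_raw(), preprocess_config())
  }
  .study$snr
}

study_filtered <- function() {
  if (is.null(.study$filtered)) {
    .study$filtered <- filter_dataset(study_raw(), preprocess_config(),
                                      snr = study_snr())
  }
  .study$filtered
}

study_raw_pp <- function() {
  if (is.null(.study$raw_pp)) {
    .study$raw_pp <- preprocess_pipeline(study_raw(), preprocess_config())
  }
  .study$raw_pp
}

study_trainset <- function() {
  if (is.null(.study$trainset)) {
    .study$trainset <- preprocess_pipeline(study_filtered(),
                                           preprocess_config())
  }
  .study$trainset
}

study_model <- function() {
  if (is.null(.study$model)) {
    .study$model <- train_classifier(study_trainset(), model_config(),
                                     train_config(seed = 7))
  }
  .study$model
}

# preprocessed replicate doublet spectra for one amino-acid pair
study_doublet <- function(pair, weights = c(0.5, 0.5), n_rep = 25,
                          seed_base = 1000) {
  m <- do.call(rbind, lapply(seq_len(n_rep), function(i) {
    mx <- simulate_mixture(stats::setNames(weights, pair), noise_model(),
                           seed = seed_base + 37 * i +
                             sum(utf8ToInt(paste(pair, collapse = ""))))
    intensity_matrix(mx$spectrum)
  }))
  preprocess_pipeline(spectra_tbl(m, raman_axis()), preprocess_config())
}
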