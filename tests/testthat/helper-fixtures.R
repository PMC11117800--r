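# Small shared fixtures for fast unit tests.

# short axis covering the template band range, cheap to preprocess
tiny_axis <- function(n = 200) raman_axis(400, 1800, n)

# two-class toy spectra on a short axis: well-separated single Lorentzians
toy_two_class <- function(n_per_class = 20, sigma = 0.02, seed = 1,
                          n_channels = 60) {
  wn <- raman_axis(400, 1800, n_channels)
  withr::with_seed(seed, {
    shapes <- list(
      A = 1 / (1 + ((wn - 700) / 40)^2),
      W = 1 / (1 + ((wn - 1500) / 40)^2)
    )
    rows <- list()
    label <- character()
    for (lab in names(shapes)) {
      for (i in seq_len(n_per_class)) {
        y <- shapes[[lab]] * stats::runif(1, 0.8, 1.2) +
          stats::rnorm(n_channels, sd = sigma)
        rows[[length(rows) + 1L]] <- (y - min(y)) / (max(y) - min(y))
        label <- c(label, lab)
      }
    }
    spectra_tbl(do.call(rbind, rows), wn, label = label)
  })
}

# tiny transformer config used for gradient checks and toy training
toy_model_cfg <- function(dropout = 0) {
  model_config(patch_size = 10, d_model = 8, n_heads = 2, n_layers = 1,
               d_ff = 12, dropout = dropout, n_classes = 2)
}

# 3-D Gaussian blob embedding with labels, for clustering tests; centers
# sit on a jittered lattice so every pair is well separated
blob_embedding <- function(k, n_per = 20, sep = 10, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    grid <- as.matrix(expand.grid(0:2, 0:2, 0:2)) * sep
    centers <- grid[sample(nrow(grid), k), , drop = FALSE] +
      matrix(stats::runif(k * 3, -sep / 5, sep / 5), k, 3)
    coords <- do.call(rbind, lapply(seq_len(k), function(i) {
      sweep(matrix(stats::rnorm(n_per * 3, sd = sd), n_per, 3), 2L,
            centers[i, ], "+")
    }))
    emb <- tibble::as_tibble(`colnames<-`(coords, c("dim1", "dim2", "dim3")))
    emb$label <- rep(paste0("c", seq_len(k)), each = n_per)
    emb
  })
}
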