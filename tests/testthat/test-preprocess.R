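test_that("ALS baseline tracks broad backgrounds and passes under narrow peaks", {
  wn <- tiny_axis(600)
  # flat limit: baseline equals a constant spectrum
  flat <- rep(3, 600)
  expect_equal(als_baseline(flat), flat, tolerance = 1e-6)

  # broad hump is absorbed almost entirely into the baseline
  hump <- 2 * exp(-((wn - 1100)^2) / (2 * 500^2))
  resid <- hump - als_baseline(hump, lambda = 1e5, p = 0.01)
  expect_lt(max(abs(resid)), 0.05 * max(hump))

  # a narrow band survives baseline subtraction nearly intact
  peak <- 1 / (1 + ((wn - 1000) / 6)^2)
  resid2 <- peak - als_baseline(peak, lambda = 1e5, p = 0.01)
  expect_gt(resid2[which.min(abs(wn - 1000))], 0.9 * max(peak))

  expect_error(als_baseline(c(1, NA, 3, 4, 5)), "finite")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and damps noise", {
  x <- seq(-1, 1, length.out = 101)
  cubic <- 2 + x - 0.5 * x^2 + 3 * x^3
  sm <- savgol_smooth(cubic, window = 11, polyorder = 3)
  interior <- 10:92
  expect_equal(sm[interior], cubic[interior], tolerance = 1e-8)

  withr::with_seed(8, {
    noise <- rnorm(500)
    expect_lt(var(savgol_smooth(noise, 11, 3)), var(noise))
  })
  expect_error(savgol_smooth(cubic, window = 10), "odd")
})

test_that("min-max normalization maps to [0, 1] and is affine-invariant", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  y <- c(0, 0.2, 1, 0.4)
  expect_equal(minmax_normalize(y), y)
  expect_error(minmax_normalize(c(5, 5, 5)), "constant")

  withr::with_seed(9, {
    for (i in 1:10) {
      z <- rnorm(50)
      a <- runif(1, 0.1, 10)
      b <- runif(1, -5, 5)
      expect_equal(minmax_normalize(a * z + b), minmax_normalize(z),
                   tolerance = 1e-12)
    }
  })
})

test_that("peptide-band masking interpolates, is idempotent, validates regions", {
  wn <- raman_axis()
  flat <- spectra_tbl(matrix(0.5, 1, length(wn)), wn)
  expect_equal(intensity_matrix(mask_peptide_bands(flat)),
               intensity_matrix(flat))

  bump <- 0.2 + 0.8 / (1 + ((wn - 1660) / 10)^2)
  x <- spectra_tbl(matrix(bump, 1), wn)
  masked <- mask_peptide_bands(x)
  m <- as.numeric(intensity_matrix(masked))
  inside <- wn >= 1630 & wn <= 1700
  edges <- max(m[!inside & wn >= 1620 & wn <= 1710])
  expect_lte(max(m[inside]), edges + 1e-9)

  expect_equal(intensity_matrix(mask_peptide_bands(masked)),
               intensity_matrix(masked))
  expect_error(mask_peptide_bands(x, list(c(1700, 1630))), "hi > lo")
})

test_that("SNR separates clean, noisy and signal-free spectra and is scale-free", {
  wn <- raman_axis()
  cfg <- preprocess_config()
  clean <- render_spectrum("F", wn, noise_model(baseline_amp = 0.4,
                                                additive_sigma = 0,
                                                band_jitter_rel = 0), seed = 1)
  snr_clean <- estimate_snr(spectra_tbl(matrix(clean, 1), wn), cfg)
  expect_gt(snr_clean, 200)

  noisy <- render_spectrum("F", wn, noise_model(), seed = 1)
  snr_noisy <- estimate_snr(spectra_tbl(matrix(noisy, 1), wn), cfg)
  expect_gt(snr_clean, 2 * snr_noisy)

  # doubling sigma roughly halves the SNR (averaged over replicates)
  snr_at <- function(s) {
    mean(vapply(1:12, function(i) {
      y <- render_spectrum("F", wn, noise_model(additive_sigma = s),
                           seed = 40 + i)
      estimate_snr(spectra_tbl(matrix(y, 1), wn), cfg)
    }, numeric(1)))
  }
  ratio <- snr_at(0.02) / snr_at(0.01)
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)

  # pure white noise, no bands
  withr::with_seed(10, {
    wnoise <- rnorm(length(wn), sd = 0.05)
    expect_lt(estimate_snr(spectra_tbl(matrix(wnoise, 1), wn), cfg), 10)
  })

  # global intensity scaling leaves SNR unchanged
  snr_scaled <- estimate_snr(spectra_tbl(matrix(137 * noisy, 1), wn), cfg)
  expect_equal(snr_scaled, snr_noisy, tolerance = 1e-6)
})

test_that("filter_dataset enforces threshold, top-k, balance and tie-breaks", {
  wn <- tiny_axis(40)
  n <- 24
  withr::with_seed(12, {
    x <- spectra_tbl(matrix(runif(n * 40), n), wn,
                     label = rep(c("A", "C"), each = 12))
  })
  snr <- c(seq(100, 45, length.out = 12),   # A: 10 pass (>= 50)
           rep(c(80, 60), 6))               # C: all pass, with ties
  cfg <- preprocess_config(snr_threshold = 50, top_k = 6)
  out <- filter_dataset(x, cfg, snr = snr)
  expect_equal(as.numeric(table(out$label)), c(6, 6))
  expect_equal(nrow(out), 12)
  # top-k by descending SNR
  expect_equal(out$snr[out$label == "A"], sort(snr[1:12], decreasing = TRUE)[1:6])
  # ties broken by original row order: the six C spectra with snr 80 come
  # from the odd original positions in order
  c80 <- out[out$label == "C" & out$snr == 80, ]
  expect_equal(nrow(c80), 6)

  # class with too few survivors is named (A keeps 11 of 12 above 50)
  cfg2 <- preprocess_config(snr_threshold = 50, top_k = 12)
  expect_error(filter_dataset(x, cfg2, snr = snr), "A")

  # threshold -Inf, k = n is the identity up to ordering
  cfg3 <- preprocess_config(snr_threshold = -Inf, top_k = 12)
  out3 <- filter_dataset(x, cfg3, snr = snr)
  expect_equal(nrow(out3), n)
  expect_equal(sort(out3$snr), sort(snr))
})

test_that("the preprocessing pipeline normalizes every spectrum and is stable", {
  x <- generate_dataset(2, noise_model(), seed = 21)
  cfg <- preprocess_config()
  pp <- preprocess_pipeline(x, cfg)
  m <- intensity_matrix(pp)
  expect_equal(unname(apply(m, 1, min)), rep(0, nrow(m)))
  expect_equal(unname(apply(m, 1, max)), rep(1, nrow(m)))

  # near-idempotence: re-running the chain changes values only slightly
  # (a second Savitzky-Golay pass broadens peaks a little, so the change
  # is small but not zero)
  pp2 <- preprocess_pipeline(pp, cfg)
  rms <- sqrt(mean((intensity_matrix(pp2) - m)^2))
  expect_lt(rms, 0.02)

  # masking during the pipeline empties the amide windows
  prot <- simulate_protein_spectrum(composition(rep(0.05, 20)),
                                    noise_model(), seed = 5)
  pm <- preprocess_pipeline(prot, cfg, mask = TRUE)
  wn <- spectra_wavenumbers(pm)
  ym <- as.numeric(intensity_matrix(pm))
  i1660 <- which.min(abs(wn - 1660))
  pn <- preprocess_pipeline(prot, cfg, mask = FALSE)
  expect_gt(as.numeric(intensity_matrix(pn))[i1660], ym[i1660] + 0.2)
})
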