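noise_free <- noise_model(baseline_amp = 0, additive_sigma = 0,
                          band_jitter_rel = 0, poor_fraction = 0)

test_that("template library has 20 distinguishable classes with anchored bands", {
  lib <- template_library()
  expect_setequal(unique(lib$amino_acid), amino_acids())
  # every class: unique centers, dominant amplitude 1, plausible widths
  by_class <- split(lib, lib$amino_acid)
  for (b in by_class) {
    expect_false(anyDuplicated(b$center) > 0)
    expect_equal(max(b$amplitude), 1)
    expect_true(all(b$hwhm >= 4 & b$hwhm <= 12))
    expect_true(dplyr::between(nrow(b), 3, 12))
  }
  dominant <- function(aa) {
    b <- by_class[[aa]]
    b$center[which.max(b$amplitude)]
  }
  expect_equal(dominant("W"), 1552)
  expect_equal(dominant("A"), 1445)
  expect_equal(dominant("F"), 1000)
  expect_true(760 %in% by_class$W$center)
  expect_true(1033 %in% by_class$F$center)

  # pairwise distinguishability of noise-free renders
  wn <- raman_axis()
  M <- t(sapply(amino_acids(), function(a)
    render_spectrum(a, wn, noise_free, seed = 1)))
  M <- M / sqrt(rowSums(M^2))
  cs <- tcrossprod(M)
  diag(cs) <- 0
  expect_lt(max(cs), 0.95)
})

test_that("rendering is deterministic and peaks at the dominant band", {
  wn <- tiny_axis(500)
  y1 <- render_spectrum("W", wn, noise_model(), seed = 5)
  y2 <- render_spectrum("W", wn, noise_model(), seed = 5)
  expect_identical(y1, y2)
  y3 <- render_spectrum("W", wn, noise_model(), seed = 6)
  expect_false(identical(y1, y3))

  clean <- render_spectrum("W", wn, noise_free, seed = 1)
  expect_equal(wn[which.max(clean)], 1552, tolerance = 3)

  bad_axis <- raman_axis(400, 700, 100) # excludes most band centers
  expect_error(render_spectrum("W", bad_axis, noise_free, 1), "outside")
})

test_that("estimated SNR decreases monotonically with additive noise", {
  wn <- raman_axis()
  cfg <- preprocess_config()
  snr_at <- function(s) {
    mean(vapply(1:5, function(i) {
      y <- render_spectrum("F", wn, noise_model(additive_sigma = s), seed = i)
      estimate_snr(spectra_tbl(matrix(y, 1), wn), cfg)
    }, numeric(1)))
  }
  v <- c(snr_at(0.01), snr_at(0.02), snr_at(0.04))
  expect_true(all(diff(v) < 0))
})

test_that("generate_dataset has the right shape, metadata and determinism", {
  one <- generate_dataset(1, noise_model(), seed = 2, wavenumbers = tiny_axis())
  expect_equal(nrow(one), 20)
  expect_setequal(one$label, amino_acids())

  a <- generate_dataset(3, noise_model(), seed = 2, wavenumbers = tiny_axis())
  b <- generate_dataset(3, noise_model(), seed = 2, wavenumbers = tiny_axis())
  expect_identical(a, b)
  c <- generate_dataset(3, noise_model(), seed = 9, wavenumbers = tiny_axis())
  expect_identical(a$label, c$label)
  expect_identical(a$replicate, c$replicate)
  expect_false(identical(intensity_matrix(a), intensity_matrix(c)))
})

test_that("mixtures are renormalized weighted sums with the stated composition", {
  wn <- tiny_axis(400)
  # degenerate single-component mixture = normalized noise-free render
  mx <- simulate_mixture(c(A = 1), noise_free, seed = 3, wavenumbers = wn)
  ref <- render_spectrum("A", wn, noise_free, seed = 3)
  expect_equal(as.numeric(intensity_matrix(mx$spectrum)),
               (ref - min(ref)) / (max(ref) - min(ref)), tolerance = 1e-12)

  # weight renormalization invariance
  m1 <- simulate_mixture(c(D = 2, H = 2), noise_free, seed = 4, wavenumbers = wn)
  m2 <- simulate_mixture(c(D = 0.5, H = 0.5), noise_free, seed = 4,
                         wavenumbers = wn)
  expect_equal(intensity_matrix(m1$spectrum), intensity_matrix(m2$spectrum))

  v <- setNames(m1$composition$fraction, m1$composition$amino_acid)
  expect_equal(unname(v[c("D", "H")]), c(0.5, 0.5))
  expect_equal(sum(v), 1)

  # noise-free mixture linearity against hand-built weighted sum
  w <- c(C = 0.25, M = 0.75)
  mx2 <- simulate_mixture(w, noise_free, seed = 5, wavenumbers = wn)
  comps <- sapply(names(w), function(a) {
    y <- render_spectrum(a, wn, noise_free, seed = 5)
    (y - min(y)) / (max(y) - min(y))
  })
  manual <- comps %*% w
  manual <- (manual - min(manual)) / (max(manual) - min(manual))
  expect_equal(as.numeric(intensity_matrix(mx2$spectrum)), as.numeric(manual),
               tolerance = 1e-9)

  expect_error(simulate_mixture(c(Zz = 1), noise_free, 1), "unknown")
})

test_that("protein spectra carry all constituents and removable amide bands", {
  wn <- raman_axis()
  uni <- composition(rep(0.05, 20))
  prot <- simulate_protein_spectrum(uni, noise_free, seed = 6,
                                    include_amide = FALSE, wavenumbers = wn)
  y <- as.numeric(intensity_matrix(prot))
  lib <- template_library()
  dom <- vapply(split(lib, lib$amino_acid),
                function(b) b$center[which.max(b$amplitude)], numeric(1))
  for (ctr in dom) {
    expect_gt(y[which.min(abs(wn - ctr))], 0.04)
  }

  # pure-class degenerate case
  pure <- simulate_protein_spectrum(c(A = 1), noise_free, seed = 7,
                                    include_amide = FALSE, wavenumbers = wn)
  ref <- render_spectrum("A", wn, noise_free, seed = 7)
  expect_equal(as.numeric(intensity_matrix(pure)),
               (ref - min(ref)) / (max(ref) - min(ref)), tolerance = 1e-12)

  # amide bands appear near 1665/1265 and masking removes them
  amide_on <- simulate_protein_spectrum(uni, noise_free, seed = 6,
                                        include_amide = TRUE, wavenumbers = wn)
  ya <- as.numeric(intensity_matrix(amide_on))
  i1665 <- which.min(abs(wn - 1665))
  expect_gt(ya[i1665] - y[i1665], 0.3)
  masked <- mask_peptide_bands(amide_on)
  ym <- as.numeric(intensity_matrix(masked))
  expect_lt(ym[i1665], 0.1)
  expect_lt(mean(abs(ym - y)), 0.01)
  expect_lt(max(abs(ym - y)), 0.1)
})

test_that("default noise keeps per-band replicate CV inside (0, 20)%", {
  wn <- raman_axis()
  reps <- 30
  for (aa in c("W", "A", "Q")) {
    m <- t(sapply(seq_len(reps), function(i)
      render_spectrum(aa, wn, noise_model(), seed = 100 + i)))
    for (j in seq_len(nrow(m))) {
      m[j, ] <- savgol_smooth(m[j, ] - als_baseline(m[j, ]))
    }
    cv <- cv_report(spectra_tbl(m, wn, label = rep(aa, reps)))
    expect_true(all(cv$cv > 0))
    expect_true(all(cv$cv < 20))
  }
})
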