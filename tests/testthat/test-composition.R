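test_that("composition construction validates and coerces", {
  u <- composition(rep(0.05, 20))
  expect_equal(sum(u$fraction), 1)
  expect_equal(u$amino_acid, amino_acids())

  named <- composition(c(Trp = 0.25, G = 0.75))
  expect_equal(named$fraction[named$amino_acid == "W"], 0.25)

  expect_error(composition(rep(0.06, 20)), "sum to 1")
  expect_error(composition(c(A = -0.1, C = 1.1)), "non-negative")
  expect_equal(as_composition(u), u)
})

test_that("error metrics reproduce hand arithmetic and basic identities", {
  expect_equal(mse(c(0.6, 0.4), c(0.5, 0.5)), 0.01, tolerance = 1e-9)
  expect_equal(rmse(c(0.6, 0.4), c(0.5, 0.5)), 0.1, tolerance = 1e-9)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(nrmse(c(0.6, 0.4), c(0.5, 0.5)), "constant")
  expect_equal(nrmse(c(0.7, 0.2, 0.1), c(0.5, 0.3, 0.2)),
               rmse(c(0.7, 0.2, 0.1), c(0.5, 0.3, 0.2)) / 0.3,
               tolerance = 1e-12)

  a <- composition(c(A = 0.6, C = 0.4))
  b <- composition(c(A = 0.5, C = 0.5))
  expect_equal(mse_composition(a, b), (0.01 + 0.01) / 20)
  expect_equal(rmse_composition(a, b), sqrt(0.001))
  expect_equal(rmse_composition(a, a), 0)

  withr::with_seed(17, {
    for (i in 1:10) {
      p <- composition(prop.table(runif(20)))
      r <- composition(prop.table(runif(20)))
      expect_equal(rmse_composition(p, r), sqrt(mse_composition(p, r)),
                   tolerance = 1e-12)
      expect_equal(rmse_composition(p, r), rmse_composition(r, p))
      expect_lte(rmse_composition(p, r), max(abs(p$fraction - r$fraction)))
      expect_gte(nrmse_composition(p, r), rmse_composition(p, r))
    }
  })
})

test_that("most_abundant uses canonical-order tie-breaking", {
  expect_equal(most_abundant(composition(c(A = 1))), "A")
  expect_equal(most_abundant(composition(rep(0.05, 20))), "A")
  expect_equal(most_abundant(composition_from_sequence("GGGAL")), "G")
  expect_equal(most_abundant(composition(c(C = 0.5, W = 0.5))), "C")
})

test_that("coefficient of variation matches the definition and is scale-free", {
  expect_equal(coefficient_of_variation(c(3, 3, 3)), 0)
  expect_equal(coefficient_of_variation(c(4, 6)), 100 * sqrt(2) / 5,
               tolerance = 1e-9)
  withr::with_seed(18, {
    v <- rexp(30) + 1
    expect_equal(coefficient_of_variation(7.3 * v),
                 coefficient_of_variation(v), tolerance = 1e-12)
  })
  expect_error(coefficient_of_variation(c(5)), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "mean")
})

test_that("major band detection recovers the documented marker bands", {
  wn <- raman_axis()
  nf <- noise_model(baseline_amp = 0, additive_sigma = 0,
                    band_jitter_rel = 0, poor_fraction = 0)
  clean <- spectra_tbl(
    do.call(rbind, lapply(c("W", "A", "F"), function(a)
      render_spectrum(a, wn, nf, seed = 1))),
    wn, label = c("W", "A", "F"))

  top2 <- major_bands(clean, n_bands = 2)
  tol <- 1.5 # one channel
  w_bands <- sort(top2$band[top2$label == "W"])
  expect_equal(w_bands, c(760, 1552), tolerance = tol)
  expect_equal(major_bands(clean, n_bands = 1) |>
                 dplyr::filter(label == "A") |> dplyr::pull(band),
               1445, tolerance = tol)
  f_bands <- sort(top2$band[top2$label == "F"])
  expect_equal(f_bands, c(1000, 1033), tolerance = tol)

  # single-Lorentzian toy
  toy <- spectra_tbl(matrix(1 / (1 + ((wn - 900) / 8)^2), 1), wn,
                     label = "toy")
  expect_equal(major_bands(toy, n_bands = 1)$band, 900, tolerance = tol)

  # small additive noise leaves the top template bands in place: every
  # clean band is recovered within ~2 channels among the same number of
  # top noisy peaks
  withr::with_seed(19, {
    for (a in c("W", "Q", "L")) {
      y <- render_spectrum(a, wn, nf, seed = 2)
      clean_bands <- suppressWarnings(
        major_bands(spectra_tbl(matrix(y, 1), wn, label = a)))
      k <- nrow(clean_bands)
      noisy_bands <- suppressWarnings(major_bands(
        spectra_tbl(matrix(y + rnorm(length(wn), sd = 0.01), 1), wn,
                    label = a), n_bands = k))
      for (b in clean_bands$band) {
        expect_true(any(abs(noisy_bands$band - b) <= 2.6),
                    label = paste("band", b, "of", a, "recovered"))
      }
    }
  })
})

test_that("cv_report is zero for identical replicates and scales with jitter", {
  wn <- tiny_axis(500)
  nf <- noise_model(baseline_amp = 0, additive_sigma = 0,
                    band_jitter_rel = 0, poor_fraction = 0)
  y <- render_spectrum("L", wn, nf, seed = 1)
  dup <- spectra_tbl(rbind(y, y, y), wn, label = rep("L", 3))
  cv0 <- cv_report(dup)
  expect_true(all(cv0$cv == 0))

  gen_cv <- function(jit) {
    m <- t(sapply(1:40, function(i)
      render_spectrum("L", wn,
                      noise_model(baseline_amp = 0, additive_sigma = 0,
                                  band_jitter_rel = jit),
                      seed = 300 + i)))
    stats::median(cv_report(spectra_tbl(m, wn, label = rep("L", 40)))$cv)
  }
  ratio <- gen_cv(0.16) / gen_cv(0.08)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)

  # CV invariant to global rescaling of all replicates
  m <- t(sapply(1:10, function(i)
    render_spectrum("L", wn, noise_model(baseline_amp = 0), seed = i)))
  cv1 <- cv_report(spectra_tbl(m, wn, label = rep("L", 10)))
  cv2 <- cv_report(spectra_tbl(5 * m, wn, label = rep("L", 10)))
  expect_equal(cv1$cv, cv2$cv, tolerance = 1e-9)

  expect_error(cv_report(dup[1, ]), ">= 2")
})

test_that("composition estimation averages probability rows", {
  x <- toy_two_class(n_per_class = 12)
  fit <- train_classifier(x, toy_model_cfg(),
                          train_config(max_epochs = 8, val_fraction = 0.25,
                                       batch_size = 8, seed = 21))
  one <- x[1, ]
  est1 <- estimate_composition(fit, one)
  p1 <- as.matrix(predict_proba(fit, one)[, fit$classes])
  expect_equal(est1$fraction[match(fit$classes, est1$amino_acid)],
               as.numeric(p1), tolerance = 1e-12)

  sub <- x[c(2, 7, 20), ]
  est_a <- estimate_composition(fit, sub)
  est_b <- estimate_composition(fit, sub[c(3, 1, 2), ])
  expect_equal(est_a, est_b)

  # evaluate_protein report is internally consistent
  ref <- estimate_composition(fit, sub)
  rep_out <- evaluate_protein(fit, sub, ref)
  expect_equal(rep_out$rmse, 0, tolerance = 1e-12)
  expect_true(rep_out$top1_match)
  ref2 <- composition(c(A = 0.7, W = 0.3))
  rep2 <- evaluate_protein(fit, sub, ref2)
  expect_equal(rep2$rmse,
               rmse_composition(estimate_composition(fit, sub), ref2),
               tolerance = 1e-12)
  expect_equal(rep2$rmse, sqrt(rep2$mse), tolerance = 1e-12)
})
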