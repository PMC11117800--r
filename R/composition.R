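#' Composition tables
#'
#' A composition is a tibble with one row per canonical amino acid
#' (`amino_acid`, one-letter code, canonical order) and a `fraction` column:
#' non-negative values summing to 1. `composition()` builds and validates
#' one from a numeric vector (named or in canonical order);
#' `as_composition()` coerces tibbles, named vectors, or passes a valid
#' composition through.
#'
#' @param fractions numeric vector of 20 fractions, optionally named by
#'   amino-acid code; or, for a subset, a named vector whose remaining
#'   amino acids are taken as 0.
#' @return a composition tibble.
#' @examples
#' composition(c(A = 0.5, G = 0.5))
#' @export
composition <- function(fractions) {
  aa <- amino_acids()
  if (!is.null(names(fractions))) {
    nm <- aa_code(names(fractions))
    if (anyDuplicated(nm)) stop("duplicated amino acids", call. = FALSE)
    full <- stats::setNames(numeric(20L), aa)
    full[nm] <- as.numeric(fractions)
    fractions <- full
  }
  fractions <- as.numeric(fractions)
  if (length(fractions) != 20L) {
    stop("a composition needs 20 fractions (or a named subset)", call. = FALSE)
  }
  if (anyNA(fractions) || any(fractions < 0)) {
    stop("fractions must be finite and non-negative", call. = FALSE)
  }
  s <- sum(fractions)
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("fractions must sum to 1 (got %.12f)", s), call. = FALSE)
  }
  tibble::tibble(amino_acid = aa, fraction = fractions)
}

#' @rdname composition
#' @param x object to coerce.
#' @export
as_composition <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("amino_acid", "fraction") %in% names(x)))
    v <- stats::setNames(x$fraction, x$amino_acid)
    return(composition(v))
  }
  composition(x)
}

comp_vec <- function(x) {
  x <- as_composition(x)
  stats::setNames(x$fraction, x$amino_acid)
}

#' Error metrics
#'
#' The standard prediction-error formulas over paired numeric vectors:
#' MSE = (1/n) * sum((pred_i - ref_i)^2) with n the vector length,
#' RMSE = sqrt(MSE), and NRMSE = RMSE / (max(ref) - min(ref)), the
#' range-normalized convention. The `_composition` variants apply them to
#' two compositions over all 20 amino-acid fractions (n = 20).
#'
#' @param pred,ref numeric vectors of equal length, or (for the
#'   `_composition` variants) compositions as accepted by
#'   [as_composition()].
#' @return a single non-negative number.
#' @examples
#' rmse(c(0.6, 0.4), c(0.5, 0.5)) # 0.1
#' @export
mse <- function(pred, ref) {
  stopifnot(is.numeric(pred), is.numeric(ref), length(pred) == length(ref),
            length(pred) > 0L)
  if (!is.null(names(pred)) && !is.null(names(ref))) {
    if (!identical(sort(names(pred)), sort(names(ref)))) {
      stop("pred and ref have different keys", call. = FALSE)
    }
    ref <- ref[names(pred)]
  }
  mean((pred - ref)^2)
}

#' @rdname mse
#' @export
rmse <- function(pred, ref) sqrt(mse(pred, ref))

#' @rdname mse
#' @export
nrmse <- function(pred, ref) {
  rng <- max(ref) - min(ref)
  if (rng <= 0) stop("constant reference: NRMSE undefined", call. = FALSE)
  rmse(pred, ref) / rng
}

#' @rdname mse
#' @export
mse_composition <- function(pred, ref) {
  mse(comp_vec(pred), comp_vec(ref))
}

#' @rdname mse
#' @export
rmse_composition <- function(pred, ref) sqrt(mse_composition(pred, ref))

#' @rdname mse
#' @export
nrmse_composition <- function(pred, ref) {
  r <- comp_vec(ref)
  rng <- max(r) - min(r)
  if (rng <= 0) stop("reference composition is constant; NRMSE undefined",
                     call. = FALSE)
  rmse_composition(pred, ref) / rng
}

#' Most abundant amino acid of a composition
#'
#' Ties are broken by canonical (alphabetical one-letter) order.
#'
#' @param comp a composition.
#' @return one-letter amino-acid code.
#' @export
most_abundant <- function(comp) {
  v <- comp_vec(comp)
  names(v)[which.max(v)]
}

#' Coefficient of variation
#'
#' CV = (sigma / mu) * 100 with the sample standard deviation (n - 1
#' denominator), the usual reproducibility metric for replicate band
#' intensities.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(4, 6)) # 28.28427
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  mu <- mean(values)
  if (mu == 0) stop("mean is zero; CV undefined", call. = FALSE)
  100 * stats::sd(values) / mu
}

#' Major Raman bands of each class
#'
#' Detects peaks (local maxima separated by at least `min_distance` cm^-1
#' and taller than `min_height` times the class-mean maximum) on each
#' class-mean spectrum and keeps the `n_bands` tallest. Classes with fewer
#' detectable peaks return all found, with a warning.
#'
#' @param x labeled spectra tibble.
#' @param n_bands bands to keep per class (default 10).
#' @param min_height minimum peak height as a fraction of the class-mean
#'   maximum.
#' @param min_distance minimum separation between reported peaks, cm^-1.
#' @return tibble with columns `label`, `band` (center, cm^-1), `height`.
#' @export
major_bands <- function(x, n_bands = 10, min_height = 0.05,
                        min_distance = 10) {
  stopifnot("label" %in% names(x))
  wn <- spectra_wavenumbers(x)
  m <- intensity_matrix(x)
  step <- stats::median(diff(wn))
  dist_pts <- max(1L, round(min_distance / step))
  out <- lapply(split(seq_len(nrow(x)), x$label), function(idx) {
    mu <- colMeans(m[idx, , drop = FALSE])
    pk <- pracma::findpeaks(mu,
                            minpeakheight = min_height * max(mu),
                            minpeakdistance = dist_pts)
    if (is.null(pk)) return(tibble::tibble(band = numeric(), height = numeric()))
    ord <- order(pk[, 1L], decreasing = TRUE)
    keep <- utils::head(ord, n_bands)
    tibble::tibble(band = wn[pk[keep, 2L]], height = pk[keep, 1L])
  })
  res <- dplyr::bind_rows(out, .id = "label")
  short <- res |> dplyr::count(.data$label) |> dplyr::filter(.data$n < n_bands)
  if (nrow(short) > 0L) {
    warning("fewer than ", n_bands, " detectable bands for: ",
            paste(short$label, collapse = ", "), call. = FALSE)
  }
  res
}

#' Replicate reproducibility of major band intensities
#'
#' For each labeled class, locates the major bands on the class-mean
#' spectrum (see [major_bands()]) and computes mean, sample standard
#' deviation and CV of the intensity at each band's fixed channel across
#' replicates. Reading at the fixed class-mean channel makes the CV measure
#' intensity variability, not peak-shift variability. Apply baseline
#' correction (and optionally smoothing) first; per-spectrum min-max
#' normalization would pin dominant bands at 1 and is not meaningful here.
#'
#' @param x labeled spectra tibble with >= 2 replicates per class.
#' @param n_bands bands per class (default 10).
#' @return tibble with columns `label`, `band`, `mean`, `sd`, `cv`.
#' @export
cv_report <- function(x, n_bands = 10) {
  stopifnot("label" %in% names(x))
  counts <- table(x$label)
  if (any(counts < 2L)) stop("need >= 2 replicates per class", call. = FALSE)
  wn <- spectra_wavenumbers(x)
  m <- intensity_matrix(x)
  bands <- suppressWarnings(major_bands(x, n_bands = n_bands))
  bands |>
    dplyr::group_by(.data$label, .data$band) |>
    dplyr::reframe({
      idx <- which(x$label == .data$label[[1L]])
      ch <- which.min(abs(wn - .data$band[[1L]]))
      v <- m[idx, ch]
      tibble::tibble(mean = mean(v), sd = stats::sd(v),
                     cv = coefficient_of_variation(v))
    }) |>
    dplyr::arrange(.data$label, dplyr::desc(.data$mean))
}

#' Estimate sample composition from classifier probabilities
#'
#' The decomposition step: averages the per-spectrum class probabilities of
#' a trained classifier over all replicate spectra of a sample and reads
#' the mean probability vector as the sample's amino-acid composition.
#'
#' @param model a fitted [train_classifier()] model.
#' @param x spectra tibble of replicate spectra of one sample, preprocessed
#'   on the model's axis.
#' @param aggregate `"mean_proba"` (default) averages per-spectrum
#'   probability rows; `"mean_spectrum"` predicts once from the channel-wise
#'   mean spectrum.
#' @return a composition tibble.
#' @export
estimate_composition <- function(model, x,
                                 aggregate = c("mean_proba", "mean_spectrum")) {
  aggregate <- match.arg(aggregate)
  if (nrow(x) == 0L) stop("need at least one spectrum", call. = FALSE)
  if (aggregate == "mean_spectrum") {
    wn <- spectra_wavenumbers(x)
    x <- spectra_tbl(matrix(colMeans(intensity_matrix(x)), 1L), wn)
  }
  p <- predict_proba(model, x)
  composition(colMeans(as.matrix(p[, model$classes])))
}

#' Evaluate a protein composition prediction
#'
#' Runs [estimate_composition()] on the protein's replicate spectra and
#' compares the estimate with a reference composition: MSE, RMSE,
#' range-normalized RMSE, and whether the most abundant amino acid was
#' recovered.
#'
#' @param model a fitted classifier.
#' @param x preprocessed protein spectra (peptide-band masking should have
#'   been applied during preprocessing).
#' @param ref reference composition (e.g. from
#'   [composition_from_sequence()]).
#' @inheritParams estimate_composition
#' @return one-row tibble: `n`, `mse`, `rmse`, `nrmse`,
#'   `most_abundant_pred`, `most_abundant_ref`, `top1_match`.
#' @export
evaluate_protein <- function(model, x, ref, aggregate = "mean_proba") {
  ref <- as_composition(ref)
  est <- estimate_composition(model, x, aggregate = aggregate)
  m <- mse_composition(est, ref)
  tibble::tibble(
    n = nrow(x),
    mse = m,
    rmse = sqrt(m),
    nrmse = nrmse_composition(est, ref),
    most_abundant_pred = most_abundant(est),
    most_abundant_ref = most_abundant(ref),
    top1_match = most_abundant(est) == most_abundant(ref)
  )
}
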