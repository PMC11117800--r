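#' Preprocessing configuration
#'
#' Bundles the parameters of the preprocessing chain: asymmetric least
#' squares (ALS) background subtraction, Savitzky-Golay smoothing,
#' peptide-band masking, min-max normalization, and the SNR quality filter.
#' Defaults follow common spectroscopy practice: ALS lambda = 1e5,
#' p = 0.01, 10 iterations; Savitzky-Golay window 11, polynomial order 3;
#' SNR threshold 50 with the top 33 spectra kept per class; mask regions
#' covering the amide I (1630-1700 cm^-1) and amide III (1230-1300 cm^-1)
#' peptide-bond bands. The amide II region is deliberately not masked by
#' default: it would delete tryptophan's 1552 cm^-1 marker band.
#'
#' @param als_lambda ALS smoothness weight (> 0).
#' @param als_p ALS asymmetry in (0, 1); small values hug the spectrum from
#'   below.
#' @param als_iters ALS reweighting iterations.
#' @param sg_window odd Savitzky-Golay window length (>= 5).
#' @param sg_polyorder polynomial order (< `sg_window`).
#' @param mask_regions list of `c(lo, hi)` intervals in cm^-1.
#' @param snr_threshold minimum acceptable SNR.
#' @param top_k spectra kept per class after filtering.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(als_lambda = 1e5, als_p = 0.01, als_iters = 10,
                              sg_window = 11, sg_polyorder = 3,
                              mask_regions = list(c(1230, 1300), c(1630, 1700)),
                              snr_threshold = 50, top_k = 33) {
  stopifnot(als_lambda > 0, als_p > 0, als_p < 1, als_iters >= 1,
            sg_window >= 5, sg_window %% 2 == 1, sg_polyorder < sg_window,
            top_k >= 1)
  structure(list(als_lambda = als_lambda, als_p = als_p,
                 als_iters = als_iters, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, mask_regions = mask_regions,
                 snr_threshold = snr_threshold, top_k = top_k),
            class = "preprocess_config")
}

#' Asymmetric least squares baseline
#'
#' Estimates the broad fluorescence background by iteratively reweighted
#' penalized least squares with a second-difference smoothness penalty
#' `lambda` and asymmetry `p`: points above the current baseline get weight
#' `p`, points below get `1 - p`, so the fit hugs the spectrum from below
#' and passes under the narrow Raman bands.
#'
#' @param y numeric intensity vector.
#' @param lambda smoothness weight.
#' @param p asymmetry parameter in (0, 1).
#' @param iters reweighting iterations.
#' @return baseline vector, same length as `y`.
#' @export
als_baseline <- function(y, lambda = 1e5, p = 0.01, iters = 10) {
  if (!all(is.finite(y))) stop("non-finite intensities", call. = FALSE)
  n <- length(y)
  if (n < 5L) stop("need at least 5 points", call. = FALSE)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(iters)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing via [signal::sgolayfilt()].
#' Polynomials of degree up to `polyorder` pass through unchanged away from
#' the edges.
#'
#' @param y numeric intensity vector.
#' @param window odd window length.
#' @param polyorder polynomial order, less than `window`.
#' @return smoothed vector.
#' @export
savgol_smooth <- function(y, window = 11, polyorder = 3) {
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  as.numeric(signal::sgolayfilt(y, p = polyorder, n = window))
}

#' Min-max normalization to [0, 1]
#'
#' `(y - min) / (max - min)`. A constant spectrum is a degenerate input
#' (typically a dead detector row) and raises an error rather than being
#' silently zeroed.
#'
#' @param y numeric vector with `max(y) > min(y)`.
#' @return vector with minimum 0 and maximum 1.
#' @export
minmax_normalize <- function(y) {
  if (!all(is.finite(y))) stop("non-finite intensities", call. = FALSE)
  rng <- range(y)
  if (rng[[2L]] <= rng[[1L]]) {
    stop("constant spectrum: min-max normalization undefined", call. = FALSE)
  }
  (y - rng[[1L]]) / (rng[[2L]] - rng[[1L]])
}

# linear interpolation across one masked interval of a single spectrum
mask_one <- function(y, wn, lo, hi) {
  if (hi <= lo) stop("mask region must have hi > lo", call. = FALSE)
  inside <- which(wn >= lo & wn <= hi)
  if (length(inside) == 0L) return(y)
  left <- max(1L, min(inside) - 1L)
  right <- min(length(y), max(inside) + 1L)
  y[inside] <- stats::approx(x = wn[c(left, right)], y = y[c(left, right)],
                             xout = wn[inside], rule = 2)$y
  y
}

#' Mask peptide-bond (amide) band regions
#'
#' Replaces channels inside each masked interval with the straight line
#' between the interval's edge channels, so proteins and free amino acids
#' share one fixed-width channel grid. Idempotent.
#'
#' @param x spectra tibble.
#' @param mask_regions list of `c(lo, hi)` cm^-1 intervals (default from
#'   [preprocess_config()]).
#' @return spectra tibble with masked intensities.
#' @export
mask_peptide_bands <- function(x, mask_regions = preprocess_config()$mask_regions) {
  wn <- spectra_wavenumbers(x)
  m <- intensity_matrix(x)
  for (reg in mask_regions) {
    for (i in seq_len(nrow(m))) m[i, ] <- mask_one(m[i, ], wn, reg[[1L]], reg[[2L]])
  }
  set_intensities(x, m)
}

snr_one <- function(y, config) {
  corrected <- y - als_baseline(y, config$als_lambda, config$als_p,
                                config$als_iters)
  smooth <- savgol_smooth(corrected, config$sg_window, config$sg_polyorder)
  resid_sd <- max(stats::sd(corrected - smooth), 1e-12)
  max(smooth) / resid_sd
}

#' Per-spectrum signal-to-noise ratio
#'
#' SNR = peak of the background-subtracted, Savitzky-Golay-smoothed signal,
#' divided by the standard deviation of the smoothing residual (floored at
#' 1e-12). Scale-invariant and computable from a single spectrum, with no
#' replicate requirement.
#'
#' @param x spectra tibble.
#' @param config a [preprocess_config()].
#' @return numeric vector, one SNR per row of `x`.
#' @export
estimate_snr <- function(x, config = preprocess_config()) {
  m <- intensity_matrix(x)
  apply(m, 1L, snr_one, config = config)
}

#' SNR threshold and per-class top-k selection
#'
#' Drops spectra whose SNR falls below `config$snr_threshold`, then keeps
#' the `config$top_k` highest-SNR spectra of every class (ties broken by
#' original row order), enforcing a perfectly class-balanced output. With
#' the defaults (threshold 50, k = 33) a 121-per-class map dataset reduces
#' to 660 spectra.
#'
#' @param x labeled spectra tibble.
#' @param config a [preprocess_config()].
#' @param snr optional precomputed SNR vector (avoids recomputation).
#' @return filtered spectra tibble with an `snr` column, `top_k` rows per
#'   class, classes in canonical order.
#' @export
filter_dataset <- function(x, config = preprocess_config(), snr = NULL) {
  stopifnot("label" %in% names(x))
  if (is.null(snr)) snr <- estimate_snr(x, config)
  stopifnot(length(snr) == nrow(x))
  x$snr <- snr
  x$.row <- seq_len(nrow(x))
  keep <- x |>
    dplyr::filter(.data$snr >= config$snr_threshold) |>
    dplyr::arrange(.data$label, dplyr::desc(.data$snr), .data$.row)
  counts <- table(factor(keep$label, levels = unique(x$label)))
  short <- names(counts)[counts < config$top_k]
  if (length(short) > 0L) {
    stop("class(es) with fewer than top_k spectra above the SNR threshold: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  keep |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_head(n = config$top_k) |>
    dplyr::ungroup() |>
    dplyr::select(-".row")
}

#' The full preprocessing chain
#'
#' For each spectrum, in order: ALS background subtraction, Savitzky-Golay
#' smoothing, optional peptide-band masking, min-max normalization to
#' [0, 1]. Apply masking when the sample may contain peptide bonds
#' (proteins/peptides); the classifier is trained on masked-or-not spectra
#' consistently.
#'
#' @param x spectra tibble.
#' @param config a [preprocess_config()].
#' @param mask apply peptide-band masking (default FALSE for free amino
#'   acids).
#' @return spectra tibble of normalized spectra (each row min 0, max 1).
#' @export
preprocess_pipeline <- function(x, config = preprocess_config(), mask = FALSE) {
  wn <- spectra_wavenumbers(x)
  m <- intensity_matrix(x)
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    y <- y - als_baseline(y, config$als_lambda, config$als_p, config$als_iters)
    y <- savgol_smooth(y, config$sg_window, config$sg_polyorder)
    if (mask) {
      for (reg in config$mask_regions) y <- mask_one(y, wn, reg[[1L]], reg[[2L]])
    }
    m[i, ] <- minmax_normalize(y)
  }
  out <- set_intensities(x, m)
  out$preprocessed <- TRUE
  out
}
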