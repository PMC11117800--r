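#' Noise model for synthetic SERS spectra
#'
#' Calibrated to emulate Raman-map replicate variability: a broad Gaussian
#' fluorescence background, white additive noise, and per-band lognormal
#' multiplicative amplitude jitter (lognormal keeps intensities positive).
#' The defaults are the package's study conditions: `band_jitter_rel = 0.08`
#' puts the per-band replicate CV of dominant-band intensities around 8-12%
#' (comfortably under the 20% reproducibility bound, with most bands under
#' 10%), and `additive_sigma = 0.01` (in units of the dominant band height)
#' puts clean spectra around SNR ~ 100. A fraction `poor_fraction` of
#' map replicates (default 20%) are rendered with `poor_factor` (5x)
#' inflated additive noise, emulating low-signal map points that the SNR-50
#' filter must reject.
#'
#' @param baseline_amp fluorescence amplitude relative to the dominant band.
#' @param baseline_center,baseline_width Gaussian background shape, cm^-1.
#' @param additive_sigma white-noise standard deviation.
#' @param band_jitter_rel relative standard deviation of per-band amplitude
#'   jitter.
#' @param poor_fraction fraction of dataset replicates rendered as poor.
#' @param poor_factor additive-noise inflation factor for poor replicates.
#' @return a `noise_model` list.
#' @export
noise_model <- function(baseline_amp = 0.4,
                        baseline_center = 1000,
                        baseline_width = 600,
                        additive_sigma = 0.01,
                        band_jitter_rel = 0.08,
                        poor_fraction = 0.2,
                        poor_factor = 5) {
  stopifnot(baseline_amp >= 0, baseline_width > 0, additive_sigma >= 0,
            band_jitter_rel >= 0, poor_fraction >= 0, poor_fraction < 1,
            poor_factor >= 1)
  structure(list(baseline_amp = baseline_amp,
                 baseline_center = baseline_center,
                 baseline_width = baseline_width,
                 additive_sigma = additive_sigma,
                 band_jitter_rel = band_jitter_rel,
                 poor_fraction = poor_fraction,
                 poor_factor = poor_factor),
            class = "noise_model")
}

noiseless <- function() {
  noise_model(baseline_amp = 0, additive_sigma = 0, band_jitter_rel = 0,
              poor_fraction = 0)
}

lorentzian_sum <- function(wn, centers, hwhm, amps) {
  out <- numeric(length(wn))
  for (i in seq_along(centers)) {
    out <- out + amps[[i]] / (1 + ((wn - centers[[i]]) / hwhm[[i]])^2)
  }
  out
}

fluorescence_baseline <- function(wn, noise) {
  noise$baseline_amp *
    exp(-((wn - noise$baseline_center)^2) / (2 * noise$baseline_width^2))
}

# lognormal factors with mean 1 and relative sd `rel`
jitter_factors <- function(n, rel) {
  if (rel <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rel^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

render_bands <- function(bands, wn, noise, jitter = TRUE, baseline = TRUE,
                         additive = TRUE, sigma_scale = 1) {
  if (any(bands$center < min(wn) | bands$center > max(wn))) {
    stop("band center outside the wavenumber axis", call. = FALSE)
  }
  amps <- bands$amplitude
  if (jitter) amps <- amps * jitter_factors(length(amps), noise$band_jitter_rel)
  y <- lorentzian_sum(wn, bands$center, bands$hwhm, amps)
  if (baseline) y <- y + fluorescence_baseline(wn, noise)
  if (additive && noise$additive_sigma > 0) {
    y <- y + stats::rnorm(length(wn), sd = sigma_scale * noise$additive_sigma)
  }
  y
}

#' Render one synthetic amino-acid spectrum
#'
#' Sum of Lorentzian bands (with per-band multiplicative jitter) plus
#' fluorescence background plus additive white noise. Deterministic for a
#' fixed seed.
#'
#' @param aa amino-acid identifier (one- or three-letter).
#' @param wavenumbers numeric axis (default [raman_axis()]).
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param library band library (default [template_library()]).
#' @return numeric vector of intensities on `wavenumbers`.
#' @export
render_spectrum <- function(aa, wavenumbers = raman_axis(),
                            noise = noise_model(), seed = 1,
                            library = template_library()) {
  bands <- template_bands(aa, library)
  withr::with_seed(as.integer(seed), render_bands(bands, wavenumbers, noise))
}

#' Generate a labeled synthetic amino-acid dataset
#'
#' Renders `n_per_class` Raman-map replicates for each of the 20 amino
#' acids. A `poor_fraction` share of replicates (per the noise model) is
#' drawn with inflated additive noise to emulate low-SNR map points. The
#' default study scale is `n_per_class = 121`, i.e. 2420 spectra.
#'
#' @inheritParams render_spectrum
#' @param n_per_class replicates per amino acid (>= 1).
#' @return spectra tibble with `label`, `replicate` and `poor` metadata.
#' @examples
#' x <- generate_dataset(2, seed = 1)
#' nrow(x) # 40
#' @export
generate_dataset <- function(n_per_class, noise = noise_model(), seed = 1,
                             wavenumbers = raman_axis(),
                             library = template_library()) {
  stopifnot(n_per_class >= 1)
  aa <- amino_acids()
  withr::with_seed(as.integer(seed), {
    rows <- vector("list", length(aa) * n_per_class)
    label <- character(length(rows))
    replicate <- integer(length(rows))
    poor <- logical(length(rows))
    k <- 0L
    for (a in aa) {
      bands <- template_bands(a, library)
      for (j in seq_len(n_per_class)) {
        k <- k + 1L
        is_poor <- stats::runif(1) < noise$poor_fraction
        rows[[k]] <- render_bands(bands, wavenumbers, noise,
                                  sigma_scale = if (is_poor) noise$poor_factor else 1)
        label[[k]] <- a
        replicate[[k]] <- j
        poor[[k]] <- is_poor
      }
    }
    spectra_tbl(do.call(rbind, rows), wavenumbers,
                label = label, replicate = replicate, poor = poor)
  })
}

minmax01 <- function(y) {
  rng <- range(y)
  if (rng[[2L]] <= rng[[1L]]) stop("constant spectrum", call. = FALSE)
  (y - rng[[1L]]) / (rng[[2L]] - rng[[1L]])
}

#' Simulate a mixture spectrum of amino acids
#'
#' Each component is rendered noise-free except for per-band amplitude
#' jitter, min-max normalized, and the components are combined as a
#' weighted sum (weights renormalized to 1). The sum is rescaled to [0, 1]
#' and the fluorescence background and additive noise are then applied.
#'
#' @param weights named numeric vector of non-negative component weights,
#'   names are amino-acid identifiers (e.g. `c(D = 1, H = 1)`).
#' @inheritParams render_spectrum
#' @return list with `spectrum` (one-row spectra tibble) and `composition`
#'   (the renormalized weights as a composition tibble).
#' @examples
#' mx <- simulate_mixture(c(D = 1, H = 1), seed = 7)
#' mx$composition
#' @export
simulate_mixture <- function(weights, noise = noise_model(), seed = 1,
                             wavenumbers = raman_axis(),
                             library = template_library()) {
  stopifnot(is.numeric(weights), length(weights) >= 1L,
            !is.null(names(weights)), all(weights >= 0), sum(weights) > 0)
  names(weights) <- aa_code(names(weights))
  w <- weights / sum(weights)
  withr::with_seed(as.integer(seed), {
    y <- numeric(length(wavenumbers))
    for (i in seq_along(w)) {
      comp <- render_bands(template_bands(names(w)[[i]], library),
                           wavenumbers, noise,
                           baseline = FALSE, additive = FALSE)
      y <- y + w[[i]] * minmax01(comp)
    }
    y <- minmax01(y) + fluorescence_baseline(wavenumbers, noise)
    if (noise$additive_sigma > 0) {
      y <- y + stats::rnorm(length(y), sd = noise$additive_sigma)
    }
    list(
      spectrum = spectra_tbl(matrix(y, 1L), wavenumbers,
                             label = paste(names(w), collapse = "+")),
      composition = composition(w)
    )
  })
}

#' Simulate a protein SERS spectrum from a composition
#'
#' Composition-weighted sum of min-max-normalized amino-acid renders,
#' optionally with fixed amide bands added (amide I at 1665 cm^-1 and
#' amide III at 1265 cm^-1, the peptide-bond modes that free amino acids
#' lack and that downstream peptide-band masking removes; the bands sit
#' centered in the default mask windows so masking removes them cleanly),
#' then background and additive noise.
#'
#' @param comp a composition (tibble or named vector).
#' @param include_amide add the peptide-bond amide bands (default TRUE).
#' @inheritParams render_spectrum
#' @return one-row spectra tibble.
#' @export
simulate_protein_spectrum <- function(comp, noise = noise_model(), seed = 1,
                                      include_amide = TRUE,
                                      wavenumbers = raman_axis(),
                                      library = template_library()) {
  v <- comp_vec(comp)
  withr::with_seed(as.integer(seed), {
    y <- numeric(length(wavenumbers))
    for (a in names(v)) {
      if (v[[a]] == 0) next
      rendered <- render_bands(template_bands(a, library), wavenumbers, noise,
                               baseline = FALSE, additive = FALSE)
      y <- y + v[[a]] * minmax01(rendered)
    }
    y <- minmax01(y)
    if (include_amide) {
      y <- y + lorentzian_sum(wavenumbers,
                              centers = c(1665, 1265),
                              hwhm = c(10, 8),
                              amps = c(0.5, 0.35))
    }
    y <- y + fluorescence_baseline(wavenumbers, noise)
    if (noise$additive_sigma > 0) {
      y <- y + stats::rnorm(length(y), sd = noise$additive_sigma)
    }
    spectra_tbl(matrix(y, 1L), wavenumbers, label = NA_character_)
  })
}
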