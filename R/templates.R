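#' The amino-acid band template library
#'
#' Idealized SERS signatures for the 20 canonical amino acids: each class is
#' a list of Lorentzian bands (center in cm^-1, half-width at half-maximum,
#' relative amplitude with the dominant band at 1). Three classes are
#' anchored at well-documented marker bands -- tryptophan's indole modes at
#' 1552 and 760 cm^-1, alanine's CH3 deformation near 1445 cm^-1, and
#' phenylalanine's ring-breathing doublet at 1000 and 1033 cm^-1. The
#' remaining 17 band sets are fixed curated constants shipped with the
#' package (synthetic fixtures chosen for pairwise distinguishability, not
#' literature assignments).
#'
#' @return tibble with columns `amino_acid`, `center`, `hwhm`, `amplitude`,
#'   in canonical class order.
#' @examples
#' lib <- template_library()
#' dplyr::filter(lib, amino_acid == "W")
#' @export
template_library <- function() {
  path <- system.file("extdata", "amino_acid_bands.csv",
                      package = "sersdecomp", mustWork = TRUE)
  lib <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           amino_acid = readr::col_character(),
                           center = readr::col_double(),
                           hwhm = readr::col_double(),
                           amplitude = readr::col_double()
                         ))
  lib$amino_acid <- factor(lib$amino_acid, levels = amino_acids())
  dplyr::arrange(lib, .data$amino_acid, dplyr::desc(.data$amplitude)) |>
    dplyr::mutate(amino_acid = as.character(.data$amino_acid))
}

# bands for one amino acid, erroring on unknown codes
template_bands <- function(aa, library = template_library()) {
  aa <- aa_code(aa)
  b <- library[library$amino_acid == aa, , drop = FALSE]
  if (nrow(b) == 0L) stop("no template for amino acid ", aa, call. = FALSE)
  b
}
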