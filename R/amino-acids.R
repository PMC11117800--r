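#' Canonical amino-acid codes
#'
#' The 20 canonical amino acids in alphabetical one-letter order. This order
#' is the canonical class order used throughout the package: composition
#' tables, classifier probability columns and tie-breaking all follow it.
#'
#' @return `amino_acids()` returns a character vector of the 20 one-letter
#'   codes; `amino_acid_names()` returns the matching three-letter codes.
#' @examples
#' amino_acids()
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname amino_acids
#' @export
amino_acid_names <- function() {
  c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
    G = "Gly", H = "His", I = "Ile", K = "Lys", L = "Leu",
    M = "Met", N = "Asn", P = "Pro", Q = "Gln", R = "Arg",
    S = "Ser", T = "Thr", V = "Val", W = "Trp", Y = "Tyr")
}

#' Normalize amino-acid identifiers to one-letter codes
#'
#' Accepts one-letter codes (any case) or three-letter codes ("Asp", "HIS").
#'
#' @param x character vector of amino-acid identifiers.
#' @return character vector of one-letter codes.
#' @export
aa_code <- function(x) {
  stopifnot(is.character(x))
  three <- amino_acid_names()
  lookup <- stats::setNames(names(three), tolower(three))
  out <- character(length(x))
  up <- toupper(x)
  is_one <- nchar(x) == 1L & up %in% amino_acids()
  out[is_one] <- up[is_one]
  is_three <- !is_one & tolower(x) %in% names(lookup)
  out[is_three] <- lookup[tolower(x[is_three])]
  bad <- !is_one & !is_three
  if (any(bad)) {
    stop("unknown amino-acid identifier(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}
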