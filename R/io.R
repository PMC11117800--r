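#' Read and write spectra CSV files
#'
#' The on-disk format is a plain CSV: a header row whose first field is
#' `label` and whose remaining fields are wavenumbers in cm^-1 (printed with
#' full precision so write -> read round-trips are lossless to ~1e-15
#' relative), followed by one row per spectrum. The label field may be
#' empty. Metadata columns other than `label` are not written.
#'
#' @param path file path.
#' @return `read_spectra_csv()` returns a spectra tibble (see
#'   [spectra_tbl()]); `write_spectra_csv()` returns `path` invisibly.
#' @export
read_spectra_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty spectra CSV: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[[1L]] != "label") {
    stop("spectra CSV must start with a 'label' column followed by wavenumbers",
         call. = FALSE)
  }
  wn <- as.numeric(header[-1L])
  if (anyNA(wn)) stop("non-numeric wavenumber in header", call. = FALSE)
  check_axis(wn)
  n <- length(lines) - 1L
  if (n == 0L) {
    return(spectra_tbl(matrix(numeric(), 0L, length(wn)), wn,
                       label = character()))
  }
  rows <- strsplit(lines[-1L], ",", fixed = TRUE)
  lens <- lengths(rows)
  # a trailing empty field ("x,y,") is dropped by strsplit; rows are
  # label + intensities, so the expected length is length(wn) + 1
  bad <- which(lens != length(wn) + 1L)
  if (length(bad) > 0L) {
    stop(sprintf("row %d has %d values, expected %d intensities",
                 bad[[1L]], lens[[bad[[1L]]]] - 1L, length(wn)),
         call. = FALSE)
  }
  label <- vapply(rows, `[[`, character(1L), 1L)
  label[label == ""] <- NA_character_
  m <- matrix(as.numeric(unlist(lapply(rows, `[`, -1L))),
              nrow = n, ncol = length(wn), byrow = TRUE)
  if (anyNA(m)) stop("non-numeric intensity value in spectra CSV", call. = FALSE)
  spectra_tbl(m, wn, label = label)
}

#' @rdname read_spectra_csv
#' @param x a spectra tibble.
#' @export
write_spectra_csv <- function(x, path) {
  wn <- spectra_wavenumbers(x)
  m <- intensity_matrix(x)
  label <- if ("label" %in% names(x)) as.character(x$label) else rep(NA_character_, nrow(x))
  label[is.na(label)] <- ""
  header <- paste(c("label", format_wavenumbers(wn)), collapse = ",")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(label[[i]], sprintf("%.15g", m[i, ])), collapse = ",")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Amino-acid composition of a protein sequence
#'
#' Counts each canonical residue in `sequence` and divides by the sequence
#' length, matching how reference compositions are derived from curated
#' sequence databases such as UniProt.
#'
#' @param sequence a single amino-acid string in one-letter codes
#'   (case-insensitive).
#' @return a composition tibble with columns `amino_acid` (all 20, canonical
#'   order) and `fraction` (non-negative, summing to 1).
#' @examples
#' composition_from_sequence("GGGAL")
#' @export
composition_from_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  if (length(chars) == 0L) stop("sequence must be non-empty", call. = FALSE)
  bad <- which(!chars %in% amino_acids())
  if (length(bad) > 0L) {
    stop("non-canonical residue(s) ",
         paste(unique(chars[bad]), collapse = ", "),
         " at position(s) ", paste(utils::head(bad, 10L), collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(chars, levels = amino_acids()))
  composition(as.numeric(counts) / length(chars))
}

#' Read a FASTA file of protein sequences
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that uppercases
#' sequences and strips whitespace, returning a tibble in file order.
#'
#' @param path FASTA file path.
#' @return tibble with columns `name` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  tibble::tibble(
    name = names(set),
    sequence = unname(gsub("\\s", "", toupper(as.character(set))))
  )
}
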