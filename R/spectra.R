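#' Construct a Raman wavenumber axis
#'
#' Evenly spaced wavenumbers from `start` to `stop` inclusive. The package
#' default mirrors a typical SERS fingerprint acquisition: 1117 channels
#' spanning 400--1800 cm^-1, which covers every band in the built-in
#' amino-acid template library.
#'
#' @param start,stop axis limits in cm^-1; `stop` must exceed `start`.
#' @param n number of channels (>= 2).
#' @return numeric vector of `n` strictly increasing wavenumbers.
#' @examples
#' ax <- raman_axis()
#' length(ax)   # 1117
#' range(ax)    # 400 1800
#' @export
raman_axis <- function(start = 400, stop = 1800, n = 1117) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(n) ||
      length(start) != 1L || length(stop) != 1L || length(n) != 1L) {
    stop("start, stop and n must be numeric scalars", call. = FALSE)
  }
  if (stop <= start) stop("stop must be greater than start", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be at least 2", call. = FALSE)
  seq(start, stop, length.out = n)
}

# intensity columns are the ones whose names parse as wavenumbers;
# everything else (label, replicate, snr, ...) is sample metadata
intensity_cols <- function(x) {
  nm <- names(x)
  suppressWarnings(v <- as.numeric(nm))
  nm[!is.na(v)]
}

#' Spectra tables
#'
#' Spectra are stored as ordinary tibbles: metadata columns (`label`,
#' `replicate`, ...) plus one numeric column per wavenumber, with column
#' names carrying the wavenumber in cm^-1. `spectra_tbl()` builds such a
#' table from an intensity matrix, `intensity_matrix()` and
#' `spectra_wavenumbers()` recover the numeric parts, and all dplyr verbs
#' apply directly.
#'
#' @param intensities numeric matrix, one spectrum per row.
#' @param wavenumbers numeric vector of strictly increasing wavenumbers,
#'   one per matrix column.
#' @param label optional character vector of per-spectrum labels.
#' @param ... further per-spectrum metadata vectors (e.g. `replicate`),
#'   recycled to the number of rows.
#' @return a tibble with metadata columns followed by intensity columns.
#' @examples
#' x <- spectra_tbl(matrix(runif(20), 2), raman_axis(400, 1800, 10),
#'                  label = c("A", "C"))
#' spectra_wavenumbers(x)
#' @export
spectra_tbl <- function(intensities, wavenumbers, label = NULL, ...) {
  if (is.null(dim(intensities))) intensities <- matrix(intensities, nrow = 1L)
  check_axis(wavenumbers)
  if (ncol(intensities) != length(wavenumbers)) {
    stop("intensities must have one column per wavenumber", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  colnames(intensities) <- format_wavenumbers(wavenumbers)
  meta <- tibble::tibble(.rows = nrow(intensities))
  if (!is.null(label)) meta$label <- label
  dots <- list(...)
  for (nm in names(dots)) meta[[nm]] <- dots[[nm]]
  dplyr::bind_cols(meta, tibble::as_tibble(intensities))
}

format_wavenumbers <- function(wn) sprintf("%.15g", wn)

check_axis <- function(wn) {
  if (length(wn) < 2L || anyNA(wn) || any(diff(wn) <= 0)) {
    stop("wavenumbers must be >= 2 strictly increasing finite values",
         call. = FALSE)
  }
  invisible(wn)
}

#' @rdname spectra_tbl
#' @param x a spectra tibble.
#' @export
spectra_wavenumbers <- function(x) {
  wn <- as.numeric(intensity_cols(x))
  check_axis(wn)
  wn
}

#' @rdname spectra_tbl
#' @export
intensity_matrix <- function(x) {
  cols <- intensity_cols(x)
  if (length(cols) == 0L) stop("no intensity columns found", call. = FALSE)
  m <- as.matrix(x[, cols])
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, cols)
  m
}

#' @rdname spectra_tbl
#' @export
spectra_meta <- function(x) {
  x[, setdiff(names(x), intensity_cols(x)), drop = FALSE]
}

# replace the intensity block, keeping metadata columns and column names
set_intensities <- function(x, m) {
  cols <- intensity_cols(x)
  stopifnot(ncol(m) == length(cols), nrow(m) == nrow(x))
  x[, cols] <- tibble::as_tibble(`colnames<-`(m, cols))
  x
}
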