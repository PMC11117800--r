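#' Plot spectra
#'
#' Line plot of up to `max_spectra` spectra, colored by label when present.
#'
#' @param x spectra tibble.
#' @param max_spectra cap on the number of spectra drawn.
#' @return a ggplot object.
#' @export
plot_spectra <- function(x, max_spectra = 20) {
  x <- utils::head(x, max_spectra)
  wn <- spectra_wavenumbers(x)
  m <- intensity_matrix(x)
  df <- tibble::tibble(
    spectrum = factor(rep(seq_len(nrow(m)), each = length(wn))),
    label = if ("label" %in% names(x)) rep(x$label, each = length(wn)) else NA,
    wavenumber = rep(wn, nrow(m)),
    intensity = as.vector(t(m))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity,
                                   group = .data$spectrum,
                                   color = .data$label)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "Intensity (a.u.)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a 3-D embedding (first two dimensions)
#'
#' @param emb embedding tibble from [tsne_embed()].
#' @return a ggplot object.
#' @export
plot_embedding <- function(emb) {
  ggplot2::ggplot(emb, ggplot2::aes(.data$dim1, .data$dim2,
                                    color = .data$label)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", color = NULL) +
    ggplot2::theme_minimal()
}

#' Double-bar comparison of predicted and reference compositions
#'
#' The standard predicted-vs-reference composition figure: one pair of
#' bars per amino acid.
#'
#' @param pred,ref compositions (tibble or named vector).
#' @return a ggplot object.
#' @export
plot_composition <- function(pred, ref) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_composition(pred), which = "predicted"),
    dplyr::mutate(as_composition(ref), which = "reference")
  )
  df$amino_acid <- factor(df$amino_acid, levels = amino_acids())
  ggplot2::ggplot(df, ggplot2::aes(.data$amino_acid, .data$fraction,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Training-history curves
#'
#' @param model a fitted `sers_classifier`.
#' @return a ggplot object with loss and accuracy panels.
#' @export
plot_training <- function(model) {
  df <- tidy(model) |>
    tidyr::pivot_longer(c("train_loss", "val_loss", "train_accuracy",
                          "val_accuracy"),
                        names_to = c("split", "metric"), names_sep = "_") |>
    dplyr::mutate(metric = factor(.data$metric, c("loss", "accuracy")))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
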