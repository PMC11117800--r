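#' Training configuration
#'
#' Adam with initial learning rate 0.001 and a plateau-halving schedule
#' (factor 0.5 after `lr_patience` epochs without validation improvement),
#' dropout 0.3 (in [model_config()]), early stopping on validation loss
#' with patience 5, and checkpointing of the weights with minimum
#' validation loss. Validation data for early stopping are a stratified
#' `val_fraction` carved from the training set; any held-out test split is
#' never touched during training.
#'
#' @param lr initial learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience, epochs.
#' @param min_delta minimum validation-loss improvement that counts as
#'   progress for early stopping and the learning-rate schedule; the best
#'   checkpoint itself is always the strict minimum.
#' @param label_smoothing label-smoothing mass spread uniformly over the
#'   off-target classes (default 0.1). Smoothing bounds the logit margins,
#'   which keeps the softmax output calibrated enough that mixture spectra
#'   receive split probabilities instead of a saturated one-hot answer —
#'   essential when probabilities are reinterpreted as compositions.
#' @param mixup_alpha Dirichlet concentration for mixup augmentation
#'   (default 1, i.e. uniform over the simplex; 0 disables). Each
#'   minibatch is convexly combined with `mixup_components - 1` shuffled
#'   copies of itself using per-row Dirichlet weights, the mixed rows
#'   re-normalized to [0, 1], and the soft targets mixed by the same
#'   weights. Mixup trains the network to map superimposed spectra to
#'   proportionally mixed probabilities — the property that the
#'   composition read-out assumes ("higher spectral contribution, higher
#'   probability").
#' @param mixup_components number of spectra combined per mixup sample
#'   (default 3; covers pairs through richer superpositions, since
#'   Dirichlet draws often put most weight on one or two components).
#' @param lr_patience plateau patience before halving the learning rate.
#' @param val_fraction share of training data held out for early stopping.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.001, batch_size = 32, max_epochs = 200,
                         patience = 5, min_delta = 1e-3,
                         label_smoothing = 0.1, mixup_alpha = 1,
                         mixup_components = 3, lr_patience = 2,
                         val_fraction = 0.1, seed = 1) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 1,
            min_delta >= 0, label_smoothing >= 0, label_smoothing < 1,
            mixup_alpha >= 0, mixup_components >= 2,
            val_fraction > 0, val_fraction < 1)
  structure(list(lr = lr, batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, min_delta = min_delta,
                 label_smoothing = label_smoothing,
                 mixup_alpha = mixup_alpha,
                 mixup_components = mixup_components,
                 lr_patience = lr_patience, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

# stratified index split; returns list(a, b) of disjoint row indices.
# Largest-remainder allocation so part b totals round(n * fraction_b)
# while staying as proportional as possible within classes.
stratified_split <- function(labels, fraction_b) {
  lv <- unique(labels)
  rows_by <- split(seq_along(labels), factor(labels, levels = lv))
  sizes <- lengths(rows_by)
  if (any(sizes < 2L)) {
    stop("class(es) with fewer than 2 spectra: ",
         paste(lv[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  raw <- sizes * fraction_b
  n_b <- pmin(pmax(floor(raw), 1L), sizes - 1L)
  target <- min(max(round(sum(raw)), length(lv)), sum(sizes - 1L))
  ord <- order(raw - floor(raw), decreasing = TRUE)
  i <- 1L
  while (sum(n_b) < target) {
    k <- ord[[(i - 1L) %% length(ord) + 1L]]
    if (n_b[[k]] < sizes[[k]] - 1L) n_b[[k]] <- n_b[[k]] + 1L
    i <- i + 1L
  }
  while (sum(n_b) > target) {
    k <- ord[[length(ord) - (i - 1L) %% length(ord)]]
    if (n_b[[k]] > 1L) n_b[[k]] <- n_b[[k]] - 1L
    i <- i + 1L
  }
  idx_b <- unlist(lapply(seq_along(rows_by), function(k) {
    sample(rows_by[[k]], n_b[[k]])
  }), use.names = FALSE)
  list(a = setdiff(seq_along(labels), idx_b), b = sort(idx_b))
}

#' Stratified train/test split of a labeled spectra set
#'
#' Random, stratified by label, deterministic for a fixed seed; the two
#' parts are disjoint and their union is the input.
#'
#' @param x labeled spectra tibble.
#' @param test_fraction share assigned to the test set (default 0.2).
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
split_dataset <- function(x, test_fraction = 0.2, seed = 1) {
  stopifnot("label" %in% names(x), test_fraction > 0, test_fraction < 1)
  sp <- withr::with_seed(as.integer(seed),
                         stratified_split(x$label, test_fraction))
  list(train = x[sp$a, ], test = x[sp$b, ])
}

model_eval <- function(params, cfg, X, y, smooth = 0, batch = 256L) {
  n <- nrow(X)
  loss <- 0
  correct <- 0
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    fw <- transformer_fwd(params, cfg, X[idx, , drop = FALSE], train = FALSE)
    loss <- loss + ce_loss(fw$probs, y[idx], smooth) * length(idx)
    correct <- correct + sum(max.col(fw$probs, ties.method = "first") == y[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train the transformer spectral classifier
#'
#' Trains a 20-class transformer encoder on preprocessed, labeled spectra
#' by minibatch cross-entropy with Adam, plateau learning-rate halving,
#' early stopping on validation loss, and best-checkpoint retention.
#' Reproducible: all randomness (initialization, validation split, batch
#' shuffling, dropout) derives from `train_cfg$seed`.
#'
#' @param x labeled, preprocessed spectra tibble (each row min 0 / max 1).
#' @param cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param quiet suppress per-epoch progress messages.
#' @return an object of class `sers_classifier`: best-checkpoint weights,
#'   configurations, class order, training axis and a per-epoch `history`
#'   tibble. Use [predict_proba()], [generics::tidy()] and
#'   [generics::glance()] on it.
#' @export
train_classifier <- function(x, cfg = model_config(),
                             train_cfg = train_config(), quiet = TRUE) {
  stopifnot("label" %in% names(x))
  classes <- intersect(amino_acids(), unique(x$label))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (!setequal(classes, unique(x$label))) {
    classes <- sort(unique(x$label))
  }
  cfg$n_classes <- length(classes)
  wn <- spectra_wavenumbers(x)
  X <- intensity_matrix(x)
  y <- match(x$label, classes)
  if (anyNA(y) || any(tabulate(y, length(classes)) == 0L)) {
    stop("every class must have training spectra", call. = FALSE)
  }

  history <- list()
  withr::with_seed(train_cfg$seed, {
    sp <- stratified_split(x$label, train_cfg$val_fraction)
    Xtr <- X[sp$a, , drop = FALSE]; ytr <- y[sp$a]
    Xva <- X[sp$b, , drop = FALSE]; yva <- y[sp$b]
    params <- init_params(cfg, seed = stats::runif(1, 1, 1e8))
    state <- adam_init(params)
    lr <- train_cfg$lr
    best <- list(loss = Inf, params = params, epoch = 0L)
    stall <- 0L
    lr_stall <- 0L
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample(length(ytr))
      tr_loss <- 0
      tr_correct <- 0
      for (s in seq(1L, length(ord), by = train_cfg$batch_size)) {
        idx <- ord[s:min(s + train_cfg$batch_size - 1L, length(ord))]
        Xb <- Xtr[idx, , drop = FALSE]
        target <- smooth_targets(ytr[idx], cfg$n_classes,
                                 train_cfg$label_smoothing)
        if (train_cfg$mixup_alpha > 0 && length(idx) > 1L) {
          # Dirichlet mixup over several shuffled copies of the batch, with
          # per-row weights: trains the network on the whole superposition
          # manifold (pairs through protein-like many-component sums)
          n_mix <- train_cfg$mixup_components
          G <- matrix(stats::rgamma(length(idx) * n_mix,
                                    shape = train_cfg$mixup_alpha),
                      length(idx), n_mix)
          W <- G / rowSums(G)
          Xmix <- W[, 1L] * Xb
          tmix <- W[, 1L] * target
          for (j in 2:n_mix) {
            perm <- sample(length(idx))
            Xmix <- Xmix + W[, j] * Xb[perm, , drop = FALSE]
            tmix <- tmix + W[, j] * target[perm, , drop = FALSE]
          }
          # re-normalize each mixed row to [0, 1]: preprocessed spectra are
          # min-max normalized, and mixture spectra at prediction time are too
          rng <- apply(Xmix, 1L, range)
          Xb <- (Xmix - rng[1L, ]) / pmax(rng[2L, ] - rng[1L, ], 1e-12)
          target <- tmix
        }
        fw <- transformer_fwd(params, cfg, Xb, train = TRUE)
        gr <- transformer_bwd(params, cfg, fw, target)
        up <- adam_step(params, gr, state, lr)
        params <- up$params
        state <- up$state
        tr_loss <- tr_loss + ce_loss(fw$probs, target) * length(idx)
        tr_correct <- tr_correct +
          sum(max.col(fw$probs, ties.method = "first") ==
                max.col(target, ties.method = "first"))
      }
      val <- model_eval(params, cfg, Xva, yva,
                        smooth = train_cfg$label_smoothing)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = tr_loss / length(ytr),
        train_accuracy = tr_correct / length(ytr),
        val_loss = val$loss,
        val_accuracy = val$acc,
        lr = lr
      )
      if (!quiet) {
        message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f  lr %.2g",
                        epoch, tr_loss / length(ytr),
                        tr_correct / length(ytr), val$loss, val$acc, lr))
      }
      improved <- val$loss < best$loss - train_cfg$min_delta
      if (val$loss < best$loss) {
        # the checkpoint is always the strict validation-loss minimum
        best <- list(loss = val$loss, params = params, epoch = epoch)
      }
      if (improved) {
        stall <- 0L
        lr_stall <- 0L
      } else {
        stall <- stall + 1L
        lr_stall <- lr_stall + 1L
        if (lr_stall >= train_cfg$lr_patience) {
          lr <- lr / 2
          lr_stall <- 0L
        }
        if (stall >= train_cfg$patience) break
      }
    }
  })

  structure(list(params = best$params, model_cfg = cfg,
                 train_cfg = train_cfg, classes = classes,
                 wavenumbers = wn, best_epoch = best$epoch,
                 best_val_loss = best$loss,
                 history = dplyr::bind_rows(history)),
            class = "sers_classifier")
}

#' Class probabilities for new spectra
#'
#' Deterministic evaluation-mode forward pass (dropout off). Each returned
#' row is a valid probability vector over the model's classes in canonical
#' amino-acid order.
#'
#' @param model a fitted `sers_classifier`.
#' @param x spectra tibble on the model's wavenumber axis, preprocessed the
#'   same way as the training data.
#' @return tibble with one probability column per class (plus `label` if
#'   present in `x`).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "sers_classifier"))
  wn <- spectra_wavenumbers(x)
  if (length(wn) != length(model$wavenumbers) ||
      max(abs(wn - model$wavenumbers)) > 1e-6) {
    stop("spectra are not on the model's wavenumber axis", call. = FALSE)
  }
  X <- intensity_matrix(x)
  out <- matrix(NA_real_, nrow(X), length(model$classes),
                dimnames = list(NULL, model$classes))
  for (s in seq(1L, nrow(X), by = 256L)) {
    idx <- s:min(s + 255L, nrow(X))
    fw <- transformer_fwd(model$params, model$model_cfg,
                          X[idx, , drop = FALSE], train = FALSE)
    out[idx, ] <- fw$probs
  }
  res <- tibble::as_tibble(out)
  if ("label" %in% names(x)) res <- dplyr::bind_cols(x["label"], res)
  res
}

#' @export
predict.sers_classifier <- function(object, newdata,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") return(p)
  m <- as.matrix(p[, object$classes])
  object$classes[max.col(m, ties.method = "first")]
}

#' Per-class and mean classification accuracy
#'
#' Per-class accuracy is correct/total within each true label; the mean is
#' the unweighted average over classes.
#'
#' @param model a fitted `sers_classifier`.
#' @param x labeled spectra tibble.
#' @return list with `per_class` (tibble of label, n, accuracy) and `mean`
#'   (unweighted class-mean accuracy).
#' @export
evaluate_accuracy <- function(model, x) {
  stopifnot("label" %in% names(x))
  if (nrow(x) == 0L) stop("empty evaluation set", call. = FALSE)
  pred <- predict(model, x, type = "class")
  per <- tibble::tibble(label = x$label, correct = pred == x$label) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), accuracy = mean(.data$correct),
                     .groups = "drop")
  list(per_class = per, mean = mean(per$accuracy))
}

#' @export
#' @method print sers_classifier
print.sers_classifier <- function(x, ...) {
  cat("Transformer SERS classifier\n")
  cat(sprintf("  classes: %d  channels: %d  tokens: %d (patch %d)\n",
              length(x$classes), length(x$wavenumbers),
              ceiling(length(x$wavenumbers) / x$model_cfg$patch_size),
              x$model_cfg$patch_size))
  cat(sprintf("  d_model %d, %d layers, %d heads, d_ff %d, dropout %.2f\n",
              x$model_cfg$d_model, x$model_cfg$n_layers, x$model_cfg$n_heads,
              x$model_cfg$d_ff, x$model_cfg$dropout))
  cat(sprintf("  best epoch %d (val loss %.4f) of %d run\n",
              x$best_epoch, x$best_val_loss, nrow(x$history)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted classifier
#'
#' @param x a `sers_classifier`.
#' @param ... unused.
#' @return tibble with one row per epoch: losses, accuracies, learning
#'   rate.
#' @export
tidy.sers_classifier <- function(x, ...) x$history

#' One-row summary of a fitted classifier
#'
#' @param x a `sers_classifier`.
#' @param ... unused.
#' @return tibble with epochs run, best epoch, best validation loss and
#'   the validation accuracy at the best epoch.
#' @export
glance.sers_classifier <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    val_accuracy = x$history$val_accuracy[[x$best_epoch]],
    n_classes = length(x$classes)
  )
}
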