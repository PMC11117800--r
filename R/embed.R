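# conditional-probability row for one point given squared distances and a
# precision beta, plus its Shannon entropy (perplexity = 2^H)
hbeta <- function(d2, beta) {
  p <- exp(-d2 * beta)
  s <- sum(p)
  if (s == 0) return(list(H = 0, p = p))
  H <- log(s) + beta * sum(d2 * p) / s
  list(H = H, p = p / s)
}

# symmetric joint probabilities for a target perplexity (binary search on
# the per-point precision, as in the reference t-SNE formulation)
tsne_p_matrix <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  ss <- rowSums(X^2)
  D2 <- pmax(outer(ss, ss, "+") - 2 * tcrossprod(X), 0)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    hb <- hbeta(d2, beta)
    for (it in seq_len(50L)) {
      if (abs(hb$H - logU) < tol) break
      if (hb$H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
      hb <- hbeta(d2, beta)
    }
    P[i, -i] <- hb$p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

tsne_core <- function(X, dims, perplexity, iters, seed) {
  n <- nrow(X)
  P <- tsne_p_matrix(X, perplexity)
  # PCA initialization, scaled small, with a seeded jitter to break ties
  Y <- withr::with_seed(as.integer(seed), {
    pc <- stats::prcomp(X, rank. = dims)
    y0 <- pc$x[, seq_len(dims), drop = FALSE]
    y0 <- y0 / stats::sd(y0) * 1e-4
    y0 + matrix(stats::rnorm(n * dims, sd = 1e-6), n, dims)
  })
  tsne_iterate_cpp(P, Y, iters = as.integer(iters), eta = 200,
                   exaggeration = 12,
                   stop_exag = as.integer(min(250L, floor(iters / 4))),
                   momentum_switch = 250L)
}

#' 3-D t-SNE embedding of a spectra set
#'
#' Embeds the 1117-dimensional spectra into 3 dimensions with exact
#' t-distributed stochastic neighbor embedding (perplexity-calibrated
#' Gaussian affinities, Student-t low-dimensional kernel, early
#' exaggeration, PCA initialization). Deterministic for a fixed seed.
#'
#' @param x preprocessed spectra tibble.
#' @param perplexity t-SNE perplexity (default 30); requires
#'   `nrow(x) > 3 * perplexity`.
#' @param seed integer seed.
#' @param iters gradient-descent iterations (default 1000).
#' @param dims output dimensionality (default 3).
#' @return tibble with columns `dim1`..`dim3` and, if present, `label`;
#'   embedding parameters are attached as attributes.
#' @export
tsne_embed <- function(x, perplexity = 30, seed = 1, iters = 1000, dims = 3) {
  m <- intensity_matrix(x)
  if (nrow(m) <= 3 * perplexity) {
    stop("need more than 3 * perplexity spectra for t-SNE", call. = FALSE)
  }
  Y <- tsne_core(m, dims = dims, perplexity = perplexity, iters = iters,
                 seed = seed)
  out <- tibble::as_tibble(`colnames<-`(Y, paste0("dim", seq_len(dims))))
  if ("label" %in% names(x)) out$label <- x$label
  attr(out, "params") <- list(perplexity = perplexity, seed = seed,
                              iters = iters)
  out
}

embedding_coords <- function(emb) {
  as.matrix(emb[, grep("^dim[0-9]+$", names(emb)), drop = FALSE])
}

mean_silhouette <- function(coords, clusters) {
  mean(cluster::silhouette(as.integer(factor(clusters)),
                           stats::dist(coords))[, "sil_width"])
}

# k-means with random restarts plus a Ward-linkage initialization: with
# many tight, widely separated clusters random restarts alone routinely
# miss the global optimum, while centroids of the Ward cut land on it
kmeans_robust <- function(coords, k, nstart, hc = NULL) {
  km <- stats::kmeans(coords, centers = k, nstart = nstart, iter.max = 50)
  if (!is.null(hc)) {
    groups <- stats::cutree(hc, k = k)
    cent <- apply(coords, 2L, function(col) tapply(col, groups, mean))
    km2 <- tryCatch(stats::kmeans(coords, centers = cent, iter.max = 50),
                    error = function(e) NULL)
    if (!is.null(km2) && km2$tot.withinss < km$tot.withinss) km <- km2
  }
  km
}

#' Mean silhouette of an embedding under a partition
#'
#' @param emb embedding tibble from [tsne_embed()].
#' @param clusters cluster assignment (defaults to the `label` column).
#' @return mean silhouette width in [-1, 1].
#' @export
embedding_silhouette <- function(emb, clusters = emb$label) {
  if (length(unique(clusters)) < 2L) stop("need >= 2 clusters", call. = FALSE)
  mean_silhouette(embedding_coords(emb), clusters)
}

#' Estimate the number of clusters in an embedding
#'
#' Runs k-means (`nstart` restarts, fixed seed) for each k in
#' `k_min:k_max` and returns the k with the highest mean silhouette; ties
#' go to the smaller k. With many tight, widely separated clusters k-means
#' needs a generous restart count to reach its global optimum, so the
#' default is 50.
#'
#' @param emb embedding tibble.
#' @param k_min,k_max sweep range (`k_min >= 2`, `k_max < n`).
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts per k.
#' @return list with `k` (selected count) and `sweep` (tibble of k and mean
#'   silhouette).
#' @export
estimate_cluster_count <- function(emb, k_min = 10, k_max = 30, seed = 1,
                                   nstart = 50) {
  coords <- embedding_coords(emb)
  n <- nrow(coords)
  stopifnot(k_min >= 2, k_max < n, k_max >= k_min)
  if (all(apply(coords, 2L, stats::sd) == 0)) {
    stop("degenerate embedding: all coordinates identical", call. = FALSE)
  }
  d <- stats::dist(coords)
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- withr::with_seed(as.integer(seed), vapply(k_min:k_max, function(k) {
    km <- kmeans_robust(coords, k, nstart, hc)
    mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }, numeric(1L)))
  ks <- k_min:k_max
  list(k = ks[[which.max(sil)]],
       sweep = tibble::tibble(k = ks, silhouette = sil))
}

#' Agreement between k-means clusters and true labels
#'
#' Adjusted Rand index between a k-means partition of the embedding
#' (k = number of distinct labels) and the true labels.
#'
#' @param emb embedding tibble.
#' @param labels true class labels (defaults to the `label` column).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return adjusted Rand index in [-1, 1].
#' @export
cluster_agreement <- function(emb, labels = emb$label, seed = 1,
                              nstart = 50) {
  stopifnot(!is.null(labels))
  k <- length(unique(labels))
  if (k < 2L) stop("need >= 2 distinct labels", call. = FALSE)
  coords <- embedding_coords(emb)
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  km <- withr::with_seed(as.integer(seed),
                         kmeans_robust(coords, k, nstart, hc))
  mclust::adjustedRandIndex(km$cluster, labels)
}
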