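#' Transformer model configuration
#'
#' Architecture of the spectral classifier: the 1117-channel spectrum is cut
#' into contiguous patches of `patch_size` channels (zero-padded at the
#' right edge), each patch is linearly embedded into `d_model` dimensions
#' (scaled by sqrt(d_model)) with an added sinusoidal positional encoding,
#' and the token sequence is passed through `n_layers` pre-norm transformer
#' encoder layers (multi-head self-attention + position-wise feed-forward,
#' each entered through layer normalization and wrapped in a residual
#' connection). Token representations are mean-pooled and projected through
#' a dropout-regularized dense layer to a 20-way softmax. The pre-norm
#' residual stream keeps pooled features approximately additive in the
#' input, which is what lets class probabilities double as composition
#' estimates for mixtures. The defaults are the smallest configuration that
#' trains to high accuracy on a desktop CPU in minutes.
#'
#' @param patch_size channels per token (default 16; 1117 channels give 70
#'   tokens).
#' @param d_model embedding width (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param n_layers encoder layers.
#' @param d_ff feed-forward hidden width.
#' @param dropout dropout rate after the dense layer (default 0.3).
#' @param n_classes output classes (20 amino acids).
#' @return a `model_config` list.
#' @export
model_config <- function(patch_size = 16, d_model = 64, n_heads = 4,
                         n_layers = 2, d_ff = 128, dropout = 0.3,
                         n_classes = 20) {
  stopifnot(patch_size >= 1, d_model %% n_heads == 0,
            dropout >= 0, dropout < 1, n_layers >= 1)
  structure(list(patch_size = patch_size, d_model = d_model,
                 n_heads = n_heads, n_layers = n_layers, d_ff = d_ff,
                 dropout = dropout, n_classes = n_classes),
            class = "model_config")
}

#' Cut a spectrum into patch tokens
#'
#' Zero-pads the intensity vector on the right to the next multiple of
#' `patch_size` and splits it into contiguous patches; concatenating the
#' rows and trimming the padding recovers the input.
#'
#' @param y numeric intensity vector.
#' @param patch_size channels per token (>= 1).
#' @return matrix with `ceiling(length(y) / patch_size)` rows of
#'   `patch_size` channels.
#' @examples
#' dim(tokenize(runif(1117), 16)) # 70 x 16
#' @export
tokenize <- function(y, patch_size) {
  if (patch_size < 1) stop("patch_size must be >= 1", call. = FALSE)
  n_tok <- ceiling(length(y) / patch_size)
  pad <- n_tok * patch_size - length(y)
  matrix(c(y, rep(0, pad)), nrow = n_tok, ncol = patch_size, byrow = TRUE)
}

# (B*T) x P token matrix, rows ordered sample-major
tokenize_batch <- function(X, patch_size) {
  n_tok <- ceiling(ncol(X) / patch_size)
  pad <- n_tok * patch_size - ncol(X)
  if (pad > 0) X <- cbind(X, matrix(0, nrow(X), pad))
  t(matrix(t(X), nrow = patch_size))
}

sinusoidal_encoding <- function(n_tok, d_model) {
  pos <- seq_len(n_tok) - 1L
  i <- seq_len(d_model) - 1L
  angle <- outer(pos, 1 / 10000^(2 * (i %/% 2) / d_model))
  enc <- matrix(0, n_tok, d_model)
  even <- which(i %% 2 == 0)
  odd <- which(i %% 2 == 1)
  enc[, even] <- sin(angle[, even, drop = FALSE])
  enc[, odd] <- cos(angle[, odd, drop = FALSE])
  enc
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_params <- function(cfg, seed) {
  withr::with_seed(as.integer(seed), {
    D <- cfg$d_model
    p <- list(
      We = glorot(cfg$patch_size, D), be = numeric(D),
      Wc = glorot(D, cfg$n_classes), Ws = glorot(D, cfg$n_classes),
      bc = numeric(cfg$n_classes),
      layers = lapply(seq_len(cfg$n_layers), function(l) {
        list(Wq = glorot(D, D), bq = numeric(D),
             Wk = glorot(D, D), bk = numeric(D),
             Wv = glorot(D, D), bv = numeric(D),
             Wo = glorot(D, D), bo = numeric(D),
             g1 = rep(1, D), b1 = numeric(D),
             W1 = glorot(D, cfg$d_ff), bf1 = numeric(cfg$d_ff),
             W2 = glorot(cfg$d_ff, D), bf2 = numeric(D),
             g2 = rep(1, D), b2 = numeric(D))
      })
    )
    p
  })
}

LN_EPS <- 1e-5

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  s <- sqrt(v + LN_EPS)
  xhat <- xc / s
  list(out = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, s = s)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / cache$s
  list(dx = dx, dg = dg, db = db)
}

addb <- function(x, b) x + rep(b, each = nrow(x))

softmax_rows <- function(x) {
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  e / rowSums(e)
}

# multi-head self-attention over a batch: X is (B*T) x D, sample-major
attention_fwd <- function(X, lp, cfg, B, T) {
  D <- cfg$d_model
  H <- cfg$n_heads
  dh <- D %/% H
  Q <- addb(X %*% lp$Wq, lp$bq)
  K <- addb(X %*% lp$Wk, lp$bk)
  V <- addb(X %*% lp$Wv, lp$bv)
  O <- matrix(0, nrow(X), D)
  A <- vector("list", B)
  scale <- 1 / sqrt(dh)
  head_cols <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    Qb <- Q[rows, , drop = FALSE]
    Kb <- K[rows, , drop = FALSE]
    Vb <- V[rows, , drop = FALSE]
    Ob <- matrix(0, T, D)
    Ab <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- head_cols[[h]]
      a <- softmax_rows(tcrossprod(Qb[, cols], Kb[, cols]) * scale)
      Ob[, cols] <- a %*% Vb[, cols]
      Ab[[h]] <- a
    }
    O[rows, ] <- Ob
    A[[b]] <- Ab
  }
  out <- addb(O %*% lp$Wo, lp$bo)
  list(out = out, Q = Q, K = K, V = V, O = O, A = A)
}

attention_bwd <- function(dout, cache, X, lp, cfg, B, T) {
  D <- cfg$d_model
  H <- cfg$n_heads
  dh <- D %/% H
  scale <- 1 / sqrt(dh)
  g <- list(Wo = crossprod(cache$O, dout), bo = colSums(dout))
  dO <- tcrossprod(dout, lp$Wo)
  dQ <- matrix(0, nrow(X), D)
  dK <- matrix(0, nrow(X), D)
  dV <- matrix(0, nrow(X), D)
  head_cols <- lapply(seq_len(H), function(h) ((h - 1L) * dh + 1L):(h * dh))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    dOb <- dO[rows, , drop = FALSE]
    Qb <- cache$Q[rows, , drop = FALSE]
    Kb <- cache$K[rows, , drop = FALSE]
    Vb <- cache$V[rows, , drop = FALSE]
    dQb <- matrix(0, T, D); dKb <- matrix(0, T, D); dVb <- matrix(0, T, D)
    for (h in seq_len(H)) {
      cols <- head_cols[[h]]
      a <- cache$A[[b]][[h]]
      dOh <- dOb[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vb[, cols, drop = FALSE])
      dVb[, cols] <- crossprod(a, dOh)
      dS <- a * (dA - rowSums(dA * a))
      dQb[, cols] <- (dS %*% Kb[, cols, drop = FALSE]) * scale
      dKb[, cols] <- crossprod(dS, Qb[, cols, drop = FALSE]) * scale
    }
    dQ[rows, ] <- dQb; dK[rows, ] <- dKb; dV[rows, ] <- dVb
  }
  g$Wq <- crossprod(X, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(X, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(X, dV); g$bv <- colSums(dV)
  dX <- tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) + tcrossprod(dV, lp$Wv)
  list(dX = dX, grads = g)
}

# full forward pass; when train = TRUE dropout masks are sampled from the
# current RNG stream and all caches needed for backprop are kept.
# Pre-norm encoder layers (x + sublayer(LN(x))) keep an identity residual
# stream from the patch embedding to the pooled features, so superimposed
# spectra produce features that interpolate between their components --
# the property the composition read-out relies on.
transformer_fwd <- function(params, cfg, X, train = FALSE) {
  B <- nrow(X)
  tok <- tokenize_batch(X, cfg$patch_size)
  T <- nrow(tok) %/% B
  # embeddings are scaled by sqrt(d_model) before the O(1) positional
  # encoding is added, so the spectral signal is not swamped by position
  E0 <- (tok %*% params$We) * sqrt(cfg$d_model)
  E <- addb(E0, params$be)
  E <- E + sinusoidal_encoding(T, cfg$d_model)[rep(seq_len(T), B), ]
  caches <- vector("list", cfg$n_layers)
  drop_mask <- function(d) {
    if (!train || cfg$dropout <= 0) return(NULL)
    matrix(stats::rbinom(prod(d), 1L, 1 - cfg$dropout), d[[1L]], d[[2L]]) /
      (1 - cfg$dropout)
  }
  Xl <- E
  for (l in seq_len(cfg$n_layers)) {
    lp <- params$layers[[l]]
    ln1 <- layernorm_fwd(Xl, lp$g1, lp$b1)
    att <- attention_fwd(ln1$out, lp, cfg, B, T)
    # dropout after each dense sublayer output (attention projection,
    # feed-forward hidden and output)
    m_att <- drop_mask(dim(att$out))
    att_out <- if (is.null(m_att)) att$out else att$out * m_att
    a1 <- Xl + att_out
    ln2 <- layernorm_fwd(a1, lp$g2, lp$b2)
    pre <- addb(ln2$out %*% lp$W1, lp$bf1)
    Z <- pre * (pre > 0)
    m_ff1 <- drop_mask(dim(Z))
    Zd <- if (is.null(m_ff1)) Z else Z * m_ff1
    f <- addb(Zd %*% lp$W2, lp$bf2)
    m_ff2 <- drop_mask(dim(f))
    fd <- if (is.null(m_ff2)) f else f * m_ff2
    caches[[l]] <- list(Xin = Xl, att = att, ln1 = ln1, a1 = a1, ln2 = ln2,
                        pre = pre, Zd = Zd, m_att = m_att, m_ff1 = m_ff1,
                        m_ff2 = m_ff2)
    Xl <- a1 + fd
  }
  # mean pool over tokens: rows are sample-major blocks of T
  pool_rows <- function(M) t(vapply(seq_len(B), function(b) {
    colMeans(M[((b - 1L) * T + 1L):(b * T), , drop = FALSE])
  }, numeric(cfg$d_model)))
  pool <- pool_rows(Xl)
  # linear skip path: mean-pooled raw patch embedding feeds the logits
  # directly, giving the classifier an explicitly additive route --
  # spectral superpositions are additive, and this path carries that
  # structure while the encoder refines it
  pool0 <- pool_rows(E0)
  mask <- drop_mask(dim(pool))
  U <- if (is.null(mask)) pool else pool * mask
  logits <- addb(U %*% params$Wc + pool0 %*% params$Ws, params$bc)
  probs <- softmax_rows(logits)
  list(probs = probs, tok = tok, caches = caches, pool = pool,
       pool0 = pool0, mask = mask, U = U, B = B, T = T)
}

# soft-target matrix for integer labels with optional label smoothing
smooth_targets <- function(y, K, smooth = 0) {
  target <- matrix(smooth / K, length(y), K)
  target[cbind(seq_along(y), y)] <- 1 - smooth + smooth / K
  target
}

# backward pass for mean cross-entropy; y is an integer class vector or a
# soft-target probability matrix (rows summing to 1)
transformer_bwd <- function(params, cfg, fw, y, smooth = 0) {
  B <- fw$B
  T <- fw$T
  D <- cfg$d_model
  K <- ncol(fw$probs)
  target <- if (is.matrix(y)) y else smooth_targets(y, K, smooth)
  dlogits <- (fw$probs - target) / B
  g <- list(Wc = crossprod(fw$U, dlogits),
            Ws = crossprod(fw$pool0, dlogits),
            bc = colSums(dlogits))
  dU <- tcrossprod(dlogits, params$Wc)
  dpool <- if (is.null(fw$mask)) dU else dU * fw$mask
  dXl <- (dpool / T)[rep(seq_len(B), each = T), , drop = FALSE]
  # skip-path gradient reaches the patch embedding directly
  dpool0 <- tcrossprod(dlogits, params$Ws)
  dE0 <- (dpool0 / T)[rep(seq_len(B), each = T), , drop = FALSE]
  g$layers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- params$layers[[l]]
    ca <- fw$caches[[l]]
    lg <- list()
    # Xl = a1 + dropout(f); f = dropout(relu(LN2(a1) W1 + b1)) W2 + b2
    da1 <- dXl
    df <- if (is.null(ca$m_ff2)) dXl else dXl * ca$m_ff2
    lg$W2 <- crossprod(ca$Zd, df); lg$bf2 <- colSums(df)
    dZd <- tcrossprod(df, lp$W2)
    dZ <- if (is.null(ca$m_ff1)) dZd else dZd * ca$m_ff1
    dpre <- dZ * (ca$pre > 0)
    lg$W1 <- crossprod(ca$ln2$out, dpre); lg$bf1 <- colSums(dpre)
    dln2 <- tcrossprod(dpre, lp$W1)
    b2 <- layernorm_bwd(dln2, ca$ln2, lp$g2)
    lg$g2 <- b2$dg; lg$b2 <- b2$db
    da1 <- da1 + b2$dx
    # a1 = Xin + dropout(attention(LN1(Xin)))
    dXin <- da1
    datt <- if (is.null(ca$m_att)) da1 else da1 * ca$m_att
    ab <- attention_bwd(datt, ca$att, ca$ln1$out, lp, cfg, fw$B, T)
    lg <- c(lg, ab$grads)
    b1 <- layernorm_bwd(ab$dX, ca$ln1, lp$g1)
    lg$g1 <- b1$dg; lg$b1 <- b1$db
    dXl <- dXin + b1$dx
    g$layers[[l]] <- lg
  }
  g$We <- crossprod(fw$tok, dXl + dE0) * sqrt(cfg$d_model)
  g$be <- colSums(dXl)
  g
}

# cross-entropy; y is an integer class vector (optionally label-smoothed)
# or a soft-target probability matrix
ce_loss <- function(probs, y, smooth = 0) {
  lp <- log(pmax(probs, 1e-12))
  if (is.matrix(y)) return(-mean(rowSums(y * lp)))
  if (smooth <= 0) return(-mean(lp[cbind(seq_along(y), y)]))
  -mean(rowSums(smooth_targets(y, ncol(probs), smooth) * lp))
}

# --- Adam ------------------------------------------------------------------

flatten_params <- function(p) {
  out <- list()
  walk <- function(x, prefix) {
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- paste0(prefix, nm)
      if (is.list(v)) {
        for (i in seq_along(v)) walk(v[[i]], paste0(key, i, "."))
      } else {
        out[[key]] <<- v
      }
    }
  }
  walk(p, "")
  out
}

adam_init <- function(params) {
  fl <- flatten_params(params)
  list(m = lapply(fl, function(v) v * 0),
       v = lapply(fl, function(v) v * 0),
       t = 0L)
}

# applies one Adam step in place on the nested parameter list
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(fp)) {
    gk <- fg[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * gk
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * gk^2
    fp[[key]] <- fp[[key]] -
      lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
  }
  list(params = unflatten_params(fp, params), state = state)
}

unflatten_params <- function(flat, skeleton) {
  build <- function(x, prefix) {
    for (nm in names(x)) {
      key <- paste0(prefix, nm)
      if (is.list(x[[nm]])) {
        for (i in seq_along(x[[nm]])) {
          x[[nm]][[i]] <- build(x[[nm]][[i]], paste0(key, i, "."))
        }
      } else {
        x[[nm]] <- flat[[key]]
      }
    }
    x
  }
  build(skeleton, "")
}
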