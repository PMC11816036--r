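#' Encoder configuration
#'
#' Hyperparameters of the BERT-style encoder over code tokens. The input
#' representation of each position is the sum of a token embedding and a
#' visit embedding indexed by the source-visit ordinal; the appended
#' next-visit `[MASK]` position uses ordinal (last visit + 1), so
#' `max_visits` must be at least the largest input ordinal plus one.
#'
#' @param embedding_dim Hidden width `d` (default 32, a desk-scale model).
#' @param n_layers Number of transformer layers.
#' @param n_heads Attention heads; must divide `embedding_dim`.
#' @param feedforward_dim Width of the position-wise feed-forward layer.
#' @param max_visits Visit-embedding table size (largest usable ordinal).
#' @param dropout Dropout probability on sublayer outputs during training;
#'   inference is always deterministic (dropout disabled).
#' @param max_len Fixed sequence length the encoder expects.
#' @param seed Seed for weight initialization.
#' @return A validated list of class `nv_encoder_config`.
#' @export
encoder_config <- function(embedding_dim = 32L, n_layers = 2L, n_heads = 2L,
                           feedforward_dim = 64L, max_visits = 16L,
                           dropout = 0, max_len = 64L, seed = 1L) {
  cfg <- list(
    embedding_dim = check_count(embedding_dim, "embedding_dim"),
    n_layers = check_count(n_layers, "n_layers"),
    n_heads = check_count(n_heads, "n_heads"),
    feedforward_dim = check_count(feedforward_dim, "feedforward_dim"),
    max_visits = check_count(max_visits, "max_visits"),
    dropout = check_prob(dropout, "dropout"),
    max_len = check_count(max_len, "max_len", min = 2L),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$embedding_dim %% cfg$n_heads != 0L)
    stop_nv("'embedding_dim' must be divisible by 'n_heads'")
  structure(cfg, class = "nv_encoder_config")
}

#' Initialize encoder weights
#'
#' Gaussian initialization (sd 0.02) of the token-embedding table, the
#' visit-embedding table, per-layer attention/feed-forward parameters, and
#' the per-token output bias of the masked-code objective. The token
#' embedding table doubles as the output projection (weight tying), which
#' is what lets downstream heads score target codes by dot product.
#'
#' @param config An `nv_encoder_config`.
#' @param vocab An `nv_vocabulary` (fixes the token table size).
#' @return Nested list of parameter arrays.
#' @export
init_encoder_weights <- function(config, vocab) {
  stopifnot(inherits(config, "nv_encoder_config"),
            inherits(vocab, "nv_vocabulary"))
  set.seed(config$seed)
  d <- config$embedding_dim
  ff <- config$feedforward_dim
  V <- vocab$size
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  layer <- function() list(
    Wq = rn(d, d), bq = numeric(d),
    Wk = rn(d, d), bk = numeric(d),
    Wv = rn(d, d), bv = numeric(d),
    Wo = rn(d, d), bo = numeric(d),
    ln1_g = rep(1, d), ln1_b = numeric(d),
    W1 = rn(d, ff), b1 = numeric(ff),
    W2 = rn(ff, d), b2 = numeric(d),
    ln2_g = rep(1, d), ln2_b = numeric(d)
  )
  list(
    tok_emb = rn(V, d),
    vis_emb = rn(config$max_visits + 1L, d),  # row 1 <-> ordinal 0 (PAD)
    layers = lapply(seq_len(config$n_layers), function(i) layer()),
    mlm_bias = numeric(V)
  )
}

#' Count trainable encoder parameters
#'
#' @param weights Encoder weights from [init_encoder_weights()].
#' @return Integer number of scalar parameters.
#' @export
n_parameters <- function(weights) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(weights)
  n
}

# ---- primitive layers -------------------------------------------------

# add a bias row-wise: M is n x d, b length d
add_bias <- function(M, b) M + rep(b, each = nrow(M))

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  y <- add_bias(xhat * rep(g, each = nrow(x)), b)
  list(y = y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

# ---- forward ----------------------------------------------------------

#' Run the encoder over a tokenized batch
#'
#' Computes contextualized embeddings for every position of every patient.
#' Self-attention is restricted by the attention mask: PAD positions are
#' never attended to, and attention rows over real positions renormalize
#' over real positions only, so appending padding cannot change any real
#' position's output.
#'
#' @param weights Encoder weights.
#' @param config The `nv_encoder_config` the weights were built with.
#' @param batch An `nv_batch` from [encode_cohort()] (or any list with
#'   integer matrices `token_ids`, `visit_ids`, `attention_mask`).
#' @param keep_cache Keep intermediate activations for backprop.
#' @param train Training mode (enables dropout if configured).
#' @return An `nv_contextual` object: `H` is a `(B*L) x d` matrix of
#'   contextual vectors in patient-major order, along with the batch
#'   geometry needed by pooling and heads.
#' @export
encoder_forward <- function(weights, config, batch,
                            keep_cache = FALSE, train = FALSE) {
  ids <- batch$token_ids
  vids <- batch$visit_ids
  amask <- batch$attention_mask
  B <- nrow(ids); L <- ncol(ids)
  if (L != config$max_len)
    stop_nv("batch length %d does not match encoder max_len %d", L, config$max_len)
  if (max(vids) > config$max_visits)
    stop_nv("visit ordinal %d exceeds max_visits (%d)", max(vids), config$max_visits)
  if (max(ids) + 1L > nrow(weights$tok_emb))
    stop_nv("token id %d outside the embedding table", max(ids))
  d <- config$embedding_dim
  H <- config$n_heads
  dh <- d %/% H
  scale <- 1 / sqrt(dh)

  flat_ids <- as.vector(t(ids))     # patient-major: rows (b-1)*L + l
  flat_vids <- as.vector(t(vids))
  mask_flat <- as.vector(t(amask))
  X <- weights$tok_emb[flat_ids + 1L, , drop = FALSE] +
       weights$vis_emb[flat_vids + 1L, , drop = FALSE]

  use_drop <- train && config$dropout > 0
  caches <- if (keep_cache) vector("list", config$n_layers)
  X0 <- X
  for (l in seq_len(config$n_layers)) {
    W <- weights$layers[[l]]
    Q <- add_bias(X %*% W$Wq, W$bq)
    K <- add_bias(X %*% W$Wk, W$bk)
    Vv <- add_bias(X %*% W$Wv, W$bv)
    O <- matrix(0, B * L, d)
    P_all <- if (keep_cache) array(0, c(L, L, H, B))
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      valid <- which(amask[b, ] == 1L)
      if (length(valid) == 0L) next  # all-PAD row: nothing attends anywhere
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- (Q[rows, cols, drop = FALSE] %*%
              t(K[rows, cols, drop = FALSE])) * scale
        Sv <- S[valid, valid, drop = FALSE]
        e <- exp(Sv - apply(Sv, 1L, max))
        Pv <- e / rowSums(e)
        P <- matrix(0, L, L)
        P[valid, valid] <- Pv
        O[rows, cols] <- P %*% Vv[rows, cols, drop = FALSE]
        if (keep_cache) P_all[, , h, b] <- P
      }
    }
    A <- add_bias(O %*% W$Wo, W$bo)
    dm_a <- NULL
    if (use_drop) {
      dm_a <- matrix(stats::rbinom(length(A), 1L, 1 - config$dropout),
                     nrow(A)) / (1 - config$dropout)
      A <- A * dm_a
    }
    ln1 <- layernorm_fwd(X + A, W$ln1_g, W$ln1_b)
    Y <- ln1$y
    Hpre <- add_bias(Y %*% W$W1, W$b1)
    Hact <- gelu(Hpre)
    Fo <- add_bias(Hact %*% W$W2, W$b2)
    dm_f <- NULL
    if (use_drop) {
      dm_f <- matrix(stats::rbinom(length(Fo), 1L, 1 - config$dropout),
                     nrow(Fo)) / (1 - config$dropout)
      Fo <- Fo * dm_f
    }
    ln2 <- layernorm_fwd(Y + Fo, W$ln2_g, W$ln2_b)
    if (keep_cache)
      caches[[l]] <- list(X = X, Q = Q, K = K, V = Vv, P = P_all, O = O,
                          ln1 = ln1, Y = Y, Hpre = Hpre, Hact = Hact,
                          dm_a = dm_a, dm_f = dm_f, ln2 = ln2)
    X <- ln2$y
  }

  structure(list(
    H = X, B = B, L = L,
    token_ids = ids, visit_ids = vids, attention_mask = amask,
    mask_position = batch$mask_position,
    cache = if (keep_cache) list(layers = caches, X0 = X0,
                                 flat_ids = flat_ids, flat_vids = flat_vids,
                                 mask_flat = mask_flat)
  ), class = "nv_contextual")
}

#' @export
print.nv_contextual <- function(x, ...) {
  cat(sprintf("<nv_contextual> %d patients x %d positions, dim %d\n",
              x$B, x$L, ncol(x$H)))
  invisible(x)
}

# ---- backward ---------------------------------------------------------

# dH: (B*L) x d gradient on the contextual output. Returns gradients for
# every encoder weight (same tree shape) including the embedding tables.
encoder_backward <- function(weights, config, contextual, dH) {
  cache <- contextual$cache
  if (is.null(cache)) stop_nv("encoder_forward was run without keep_cache")
  amask <- contextual$attention_mask
  B <- contextual$B; L <- contextual$L
  d <- config$embedding_dim
  Hh <- config$n_heads
  dh <- d %/% Hh
  scale <- 1 / sqrt(dh)

  g_layers <- vector("list", config$n_layers)
  dX <- dH
  for (l in rev(seq_len(config$n_layers))) {
    W <- weights$layers[[l]]
    cc <- cache$layers[[l]]
    b2 <- layernorm_bwd(dX, cc$ln2, W$ln2_g)
    dR2 <- b2$dx
    dFo <- dR2
    if (!is.null(cc$dm_f)) dFo <- dFo * cc$dm_f
    dHact <- dFo %*% t(W$W2)
    dW2 <- t(cc$Hact) %*% dFo
    db2f <- colSums(dFo)
    dHpre <- dHact * gelu_grad(cc$Hpre)
    dW1 <- t(cc$ln1$y) %*% dHpre
    db1f <- colSums(dHpre)
    dY <- dR2 + dHpre %*% t(W$W1)
    b1 <- layernorm_bwd(dY, cc$ln1, W$ln1_g)
    dR1 <- b1$dx
    dA <- dR1
    if (!is.null(cc$dm_a)) dA <- dA * cc$dm_a
    dO <- dA %*% t(W$Wo)
    dWo <- t(cc$O) %*% dA
    dbo <- colSums(dA)

    dQ <- matrix(0, B * L, d)
    dK <- matrix(0, B * L, d)
    dV <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * L + 1L):(b * L)
      for (h in seq_len(Hh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        P <- cc$P[, , h, b]
        dOb <- dO[rows, cols, drop = FALSE]
        dP <- dOb %*% t(cc$V[rows, cols, drop = FALSE])
        dV[rows, cols] <- t(P) %*% dOb
        dS <- P * (dP - rowSums(dP * P))
        dQ[rows, cols] <- (dS %*% cc$K[rows, cols, drop = FALSE]) * scale
        dK[rows, cols] <- (t(dS) %*% cc$Q[rows, cols, drop = FALSE]) * scale
      }
    }
    X <- cc$X
    g_layers[[l]] <- list(
      Wq = t(X) %*% dQ, bq = colSums(dQ),
      Wk = t(X) %*% dK, bk = colSums(dK),
      Wv = t(X) %*% dV, bv = colSums(dV),
      Wo = dWo, bo = dbo,
      ln1_g = b1$dg, ln1_b = b1$db,
      W1 = dW1, b1 = db1f,
      W2 = dW2, b2 = db2f,
      ln2_g = b2$dg, ln2_b = b2$db
    )
    dX <- dR1 + dQ %*% t(W$Wq) + dK %*% t(W$Wk) + dV %*% t(W$Wv)
  }

  dtok <- matrix(0, nrow(weights$tok_emb), d)
  acc <- rowsum(dX, group = cache$flat_ids, reorder = FALSE)
  dtok[as.integer(rownames(acc)) + 1L, ] <- acc
  dvis <- matrix(0, nrow(weights$vis_emb), d)
  accv <- rowsum(dX, group = cache$flat_vids, reorder = FALSE)
  dvis[as.integer(rownames(accv)) + 1L, ] <- accv

  list(tok_emb = dtok, vis_emb = dvis, layers = g_layers,
       mlm_bias = numeric(length(weights$mlm_bias)))
}

# ---- pooling ----------------------------------------------------------

#' Sum-pool contextual embeddings into patient context vectors
#'
#' The patient context vector is the exact sum of the contextualized
#' embeddings over real (non-PAD) sequence positions — no averaging or
#' normalization — so its dimension is `[1, embedding_dim]` per patient.
#' PAD rows are excluded; otherwise the vector would depend on how much
#' padding a batch happens to carry.
#'
#' @param contextual An `nv_contextual` from [encoder_forward()].
#' @return A `B x d` matrix, one patient context vector per row.
#' @export
pool_sum <- function(contextual) {
  stopifnot(inherits(contextual, "nv_contextual"))
  m <- as.vector(t(contextual$attention_mask))
  if (any(rowSums(contextual$attention_mask) == 0))
    stop_nv("pool_sum: a patient has no non-PAD position")
  grp <- rep(seq_len(contextual$B), each = contextual$L)
  rowsum(contextual$H * m, group = grp, reorder = TRUE)
}

# scatter a B x d gradient on pooled vectors back to sequence positions
pool_sum_backward <- function(contextual, dC) {
  m <- as.vector(t(contextual$attention_mask))
  dC[rep(seq_len(contextual$B), each = contextual$L), , drop = FALSE] * m
}
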