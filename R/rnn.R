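# Recurrent sequence classifiers (GRU / LSTM, optionally bidirectional)
# trained from scratch: embedding layer -> recurrent cell -> final hidden
# state -> logistic output. Padding is handled by carrying the previous
# hidden state through PAD steps, so the state at position L is the state
# at each patient's last real token.

init_rnn_weights <- function(kind, V, de, hd, bidir, seed) {
  set.seed(seed)
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.1), nr, nc)
  gates <- if (kind == "gru") c("z", "r", "h") else c("i", "f", "o", "g")
  cell <- function() {
    w <- list()
    for (g in gates) {
      w[[paste0("U", g)]] <- rn(de, hd)
      w[[paste0("W", g)]] <- rn(hd, hd)
      w[[paste0("b", g)]] <- numeric(hd)
    }
    w
  }
  p <- list(emb = rn(V, de), fwd = cell())
  if (bidir) p$bwd <- cell()
  p$w <- stats::rnorm(hd * (1L + bidir), sd = 0.1)
  p$b <- 0
  p
}

# reverse each patient's real-token prefix, keeping trailing pads
reverse_batch <- function(ids, amask) {
  out <- ids
  for (b in seq_len(nrow(ids))) {
    n <- sum(amask[b, ])
    if (n > 1L) out[b, seq_len(n)] <- ids[b, n:1]
  }
  out
}

gru_forward <- function(cell, emb, ids, amask, keep_cache = FALSE) {
  B <- nrow(ids); L <- ncol(ids); hd <- ncol(cell$Wz)
  h <- matrix(0, B, hd)
  cache <- if (keep_cache) vector("list", L)
  for (t in seq_len(L)) {
    x <- emb[ids[, t] + 1L, , drop = FALSE]
    m <- amask[, t]
    z <- logistic(add_bias(x %*% cell$Uz + h %*% cell$Wz, cell$bz))
    r <- logistic(add_bias(x %*% cell$Ur + h %*% cell$Wr, cell$br))
    hc <- tanh(add_bias(x %*% cell$Uh + (r * h) %*% cell$Wh, cell$bh))
    hnew <- (1 - z) * h + z * hc
    hh <- m * hnew + (1 - m) * h
    if (keep_cache) cache[[t]] <- list(h_prev = h, z = z, r = r, hc = hc)
    h <- hh
  }
  list(h = h, cache = cache)
}

gru_backward <- function(cell, emb, ids, amask, cache, dh) {
  B <- nrow(ids); L <- ncol(ids)
  g <- tree_zero(cell)
  demb <- matrix(0, nrow(emb), ncol(emb))
  for (t in rev(seq_len(L))) {
    cc <- cache[[t]]
    m <- amask[, t]
    x <- emb[ids[, t] + 1L, , drop = FALSE]
    dhnew <- dh * m
    dh_prev <- dh * (1 - m)
    dz <- dhnew * (cc$hc - cc$h_prev)
    dhc <- dhnew * cc$z
    dh_prev <- dh_prev + dhnew * (1 - cc$z)
    dhc_pre <- dhc * (1 - cc$hc^2)
    g$Wh <- g$Wh + t(cc$r * cc$h_prev) %*% dhc_pre
    dtmp <- dhc_pre %*% t(cell$Wh)
    dr <- dtmp * cc$h_prev
    dh_prev <- dh_prev + dtmp * cc$r
    g$Uh <- g$Uh + t(x) %*% dhc_pre
    g$bh <- g$bh + colSums(dhc_pre)
    dx <- dhc_pre %*% t(cell$Uh)
    dz_pre <- dz * cc$z * (1 - cc$z)
    dr_pre <- dr * cc$r * (1 - cc$r)
    g$Uz <- g$Uz + t(x) %*% dz_pre
    g$Wz <- g$Wz + t(cc$h_prev) %*% dz_pre
    g$bz <- g$bz + colSums(dz_pre)
    g$Ur <- g$Ur + t(x) %*% dr_pre
    g$Wr <- g$Wr + t(cc$h_prev) %*% dr_pre
    g$br <- g$br + colSums(dr_pre)
    dh_prev <- dh_prev + dz_pre %*% t(cell$Wz) + dr_pre %*% t(cell$Wr)
    dx <- dx + dz_pre %*% t(cell$Uz) + dr_pre %*% t(cell$Ur)
    acc <- rowsum(dx, group = ids[, t], reorder = FALSE)
    ridx <- as.integer(rownames(acc)) + 1L
    demb[ridx, ] <- demb[ridx, ] + acc
    dh <- dh_prev
  }
  list(cell = g, demb = demb)
}

lstm_forward <- function(cell, emb, ids, amask, keep_cache = FALSE) {
  B <- nrow(ids); L <- ncol(ids); hd <- ncol(cell$Wi)
  h <- matrix(0, B, hd)
  cs <- matrix(0, B, hd)
  cache <- if (keep_cache) vector("list", L)
  for (t in seq_len(L)) {
    x <- emb[ids[, t] + 1L, , drop = FALSE]
    m <- amask[, t]
    i <- logistic(add_bias(x %*% cell$Ui + h %*% cell$Wi, cell$bi))
    f <- logistic(add_bias(x %*% cell$Uf + h %*% cell$Wf, cell$bf))
    o <- logistic(add_bias(x %*% cell$Uo + h %*% cell$Wo, cell$bo))
    gg <- tanh(add_bias(x %*% cell$Ug + h %*% cell$Wg, cell$bg))
    cnew <- f * cs + i * gg
    tc <- tanh(cnew)
    hnew <- o * tc
    hh <- m * hnew + (1 - m) * h
    cc_ <- m * cnew + (1 - m) * cs
    if (keep_cache)
      cache[[t]] <- list(h_prev = h, c_prev = cs, i = i, f = f, o = o,
                         g = gg, tc = tc)
    h <- hh
    cs <- cc_
  }
  list(h = h, cache = cache)
}

lstm_backward <- function(cell, emb, ids, amask, cache, dh) {
  B <- nrow(ids); L <- ncol(ids)
  g <- tree_zero(cell)
  demb <- matrix(0, nrow(emb), ncol(emb))
  dc <- matrix(0, nrow(dh), ncol(dh))
  for (t in rev(seq_len(L))) {
    cc <- cache[[t]]
    m <- amask[, t]
    x <- emb[ids[, t] + 1L, , drop = FALSE]
    dhnew <- dh * m
    dh_prev <- dh * (1 - m)
    dcnew <- dc * m
    dc_prev <- dc * (1 - m)
    do_ <- dhnew * cc$tc
    dtc <- dhnew * cc$o * (1 - cc$tc^2) + dcnew
    df <- dtc * cc$c_prev
    dc_prev <- dc_prev + dtc * cc$f
    di <- dtc * cc$g
    dg <- dtc * cc$i
    di_pre <- di * cc$i * (1 - cc$i)
    df_pre <- df * cc$f * (1 - cc$f)
    do_pre <- do_ * cc$o * (1 - cc$o)
    dg_pre <- dg * (1 - cc$g^2)
    for (nm in c("i", "f", "o", "g")) {
      dp <- switch(nm, i = di_pre, f = df_pre, o = do_pre, g = dg_pre)
      g[[paste0("U", nm)]] <- g[[paste0("U", nm)]] + t(x) %*% dp
      g[[paste0("W", nm)]] <- g[[paste0("W", nm)]] + t(cc$h_prev) %*% dp
      g[[paste0("b", nm)]] <- g[[paste0("b", nm)]] + colSums(dp)
    }
    dh_prev <- dh_prev + di_pre %*% t(cell$Wi) + df_pre %*% t(cell$Wf) +
      do_pre %*% t(cell$Wo) + dg_pre %*% t(cell$Wg)
    dx <- di_pre %*% t(cell$Ui) + df_pre %*% t(cell$Uf) +
      do_pre %*% t(cell$Uo) + dg_pre %*% t(cell$Ug)
    acc <- rowsum(dx, group = ids[, t], reorder = FALSE)
    ridx <- as.integer(rownames(acc)) + 1L
    demb[ridx, ] <- demb[ridx, ] + acc
    dh <- dh_prev
    dc <- dc_prev
  }
  list(cell = g, demb = demb)
}

# final-state representation (concatenating directions when bidirectional)
rnn_represent <- function(params, kind, ids, amask, keep_cache = FALSE) {
  fwd_fn <- if (kind == "gru") gru_forward else lstm_forward
  fw <- fwd_fn(params$fwd, params$emb, ids, amask, keep_cache)
  rep_mat <- fw$h
  bw <- NULL
  rids <- NULL
  if (!is.null(params$bwd)) {
    rids <- reverse_batch(ids, amask)
    bw <- fwd_fn(params$bwd, params$emb, rids, amask, keep_cache)
    rep_mat <- cbind(fw$h, bw$h)
  }
  list(rep = rep_mat, fw = fw, bw = bw, rids = rids)
}

# loss + full gradient tree for one minibatch
rnn_batch_grads <- function(params, kind, ids, amask, y) {
  fwd <- rnn_represent(params, kind, ids, amask, keep_cache = TRUE)
  s <- as.vector(logistic(fwd$rep %*% params$w + params$b))
  loss <- mean(bce(s, y))
  B <- length(y)
  du <- (s - y) / B
  hd <- ncol(fwd$fw$h)
  bwd_fn <- if (kind == "gru") gru_backward else lstm_backward
  dh_f <- outer(du, params$w[seq_len(hd)])
  gf <- bwd_fn(params$fwd, params$emb, ids, amask, fwd$fw$cache, dh_f)
  demb <- gf$demb
  gb <- NULL
  if (!is.null(params$bwd)) {
    dh_b <- outer(du, params$w[hd + seq_len(hd)])
    gb <- bwd_fn(params$bwd, params$emb, fwd$rids, amask, fwd$bw$cache, dh_b)
    demb <- demb + gb$demb
  }
  grads <- list(emb = demb, fwd = gf$cell)
  if (!is.null(gb)) grads$bwd <- gb$cell
  grads$w <- as.vector(t(fwd$rep) %*% du)
  grads$b <- sum(du)
  list(loss = loss, scores = s, grads = grads)
}

rnn_scores <- function(params, kind, ids, amask) {
  r <- rnn_represent(params, kind, ids, amask)
  as.vector(logistic(r$rep %*% params$w + params$b))
}
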