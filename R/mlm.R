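#' Masked-code corruption configuration
#'
#' The BERT recipe for the masked language-model objective on code
#' sequences: each real position is selected for prediction with
#' probability `select_rate`; a selected position's code is replaced by
#' `[MASK]` with probability `p_mask`, replaced by a random ordinary code
#' with probability `p_random`, and left unchanged with probability
#' `p_keep`. Defaults are 0.15 and 0.80/0.10/0.10.
#'
#' @param select_rate Probability a real position is selected.
#' @param p_mask,p_random,p_keep Treatment probabilities; must sum to 1.
#' @param seed Seed making the corruption draw reproducible.
#' @return A list of class `nv_corruption_config`.
#' @export
corruption_config <- function(select_rate = 0.15, p_mask = 0.80,
                              p_random = 0.10, p_keep = 0.10, seed = 1L) {
  cfg <- list(
    select_rate = check_prob(select_rate, "select_rate"),
    p_mask = check_prob(p_mask, "p_mask"),
    p_random = check_prob(p_random, "p_random"),
    p_keep = check_prob(p_keep, "p_keep"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$select_rate <= 0)
    stop_nv("'select_rate' must be in (0, 1]")
  if (abs(cfg$p_mask + cfg$p_random + cfg$p_keep - 1) > 1e-9)
    stop_nv("p_mask + p_random + p_keep must equal 1")
  structure(cfg, class = "nv_corruption_config")
}

#' Corrupt token sequences for masked-code pretraining
#'
#' PAD positions are never selected; random replacements are drawn from
#' ordinary code ids only (never PAD or MASK). The returned
#' `prediction_targets` matrix holds the original token id at selected
#' positions and the sentinel `NA` elsewhere; only selected positions
#' contribute to the pretraining loss.
#'
#' @param token_ids Integer matrix `B x L` of token ids.
#' @param attention_mask Binary matrix `B x L` (1 = real position).
#' @param vocab An `nv_vocabulary`.
#' @param config An `nv_corruption_config`; its `seed` makes the draw
#'   deterministic.
#' @return List with `corrupted_ids` and `prediction_targets`, both
#'   `B x L` integer matrices.
#' @export
corrupt_sequence <- function(token_ids, attention_mask, vocab, config) {
  stopifnot(inherits(vocab, "nv_vocabulary"),
            inherits(config, "nv_corruption_config"))
  if (vocab$n_codes == 0L)
    stop_nv("vocabulary has no non-special code ids to sample from")
  set.seed(config$seed)
  real <- which(attention_mask == 1L)
  sel <- real[stats::runif(length(real)) < config$select_rate]
  targets <- matrix(NA_integer_, nrow(token_ids), ncol(token_ids))
  corrupted <- token_ids
  if (length(sel)) {
    targets[sel] <- token_ids[sel]
    u <- stats::runif(length(sel))
    to_mask <- sel[u < config$p_mask]
    to_rand <- sel[u >= config$p_mask & u < config$p_mask + config$p_random]
    corrupted[to_mask] <- vocab$mask_id
    if (length(to_rand))
      corrupted[to_rand] <- sample.int(vocab$n_codes, length(to_rand),
                                       replace = TRUE) + 1L  # ids start at 2
  }
  list(corrupted_ids = corrupted, prediction_targets = targets)
}

#' Full-vocabulary masked-code scores
#'
#' Scores every vocabulary token at every given contextual vector by dot
#' product with the (tied) token-embedding table, plus a per-token bias:
#' `score[p, v] = h_p . e_v + bias_v`. Restricting the score vector to the
#' target-code ids reproduces the token-prediction and masked-token head
#' logits exactly — the geometric link between pretraining and the heads.
#'
#' @param contextual Matrix `n x d` of contextual vectors (rows).
#' @param token_embedding Token-embedding table `V x d`.
#' @param bias Optional per-token bias of length `V` (default zero).
#' @return `n x V` score matrix.
#' @export
mlm_logits <- function(contextual, token_embedding, bias = NULL) {
  contextual <- if (is.matrix(contextual)) contextual
                else matrix(contextual, nrow = 1L)
  if (ncol(contextual) != ncol(token_embedding))
    stop_nv("embedding dimension mismatch: %d vs %d",
            ncol(contextual), ncol(token_embedding))
  S <- contextual %*% t(token_embedding)
  if (!is.null(bias)) {
    if (length(bias) != nrow(token_embedding))
      stop_nv("bias length %d does not match vocabulary size %d",
              length(bias), nrow(token_embedding))
    S <- S + rep(bias, each = nrow(S))
  }
  S
}

# cross-entropy over selected positions; returns loss and, optionally,
# gradients on the selected contextual rows, the embedding table and bias
mlm_loss <- function(H, sel, target_ids0, weights, with_grads = FALSE) {
  S <- length(sel)
  logits <- mlm_logits(H[sel, , drop = FALSE], weights$tok_emb,
                       weights$mlm_bias)
  mx <- apply(logits, 1L, max)
  Z <- exp(logits - mx)
  P <- Z / rowSums(Z)
  idx <- cbind(seq_len(S), target_ids0 + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  if (!with_grads) return(list(loss = loss))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / S
  list(loss = loss,
       dH_sel = dlogits %*% weights$tok_emb,
       dtok_emb = t(dlogits) %*% H[sel, , drop = FALSE],
       dbias = colSums(dlogits))
}

# evaluate masked-code cross-entropy of current weights on a batch with a
# fixed corruption draw (no gradients)
mlm_eval <- function(weights, config, batch, vocab, corrupt) {
  cb <- batch
  cb$token_ids <- corrupt$corrupted_ids
  ctx <- encoder_forward(weights, config, cb)
  sel <- which(!is.na(t(corrupt$prediction_targets)))  # patient-major order
  tids <- t(corrupt$prediction_targets)[sel]
  mlm_loss(ctx$H, sel, tids, weights)$loss
}

#' Pretrain the encoder with the masked-code objective
#'
#' Encodes the cohort's full trajectories (onset visits included, no
#' next-visit masks): pretraining plays the role of general-population
#' pretraining, in which future disease codes are observed, so the
#' masked-code objective can place target-code embeddings near the
#' precursor contexts they co-occur with. It repeatedly corrupts the
#' training sequences (a fresh draw each epoch) and minimizes
#' cross-entropy at the selected positions with Adam. The output
#' projection is the tied token-embedding table, so pretraining shapes
#' exactly the embedding geometry the downstream heads score against.
#' A held-out fraction of patients (fixed corruption draw) is monitored
#' each epoch; training stops early when the held-out loss has not
#' improved for `patience` epochs, and the best weights are kept.
#'
#' @param cohort List of patient records.
#' @param vocab An `nv_vocabulary`.
#' @param config An `nv_encoder_config`.
#' @param corruption An `nv_corruption_config`.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience on held-out loss.
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Patients per optimization step (default 100).
#' @param holdout_fraction Fraction of patients held out for monitoring.
#' @param seed Seed governing shuffling and per-epoch corruption.
#' @param verbose Print per-epoch losses.
#' @return An `nv_checkpoint`: `weights`, `encoder_config`,
#'   `corruption_config`, `vocab`, a `history` data frame (epoch 0 is the
#'   initialization), and the seed. Save with [save_checkpoint()].
#' @export
pretrain <- function(cohort, vocab, config,
                     corruption = corruption_config(),
                     epochs = 30L, patience = 5L, lr = 1e-3,
                     batch_size = 100L, holdout_fraction = 0.1,
                     seed = 1L, verbose = FALSE) {
  stopifnot(inherits(vocab, "nv_vocabulary"),
            inherits(config, "nv_encoder_config"),
            inherits(corruption, "nv_corruption_config"))
  epochs <- check_count(epochs, "epochs")
  batch_size <- check_count(batch_size, "batch_size")

  batch <- encode_cohort(cohort, vocab, max_len = config$max_len,
                         add_next_visit_mask = FALSE, window = "full")
  B <- nrow(batch$token_ids)
  seeds <- derive_seeds(seed, 2L + epochs)
  set.seed(seeds[1])
  n_hold <- max(1L, floor(holdout_fraction * B))
  hold <- sample.int(B, n_hold)
  train_idx <- setdiff(seq_len(B), hold)
  hold_batch <- subset_batch(batch, hold)
  hold_corrupt <- corrupt_sequence(hold_batch$token_ids,
                                   hold_batch$attention_mask, vocab,
                                   replace_seed(corruption, seeds[2]))

  weights <- init_encoder_weights(config, vocab)
  state <- adam_init(weights)
  hist <- data.frame(epoch = 0L, train_loss = NA_real_,
                     holdout_loss = mlm_eval(weights, config, hold_batch,
                                             vocab, hold_corrupt))
  best <- list(weights = weights, loss = hist$holdout_loss[1], epoch = 0L)
  stall <- 0L

  for (ep in seq_len(epochs)) {
    set.seed(seeds[2L + ep])
    order_idx <- sample(train_idx)
    ep_corrupt <- corrupt_sequence(
      batch$token_ids, batch$attention_mask, vocab,
      replace_seed(corruption, seeds[2L + ep]))
    losses <- c()
    for (start in seq(1L, length(order_idx), by = batch_size)) {
      idx <- order_idx[start:min(start + batch_size - 1L, length(order_idx))]
      mb <- subset_batch(batch, idx)
      cor_ids <- ep_corrupt$corrupted_ids[idx, , drop = FALSE]
      tg <- ep_corrupt$prediction_targets[idx, , drop = FALSE]
      sel <- which(!is.na(t(tg)))
      if (length(sel) == 0L) next
      mb$token_ids <- cor_ids
      ctx <- encoder_forward(weights, config, mb, keep_cache = TRUE,
                             train = TRUE)
      ml <- mlm_loss(ctx$H, sel, t(tg)[sel], weights, with_grads = TRUE)
      if (!is.finite(ml$loss))
        stop_nv("pretraining diverged (loss %s) at epoch %d", ml$loss, ep)
      dH <- matrix(0, nrow(ctx$H), ncol(ctx$H))
      dH[sel, ] <- ml$dH_sel
      grads <- encoder_backward(weights, config, ctx, dH)
      grads$tok_emb <- grads$tok_emb + ml$dtok_emb   # weight tying
      grads$mlm_bias <- grads$mlm_bias + ml$dbias
      stepped <- adam_step(weights, grads, state, lr)
      weights <- stepped$params
      state <- stepped$state
      losses <- c(losses, ml$loss)
    }
    hold_loss <- mlm_eval(weights, config, hold_batch, vocab, hold_corrupt)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   holdout_loss = hold_loss))
    if (verbose)
      message(sprintf("epoch %d: train %.4f holdout %.4f",
                      ep, mean(losses), hold_loss))
    if (hold_loss < best$loss - 1e-6) {
      best <- list(weights = weights, loss = hold_loss, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  structure(list(
    weights = best$weights,
    encoder_config = config,
    corruption_config = corruption,
    vocab = vocab,
    history = hist,
    best_epoch = best$epoch,
    seed = seed,
    format_version = 1L
  ), class = "nv_checkpoint")
}

replace_seed <- function(corruption, seed) {
  corruption$seed <- as.integer(seed)
  corruption
}

#' @export
print.nv_checkpoint <- function(x, ...) {
  cat(sprintf(paste0("<nv_checkpoint> d=%d, %d layers, vocab %d tokens; ",
                     "best held-out MLM loss %.4f at epoch %d\n"),
              x$encoder_config$embedding_dim, x$encoder_config$n_layers,
              x$vocab$size, min(x$history$holdout_loss), x$best_epoch))
  invisible(x)
}

#' Save / load an encoder checkpoint
#'
#' Checkpoints are single serialized archives with the producing
#' configuration, vocabulary and seed embedded, and a format version that
#' is checked on load.
#'
#' @param checkpoint An `nv_checkpoint`.
#' @param path File path.
#' @return `path` invisibly for save; the checkpoint for load.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "nv_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "nv_checkpoint"))
    stop_nv("'%s' is not an encoder checkpoint", path)
  if (!identical(ck$format_version, 1L))
    stop_nv("unsupported checkpoint format version: %s", ck$format_version)
  ck
}
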