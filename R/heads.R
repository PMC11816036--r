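#' Extract the target-code label tensor
#'
#' The `[K, d]` matrix whose row `k` is the token-embedding row of the
#' `k`-th target code (K = 8 by default). Because the embedding table is
#' the tied output projection of the masked-code objective, these rows are
#' exactly the directions pretraining uses to score target codes — the
#' verbalizer the token-prediction and masked-token heads dot against.
#'
#' @param weights Encoder weights.
#' @param vocab An `nv_vocabulary`.
#' @return `K x d` numeric matrix.
#' @export
label_tensor <- function(weights, vocab) {
  stopifnot(inherits(vocab, "nv_vocabulary"))
  weights$tok_emb[vocab$target_ids + 1L, , drop = FALSE]
}

head_output <- function(per_token_probs, patient_score) {
  structure(list(per_token_probs = per_token_probs,
                 patient_score = patient_score),
            class = "nv_head_output")
}

as_row <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Binary-classification head
#'
#' A linear layer on the pooled patient context vector:
#' `score = logistic(w . context + b)`. No per-token output.
#'
#' @param context Patient context vector(s): length-`d` vector or `B x d`
#'   matrix.
#' @param w Weight vector of length `d`.
#' @param b Scalar bias.
#' @return An `nv_head_output` with `patient_score` (length `B`) and
#'   `per_token_probs = NULL`.
#' @export
bc_head <- function(context, w, b = 0) {
  C <- as_row(context)
  if (ncol(C) != length(w))
    stop_nv("dimension mismatch: context has %d columns, w has length %d",
            ncol(C), length(w))
  head_output(NULL, as.vector(logistic(C %*% w + b)))
}

#' Token-prediction head on the pooled patient vector
#'
#' Dot product of the patient context vector with every label-tensor row,
#' elementwise logistic, giving one probability per target code; the
#' patient score is the maximum of the K probabilities.
#'
#' @param context Patient context vector(s): length-`d` vector or `B x d`.
#' @param labels Label tensor `K x d` from [label_tensor()].
#' @return An `nv_head_output`: `per_token_probs` (`B x K`) and
#'   `patient_score` (length `B`).
#' @export
sum_head <- function(context, labels) {
  C <- as_row(context)
  if (ncol(C) != ncol(labels))
    stop_nv("dimension mismatch: context dim %d vs label tensor dim %d",
            ncol(C), ncol(labels))
  probs <- unname(logistic(C %*% t(labels)))
  head_output(probs, apply(probs, 1L, max))
}

#' Masked-token prediction head at the next-visit position
#'
#' Dot product of the contextual vector at the appended `[MASK]` position
#' with the label tensor. The logits equal the restriction of the
#' full-vocabulary masked-code scores ([mlm_logits()] with zero bias) to
#' the target-code ids — the formal sense in which this head re-uses the
#' pretraining task.
#'
#' @param contextual An `nv_contextual` from [encoder_forward()] on a
#'   batch encoded with `add_next_visit_mask = TRUE`.
#' @param labels Label tensor `K x d`.
#' @param mask_position Optional integer vector overriding the positions
#'   recorded in the batch.
#' @return An `nv_head_output`: `per_token_probs` (`B x K`) and
#'   `patient_score` (length `B`).
#' @export
mask_head <- function(contextual, labels, mask_position = NULL) {
  stopifnot(inherits(contextual, "nv_contextual"))
  pos <- mask_position %||% contextual$mask_position
  if (is.null(pos) || anyNA(pos))
    stop_nv("mask_position is not set; encode with add_next_visit_mask = TRUE")
  if (length(pos) != contextual$B)
    stop_nv("need one mask position per patient")
  tok_at <- contextual$token_ids[cbind(seq_len(contextual$B), pos)]
  if (any(tok_at != 1L))
    stop_nv("token at mask_position is not [MASK]")
  rows <- (seq_len(contextual$B) - 1L) * contextual$L + pos
  Hm <- contextual$H[rows, , drop = FALSE]
  if (ncol(Hm) != ncol(labels))
    stop_nv("dimension mismatch: contextual dim %d vs label tensor dim %d",
            ncol(Hm), ncol(labels))
  probs <- logistic(Hm %*% t(labels))
  head_output(probs, apply(probs, 1L, max))
}

#' Fine-tuning loss of a head output
#'
#' Binary classification: binary cross-entropy of the patient score
#' against the case label. For the token-prediction and masked-token
#' heads two policies exist. The default, `"max"`, is binary
#' cross-entropy of the max-probability patient score against the label —
#' the same quantity the evaluation uses. `"per_token"` is the mean
#' binary cross-entropy of the K per-token probabilities against the
#' multi-hot onset-code target (all-zero for controls); it uses richer
#' supervision but, under single-onset labels, penalizes the 7
#' non-onset codes whose embeddings pretraining makes nearly parallel
#' to the onset code, which can erode the shared onset direction the
#' max score relies on (see the methods vignette). Losses are averaged
#' over patients.
#'
#' @param output An `nv_head_output`.
#' @param label Integer 0/1 vector of case labels.
#' @param target_multi_hot `B x K` 0/1 matrix (required for sum/mask).
#' @param head_kind `"bc"`, `"sum"` or `"mask"`.
#' @param policy `"max"` or `"per_token"` (sum/mask heads only).
#' @return Scalar loss.
#' @export
finetune_loss <- function(output, label, target_multi_hot = NULL,
                          head_kind = c("bc", "sum", "mask"),
                          policy = c("max", "per_token")) {
  head_kind <- match.arg(head_kind)
  policy <- match.arg(policy)
  stopifnot(inherits(output, "nv_head_output"))
  label <- as.integer(label)
  if (head_kind == "bc")
    return(mean(bce(output$patient_score, label)))
  M <- rbind(target_multi_hot)
  if (is.null(target_multi_hot))
    stop_nv("sum/mask losses need 'target_multi_hot'")
  if (any((rowSums(M) > 0) != (label == 1L)))
    stop_nv(paste0("'target_multi_hot' inconsistent with 'label': the ",
                   "multi-hot row must be non-zero exactly for cases"))
  if (policy == "max")
    return(mean(bce(output$patient_score, label)))
  mean(rowMeans(bce(output$per_token_probs, M)))
}

# ---- fine-tuning ------------------------------------------------------

init_head_params <- function(head_kind, d, seed) {
  set.seed(seed)
  if (head_kind == "bc")
    list(w = stats::rnorm(d, sd = 0.02), b = 0)
  else
    list()  # sum/mask score against the (tied) label tensor
}

# forward + loss + gradients for one minibatch; returns loss, scores and
# the gradient tree (encoder weights + head params)
head_batch_grads <- function(weights, head, config, vocab, mb, head_kind,
                             policy, label_trainable) {
  ctx <- encoder_forward(weights, config, mb, keep_cache = TRUE, train = TRUE)
  B <- ctx$B
  y <- mb$labels
  Lt <- label_tensor(weights, vocab)
  K <- nrow(Lt)
  dH <- matrix(0, nrow(ctx$H), ncol(ctx$H))
  dhead <- list()
  dLt <- NULL

  if (head_kind == "bc") {
    C <- pool_sum(ctx)
    s <- as.vector(logistic(C %*% head$w + head$b))
    loss <- mean(bce(s, y))
    du <- (s - y) / B
    dC <- outer(du, head$w)
    dhead <- list(w = as.vector(t(C) %*% du), b = sum(du))
    dH <- pool_sum_backward(ctx, dC)
    scores <- s
  } else {
    if (head_kind == "sum") {
      C <- pool_sum(ctx)
      Z <- C %*% t(Lt)
    } else {
      pos <- mb$mask_position
      rows <- (seq_len(B) - 1L) * ctx$L + pos
      Hm <- ctx$H[rows, , drop = FALSE]
      Z <- Hm %*% t(Lt)
    }
    P <- logistic(Z)
    M <- mb$target_multi_hot
    if (policy == "per_token") {
      loss <- mean(rowMeans(bce(P, M)))
      dZ <- (P - M) / (B * K)
    } else {
      kmax <- max.col(P, ties.method = "first")
      s <- P[cbind(seq_len(B), kmax)]
      loss <- mean(bce(s, y))
      dZ <- matrix(0, B, K)
      dZ[cbind(seq_len(B), kmax)] <- (s - y) / B
    }
    dIn <- dZ %*% Lt
    dLt <- t(dZ) %*% (if (head_kind == "sum") C else Hm)
    if (head_kind == "sum") {
      dH <- pool_sum_backward(ctx, dIn)
    } else {
      dH[rows, ] <- dIn
    }
    scores <- apply(P, 1L, max)
  }

  grads <- encoder_backward(weights, config, ctx, dH)
  if (!is.null(dLt) && label_trainable)
    grads$tok_emb[vocab$target_ids + 1L, ] <-
      grads$tok_emb[vocab$target_ids + 1L, ] + dLt
  list(loss = loss, scores = scores, grads = grads, dhead = dhead)
}

# score a batch with fixed weights (no gradients)
head_scores <- function(weights, head, config, vocab, batch, head_kind) {
  ctx <- encoder_forward(weights, config, batch)
  out <- switch(head_kind,
    bc = bc_head(pool_sum(ctx), head$w, head$b),
    sum = sum_head(pool_sum(ctx), label_tensor(weights, vocab)),
    mask = mask_head(ctx, label_tensor(weights, vocab))
  )
  out$patient_score
}

#' Fine-tune a prediction head on labeled patients
#'
#' Starts from a pretrained checkpoint and jointly updates the encoder and
#' the head with Adam, monitoring validation AUROC after every epoch;
#' training stops when the validation AUROC has not improved for
#' `patience` epochs and the best weights are kept. For the
#' token-prediction and masked-token heads the label tensor stays tied to
#' the embedding table; set `label_trainable = FALSE` to freeze the target
#' rows against head-gradient updates.
#'
#' @param checkpoint An `nv_checkpoint` from [pretrain()] (or an
#'   equivalent list with `weights`, `encoder_config`, `vocab`).
#' @param head_kind `"bc"`, `"sum"` or `"mask"`.
#' @param train_cohort,val_cohort Lists of patient records.
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Patients per step (default 100).
#' @param max_epochs,patience Early-stopping schedule.
#' @param policy Fine-tuning loss policy for sum/mask heads
#'   (see [finetune_loss()]).
#' @param label_trainable Update the label-tensor rows during fine-tuning.
#' @param seed Seed for head init and shuffling.
#' @return An `nv_model`: fitted weights, head parameters, configuration
#'   and training history. Score new cohorts with [predict_scores()].
#' @export
finetune <- function(checkpoint, head_kind = c("bc", "sum", "mask"),
                     train_cohort, val_cohort,
                     lr = 1e-3, batch_size = 100L,
                     max_epochs = 50L, patience = 5L,
                     policy = c("max", "per_token"),
                     label_trainable = TRUE, seed = 1L) {
  head_kind <- match.arg(head_kind)
  policy <- match.arg(policy)
  config <- checkpoint$encoder_config
  vocab <- checkpoint$vocab
  with_mask <- head_kind == "mask"
  tb <- encode_cohort(train_cohort, vocab, config$max_len, with_mask)
  vb <- encode_cohort(val_cohort, vocab, config$max_len, with_mask)
  if (length(unique(tb$labels)) < 2L)
    stop_nv("fine-tuning set must contain both classes")

  seeds <- derive_seeds(seed, 1L + max_epochs)
  weights <- checkpoint$weights
  head <- init_head_params(head_kind, config$embedding_dim, seeds[1])
  params <- list(enc = weights, head = head)
  state <- adam_init(params)
  B <- nrow(tb$token_ids)

  best <- list(params = params, auroc = -Inf, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_auroc = numeric())
  stall <- 0L
  for (ep in seq_len(max_epochs)) {
    set.seed(seeds[1L + ep])
    order_idx <- sample.int(B)
    losses <- c()
    for (start in seq(1L, B, by = batch_size)) {
      idx <- order_idx[start:min(start + batch_size - 1L, B)]
      mb <- subset_batch(tb, idx)
      g <- head_batch_grads(params$enc, params$head, config, vocab, mb,
                            head_kind, policy, label_trainable)
      if (!is.finite(g$loss))
        stop_nv("fine-tuning diverged (loss %s) at epoch %d", g$loss, ep)
      grads <- list(enc = g$grads,
                    head = if (length(params$head)) g$dhead else list())
      stepped <- adam_step(params, grads, state, lr)
      params <- stepped$params
      state <- stepped$state
      losses <- c(losses, g$loss)
    }
    val_scores <- head_scores(params$enc, params$head, config, vocab, vb,
                              head_kind)
    va <- if (length(unique(vb$labels)) < 2L) NA_real_
          else auroc(val_scores, vb$labels)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_auroc = va))
    if (!is.na(va) && va > best$auroc + 1e-9) {
      best <- list(params = params, auroc = va, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  if (is.infinite(best$auroc)) best$params <- params  # degenerate validation

  structure(list(
    kind = head_kind,
    weights = best$params$enc,
    head = best$params$head,
    encoder_config = config,
    vocab = vocab,
    policy = policy,
    history = hist,
    best_epoch = best$epoch,
    seed = seed
  ), class = "nv_model")
}

#' Score patients with a fitted model
#'
#' Dispatches on the fitted model kind (head models from [finetune()] or
#' baselines from [train_baseline()]) and returns one probability-scale
#' risk score per patient; for the token heads this is the maximum of the
#' per-target-code probabilities.
#'
#' @param model An `nv_model` or `nv_baseline`.
#' @param cohort List of patient records.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(model, cohort) {
  if (inherits(model, "nv_baseline"))
    return(predict_baseline(model, cohort))
  stopifnot(inherits(model, "nv_model"))
  batch <- encode_cohort(cohort, model$vocab, model$encoder_config$max_len,
                         model$kind == "mask")
  head_scores(model$weights, model$head, model$encoder_config, model$vocab,
              batch, model$kind)
}

#' @export
print.nv_model <- function(x, ...) {
  va <- if (nrow(x$history)) suppressWarnings(max(x$history$val_auroc, na.rm = TRUE))
        else NA_real_
  cat(sprintf("<nv_model> %s head; best val AUROC %.3f at epoch %d\n",
              x$kind, va, x$best_epoch))
  invisible(x)
}
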