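#' Baseline model configuration
#'
#' The five comparison models trained from scratch on the same tokenized
#' cohorts: logistic regression on bag-of-code counts, and GRU / BiGRU /
#' LSTM / BiLSTM sequence classifiers with their own (non-pretrained)
#' embeddings. Default learning rates follow the experimental settings:
#' 0.001 for GRU and LSTM, 1e-5 for the bidirectional variants.
#'
#' @param model_kind One of `"lr"`, `"gru"`, `"bigru"`, `"lstm"`, `"bilstm"`.
#' @param embedding_dim,hidden_dim Recurrent model widths.
#' @param learning_rate Adam learning rate; `NULL` picks the per-kind
#'   default.
#' @param batch_size Patients per step (default 100).
#' @param max_epochs,patience Early-stopping schedule (validation AUROC).
#' @param lambda Ridge penalty of the logistic-regression baseline.
#' @param seed Seed for initialization and shuffling.
#' @return A list of class `nv_baseline_config`.
#' @export
baseline_config <- function(model_kind = c("lr", "gru", "bigru", "lstm", "bilstm"),
                            embedding_dim = 32L, hidden_dim = 32L,
                            learning_rate = NULL, batch_size = 100L,
                            max_epochs = 50L, patience = 5L,
                            lambda = 0.01, seed = 1L) {
  model_kind <- match.arg(model_kind)
  if (is.null(learning_rate))
    learning_rate <- if (model_kind %in% c("bigru", "bilstm")) 1e-5 else 1e-3
  if (learning_rate <= 0) stop_nv("'learning_rate' must be positive")
  structure(list(
    model_kind = model_kind,
    embedding_dim = check_count(embedding_dim, "embedding_dim"),
    hidden_dim = check_count(hidden_dim, "hidden_dim"),
    learning_rate = as.numeric(learning_rate),
    batch_size = check_count(batch_size, "batch_size"),
    max_epochs = check_count(max_epochs, "max_epochs"),
    patience = check_count(patience, "patience"),
    lambda = as.numeric(lambda),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "nv_baseline_config")
}

#' Bag-of-code count features
#'
#' Counts of every non-special token in a tokenized batch (so counts
#' reflect the same truncated 64-code window the sequence models see).
#' Columns span the whole vocabulary; the PAD and MASK columns are always
#' zero.
#'
#' @param batch An `nv_batch` encoded without the next-visit mask.
#' @param vocab An `nv_vocabulary`.
#' @return Integer matrix `B x vocab$size`.
#' @export
featurize_bag_of_codes <- function(batch, vocab) {
  stopifnot(inherits(vocab, "nv_vocabulary"))
  B <- nrow(batch$token_ids)
  X <- matrix(0L, B, vocab$size)
  for (b in seq_len(B)) {
    ids <- batch$token_ids[b, ]
    ids <- ids[ids >= 2L]
    X[b, ] <- tabulate(ids + 1L, nbins = vocab$size)
  }
  colnames(X) <- c("[PAD]", "[MASK]", vocab$id_to_code)
  X
}

#' Train a baseline model
#'
#' Logistic regression is fitted as an L2-regularized model on
#' bag-of-code counts. The recurrent kinds embed the token sequence,
#' run the recurrent cell(s) over real positions (padding carries the
#' state through), and map the final hidden state to a logistic output;
#' they are trained with Adam and early stopping on validation AUROC.
#'
#' @param config An `nv_baseline_config`.
#' @param train_cohort,val_cohort Lists of patient records; the training
#'   set must contain both classes.
#' @param vocab An `nv_vocabulary`.
#' @param max_len Fixed sequence length (default 64).
#' @return An `nv_baseline` with a [predict_scores()] contract.
#' @export
train_baseline <- function(config, train_cohort, val_cohort, vocab,
                           max_len = 64L) {
  stopifnot(inherits(config, "nv_baseline_config"),
            inherits(vocab, "nv_vocabulary"))
  tb <- encode_cohort(train_cohort, vocab, max_len, add_next_visit_mask = FALSE)
  if (length(unique(tb$labels)) < 2L)
    stop_nv("training set must contain both classes")
  vb <- encode_cohort(val_cohort, vocab, max_len, add_next_visit_mask = FALSE)

  if (config$model_kind == "lr") {
    X <- featurize_bag_of_codes(tb, vocab)
    # few-shot fits routinely have < 8 observations per class; the glmnet
    # small-class warning is the expected regime here, not a defect
    fit <- suppressWarnings(
      glmnet::glmnet(X, factor(tb$labels, levels = c(0, 1)),
                     family = "binomial", alpha = 0,
                     lambda = config$lambda, standardize = FALSE))
    return(structure(list(kind = "lr", fit = fit, vocab = vocab,
                          max_len = as.integer(max_len), config = config),
                     class = "nv_baseline"))
  }

  kind <- if (config$model_kind %in% c("gru", "bigru")) "gru" else "lstm"
  bidir <- config$model_kind %in% c("bigru", "bilstm")
  seeds <- derive_seeds(config$seed, 1L + config$max_epochs)
  params <- init_rnn_weights(kind, vocab$size, config$embedding_dim,
                             config$hidden_dim, bidir, seeds[1])
  state <- adam_init(params)
  B <- nrow(tb$token_ids)
  best <- list(params = params, auroc = -Inf, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_auroc = numeric())
  stall <- 0L
  for (ep in seq_len(config$max_epochs)) {
    set.seed(seeds[1L + ep])
    order_idx <- sample.int(B)
    losses <- c()
    for (start in seq(1L, B, by = config$batch_size)) {
      idx <- order_idx[start:min(start + config$batch_size - 1L, B)]
      g <- rnn_batch_grads(params, kind,
                           tb$token_ids[idx, , drop = FALSE],
                           tb$attention_mask[idx, , drop = FALSE],
                           tb$labels[idx])
      if (!is.finite(g$loss))
        stop_nv("baseline training diverged at epoch %d", ep)
      stepped <- adam_step(params, g$grads, state, config$learning_rate)
      params <- stepped$params
      state <- stepped$state
      losses <- c(losses, g$loss)
    }
    vs <- rnn_scores(params, kind, vb$token_ids, vb$attention_mask)
    va <- if (length(unique(vb$labels)) < 2L) NA_real_
          else auroc(vs, vb$labels)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_auroc = va))
    if (!is.na(va) && va > best$auroc + 1e-9) {
      best <- list(params = params, auroc = va, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  if (is.infinite(best$auroc)) best$params <- params

  structure(list(kind = config$model_kind, cell = kind, params = best$params,
                 vocab = vocab, max_len = as.integer(max_len),
                 config = config, history = hist, best_epoch = best$epoch),
            class = "nv_baseline")
}

predict_baseline <- function(model, cohort) {
  batch <- encode_cohort(cohort, model$vocab, model$max_len,
                         add_next_visit_mask = FALSE)
  if (model$kind == "lr") {
    X <- featurize_bag_of_codes(batch, model$vocab)
    return(as.vector(stats::predict(model$fit, newx = X, type = "response")))
  }
  rnn_scores(model$params, model$cell, batch$token_ids, batch$attention_mask)
}

#' @export
print.nv_baseline <- function(x, ...) {
  cat(sprintf("<nv_baseline> %s\n", x$kind))
  invisible(x)
}
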