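test_that("binary-classification head is a plain logistic unit", {
  set.seed(1)
  d <- 6L
  ctxv <- rnorm(d)
  w <- rnorm(d)
  b <- rnorm(1)
  out <- bc_head(ctxv, w, b)
  expect_null(out$per_token_probs)
  expect_equal(out$patient_score, 1 / (1 + exp(-(sum(w * ctxv) + b))),
               tolerance = 1e-12)
  expect_equal(bc_head(ctxv, numeric(d), 0)$patient_score, 0.5)
  expect_equal(bc_head(ctxv, w, 1e4)$patient_score, 1)
  expect_error(bc_head(ctxv, numeric(d + 1L)), "dimension")
})

test_that("token-prediction head scores eight codes and takes the max", {
  set.seed(2)
  d <- 6L
  L8 <- matrix(rnorm(8 * d), 8, d)
  ctxv <- rnorm(d)
  out <- sum_head(ctxv, L8)
  expect_length(out$per_token_probs, 8L)
  expect_equal(as.vector(out$per_token_probs),
               1 / (1 + exp(-as.vector(L8 %*% ctxv))), tolerance = 1e-12)
  expect_equal(out$patient_score, max(out$per_token_probs))
  # zero context or orthogonal context: all probabilities 0.5
  expect_true(all(sum_head(numeric(d), L8)$per_token_probs == 0.5))
  ortho <- MASS::Null(t(L8[1:5, ]))[, 1]  # orthogonal to a 5-row tensor
  expect_equal(max(abs(sum_head(ortho, L8[1:5, ])$per_token_probs - 0.5)), 0,
               tolerance = 1e-12)
})

test_that("masked-token head equals the restriction of full-vocab scores", {
  s <- small_setup(n = 10L)
  batch <- encode_cohort(s$cohort, s$vocab, max_len = 16L,
                         add_next_visit_mask = TRUE)
  ctx <- encoder_forward(s$weights, s$enc, batch)
  out <- mask_head(ctx, label_tensor(s$weights, s$vocab))
  rows <- (seq_len(ctx$B) - 1L) * ctx$L + batch$mask_position
  full <- mlm_logits(ctx$H[rows, , drop = FALSE], s$weights$tok_emb)
  restricted <- full[, s$vocab$target_ids + 1L, drop = FALSE]
  expect_equal(unname(out$per_token_probs),
               unname(1 / (1 + exp(-restricted))), tolerance = 1e-14)
  expect_equal(out$patient_score, apply(out$per_token_probs, 1, max))
})

test_that("mask head validates its mask position", {
  s <- small_setup(n = 4L)
  L8 <- label_tensor(s$weights, s$vocab)
  nomask <- encode_cohort(s$cohort[1:4], s$vocab, max_len = 16L)
  ctx <- encoder_forward(s$weights, s$enc, nomask)
  expect_error(mask_head(ctx, L8), "mask_position")
  expect_error(mask_head(ctx, L8, mask_position = rep(1L, 4L)), "MASK")
})

test_that("permuting label rows permutes probabilities, not the score", {
  s <- small_setup(n = 6L)
  batch <- encode_cohort(s$cohort, s$vocab, max_len = 16L,
                         add_next_visit_mask = TRUE)
  ctx <- encoder_forward(s$weights, s$enc, batch)
  L8 <- label_tensor(s$weights, s$vocab)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  a <- mask_head(ctx, L8)
  b <- mask_head(ctx, L8[perm, ])
  expect_equal(b$per_token_probs, a$per_token_probs[, perm],
               tolerance = 1e-14)
  expect_equal(b$patient_score, a$patient_score, tolerance = 1e-14)
})

test_that("fine-tuning losses match their closed forms", {
  probs <- matrix(0.5, 1, 8)
  out <- nextvisit:::head_output(probs, 0.5)
  # control with all probabilities 0.5 under the per-token policy: ln 2
  expect_equal(finetune_loss(out, 0L, matrix(0L, 1, 8), "sum"), log(2),
               tolerance = 1e-12)
  # perfect prediction sits at the numerical floor
  hot <- matrix(c(1L, integer(7)), 1)
  perfect <- nextvisit:::head_output(matrix(c(1, numeric(7)), 1), 1)
  expect_lt(finetune_loss(perfect, 1L, hot, "mask"), 1e-10)
  # BC is plain binary cross-entropy on the patient score
  bco <- nextvisit:::head_output(NULL, 0.8)
  expect_equal(finetune_loss(bco, 1L, head_kind = "bc"), -log(0.8),
               tolerance = 1e-12)
  # max policy scores the patient probability against the label
  expect_equal(finetune_loss(out, 0L, matrix(0L, 1, 8), "sum", policy = "max"),
               log(2), tolerance = 1e-12)
  # inconsistent multi-hot is rejected
  expect_error(finetune_loss(out, 0L, hot, "sum"), "inconsistent")
})

test_that("fine-tuning gradients agree with finite differences", {
  s <- small_setup(n = 10L)
  for (kind in c("bc", "sum", "mask")) {
    batch <- encode_cohort(s$cohort, s$vocab, max_len = 16L,
                           add_next_visit_mask = (kind == "mask"))
    head <- nextvisit:::init_head_params(kind, s$enc$embedding_dim, 3L)
    g <- nextvisit:::head_batch_grads(s$weights, head, s$enc, s$vocab, batch,
                                      kind, "per_token", TRUE)
    lossfun <- function(w, h) {
      nextvisit:::head_batch_grads(w, h, s$enc, s$vocab, batch, kind,
                                   "per_token", TRUE)$loss
    }
    set.seed(11)
    # spot-check encoder weights across components
    checks <- list(
      list(get = function(w) w$tok_emb,
           set = function(w, v) { w$tok_emb[] <- v; w },
           grad = g$grads$tok_emb),
      list(get = function(w) w$layers[[1]]$Wv,
           set = function(w, v) { w$layers[[1]]$Wv[] <- v; w },
           grad = g$grads$layers[[1]]$Wv),
      list(get = function(w) w$layers[[2]]$W2,
           set = function(w, v) { w$layers[[2]]$W2[] <- v; w },
           grad = g$grads$layers[[2]]$W2)
    )
    for (ch in checks) {
      v <- ch$get(s$weights)
      idx <- sample(length(v), 6L)
      for (i in idx) {
        eps <- 1e-5
        wp <- ch$set(s$weights, replace(v, i, v[i] + eps))
        wm <- ch$set(s$weights, replace(v, i, v[i] - eps))
        gn <- (lossfun(wp, head) - lossfun(wm, head)) / (2 * eps)
        expect_equal(ch$grad[i], gn, tolerance = 1e-4)
      }
    }
    if (kind == "bc") {
      for (i in 1:4) {
        eps <- 1e-6
        hp <- head; hp$w[i] <- hp$w[i] + eps
        hm <- head; hm$w[i] <- hm$w[i] - eps
        gn <- (lossfun(s$weights, hp) - lossfun(s$weights, hm)) / (2 * eps)
        expect_equal(g$dhead$w[i], gn, tolerance = 1e-5)
      }
    }
  }
})

test_that("fine-tuning improves a head on a separable cohort and is seeded", {
  cohort <- generate_cohort(generator_config(n_patients = 120, vocab_size = 40,
                                             precursor_effect = 1.5, seed = 6))
  vocab <- build_vocabulary(cohort)
  enc <- encoder_config(embedding_dim = 12L, n_layers = 1L, n_heads = 2L,
                        feedforward_dim = 16L, max_len = 24L, seed = 2)
  ck <- pretrain(cohort, vocab, enc, epochs = 1, seed = 9)
  tr <- cohort[1:80]
  va <- cohort[81:120]
  m1 <- finetune(ck, "bc", tr, va, batch_size = 20L, max_epochs = 8,
                 patience = 8, seed = 5)
  m2 <- finetune(ck, "bc", tr, va, batch_size = 20L, max_epochs = 8,
                 patience = 8, seed = 5)
  expect_equal(predict_scores(m1, va), predict_scores(m2, va),
               tolerance = 1e-12)
  labels <- vapply(va, function(p) p$label, integer(1))
  expect_gt(auroc(predict_scores(m1, va), labels), 0.55)
  expect_error(finetune(ck, "bc", cohort[vapply(cohort, function(p) p$label,
                                                integer(1)) == 0][1:10], va),
               "both classes")
})
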