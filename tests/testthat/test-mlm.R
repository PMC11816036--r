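test_that("corruption limit cases behave exactly", {
  s <- small_setup(n = 10L)
  batch <- encode_cohort(s$cohort, s$vocab, max_len = 16L)
  all_mask <- corrupt_sequence(batch$token_ids, batch$attention_mask, s$vocab,
                               corruption_config(select_rate = 1, p_mask = 1,
                                                 p_random = 0, p_keep = 0))
  real <- batch$attention_mask == 1L
  expect_true(all(all_mask$corrupted_ids[real] == 1L))
  expect_true(all(all_mask$corrupted_ids[!real] == 0L))
  expect_identical(all_mask$prediction_targets[real][1:5],
                   batch$token_ids[real][1:5])

  keep <- corrupt_sequence(batch$token_ids, batch$attention_mask, s$vocab,
                           corruption_config(select_rate = 1, p_mask = 0,
                                             p_random = 0, p_keep = 1))
  expect_identical(keep$corrupted_ids, batch$token_ids)
  expect_true(all(!is.na(keep$prediction_targets[real])))
})

test_that("corruption never touches PAD and draws randoms from real codes", {
  s <- small_setup(n = 20L)
  batch <- encode_cohort(s$cohort, s$vocab, max_len = 16L)
  out <- corrupt_sequence(batch$token_ids, batch$attention_mask, s$vocab,
                          corruption_config(seed = 5))
  pad <- batch$attention_mask == 0L
  expect_true(all(is.na(out$prediction_targets[pad])))
  expect_identical(out$corrupted_ids[pad], batch$token_ids[pad])
  changed <- out$corrupted_ids != batch$token_ids
  expect_true(all(out$corrupted_ids[changed] %in%
                    c(1L, seq_len(s$vocab$n_codes) + 1L)))
  # deterministic given the seed
  out2 <- corrupt_sequence(batch$token_ids, batch$attention_mask, s$vocab,
                           corruption_config(seed = 5))
  expect_identical(out, out2)
})

test_that("corruption proportions converge to 80/10/10 among selections", {
  cfg <- generator_config(n_patients = 800, seed = 31)
  cohort <- generate_cohort(cfg)
  vocab <- build_vocabulary(cohort)
  batch <- encode_cohort(cohort, vocab, max_len = 64L, window = "full")
  out <- corrupt_sequence(batch$token_ids, batch$attention_mask, vocab,
                          corruption_config(seed = 77))
  sel <- which(!is.na(out$prediction_targets))
  n <- length(sel)
  expect_gt(n, 4000)
  frac_mask <- mean(out$corrupted_ids[sel] == 1L)
  frac_keep <- mean(out$corrupted_ids[sel] == batch$token_ids[sel])
  frac_rand <- 1 - frac_mask - frac_keep
  expect_lt(abs(frac_mask - 0.80), 3 * sqrt(0.8 * 0.2 / n))
  # a random replacement can coincide with the original; allow that slack
  expect_lt(abs(frac_rand - 0.10), 3 * sqrt(0.1 * 0.9 / n) + 0.1 / 200)
  # selection rate across real positions
  real_n <- sum(batch$attention_mask)
  expect_lt(abs(n / real_n - 0.15), 3 * sqrt(0.15 * 0.85 / real_n))
})

test_that("full-vocabulary scores are brute-force dot products", {
  set.seed(4)
  E <- matrix(rnorm(7 * 5), 7, 5)
  H <- matrix(rnorm(3 * 5), 3, 5)
  b <- rnorm(7)
  S <- mlm_logits(H, E, b)
  for (p in 1:3) for (v in 1:7)
    expect_equal(S[p, v], sum(H[p, ] * E[v, ]) + b[v], tolerance = 1e-12)
  # a contextual row equal to an embedding row wins the argmax when rows
  # are distinct directions of equal norm (zero bias)
  En <- E / sqrt(rowSums(E^2))
  S2 <- mlm_logits(En[4, , drop = FALSE], En)
  expect_identical(which.max(S2[1, ]), 4L)
  # zero context, zero bias: all scores equal
  expect_true(all(mlm_logits(matrix(0, 1, 5), E) == 0))
  expect_error(mlm_logits(matrix(0, 1, 4), E), "dimension")
})

test_that("masked-code loss only sees selected positions", {
  s <- small_setup(n = 12L)
  batch <- encode_cohort(s$cohort, s$vocab, max_len = 16L, window = "full")
  ctx <- encoder_forward(s$weights, s$enc, batch)
  tg <- matrix(NA_integer_, nrow(batch$token_ids), 16L)
  tg[1, 2] <- batch$token_ids[1, 2]
  tg[3, 1] <- batch$token_ids[3, 1]
  sel <- which(!is.na(t(tg)))
  l1 <- nextvisit:::mlm_loss(ctx$H, sel, t(tg)[sel], s$weights)$loss
  # hand-computed softmax cross-entropy over the two positions
  ce <- function(h, target_id) {
    z <- as.vector(h %*% t(s$weights$tok_emb)) + s$weights$mlm_bias
    -log(exp(z[target_id + 1]) / sum(exp(z)))
  }
  rows <- c((1 - 1) * 16 + 2, (3 - 1) * 16 + 1)
  expected <- mean(c(ce(ctx$H[rows[1], , drop = FALSE], tg[1, 2]),
                     ce(ctx$H[rows[2], , drop = FALSE], tg[3, 1])))
  expect_equal(l1, expected, tolerance = 1e-10)
})

test_that("pretraining runs, reduces held-out loss, and is reproducible", {
  cohort <- generate_cohort(generator_config(n_patients = 60, vocab_size = 40,
                                             seed = 3))
  vocab <- build_vocabulary(cohort)
  enc <- encoder_config(embedding_dim = 12L, n_layers = 1L, n_heads = 2L,
                        feedforward_dim = 16L, max_len = 24L, seed = 2)
  ck <- pretrain(cohort, vocab, enc, epochs = 2, seed = 9)
  expect_s3_class(ck, "nv_checkpoint")
  expect_lt(ck$history$holdout_loss[nrow(ck$history)],
            ck$history$holdout_loss[1])
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  back <- load_checkpoint(f)
  expect_equal(back$weights, ck$weights)
  ck2 <- pretrain(cohort, vocab, enc, epochs = 2, seed = 9)
  expect_equal(ck$weights, ck2$weights, tolerance = 1e-12)
})

test_that("weight tying: an embedding row drives input and output together", {
  s <- small_setup(n = 8L)
  batch <- encode_cohort(s$cohort[1:2], s$vocab, max_len = 16L)
  w <- s$weights
  ctx <- encoder_forward(w, s$enc, batch)
  scores <- mlm_logits(ctx$H[1, , drop = FALSE], w$tok_emb, w$mlm_bias)
  vid <- batch$token_ids[1, 1]  # a token present in the input
  w2 <- w
  w2$tok_emb[vid + 1L, ] <- w2$tok_emb[vid + 1L, ] + 0.5
  ctx2 <- encoder_forward(w2, s$enc, batch)
  scores2 <- mlm_logits(ctx2$H[1, , drop = FALSE], w2$tok_emb, w2$mlm_bias)
  # input path changed (contextual rows move) and output path changed
  expect_gt(max(abs(ctx2$H - ctx$H)), 0)
  expect_gt(abs(scores2[1, vid + 1L] - scores[1, vid + 1L]), 0)
})

test_that("corruption configuration is validated", {
  expect_error(corruption_config(p_mask = 0.9), "equal 1")
  expect_error(corruption_config(select_rate = 0), "select_rate")
})
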