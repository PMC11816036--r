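test_that("split sizes reproduce the 7:1:2 arithmetic exactly", {
  # floor/floor/remainder rule checked against the printed cohort sizes
  sizes <- function(N) {
    v <- floor(0.1 * N); t <- floor(0.2 * N); c(N - v - t, v, t)
  }
  expect_identical(sizes(31243), c(21871, 3124, 6248))
  expect_identical(sizes(3810), c(2667, 381, 762))
  expect_identical(sizes(10), c(7, 1, 2))
  # and the implementation follows it on a real cohort object
  cohort <- generate_cohort(generator_config(n_patients = 127, seed = 2))
  sp <- split_cohort(cohort, split_spec(seed = 5))
  expect_identical(lengths(sp)[["validation"]], 12L)
  expect_identical(lengths(sp)[["test"]], 25L)
  expect_identical(lengths(sp)[["train"]], 90L)
})

test_that("splits partition the cohort and are deterministic", {
  cohort <- generate_cohort(generator_config(n_patients = 85, seed = 9))
  sp <- split_cohort(cohort, split_spec(seed = 4))
  ids <- function(x) vapply(x, `[[`, character(1), "patient_id")
  all_ids <- c(ids(sp$train), ids(sp$validation), ids(sp$test))
  expect_identical(sort(all_ids), sort(ids(cohort)))
  expect_identical(anyDuplicated(all_ids), 0L)
  sp2 <- split_cohort(cohort, split_spec(seed = 4))
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_cohort(cohort, split_spec(seed = 5))))
  expect_error(split_cohort(cohort[1:9], split_spec()), "at least 10")
})

test_that("balanced sampling delivers the advertised case/control counts", {
  cohort <- generate_cohort(generator_config(n_patients = 400, seed = 14))
  sp <- split_cohort(cohort, split_spec(seed = 1))
  n_cases <- function(x) sum(vapply(x, function(p) p$label, integer(1)))
  few <- sample_fewshot(sp$train, sp$validation, 10,
                        sampling_policy("balanced_both"), seed = 3)
  expect_length(few$finetune, 10L)
  expect_identical(n_cases(few$finetune), 5L)
  expect_length(few$validation, 10L)
  expect_identical(n_cases(few$validation), 5L)
  # deterministic, and sampling without replacement
  few2 <- sample_fewshot(sp$train, sp$validation, 10,
                         sampling_policy("balanced_both"), seed = 3)
  expect_identical(few, few2)
  ids <- vapply(few$finetune, `[[`, character(1), "patient_id")
  expect_identical(anyDuplicated(ids), 0L)
  # large sizes keep the full validation split
  big <- sample_fewshot(sp$train, sp$validation, 40,
                        sampling_policy("balanced_train_full_val"), seed = 3)
  expect_identical(big$validation, sp$validation)
  expect_identical(n_cases(big$finetune), 20L)
})

test_that("the external-cohort ladder applies its size-keyed regimes", {
  cohort <- generate_cohort(generator_config(n_patients = 3000,
                                             case_fraction_target = 0.12,
                                             seed = 8))
  sp <- split_cohort(cohort, split_spec(seed = 2))
  pol <- sampling_policy("ehrshot_ladder")
  n_cases <- function(x) sum(vapply(x, function(p) p$label, integer(1)))
  # <= 30: balanced both
  r20 <- sample_fewshot(sp$train, sp$validation, 20, pol, seed = 5)
  expect_identical(n_cases(r20$finetune), 10L)
  expect_identical(n_cases(r20$validation), 10L)
  # 40-200: balanced fine-tune; validation takes all its cases + controls
  r60 <- sample_fewshot(sp$train, sp$validation, 60, pol, seed = 5)
  expect_identical(n_cases(r60$finetune), 30L)
  expect_identical(n_cases(r60$validation), n_cases(sp$validation))
  expect_length(r60$validation, 60L)
  # 300: both sets take all cases + sampled controls
  r300 <- sample_fewshot(sp$train, sp$validation, 300, pol, seed = 5)
  expect_identical(n_cases(r300$finetune), n_cases(sp$train))
  expect_length(r300$finetune, 300L)
  expect_identical(n_cases(r300$validation), n_cases(sp$validation))
  expect_length(r300$validation, 300L)
  # 400-1000: all cases + sampled controls for training, full validation
  r500 <- sample_fewshot(sp$train, sp$validation, 500, pol, seed = 5)
  expect_identical(n_cases(r500$finetune), n_cases(sp$train))
  expect_length(r500$finetune, 500L)
  expect_identical(r500$validation, sp$validation)
  expect_error(sample_fewshot(sp$train, sp$validation, 1200, pol, seed = 5),
               "ladder")
})

test_that("infeasible requests fail with a clear shortfall message", {
  few_cases <- generate_cohort(generator_config(n_patients = 60,
                                                case_fraction_target = 0.02,
                                                seed = 4))
  sp <- split_cohort(few_cases, split_spec(seed = 1))
  expect_error(sample_fewshot(sp$train, sp$validation, 40,
                              sampling_policy("balanced_both"), seed = 1),
               "cases")
  expect_error(sample_fewshot(sp$train, sp$validation, 5,
                              sampling_policy("balanced_both"), seed = 1),
               "even")
})

test_that("AUROC matches the O(n^2) pairwise oracle, ties counted half", {
  pairwise_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(33)
  for (rep in 1:5) {
    n <- 40
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auroc(s, y), pairwise_auc(s, y), tolerance = 1e-12)
  }
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rbinom(60, 1, 0.5)
  s <- runif(60)
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("learning-curve bookkeeping: grid size, determinism, aggregation", {
  cohort <- generate_cohort(generator_config(n_patients = 400, vocab_size = 40,
                                             seed = 19))
  sp <- split_cohort(cohort, split_spec(seed = 7))
  res <- run_learning_curve(sp, c("lr", "gru"), sizes = c(10L, 20L),
                            n_runs = 3L, seed = 11,
                            baseline_args = list(max_epochs = 2L,
                                                 embedding_dim = 8L,
                                                 hidden_dim = 8L))
  expect_identical(nrow(res), 12L)  # 2 models x 2 sizes x 3 runs
  expect_true(all(res$auroc >= 0 & res$auroc <= 1))
  res2 <- run_learning_curve(sp, c("lr", "gru"), sizes = c(10L, 20L),
                             n_runs = 3L, seed = 11,
                             baseline_args = list(max_epochs = 2L,
                                                  embedding_dim = 8L,
                                                  hidden_dim = 8L))
  expect_identical(res, res2)
  s <- learning_curve_summary(res)
  expect_identical(nrow(s), 4L)
  for (i in seq_len(nrow(s))) {
    cell <- res$auroc[res$model == s$model[i] & res$size == s$size[i]]
    expect_equal(s$mean_auroc[i], mean(cell), tolerance = 1e-12)
    expect_equal(s$sd_auroc[i], sd(cell), tolerance = 1e-12)
    expect_identical(s$n_runs[i], 3L)
  }
  expect_error(run_learning_curve(sp, c("bc"), sizes = 10L, n_runs = 1L),
               "checkpoint")
  expect_error(run_learning_curve(sp, c("nope"), sizes = 10L), "unknown")
  f <- withr::local_tempfile(fileext = ".csv")
  write_learning_curve(res, f)
  expect_identical(nrow(utils::read.csv(f)), 12L)
})
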