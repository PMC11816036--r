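#' Train/validation/test split specification
#'
#' The 7:1:2 patient-level split with the rounding rule that reproduces
#' the printed cohort arithmetic exactly: validation and test sizes are
#' floored, the remainder goes to training.
#'
#' @param ratios Numeric triple summing to 1 (default `c(0.7, 0.1, 0.2)`).
#' @param seed Shuffling seed.
#' @return A list of class `nv_split_spec`.
#' @export
split_spec <- function(ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9)
    stop_nv("'ratios' must be three non-negative numbers summing to 1")
  structure(list(ratios = as.numeric(ratios),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "nv_split_spec")
}

#' Split a cohort into train / validation / test
#'
#' Sizes follow the floor/floor/remainder rule:
#' `|validation| = floor(r2 * N)`, `|test| = floor(r3 * N)`, and training
#' receives the rest. Patients are shuffled once with the spec's seed, so
#' the partition is disjoint, exhaustive and deterministic. No class
#' stratification is applied.
#'
#' @param cohort List of at least 10 patient records.
#' @param spec An `nv_split_spec`.
#' @return List with elements `train`, `validation`, `test`.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 50, seed = 1))
#' lengths(split_cohort(cohort, split_spec(seed = 4)))
split_cohort <- function(cohort, spec = split_spec()) {
  stopifnot(inherits(spec, "nv_split_spec"))
  N <- length(cohort)
  if (N < 10L) stop_nv("cohort must have at least 10 patients (has %d)", N)
  n_val <- floor(spec$ratios[2] * N)
  n_test <- floor(spec$ratios[3] * N)
  n_train <- N - n_val - n_test
  set.seed(spec$seed)
  perm <- sample.int(N)
  keep_class <- function(idx) structure(cohort[idx], class = class(cohort))
  list(
    train = keep_class(perm[seq_len(n_train)]),
    validation = keep_class(perm[n_train + seq_len(n_val)]),
    test = keep_class(perm[n_train + n_val + seq_len(n_test)])
  )
}

#' Few-shot sampling policy
#'
#' How fine-tuning and validation sets of a given size are drawn:
#' `"balanced_both"` draws size/2 cases and size/2 controls for both sets
#' (the protocol for sizes up to 1000); `"balanced_train_full_val"` draws
#' a balanced fine-tuning set and uses the whole validation split (sizes
#' 2000 and above); `"ehrshot_ladder"` applies the size-keyed regimes
#' used for the small external cohort (see [sample_fewshot()]).
#'
#' @param policy_kind One of the three policy names.
#' @return A list of class `nv_sampling_policy`.
#' @export
sampling_policy <- function(policy_kind = c("balanced_both",
                                            "balanced_train_full_val",
                                            "ehrshot_ladder")) {
  structure(list(policy_kind = match.arg(policy_kind)),
            class = "nv_sampling_policy")
}

draw_cases_controls <- function(split, n_pos, n_neg, what) {
  labels <- vapply(split, function(p) as.integer(p$label), integer(1))
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) < n_pos)
    stop_nv("%s: need %d cases but only %d available", what, n_pos, length(pos))
  if (length(neg) < n_neg)
    stop_nv("%s: need %d controls but only %d available", what, n_neg,
            length(neg))
  idx <- c(if (n_pos == length(pos)) pos else sample(pos, n_pos),
           if (n_neg == length(neg)) neg else sample(neg, n_neg))
  structure(split[idx], class = class(split))
}

all_pos_sampled_neg <- function(split, size, what) {
  labels <- vapply(split, function(p) as.integer(p$label), integer(1))
  n_pos <- sum(labels == 1L)
  if (n_pos > size)
    stop_nv("%s: %d cases exceed the target size %d", what, n_pos, size)
  draw_cases_controls(split, n_pos, size - n_pos, what)
}

#' Draw few-shot fine-tuning and validation sets
#'
#' Sampling is without replacement and deterministic given `seed`.
#' Balanced policies split the size evenly between cases and controls
#' (for a size of 10: 5 cases and 5 controls). The `ehrshot_ladder`
#' policy keys its regime on `size`: sizes up to 30, balanced fine-tuning
#' and validation; 40-200, balanced fine-tuning while validation takes
#' all its cases plus sampled controls up to `size`; 300, both sets take
#' all cases plus sampled controls; 400-1000, fine-tuning takes all cases
#' plus sampled controls and validation is the full split.
#'
#' @param train_split,val_split Cohort splits from [split_cohort()].
#' @param size Total sample size requested.
#' @param policy An `nv_sampling_policy`.
#' @param seed Sampling seed.
#' @return List with elements `finetune` and `validation`.
#' @export
sample_fewshot <- function(train_split, val_split, size,
                           policy = sampling_policy("balanced_both"),
                           seed = 1L) {
  stopifnot(inherits(policy, "nv_sampling_policy"))
  size <- check_count(size, "size", min = 2L)
  set.seed(seed)
  kind <- policy$policy_kind
  half <- function() {
    if (size %% 2L != 0L)
      stop_nv("balanced sampling needs an even size (got %d)", size)
    size %/% 2L
  }
  if (kind == "balanced_both") {
    h <- half()
    list(finetune = draw_cases_controls(train_split, h, h, "fine-tuning set"),
         validation = draw_cases_controls(val_split, h, h, "validation set"))
  } else if (kind == "balanced_train_full_val") {
    h <- half()
    list(finetune = draw_cases_controls(train_split, h, h, "fine-tuning set"),
         validation = val_split)
  } else {
    if (size <= 30L) {
      h <- half()
      list(finetune = draw_cases_controls(train_split, h, h, "fine-tuning set"),
           validation = draw_cases_controls(val_split, h, h, "validation set"))
    } else if (size <= 200L) {
      h <- half()
      list(finetune = draw_cases_controls(train_split, h, h, "fine-tuning set"),
           validation = all_pos_sampled_neg(val_split, size, "validation set"))
    } else if (size == 300L) {
      list(finetune = all_pos_sampled_neg(train_split, size, "fine-tuning set"),
           validation = all_pos_sampled_neg(val_split, size, "validation set"))
    } else if (size <= 1000L) {
      list(finetune = all_pos_sampled_neg(train_split, size, "fine-tuning set"),
           validation = val_split)
    } else {
      stop_nv("size %d is outside the ladder (10-1000)", size)
    }
  }
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) computation: the probability that a random
#' case outscores a random control, with ties counted half.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels 0/1 case indicators; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_nv("'scores' and 'labels' differ in length")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_nv("AUROC needs both classes present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Run the few-shot learning-curve protocol
#'
#' For every combination of model, sample size and run: draw the
#' fine-tuning/validation sets under the sampling policy, train the model
#' (head models start from the same pretrained checkpoint in every cell;
#' baselines train from scratch), and evaluate AUROC on the complete test
#' split. All randomness is derived from `seed`, so the result table is
#' exactly reproducible.
#'
#' The default policy (`"auto"`) mirrors the study protocol: sizes up to
#' 1000 use balanced fine-tuning and validation sets; larger sizes use a
#' balanced fine-tuning set with the full validation split.
#'
#' @param splits A list with `train`, `validation`, `test` from
#'   [split_cohort()].
#' @param models Character vector among
#'   `c("bc", "sum", "mask", "lr", "gru", "bigru", "lstm", "bilstm")`.
#' @param sizes Integer sample sizes (default the desk-scale ladder
#'   `c(10, 20, 50, 100, 200, 500, 1000)`).
#' @param n_runs Runs per cell (default 3).
#' @param checkpoint Pretrained `nv_checkpoint` (required for head models).
#' @param policy `"auto"`, an `nv_sampling_policy`, or a policy name.
#' @param seed Master seed.
#' @param finetune_args,baseline_args Named lists of overrides passed to
#'   [finetune()] / [baseline_config()].
#' @param verbose Print one line per completed cell.
#' @return An `nv_learning_curve` data frame with columns
#'   `model`, `size`, `run`, `seed`, `auroc`.
#' @export
run_learning_curve <- function(splits, models, sizes = c(10L, 20L, 50L, 100L,
                                                         200L, 500L, 1000L),
                               n_runs = 3L, checkpoint = NULL,
                               policy = "auto", seed = 1L,
                               finetune_args = list(),
                               baseline_args = list(), verbose = FALSE) {
  head_kinds <- c("bc", "sum", "mask")
  base_kinds <- c("lr", "gru", "bigru", "lstm", "bilstm")
  if (!all(models %in% c(head_kinds, base_kinds)))
    stop_nv("unknown model(s): %s",
            paste(setdiff(models, c(head_kinds, base_kinds)), collapse = ", "))
  if (any(models %in% head_kinds) && is.null(checkpoint))
    stop_nv("head models need a pretrained checkpoint")
  n_runs <- check_count(n_runs, "n_runs")
  vocab <- if (!is.null(checkpoint)) checkpoint$vocab
           else build_vocabulary(c(splits$train, splits$validation, splits$test))
  max_len <- if (!is.null(checkpoint)) checkpoint$encoder_config$max_len else 64L

  grid <- expand.grid(run = seq_len(n_runs), size = as.integer(sizes),
                      model = models, stringsAsFactors = FALSE)
  cell_seeds <- derive_seeds(seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  test_batchless <- splits$test
  test_labels <- vapply(test_batchless, function(p) as.integer(p$label),
                        integer(1))

  for (i in seq_len(nrow(grid))) {
    model <- grid$model[i]; size <- grid$size[i]; run <- grid$run[i]
    cs <- cell_seeds[i]
    pol <- if (inherits(policy, "nv_sampling_policy")) policy
           else if (identical(policy, "auto"))
             sampling_policy(if (size <= 1000L) "balanced_both"
                             else "balanced_train_full_val")
           else sampling_policy(policy)
    sets <- sample_fewshot(splits$train, splits$validation, size, pol,
                           seed = cs)
    if (model %in% head_kinds) {
      fit <- do.call(finetune, c(list(
        checkpoint = checkpoint, head_kind = model,
        train_cohort = sets$finetune, val_cohort = sets$validation,
        seed = cs), finetune_args))
    } else {
      cfg <- do.call(baseline_config,
                     c(list(model_kind = model, seed = cs), baseline_args))
      fit <- train_baseline(cfg, sets$finetune, sets$validation, vocab,
                            max_len = max_len)
    }
    a <- auroc(predict_scores(fit, test_batchless), test_labels)
    rows[[i]] <- data.frame(model = model, size = size, run = run,
                            seed = cs, auroc = a)
    if (verbose)
      message(sprintf("%s size=%d run=%d auroc=%.3f", model, size, run, a))
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$model, models), out$size, out$run), ]
  rownames(out) <- NULL
  class(out) <- c("nv_learning_curve", "data.frame")
  out
}

#' Aggregate a learning-curve table
#'
#' @param result An `nv_learning_curve` (or plain data frame with columns
#'   `model`, `size`, `run`, `auroc`).
#' @return Data frame with per-(model, size) `mean_auroc`, `sd_auroc` and
#'   `n_runs`.
#' @export
learning_curve_summary <- function(result) {
  agg <- stats::aggregate(auroc ~ model + size, data = result,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(model = agg$model, size = agg$size,
                    mean_auroc = agg$auroc[, "mean"],
                    sd_auroc = agg$auroc[, "sd"],
                    n_runs = as.integer(agg$auroc[, "n"]))
  out[order(out$model, out$size), ]
}

#' Paired seed-level comparison of two models' few-shot AUROC
#'
#' Averages each model's AUROC per run seed over the given sizes and
#' bootstraps the mean paired difference (model A minus model B) over
#' runs. Used to report the directional few-shot contrast between the
#' masked-token head and the binary-classification head.
#'
#' @param result Learning-curve table containing both models.
#' @param model_a,model_b Model names to compare.
#' @param sizes Sizes to include (default: all shared sizes).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Bootstrap seed.
#' @return List with `mean_diff`, `ci` (length-2), `n_pairs`.
#' @export
paired_auroc_diff <- function(result, model_a, model_b, sizes = NULL,
                              n_boot = 2000L, conf = 0.95, seed = 1L) {
  r <- result[result$model %in% c(model_a, model_b), ]
  if (!is.null(sizes)) r <- r[r$size %in% sizes, ]
  wide <- merge(
    stats::aggregate(auroc ~ run, data = r[r$model == model_a, ], FUN = mean),
    stats::aggregate(auroc ~ run, data = r[r$model == model_b, ], FUN = mean),
    by = "run", suffixes = c("_a", "_b"))
  d <- wide$auroc_a - wide$auroc_b
  if (length(d) < 2L) stop_nv("need at least two paired runs")
  set.seed(seed)
  boots <- replicate(n_boot, mean(sample(d, replace = TRUE)))
  alpha <- (1 - conf) / 2
  list(mean_diff = mean(d),
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n_pairs = length(d))
}

#' Write a learning-curve table to CSV
#'
#' @param result An `nv_learning_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_learning_curve <- function(result, path) {
  utils::write.csv(result, path, row.names = FALSE)
  invisible(path)
}

#' Plot learning curves (base graphics)
#'
#' Mean test AUROC against fine-tuning sample size (log axis), one line
#' per model.
#'
#' @param result An `nv_learning_curve`.
#' @param ... Passed to [graphics::matplot()].
#' @return The summary table, invisibly.
#' @export
plot_learning_curve <- function(result, ...) {
  s <- learning_curve_summary(result)
  models <- unique(s$model)
  sizes <- sort(unique(s$size))
  M <- sapply(models, function(m)
    s$mean_auroc[s$model == m][match(sizes, s$size[s$model == m])])
  graphics::matplot(sizes, M, type = "b", log = "x", pch = 19, lty = 1,
                    xlab = "fine-tuning sample size", ylab = "mean test AUROC",
                    ...)
  graphics::legend("bottomright", legend = models, col = seq_along(models),
                   pch = 19, lty = 1, bty = "n")
  invisible(s)
}
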