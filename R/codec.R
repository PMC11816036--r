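#' Build a token vocabulary from a cohort
#'
#' Assigns contiguous integer ids to every code occurring in the cohort,
#' plus any explicitly registered target codes. Ids are deterministic:
#' `PAD = 0`, `MASK = 1`, and codes start at 2 in lexicographic order of
#' the code string (C locale).
#'
#' @param cohort List of patient records.
#' @param target_codes Character vector of target onset codes (default the
#'   eight pancreatic-cancer diagnosis codes of [paca_target_codes()]).
#'   Registered even if absent from the cohort.
#' @return An `nv_vocabulary`: `code_to_id` (named integer vector),
#'   `target_codes`, `target_ids`, special ids `pad_id`/`mask_id`, and
#'   `size` (total token count including the two specials).
#' @export
build_vocabulary <- function(cohort, target_codes = paca_target_codes()) {
  if (length(target_codes) == 0L) stop_nv("'target_codes' must be non-empty")
  if (anyDuplicated(target_codes))
    stop_nv("duplicate target codes: %s",
            paste(unique(target_codes[duplicated(target_codes)]), collapse = ", "))
  seen <- unique(unlist(lapply(cohort, function(p) unlist(p$visits)),
                        use.names = FALSE))
  codes <- sort(unique(c(seen, target_codes)), method = "radix")
  code_to_id <- stats::setNames(seq_along(codes) + 1L, codes)  # ids from 2
  target_codes <- sort(target_codes, method = "radix")
  structure(list(
    code_to_id = code_to_id,
    id_to_code = codes,             # code with id k is id_to_code[k - 1]
    target_codes = target_codes,
    target_ids = unname(code_to_id[target_codes]),
    pad_id = 0L, mask_id = 1L,
    n_codes = length(codes),
    size = length(codes) + 2L
  ), class = "nv_vocabulary")
}

#' @export
print.nv_vocabulary <- function(x, ...) {
  cat(sprintf("<nv_vocabulary> %d codes + 2 specials (PAD=0, MASK=1), %d target codes\n",
              x$n_codes, length(x$target_ids)))
  invisible(x)
}

#' Map token ids back to code strings
#'
#' Inverse of the vocabulary mapping; PAD and MASK become `"[PAD]"` and
#' `"[MASK]"`.
#'
#' @param token_ids Integer vector of token ids.
#' @param vocab An `nv_vocabulary`.
#' @return Character vector of the same length.
#' @export
decode_tokens <- function(token_ids, vocab) {
  stopifnot(inherits(vocab, "nv_vocabulary"))
  out <- character(length(token_ids))
  out[token_ids == vocab$pad_id] <- "[PAD]"
  out[token_ids == vocab$mask_id] <- "[MASK]"
  ord <- token_ids >= 2L
  out[ord] <- vocab$id_to_code[token_ids[ord] - 1L]
  out
}

#' Tokenize one patient record
#'
#' Flattens the censored input window (visits up to `index_visit`) into a
#' code sequence with per-code source-visit ordinals, keeps the most
#' recent `max_len` codes (reverse-chronological retention; one slot is
#' reserved when the next-visit mask is requested), presents the retained
#' codes in chronological order, optionally appends one `[MASK]` token at
#' the next-visit position (visit ordinal = last retained ordinal + 1),
#' and pads to `max_len`.
#'
#' @param record A patient record.
#' @param vocab An `nv_vocabulary`.
#' @param max_len Fixed sequence length (default 64).
#' @param add_next_visit_mask Append the next-visit `[MASK]` token.
#' @param window `"censored"` (the default) uses visits up to
#'   `index_visit` and raises an error if a target code leaks into the
#'   input — the contract for prediction-task inputs. `"full"` uses the
#'   complete trajectory including any onset visit; this is the
#'   pretraining view, the stand-in for general-population trajectories
#'   in which future disease codes are observed.
#' @return An `nv_tokenized` list: `token_ids`, `visit_ids`,
#'   `attention_mask` (each length `max_len`), `mask_position` (or `NULL`),
#'   `label`, and `target_multi_hot`.
#' @export
encode_patient <- function(record, vocab, max_len = 64L,
                           add_next_visit_mask = FALSE,
                           window = c("censored", "full")) {
  stopifnot(inherits(vocab, "nv_vocabulary"))
  max_len <- check_count(max_len, "max_len", min = 2L)
  add_next_visit_mask <- check_flag(add_next_visit_mask, "add_next_visit_mask")
  window <- match.arg(window)

  input_visits <- if (window == "censored")
    record$visits[seq_len(record$index_visit)] else record$visits
  codes <- unlist(input_visits, use.names = FALSE)
  if (length(codes) == 0L)
    stop_nv("patient %s has no codes in the input window", record$patient_id)
  if (window == "censored" && any(codes %in% vocab$target_codes))
    stop_nv("patient %s: target code in the censored input window",
            record$patient_id)
  unknown <- setdiff(unique(codes), names(vocab$code_to_id))
  if (length(unknown))
    stop_nv("unknown code(s): %s", paste(unknown, collapse = ", "))

  ordinals <- rep.int(seq_along(input_visits),
                      lengths(input_visits))
  budget <- max_len - as.integer(add_next_visit_mask)
  if (length(codes) > budget) {
    keep <- (length(codes) - budget + 1L):length(codes)
    codes <- codes[keep]
    ordinals <- ordinals[keep]
  }
  ids <- unname(vocab$code_to_id[codes])
  mask_position <- NULL
  if (add_next_visit_mask) {
    ids <- c(ids, vocab$mask_id)
    ordinals <- c(ordinals, ordinals[length(ordinals)] + 1L)
    mask_position <- length(ids)
  }
  n <- length(ids)
  pad <- max_len - n
  structure(list(
    token_ids = c(ids, rep.int(vocab$pad_id, pad)),
    visit_ids = c(as.integer(ordinals), rep.int(0L, pad)),
    attention_mask = c(rep.int(1L, n), rep.int(0L, pad)),
    mask_position = mask_position,
    label = as.integer(record$label),
    target_multi_hot = extract_target_multi_hot(record, vocab)
  ), class = "nv_tokenized")
}

#' Multi-hot target vector of a patient record
#'
#' Position `k` is 1 iff the record's onset code is the `k`-th target code
#' (lexicographic order); all-zero for controls. Under the generator's
#' single-onset convention at most one entry is 1.
#'
#' @param record A patient record.
#' @param vocab An `nv_vocabulary`.
#' @return Integer 0/1 vector, one entry per target code.
#' @export
extract_target_multi_hot <- function(record, vocab) {
  stopifnot(inherits(vocab, "nv_vocabulary"))
  out <- integer(length(vocab$target_codes))
  if (as.integer(record$label) == 1L) {
    k <- match(record$onset_target_code, vocab$target_codes)
    if (is.na(k))
      stop_nv("patient %s: onset code %s is not a target code",
              record$patient_id, record$onset_target_code %||% "<missing>")
    out[k] <- 1L
  }
  out
}

#' Tokenize a whole cohort into batch matrices
#'
#' Stacks [encode_patient()] output into the integer matrices the encoder
#' and baselines consume.
#'
#' @param cohort List of patient records.
#' @param vocab An `nv_vocabulary`.
#' @param max_len Fixed sequence length.
#' @param add_next_visit_mask Append the next-visit `[MASK]` token.
#' @param window Input window, as in [encode_patient()].
#' @return An `nv_batch`: matrices `token_ids`, `visit_ids`,
#'   `attention_mask` (`B x max_len`), `mask_position` (integer vector,
#'   `NA` when no mask), `labels`, `target_multi_hot` (`B x K`) and
#'   `patient_ids`.
#' @export
encode_cohort <- function(cohort, vocab, max_len = 64L,
                          add_next_visit_mask = FALSE,
                          window = c("censored", "full")) {
  if (length(cohort) == 0L) stop_nv("cohort is empty")
  window <- match.arg(window)
  toks <- lapply(cohort, encode_patient, vocab = vocab, max_len = max_len,
                 add_next_visit_mask = add_next_visit_mask, window = window)
  B <- length(toks)
  structure(list(
    token_ids = do.call(rbind, lapply(toks, `[[`, "token_ids")),
    visit_ids = do.call(rbind, lapply(toks, `[[`, "visit_ids")),
    attention_mask = do.call(rbind, lapply(toks, `[[`, "attention_mask")),
    mask_position = vapply(toks, function(t) t$mask_position %||% NA_integer_,
                           integer(1)),
    labels = vapply(toks, `[[`, integer(1), "label"),
    target_multi_hot = do.call(rbind, lapply(toks, `[[`, "target_multi_hot")),
    patient_ids = vapply(cohort, `[[`, character(1), "patient_id"),
    max_len = as.integer(max_len),
    has_mask = add_next_visit_mask
  ), class = "nv_batch")
}

subset_batch <- function(batch, idx) {
  structure(list(
    token_ids = batch$token_ids[idx, , drop = FALSE],
    visit_ids = batch$visit_ids[idx, , drop = FALSE],
    attention_mask = batch$attention_mask[idx, , drop = FALSE],
    mask_position = batch$mask_position[idx],
    labels = batch$labels[idx],
    target_multi_hot = batch$target_multi_hot[idx, , drop = FALSE],
    patient_ids = batch$patient_ids[idx],
    max_len = batch$max_len,
    has_mask = batch$has_mask
  ), class = "nv_batch")
}

#' Write a vocabulary to JSON
#'
#' Serializes the code-to-id map and the target code list; [read_vocabulary()]
#' restores an identical object.
#'
#' @param vocab An `nv_vocabulary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "nv_vocabulary"))
  jsonlite::write_json(
    list(codes = vocab$id_to_code, target_codes = vocab$target_codes),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' Read a vocabulary written by [write_vocabulary()]
#'
#' @param path JSON file path.
#' @return An `nv_vocabulary`.
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  codes <- as.character(x$codes)
  code_to_id <- stats::setNames(seq_along(codes) + 1L, codes)
  target_codes <- sort(as.character(x$target_codes), method = "radix")
  structure(list(
    code_to_id = code_to_id,
    id_to_code = codes,
    target_codes = target_codes,
    target_ids = unname(code_to_id[target_codes]),
    pad_id = 0L, mask_id = 1L,
    n_codes = length(codes),
    size = length(codes) + 2L
  ), class = "nv_vocabulary")
}
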