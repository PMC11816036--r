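#' Write a cohort as JSON Lines
#'
#' One patient per line with keys `patient_id`, `visits` (list of lists of
#' code strings), `label` (0/1) and `onset_target_code` (string or null),
#' UTF-8 and newline-delimited. `index_visit` is not serialized: under the
#' onset-visit convention it is the last visit for controls and the
#' second-to-last for cases, so [read_cohort()] reconstructs it.
#'
#' @param cohort List of patient records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  lines <- vapply(cohort, function(p) {
    jsonlite::toJSON(list(
      patient_id = p$patient_id,
      visits = lapply(p$visits, I),   # keep single-code visits as arrays
      label = as.integer(p$label),
      onset_target_code = p$onset_target_code %||% NA_character_
    ), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSONL cohort
#'
#' Validates each line against the cohort schema and reports the first
#' offending line on failure.
#'
#' @param path JSONL file path.
#' @return An `nv_cohort` list of patient records.
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_nv("cohort file '%s' is empty", path)
  cohort <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec))
      stop_nv("line %d: not valid JSON", i)
    for (key in c("patient_id", "visits", "label"))
      if (is.null(rec[[key]]))
        stop_nv("line %d: missing required key '%s'", i, key)
    if (!is.list(rec$visits) || length(rec$visits) == 0L)
      stop_nv("line %d: 'visits' must be a non-empty list", i)
    visits <- lapply(rec$visits, function(v) {
      v <- unlist(v, use.names = FALSE)
      if (length(v) == 0L || !is.character(v))
        stop_nv("line %d: every visit must be a non-empty list of strings", i)
      v
    })
    label <- rec$label
    if (!is.numeric(label) || !(label %in% c(0, 1)))
      stop_nv("line %d: 'label' must be 0 or 1", i)
    label <- as.integer(label)
    onset <- rec$onset_target_code
    if (!is.null(onset) && !is.character(onset))
      stop_nv("line %d: 'onset_target_code' must be a string or null", i)
    if (label == 1L && is.null(onset))
      stop_nv("line %d: cases must carry 'onset_target_code'", i)
    if (label == 1L && length(visits) < 2L)
      stop_nv("line %d: a case needs at least one input visit before its onset visit", i)
    if (label == 0L && !is.null(onset))
      stop_nv("line %d: controls must not carry 'onset_target_code'", i)
    cohort[[i]] <- list(
      patient_id = as.character(rec$patient_id),
      visits = visits,
      label = label,
      onset_target_code = onset,
      index_visit = length(visits) - label
    )
  }
  structure(cohort, class = "nv_cohort")
}
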