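#' Configuration for the synthetic coded-visit cohort generator
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' generator emulates the structure the prediction task needs: patients are
#' ordered sequences of visits, each visit an ordered set of clinical codes
#' drawn from a fixed vocabulary; a reserved set of target diagnosis codes
#' defines case status; a subset of ordinary "precursor" codes carries the
#' predictive signal; and all input data are censored strictly before onset.
#'
#' The risk model is logistic in the patient's precursor-code exposure:
#' a patient whose generated visits contain `c` occurrences of precursor
#' codes has onset log-odds `intercept + precursor_effect * c`. The
#' intercept is calibrated internally (by root finding on the cohort's
#' realized precursor counts) so that the expected case fraction equals
#' `case_fraction_target`; set `case_fraction_target = NULL` to skip
#' calibration and use `qlogis(base_risk)` directly.
#'
#' @param vocab_size Number of ordinary (non-target) codes. Ordinary codes
#'   are named `D###`/`M###`/`P###`, mimicking the diagnosis, medication
#'   and procedure mix of coded trajectories.
#' @param n_target_codes Number of target onset codes (at most 8; the codes
#'   are taken from [paca_target_codes()]).
#' @param n_precursor_codes Number of ordinary codes that carry signal.
#' @param n_patients Cohort size.
#' @param visits_per_patient_range Integer pair (min, max) of input visits.
#' @param codes_per_visit_range Integer pair (min, max) codes per visit.
#' @param base_risk Baseline onset probability; used as the uncalibrated
#'   intercept when `case_fraction_target` is `NULL`.
#' @param precursor_effect Log-odds increment per precursor-code occurrence.
#' @param case_fraction_target Desired expected case fraction, or `NULL`.
#' @param precursor_propensity_beta Beta(a, b) parameters of the latent
#'   per-patient precursor share. Each patient draws a propensity
#'   `pi ~ Beta(a, b)` and every code is a uniformly chosen precursor code
#'   with probability `pi`, otherwise a uniformly chosen non-precursor
#'   code. This emulates the comorbidity clustering of real coded
#'   trajectories: precursor codes co-occur within high-burden patients
#'   rather than appearing independently. The default `c(1, 9)` gives a
#'   mean share of 0.1 with substantial patient-level spread.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A validated list of class `nv_generator_config`.
#' @export
generator_config <- function(vocab_size = 200L,
                             n_target_codes = 8L,
                             n_precursor_codes = 20L,
                             n_patients = 1000L,
                             visits_per_patient_range = c(4L, 12L),
                             codes_per_visit_range = c(2L, 8L),
                             base_risk = 0.1,
                             precursor_effect = 0.5,
                             case_fraction_target = 0.4,
                             precursor_propensity_beta = c(1, 9),
                             seed = 1L) {
  cfg <- list(
    vocab_size = check_count(vocab_size, "vocab_size"),
    n_target_codes = check_count(n_target_codes, "n_target_codes"),
    n_precursor_codes = check_count(n_precursor_codes, "n_precursor_codes"),
    n_patients = check_count(n_patients, "n_patients"),
    visits_per_patient_range =
      check_range_pair(visits_per_patient_range, "visits_per_patient_range"),
    codes_per_visit_range =
      check_range_pair(codes_per_visit_range, "codes_per_visit_range"),
    base_risk = check_prob(base_risk, "base_risk"),
    precursor_effect = as.numeric(precursor_effect),
    case_fraction_target =
      if (is.null(case_fraction_target)) NULL
      else check_prob(case_fraction_target, "case_fraction_target"),
    precursor_propensity_beta = as.numeric(precursor_propensity_beta),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$precursor_propensity_beta) != 2L ||
      any(cfg$precursor_propensity_beta <= 0))
    stop_nv("'precursor_propensity_beta' must be two positive Beta parameters")
  if (cfg$precursor_effect < 0)
    stop_nv("'precursor_effect' must be non-negative")
  if (cfg$n_target_codes > length(paca_target_codes()))
    stop_nv("'n_target_codes' must be at most %d", length(paca_target_codes()))
  if (cfg$n_precursor_codes > cfg$vocab_size)
    stop_nv("'n_precursor_codes' cannot exceed 'vocab_size'")
  structure(cfg, class = "nv_generator_config")
}

#' Names of the ordinary codes implied by a generator configuration
#'
#' Ordinary code `k` is named by cycling the `D`/`M`/`P` prefixes, so the
#' vocabulary mixes diagnosis-, medication- and procedure-like codes.
#'
#' @param vocab_size Number of ordinary codes.
#' @return Character vector of length `vocab_size`.
#' @export
ordinary_codes <- function(vocab_size) {
  vocab_size <- check_count(vocab_size, "vocab_size")
  idx <- seq_len(vocab_size) - 1L
  sprintf("%s%03d", c("D", "M", "P")[idx %% 3L + 1L], idx %/% 3L + 1L)
}

#' Precursor codes of a generator configuration
#'
#' The first `n_precursor_codes` ordinary codes; occurrences of these codes
#' raise a patient's onset log-odds by `precursor_effect` each.
#'
#' @param config An `nv_generator_config`.
#' @return Character vector of precursor code names.
#' @export
precursor_codes <- function(config) {
  stopifnot(inherits(config, "nv_generator_config"))
  ordinary_codes(config$vocab_size)[seq_len(config$n_precursor_codes)]
}

#' Generate a synthetic coded-visit cohort
#'
#' Draws `n_patients` patient records. Each patient receives a random number
#' of visits, each visit a random number of codes sampled uniformly from the
#' ordinary vocabulary. The onset label is Bernoulli with log-odds linear in
#' the patient's precursor-code count (see [generator_config()]). Cases get
#' exactly one uniformly chosen target code, appended as a dedicated final
#' onset visit that is excluded from model input (`index_visit` points at
#' the preceding visit), so inputs are always censored before onset.
#'
#' @param config An `nv_generator_config`.
#' @return A list of patient records (class `nv_cohort`). Each record has
#'   fields `patient_id`, `visits` (list of character vectors), `label`
#'   (0/1), `onset_target_code` (string or `NULL`), and `index_visit`
#'   (index of the last visit available as model input).
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 20, seed = 7))
#' cohort_summary(cohort)[c("n_patients", "n_cases", "n_controls")]
generate_cohort <- function(config) {
  stopifnot(inherits(config, "nv_generator_config"))
  set.seed(config$seed)

  codes <- ordinary_codes(config$vocab_size)
  precursors <- precursor_codes(config)
  targets <- paca_target_codes()[seq_len(config$n_target_codes)]
  n <- config$n_patients
  vr <- config$visits_per_patient_range
  cr <- config$codes_per_visit_range

  # draw visit structure for every patient first, so the intercept can be
  # calibrated against the realized precursor counts
  others <- setdiff(codes, precursors)
  ab <- config$precursor_propensity_beta
  visits <- vector("list", n)
  prec_count <- integer(n)
  for (i in seq_len(n)) {
    n_vis <- sample.int(vr[2] - vr[1] + 1L, 1L) + vr[1] - 1L
    sizes <- sample.int(cr[2] - cr[1] + 1L, n_vis, replace = TRUE) + cr[1] - 1L
    total <- sum(sizes)
    # latent comorbidity burden: high-propensity patients accumulate
    # precursor codes together, low-propensity patients rarely see them
    prop <- stats::rbeta(1L, ab[1], ab[2])
    is_prec <- stats::runif(total) < prop
    if (length(others) == 0L) is_prec[] <- TRUE
    drawn <- character(total)
    if (any(is_prec))
      drawn[is_prec] <- sample(precursors, sum(is_prec), replace = TRUE)
    if (any(!is_prec))
      drawn[!is_prec] <- sample(others, sum(!is_prec), replace = TRUE)
    visits[[i]] <- split(drawn, rep.int(seq_len(n_vis), sizes))
    names(visits[[i]]) <- NULL
    prec_count[i] <- sum(is_prec)
  }

  intercept <- calibrate_intercept(prec_count, config)
  risk <- logistic(intercept + config$precursor_effect * prec_count)
  label <- as.integer(stats::runif(n) < risk)
  onset_idx <- sample.int(length(targets), n, replace = TRUE)

  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    vis <- visits[[i]]
    onset <- NULL
    if (label[i] == 1L) {
      onset <- targets[onset_idx[i]]
      vis <- c(vis, list(onset))
    }
    cohort[[i]] <- list(
      patient_id = sprintf("P%06d", i),
      visits = vis,
      label = label[i],
      onset_target_code = onset,
      index_visit = length(visits[[i]])
    )
  }
  structure(cohort, class = "nv_cohort")
}

# solve for the log-odds intercept making the expected case fraction match
# the target, given the cohort's realized precursor counts
calibrate_intercept <- function(prec_count, config) {
  if (is.null(config$case_fraction_target))
    return(stats::qlogis(min(max(config$base_risk, 1e-12), 1 - 1e-12)))
  target <- config$case_fraction_target
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(b)
    mean(logistic(b + config$precursor_effect * prec_count)) - target
  stats::uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
}

#' Summarize a cohort
#'
#' @param cohort A list of patient records.
#' @return A list with `n_patients`, `n_cases`, `n_controls`, and
#'   `code_freq`, a named integer vector counting every code occurrence
#'   across all visits (onset visits included).
#' @export
cohort_summary <- function(cohort) {
  if (length(cohort) == 0L) stop_nv("cohort is empty")
  labels <- vapply(cohort, function(p) as.integer(p$label), integer(1))
  all_codes <- unlist(lapply(cohort, function(p) unlist(p$visits)),
                      use.names = FALSE)
  freq <- table(all_codes)
  list(
    n_patients = length(cohort),
    n_cases = sum(labels == 1L),
    n_controls = sum(labels == 0L),
    code_freq = stats::setNames(as.integer(freq), names(freq))
  )
}

#' @export
print.nv_cohort <- function(x, ...) {
  s <- cohort_summary(x)
  cat(sprintf("<nv_cohort> %d patients (%d cases, %d controls), %d distinct codes\n",
              s$n_patients, s$n_cases, s$n_controls, length(s$code_freq)))
  invisible(x)
}
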