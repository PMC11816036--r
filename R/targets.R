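#' Target diagnosis codes for pancreatic-cancer onset
#'
#' The eight ICD-10 codes whose future occurrence defines case status:
#' malignant neoplasm of head (C25.0), body (C25.1), tail (C25.2),
#' pancreatic duct (C25.3), endocrine pancreas (C25.4), other parts
#' (C25.7), overlapping sites (C25.8), and pancreas unspecified (C25.9).
#' Note that C25.5 and C25.6 are not assigned in ICD-10, so the set has
#' eight members.
#'
#' @return Character vector of length 8, lexicographically sorted.
#' @export
#' @examples
#' paca_target_codes()
paca_target_codes <- function() {
  c("C25.0", "C25.1", "C25.2", "C25.3", "C25.4", "C25.7", "C25.8", "C25.9")
}
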