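#' Combine GI status and BRCA1/2 mutation status into an HRD call
#'
#' A tumor is HRD-positive when it carries a pathogenic BRCA1/2 mutation
#' and/or its genomic-instability status is positive. A BRCA1/2 mutation
#' therefore always yields a positive call, even when the GI assay is
#' negative or inconclusive; HRD is inconclusive only when the GI result is
#' inconclusive and no mutation is present. Vectorized.
#'
#' @param gi_status `"positive"`, `"negative"` or `"inconclusive"`.
#' @param brca_mutated `"yes"` or `"no"` (logical also accepted).
#' @return `"positive"`, `"negative"` or `"inconclusive"`, same length as
#'   the inputs.
#' @examples
#' call_hrd("negative", "yes")       # "positive"
#' call_hrd("inconclusive", "no")    # "inconclusive"
#' @export
call_hrd <- function(gi_status, brca_mutated) {
  if (is.logical(brca_mutated))
    brca_mutated <- ifelse(brca_mutated, "yes", "no")
  gi_status <- tolower(gi_status)
  brca_mutated <- tolower(brca_mutated)
  if (!all(gi_status %in% c("positive", "negative", "inconclusive")))
    stop("gi_status must be positive/negative/inconclusive")
  if (!all(brca_mutated %in% c("yes", "no")))
    stop("brca_mutated must be yes/no")
  n <- max(length(gi_status), length(brca_mutated))
  gi_status <- rep_len(gi_status, n)
  brca_mutated <- rep_len(brca_mutated, n)
  out <- ifelse(brca_mutated == "yes" | gi_status == "positive", "positive",
                ifelse(gi_status == "inconclusive", "inconclusive",
                       "negative"))
  out
}

#' HRD calls for a score table
#'
#' Joins a GI-score table (as from [score_profiles()]) with per-sample
#' BRCA1/2 mutation flags and applies [call_hrd()].
#'
#' @param scores Data frame with columns `sample` and `gi_status`.
#' @param brca Data frame with columns `sample` and `brca_mutated`
#'   (`"yes"`/`"no"`); samples absent from it are treated as `"no"`.
#' @return `scores` with added columns `brca_mutated` and `hrd_status`.
#' @export
call_hrd_table <- function(scores, brca) {
  stopifnot(all(c("sample", "gi_status") %in% names(scores)),
            all(c("sample", "brca_mutated") %in% names(brca)))
  idx <- match(scores$sample, brca$sample)
  mut <- ifelse(is.na(idx), "no", tolower(brca$brca_mutated[idx]))
  scores$brca_mutated <- mut
  scores$hrd_status <- call_hrd(scores$gi_status, mut)
  scores
}
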