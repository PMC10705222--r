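# Per-sample multi-assay call tables: one row per tumor with the HRD / GI /
# BRCA1/2 calls of each assay. "missing" (printed "-") is kept distinct from
# "negative"; a trailing "*" on a call marks the sample as excluded from the
# AmoyDx analyses for low tumor cell content (<30%) and sets
# low_tcc_excluded rather than deleting the row, so exclusion stays an
# explicit, auditable pipeline step.

.call_columns <- c(myriad_hrd = "Myriad_HRD", amoy_hrd = "Amoy_HRD",
                   myriad_gi = "Myriad_GI", amoy_gi = "Amoy_GI",
                   oncoscan_gi = "OncoScan_GI", myriad_brca = "Myriad_BRCA",
                   amoy_brca = "Amoy_BRCA")

.call_levels <- list(
  myriad_hrd = c("positive", "negative", "inconclusive"),
  amoy_hrd = c("positive", "negative", "missing"),
  myriad_gi = c("positive", "negative", "inconclusive"),
  amoy_gi = c("positive", "negative", "missing"),
  oncoscan_gi = c("positive", "negative", "missing"),
  myriad_brca = c("yes", "no"),
  amoy_brca = c("yes", "no")
)

.normalize_call <- function(x) {
  x <- trimws(tolower(x))
  x[x == "-"] <- "missing"
  x
}

#' Read a per-sample multi-assay call table
#'
#' Reads a CSV with header `ID, Myriad_HRD, Amoy_HRD, Myriad_GI, Amoy_GI,
#' OncoScan_GI, Myriad_BRCA, Amoy_BRCA`. Tokens (`Positive`, `Negative`,
#' `Inconclusive`, `Yes`, `No`, `-`) are case-insensitive; `-` is normalized
#' to `"missing"`; a trailing `*` on any call sets `low_tcc_excluded` for
#' that sample (low tumor cell content).
#'
#' @param path CSV path.
#' @return A data frame with columns `sample_id`, `myriad_hrd`, `amoy_hrd`,
#'   `myriad_gi`, `amoy_gi`, `oncoscan_gi`, `myriad_brca`, `amoy_brca`
#'   (character, normalized) and logical `low_tcc_excluded`.
#' @export
read_call_table <- function(path) {
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(.call_columns, names(raw))
  if (length(missing) > 0)
    stop("call table lacks column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(sample_id = raw$ID, stringsAsFactors = FALSE)
  low_tcc <- rep(FALSE, nrow(raw))
  for (col in names(.call_columns)) {
    vals <- raw[[.call_columns[[col]]]]
    starred <- grepl("\\*\\s*$", vals)
    low_tcc <- low_tcc | starred
    vals <- .normalize_call(sub("\\*\\s*$", "", vals))
    bad <- which(!vals %in% .call_levels[[col]])
    if (length(bad) > 0)
      stop("unknown token '", raw[[.call_columns[[col]]]][bad[1]],
           "' at row ", bad[1], ", column ", .call_columns[[col]])
    out[[col]] <- vals
  }
  out$low_tcc_excluded <- low_tcc
  out
}

#' The packaged 50-sample three-assay call table
#'
#' Loads the transcription of the study's published per-sample call table:
#' 50 ovarian tumors with the reference assay's HRD status, GI status and
#' BRCA1/2 mutation flag alongside the two alternative platforms' calls
#' (AmoyDx HRD/GI/BRCA, OncoScan GI). Four samples carry the low-TCC
#' exclusion flag; seven lack an OncoScan result; the reference GI call is
#' inconclusive for four samples (two of which also have inconclusive HRD
#' status). The source table's footnote mentions one further sample without
#' a GI score that is not printed as inconclusive; the transcription follows
#' the printed table verbatim.
#'
#' @return See [read_call_table()].
#' @examples
#' calls <- assay_call_fixture()
#' nrow(calls)                         # 50
#' sum(calls$low_tcc_excluded)         # 4
#' @export
assay_call_fixture <- function() {
  read_call_table(system.file("extdata", "three_assay_calls.csv",
                              package = "giscar", mustWork = TRUE))
}
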