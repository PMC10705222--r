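#' Run the end-to-end scoring and concordance pipeline
#'
#' Thin orchestration over the module functions, with no hidden state:
#' (1) read/score segment profiles with the chosen engine (when `segments`
#' is given); (2) attach BRCA1/2 flags and derive HRD calls (when `brca`
#' is given); (3) run the requested assay-concordance comparisons on a
#' call table (when `calls` is given), logging the sample count remaining
#' after each exclusion step so the analysis n's are auditable. All outputs
#' are plain TSV plus a human-readable summary; repeated runs on the same
#' inputs are byte-identical.
#'
#' @param output_dir Directory for report files (created if needed).
#' @param segments Path to a SEG-like file, or a list of `ascn_profile`
#'   objects, or `NULL` to skip scoring.
#' @param calls Path to a call-table CSV, or a call-table data frame, or
#'   `NULL` to skip concordance.
#' @param engine `"scar"` or `"gs"`.
#' @param genome Genome build name/path or a `genome_build`.
#' @param config Engine configuration ([scar_config()] or [gs_config()]);
#'   defaults to the engine's defaults.
#' @param brca Optional data frame (`sample`, `brca_mutated`) for HRD
#'   calling of scored profiles.
#' @param comparisons List of `c(test_assay, metric)` pairs to run on the
#'   call table.
#' @return Invisibly, a list with `scores`, `hrd_calls`, `concordance`
#'   (named list of `confusion_summary`), and `files` written.
#' @export
run_pipeline <- function(output_dir,
                         segments = NULL, calls = NULL,
                         engine = c("scar", "gs"), genome = "hg19",
                         config = NULL, brca = NULL,
                         comparisons = list(c("amoy", "gi_status"),
                                            c("amoy", "hrd_status"),
                                            c("oncoscan", "gi_status"))) {
  engine <- match.arg(engine)
  if (!inherits(genome, "genome_build")) genome <- load_genome(genome)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  summary_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    message(line)
    summary_lines <<- c(summary_lines, line)
  }

  scores <- NULL
  hrd_calls <- NULL
  if (!is.null(segments)) {
    profiles <- if (is.character(segments)) {
      p <- tryCatch(read_segments(segments, genome = genome),
                    error = function(e)
                      stop("stage read_segments: ", conditionMessage(e)))
      if (length(p) == 0) stop("stage read_segments: no profiles in file")
      p
    } else segments
    note("scoring %d profile(s) with the %s engine", length(profiles),
         engine)
    scores <- if (engine == "scar")
      score_profiles(profiles, genome,
                     if (is.null(config)) scar_config() else config)
    else
      gs_score_profiles(profiles, genome,
                        if (is.null(config)) gs_config() else config)
    f <- file.path(output_dir, paste0("scores_", engine, ".tsv"))
    utils::write.table(scores, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
    if (!is.null(brca)) {
      hrd_calls <- call_hrd_table(scores, brca)
      f <- file.path(output_dir, "hrd_calls.tsv")
      utils::write.table(hrd_calls, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
    }
  }

  concordance <- list()
  if (!is.null(calls)) {
    tab <- if (is.character(calls)) {
      tryCatch(read_call_table(calls), error = function(e)
        stop("stage read_call_table: ", conditionMessage(e)))
    } else calls
    note("call table: %d sample(s)", nrow(tab))
    for (cmp in comparisons) {
      key <- paste(cmp[1], cmp[2], sep = "_")
      filtered <- apply_exclusions(tab, cmp[1], cmp[2])
      note("%s: %d sample(s) after exclusions", key, nrow(filtered))
      cols <- .assay_cols(cmp[1], cmp[2])
      cs <- confusion_summary(filtered[[cols$ref]], filtered[[cols$test]])
      concordance[[key]] <- cs
      note("%s: n=%d tp=%d fp=%d fn=%d tn=%d OPA=%.1f%%",
           key, cs$n, cs$tp, cs$fp, cs$fn, cs$tn, cs$opa)
      df <- data.frame(comparison = key, n = cs$n, tp = cs$tp, fp = cs$fp,
                       fn = cs$fn, tn = cs$tn, opa = cs$opa,
                       sensitivity = cs$sensitivity,
                       specificity = cs$specificity, ppv = cs$ppv,
                       npv = cs$npv, fpr = cs$fpr, fnr = cs$fnr)
      f <- file.path(output_dir, paste0("concordance_", key, ".tsv"))
      utils::write.table(df, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
    }
  }

  f <- file.path(output_dir, "summary.txt")
  writeLines(summary_lines, f)
  files <- c(files, f)
  invisible(list(scores = scores, hrd_calls = hrd_calls,
                 concordance = concordance, files = files))
}
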