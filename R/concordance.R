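# Assay-concordance statistics against the reference assay: cohort
# exclusion rules, 2x2 confusion matrices with exact binomial confidence
# intervals, and Pearson correlation for continuous scores.

.assay_cols <- function(test_assay, metric) {
  test_assay <- match.arg(test_assay, c("amoy", "oncoscan"))
  metric <- match.arg(metric, c("gi_status", "hrd_status", "brca_status"))
  ref <- switch(metric, gi_status = "myriad_gi", hrd_status = "myriad_hrd",
                brca_status = "myriad_brca")
  test <- switch(metric,
                 gi_status = paste0(test_assay, "_gi"),
                 hrd_status = if (test_assay == "amoy") "amoy_hrd"
                   else stop("HRD status is not available for the OncoScan comparison"),
                 brca_status = if (test_assay == "amoy") "amoy_brca"
                   else stop("BRCA status is not available for the OncoScan comparison"))
  list(ref = ref, test = test)
}

#' Apply the cohort exclusion rules for one assay comparison
#'
#' Removes, in order: (a) samples flagged `low_tcc_excluded` when the test
#' assay is AmoyDx (the low tumor-cell-content exclusion applies to that
#' platform only; OncoScan comparisons retain those samples); (b) samples
#' whose reference value for the chosen metric is inconclusive; (c) samples
#' whose test value is missing. Set semantics: the result does not depend
#' on rule order.
#'
#' @param calls Call table as from [read_call_table()].
#' @param test_assay `"amoy"` or `"oncoscan"`.
#' @param metric `"gi_status"`, `"hrd_status"` or `"brca_status"`.
#' @return The filtered call table.
#' @examples
#' nrow(apply_exclusions(assay_call_fixture(), "amoy", "gi_status"))   # 42
#' @export
apply_exclusions <- function(calls, test_assay, metric) {
  cols <- .assay_cols(test_assay, metric)
  keep <- rep(TRUE, nrow(calls))
  if (test_assay == "amoy") keep <- keep & !calls$low_tcc_excluded
  keep <- keep & calls[[cols$ref]] != "inconclusive"
  keep <- keep & calls[[cols$test]] != "missing"
  out <- calls[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no samples left after exclusions for ", test_assay, " / ", metric)
  rownames(out) <- NULL
  out
}

.pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

.exact_ci <- function(x, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  100 * as.numeric(stats::binom.test(x, n)$conf.int)
}

#' 2x2 confusion summary of a test assay against the reference
#'
#' Cross-tabulates test-positive/negative against reference-positive/
#' negative and derives overall percent agreement (OPA), sensitivity,
#' specificity, PPV, NPV, false-positive and false-negative rates, all as
#' percentages with the reference assay defining truth. 95% confidence
#' intervals for OPA, sensitivity and specificity are exact
#' (Clopper-Pearson) binomial intervals. FPR and FNR use the reference
#' assay's negatives and positives as denominators. Zero-denominator
#' metrics are reported as `NA` (undefined), never as 0.
#'
#' @param ref Character vector of reference calls
#'   (`"positive"`/`"negative"`, or `"yes"`/`"no"` for mutation status).
#' @param test Character vector of test calls, same length and coding.
#' @return An object of class `confusion_summary`: counts `tp`, `fp`,
#'   `fn`, `tn`, `n`, percentages `opa`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `fpr`, `fnr`, and `ci` (a 3 x 2 matrix of 95% bounds
#'   for opa/sensitivity/specificity).
#' @export
confusion_summary <- function(ref, test) {
  stopifnot(length(ref) == length(test))
  pos <- c("positive", "yes")
  neg <- c("negative", "no")
  ref <- tolower(ref); test <- tolower(test)
  if (!all(ref %in% c(pos, neg)) || !all(test %in% c(pos, neg)))
    stop("confusion_summary expects binary positive/negative (or yes/no) calls; ",
         "apply exclusions first")
  rp <- ref %in% pos; tp_ <- test %in% pos
  tp <- sum(tp_ & rp); fp <- sum(tp_ & !rp)
  fn <- sum(!tp_ & rp); tn <- sum(!tp_ & !rp)
  n <- tp + fp + fn + tn
  ci <- rbind(opa = .exact_ci(tp + tn, n),
              sensitivity = .exact_ci(tp, tp + fn),
              specificity = .exact_ci(tn, tn + fp))
  colnames(ci) <- c("low", "high")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
                 opa = .pct(tp + tn, n),
                 sensitivity = .pct(tp, tp + fn),
                 specificity = .pct(tn, tn + fp),
                 ppv = .pct(tp, tp + fp),
                 npv = .pct(tn, tn + fn),
                 fpr = .pct(fp, fp + tn),
                 fnr = .pct(fn, tp + fn),
                 ci = ci),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("n = %d   [tp %d  fp %d | fn %d  tn %d]\n",
              x$n, x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) ifelse(is.na(v), "undef", sprintf("%.1f%%", v))
  cat(sprintf("OPA %s (%.1f-%.1f)  Se %s (%.1f-%.1f)  Sp %s (%.1f-%.1f)\n",
              fmt(x$opa), x$ci["opa", 1], x$ci["opa", 2],
              fmt(x$sensitivity), x$ci["sensitivity", 1],
              x$ci["sensitivity", 2],
              fmt(x$specificity), x$ci["specificity", 1],
              x$ci["specificity", 2]))
  cat(sprintf("PPV %s  NPV %s  FPR %s  FNR %s\n",
              fmt(x$ppv), fmt(x$npv), fmt(x$fpr), fmt(x$fnr)))
  invisible(x)
}

#' Concordance of one assay comparison from a call table
#'
#' Applies [apply_exclusions()] for the chosen comparison, then computes
#' the [confusion_summary()] of the test assay against the reference.
#'
#' @inheritParams apply_exclusions
#' @return A `confusion_summary`.
#' @examples
#' assay_concordance(assay_call_fixture(), "amoy", "gi_status")
#' @export
assay_concordance <- function(calls, test_assay, metric) {
  cols <- .assay_cols(test_assay, metric)
  filtered <- apply_exclusions(calls, test_assay, metric)
  confusion_summary(filtered[[cols$ref]], filtered[[cols$test]])
}

#' Pearson correlation between two score vectors
#'
#' Standard product-moment correlation with explicit degenerate-input
#' handling: requires at least three paired finite values; a zero-variance
#' vector yields `NA` with a warning rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("scores must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
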