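# ROC analysis for continuous GI scores against a binary reference label,
# and Youden-index cut-off selection (empirical and binormal).

.binary_labels <- function(labels) {
  if (is.character(labels)) labels <- tolower(labels) %in% c("positive", "yes", "1", "true")
  if (is.factor(labels)) labels <- as.character(labels) %in% c("positive", "yes", "1", "TRUE")
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be binary")
  if (length(unique(labels)) < 2)
    stop("both classes must be present in labels")
  labels
}

#' Empirical ROC curve and AUC with DeLong confidence interval
#'
#' Empirical AUC (trapezoidal, equal to the Mann-Whitney rank statistic
#' with ties counted 1/2), with a 95% DeLong confidence interval and the
#' full curve at all distinct thresholds. Computed with \pkg{pROC}.
#'
#' @param scores Numeric scores; higher means more test-positive.
#' @param labels Binary reference labels (logical, 0/1, or
#'   `"positive"`/`"negative"`).
#' @return A list of class `roc_result`: `auc`, `auc_ci_low`,
#'   `auc_ci_high`, and `curve`, a data frame with `threshold`,
#'   `sensitivity`, `specificity`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- .binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  r <- pROC::roc(response = factor(labels, levels = c(FALSE, TRUE)),
                 predictor = scores, direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 auc_ci_low = ci[1], auc_ci_high = ci[3],
                 curve = data.frame(threshold = r$thresholds,
                                    sensitivity = r$sensitivities,
                                    specificity = r$specificities)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d curve points\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, nrow(x$curve)))
  invisible(x)
}

#' Youden-index cut-offs, empirical and binormal
#'
#' The empirical cut-off is the observed score maximizing
#' `J = sensitivity + specificity - 1`, with test-positive defined as
#' `score >= cutoff`; ties are broken toward the lowest such score. The
#' binormal cut-off fits a normal distribution to the scores of each class
#' (moment estimates of mean and SD) and maximizes J on a fine grid
#' between the two class means; it is `NA` (with the empirical cut-off
#' still returned) when either class has fewer than two observations or
#' zero variance.
#'
#' @inheritParams roc_auc
#' @param grid_n Number of grid points for the binormal search.
#' @return List with `empirical`, `j_empirical`, `binormal`.
#' @export
youden_cutoffs <- function(scores, labels, grid_n = 10001) {
  labels <- .binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- scores[labels]; neg <- scores[!labels]
  thresholds <- sort(unique(scores))
  j <- vapply(thresholds, function(t)
    mean(pos >= t) + mean(neg < t) - 1, numeric(1))
  best <- which(j == max(j))[1]   # ties -> lowest threshold
  empirical <- thresholds[best]
  binormal <- NA_real_
  if (length(pos) >= 2 && length(neg) >= 2 &&
      stats::sd(pos) > 0 && stats::sd(neg) > 0) {
    m1 <- mean(pos); s1 <- stats::sd(pos)
    m0 <- mean(neg); s0 <- stats::sd(neg)
    grid <- seq(min(m0, m1), max(m0, m1), length.out = grid_n)
    jb <- (1 - stats::pnorm(grid, m1, s1)) + stats::pnorm(grid, m0, s0) - 1
    binormal <- grid[which.max(jb)]
  } else {
    warning("degenerate class variance: binormal cut-off unavailable")
  }
  list(empirical = empirical, j_empirical = j[best], binormal = binormal)
}
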