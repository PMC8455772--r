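# Evaluation suite: localization error summaries in centimeters and
# classification metrics with 95% confidence intervals.

#' Summarize absolute localization errors
#'
#' @param errors_cm Non-negative numeric vector of per-exam errors (cm).
#' @return An `error_summary`: `mean`, `median`, `q25`, `q75`
#'   (linear-interpolation quantiles, `type = 7`) and `n`.
#' @export
error_summary <- function(errors_cm) {
  errors_cm <- as.numeric(errors_cm)
  if (length(errors_cm) < 1) {
    ettc_error("error_summary needs at least one value", "ettc_input_error")
  }
  if (any(!is.finite(errors_cm)) || any(errors_cm < 0)) {
    ettc_error("errors must be finite and non-negative", "ettc_input_error")
  }
  q <- quantile(errors_cm, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(mean = mean(errors_cm), median = q[2],
                 q25 = q[1], q75 = q[3], n = length(errors_cm)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("n=%d  mean %.3f  median %.3f  IQR [%.3f, %.3f] cm\n",
              x$n, x$mean, x$median, x$q25, x$q75))
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return `c(lo, hi)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' Area under the ROC curve (rank statistic)
#'
#' Equals the probability that a random positive outscores a random
#' negative, with ties counted one half (Mann-Whitney form).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels, both classes present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    ettc_error("AUROC undefined with a single class", "ettc_input_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics with 95% confidence intervals
#'
#' Accuracy, sensitivity, specificity, PPV and NPV from the confusion
#' counts with Wilson score intervals; AUROC with a seeded percentile
#' bootstrap interval (stratified resampling of exams).
#'
#' @param decisions Binary 0/1 predicted classes.
#' @param labels Binary 0/1 ground truth.
#' @param scores Continuous scores for the AUROC (default: `decisions`).
#' @param conf Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples for the AUROC CI (default 2000).
#' @param boot_seed Seed for the bootstrap (default 1).
#' @return A `classification_report`: each metric as
#'   `list(value, ci_lo, ci_hi)` plus the confusion counts.
#' @export
classification_report <- function(decisions, labels, scores = decisions,
                                  conf = 0.95, n_boot = 2000, boot_seed = 1) {
  decisions <- as.integer(decisions); labels <- as.integer(labels)
  stopifnot(length(decisions) == length(labels),
            length(scores) == length(labels),
            all(decisions %in% c(0L, 1L)), all(labels %in% c(0L, 1L)))
  tp <- sum(decisions == 1 & labels == 1)
  fn <- sum(decisions == 0 & labels == 1)
  tn <- sum(decisions == 0 & labels == 0)
  fp <- sum(decisions == 1 & labels == 0)
  n <- length(labels)
  met <- function(x, d) {
    ci <- if (d > 0) wilson_ci(x, d, conf) else c(NA_real_, NA_real_)
    list(value = if (d > 0) x / d else NA_real_, ci_lo = ci[1], ci_hi = ci[2])
  }
  auc_val <- auroc(scores, labels)
  idx1 <- which(labels == 1L); idx0 <- which(labels == 0L)
  boot <- withr_seed(boot_seed, {
    vapply(seq_len(n_boot), function(i) {
      s1 <- sample(idx1, length(idx1), replace = TRUE)
      s0 <- sample(idx0, length(idx0), replace = TRUE)
      ii <- c(s1, s0)
      auroc(scores[ii], labels[ii])
    }, numeric(1))
  })
  aci <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(list(
    accuracy = met(tp + tn, n),
    sensitivity = met(tp, tp + fn),
    specificity = met(tn, tn + fp),
    ppv = met(tp, tp + fp),
    npv = met(tn, tn + fn),
    auroc = list(value = auc_val, ci_lo = aci[1], ci_hi = aci[2]),
    counts = list(tp = tp, fp = fp, tn = tn, fn = fn, n = n)),
    class = "classification_report")
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @export
print.classification_report <- function(x, ...) {
  cat(format_classification_report(x), sep = "\n")
  invisible(x)
}

#' Agreement between predicted and reference distances
#'
#' Summarizes `|predicted - reference|`; pairs with a missing reference are
#' excluded and counted.
#'
#' @param predicted_cm,reference_cm Paired numeric vectors (cm); `NA`
#'   allowed in `reference_cm`.
#' @return An `error_summary` with attribute `n_missing`.
#' @export
distance_agreement <- function(predicted_cm, reference_cm) {
  if (length(predicted_cm) != length(reference_cm)) {
    ettc_error("predicted and reference vectors differ in length",
               "ettc_input_error")
  }
  keep <- !is.na(reference_cm) & !is.na(predicted_cm)
  s <- error_summary(abs(predicted_cm[keep] - reference_cm[keep]))
  attr(s, "n_missing") <- sum(!keep)
  s
}

#' Format an evaluation report as aligned plain text
#'
#' @param x A `classification_report`.
#' @return Character vector of lines (one per metric) mirroring the
#'   statistic / value / CI row structure of a clinical metrics table.
#' @export
format_classification_report <- function(x) {
  rows <- c(accuracy = "Accuracy", sensitivity = "Sensitivity",
            specificity = "Specificity", ppv = "Positive predictive value",
            npv = "Negative predictive value", auroc = "AUROC")
  vapply(names(rows), function(k) {
    m <- x[[k]]
    sprintf("%-26s %6.2f%%  (%.2f to %.2f%%)", rows[[k]],
            100 * m$value, 100 * m$ci_lo, 100 * m$ci_hi)
  }, character(1))
}

#' Serialize evaluation results to JSON
#'
#' @param summaries Named list of `error_summary` objects.
#' @param report Optional `classification_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(summaries, report = NULL, path) {
  out <- list(localization = lapply(summaries, unclass))
  if (!is.null(report)) out$classification <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
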