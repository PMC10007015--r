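#' Confusion matrix for case/control classification
#'
#' "Case" is the positive class: TP = predicted case and reference case,
#' FP = predicted case and reference control, and so on.
#'
#' @param predicted,reference Label sets (see [label_set()]) over identical
#'   report id sets.
#' @return Object of class `aaa_confusion` with integer fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_matrix <- function(predicted, reference) {
  miss_p <- setdiff(names(reference), names(predicted))
  miss_r <- setdiff(names(predicted), names(reference))
  if (length(miss_p) || length(miss_r)) {
    stop("label sets cover different reports; missing from predicted: ",
         paste(miss_p, collapse = ", "), "; missing from reference: ",
         paste(miss_r, collapse = ", "))
  }
  p <- predicted[names(reference)]
  r <- reference
  aaa_confusion(tp = sum(p == "case" & r == "case"),
                fp = sum(p == "case" & r == "control"),
                tn = sum(p == "control" & r == "control"),
                fn = sum(p == "control" & r == "case"))
}

#' Build a confusion matrix from counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Object of class `aaa_confusion`.
#' @export
#' @examples
#' aaa_confusion(tp = 59, fp = 1, tn = 57, fn = 3)
aaa_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "aaa_confusion")
}

#' @export
print.aaa_confusion <- function(x, ...) {
  cat("<aaa_confusion>  TP:", x$tp, " FN:", x$fn, " FP:", x$fp,
      " TN:", x$tn, " total:", x$tp + x$fp + x$tn + x$fn, "\n")
  invisible(x)
}

# display rounding: half-up at `digits` decimals (round() is half-even)
round_half_up <- function(x, digits = 2) {
  ifelse(is.na(x), NA_real_, floor(x * 10^digits + 0.5) / 10^digits)
}

#' Diagnostic performance metrics
#'
#' Sensitivity TP/(TP+FN), positive predictive value TP/(TP+FP), specificity
#' TN/(TN+FP), accuracy (TP+TN)/total, and the F1 score
#' 2\*((PPV\*sensitivity)/(PPV+sensitivity)). F1 is computed from the
#' unrounded PPV and sensitivity; full precision is retained internally and
#' rounding (half-up, 2 decimals by default) is applied for display only.
#' A metric whose denominator is zero is undefined and reported as `NA`.
#'
#' @param cm An `aaa_confusion` (from [confusion_matrix()] or
#'   [aaa_confusion()]).
#' @param digits Decimal places used when printing.
#' @return Object of class `aaa_metrics`: `sensitivity`, `ppv`,
#'   `specificity`, `f1`, `accuracy` (numeric or `NA` when undefined), plus
#'   the source counts.
#' @export
#' @examples
#' compute_metrics(aaa_confusion(tp = 59, fp = 1, tn = 57, fn = 3))
compute_metrics <- function(cm, digits = 2) {
  stopifnot(inherits(cm, "aaa_confusion"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  stopifnot(total >= 1)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(cm$tp, cm$tp + cm$fn)
  ppv <- div(cm$tp, cm$tp + cm$fp)
  spec <- div(cm$tn, cm$tn + cm$fp)
  acc <- div(cm$tp + cm$tn, total)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (ppv + sens) > 0) {
    2 * ((ppv * sens) / (ppv + sens))
  } else NA_real_
  structure(list(sensitivity = sens, ppv = ppv, specificity = spec,
                 f1 = f1, accuracy = acc, counts = cm, digits = digits),
            class = "aaa_metrics")
}

#' @export
print.aaa_metrics <- function(x, ...) {
  fmt <- function(v) {
    if (is.na(v)) "undefined"
    else formatC(round_half_up(v, x$digits), format = "f", digits = x$digits)
  }
  cat("Performance metrics (n = ",
      x$counts$tp + x$counts$fp + x$counts$tn + x$counts$fn, ")\n", sep = "")
  cat("  Sensitivity ", fmt(x$sensitivity), "\n",
      "  PPV         ", fmt(x$ppv), "\n",
      "  Specificity ", fmt(x$specificity), "\n",
      "  F1 score    ", fmt(x$f1), "\n",
      "  Accuracy    ", fmt(x$accuracy), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.aaa_metrics <- function(x, ...) {
  data.frame(metric = c("sensitivity", "ppv", "specificity", "f1", "accuracy"),
             value = c(x$sensitivity, x$ppv, x$specificity, x$f1, x$accuracy),
             rounded = round_half_up(
               c(x$sensitivity, x$ppv, x$specificity, x$f1, x$accuracy),
               x$digits),
             stringsAsFactors = FALSE)
}

#' Cohen's kappa between two label sets
#'
#' Chance-corrected agreement: kappa = (p_o - p_e)/(1 - p_e) with expected
#' agreement p_e from the marginal products. When both raters assign a single
#' identical class to every report (p_e = 1, p_o = 1), kappa is defined as
#' 1.0 by convention.
#'
#' @param labels_a,labels_b Label sets over identical id sets, at least 2
#'   reports.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (!setequal(names(labels_a), names(labels_b))) {
    stop("label sets cover different reports")
  }
  n <- length(labels_a)
  stopifnot(n >= 2)
  b <- labels_b[names(labels_a)]
  po <- mean(labels_a == b)
  pe <- mean(labels_a == "case") * mean(b == "case") +
    mean(labels_a == "control") * mean(b == "control")
  if (pe == 1) return(if (po == 1) 1.0 else 0.0)
  (po - pe) / (1 - pe)
}

#' List the misclassified reports with their mention evidence
#'
#' For every false positive and false negative, reports the sentences that
#' contain concept mentions (with assertion status), or notes the absence of
#' any mention — the raw material of an error analysis.
#'
#' @param predicted,reference Label sets over identical id sets.
#' @param reports List of [radiology_report()] objects covering those ids.
#' @param config An [aaa_config()].
#' @return Data frame with columns `report_id`, `error_type` (`"FP"`/`"FN"`),
#'   `evidence` (semicolon-joined `assertion: sentence` strings, or
#'   `"no mentions"`).
#' @export
error_listing <- function(predicted, reference, reports,
                          config = aaa_config()) {
  cm <- confusion_matrix(predicted, reference)  # validates key sets
  ids <- names(reference)
  type <- ifelse(predicted[ids] == "case" & reference == "control", "FP",
                 ifelse(predicted[ids] == "control" & reference == "case",
                        "FN", NA_character_))
  bad <- ids[!is.na(type)]
  by_id <- stats::setNames(reports,
                           vapply(reports, `[[`, character(1), "report_id"))
  rows <- lapply(bad, function(id) {
    ann <- annotate_report(by_id[[id]], config)
    ev <- if (nrow(ann$mentions)) {
      paste(paste0(ann$mentions$assertion, ": ", ann$mentions$sentence),
            collapse = " ; ")
    } else "no mentions"
    data.frame(report_id = id, error_type = type[ids == id][1], evidence = ev,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(report_id = character(0), error_type = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
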