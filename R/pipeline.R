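#' Batch-process a corpus file
#'
#' Reads a JSONL corpus, classifies every report, writes one JSON prediction
#' line per report (`report_id`, `label`, `n_affirmed`, evidence sentences)
#' and, when requested, a TSV label file. If the corpus carries gold labels,
#' performance metrics against them are computed and returned.
#'
#' @param input Path to a JSONL corpus (see [read_reports()]).
#' @param output Optional path for JSONL predictions.
#' @param labels_out Optional path for a TSV label file.
#' @param config An [aaa_config()].
#' @return Invisibly, a list with `predictions` (data frame), `labels`
#'   (label set) and `metrics` (an `aaa_metrics`, or `NULL` without gold
#'   labels).
#' @export
run_batch <- function(input, output = NULL, labels_out = NULL,
                      config = aaa_config()) {
  reports <- read_reports(input, "jsonl")
  labels <- character(0)
  lines <- character(0)
  rows <- vector("list", length(reports))
  for (i in seq_along(reports)) {
    dl <- classify_report(reports[[i]], config)
    rows[[i]] <- data.frame(report_id = dl$report_id, label = dl$label,
                            n_mentions = nrow(dl$mentions),
                            n_affirmed = sum(dl$mentions$assertion == "affirmed"),
                            gold_label = reports[[i]]$gold_label,
                            stringsAsFactors = FALSE)
    lines[i] <- .prediction_json(dl)
  }
  predictions <- if (length(rows)) do.call(rbind, rows) else
    process_corpus(list(), config)
  if (!is.null(output)) writeLines(lines, output, useBytes = TRUE)
  pred_labels <- label_set(predictions$report_id, predictions$label)
  if (!is.null(labels_out)) write_labels(pred_labels, labels_out)
  metrics <- NULL
  gold <- gold_labels(reports)
  if (length(gold) && setequal(names(gold), names(pred_labels))) {
    metrics <- compute_metrics(confusion_matrix(pred_labels, gold))
  }
  invisible(list(predictions = predictions, labels = pred_labels,
                 metrics = metrics))
}

.prediction_json <- function(dl) {
  jsonlite::toJSON(list(
    report_id = dl$report_id, label = dl$label,
    n_affirmed = nrow(dl$evidence),
    evidence = unique(dl$evidence$sentence)), auto_unbox = TRUE)
}

#' Stream-process reports line by line
#'
#' Reads one JSONL report per line from a connection, classifies it, and
#' writes one prediction line per report in input order, flushing after every
#' document so downstream consumers see each verdict immediately. A malformed
#' line produces an error record (JSON with `error` and `line` fields) on the
#' output stream; processing continues.
#'
#' @param input Input connection or file path (default standard input).
#' @param output Output connection (default standard output).
#' @param config An [aaa_config()].
#' @return Invisibly, the number of successfully processed reports.
#' @export
run_stream <- function(input = "stdin", output = stdout(),
                       config = aaa_config()) {
  con <- if (is.character(input)) {
    cc <- file(input, open = "r", encoding = "UTF-8"); on.exit(close(cc)); cc
  } else input
  n_ok <- 0L
  line_no <- 0L
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (!length(ln)) break
    line_no <- line_no + 1L
    if (!nzchar(trimws(ln))) next
    rec <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$report_id) || is.null(rec$text)) {
      writeLines(as.character(jsonlite::toJSON(
        list(error = "malformed report record", line = line_no),
        auto_unbox = TRUE)), output)
      flush(output)
      next
    }
    r <- radiology_report(as.character(rec$report_id),
                          as.character(rec$text))
    dl <- classify_report(r, config)
    writeLines(as.character(.prediction_json(dl)), output, useBytes = TRUE)
    flush(output)
    n_ok <- n_ok + 1L
  }
  invisible(n_ok)
}
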