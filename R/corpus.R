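#' Construct a radiology report object
#'
#' The basic document unit of the pipeline: an identifier, the full report
#' text, and optional metadata. Sections are not parsed at construction time;
#' [split_sections()] fills them in from the raw text.
#'
#' @param report_id Opaque report identifier (scalar character).
#' @param text Full raw report text. Preserved byte-for-byte by all readers
#'   and writers.
#' @param exam_type Free-text exam type, e.g. `"US abdomen complete"`.
#' @param patient_id Optional patient identifier (used by
#'   [aggregate_patient()]).
#' @param gold_label Optional reference label, `"case"` or `"control"`.
#' @param sections Optional pre-parsed section table as returned by
#'   [split_sections()].
#' @return An object of class `radiology_report`.
#' @export
#' @examples
#' r <- radiology_report("r1", "FINDINGS:\nThe aorta is normal in caliber.")
#' print(r)
radiology_report <- function(report_id, text, exam_type = NA_character_,
                             patient_id = NA_character_,
                             gold_label = NA_character_, sections = NULL) {
  stopifnot(is.character(report_id), length(report_id) == 1L, nzchar(report_id),
            is.character(text), length(text) == 1L)
  if (!is.na(gold_label) && !gold_label %in% c("case", "control")) {
    stop("gold_label must be 'case', 'control' or NA, got: ", gold_label)
  }
  structure(
    list(report_id = report_id, patient_id = patient_id,
         exam_type = exam_type, text = text, sections = sections,
         gold_label = gold_label),
    class = "radiology_report"
  )
}

#' @export
print.radiology_report <- function(x, ...) {
  cat("<radiology_report> id:", x$report_id)
  if (!is.na(x$exam_type)) cat("  exam:", x$exam_type)
  if (!is.na(x$gold_label)) cat("  gold:", x$gold_label)
  cat("  (", nchar(x$text), " chars)\n", sep = "")
  invisible(x)
}

#' Read a corpus of radiology reports
#'
#' Two on-disk formats are supported: JSON-lines (one report object per line,
#' fields `report_id`, `text`, optional `patient_id`, `exam_type`, `label`)
#' and a plain-text directory (one `.txt` file per report, file name =
#' report id). Raw text is preserved exactly; no section parsing happens here.
#'
#' @param path File (jsonl) or directory (plaintext_dir) to read.
#' @param format `"jsonl"` or `"plaintext_dir"`.
#' @return A list of [radiology_report] objects.
#' @export
read_reports <- function(path, format = c("jsonl", "plaintext_dir")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    reports <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e) NULL)
      if (is.null(rec) || is.null(rec$report_id) || is.null(rec$text)) {
        stop("malformed jsonl record at line ", i, " of ", path)
      }
      reports[[i]] <- radiology_report(
        report_id = as.character(rec$report_id),
        text = as.character(rec$text),
        exam_type = if (is.null(rec$exam_type)) NA_character_ else as.character(rec$exam_type),
        patient_id = if (is.null(rec$patient_id)) NA_character_ else as.character(rec$patient_id),
        gold_label = if (is.null(rec$label)) NA_character_ else as.character(rec$label)
      )
    }
  } else {
    if (!dir.exists(path)) stop("no such directory: ", path)
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    reports <- lapply(files, function(f) {
      radiology_report(
        report_id = sub("\\.txt$", "", basename(f)),
        text = paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                     collapse = "\n")
      )
    })
  }
  ids <- vapply(reports, `[[`, character(1), "report_id")
  if (anyDuplicated(ids)) {
    stop("duplicate report_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  reports
}

#' Write a corpus of radiology reports as JSON-lines
#'
#' @param reports List of [radiology_report] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  lines <- vapply(reports, function(r) {
    rec <- list(report_id = r$report_id, text = r$text)
    if (!is.na(r$patient_id)) rec$patient_id <- r$patient_id
    if (!is.na(r$exam_type))  rec$exam_type  <- r$exam_type
    if (!is.na(r$gold_label)) rec$label      <- r$gold_label
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a label set
#'
#' A label set maps report ids to `"case"`/`"control"` verdicts; it is the
#' common currency between the classifier, reference annotations and the
#' evaluation suite. Represented as a named character vector.
#'
#' @param ids Character vector of report ids (must be unique).
#' @param labels Character vector of labels, each `"case"` or `"control"`.
#' @return Named character vector, names = ids.
#' @export
label_set <- function(ids, labels) {
  stopifnot(length(ids) == length(labels))
  if (anyDuplicated(ids)) {
    stop("duplicate report_id in label set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad)) stop("invalid label(s): ", paste(bad, collapse = ", "))
  stats::setNames(as.character(labels), as.character(ids))
}

#' Write a label set as a two-column TSV
#'
#' Rows are `report_id<TAB>label`, sorted by report id, no header.
#'
#' @param labels Label set (see [label_set()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  labels <- label_set(names(labels), unname(labels))
  ord <- order(names(labels))
  writeLines(paste(names(labels)[ord], unname(labels)[ord], sep = "\t"), path)
  invisible(path)
}

#' Read a label set from a two-column TSV
#'
#' @param path File written by [write_labels()] (or any headerless
#'   `report_id<TAB>label` file).
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(label_set(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed label line ", bad[1], " in ", path)
  label_set(vapply(parts, `[[`, character(1), 1L),
            vapply(parts, `[[`, character(1), 2L))
}

#' Extract the gold labels carried by a corpus
#'
#' @param reports List of [radiology_report] objects.
#' @return Label set for the reports that carry a gold label.
#' @export
gold_labels <- function(reports) {
  ids <- vapply(reports, `[[`, character(1), "report_id")
  lab <- vapply(reports, `[[`, character(1), "gold_label")
  keep <- !is.na(lab)
  label_set(ids[keep], lab[keep])
}
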