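#' Pipeline configuration
#'
#' Bundles the section policy, lexicon and trigger set together with the
#' classification options. `strict_diameter` is OFF by default: the base
#' algorithm classifies on asserted mentions alone and does not interpret the
#' reported diameter; strict mode is an opt-in extension that additionally
#' requires any measurement linked to a mention to meet the size criterion.
#'
#' @param policy A [section_policy()].
#' @param lexicon Lexicon data frame (see [default_lexicon()]).
#' @param triggers A [trigger_set()].
#' @param strict_diameter Logical; gate case verdicts on the diameter
#'   criterion (default `FALSE`).
#' @param threshold_cm Diameter criterion used in strict mode, default 3.0 cm.
#' @return An object of class `aaa_config`.
#' @export
aaa_config <- function(policy = section_policy(), lexicon = default_lexicon(),
                       triggers = trigger_set(), strict_diameter = FALSE,
                       threshold_cm = 3.0) {
  stopifnot(inherits(policy, "section_policy"),
            inherits(triggers, "trigger_set"),
            is.data.frame(lexicon), nrow(lexicon) >= 1L,
            is.logical(strict_diameter), length(strict_diameter) == 1L,
            is.numeric(threshold_cm), threshold_cm > 0)
  structure(list(policy = policy, lexicon = lexicon, triggers = triggers,
                 strict_diameter = strict_diameter,
                 threshold_cm = threshold_cm),
            class = "aaa_config")
}

#' @export
print.aaa_config <- function(x, ...) {
  cat("<aaa_config> lexicon entries:", nrow(x$lexicon),
      " strict_diameter:", x$strict_diameter,
      " threshold:", x$threshold_cm, "cm\n")
  invisible(x)
}

#' Annotate a report: sections, sentences, mentions, assertions, measurements
#'
#' Runs the full extraction cascade on one report and returns the mention
#' table: sections are detected and filtered by the policy, processable
#' section bodies are split into sentences, sentences are matched against the
#' lexicon, each mention receives an assertion status, and dimension
#' expressions are extracted and linked.
#'
#' @param report A [radiology_report()].
#' @param config An [aaa_config()].
#' @return List with `sections` (full section table) and `mentions`, a data
#'   frame with one row per concept mention: `section`, `sentence`,
#'   `surface`, `start`, `end` (span into the sentence), `assertion`,
#'   `trigger`, `max_diameter_cm` (nearest linked measurement in the same
#'   sentence, `NA` when unmeasured).
#' @export
annotate_report <- function(report, config = aaa_config()) {
  stopifnot(inherits(report, "radiology_report"))
  sections <- report$sections
  if (is.null(sections)) sections <- split_sections(report$text, config$policy)
  proc <- filter_processable(sections, config$policy)
  rows <- list()
  for (s in seq_len(nrow(proc))) {
    sentences <- split_sentences(proc$body[s])
    for (i in seq_len(nrow(sentences))) {
      sent <- sentences$text[i]
      mentions <- match_concepts(sent, config$lexicon)
      if (!nrow(mentions)) next
      mentions <- classify_assertions(mentions, sent, config$triggers)
      meas <- extract_measurements(sent, mentions)
      mentions$max_diameter_cm <- NA_real_
      if (nrow(meas)) {
        for (k in seq_len(nrow(mentions))) {
          linked <- meas$max_diameter_cm[!is.na(meas$mention_index) &
                                           meas$mention_index == k]
          # several measurements on one mention: the largest governs
          if (length(linked)) mentions$max_diameter_cm[k] <- max(linked)
        }
      }
      mentions$section <- proc$name[s]
      mentions$sentence <- sent
      rows[[length(rows) + 1L]] <- mentions
    }
  }
  mentions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(surface = character(0), start = integer(0), end = integer(0),
               entry = character(0), assertion = character(0),
               trigger = character(0), max_diameter_cm = numeric(0),
               section = character(0), sentence = character(0),
               stringsAsFactors = FALSE)
  list(sections = sections, mentions = mentions)
}

#' Classify one report as AAA case or control
#'
#' A report is a case when at least one affirmed AAA mention occurs in a
#' processable section; otherwise it is a control ("no evidence of AAA").
#' Negated mentions never contribute. In strict mode, an affirmed mention
#' whose linked measurement falls below the diameter criterion does not
#' qualify (unmeasured mentions still do), so enabling strict mode can only
#' move verdicts from case to control.
#'
#' @param report A [radiology_report()].
#' @param config An [aaa_config()].
#' @return List of class `aaa_document_label`: `report_id`, `label`
#'   (`"case"`/`"control"`), `evidence` (the qualifying affirmed mentions),
#'   `mentions` (all mentions), `strict_mode_applied`.
#' @export
#' @examples
#' rep <- radiology_report("r1",
#'   "FINDINGS:\nSuprarenal aortic abdominal aneurysm which measures up to 5.2 cm.")
#' classify_report(rep)$label  # "case"
classify_report <- function(report, config = aaa_config()) {
  ann <- annotate_report(report, config)
  m <- ann$mentions
  qual <- m$assertion == "affirmed"
  if (config$strict_diameter && nrow(m)) {
    # unmeasured mentions still qualify: substitute the threshold for NA
    d <- as.numeric(ifelse(is.na(m$max_diameter_cm), config$threshold_cm,
                           m$max_diameter_cm))
    qual <- qual & meets_aaa_threshold(d, config$threshold_cm)
  }
  evidence <- m[qual, , drop = FALSE]
  structure(list(report_id = report$report_id,
                 label = if (nrow(evidence)) "case" else "control",
                 evidence = evidence, mentions = m,
                 strict_mode_applied = config$strict_diameter),
            class = "aaa_document_label")
}

#' @export
print.aaa_document_label <- function(x, ...) {
  cat("<aaa_document_label>", x$report_id, "->", x$label,
      sprintf("(%d affirmed of %d mentions%s)\n", nrow(x$evidence),
              nrow(x$mentions),
              if (x$strict_mode_applied) ", strict diameter mode" else ""))
  invisible(x)
}

#' Classify every report of a corpus
#'
#' @param reports List of [radiology_report()] objects.
#' @param config An [aaa_config()].
#' @return Data frame with one row per report: `report_id`, `label`,
#'   `n_mentions`, `n_affirmed`, and `gold_label` where carried by the
#'   report.
#' @export
process_corpus <- function(reports, config = aaa_config()) {
  rows <- lapply(reports, function(r) {
    dl <- classify_report(r, config)
    data.frame(report_id = r$report_id, label = dl$label,
               n_mentions = nrow(dl$mentions),
               n_affirmed = sum(dl$mentions$assertion == "affirmed"),
               gold_label = r$gold_label, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(report_id = character(0), label = character(0),
                      n_mentions = integer(0), n_affirmed = integer(0),
                      gold_label = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Roll report labels up to a patient-level verdict
#'
#' A patient is a case when any of their reports is a case. (The study data
#' showed no within-patient discrepancies, so any/all rules coincide there;
#' any-positive is the sensitive choice for surveillance.)
#'
#' @param labels Character vector of report labels for one patient
#'   (`"case"`/`"control"`).
#' @return `"case"` or `"control"`.
#' @export
aggregate_patient <- function(labels) {
  if (!length(labels)) stop("cannot aggregate an empty label list")
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad)) stop("invalid label(s): ", paste(bad, collapse = ", "))
  if (any(labels == "case")) "case" else "control"
}
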