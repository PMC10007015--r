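#' Extract aortic dimension expressions from a sentence
#'
#' Recognizes `number unit` ("5.2 cm", "56 mm") and two-dimension products
#' `number x number unit` ("5.7x5.1 cm", "42×40 mm"; the ASCII "x" and the
#' multiplication sign are interchangeable, with or without surrounding
#' spaces). Millimetre values are divided by 10 exactly. Each measurement is
#' linked to the nearest concept mention in the same sentence by character
#' distance, if any.
#'
#' @param sentence_text Sentence text.
#' @param mentions Optional mention table from [match_concepts()] for linking.
#' @return Data frame with one row per measurement: `text`, `start`, `end`
#'   (character span), `unit` as written (`"cm"`/`"mm"`), `dims_cm`
#'   (list-column of dimensions in cm), `max_diameter_cm`, and
#'   `mention_index` (row index into `mentions`, `NA` if none).
#' @export
#' @examples
#' extract_measurements("partially thrombosed infrarenal AAA measuring 42×40 mm")
extract_measurements <- function(sentence_text, mentions = NULL) {
  pat <- "(?i)(?<![0-9.])([0-9]+(?:\\.[0-9]+)?)(?:\\s*[x×]\\s*([0-9]+(?:\\.[0-9]+)?))?\\s*(cm|mm)\\b"
  m <- gregexpr(pat, sentence_text, perl = TRUE)[[1]]
  empty <- data.frame(text = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      max_diameter_cm = numeric(0),
                      mention_index = integer(0), stringsAsFactors = FALSE)
  empty$dims_cm <- list()
  if (m[1] < 0) return(empty[, c("text", "start", "end", "unit", "dims_cm",
                                 "max_diameter_cm", "mention_index")])
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  rows <- lapply(seq_along(start), function(i) {
    txt <- substr(sentence_text, start[i], end[i])
    unit <- tolower(sub(".*?(cm|mm)\\s*$", "\\1", txt, ignore.case = TRUE))
    nums <- regmatches(txt, gregexpr("[0-9]+(?:\\.[0-9]+)?", txt))[[1]]
    dims <- as.numeric(nums)
    if (unit == "mm") dims <- dims / 10
    df <- data.frame(text = txt, start = start[i], end = end[i], unit = unit,
                     max_diameter_cm = max(dims),
                     mention_index = NA_integer_, stringsAsFactors = FALSE)
    df$dims_cm <- list(dims)
    df[, c("text", "start", "end", "unit", "dims_cm", "max_diameter_cm",
           "mention_index")]
  })
  out <- do.call(rbind, rows)
  if (!is.null(mentions) && nrow(mentions)) {
    for (i in seq_len(nrow(out))) {
      # character gap between spans; 0 when overlapping
      gap <- pmax(0L, pmax(mentions$start - out$end[i],
                           out$start[i] - mentions$end))
      out$mention_index[i] <- which.min(gap)
    }
  }
  out
}

#' Test a diameter against the AAA size criterion
#'
#' The clinical definition of an abdominal aortic aneurysm used here is a
#' maximal aortic diameter of at least 3 cm on imaging.
#'
#' @param max_diameter_cm Maximal diameter in cm (vectorized).
#' @param threshold_cm Diameter criterion in cm, default 3.0.
#' @return Logical: `max_diameter_cm >= threshold_cm`.
#' @export
#' @examples
#' meets_aaa_threshold(c(2.7, 3.0, 5.2))  # FALSE TRUE TRUE
meets_aaa_threshold <- function(max_diameter_cm, threshold_cm = 3.0) {
  stopifnot(is.numeric(max_diameter_cm), all(max_diameter_cm > 0))
  max_diameter_cm >= threshold_cm
}
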