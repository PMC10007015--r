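#' Section policy: which report sections are processed downstream
#'
#' Radiology reports are organised into named sections (exam type, reason for
#' exam, referral diagnosis, findings, impression, signed by). Concept
#' extraction is restricted to the narrative sections: mentions in
#' administrative sections (e.g. a referral diagnosis of "AAA surveillance")
#' must not drive classification. The default policy processes findings and
#' impression only and excludes everything else, including unknown headers.
#'
#' @param include Canonical names of sections processed downstream.
#' @param exclude Canonical names explicitly skipped.
#' @param synonyms Named character vector mapping header surface forms (after
#'   normalization) to canonical names, e.g. `c(impressions = "impression")`.
#' @param unknown_policy What to do with sections whose canonical name is in
#'   neither list: `"exclude"` (default) or `"include"`.
#' @return An object of class `section_policy`.
#' @export
section_policy <- function(include = c("findings", "impression"),
                           exclude = c("reason for exam", "referral diagnosis",
                                       "exam type", "signed by"),
                           synonyms = c("impressions" = "impression",
                                        "finding" = "findings",
                                        "reason for examination" = "reason for exam",
                                        "electronically signed by" = "signed by"),
                           unknown_policy = c("exclude", "include")) {
  unknown_policy <- match.arg(unknown_policy)
  include <- tolower(include)
  exclude <- tolower(exclude)
  if (length(intersect(include, exclude))) {
    stop("include and exclude lists overlap: ",
         paste(intersect(include, exclude), collapse = ", "))
  }
  structure(
    list(include = include, exclude = exclude,
         synonyms = synonyms, unknown_policy = unknown_policy,
         known_headers = sort(unique(c(include, exclude, unname(synonyms))))),
    class = "section_policy"
  )
}

#' @export
print.section_policy <- function(x, ...) {
  cat("<section_policy>\n  include:", paste(x$include, collapse = ", "),
      "\n  exclude:", paste(x$exclude, collapse = ", "),
      "\n  unknown:", x$unknown_policy, "\n")
  invisible(x)
}

#' Read a section policy from a config file
#'
#' Plain-text format with `[include]`, `[exclude]` and `[synonyms]` blocks;
#' one canonical name per line in the first two, `surface = canonical` lines
#' in the third. `#` starts a comment. See
#' `system.file("extdata", "sections.conf", package = "aaanlp")`.
#'
#' @param path Config file.
#' @param unknown_policy Passed through to [section_policy()].
#' @return A `section_policy`.
#' @export
read_section_policy <- function(path, unknown_policy = "exclude") {
  lines <- .read_config_lines(path)
  include <- character(0); exclude <- character(0)
  syn <- character(0); syn_names <- character(0)
  block <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) { block <- tolower(gsub("\\[|\\]", "", ln)); next }
    if (block == "synonyms") {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed synonym line in ", path, ": ", ln)
      syn_names <- c(syn_names, tolower(trimws(kv[1])))
      syn <- c(syn, tolower(trimws(kv[2])))
    } else if (block == "include") {
      include <- c(include, tolower(ln))
    } else if (block == "exclude") {
      exclude <- c(exclude, tolower(ln))
    } else {
      stop("line outside a recognized block in ", path, ": ", ln)
    }
  }
  section_policy(include = include, exclude = exclude,
                 synonyms = stats::setNames(syn, syn_names),
                 unknown_policy = unknown_policy)
}

# shared config reader: strips comments/blank lines
.read_config_lines <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  trimws(lines[nzchar(trimws(lines))])
}

#' Normalize a section header
#'
#' Lower-cases, collapses internal whitespace, strips surrounding whitespace
#' and a trailing colon, then maps the result through the policy's synonym
#' table when a mapping exists.
#'
#' @param raw_header Header text as printed, e.g. `"FINDINGS:"`.
#' @param policy A [section_policy()] supplying the synonym table.
#' @return Canonical lower-case header name.
#' @export
#' @examples
#' normalize_header("FINDINGS:")        # "findings"
#' normalize_header("Reason  For Exam") # "reason for exam"
normalize_header <- function(raw_header, policy = section_policy()) {
  h <- tolower(trimws(raw_header))
  h <- gsub("\\s+", " ", h)
  h <- sub("\\s*:$", "", h)
  mapped <- unname(policy$synonyms[h])
  ifelse(is.na(mapped), h, mapped)
}

#' Split report text into sections
#'
#' A header is a known section name at the start of a line (matched
#' case-insensitively after normalization), either occupying the whole line
#' with an optional trailing colon, or followed by a colon and inline body
#' text. A section body runs to the next recognized header or the end of the
#' text. Text before the first header becomes a section named `"preamble"`.
#' Every character of the input belongs to exactly one header or body span;
#' spans are 1-based inclusive character intervals into `raw_text`.
#'
#' @param raw_text Full report text.
#' @param policy A [section_policy()].
#' @return A data frame with one row per section: `name` (canonical),
#'   `raw_header`, `header_start`, `body_start`, `body_end` (spans into
#'   `raw_text`; an empty body has `body_end < body_start`), `body` (the
#'   sliced text) and `processable` (per [filter_processable()] policy).
#' @export
split_sections <- function(raw_text, policy = section_policy()) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  n <- nchar(raw_text)
  # line starts/ends (inclusive of the trailing newline in the line span,
  # so that header + body spans tile the whole text)
  nl <- c(gregexpr("\n", raw_text, fixed = TRUE)[[1]])
  nl <- nl[nl > 0]
  line_start <- c(1L, nl + 1L)
  line_end <- c(nl, n)                      # line span includes its newline
  keep <- line_start <= n
  line_start <- line_start[keep]; line_end <- line_end[keep]

  headers <- list()
  for (i in seq_along(line_start)) {
    # line content without its trailing newline
    txt_end <- line_end[i]
    line_txt <- substr(raw_text, line_start[i], txt_end)
    content <- sub("\n$", "", line_txt)
    norm <- normalize_header(content, policy)
    if (norm %in% policy$known_headers && nzchar(trimws(content))) {
      headers[[length(headers) + 1L]] <- list(
        name = norm, raw_header = content,
        header_start = line_start[i], header_end = line_end[i],
        body_start = line_end[i] + 1L)
      next
    }
    # inline form: "HEADER: body text on the same line"
    m <- regexpr("^\\s*[^:\n]{1,60}:", content, perl = TRUE)
    if (m > 0) {
      head_txt <- substr(content, 1L, attr(m, "match.length"))
      norm2 <- normalize_header(head_txt, policy)
      if (norm2 %in% policy$known_headers) {
        headers[[length(headers) + 1L]] <- list(
          name = norm2, raw_header = head_txt,
          header_start = line_start[i],
          header_end = line_start[i] + attr(m, "match.length") - 1L,
          body_start = line_start[i] + attr(m, "match.length"))
      }
    }
  }

  rows <- list()
  add_row <- function(name, raw_header, header_start, body_start, body_end) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, raw_header = raw_header, header_start = header_start,
      body_start = body_start, body_end = body_end,
      body = if (body_end >= body_start) substr(raw_text, body_start, body_end) else "",
      stringsAsFactors = FALSE)
  }
  if (!length(headers)) {
    if (n > 0) add_row("preamble", NA_character_, NA_integer_, 1L, n)
  } else {
    first <- headers[[1]]
    if (first$header_start > 1L) {
      add_row("preamble", NA_character_, NA_integer_, 1L, first$header_start - 1L)
    }
    for (i in seq_along(headers)) {
      h <- headers[[i]]
      nxt <- if (i < length(headers)) headers[[i + 1]]$header_start - 1L else n
      add_row(h$name, h$raw_header, h$header_start, h$body_start, nxt)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), raw_header = character(0),
               header_start = integer(0), body_start = integer(0),
               body_end = integer(0), body = character(0),
               stringsAsFactors = FALSE)
  out$processable <- .is_processable(out$name, policy)
  out
}

.is_processable <- function(name, policy) {
  ifelse(name %in% policy$include, TRUE,
         ifelse(name %in% policy$exclude, FALSE,
                policy$unknown_policy == "include"))
}

#' Keep only the sections the policy marks processable
#'
#' Idempotent, order-preserving filter: sections whose canonical name is in
#' the include list, plus unknown-named sections when the policy says to
#' include them.
#'
#' @param sections Section table from [split_sections()].
#' @param policy A [section_policy()].
#' @return The subset of rows that are processable.
#' @export
filter_processable <- function(sections, policy = section_policy()) {
  sections[.is_processable(sections$name, policy), , drop = FALSE]
}
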