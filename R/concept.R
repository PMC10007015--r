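#' Split a section body into sentences
#'
#' Splits at sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace and an upper-case letter or digit-initial sentence, and never
#' inside decimal numbers or dimension expressions (`5.2 cm`, `5.7x5.1 cm`).
#' Newlines that end a line also terminate a sentence.
#'
#' @param body Section body text.
#' @return Data frame with columns `text`, `start`, `end` (1-based inclusive
#'   spans into `body`, trimmed of surrounding whitespace).
#' @export
#' @examples
#' split_sentences("Negative for abdominal aortic aneurysm. AAA is absent.")
split_sentences <- function(body) {
  stopifnot(is.character(body), length(body) == 1L)
  if (!nzchar(trimws(body))) {
    return(data.frame(text = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  # boundary = terminal punctuation followed by whitespace + capital/digit,
  # or a newline; a '.' flanked by digits (decimal point) never splits
  m <- gregexpr("(?<!\\d)[.!?](?=\\s+[A-Z0-9])|\\n", body, perl = TRUE)[[1]]
  bounds <- if (m[1] > 0) as.integer(m) else integer(0)
  starts <- integer(0); ends <- integer(0)
  cur <- 1L
  n <- nchar(body)
  for (b in c(bounds, n)) {
    seg_end <- if (substr(body, b, b) == "\n") b - 1L else b
    if (seg_end >= cur) { starts <- c(starts, cur); ends <- c(ends, seg_end) }
    cur <- b + 1L
  }
  # trim whitespace off each span
  out <- lapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- ends[i]
    while (s <= e && grepl("^\\s$", substr(body, s, s))) s <- s + 1L
    while (e >= s && grepl("^\\s$", substr(body, e, e))) e <- e - 1L
    if (e < s) return(NULL)
    data.frame(text = substr(body, s, e), start = s, end = e,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(text = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Tokenize a sentence
#'
#' Tokens are decimal numbers (`5.2`), maximal alphanumeric runs, or single
#' punctuation marks; whitespace separates tokens and is discarded.
#'
#' @param text Sentence text.
#' @return Data frame with columns `token`, `start`, `end` (1-based inclusive
#'   character spans into `text`).
#' @export
#' @examples
#' tokenize("AAA, 5.2 cm")$token  # "AAA" "," "5.2" "cm"
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[0-9]+\\.[0-9]+|[[:alnum:]]+|[^[:alnum:][:space:]]",
                text, perl = TRUE)[[1]]
  if (m[1] < 0) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(token = substring(text, start, start + len - 1L),
             start = start, end = start + len - 1L, stringsAsFactors = FALSE)
}

# inflection map applied during lexicon matching; maps surface token
# variants to a shared normal form so that word-order permutations of the
# UMLS-normalized lexicon entries are recognized
.norm_token <- function(tokens) {
  x <- tolower(tokens)
  map <- c(aortic = "aorta", aortas = "aorta", aneurysms = "aneurysm")
  hit <- match(x, names(map))
  x[!is.na(hit)] <- map[hit[!is.na(hit)]]
  x
}

#' The default AAA lexicon
#'
#' The five concept terms used for AAA identification (UMLS-normalized word
#' orders) plus the pluralized acronym. The bare acronym is matched
#' case-sensitively as a standalone token; multi-word terms are matched
#' case-insensitively as normalized token bags, so inflectional and
#' word-order variants ("abdominal aortic aneurysm", "aortic abdominal
#' aneurysm") are recognized.
#'
#' @return Data frame with columns `surface`, `case_sensitive`.
#' @export
default_lexicon <- function() {
  data.frame(
    surface = c("aorta abdominal aneurysm", "aortic aneurysm abdominal",
                "aneurysm abdominal aorta", "infrarenal aortic aneurysm",
                "AAA", "AAAs"),
    case_sensitive = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Read a lexicon from a config file
#'
#' One entry per line: `surface_form<TAB>case_sensitive` with
#' `case_sensitive` in `{true,false}`; `#` starts a comment. See
#' `system.file("extdata", "lexicon.tsv", package = "aaanlp")`.
#'
#' @param path Config file.
#' @return Data frame with columns `surface`, `case_sensitive`.
#' @export
read_lexicon <- function(path) {
  lines <- .read_config_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed lexicon line ", bad[1], " in ", path)
  surface <- trimws(vapply(parts, `[[`, character(1), 1L))
  cs <- tolower(trimws(vapply(parts, `[[`, character(1), 2L)))
  if (!all(cs %in% c("true", "false"))) {
    stop("case_sensitive flag must be 'true' or 'false' in ", path)
  }
  if (!all(nzchar(surface))) stop("empty surface form in ", path)
  data.frame(surface = surface, case_sensitive = cs == "true",
             stringsAsFactors = FALSE)
}

#' Match AAA concept mentions in a sentence
#'
#' Token-level phrase matching against the lexicon. Case-sensitive entries
#' (the bare acronym) must match a standalone token exactly. Multi-word
#' entries match any contiguous token window whose normalized token bag
#' (lower-cased, inflection-mapped) equals the entry's, which makes matching
#' insensitive to internal whitespace, capitalization, inflection and word
#' order. Overlapping candidates are resolved leftmost-longest. The
#' surrounding context is unconstrained: a keyword at the sentence boundary
#' still matches.
#'
#' @param sentence_text Sentence text.
#' @param lexicon Lexicon data frame (see [default_lexicon()]).
#' @return Data frame with one row per mention: `surface`, `start`, `end`
#'   (character span into `sentence_text`), `entry` (the matched lexicon
#'   surface form) and `assertion` (always `"unassigned"`; see
#'   [classify_assertion()]).
#' @export
#' @examples
#' match_concepts("Suprarenal aortic abdominal aneurysm which measures up to 5.2 cm")
match_concepts <- function(sentence_text, lexicon = default_lexicon()) {
  stopifnot(nrow(lexicon) >= 1L)
  toks <- tokenize(sentence_text)
  empty <- data.frame(surface = character(0), start = integer(0),
                      end = integer(0), entry = character(0),
                      assertion = character(0), stringsAsFactors = FALSE)
  if (!nrow(toks)) return(empty)
  norm <- .norm_token(toks$token)
  nt <- nrow(toks)
  cand <- list()
  for (j in seq_len(nrow(lexicon))) {
    entry <- lexicon$surface[j]
    etoks <- tokenize(entry)$token
    k <- length(etoks)
    if (k == 0L || k > nt) next
    if (lexicon$case_sensitive[j]) {
      hits <- which(toks$token == entry)   # standalone exact token
      if (k == 1L) for (h in hits) {
        cand[[length(cand) + 1L]] <- c(i1 = h, i2 = h, j = j)
      }
    } else {
      ebag <- sort(.norm_token(etoks))
      for (i in seq_len(nt - k + 1L)) {
        if (identical(sort(norm[i:(i + k - 1L)]), ebag)) {
          cand[[length(cand) + 1L]] <- c(i1 = i, i2 = i + k - 1L, j = j)
        }
      }
    }
  }
  if (!length(cand)) return(empty)
  cm <- unique(do.call(rbind, cand)[, 1:2, drop = FALSE])
  cm <- cm[order(cm[, 1], -(cm[, 2] - cm[, 1])), , drop = FALSE]
  # leftmost-longest: greedy accept non-overlapping token ranges
  taken <- rep(FALSE, nt)
  rows <- list()
  for (r in seq_len(nrow(cm))) {
    i1 <- cm[r, 1]; i2 <- cm[r, 2]
    if (any(taken[i1:i2])) next
    taken[i1:i2] <- TRUE
    # recover which entry produced this span (first match, lexicon order)
    jj <- Filter(function(cc) cc["i1"] == i1 && cc["i2"] == i2, cand)[[1]]["j"]
    rows[[length(rows) + 1L]] <- data.frame(
      surface = substr(sentence_text, toks$start[i1], toks$end[i2]),
      start = toks$start[i1], end = toks$end[i2],
      entry = lexicon$surface[jj], assertion = "unassigned",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}
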