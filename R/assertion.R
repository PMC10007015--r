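#' Negation trigger set
#'
#' ConText-style sentence-level assertion cues, in four disjoint categories:
#' pre-negation phrases negate a concept that follows them; post-negation
#' phrases negate a concept that precedes them; pseudo-negation phrases look
#' negative but do not negate concept presence ("no significant interval
#' change in the known AAA" asserts the aneurysm is present and stable) and
#' are masked before trigger search; terminator phrases end a negation scope.
#' A trigger only negates a mention within `scope_tokens` intervening tokens
#' and with no terminator in between.
#'
#' @param pre_negation,post_negation,pseudo_negation,terminators Character
#'   vectors of lower-case phrases.
#' @param scope_tokens Maximum number of tokens between trigger and mention.
#' @return An object of class `trigger_set`.
#' @export
trigger_set <- function(pre_negation = .default_pre_negation,
                        post_negation = .default_post_negation,
                        pseudo_negation = .default_pseudo_negation,
                        terminators = .default_terminators,
                        scope_tokens = 6L) {
  pre_negation <- tolower(pre_negation)
  post_negation <- tolower(post_negation)
  pseudo_negation <- tolower(pseudo_negation)
  terminators <- tolower(terminators)
  overlap <- c(intersect(pre_negation, post_negation),
               intersect(pre_negation, pseudo_negation),
               intersect(post_negation, pseudo_negation))
  if (length(overlap)) {
    stop("trigger categories must be disjoint; shared: ",
         paste(unique(overlap), collapse = ", "))
  }
  stopifnot(scope_tokens >= 0L)
  structure(list(pre_negation = pre_negation, post_negation = post_negation,
                 pseudo_negation = pseudo_negation, terminators = terminators,
                 scope_tokens = as.integer(scope_tokens)),
            class = "trigger_set")
}

.default_pre_negation <- c(
  "no", "without", "negative for", "no evidence of", "absence of",
  "free of", "without evidence of", "ruled out for"
)
.default_post_negation <- c(
  "is absent", "are absent", "not seen", "not identified",
  "not visualized", "is excluded", "has resolved"
)
.default_pseudo_negation <- c(
  "no significant interval change", "no significant interval changes",
  "no interval change", "no interval changes",
  "no significant change", "no significant changes",
  "no signs of rupture", "no sign of rupture", "no evidence of rupture",
  "not significantly changed", "no slightly increased size",
  "no increase in size", "no change in size"
)
.default_terminators <- c(
  "but", "however", "although", "aside from", "apart from", "except",
  ";", ":", "of the known"
)

#' @export
print.trigger_set <- function(x, ...) {
  cat("<trigger_set> pre:", length(x$pre_negation),
      " post:", length(x$post_negation),
      " pseudo:", length(x$pseudo_negation),
      " terminators:", length(x$terminators),
      " scope:", x$scope_tokens, "tokens\n")
  invisible(x)
}

#' Read a trigger set from a config file
#'
#' Plain-text format with `[pre_negation]`, `[post_negation]`,
#' `[pseudo_negation]` and `[terminators]` blocks, one phrase per line; `#`
#' starts a comment. See
#' `system.file("extdata", "triggers.conf", package = "aaanlp")`.
#'
#' @param path Config file.
#' @param scope_tokens Scope window, passed to [trigger_set()].
#' @return A `trigger_set`.
#' @export
read_triggers <- function(path, scope_tokens = 6L) {
  lines <- .read_config_lines(path)
  sets <- list(pre_negation = character(0), post_negation = character(0),
               pseudo_negation = character(0), terminators = character(0))
  block <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      block <- tolower(gsub("\\[|\\]", "", ln))
      if (!block %in% names(sets)) stop("unknown block [", block, "] in ", path)
      next
    }
    if (!nzchar(block)) stop("phrase outside a block in ", path, ": ", ln)
    sets[[block]] <- c(sets[[block]], ln)
  }
  trigger_set(pre_negation = sets$pre_negation,
              post_negation = sets$post_negation,
              pseudo_negation = sets$pseudo_negation,
              terminators = sets$terminators,
              scope_tokens = scope_tokens)
}

# token-level occurrences of a phrase within a token vector (lower-cased
# comparison); returns matrix with columns i1, i2 (token index range)
.phrase_hits <- function(tokens_lower, phrase) {
  ptoks <- tokenize(phrase)$token
  k <- length(ptoks)
  n <- length(tokens_lower)
  if (k == 0L || k > n) return(matrix(integer(0), ncol = 2))
  ptoks <- tolower(ptoks)
  hits <- which(vapply(seq_len(n - k + 1L), function(i) {
    all(tokens_lower[i:(i + k - 1L)] == ptoks)
  }, logical(1)))
  cbind(hits, hits + k - 1L)
}

#' Assign assertion status to a concept mention
#'
#' A mention is negated when an unmasked pre-negation trigger ends within
#' `scope_tokens` tokens before it, or an unmasked post-negation trigger
#' starts within `scope_tokens` tokens after it, with no terminator phrase in
#' the gap. Pseudo-negation phrases are masked first: tokens covered by any
#' pseudo-negation occurrence can serve neither as trigger nor as terminator
#' tokens. Anything else is affirmed — affirmed is the default, so hedged
#' statements ("possible AAA") count as affirmed.
#'
#' @param mention One row of the mention table from [match_concepts()] (or
#'   any list/row with `start` and `end` character offsets).
#' @param sentence_text The sentence containing the mention.
#' @param triggers A [trigger_set()].
#' @return List with `value` (`"affirmed"` or `"negated"`) and `trigger`
#'   (the matched trigger phrase, or `NA` when affirmed).
#' @export
#' @examples
#' m <- match_concepts("Negative for abdominal aortic aneurysm or dissection")
#' classify_assertion(m[1, ], "Negative for abdominal aortic aneurysm or dissection")
classify_assertion <- function(mention, sentence_text,
                               triggers = trigger_set()) {
  toks <- tokenize(sentence_text)
  if (!nrow(toks)) return(list(value = "affirmed", trigger = NA_character_))
  low <- tolower(toks$token)
  nt <- nrow(toks)

  # mention token range = tokens overlapping the mention's character span
  in_mention <- which(toks$end >= mention$start & toks$start <= mention$end)
  if (!length(in_mention)) {
    stop("mention span [", mention$start, ",", mention$end,
         "] does not overlap any token of the sentence")
  }
  m1 <- min(in_mention); m2 <- max(in_mention)

  # mask pseudo-negation: union of all occurrences
  masked <- rep(FALSE, nt)
  for (ph in triggers$pseudo_negation) {
    h <- .phrase_hits(low, ph)
    for (r in seq_len(nrow(h))) masked[h[r, 1]:h[r, 2]] <- TRUE
  }

  term_tokens <- rep(FALSE, nt)  # tokens covered by an unmasked terminator
  for (ph in triggers$terminators) {
    h <- .phrase_hits(low, ph)
    for (r in seq_len(nrow(h))) {
      if (!any(masked[h[r, 1]:h[r, 2]])) term_tokens[h[r, 1]:h[r, 2]] <- TRUE
    }
  }

  gap_clear <- function(from, to) {            # token gap (from, to) exclusive
    if (to - from - 1L > triggers$scope_tokens) return(FALSE)
    if (to - from >= 2L && any(term_tokens[(from + 1L):(to - 1L)])) return(FALSE)
    TRUE
  }

  best <- NULL                                  # prefer the longest phrase
  consider <- function(phrase) {
    if (is.null(best) || nchar(phrase) > nchar(best)) best <<- phrase
  }
  for (ph in triggers$pre_negation) {
    h <- .phrase_hits(low, ph)
    for (r in seq_len(nrow(h))) {
      if (any(masked[h[r, 1]:h[r, 2]])) next
      if (h[r, 2] < m1 && gap_clear(h[r, 2], m1)) consider(ph)
    }
  }
  for (ph in triggers$post_negation) {
    h <- .phrase_hits(low, ph)
    for (r in seq_len(nrow(h))) {
      if (any(masked[h[r, 1]:h[r, 2]])) next
      if (h[r, 1] > m2 && gap_clear(m2, h[r, 1])) consider(ph)
    }
  }
  if (is.null(best)) list(value = "affirmed", trigger = NA_character_)
  else list(value = "negated", trigger = best)
}

#' Assign assertion status to every mention in a sentence
#'
#' @param mentions Mention table from [match_concepts()].
#' @param sentence_text The sentence text.
#' @param triggers A [trigger_set()].
#' @return The mention table with `assertion` filled in and a `trigger`
#'   column added.
#' @export
classify_assertions <- function(mentions, sentence_text,
                                triggers = trigger_set()) {
  if (!nrow(mentions)) {
    mentions$trigger <- character(0)
    return(mentions)
  }
  res <- lapply(seq_len(nrow(mentions)), function(i) {
    classify_assertion(mentions[i, ], sentence_text, triggers)
  })
  mentions$assertion <- vapply(res, `[[`, character(1), "value")
  mentions$trigger <- vapply(res, `[[`, character(1), "trigger")
  mentions
}
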