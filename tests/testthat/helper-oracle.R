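# Brute-force negation-scope oracle, independent of the package's
# implementation: operates directly on a token vector with naive loops,
# enumerating every phrase occurrence by subsequence comparison.
#
# Semantics (shared contract with classify_assertion):
#   - pseudo-negation occurrences mask their tokens (union over occurrences);
#   - a trigger/terminator occurrence is valid only if none of its tokens
#     is masked;
#   - a pre-negation trigger ending at e negates a mention starting at m1
#     iff m1 - e - 1 <= scope and no valid terminator token lies strictly
#     between e and m1; symmetrically for post-negation triggers.
oracle_assertion <- function(tokens, mention_idx, triggers) {
  low <- tolower(tokens)
  n <- length(tokens)
  m1 <- min(mention_idx); m2 <- max(mention_idx)

  occurrences <- function(phrase) {
    ptoks <- tolower(strsplit(phrase, "\\s+")[[1]])
    k <- length(ptoks)
    out <- list()
    if (k > n) return(out)
    for (i in 1:(n - k + 1)) {
      ok <- TRUE
      for (j in 1:k) if (low[i + j - 1] != ptoks[j]) { ok <- FALSE; break }
      if (ok) out[[length(out) + 1]] <- c(i, i + k - 1)
    }
    out
  }

  masked <- rep(FALSE, n)
  for (ph in triggers$pseudo_negation) {
    for (occ in occurrences(ph)) masked[occ[1]:occ[2]] <- TRUE
  }
  term <- rep(FALSE, n)
  for (ph in triggers$terminators) {
    for (occ in occurrences(ph)) {
      if (!any(masked[occ[1]:occ[2]])) term[occ[1]:occ[2]] <- TRUE
    }
  }
  scope <- triggers$scope_tokens
  for (ph in triggers$pre_negation) {
    for (occ in occurrences(ph)) {
      if (any(masked[occ[1]:occ[2]])) next
      e <- occ[2]
      if (e >= m1) next
      if (m1 - e - 1 > scope) next
      if (e + 1 <= m1 - 1 && any(term[(e + 1):(m1 - 1)])) next
      return("negated")
    }
  }
  for (ph in triggers$post_negation) {
    for (occ in occurrences(ph)) {
      if (any(masked[occ[1]:occ[2]])) next
      s <- occ[1]
      if (s <= m2) next
      if (s - m2 - 1 > scope) next
      if (m2 + 1 <= s - 1 && any(term[(m2 + 1):(s - 1)])) next
      return("negated")
    }
  }
  "affirmed"
}

# Random short sentences around a single "AAA" token. The filler vocabulary
# deliberately contains the words the default trigger phrases are built from,
# so multi-token triggers, pseudo-negations and terminators all arise by
# chance; it avoids the multi-word lexicon vocabulary so "AAA" is always the
# only mention.
oracle_vocab <- c("no", "evidence", "of", "significant", "interval",
                  "change", "changes", "signs", "rupture", "without",
                  "negative", "for", "is", "are", "absent", "seen", "not",
                  "identified", "but", "however", ";", "the", "known",
                  "stable", "liver", "size", "increased")

random_oracle_sentence <- function(max_tokens = 8) {
  n <- sample(seq_len(max_tokens - 1), 1)   # +1 for the mention token
  toks <- sample(oracle_vocab, n, replace = TRUE)
  pos <- sample(seq_len(n + 1), 1) - 1
  append(toks, "AAA", after = pos)
}

# small fixed default config shared by several test files
default_cfg <- aaanlp::aaa_config()
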