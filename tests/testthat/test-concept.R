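test_that("sentence splitting respects decimals and dimension strings", {
  s <- split_sentences(paste(
    "Negative for abdominal aortic aneurysm or dissection.",
    "Abdominal aortic aneurysm is absent."))
  expect_identical(nrow(s), 2L)
  expect_match(s$text[1], "^Negative")
  expect_match(s$text[2], "absent\\.$")

  # never split inside "5.7×5.1" or "image 175 of series 4"
  one <- split_sentences(
    "There is a 5.7×5.1 cm infrarenal aortic aneurysm measured on image 175 of series 4.")
  expect_identical(nrow(one), 1L)

  expect_identical(nrow(split_sentences("")), 0L)
  expect_identical(nrow(split_sentences("   \n  ")), 0L)

  # spans slice back to the sentence text
  body <- "The aorta measures 3.4 cm. No focal lesion is seen."
  s2 <- split_sentences(body)
  expect_identical(substr(body, s2$start[1], s2$end[1]), s2$text[1])
  expect_identical(substr(body, s2$start[2], s2$end[2]), s2$text[2])
})

test_that("tokenization yields numbers, word runs and single punctuation", {
  expect_identical(tokenize("AAA, 5.2 cm")$token, c("AAA", ",", "5.2", "cm"))
  expect_identical(tokenize("42×40 mm")$token, c("42", "×", "40", "mm"))
  expect_identical(nrow(tokenize("")), 0L)
  # spans tile the non-whitespace text
  t <- tokenize("no evidence of AAA; stable.")
  expect_identical(
    vapply(seq_len(nrow(t)),
           function(i) substr("no evidence of AAA; stable.", t$start[i], t$end[i]),
           character(1)),
    t$token)
})

test_that("lexicon matching reproduces the canonical mention surfaces", {
  m1 <- match_concepts(
    "Suprarenal aortic abdominal aneurysm which measures up to 5.2 cm")
  expect_identical(m1$surface, "aortic abdominal aneurysm")
  expect_identical(m1$assertion, "unassigned")

  expect_identical(
    nrow(match_concepts("The liver and kidneys are unremarkable")), 0L)

  m2 <- match_concepts(
    "no signs of rupture or impending rupture of the known infrarenal AAA")
  expect_identical(m2$surface, "AAA")

  # leftmost-longest across overlapping word-order variants
  m3 <- match_concepts(
    "fusiform infrarenal abdominal aortic aneurysm terminating proximal")
  expect_identical(nrow(m3), 1L)
  expect_identical(m3$surface, "abdominal aortic aneurysm")

  m4 <- match_concepts(
    "There is a 5.7×5.1 cm infrarenal aortic aneurysm measured on image 175 of series 4")
  expect_identical(m4$surface, "infrarenal aortic aneurysm")
})

test_that("the acronym is case-sensitive and standalone; phrases are not", {
  expect_identical(nrow(match_concepts("banaaana republic")), 0L)
  expect_identical(nrow(match_concepts("the aaa battery died")), 0L)
  expect_identical(match_concepts("known infrarenal AAA")$surface, "AAA")
  # pluralized acronym variant
  expect_identical(match_concepts("history of AAAs")$surface, "AAAs")
  # case- and whitespace-insensitive phrase matching
  expect_identical(
    match_concepts("ABDOMINAL   AORTIC   ANEURYSM is present")$surface,
    "ABDOMINAL   AORTIC   ANEURYSM")
  # pluralization via inflection normalization
  expect_identical(
    match_concepts("multiple abdominal aortic aneurysms")$surface,
    "abdominal aortic aneurysms")
})

test_that("mention spans slice the sentence and never overlap", {
  s <- "Infrarenal AAA and a second abdominal aortic aneurysm are described"
  m <- match_concepts(s)
  expect_identical(nrow(m), 2L)
  for (i in seq_len(nrow(m))) {
    expect_identical(substr(s, m$start[i], m$end[i]), m$surface[i])
  }
  expect_true(all(m$start[-1] > m$end[-nrow(m)]))
})

test_that("the lexicon loads from its config file", {
  lex <- read_lexicon(system.file("extdata", "lexicon.tsv", package = "aaanlp"))
  expect_identical(lex, default_lexicon())
  bad <- withr::local_tempfile()
  writeLines("only one field", bad)
  expect_error(read_lexicon(bad), "malformed")
})
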