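assert_one <- function(sentence, triggers = trigger_set()) {
  m <- match_concepts(sentence)
  expect_identical(nrow(m), 1L)
  classify_assertion(m[1, ], sentence, triggers)
}

test_that("the six canonical spans classify 3 affirmed / 3 negated", {
  affirmed <- c(
    "Suprarenal aortic abdominal aneurysm which measures up to 5.2 cm",
    "Fusiform infrarenal abdominal aortic aneurysm terminating proximal to the aortobiiliac bifurcation, 56 mm, previously 56 mm",
    "There is a 5.7×5.1 cm infrarenal aortic aneurysm measured on image 175 of series 4")
  negated <- c(
    "Negative for abdominal aortic aneurysm or dissection",
    "Abdominal aortic aneurysm is absent",
    "Negative for thoracic or abdominal aortic aneurysm, dissection, penetrating atherosclerotic ulcer or intramural hematoma")
  for (s in affirmed) expect_identical(assert_one(s)$value, "affirmed")
  for (s in negated) {
    res <- assert_one(s)
    expect_identical(res$value, "negated")
    expect_false(is.na(res$trigger))
  }
})

test_that("pseudo-negation constructions are masked and stay affirmed", {
  pseudo <- c(
    "No significant interval changes in appearances of a partially thrombosed infrarenal AAA measuring 42×40 mm, extending to the level of the aortic bifurcation and proximal common iliac arteries",
    "No signs of rupture or impending rupture of the known infrarenal AAA",
    "No slightly increased size of fusiform infrarenal AAA")
  for (s in pseudo) {
    res <- assert_one(s)
    expect_identical(res$value, "affirmed")
    expect_true(is.na(res$trigger))
  }
  # with masking disabled, at least the short constructions turn negated
  no_mask <- trigger_set(pseudo_negation = character(0))
  expect_identical(
    assert_one("No significant change of the infrarenal AAA", no_mask)$value,
    "negated")
})

test_that("scope window and terminators bound negation", {
  # within 6 tokens: negated
  expect_identical(
    assert_one("No thoracic or infrarenal abdominal aortic aneurysm")$value,
    "negated")
  # beyond 6 intervening tokens: out of scope
  far <- "No lesion of the liver spleen kidneys pancreas or adrenal glands; infrarenal AAA is present"
  expect_identical(assert_one(far)$value, "affirmed")
  # terminator between trigger and mention blocks the scope
  expect_identical(
    assert_one("No acute findings but the known infrarenal AAA persists")$value,
    "affirmed")
  # affirmed is the default when no trigger phrase occurs at all
  expect_identical(assert_one("Stable infrarenal AAA")$value, "affirmed")
})

test_that("assertion matches the brute-force trigger-scope oracle on short sentences", {
  triggers <- trigger_set()
  set.seed(4242)
  n_checked <- 0L
  for (i in 1:400) {
    toks <- random_oracle_sentence(max_tokens = 8)
    sentence <- paste(toks, collapse = " ")
    m <- match_concepts(sentence)
    # vocabulary guarantees exactly one mention (the AAA token)
    expect_identical(nrow(m), 1L)
    got <- classify_assertion(m[1, ], sentence, triggers)$value
    want <- oracle_assertion(toks, which(toks == "AAA"), triggers)
    if (!identical(got, want)) {
      fail(sprintf("oracle mismatch on: '%s' (got %s, want %s)",
                   sentence, got, want))
    }
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 400L)
})

test_that("trigger categories must be disjoint and load from config", {
  expect_error(trigger_set(pre_negation = c("no", "not seen"),
                           post_negation = "not seen"),
               "disjoint")
  tr <- read_triggers(system.file("extdata", "triggers.conf",
                                  package = "aaanlp"))
  def <- trigger_set()
  expect_setequal(tr$pre_negation, def$pre_negation)
  expect_setequal(tr$post_negation, def$post_negation)
  expect_setequal(tr$pseudo_negation, def$pseudo_negation)
  expect_setequal(tr$terminators, def$terminators)
  expect_identical(tr$scope_tokens, 6L)
})
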