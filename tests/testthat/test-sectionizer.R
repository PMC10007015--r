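fig2_text <- paste0(
  "EXAM TYPE: US abdomen complete\n",
  "REASON FOR EXAM: Pulsatile abdominal mass.\n",
  "FINDINGS:\nThe aorta is aneurysmal.\nThe liver is unremarkable.\n",
  "IMPRESSION:\n1. Infrarenal abdominal aortic aneurysm.\n",
  "SIGNED BY: Physician, M.D.")

test_that("a standard multi-section report splits into its sections in order", {
  secs <- split_sections(fig2_text)
  expect_identical(secs$name, c("exam type", "reason for exam", "findings",
                                "impression", "signed by"))
  expect_identical(secs$processable,
                   c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # inline header bodies start right after the colon
  expect_identical(secs$body[1], " US abdomen complete\n")
  expect_match(secs$body[3], "aneurysmal")
})

test_that("headers + bodies tile the raw text exactly", {
  for (txt in c(fig2_text,
                vapply(golden_fixture(), `[[`, character(1), "text"))) {
    secs <- split_sections(txt)
    pieces <- vapply(seq_len(nrow(secs)), function(i) {
      from <- if (is.na(secs$header_start[i])) secs$body_start[i] else
        secs$header_start[i]
      substr(txt, from, secs$body_end[i])
    }, character(1))
    expect_identical(paste(pieces, collapse = ""), txt)
    # bodies are non-overlapping and strictly increasing
    expect_true(all(diff(secs$body_start) > 0))
    expect_true(all(secs$body_start[-1] > secs$body_end[-nrow(secs)]))
  }
})

test_that("degenerate structures fall back gracefully", {
  # no recognized header: one preamble section spanning everything
  secs <- split_sections("Just a note with no structure at all.")
  expect_identical(secs$name, "preamble")
  expect_identical(secs$body[1], "Just a note with no structure at all.")
  expect_false(secs$processable[1])

  # header as final line: empty body span
  secs2 <- split_sections("FINDINGS:\nSome text.\nIMPRESSION:")
  expect_identical(secs2$name, c("findings", "impression"))
  expect_lt(secs2$body_end[2], secs2$body_start[2])
  expect_identical(secs2$body[2], "")

  # text before the first header becomes preamble
  secs3 <- split_sections("Dictated 10:45.\nFINDINGS:\nNormal.")
  expect_identical(secs3$name[1], "preamble")
})

test_that("header normalization lower-cases, collapses space, strips colon", {
  expect_identical(normalize_header("FINDINGS:"), "findings")
  expect_identical(normalize_header("Reason  For Exam"), "reason for exam")
  expect_identical(normalize_header("IMPRESSION :"), "impression")
  # synonym table maps variant forms to the canonical name
  expect_identical(normalize_header("IMPRESSIONS:"), "impression")
  expect_identical(normalize_header("Electronically Signed By"), "signed by")
  # unmapped headers come back normalized but unchanged
  expect_identical(normalize_header("  Comparison : "), "comparison")
})

test_that("filter_processable applies the include/exclude policy", {
  secs <- split_sections(fig2_text)
  kept <- filter_processable(secs)
  expect_identical(kept$name, c("findings", "impression"))
  # idempotent and order-preserving
  expect_identical(filter_processable(kept), kept)
  # empty in, empty out
  expect_identical(nrow(filter_processable(secs[0, ])), 0L)
  # unknown sections follow unknown_policy
  pre <- split_sections("free text only")
  expect_identical(nrow(filter_processable(pre)), 0L)
  pol_inc <- section_policy(unknown_policy = "include")
  expect_identical(filter_processable(pre, pol_inc)$name, "preamble")
})

test_that("a section policy loads from its config file", {
  pol <- read_section_policy(system.file("extdata", "sections.conf",
                                         package = "aaanlp"))
  expect_setequal(pol$include, c("findings", "impression"))
  expect_setequal(pol$exclude, c("reason for exam", "referral diagnosis",
                                 "exam type", "signed by"))
  expect_identical(unname(pol$synonyms["impressions"]), "impression")
  expect_error(section_policy(include = "findings", exclude = "findings"),
               "overlap")
})
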