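test_that("confusion matrices count pairs and validate id sets", {
  ref <- label_set(paste0("r", 1:10),
                   c(rep("case", 4), rep("control", 6)))
  cm <- confusion_matrix(ref, ref)
  expect_identical(c(cm$tp, cm$fn, cm$fp, cm$tn), c(4L, 0L, 0L, 6L))

  all_ctrl <- label_set(paste0("r", 1:5), rep("control", 5))
  ref5 <- label_set(paste0("r", 1:5),
                    c("case", "case", "case", "control", "control"))
  cm2 <- confusion_matrix(all_ctrl, ref5)
  expect_identical(c(cm2$tp, cm2$fn, cm2$tn, cm2$fp), c(0L, 3L, 2L, 0L))

  expect_error(confusion_matrix(all_ctrl, ref), "different reports")
  expect_error(aaa_confusion(-1, 0, 0, 1))
})

test_that("undefined metrics are NA, not zero, and print as undefined", {
  m <- compute_metrics(aaa_confusion(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(m$ppv))
  expect_true(is.na(m$sensitivity))
  expect_identical(m$specificity, 1.0)
  expect_output(print(m), "undefined")
})

test_that("F1 equals the harmonic mean of PPV and sensitivity (identity)", {
  set.seed(7)
  for (i in 1:200) {
    counts <- stats::rmultinom(1, size = sample(5:500, 1),
                               prob = stats::runif(4, 0.05, 1))[, 1]
    cm <- aaa_confusion(counts[1], counts[2], counts[3], counts[4])
    m <- compute_metrics(cm)
    if (is.na(m$f1)) next
    expect_equal(m$f1, 2 / (1 / m$ppv + 1 / m$sensitivity), tolerance = 1e-12)
    expect_gte(m$f1, min(m$sensitivity, m$ppv) - 1e-12)
    expect_lte(m$f1, max(m$sensitivity, m$ppv) + 1e-12)
    expect_equal(m$accuracy, (cm$tp + cm$tn) / sum(unlist(cm[1:4])),
                 tolerance = 1e-12)
  }
})

test_that("display rounding is half-up at 2 decimals", {
  rhu <- aaanlp:::round_half_up
  expect_identical(rhu(0.005, 2), 0.01)
  expect_identical(rhu(0.965, 2), 0.97)
  expect_identical(rhu(0.9644, 2), 0.96)
  # F1 must come from unrounded inputs: with ppv .9833 and sens .9516,
  # rounding first would give 2/(1/.98 + 1/.95) -> 0.96, not the correct 0.97
  m <- compute_metrics(aaa_confusion(tp = 59, fp = 1, tn = 57, fn = 3))
  expect_identical(rhu(m$f1, 2), 0.97)
})

test_that("kappa matches hand computations and its conventions", {
  ids <- paste0("r", 1:4)
  a <- label_set(ids, c("case", "case", "control", "control"))
  b <- label_set(ids, c("case", "control", "case", "control"))
  expect_equal(cohen_kappa(a, b), 0.0)          # p_o = p_e = 0.5
  expect_equal(cohen_kappa(a, a), 1.0)
  expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))  # symmetric
  allc <- label_set(ids, rep("case", 4))
  expect_equal(cohen_kappa(allc, allc), 1.0)    # degenerate convention
  # perfectly anti-correlated raters
  expect_equal(cohen_kappa(a, label_set(ids, c("control", "control", "case", "case"))), -1.0)
  expect_error(cohen_kappa(a, label_set("r9", "case")), "different")
})

test_that("error listings expose FP/FN reports with their evidence", {
  fx <- golden_fixture()
  gold <- gold_labels(fx)
  pred <- process_corpus(fx)
  plabs <- label_set(pred$report_id, pred$label)
  el <- error_listing(plabs, gold, fx)
  # default pipeline: exactly the sub-threshold typo report is an FP
  expect_identical(el$report_id, "gf10")
  expect_identical(el$error_type, "FP")
  expect_match(el$evidence, "affirmed")
  # perfect predictions -> empty listing
  expect_identical(nrow(error_listing(gold, gold, fx)), 0L)
  # an artificial FN is listed as such
  flipped <- gold
  flipped["gf01"] <- "control"
  el2 <- error_listing(flipped, gold, fx)
  expect_identical(el2$error_type, "FN")
})
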