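# aaanlp

Rule-based clinical NLP for extracting **abdominal aortic aneurysm (AAA)
diagnoses from free-text radiology reports**, for EHR phenotyping,
case-finding and near real-time surveillance pipelines. Given a report, the
package answers one question — *does this report assert a present AAA?* —
and backs it with an auditable chain of evidence.

The pipeline is a deterministic rule cascade:

1. **Sectionizer** — detects named sections (exam type, reason for exam,
   referral diagnosis, findings, impression, signed by) and processes only
   the narrative ones (*findings*, *impression*).
2. **Concept matcher** — lexicon-based matching of AAA surface forms
   ("abdominal aortic aneurysm", "infrarenal aortic aneurysm", the acronym
   "AAA"), token-level, leftmost-longest, word-order and inflection
   tolerant.
3. **Assertion classifier** — ConText-style negation detection with a
   6-token scope, terminator phrases, and *pseudo-negation masking* so that
   "no significant interval change of the known AAA" is (correctly) an
   affirmed, stable aneurysm.
4. **Measurement extraction** — "5.2 cm", "56 mm", "5.7×5.1 cm" parsed and
   normalized to cm; an optional strict mode gates case verdicts on the
   clinical criterion (maximal diameter ≥ 3 cm), OFF by default.
5. **Document classifier** — case iff ≥ 1 affirmed mention in a processable
   section; any-positive rollup to patients.
6. **Evaluation** — confusion matrices and the standard metric suite:
   sensitivity TP/(TP+FN), PPV TP/(TP+FP), specificity TN/(TN+FP),
   accuracy, F1 = 2·(PPV·sens)/(PPV+sens) computed from unrounded inputs,
   plus Cohen's kappa.
7. **Synthetic corpus generator** — template-grammar radiology reports with
   exact gold labels, so every stage is testable without clinical data.

## Worked example

```r
library(aaanlp)

report <- radiology_report("r1", paste0(
  "EXAM TYPE: US abdomen complete\n",
  "REASON FOR EXAM: Pulsatile abdominal mass.\n",
  "FINDINGS:\n",
  "Suprarenal aortic abdominal aneurysm which measures up to 5.2 cm. ",
  "No free fluid in the abdomen.\n",
  "IMPRESSION:\n1. Abdominal aortic aneurysm as described.\n",
  "SIGNED BY: Physician, M.D."))

classify_report(report)
#> <aaa_document_label> r1 -> case (2 affirmed of 2 mentions)
```

The verdict is `case` because two affirmed mentions sit in processable
sections; the annotation table (`annotate_report(report)$mentions`) shows
each mention's surface, section, assertion and the 5.2 cm linked diameter.
A negated report stays a control:

```r
ctrl <- radiology_report("r2",
  "FINDINGS:\nNegative for abdominal aortic aneurysm or dissection.")
classify_report(ctrl)
#> <aaa_document_label> r2 -> control (0 affirmed of 1 mentions)
```

Evaluation against reference labels:

```r
fx   <- golden_fixture()                      # 12 frozen hand-labeled reports
pred <- process_corpus(fx)
cm   <- confusion_matrix(label_set(pred$report_id, pred$label), gold_labels(fx))
print(cm)
#> <aaa_confusion>  TP: 6  FN: 0  FP: 1  TN: 5  total: 12
compute_metrics(cm)
#> Performance metrics (n = 12)
#>   Sensitivity 1.00
#>   PPV         0.86
#>   Specificity 0.83
#>   F1 score    0.92
#>   Accuracy    0.92
```

The one false positive is the fixture's sub-threshold "typo" report (an
aorta of 2.7 cm textually labeled as AAA) — by design, since the default
pipeline does not interpret diameters. Strict mode suppresses it:

```r
pred_s <- process_corpus(fx, aaa_config(strict_diameter = TRUE))
sum(pred_s$label == "case")   # 6, and specificity rises to 1.00
```

Synthetic corpora for testing:

```r
corpus <- generate_corpus(generator_config(n_reports = 120, seed = 1))
table(vapply(corpus, function(r) r$gold_label, character(1)))
```

## Command line

A thin front end over the same functions ships at `inst/cli/aaa-nlp`
(subcommands `process`, `stream`, `evaluate`, `generate`; JSONL in/out, TSV
labels, per-document flush in stream mode):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","aaa-nlp",package="aaanlp"))')" \
  generate --output corpus.jsonl --gold gold.tsv --n 120 --seed 1
```

## Configuration

The lexicon, trigger set and section policy ship as editable plain-text
config in `inst/extdata/` (`lexicon.tsv`, `triggers.conf`,
`sections.conf`) with readers `read_lexicon()`, `read_triggers()`,
`read_section_policy()`. See the methods vignette
(`vignettes/aaa-nlp-methods.Rmd`) for the design rationale, parameter
semantics and known limitations.
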