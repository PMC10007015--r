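---
title: "Methods: rule-based AAA extraction from radiology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based AAA extraction from radiology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaanlp)
```

## The problem

Radiology reports describe abdominal aortic aneurysms (AAA) in free text:
"Fusiform infrarenal abdominal aortic aneurysm ... 56 mm", "Negative for
abdominal aortic aneurysm or dissection", "No significant interval change of
the known AAA". A surveillance or phenotyping system needs a report-level
verdict — AAA case or control — extracted deterministically and fast enough
to run per document as reports are released. `aaanlp` implements this as a
transparent rule cascade. Every stage is configuration-driven and
deterministic; all randomness in the package lives in the synthetic corpus
generator.

## Pipeline

1. **Sectionizing.** Headers are detected at line start, case-insensitively,
   with an optional trailing colon, either on their own line or followed by
   inline body text. Header names are normalized (lower-case, whitespace
   collapsed, trailing colon stripped) and mapped through a synonym table
   ("impressions" → "impression"). Only *findings* and *impression* are
   processed by default; *exam type*, *reason for exam*, *referral
   diagnosis* and *signed by* are excluded, and unknown headers default to
   excluded because the processable set is enumerated positively. Detection
   by header *name* rather than positional section IDs is deliberate: names
   are the robust signal across report layouts. Text before the first
   recognized header becomes a `preamble` section (excluded by default), so
   unstructured input degrades gracefully rather than failing.

2. **Sentences and tokens.** Sentences split at terminal punctuation
   followed by whitespace and a capital or digit, never between digits
   (decimal points and dimension products survive), and at line breaks.
   Tokens are decimal numbers, alphanumeric runs, or single punctuation
   marks.

3. **Concept matching.** The lexicon ships with five multi-word AAA terms in
   UMLS-normalized word order plus the bare acronym. Multi-word entries are
   matched as *normalized token bags* over contiguous token windows: tokens
   are lower-cased and inflection-mapped (aortic → aorta, aneurysms →
   aneurysm) and a window matches when its bag equals an entry's bag. This
   is how normalized-lexicon matchers behave in practice and is what lets
   "aortic abdominal aneurysm", "abdominal aortic aneurysm" and "abdominal
   aortic aneurysms" all resolve to the same concept without enumerating
   every permutation in the config file. The acronym "AAA" is matched
   case-sensitively as a standalone token — lower-case "aaa" inside
   ordinary words or strings must not fire. Overlapping candidates are
   resolved leftmost-longest, the standard lexicon-matching convention, so
   mentions never overlap.

4. **Assertion.** Each mention is affirmed or negated from sentence-level
   cues in the ConText style. A pre-negation trigger ("negative for", "no",
   "without", ...) negates a mention up to 6 tokens downstream; a
   post-negation trigger ("is absent", "not seen", ...) negates up to 6
   tokens upstream; a terminator ("but", ";", "of the known", ...) in the
   gap blocks the scope. Six tokens is the conventional ConText window; the
   scope is bounded to the sentence. **Pseudo-negation masking runs first**:
   phrases such as "no significant interval change", "no signs of rupture"
   or "no slightly increased size" contain a negative word but assert a
   *present, stable* aneurysm. Tokens covered by a pseudo-negation phrase
   can serve neither as trigger nor as terminator. These constructions are
   exactly the documented failure mode of naive negation rules on
   surveillance reports, and masking them is the package's corrective
   design choice. Affirmed is the default: hedged language ("possible AAA")
   counts as affirmed, since the labeling scheme is binary. The full trigger
   inventory is editable config (`inst/extdata/triggers.conf`); the shipped
   set is seeded from the canonical example spans plus standard
   ConText-style cues, because no complete inventory is published for this
   task.

5. **Measurements (optional gating).** Dimension expressions — `5.2 cm`,
   `56 mm`, `5.7×5.1 cm`, `42×40 mm`, with `×` or `x` and arbitrary
   spacing — are parsed, mm divided by 10 exactly, and linked to the
   nearest mention in the sentence by character distance. The diameter of a
   product expression is the maximum dimension (clinical convention for
   aneurysm sizing). **Strict diameter mode is OFF by default**: the base
   algorithm does not interpret the reported diameter, and a report whose
   only evidence is "aorta of 2.7 cm labeled as AAA" is therefore
   (deliberately) a false positive in default mode. Enabling
   `strict_diameter` requires any *measured* mention to meet the ≥ 3 cm
   criterion (unmeasured mentions still qualify), which can only move
   verdicts from case to control — a monotonicity the tests assert.

6. **Classification.** A report is a case iff at least one qualifying
   affirmed mention occurs in a processable section; otherwise control
   ("no evidence of AAA" — existential case logic, so a report with both
   affirmed and negated mentions is a case). Patient-level rollup is
   any-positive, the sensitive choice for surveillance; with per-patient
   report sets that never disagree, any/all rules coincide.

## Evaluation suite

`confusion_matrix()` treats *case* as the positive class;
`compute_metrics()` derives sensitivity, PPV, specificity, accuracy and
F1 = 2·(PPV·sens)/(PPV+sens). F1 is computed from **unrounded** PPV and
sensitivity — rounding first distorts it (e.g. counts TP 59 / FP 1 / TN 57 /
FN 3 give F1 0.967 → 0.97, but 2/(1/0.98 + 1/0.95) rounds to 0.96). Display
rounding is half-up at 2 decimals; full precision is kept internally. A
metric with a zero denominator is reported as undefined (`NA`), never as a
silent zero. `cohen_kappa()` uses marginal-product expected agreement and
defines the doubly-degenerate identical-single-class case as 1.0.

## Synthetic corpus generator

Template-grammar generation, not language-model text: gold labels must be
exact by construction. Each report gets the six-section layout; case reports
embed one affirmed AAA sentence drawn from templates spanning all five
lexicon surface forms; control reports draw benign-findings distractors and,
with configurable probability, a *negated* AAA sentence. Roughly 30% of
reports of either class mention AAA in the reason-for-exam section, so the
section policy is exercised end to end.

Defaults (chosen once, from the study conditions the package emulates):

| parameter | default | rationale |
|---|---|---|
| `n_reports` | 120 | one validation-iteration batch |
| `prevalence` | 0.5 | validation batches were near-balanced |
| `pseudo_negation_rate` | 0.05 | ≈ 3 of 62 case reports phrased this way |
| `subthreshold_rate` | 0.01 | ≈ 1 "typo" report per 120 |
| `measurement_rate` | 0.7 | most case sentences carry a dimension |
| `mm_unit_rate` | 0.25 | mm is the minority unit in practice |
| diameter | trunc. normal, mean 4.9, sd 1.2, ≥ 3 cm | printed case-diameter statistics |

Generation is a pure function of the seed and restores the caller's RNG
state. What the generator does *not* emulate: typos and OCR noise, header
variants beyond the synonym table, hedged or historical language, thoracic
and iliac aneurysms, multi-aneurysm reports. Perfect scores on clean
synthetic corpora therefore demonstrate internal consistency — that the
pipeline inverts its own generator's grammar — not clinical-grade accuracy
on real reports.

`golden_fixture()` freezes 12 hand-written reports embedding the canonical
example spans (three confirmatory, three negated), the three pseudo-negation
constructions, one sub-threshold typo report (gold control; a designed false
positive in default mode, suppressed in strict mode), one benign control and
one control whose only mention sits in an excluded section.

## Numerical and convention choices

* Character spans are 1-based inclusive throughout, the natural R
  convention: `substr(text, start, end)` on any stored span reproduces the
  stored text. Sections tile the raw text; sentences tile the non-whitespace
  of a body; token spans tile a sentence.
* mm → cm conversion is a single division by 10; `56 mm` compares equal to
  `5.6`.
* `×` (U+00D7) and ASCII `x` are interchangeable in dimension products.
* Ties between overlapping lexicon candidates: leftmost, then longest.
* Several measurements linked to one mention: the largest governs strict
  gating.
* Degenerate inputs: empty text → one empty verdict chain → control;
  unrecognized structure → single excluded preamble; empty label sets
  round-trip; zero-denominator metrics are undefined.

## Test design and problem sizes

The negation classifier is verified against a brute-force oracle that
enumerates every trigger/terminator occurrence by naive token-subsequence
comparison on randomly generated ≤ 8-token sentences (400 + 300 cases, fixed
seeds). End-to-end separability is checked on a 2000-report synthetic corpus;
the masking ablation on 400 reports with `pseudo_negation_rate = 0.3`; the
F1 identity on 1000 random multinomial confusion matrices; the diameter
distribution against the closed-form truncated-normal mean at n = 2000.
These sizes keep the full suite under a few minutes on one CPU while leaving
the binomial and law-of-large-numbers checks well-powered.

## Known limitations

* The trigger inventory and lexicon are seeds, not complete inventories;
  real deployments must extend both from their own corpus.
* Assertion is binary; hypothetical, historical and experiencer dimensions
  are out of scope, as are machine-learned assertion models.
* Post-repair aortas are cases iff an affirmed AAA mention appears; the
  package does not model repair status.
* "previously 56 mm" contributes a measurement and links by proximity; prior
  studies are not modeled as separate events.
* Only abdominal aortic aneurysms: thoracic/iliac aneurysm phrases are not
  in the lexicon and "Negative for thoracic or abdominal aortic aneurysm"
  yields a single (abdominal) mention.
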