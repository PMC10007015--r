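#' Configuration for the synthetic report generator
#'
#' Defaults mirror one validation set of the study design this pipeline is
#' built for: 120 reports with roughly balanced case prevalence, case
#' diameters drawn from a truncated normal (mean 4.9 cm, sd 1.2 cm, floored
#' at the 3 cm criterion), a small fraction of case reports phrased with
#' pseudo-negation ("no significant change of the known AAA..."), and a
#' ~1 percent rate of sub-threshold "mislabeled" sentences that exercise
#' strict diameter mode.
#'
#' @param n_reports Number of reports.
#' @param prevalence Probability a report is a case.
#' @param negated_distractor_rate Probability a control report carries a
#'   negated AAA sentence.
#' @param pseudo_negation_rate Probability a case report phrases its AAA
#'   sentence with a pseudo-negation construction (still a gold case).
#' @param measurement_rate Probability a case sentence carries a dimension
#'   string.
#' @param mm_unit_rate Probability a dimension is written in mm.
#' @param diameter_range_cm Length-2 numeric, truncation bounds for case
#'   diameters in cm.
#' @param diameter_mean_cm,diameter_sd_cm Parameters of the (truncated)
#'   normal diameter distribution.
#' @param subthreshold_rate Probability a control report contains an affirmed
#'   AAA sentence with a sub-threshold diameter (a "typo" report: gold
#'   control, but textual evidence of AAA).
#' @param seed Integer seed; generation is a pure function of the seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_reports = 120L, prevalence = 0.5,
                             negated_distractor_rate = 0.3,
                             pseudo_negation_rate = 0.05,
                             measurement_rate = 0.7, mm_unit_rate = 0.25,
                             diameter_range_cm = c(3.0, 9.0),
                             diameter_mean_cm = 4.9, diameter_sd_cm = 1.2,
                             subthreshold_rate = 0.01, seed = 1L) {
  probs <- c(prevalence, negated_distractor_rate, pseudo_negation_rate,
             measurement_rate, mm_unit_rate, subthreshold_rate)
  if (any(probs < 0 | probs > 1)) stop("rates must lie in [0, 1]")
  if (n_reports < 0) stop("n_reports must be >= 0")
  if (length(diameter_range_cm) != 2L ||
      diameter_range_cm[1] >= diameter_range_cm[2]) {
    stop("diameter_range_cm must be (low, high) with low < high")
  }
  structure(list(n_reports = as.integer(n_reports), prevalence = prevalence,
                 negated_distractor_rate = negated_distractor_rate,
                 pseudo_negation_rate = pseudo_negation_rate,
                 measurement_rate = measurement_rate,
                 mm_unit_rate = mm_unit_rate,
                 diameter_range_cm = diameter_range_cm,
                 diameter_mean_cm = diameter_mean_cm,
                 diameter_sd_cm = diameter_sd_cm,
                 subthreshold_rate = subthreshold_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

.exam_types <- c(
  "CT abdomen pelvis without IV contrast",
  "CT chest abdomen pelvis angiogram with IV contrast",
  "US abdomen complete",
  "US aorta iliac arteries bilateral with doppler",
  "MRI abdomen with and without IV contrast",
  "MRI pelvis with and without IV contrast"
)

.benign_findings <- c(
  "The liver is normal in size and echotexture.",
  "The kidneys are unremarkable without hydronephrosis.",
  "The spleen and pancreas are unremarkable.",
  "The visualized aorta is normal in caliber.",
  "The gallbladder is unremarkable without cholelithiasis.",
  "No free fluid in the abdomen or pelvis.",
  "Mild atherosclerotic calcification of the iliac arteries.",
  "The urinary bladder is unremarkable."
)

.negated_aaa <- c(
  "Negative for abdominal aortic aneurysm or dissection.",
  "Abdominal aortic aneurysm is absent.",
  "No evidence of abdominal aortic aneurysm.",
  "Negative for thoracic or abdominal aortic aneurysm, dissection, penetrating atherosclerotic ulcer or intramural hematoma."
)

# affirmed case templates span all five lexicon surface forms; {DIM}
# optionally carries the dimension string
.case_templates <- c(
  "Suprarenal aortic abdominal aneurysm which measures up to {DIM}.",
  "Fusiform infrarenal abdominal aortic aneurysm terminating proximal to the aortobiiliac bifurcation, {DIM}.",
  "There is a {DIM} infrarenal aortic aneurysm measured on image 175 of series 4.",
  "Partially thrombosed infrarenal AAA measuring {DIM}.",
  "Stable appearance of the known aneurysm abdominal aorta, {DIM}.",
  "Saccular aortic aneurysm abdominal in location, {DIM}."
)
.case_templates_nodim <- c(
  "Fusiform infrarenal abdominal aortic aneurysm is again demonstrated.",
  "There is an infrarenal aortic aneurysm with mural thrombus.",
  "Known infrarenal AAA, unchanged in configuration.",
  "Ectatic vessel with aortic abdominal aneurysm noted."
)

# pseudo-negation phrasings of a present aneurysm (gold = case); the first
# two fall under pre-negation scope once masking is disabled
.pseudo_templates <- c(
  "No significant change of the infrarenal AAA measuring {DIM}.",
  "No interval change of the fusiform infrarenal AAA.",
  "No signs of rupture or impending rupture of the known infrarenal AAA."
)

.subthreshold_templates <- c(
  "Infrarenal AAA measuring {DIM}.",
  "There is a {DIM} infrarenal aortic aneurysm."
)

# truncated-normal sampler (rejection; bounds are a few sd from the mean)
.rtruncnorm <- function(n, mean, sd, low, high) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= low & x <= high])
  }
  out[seq_len(n)]
}

.format_dim <- function(d_cm, use_mm, two_dims) {
  if (two_dims) {
    d2 <- max(0.5, d_cm - stats::runif(1, 0.1, 0.8))
    if (use_mm) sprintf("%d×%d mm", round(d_cm * 10), round(d2 * 10))
    else sprintf("%.1f×%.1f cm", d_cm, d2)
  } else {
    if (use_mm) sprintf("%d mm", round(d_cm * 10))
    else sprintf("%.1f cm", d_cm)
  }
}

#' Generate a synthetic labeled radiology-report corpus
#'
#' Template-grammar generation: each report has the six-section layout (exam
#' type, reason for exam, referral diagnosis, findings, impression, signed
#' by); case reports contain at least one affirmed AAA sentence drawn from a
#' template pool spanning all five lexicon surface forms; control reports
#' contain benign findings, optionally a negated AAA distractor, and (rarely)
#' an affirmed sub-threshold "typo" sentence. Some reports of either class
#' mention AAA in the reason-for-exam section, which the section policy must
#' screen out. Gold labels are exact by construction. Generation is a pure
#' function of `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List of [radiology_report()] objects with gold labels.
#' @export
#' @examples
#' corpus <- generate_corpus(generator_config(n_reports = 4, seed = 42))
#' vapply(corpus, function(r) r$gold_label, character(1))
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  lapply(seq_len(config$n_reports), function(i) {
    id <- sprintf("syn%05d", i)
    patient <- sprintf("pt%05d", stats::rbinom(1, 1e5, 0.5))
    is_case <- stats::runif(1) < config$prevalence
    exam <- sample(.exam_types, 1)

    reason <- if (stats::runif(1) < 0.3) {
      "Surveillance of known abdominal aortic aneurysm."
    } else {
      sample(c("Abdominal pain.", "Follow-up of renal cyst.",
               "Evaluation of pulsatile abdominal mass.",
               "Routine screening examination."), 1)
    }
    referral <- sample(c("Hypertension.", "Peripheral artery disease.",
                         "Abdominal aortic aneurysm surveillance.",
                         "Tobacco use disorder."), 1)

    findings <- sample(.benign_findings, sample(2:4, 1))
    impression <- character(0)

    if (is_case) {
      pseudo <- stats::runif(1) < config$pseudo_negation_rate
      with_dim <- stats::runif(1) < config$measurement_rate
      dim_str <- .format_dim(
        .rtruncnorm(1, config$diameter_mean_cm, config$diameter_sd_cm,
                    config$diameter_range_cm[1], config$diameter_range_cm[2]),
        use_mm = stats::runif(1) < config$mm_unit_rate,
        two_dims = stats::runif(1) < 0.4)
      sent <- if (pseudo) {
        sample(.pseudo_templates, 1)
      } else if (with_dim) {
        sample(.case_templates, 1)
      } else {
        sample(.case_templates_nodim, 1)
      }
      sent <- gsub("{DIM}", dim_str, sent, fixed = TRUE)
      findings <- append(findings, sent, after = sample(0:length(findings), 1))
      # pseudo-negation reports keep a neutral impression so the pseudo
      # sentence is the only case evidence (the failure mode under study)
      impression <- if (pseudo) "1. See findings." else
        "1. Abdominal aortic aneurysm as described above."
      label <- "case"
    } else {
      if (stats::runif(1) < config$negated_distractor_rate) {
        findings <- append(findings, sample(.negated_aaa, 1),
                           after = sample(0:length(findings), 1))
      }
      if (stats::runif(1) < config$subthreshold_rate) {
        d <- stats::runif(1, 2.2, 2.9)
        sent <- gsub("{DIM}", .format_dim(d, use_mm = FALSE, two_dims = FALSE),
                     sample(.subthreshold_templates, 1), fixed = TRUE)
        findings <- c(findings, sent)
      }
      impression <- sample(c("1. No acute abdominal abnormality.",
                             "1. Unremarkable examination."), 1)
      label <- "control"
    }

    text <- paste0(
      "EXAM TYPE: ", exam, "\n",
      "REASON FOR EXAM: ", reason, "\n",
      "REFERRAL DIAGNOSIS: ", referral, "\n",
      "FINDINGS:\n", paste(findings, collapse = " "), "\n",
      "IMPRESSION:\n", paste(impression, collapse = " "), "\n",
      "SIGNED BY: Physician, M.D.")
    radiology_report(id, text, exam_type = exam, patient_id = patient,
                     gold_label = label)
  })
}

#' A frozen 12-report regression corpus
#'
#' Hand-written reports embedding the canonical assertion examples (three
#' confirmatory spans, three negated spans), the three pseudo-negation
#' constructions known to defeat naive negation rules, one sub-threshold
#' "typo" report (an aorta of 2.7 cm textually labeled as AAA: gold control,
#' but affirmed in the text — the pipeline's designed false positive in
#' default mode, correctly suppressed in strict diameter mode), one benign
#' control, and one control whose only AAA mention sits in an excluded
#' section. Gold labels are hand-assigned.
#'
#' @return List of 12 [radiology_report()] objects.
#' @export
golden_fixture <- function() {
  wrap <- function(id, findings, impression = "1. See findings.",
                   reason = "Abdominal imaging.", gold = NA_character_) {
    radiology_report(
      id,
      paste0("EXAM TYPE: CT abdomen pelvis without IV contrast\n",
             "REASON FOR EXAM: ", reason, "\n",
             "REFERRAL DIAGNOSIS: Abdominal pain.\n",
             "FINDINGS:\n", findings, "\n",
             "IMPRESSION:\n", impression, "\n",
             "SIGNED BY: Physician, M.D."),
      exam_type = "CT abdomen pelvis without IV contrast",
      gold_label = gold)
  }
  list(
    wrap("gf01", "Suprarenal aortic abdominal aneurysm which measures up to 5.2 cm.",
         gold = "case"),
    wrap("gf02", "Fusiform infrarenal abdominal aortic aneurysm terminating proximal to the aortobiiliac bifurcation, 56 mm, previously 56 mm.",
         gold = "case"),
    wrap("gf03", "There is a 5.7×5.1 cm infrarenal aortic aneurysm measured on image 175 of series 4.",
         gold = "case"),
    wrap("gf04", "Negative for abdominal aortic aneurysm or dissection.",
         impression = "1. No acute abdominal abnormality.", gold = "control"),
    wrap("gf05", "Abdominal aortic aneurysm is absent.",
         impression = "1. Unremarkable examination.", gold = "control"),
    wrap("gf06", "Negative for thoracic or abdominal aortic aneurysm, dissection, penetrating atherosclerotic ulcer or intramural hematoma.",
         impression = "1. No acute abnormality.", gold = "control"),
    wrap("gf07", "No significant interval changes in appearances of a partially thrombosed infrarenal AAA measuring 42×40 mm, extending to the level of the aortic bifurcation and proximal common iliac arteries.",
         gold = "case"),
    wrap("gf08", "No signs of rupture or impending rupture of the known infrarenal AAA.",
         gold = "case"),
    wrap("gf09", "No slightly increased size of fusiform infrarenal AAA.",
         gold = "case"),
    wrap("gf10", "Infrarenal AAA measuring 2.7 cm.",
         impression = "1. Ectatic infrarenal aorta.", gold = "control"),
    wrap("gf11", "The liver, kidneys and spleen are unremarkable. The visualized aorta is normal in caliber.",
         impression = "1. Unremarkable examination.", gold = "control"),
    wrap("gf12", "The liver is normal in size. No free fluid in the abdomen.",
         impression = "1. No acute abnormality.",
         reason = "Surveillance of known abdominal aortic aneurysm.",
         gold = "control")
  )
}
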