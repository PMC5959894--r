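# Candidate-mart inclusion filters and the empirical case-definition
# rules used for reference labeling.
#
# The candidate mart is deliberately over-inclusive: any insomnia billing
# code, any insomnia-only medication, or any note merely mentioning
# "sleep"/"insomnia" admits a patient, provided the record is substantive
# (at least two notes of 500+ characters by default). The empirical case
# rules are the stricter definition used to label physician-documented
# insomnia: any one criterion suffices.

#' Candidate-mart inclusion test
#'
#' A patient enters the candidate mart when at least one of three broad
#' screens fires — an insomnia-related billing code, an insomnia
#' medication prescription, or a note containing a sleep-related keyword —
#' and the record holds at least `min_qualifying_notes` notes of
#' `min_note_chars` characters or more.
#'
#' @param patient A `patient_record`.
#' @param vocab A `vocabulary_config`.
#' @return Logical scalar with attribute `reasons`: a named logical vector
#'   over `code`, `medication`, `keyword_note`, `note_count`.
#' @export
in_candidate_mart <- function(patient, vocab = default_vocabulary()) {
  has_code <- count_codes(patient, vocab$insomnia_codes) >= 1L
  has_med <- count_prescriptions(patient, vocab$insomnia_medications) >= 1L
  kw <- tolower(vocab$candidate_keywords)
  has_kw <- nrow(patient$notes) > 0L &&
    any(vapply(tolower(patient$notes$text),
               function(tx) any(vapply(kw, grepl, logical(1), x = tx,
                                       fixed = TRUE)),
               logical(1)))
  n_long <- sum(nchar(patient$notes$text) >= vocab$min_note_chars)
  note_ok <- n_long >= vocab$min_qualifying_notes
  included <- (has_code || has_med || has_kw) && note_ok
  structure(included,
            reasons = c(code = has_code, medication = has_med,
                        keyword_note = has_kw, note_count = note_ok))
}

#' Empirical case rules for physician-documented insomnia
#'
#' An automated rendering of the study's empirical case definition, used
#' here as the reference labeler for synthetic corpora: a patient is a
#' case when any one of three criteria holds — an insomnia billing code,
#' a prescription for a medication indicated only for insomnia, or a note
#' containing a sleep-disorder expression. It approximates, but does not
#' reproduce, manual chart review.
#'
#' @param patient A `patient_record`.
#' @param vocab A `vocabulary_config`.
#' @return `"insomnia"` or `"no_insomnia"`.
#' @export
empirical_case_rules <- function(patient, vocab = default_vocabulary()) {
  if (count_codes(patient, vocab$insomnia_codes) >= 1L ||
      count_prescriptions(patient, vocab$insomnia_medications) >= 1L ||
      count_indicator_notes(patient, vocab$sleep_expressions,
                            vocab$min_note_chars) >= 1L)
    "insomnia"
  else
    "no_insomnia"
}

#' Exclude patients younger than 18 at end of follow-up
#'
#' Age is evaluated at death, or at the study end date for patients alive
#' then; patients under 18 at that point are removed. The boundary is
#' inclusive: a patient who turns exactly 18 on the evaluation day is
#' retained. Exact-day arithmetic; patients with no parseable birth date
#' are excluded with a warning.
#'
#' @param corpus An `emr_corpus` or list of `patient_record`s.
#' @param labels Optional data frame with `patient_id` column, filtered in
#'   step with the corpus.
#' @param study_end Study end date (default `"2010-12-31"`).
#' @return List with `corpus` (filtered), `labels` (filtered or `NULL`),
#'   and `excluded_ids`.
#' @export
apply_age_exclusion <- function(corpus, labels = NULL,
                                study_end = as.Date("2010-12-31")) {
  study_end <- as.Date(study_end)
  keep <- vapply(corpus, function(p) {
    if (is.na(p$birth_date)) {
      warning("patient '", p$patient_id, "' lacks a birth_date; excluded")
      return(FALSE)
    }
    eval_date <- if (!is.na(p$death_date)) min(p$death_date, study_end)
                 else study_end
    # 18th-birthday comparison avoids leap-day off-by-ones from day counts
    eighteenth <- seq(p$birth_date, by = "18 years", length.out = 2)[2]
    eval_date >= eighteenth
  }, logical(1))
  kept <- structure(corpus[keep], class = "emr_corpus")
  excluded <- vapply(corpus[!keep], function(p) p$patient_id, character(1))
  if (!is.null(labels))
    labels <- labels[!(labels$patient_id %in% excluded), , drop = FALSE]
  list(corpus = kept, labels = labels, excluded_ids = unname(excluded))
}
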