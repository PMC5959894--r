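# The seven model covariates, computed per patient from structured events
# and note text via fixed-expression matching.
#
# Matching is deliberately literal: case-insensitive substring search
# after whitespace normalization, with no stemming and no negation-scope
# detection. The expression lists were curated upstream to be non-negated
# descriptors, so a match is taken at face value; phrases such as
# "patient sleeps well" contain the candidate keyword "sleep" but none of
# the disorder expressions, and therefore never contribute to the
# sleep-note covariate.

normalize_ws <- function(text) {
  gsub("[[:space:]]+", " ", text)
}

#' Match a list of expressions inside free text
#'
#' Case-insensitive literal substring search after whitespace
#' normalization (runs of whitespace collapse to a single space). All
#' matches of all expressions are returned, including overlaps between
#' distinct expressions; offsets index the start of the match in the
#' normalized text (1-based).
#'
#' @param text A single character string (may be empty).
#' @param expressions Non-empty character vector of expressions.
#' @return Data frame with columns `expression`, `offset`, ordered by
#'   offset then by expression-list position.
#' @export
match_expressions <- function(text, expressions) {
  stopifnot(is.character(expressions), length(expressions) >= 1L)
  if (length(text) != 1L) stop("text must be a single string")
  if (is.na(text) || !nzchar(text))
    return(data.frame(expression = character(0), offset = integer(0)))
  norm <- tolower(normalize_ws(text))
  hits <- lapply(seq_along(expressions), function(i) {
    ex <- tolower(normalize_ws(expressions[[i]]))
    m <- gregexpr(ex, norm, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(expression = expressions[[i]], offset = as.integer(m),
               .rank = i)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(expression = character(0), offset = integer(0)))
  out <- out[order(out$offset, out$.rank), c("expression", "offset")]
  rownames(out) <- NULL
  out
}

#' Count a patient's notes containing at least one expression
#'
#' Note-level, not mention-level: a note containing several matches (or
#' the same expression repeatedly) counts once. Notes shorter than
#' `min_chars` are ignored.
#'
#' @param patient A `patient_record`.
#' @param expressions Character vector of expressions.
#' @param min_chars Minimum note length in characters (default 0).
#' @return Integer count of qualifying indicator notes.
#' @export
count_indicator_notes <- function(patient, expressions, min_chars = 0L) {
  stopifnot(min_chars >= 0L)
  notes <- patient$notes
  if (nrow(notes) == 0L) return(0L)
  keep <- nchar(notes$text) >= min_chars
  if (!any(keep)) return(0L)
  sum(vapply(notes$text[keep],
             function(tx) nrow(match_expressions(tx, expressions)) > 0L,
             logical(1)))
}

#' Count a patient's coded events falling in an ICD-9 code set
#'
#' Counts dated occurrences, not distinct codes: the same code billed at
#' three encounters contributes three.
#'
#' @param patient A `patient_record`.
#' @param code_set Character vector of ICD-9 codes; a trailing `*` marks a
#'   prefix wildcard.
#' @return Integer count.
#' @export
count_codes <- function(patient, code_set) {
  stopifnot(length(code_set) >= 1L)
  sum(codes_in_set(patient$coded_events$code, code_set))
}

#' Count a patient's prescriptions for listed medications
#'
#' A prescription matches when its name equals any listed brand or generic
#' variant, case-insensitively after trimming. Drugs whose secondary use
#' can help with sleep (e.g. trazodone) are deliberately absent from the
#' default list, which holds only medications indicated solely for
#' insomnia.
#'
#' @param patient A `patient_record`.
#' @param medications Character vector of medication name variants.
#' @return Integer count.
#' @export
count_prescriptions <- function(patient, medications) {
  stopifnot(length(medications) >= 1L)
  meds <- tolower(trimws(medications))
  sum(tolower(trimws(patient$prescriptions$medication_name)) %in% meds)
}

#' Count a patient's EMR facts
#'
#' The utilization-proxy covariate: the total number of data entries
#' attached to the patient, regardless of vocabulary membership. In this
#' data model that is all coded events plus all prescriptions plus all
#' notes; richer records (labs, visits) would extend the tally, so the
#' formula is a documented convention rather than a fixed truth.
#'
#' @param patient A `patient_record`.
#' @return Integer count.
#' @export
count_emr_facts <- function(patient) {
  nrow(patient$coded_events) + nrow(patient$prescriptions) + nrow(patient$notes)
}

#' Extract the seven model covariates for one patient
#'
#' @param patient A `patient_record`.
#' @param vocab A `vocabulary_config` (default [default_vocabulary()]).
#' @return Named integer vector over the seven covariates, in canonical
#'   order.
#' @export
extract_features <- function(patient, vocab = default_vocabulary()) {
  stopifnot(inherits(patient, "patient_record"),
            inherits(vocab, "vocabulary_config"))
  fv <- c(
    n_sleep_notes = count_indicator_notes(patient, vocab$sleep_expressions,
                                          vocab$min_note_chars),
    n_insomnia_codes = count_codes(patient, vocab$insomnia_codes),
    n_anxdep_codes = count_codes(patient, vocab$anxdep_codes),
    n_psych_notes = count_indicator_notes(patient, vocab$psych_expressions,
                                          vocab$min_note_chars),
    n_insomnia_rx = count_prescriptions(patient, vocab$insomnia_medications),
    n_joint_codes = count_codes(patient, vocab$joint_codes),
    n_emr_facts = count_emr_facts(patient))
  storage.mode(fv) <- "integer"
  fv
}

#' Extract features for every patient in a corpus
#'
#' @param corpus An `emr_corpus`.
#' @param vocab A `vocabulary_config`.
#' @return Data frame with `patient_id` and the seven covariate columns,
#'   one row per patient in corpus order.
#' @export
extract_features_corpus <- function(corpus, vocab = default_vocabulary()) {
  rows <- lapply(corpus, function(p) {
    fv <- extract_features(p, vocab)
    cbind(data.frame(patient_id = p$patient_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
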