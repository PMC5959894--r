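# Vocabulary configuration: the ICD-9 code sets, the insomnia-only
# medication list, and the text-expression lists that drive extraction.
#
# The insomnia code set, the sleep-disorder expression list, and the
# insomnia-only medication list are the published ones. The anxiety/
# depression, joint-disorder and psychiatric code sets and the psychiatric
# expression list were published only in supplementary material; the
# defaults below are clearly-marked placeholder sets chosen from standard
# ICD-9 groupings, and every set is overridable from a YAML/JSON config.

#' Default vocabulary configuration
#'
#' @param ... Named overrides for any field of the configuration (see
#'   Details).
#'
#' @details Fields: `insomnia_codes`, `anxdep_codes`, `joint_codes`,
#' `psych_codes` (character vectors of ICD-9 codes; a trailing `*` marks
#' an explicit prefix wildcard, otherwise comparison is exact after
#' trimming); `insomnia_medications` (brand and generic name variants,
#' matched case-insensitively); `sleep_expressions` and
#' `psych_expressions` (ordered expression lists matched as literal
#' substrings after whitespace normalization); `candidate_keywords`
#' (keywords for candidate-mart inclusion); `min_note_chars` (minimum note
#' length, default 500); `min_qualifying_notes` (minimum number of long
#' notes for mart inclusion, default 2).
#'
#' @return A list of class `vocabulary_config`.
#' @export
default_vocabulary <- function(...) {
  vocab <- list(
    insomnia_codes = c("307.41", "307.42", "327.00", "327.01",
                       "327.02", "327.09", "780.52"),
    # placeholder supplementary sets (common ICD-9 groupings), overridable
    anxdep_codes = c("300.00", "300.01", "300.02", "300.4",
                     "296.2*", "296.3*", "311"),
    joint_codes = c("715*", "716*", "719.4*"),
    psych_codes = c("295*", "296*", "298*", "300*", "309*", "311"),
    insomnia_medications = c(
      "Ambien", "Zolpidem", "Ambien CR", "Zolpidem CR",
      "Lunesta", "Eszopiclone", "Restoril", "Temazepam",
      "Sonata", "Zaleplon", "Dalmane", "Flurazepam",
      "ProSom", "Eurodin", "Estazolam"),
    sleep_expressions = c(
      "poor sleep", "has trouble sleep", "reduced sleep",
      "increased sleep", "decreased sleep", "excessive sleep",
      "fragmented sleep", "sleeplessness", "sleep disruption",
      "sleeps poorly"),
    # placeholder psychiatric descriptor list, overridable
    psych_expressions = c(
      "severe anxiety", "depressed mood", "panic attacks",
      "major depression", "psychiatric history", "bipolar disorder"),
    candidate_keywords = c("sleep", "insomnia"),
    min_note_chars = 500L,
    min_qualifying_notes = 2L)
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(vocab))
    if (length(bad)) stop("unknown vocabulary field(s): ", paste(bad, collapse = ", "))
    vocab[names(overrides)] <- overrides
  }
  validate_vocabulary(vocab)
}

validate_vocabulary <- function(vocab) {
  setfields <- c("insomnia_codes", "anxdep_codes", "joint_codes", "psych_codes",
                 "insomnia_medications", "sleep_expressions",
                 "psych_expressions", "candidate_keywords")
  for (nm in setfields) {
    if (is.null(vocab[[nm]]) || length(vocab[[nm]]) == 0L)
      stop("vocabulary field ", nm, " must be non-empty")
    vocab[[nm]] <- as.character(vocab[[nm]])
  }
  vocab$min_note_chars <- as.integer(vocab$min_note_chars)
  vocab$min_qualifying_notes <- as.integer(vocab$min_qualifying_notes)
  if (vocab$min_note_chars < 0L) stop("min_note_chars must be >= 0")
  structure(vocab, class = "vocabulary_config")
}

#' Load a vocabulary configuration from YAML or JSON
#'
#' Fields absent from the file keep their defaults.
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `vocabulary_config`.
#' @export
load_vocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(default_vocabulary, doc)
}

#' @export
print.vocabulary_config <- function(x, ...) {
  cat("<vocabulary_config>\n")
  cat("  insomnia codes:", paste(x$insomnia_codes, collapse = " "), "\n")
  cat("  sleep expressions:", length(x$sleep_expressions),
      "| psych expressions:", length(x$psych_expressions), "\n")
  cat("  insomnia medications:", length(x$insomnia_medications), "variants\n")
  cat("  note filter: >=", x$min_qualifying_notes, "notes of >=",
      x$min_note_chars, "chars\n")
  invisible(x)
}

# Match a vector of ICD-9 codes against a code set with explicit trailing-*
# prefix wildcards; exact string comparison otherwise.
codes_in_set <- function(codes, code_set) {
  if (length(codes) == 0L) return(logical(0))
  codes <- trimws(codes)
  code_set <- trimws(code_set)
  wild <- endsWith(code_set, "*")
  hit <- codes %in% code_set[!wild]
  for (pfx in sub("\\*$", "", code_set[wild]))
    hit <- hit | startsWith(codes, pfx)
  hit
}
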