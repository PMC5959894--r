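# In-code fixtures shared across test files.

long_note <- function(core, n = 520L) {
  paste0(core, " ", paste(rep("Stable on current regimen.", 25), collapse = " "))
}

# A tiny hand-built patient: 3 insomnia codes, 1 anxiety code, 1 zolpidem
# prescription, one qualifying sleep-disorder note, one short note.
fixture_patient <- function(id = "PX01") {
  patient_record(
    patient_id = id, birth_date = "1960-05-04",
    coded_events = data.frame(
      code = c("780.52", "780.52", "327.00", "300.00"),
      date = c("2001-01-01", "2003-06-01", "2004-02-02", "2004-02-02")),
    prescriptions = data.frame(medication_name = "Zolpidem", date = "2002-03-03"),
    notes = data.frame(
      note_id = c("n1", "n2"),
      date = c("2001-01-01", "2001-02-01"),
      text = c(long_note("Patient reports poor sleep for months."),
               "short note")))
}

empty_patient <- function(id = "PE01") {
  patient_record(patient_id = id, birth_date = "1950-01-01")
}

# Brute-force oracle for expression matching: scan every offset of the
# normalized text and compare substrings directly.
match_oracle <- function(text, expressions) {
  norm <- tolower(gsub("[[:space:]]+", " ", text))
  out <- list()
  for (ex in expressions) {
    exn <- tolower(gsub("[[:space:]]+", " ", ex))
    w <- nchar(exn)
    if (w == 0L || w > nchar(norm)) next
    for (i in seq_len(nchar(norm) - w + 1L))
      if (substr(norm, i, i + w - 1L) == exn)
        out[[length(out) + 1L]] <- data.frame(expression = ex, offset = i)
  }
  if (!length(out)) return(data.frame(expression = character(0), offset = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$offset, match(df$expression, expressions)), , drop = FALSE]
}
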