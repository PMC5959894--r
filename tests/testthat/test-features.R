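vocab <- default_vocabulary()

test_that("expression matching is literal, case-insensitive, note-safe", {
  hits <- match_expressions("Patient reports poor sleep for months",
                            vocab$sleep_expressions)
  expect_identical(hits$expression, "poor sleep")
  # benign phrasing never matches a disorder expression
  expect_identical(nrow(match_expressions("patient sleeps well",
                                          vocab$sleep_expressions)), 0L)
  expect_identical(nrow(match_expressions("", vocab$sleep_expressions)), 0L)
  # whitespace runs collapse before matching
  hits <- match_expressions("poor\n   sleep", vocab$sleep_expressions)
  expect_identical(hits$expression, "poor sleep")
  expect_identical(hits$offset, 1L)
  # overlapping matches of distinct expressions are all returned
  hits <- match_expressions("notes increased sleeplessness",
                            c("increased sleep", "sleeplessness"))
  expect_setequal(hits$expression, c("increased sleep", "sleeplessness"))
})

test_that("expression matching agrees with a brute-force oracle", {
  set.seed(404)
  words <- c("sleep", "poor", "sleeps", "well", "poorly", "patient", "notes",
             "reduced", "fragmented", "x")
  for (i in 1:40) {
    txt <- paste(sample(words, sample(3:25, 1), replace = TRUE), collapse = " ")
    got <- match_expressions(txt, vocab$sleep_expressions)
    want <- match_oracle(txt, vocab$sleep_expressions)
    expect_identical(got$expression, want$expression)
    expect_identical(got$offset, as.integer(want$offset))
  }
})

test_that("sleep-note counting is note-level and honours the length filter", {
  p1 <- patient_record("a", "1960-01-01", notes = data.frame(
    note_id = "n1", date = "2000-01-01",
    text = long_note("poor sleep twice: poor sleep.")))
  expect_identical(count_indicator_notes(p1, vocab$sleep_expressions, 500L), 1L)
  p2 <- patient_record("b", "1960-01-01", notes = data.frame(
    note_id = c("n1", "n2"), date = rep("2000-01-01", 2),
    text = c(long_note("sleeplessness reported."),
             long_note("ongoing sleeplessness."))))
  expect_identical(count_indicator_notes(p2, vocab$sleep_expressions, 500L), 2L)
  # short notes are invisible at the default filter but count at 0
  p3 <- patient_record("c", "1960-01-01", notes = data.frame(
    note_id = "n1", date = "2000-01-01", text = "brief: poor sleep"))
  expect_identical(count_indicator_notes(p3, vocab$sleep_expressions, 500L), 0L)
  expect_identical(count_indicator_notes(p3, vocab$sleep_expressions, 0L), 1L)
  expect_identical(count_indicator_notes(empty_patient(),
                                         vocab$sleep_expressions, 500L), 0L)
})

test_that("code counting is per dated occurrence with wildcard support", {
  p <- fixture_patient()
  expect_identical(count_codes(p, vocab$insomnia_codes), 3L)  # 780.52 x2 + 327.00
  expect_identical(count_codes(p, vocab$anxdep_codes), 1L)    # 300.00
  expect_identical(count_codes(empty_patient(), vocab$insomnia_codes), 0L)
  # explicit wildcard matches by prefix; exact entries never do
  pw <- patient_record("w", "1960-01-01", coded_events = data.frame(
    code = c("715.90", "715.16", "780.52"), date = rep("2000-01-01", 3)))
  expect_identical(count_codes(pw, c("715*")), 2L)
  expect_identical(count_codes(pw, c("715.90")), 1L)
})

test_that("prescription counting matches listed variants only", {
  p <- fixture_patient()
  expect_identical(count_prescriptions(p, vocab$insomnia_medications), 1L)
  ptz <- patient_record("t", "1960-01-01", prescriptions = data.frame(
    medication_name = c("trazodone", "  zolpidem ", "AMBIEN"),
    date = rep("2000-01-01", 3)))
  # trazodone (secondary-use drug) excluded; trimming and case ignored
  expect_identical(count_prescriptions(ptz, vocab$insomnia_medications), 2L)
  expect_identical(count_prescriptions(empty_patient(),
                                       vocab$insomnia_medications), 0L)
})

test_that("EMR fact tally is the total entry count and is additive", {
  p <- fixture_patient()  # 4 codes + 1 rx + 2 notes
  expect_identical(count_emr_facts(p), 7L)
  expect_identical(count_emr_facts(empty_patient()), 0L)
  p2 <- patient_record(p$patient_id, p$birth_date,
                       coded_events = rbind(as.data.frame(p$coded_events),
                                            data.frame(code = "401.9",
                                                       date = as.Date("2005-01-01"))),
                       prescriptions = p$prescriptions, notes = p$notes)
  expect_identical(count_emr_facts(p2), count_emr_facts(p) + 1L)
})

test_that("full extraction assembles the seven covariates coherently", {
  fv <- extract_features(fixture_patient())
  expect_identical(fv, c(n_sleep_notes = 1L, n_insomnia_codes = 3L,
                         n_anxdep_codes = 1L, n_psych_notes = 0L,
                         n_insomnia_rx = 1L, n_joint_codes = 0L,
                         n_emr_facts = 7L))
  expect_identical(unname(extract_features(empty_patient())), rep(0L, 7))
  expect_invisible(validate_feature_vector(fv))
})

test_that("appending qualifying events never decreases any covariate", {
  base <- fixture_patient()
  fv0 <- extract_features(base)
  more <- patient_record(
    base$patient_id, base$birth_date,
    coded_events = rbind(as.data.frame(base$coded_events),
                         data.frame(code = "780.52", date = as.Date("2006-01-01"))),
    prescriptions = rbind(as.data.frame(base$prescriptions),
                          data.frame(medication_name = "Lunesta",
                                     date = as.Date("2006-01-01"))),
    notes = rbind(as.data.frame(base$notes),
                  data.frame(note_id = "n3", date = as.Date("2006-01-01"),
                             text = long_note("fragmented sleep noted."))))
  fv1 <- extract_features(more)
  expect_true(all(fv1 >= fv0))
  # duplicating an expression inside an existing note changes nothing
  dup <- base
  dup$notes$text[1] <- paste(dup$notes$text[1], "poor sleep again")
  expect_identical(extract_features(dup)["n_sleep_notes"], fv0["n_sleep_notes"])
})
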