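test_that("patient records enforce their invariants", {
  expect_error(patient_record("", "1960-01-01"), "non-empty")
  expect_error(patient_record("A", "1960-01-01", death_date = "1950-01-01"),
               "death_date precedes")
  expect_error(patient_record("A", "not-a-date"), "birth")
  expect_error(
    patient_record("A", "1960-01-01",
                   coded_events = data.frame(code = "garbage", date = "1990-01-01")),
    "malformed ICD-9")
  expect_error(
    patient_record("A", "1960-01-01",
                   coded_events = data.frame(code = "780.52", date = "1950-01-01")),
    "before birth_date")
  expect_error(
    patient_record("A", "1960-01-01",
                   notes = data.frame(note_id = c("n", "n"),
                                      date = c("1990-01-01", "1991-01-01"),
                                      text = c("a", "b"))),
    "duplicate note_id")
  # valid ICD-9 shapes, including V/E prefixes
  p <- patient_record("A", "1960-01-01",
                      coded_events = data.frame(code = c("V70.0", "E849.7", "780"),
                                                date = rep("1990-01-01", 3)))
  expect_s3_class(p, "patient_record")
})

test_that("jsonl corpus round-trips and reports malformed lines", {
  corpus <- structure(list(fixture_patient("P1"), empty_patient("P2")),
                      class = "emr_corpus")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_patients(corpus, path)
  back <- read_patients(path)
  expect_length(back, 2L)
  expect_identical(back[[1]]$patient_id, "P1")
  expect_identical(back[[1]]$coded_events$code, corpus[[1]]$coded_events$code)
  expect_identical(back[[1]]$notes$text, corpus[[1]]$notes$text)
  expect_identical(back[[1]]$birth_date, corpus[[1]]$birth_date)

  # empty file -> empty corpus, no error
  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), empty)
  expect_length(read_patients(empty), 0L)

  # line number reported for a corrupt record
  badfile <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(readLines(path)[1], "{not json"), badfile)
  expect_error(read_patients(badfile), "line 2")

  # duplicate patient_id across lines is a hard error
  dupfile <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(rep(readLines(path)[1], 2), dupfile)
  expect_error(read_patients(dupfile), "duplicate patient_id")
})

test_that("csv-bundle corpus reader agrees with the jsonl reader", {
  corpus <- structure(list(fixture_patient("P1")), class = "emr_corpus")
  dir <- withr::local_tempdir()
  p <- corpus[[1]]
  write.csv(data.frame(patient_id = "P1", birth_date = "1960-05-04",
                       death_date = "", sex = "F"),
            file.path(dir, "patients.csv"), row.names = FALSE)
  write.csv(cbind(patient_id = "P1", p$coded_events),
            file.path(dir, "codes.csv"), row.names = FALSE)
  write.csv(cbind(patient_id = "P1", p$prescriptions),
            file.path(dir, "meds.csv"), row.names = FALSE)
  write.csv(cbind(patient_id = "P1", p$notes),
            file.path(dir, "notes.csv"), row.names = FALSE)
  back <- read_patients(dir, format = "csv")
  expect_identical(back[["P1"]]$coded_events$code, p$coded_events$code)
  expect_identical(extract_features(back[["P1"]]), extract_features(p))
})

test_that("feature matrix CSV round-trips, sorted by patient id", {
  f <- extract_features_corpus(structure(list(fixture_patient("PB"),
                                              empty_patient("PA")),
                                         class = "emr_corpus"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(f, path)
  back <- read_feature_matrix(path)
  expect_identical(back$patient_id, c("PA", "PB"))  # deterministic ordering
  expect_identical(names(back), c("patient_id", covariate_names()))
  merged <- merge(f, back, by = "patient_id")
  for (nm in covariate_names())
    expect_identical(as.integer(merged[[paste0(nm, ".x")]]),
                     merged[[paste0(nm, ".y")]])
  # all-zero row survives
  expect_identical(sum(unlist(back[back$patient_id == "PA", -1])), 0L)
})

test_that("label files round-trip and reject invalid status values", {
  lab <- data.frame(patient_id = c("a", "b"),
                    status = c("insomnia", "undetermined"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(lab, path)
  expect_identical(read_labels(path), lab)
  writeLines("patient_id,status\nx,maybe", path)
  expect_error(read_labels(path), "invalid label status")
})

test_that("feature-vector invariants catch negative and inconsistent counts", {
  fv <- feature_vector(n_insomnia_codes = 2, n_emr_facts = 5)
  expect_invisible(validate_feature_vector(fv))
  bad <- feature_vector(n_insomnia_codes = 3)  # facts (0) < codes (3)
  expect_error(validate_feature_vector(bad), "n_emr_facts")
  expect_error(feature_vector(n_sleep_notes = -1), "non-negative")
})
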