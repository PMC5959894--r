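# Patient records, chart labels, and corpus / feature-matrix / label I/O.
#
# A patient record is a plain list:
#   patient_id    opaque non-empty string, unique within a corpus
#   birth_date    Date
#   death_date    Date or NA
#   sex, ethnicity, marital, insurance   pass-through strings (may be NA)
#   coded_events  data.frame(code, date)        ICD-9 diagnosis events
#   prescriptions data.frame(medication_name, date)
#   notes         data.frame(note_id, date, text)
# A corpus is a list of such records with class "emr_corpus".

ICD9_RE <- "^[VE]?[0-9]{2,3}(\\.[0-9]{1,2})?$"

as_date_strict <- function(x, what, id = NULL) {
  d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  bad <- !is.na(x) & is.na(d)
  if (any(bad))
    stop("unparseable ", what, " date(s)",
         if (!is.null(id)) paste0(" for patient '", id, "'"),
         ": ", paste(utils::head(x[bad], 3), collapse = ", "))
  d
}

#' Construct and validate a patient record
#'
#' @param patient_id Non-empty string.
#' @param birth_date,death_date ISO-8601 date strings or `Date`s;
#'   `death_date` may be `NA`.
#' @param coded_events Data frame with columns `code`, `date` (ICD-9
#'   dated diagnosis occurrences), or `NULL`.
#' @param prescriptions Data frame with columns `medication_name`, `date`,
#'   or `NULL`.
#' @param notes Data frame with columns `note_id`, `date`, `text`, or
#'   `NULL`.
#' @param sex,ethnicity,marital,insurance Optional demographic strings
#'   (carried through; not used by the model).
#' @return A list of class `patient_record`.
#' @export
patient_record <- function(patient_id, birth_date, death_date = NA,
                           coded_events = NULL, prescriptions = NULL,
                           notes = NULL, sex = NA_character_,
                           ethnicity = NA_character_, marital = NA_character_,
                           insurance = NA_character_) {
  if (!is.character(patient_id) || length(patient_id) != 1L || !nzchar(patient_id))
    stop("patient_id must be a non-empty string")
  birth <- as_date_strict(as.character(birth_date), "birth", patient_id)
  if (is.na(birth)) stop("patient '", patient_id, "' has no parseable birth_date")
  death <- if (length(death_date) == 1L && is.na(death_date)) as.Date(NA)
           else as_date_strict(as.character(death_date), "death", patient_id)
  if (!is.na(death) && death < birth)
    stop("patient '", patient_id, "': death_date precedes birth_date")

  coded_events <- normalize_events(coded_events,
    c(code = "character", date = "character"), patient_id)
  prescriptions <- normalize_events(prescriptions,
    c(medication_name = "character", date = "character"), patient_id)
  notes <- normalize_events(notes,
    c(note_id = "character", date = "character", text = "character"), patient_id)

  coded_events$code <- trimws(coded_events$code)
  badcode <- !grepl(ICD9_RE, coded_events$code)
  if (any(badcode))
    stop("patient '", patient_id, "': malformed ICD-9 code(s): ",
         paste(unique(coded_events$code[badcode]), collapse = ", "))
  if (any(!nzchar(trimws(prescriptions$medication_name))))
    stop("patient '", patient_id, "': empty medication_name")
  if (anyDuplicated(notes$note_id))
    stop("patient '", patient_id, "': duplicate note_id")

  for (nm in c("coded_events", "prescriptions", "notes")) {
    df <- get(nm)
    df$date <- as_date_strict(as.character(df$date), nm, patient_id)
    if (any(!is.na(df$date) & df$date < birth))
      stop("patient '", patient_id, "': ", nm, " dated before birth_date")
    assign(nm, df)
  }

  structure(list(patient_id = patient_id, birth_date = birth,
                 death_date = death, sex = sex, ethnicity = ethnicity,
                 marital = marital, insurance = insurance,
                 coded_events = coded_events, prescriptions = prescriptions,
                 notes = notes),
            class = "patient_record")
}

normalize_events <- function(df, cols, id) {
  if (is.null(df) || (is.data.frame(df) && nrow(df) == 0L) ||
      (is.list(df) && length(df) == 0L)) {
    out <- lapply(cols, function(ty) character(0))
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(names(cols), names(df))
  if (length(missing))
    stop("patient '", id, "': event table lacks column(s): ",
         paste(missing, collapse = ", "))
  df <- df[names(cols)]
  for (nm in names(cols)) df[[nm]] <- as.character(df[[nm]])
  df
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record ", x$patient_id, "> born ", format(x$birth_date),
      if (!is.na(x$death_date)) paste0(", died ", format(x$death_date)),
      "; ", nrow(x$coded_events), " coded events, ",
      nrow(x$prescriptions), " prescriptions, ",
      nrow(x$notes), " notes\n", sep = "")
  invisible(x)
}

new_corpus <- function(records) {
  ids <- vapply(records, function(p) p$patient_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate patient_id in corpus: ", paste(unique(dup), collapse = ", "))
  names(records) <- ids
  structure(records, class = "emr_corpus")
}

#' @export
print.emr_corpus <- function(x, ...) {
  cat("<emr_corpus> ", length(x), " patients\n", sep = "")
  invisible(x)
}

record_from_list <- function(obj, line = NA) {
  tryCatch(
    patient_record(
      patient_id = obj$patient_id,
      birth_date = obj$birth_date,
      death_date = if (is.null(obj$death_date)) NA else obj$death_date,
      sex = obj$sex %||% NA_character_,
      ethnicity = obj$ethnicity %||% NA_character_,
      marital = obj$marital %||% NA_character_,
      insurance = obj$insurance %||% NA_character_,
      coded_events = obj$coded_events,
      prescriptions = obj$prescriptions,
      notes = obj$notes),
    error = function(e)
      stop("invalid patient record",
           if (!is.na(line)) paste0(" at line ", line), ": ",
           conditionMessage(e), call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a patient corpus
#'
#' Two on-disk dialects are supported. `"jsonl"` (the default) is one JSON
#' document per line per patient, with `coded_events`, `prescriptions`,
#' and `notes` embedded as arrays of objects. `"csv"` is a directory
#' holding `patients.csv`, `codes.csv`, `meds.csv`, `notes.csv`, joined on
#' `patient_id`.
#'
#' @param path File (jsonl) or directory (csv).
#' @param format `"jsonl"` or `"csv"`.
#' @return An `emr_corpus` (list of `patient_record`s, in file order).
#' @export
read_patients <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e)
                        stop("malformed JSON at line ", i, ": ",
                             conditionMessage(e), call. = FALSE))
      recs[[i]] <- record_from_list(obj, line = i)
    }
    new_corpus(recs)
  } else {
    need <- c("patients.csv", "codes.csv", "meds.csv", "notes.csv")
    files <- file.path(path, need)
    miss <- need[!file.exists(files)]
    if (length(miss)) stop("csv corpus missing file(s): ", paste(miss, collapse = ", "))
    pat <- utils::read.csv(files[1], stringsAsFactors = FALSE, colClasses = "character")
    cod <- utils::read.csv(files[2], stringsAsFactors = FALSE, colClasses = "character")
    med <- utils::read.csv(files[3], stringsAsFactors = FALSE, colClasses = "character")
    noz <- utils::read.csv(files[4], stringsAsFactors = FALSE, colClasses = "character")
    recs <- lapply(seq_len(nrow(pat)), function(i) {
      id <- pat$patient_id[i]
      record_from_list(list(
        patient_id = id, birth_date = pat$birth_date[i],
        death_date = if (!is.null(pat$death_date) && nzchar(pat$death_date[i]))
                       pat$death_date[i] else NA,
        sex = pat$sex[i] %||% NA_character_,
        coded_events = cod[cod$patient_id == id, c("code", "date"), drop = FALSE],
        prescriptions = med[med$patient_id == id,
                            c("medication_name", "date"), drop = FALSE],
        notes = noz[noz$patient_id == id,
                    c("note_id", "date", "text"), drop = FALSE]))
    })
    new_corpus(recs)
  }
}

#' Write a patient corpus as JSON lines
#' @param corpus An `emr_corpus` or list of `patient_record`s.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_patients <- function(corpus, path) {
  fmt_df <- function(df) {
    df$date <- format(df$date)
    df
  }
  lines <- vapply(corpus, function(p) {
    obj <- list(patient_id = p$patient_id,
                birth_date = format(p$birth_date),
                death_date = if (is.na(p$death_date)) NULL else format(p$death_date),
                sex = p$sex, ethnicity = p$ethnicity, marital = p$marital,
                insurance = p$insurance,
                coded_events = fmt_df(p$coded_events),
                prescriptions = fmt_df(p$prescriptions),
                notes = fmt_df(p$notes))
    obj <- obj[!vapply(obj, is.null, logical(1))]
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                     dataframe = "rows")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read chart-review labels
#'
#' Two-column CSV `patient_id,status` with status one of `insomnia`,
#' `no_insomnia`, `undetermined`.
#' @param path CSV file path.
#' @return Data frame with columns `patient_id`, `status`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("patient_id", "status") %in% names(df)))
    stop("label file must have columns patient_id,status")
  bad <- setdiff(unique(df$status), c("insomnia", "no_insomnia", "undetermined"))
  if (length(bad)) stop("invalid label status value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id in label file")
  df[c("patient_id", "status")]
}

#' Write chart-review labels
#' @param labels Data frame with columns `patient_id`, `status`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels[c("patient_id", "status")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a feature matrix as CSV
#'
#' One row per patient, sorted by `patient_id` for determinism; columns in
#' the fixed covariate order of the scoring equation.
#'
#' @param features Data frame with a `patient_id` column and the seven
#'   covariate columns (as produced by [extract_features_corpus()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(features, path) {
  stopifnot(is.data.frame(features), nrow(features) >= 1L)
  miss <- setdiff(c("patient_id", INSOMNIA_COVARIATES), names(features))
  if (length(miss)) stop("feature matrix lacks column(s): ", paste(miss, collapse = ", "))
  out <- features[order(features$patient_id), c("patient_id", INSOMNIA_COVARIATES)]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix CSV
#' @param path CSV file path written by [write_feature_matrix()].
#' @return Data frame with `patient_id` and the seven covariate columns.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("feature matrix not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("patient_id", INSOMNIA_COVARIATES), names(df))
  if (length(miss)) stop("feature matrix lacks column(s): ", paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  for (nm in INSOMNIA_COVARIATES) {
    v <- df[[nm]]
    if (any(v < 0) || any(v != floor(v)))
      stop("feature column ", nm, " must hold non-negative integer counts")
    df[[nm]] <- as.integer(v)
  }
  df[c("patient_id", INSOMNIA_COVARIATES)]
}

#' Validate a feature vector's invariants
#'
#' Every covariate must be a non-negative integer count, and the EMR-fact
#' tally must be at least the sum of the four vocabulary-specific
#' structured counts (it is a superset tally of all data entries).
#'
#' @param fv Named numeric vector or one-row data frame holding the seven
#'   covariates.
#' @return Invisibly `TRUE`; error otherwise.
#' @export
validate_feature_vector <- function(fv) {
  if (is.data.frame(fv)) fv <- unlist(fv[1, INSOMNIA_COVARIATES])
  miss <- setdiff(INSOMNIA_COVARIATES, names(fv))
  if (length(miss)) stop("feature vector lacks: ", paste(miss, collapse = ", "))
  v <- fv[INSOMNIA_COVARIATES]
  if (any(v < 0) || any(v != floor(v)))
    stop("feature counts must be non-negative integers")
  strut <- sum(v[c("n_insomnia_codes", "n_anxdep_codes",
                   "n_joint_codes", "n_insomnia_rx")])
  if (v[["n_emr_facts"]] < strut)
    stop("n_emr_facts must be >= the sum of coded/prescription counts")
  invisible(TRUE)
}
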