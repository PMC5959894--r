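# Synthetic EMR corpus generator.
#
# The generator emulates the statistical structure the phenotyping
# algorithm assumes — not clinical prose. Each patient draws a latent
# insomnia status, then status-conditional Poisson counts for each of the
# covariate-generating event types. Every planted sleep-disorder note
# carries exactly one expression from the sleep vocabulary, padded with
# vocabulary-free clinical filler to the configured length, so the planted
# count is recoverable exactly by extraction; distractor notes carry
# benign sleep phrases ("patient sleeps well") that satisfy the
# candidate-mart keyword screen but must never match a disorder
# expression. The planted per-patient counts are recorded as ground truth.

# Filler sentences avoid every default vocabulary expression and the
# candidate keywords, so padding never creates a spurious match.
FILLER_SENTENCES <- c(
  "Patient seen in clinic for routine follow up.",
  "Vital signs stable and within normal limits.",
  "Continue current medication regimen as prescribed.",
  "Laboratory panel reviewed with the patient today.",
  "Diet and exercise counseling provided at length.",
  "Return to clinic in three months for reassessment.")

DISTRACTOR_PHRASES <- c("patient sleeps well", "denies insomnia",
                        "slept 8 hours with no sleep complaints")

BACKGROUND_CODES <- c("250.00", "401.9", "272.4", "530.81", "414.01")
BACKGROUND_MEDS <- c("Metformin", "Lisinopril", "Atorvastatin", "Omeprazole")

#' Simulation configuration for synthetic EMR corpora
#'
#' Default rates encode the documentation pattern the phenotyping problem
#' presupposes: insomnia cases accumulate sleep-disorder notes far more
#' often than insomnia billing codes (most cases carry no insomnia code at
#' all), psychiatric and joint comorbidity are enriched in cases, and both
#' groups share a background of unrelated notes, codes and prescriptions
#' that feed only the utilization tally.
#'
#' @param n_patients Number of patients (>= 1).
#' @param insomnia_prevalence Probability a patient is a latent case.
#' @param case_rates,control_rates Named lists of Poisson means for
#'   `sleep_notes`, `insomnia_codes`, `anxdep_codes`, `psych_notes`,
#'   `insomnia_rx`, `joint_codes` in the respective status group.
#' @param background_note_rate,background_code_rate,background_rx_rate
#'   Poisson means for vocabulary-free filler events (both groups).
#' @param distractor_fraction Probability that a background note embeds a
#'   benign sleep phrase instead of pure filler.
#' @param note_padding_chars Minimum generated note length (>= 500 keeps
#'   generated notes past the default length filter).
#' @param severity_sd Standard deviation of an optional shared log-normal
#'   severity factor multiplying all of a patient's rates (0 disables it).
#' @param seed Integer seed; identical seeds give bit-identical corpora.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000L,
                       insomnia_prevalence = 0.46,
                       case_rates = list(sleep_notes = 2.0,
                                         insomnia_codes = 0.3,
                                         anxdep_codes = 1.5,
                                         psych_notes = 1.2,
                                         insomnia_rx = 0.4,
                                         joint_codes = 1.0),
                       control_rates = list(sleep_notes = 0.05,
                                            insomnia_codes = 0.02,
                                            anxdep_codes = 0.8,
                                            psych_notes = 0.6,
                                            insomnia_rx = 0.02,
                                            joint_codes = 0.8),
                       background_note_rate = 2.5,
                       background_code_rate = 3.0,
                       background_rx_rate = 1.0,
                       distractor_fraction = 0.3,
                       note_padding_chars = 600L,
                       severity_sd = 0,
                       seed = 1L) {
  stopifnot(n_patients >= 1L,
            insomnia_prevalence > 0 || insomnia_prevalence == 0,
            insomnia_prevalence < 1 || insomnia_prevalence == 1,
            distractor_fraction >= 0, distractor_fraction <= 1,
            severity_sd >= 0)
  needed <- c("sleep_notes", "insomnia_codes", "anxdep_codes",
              "psych_notes", "insomnia_rx", "joint_codes")
  for (rl in list(case_rates, control_rates)) {
    miss <- setdiff(needed, names(rl))
    if (length(miss)) stop("rate list lacks: ", paste(miss, collapse = ", "))
    if (any(unlist(rl[needed]) < 0)) stop("rates must be >= 0")
  }
  structure(list(n_patients = as.integer(n_patients),
                 insomnia_prevalence = insomnia_prevalence,
                 case_rates = case_rates, control_rates = control_rates,
                 background_note_rate = background_note_rate,
                 background_code_rate = background_code_rate,
                 background_rx_rate = background_rx_rate,
                 distractor_fraction = distractor_fraction,
                 note_padding_chars = as.integer(note_padding_chars),
                 severity_sd = severity_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

pad_note <- function(core, min_chars) {
  txt <- core
  i <- 0L
  while (nchar(txt) < min_chars) {
    i <- i + 1L
    txt <- paste(txt, FILLER_SENTENCES[(i - 1L) %% length(FILLER_SENTENCES) + 1L])
  }
  txt
}

rand_dates <- function(n, birth) {
  if (n == 0L) return(as.Date(character(0)))
  birth + sample.int(6000L, n, replace = TRUE) + 2000L
}

#' Simulate a labeled synthetic EMR corpus
#'
#' @param config A `sim_config`.
#' @param vocab A `vocabulary_config` supplying the code sets, medication
#'   names and expression lists sampled from.
#' @return List with `corpus` (an `emr_corpus`), `truth` (data frame
#'   `patient_id`, `status`), and `planted` (data frame of the generator's
#'   per-patient covariate counts, the extraction ground truth).
#' @export
simulate_corpus <- function(config = sim_config(),
                            vocab = default_vocabulary()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  status <- stats::rbinom(n, 1L, config$insomnia_prevalence)
  recs <- vector("list", n)
  planted <- vector("list", n)
  id_w <- max(6L, nchar(as.character(n)))
  for (i in seq_len(n)) {
    id <- sprintf(paste0("P%0", id_w, "d"), i)
    rates <- if (status[i] == 1L) config$case_rates else config$control_rates
    sev <- if (config$severity_sd > 0)
      exp(stats::rnorm(1, -config$severity_sd^2 / 2, config$severity_sd)) else 1
    k <- function(lambda) stats::rpois(1L, lambda * sev)
    n_sleep <- k(rates$sleep_notes)
    n_icode <- k(rates$insomnia_codes)
    n_anx <- k(rates$anxdep_codes)
    n_psy <- k(rates$psych_notes)
    n_rx <- k(rates$insomnia_rx)
    n_joint <- k(rates$joint_codes)
    n_bg_note <- k(config$background_note_rate)
    n_bg_code <- k(config$background_code_rate)
    n_bg_rx <- k(config$background_rx_rate)

    birth <- as.Date("1950-01-01") + sample.int(14600L, 1L)

    # notes: planted sleep-disorder, planted psychiatric, background
    sleep_txt <- if (n_sleep > 0L) vapply(seq_len(n_sleep), function(j)
      pad_note(paste0("Clinical note. Patient reports ",
                      sample(vocab$sleep_expressions, 1L), " at this visit."),
               config$note_padding_chars), character(1)) else character(0)
    psych_txt <- if (n_psy > 0L) vapply(seq_len(n_psy), function(j)
      pad_note(paste0("Clinical note. History notable for ",
                      sample(vocab$psych_expressions, 1L), "."),
               config$note_padding_chars), character(1)) else character(0)
    bg_txt <- if (n_bg_note > 0L) vapply(seq_len(n_bg_note), function(j) {
      core <- if (stats::runif(1) < config$distractor_fraction)
        paste0("Clinical note. ", sample(DISTRACTOR_PHRASES, 1L), ".")
      else "Clinical note. No new complaints today."
      pad_note(core, config$note_padding_chars)
    }, character(1)) else character(0)
    texts <- c(sleep_txt, psych_txt, bg_txt)
    notes <- if (length(texts)) data.frame(
      note_id = sprintf("%s-N%03d", id, seq_along(texts)),
      date = rand_dates(length(texts), birth), text = texts,
      stringsAsFactors = FALSE) else NULL

    # coded events: planted vocabulary codes + vocabulary-free background
    codes <- c(
      if (n_icode > 0L) sample(vocab$insomnia_codes, n_icode, replace = TRUE),
      if (n_anx > 0L) sample(c("300.00", "300.02", "311"), n_anx, replace = TRUE),
      if (n_joint > 0L) sample(c("715.90", "716.90", "719.40"), n_joint,
                               replace = TRUE),
      if (n_bg_code > 0L) sample(BACKGROUND_CODES, n_bg_code, replace = TRUE))
    coded <- if (length(codes)) data.frame(
      code = codes, date = rand_dates(length(codes), birth),
      stringsAsFactors = FALSE) else NULL

    meds <- c(
      if (n_rx > 0L) sample(vocab$insomnia_medications, n_rx, replace = TRUE),
      if (n_bg_rx > 0L) sample(BACKGROUND_MEDS, n_bg_rx, replace = TRUE))
    rx <- if (length(meds)) data.frame(
      medication_name = meds, date = rand_dates(length(meds), birth),
      stringsAsFactors = FALSE) else NULL

    recs[[i]] <- patient_record(
      patient_id = id, birth_date = birth,
      sex = sample(c("F", "M"), 1L),
      coded_events = coded, prescriptions = rx, notes = notes)
    planted[[i]] <- data.frame(
      patient_id = id,
      n_sleep_notes = n_sleep, n_insomnia_codes = n_icode,
      n_anxdep_codes = n_anx, n_psych_notes = n_psy,
      n_insomnia_rx = n_rx, n_joint_codes = n_joint,
      n_emr_facts = length(texts) + length(codes) + length(meds),
      stringsAsFactors = FALSE)
  }
  truth <- data.frame(
    patient_id = vapply(recs, function(p) p$patient_id, character(1)),
    status = ifelse(status == 1L, "insomnia", "no_insomnia"),
    stringsAsFactors = FALSE)
  planted <- do.call(rbind, planted)
  rownames(planted) <- NULL
  list(corpus = new_corpus(recs), truth = truth, planted = planted)
}

#' Simulate feature matrices and labels directly from a scoring model
#'
#' Covariates are drawn from status-free count laws; each label is then
#' Bernoulli of the model probability for that row. Used for
#' parameter-recovery checks: the model that generated the labels is the
#' oracle a refit should recover.
#'
#' The default covariate law draws the six vocabulary counts from Poisson
#' distributions and adds an overdispersed negative-binomial surplus of
#' unrelated EMR facts (mean 500, size 0.8) on top of the structured
#' counts — long multi-year records accumulate hundreds of entries with
#' large between-patient spread. The default means are chosen for
#' identifiability: every coefficient, including the small per-fact and
#' per-joint-code effects, carries several standard errors of information
#' at moderate sample sizes, so parameter recovery is a property of the
#' estimator rather than of sampling luck. Recurrent events (prescription
#' refills, repeat comorbidity billing) accumulate over a multi-year
#' record, hence the larger means for those counts.
#'
#' @param model An `insomnia_model`.
#' @param n Number of rows.
#' @param means Named list of Poisson means for the six vocabulary counts.
#' @param facts_mu,facts_size Negative-binomial mean and size for the
#'   surplus EMR facts.
#' @param seed Integer seed.
#' @return List with `features` (data frame, `patient_id` + seven
#'   covariates) and `labels` (data frame `patient_id`, `status`).
#' @export
simulate_from_model <- function(model = published_model(), n = 1000L,
                                means = list(sleep_notes = 0.3,
                                             insomnia_codes = 0.8,
                                             anxdep_codes = 2,
                                             psych_notes = 4,
                                             insomnia_rx = 4,
                                             joint_codes = 12),
                                facts_mu = 500, facts_size = 0.8,
                                seed = 1L) {
  stopifnot(inherits(model, "insomnia_model"), n >= 1L)
  set.seed(as.integer(seed))
  ids <- sprintf("S%07d", seq_len(n))
  fv <- data.frame(
    patient_id = ids,
    n_sleep_notes = stats::rpois(n, means$sleep_notes),
    n_insomnia_codes = stats::rpois(n, means$insomnia_codes),
    n_anxdep_codes = stats::rpois(n, means$anxdep_codes),
    n_psych_notes = stats::rpois(n, means$psych_notes),
    n_insomnia_rx = stats::rpois(n, means$insomnia_rx),
    n_joint_codes = stats::rpois(n, means$joint_codes),
    stringsAsFactors = FALSE)
  fv$n_emr_facts <- fv$n_insomnia_codes + fv$n_anxdep_codes +
    fv$n_joint_codes + fv$n_insomnia_rx + fv$n_sleep_notes + fv$n_psych_notes +
    stats::rnbinom(n, mu = facts_mu, size = facts_size)
  p <- predict(model, fv, type = "response")
  y <- stats::rbinom(n, 1L, p)
  labels <- data.frame(patient_id = ids,
                       status = ifelse(y == 1L, "insomnia", "no_insomnia"),
                       stringsAsFactors = FALSE)
  list(features = fv, labels = labels)
}
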