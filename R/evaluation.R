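# Chart-review-style evaluation: confusion metrics at the operating
# threshold, labeled-sample preparation, cohort-level summaries.

#' Confusion metrics at the operating threshold
#'
#' @param scores Data frame of score results (from [score_corpus()] or
#'   [classify()]): needs `patient_id` and `classified_insomnia`.
#' @param labels Data frame (`patient_id`, `status`) with status
#'   insomnia/no_insomnia only; undetermined labels must be dropped
#'   upstream (see [prepare_labeled_sample()]).
#' @return List with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`; a ratio with zero denominator is `NA`, never 0.
#' @export
confusion_metrics <- function(scores, labels) {
  orphans_s <- setdiff(scores$patient_id, labels$patient_id)
  orphans_l <- setdiff(labels$patient_id, scores$patient_id)
  if (length(orphans_s) || length(orphans_l))
    stop("score/label id mismatch; unmatched ids: ",
         paste(utils::head(c(orphans_s, orphans_l), 5), collapse = ", "))
  y <- as_binary_labels(labels, scores$patient_id)
  pred <- scores$classified_insomnia
  tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L)
  tn <- sum(!pred & y == 0L); fn <- sum(!pred & y == 1L)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn))
}

#' Prepare a chart-review label set for evaluation
#'
#' Drops undetermined labels, then applies the under-18 exclusion (age at
#' death or at the study end date, whichever is earlier).
#'
#' @param labels Raw chart labels (`patient_id`, `status`, possibly
#'   including `undetermined`).
#' @param corpus The `emr_corpus` the labels refer to.
#' @param study_end Study end date.
#' @return List with `labels` (filtered data frame) and `dropped` (named
#'   counts: `undetermined`, `under_18`).
#' @export
prepare_labeled_sample <- function(labels, corpus,
                                   study_end = as.Date("2010-12-31")) {
  names(corpus) <- vapply(corpus, function(p) p$patient_id, character(1))
  miss <- setdiff(labels$patient_id, names(corpus))
  if (length(miss))
    stop("labels reference unknown patient(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  n0 <- nrow(labels)
  keep <- labels$status != "undetermined"
  labels <- labels[keep, , drop = FALSE]
  n_undet <- n0 - nrow(labels)
  sub <- structure(corpus[labels$patient_id], class = "emr_corpus")
  filt <- apply_age_exclusion(sub, labels, study_end = study_end)
  list(labels = filt$labels,
       dropped = c(undetermined = n_undet,
                   under_18 = length(filt$excluded_ids)))
}

#' Fraction of classified positives carrying an insomnia billing code
#'
#' A cohort-level summary of how much of the identified phenotype is
#' invisible to billing codes alone: among patients classified insomnia,
#' the fraction with at least one insomnia ICD-9 code.
#'
#' @param scores Score results with `classified_insomnia`.
#' @param features Feature data frame aligned by `patient_id`.
#' @return Fraction in [0, 1], or `NA` when there are no positives.
#' @export
cohort_positive_fraction_with_codes <- function(scores, features) {
  m <- match(scores$patient_id, features$patient_id)
  if (anyNA(m)) stop("scores and features are not aligned")
  pos <- scores$classified_insomnia
  if (!any(pos)) return(NA_real_)
  mean(features$n_insomnia_codes[m][pos] >= 1L)
}
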