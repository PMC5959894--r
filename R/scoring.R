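# Evaluation of a scoring model on feature vectors: linear predictor,
# probability, thresholded classification.

coerce_fv <- function(fv, needed) {
  if (is.data.frame(fv)) fv <- unlist(fv[1, , drop = TRUE])
  miss <- setdiff(needed, names(fv))
  if (length(miss))
    stop("feature vector lacks covariate(s): ", paste(miss, collapse = ", "))
  fv
}

#' Linear predictor of an insomnia model
#'
#' Intercept plus the coefficient-weighted covariate counts, summed in the
#' model's fixed covariate order so results are bit-stable.
#'
#' @param fv Named numeric vector (or one-row data frame) of covariate
#'   counts.
#' @param model An `insomnia_model` (default the published model).
#' @return Numeric scalar L.
#' @export
linear_predictor <- function(fv, model = published_model()) {
  fv <- coerce_fv(fv, names(model$coefficients))
  L <- model$intercept
  for (nm in names(model$coefficients))
    L <- L + model$coefficients[[nm]] * as.numeric(fv[[nm]])
  L
}

# Numerically stable logistic: never overflows, returns values in [0,1].
stable_logistic <- function(L) {
  ifelse(L >= 0, 1 / (1 + exp(-L)), exp(L) / (1 + exp(L)))
}

#' Insomnia probability under a scoring model
#'
#' The logistic transform `exp(L) / (1 + exp(L))` of the linear predictor,
#' computed in the overflow-safe form.
#'
#' @inheritParams linear_predictor
#' @return Probability in (0, 1).
#' @export
insomnia_probability <- function(fv, model = published_model()) {
  stable_logistic(linear_predictor(fv, model))
}

#' Classify one patient at the model's operating threshold
#'
#' Ties classify positive: probability exactly equal to the threshold is
#' called insomnia.
#'
#' @inheritParams linear_predictor
#' @param patient_id Optional identifier carried into the result.
#' @return One-row data frame: `patient_id`, `linear_predictor`,
#'   `probability`, `classified_insomnia`.
#' @export
classify <- function(fv, model = published_model(), patient_id = NA_character_) {
  if (is.na(model$threshold))
    stop("model has no calibrated threshold; run select_threshold() first")
  L <- linear_predictor(fv, model)
  p <- stable_logistic(L)
  data.frame(patient_id = patient_id, linear_predictor = L, probability = p,
             classified_insomnia = p >= model$threshold,
             stringsAsFactors = FALSE)
}

#' Score every patient in a feature matrix
#'
#' @param features Data frame with `patient_id` and the model's covariate
#'   columns.
#' @param model An `insomnia_model` with a calibrated threshold.
#' @return Data frame of score results ordered by `patient_id`, with a
#'   `n_positive` attribute holding the number classified insomnia.
#' @export
score_corpus <- function(features, model = published_model()) {
  stopifnot(is.data.frame(features), nrow(features) >= 1L)
  if (is.na(model$threshold))
    stop("model has no calibrated threshold; run select_threshold() first")
  X <- as.matrix(features[names(model$coefficients)])
  L <- as.numeric(model$intercept + X %*% model$coefficients)
  p <- stable_logistic(L)
  out <- data.frame(patient_id = features$patient_id, linear_predictor = L,
                    probability = p,
                    classified_insomnia = p >= model$threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id), ]
  rownames(out) <- NULL
  attr(out, "n_positive") <- sum(out$classified_insomnia)
  out
}

#' Predict method for insomnia models
#'
#' @param object An `insomnia_model`.
#' @param newdata Data frame of covariate counts (and optionally
#'   `patient_id`).
#' @param type `"link"` (linear predictor), `"response"` (probability), or
#'   `"class"` (logical classification at the model threshold).
#' @param ... Unused.
#' @return Numeric or logical vector, one element per row of `newdata`.
#' @export
predict.insomnia_model <- function(object, newdata,
                                   type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  miss <- setdiff(names(object$coefficients), names(newdata))
  if (length(miss))
    stop("newdata lacks covariate(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[names(object$coefficients)])
  L <- as.numeric(object$intercept + X %*% object$coefficients)
  switch(type,
         link = L,
         response = stable_logistic(L),
         class = {
           if (is.na(object$threshold))
             stop("model has no calibrated threshold")
           stable_logistic(L) >= object$threshold
         })
}

#' Build a feature vector by naming only the nonzero covariates
#'
#' Convenience constructor: all seven covariates default to zero. Useful
#' for hypothetical scoring scenarios (e.g. "a patient with two
#' sleep-disorder notes and nothing else"); vectors extracted from real
#' records additionally satisfy the superset-tally invariant checked by
#' [validate_feature_vector()].
#'
#' @param ... Named counts, e.g. `n_sleep_notes = 2`.
#' @return Named integer vector over the seven covariates.
#' @export
feature_vector <- function(...) {
  fv <- stats::setNames(integer(length(INSOMNIA_COVARIATES)), INSOMNIA_COVARIATES)
  args <- list(...)
  if (length(args)) {
    bad <- setdiff(names(args), INSOMNIA_COVARIATES)
    if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
    vals <- unlist(args)
    if (any(vals < 0) || any(vals != floor(vals)))
      stop("covariate counts must be non-negative integers")
    fv[names(args)] <- as.integer(vals)
  }
  fv
}
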