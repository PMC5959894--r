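# Fixed covariate order of the scoring equation. All feature matrices,
# model documents and score summaries use this order.
INSOMNIA_COVARIATES <- c(
  "n_sleep_notes",    # notes indicating a sleep disorder
  "n_insomnia_codes", # billing codes for insomnia
  "n_anxdep_codes",   # billing codes for anxiety or depression
  "n_psych_notes",    # notes indicating a psychiatric disorder
  "n_insomnia_rx",    # pharmacy prescriptions for insomnia
  "n_joint_codes",    # billing codes for joint disorder
  "n_emr_facts"       # total EMR data entries (utilization proxy)
)

VARIABLE_SUBSETS <- list(
  icd_only          = "n_insomnia_codes",
  structured_only   = c("n_insomnia_codes", "n_anxdep_codes",
                        "n_insomnia_rx", "n_joint_codes", "n_emr_facts"),
  unstructured_only = c("n_sleep_notes", "n_psych_notes"),
  combined          = INSOMNIA_COVARIATES
)

#' Construct an insomnia scoring model
#'
#' An `insomnia_model` is a logistic scoring rule: an intercept, named
#' coefficients over the seven phenotyping covariates (or a subset of
#' them), and a probability threshold above which a patient is classified
#' as having physician-documented insomnia.
#'
#' @param intercept Numeric scalar.
#' @param coefficients Named numeric vector; every name must be one of the
#'   seven recognised covariates (see [covariate_names()]).
#' @param threshold Probability in (0, 1), or `NA` for a model whose
#'   operating point has not yet been calibrated (see
#'   [select_threshold()]).
#' @param variable_subset One of `"icd_only"`, `"structured_only"`,
#'   `"unstructured_only"`, `"combined"`.
#' @return An object of class `insomnia_model`.
#' @seealso [published_model()], [fit_insomnia_model()], [predict.insomnia_model()]
#' @export
insomnia_model <- function(intercept, coefficients, threshold = NA_real_,
                           variable_subset = "combined") {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("coefficients must be a fully named numeric vector")
  bad <- setdiff(names(coefficients), INSOMNIA_COVARIATES)
  if (length(bad))
    stop("unknown covariate name(s) in model: ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(coefficients)))
    stop("duplicate covariate names in model coefficients")
  if (!is.na(threshold) && (threshold <= 0 || threshold >= 1))
    stop("threshold must lie in the open interval (0, 1)")
  variable_subset <- match.arg(variable_subset, names(VARIABLE_SUBSETS))
  # keep coefficients in canonical covariate order
  ord <- INSOMNIA_COVARIATES[INSOMNIA_COVARIATES %in% names(coefficients)]
  structure(
    list(intercept = unname(intercept),
         coefficients = coefficients[ord],
         threshold = unname(threshold),
         variable_subset = variable_subset),
    class = "insomnia_model")
}

#' Covariate names of the scoring equation, in canonical order
#' @return Character vector of length seven.
#' @export
covariate_names <- function() INSOMNIA_COVARIATES

#' Covariates belonging to a variable-subset configuration
#' @param subset One of `"icd_only"`, `"structured_only"`,
#'   `"unstructured_only"`, `"combined"`.
#' @return Character vector of covariate names.
#' @export
subset_covariates <- function(subset) {
  subset <- match.arg(subset, names(VARIABLE_SUBSETS))
  VARIABLE_SUBSETS[[subset]]
}

#' The published insomnia scoring model
#'
#' Returns the seven-variable logistic model, with coefficients exactly as
#' printed, and the decision threshold of 0.828 that corresponds to a
#' target specificity of 97% in the source validation set.
#'
#' @return An `insomnia_model`.
#' @examples
#' m <- published_model()
#' coef(m)
#' @export
published_model <- function() {
  insomnia_model(
    intercept = -1.927027677,
    coefficients = c(
      n_sleep_notes    = 2.329738590,
      n_insomnia_codes = 0.802462562,
      n_anxdep_codes   = 0.264231683,
      n_psych_notes    = 0.098835169,
      n_insomnia_rx    = 0.086364249,
      n_joint_codes    = 0.048271004,
      n_emr_facts      = 0.000231521),
    threshold = 0.828,
    variable_subset = "combined")
}

#' Load a scoring model from a JSON document or by name
#'
#' `load_model("published")` returns the built-in published model.
#' Otherwise `path` must name a JSON document with fields `intercept`,
#' `coefficients` (an object keyed by covariate name), `threshold`, and
#' optionally `variable_subset`.
#'
#' @param path File path, or the literal string `"published"`.
#' @return An `insomnia_model`.
#' @export
load_model <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (identical(path, "published")) return(published_model())
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$intercept)) stop("model document lacks an 'intercept' field")
  if (is.null(doc$coefficients)) stop("model document lacks a 'coefficients' field")
  if (is.null(doc$threshold))
    stop("model document lacks a 'threshold' field; supply an explicit threshold")
  co <- unlist(doc$coefficients)
  insomnia_model(intercept = as.numeric(doc$intercept),
                 coefficients = co,
                 threshold = as.numeric(doc$threshold),
                 variable_subset = if (is.null(doc$variable_subset)) "combined"
                                   else doc$variable_subset)
}

#' Write a scoring model to a JSON document
#' @param model An `insomnia_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "insomnia_model"))
  doc <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              threshold = model$threshold,
              variable_subset = model$variable_subset)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.insomnia_model <- function(x, ...) {
  cat("Insomnia phenotyping model (", x$variable_subset, " covariates)\n", sep = "")
  cat(sprintf("  intercept: %.9f\n", x$intercept))
  for (nm in names(x$coefficients))
    cat(sprintf("  %-17s %12.9f\n", nm, x$coefficients[[nm]]))
  if (is.na(x$threshold)) cat("  threshold: <not calibrated>\n")
  else cat(sprintf("  threshold: %.3f (probability; ties classify positive)\n",
                   x$threshold))
  invisible(x)
}

#' @export
coef.insomnia_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.insomnia_model <- function(object, ...) {
  or <- exp(object$coefficients)
  out <- data.frame(coefficient = unname(object$coefficients),
                    odds_ratio = unname(or),
                    row.names = names(object$coefficients))
  structure(list(model = object, table = out), class = "summary.insomnia_model")
}

#' @export
print.summary.insomnia_model <- function(x, ...) {
  print(x$model)
  cat("\nPer-unit odds ratios:\n")
  print(round(x$table, 6))
  invisible(x)
}
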