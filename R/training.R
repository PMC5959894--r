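# Model development protocol: adaptive-LASSO logistic regression over
# variable-subset configurations, specificity-anchored threshold
# calibration, bootstrap AUROC confidence intervals, and a permutation
# overfitting check.
#
# The adaptive LASSO is a two-stage estimator: a pilot (unpenalized
# maximum-likelihood, ridge-stabilized under separation) fit supplies
# per-covariate penalty weights 1/|beta0|^gamma, and the second stage
# solves the weighted L1-penalized logistic problem over a cross-validated
# penalty path. Counts enter raw and unstandardized — the published
# coefficients operate on raw counts, and the adaptive weights absorb
# scale differences between covariates.

#' Training configuration
#'
#' @param variable_subset Which covariates to offer the fit.
#' @param train_fraction Fraction assigned to the training split.
#' @param target_specificity Specificity anchored by threshold selection.
#' @param bootstrap_reps Bootstrap replicates for the AUROC CI.
#' @param overfit_permutations Sub-split permutations for the overfitting
#'   check.
#' @param adaptive_gamma Exponent of the pilot coefficients in the penalty
#'   weights.
#' @param cv_folds Cross-validation folds for penalty selection.
#' @param seed Master seed for every stochastic step.
#' @return A list of class `train_config`.
#' @export
train_config <- function(variable_subset = "combined", train_fraction = 2 / 3,
                         target_specificity = 0.97, bootstrap_reps = 1000L,
                         overfit_permutations = 100L, adaptive_gamma = 1,
                         cv_folds = 5L, seed = 1L) {
  variable_subset <- match.arg(variable_subset, names(VARIABLE_SUBSETS))
  stopifnot(train_fraction > 0, train_fraction < 1,
            target_specificity >= 0, target_specificity < 1,
            bootstrap_reps >= 1L, overfit_permutations >= 1L,
            adaptive_gamma > 0, cv_folds >= 2L)
  structure(list(variable_subset = variable_subset,
                 train_fraction = train_fraction,
                 target_specificity = target_specificity,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 overfit_permutations = as.integer(overfit_permutations),
                 adaptive_gamma = adaptive_gamma,
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "train_config")
}

as_binary_labels <- function(labels, ids = NULL) {
  if (is.data.frame(labels)) {
    if (!is.null(ids))
      labels <- labels[match(ids, labels$patient_id), ]
    if (anyNA(labels$status)) stop("labels missing for some patients")
    y <- labels$status
  } else y <- labels
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("insomnia", "no_insomnia"))
    if (length(bad))
      stop("labels must be insomnia/no_insomnia (drop undetermined upstream); got: ",
           paste(bad, collapse = ", "))
    y <- as.integer(y == "insomnia")
  }
  as.integer(y)
}

#' Stratified train/validation split
#'
#' Random split stratified by label, deterministic under the seed. The
#' training share of each stratum is `floor(fraction * stratum size)`, so
#' rounding always favours the validation side.
#'
#' @param ids Character vector of patient ids.
#' @param labels Data frame (`patient_id`, `status`) or vector aligned
#'   with `ids`.
#' @param fraction Training fraction, default 2/3.
#' @param seed Integer seed.
#' @return List with `train` and `validation` id vectors (disjoint,
#'   exhaustive).
#' @export
split_train_validation <- function(ids, labels, fraction = 2 / 3, seed = 1L) {
  stopifnot(length(ids) >= 2L, fraction > 0, fraction < 1)
  y <- as_binary_labels(labels, ids)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to split")
  set.seed(as.integer(seed))
  train <- character(0)
  for (cls in c(0L, 1L)) {
    grp <- ids[y == cls]
    n_tr <- floor(fraction * length(grp))
    train <- c(train, sample(grp, n_tr))
  }
  list(train = sort(train), validation = sort(setdiff(ids, train)))
}

#' Area under the ROC curve (rank form)
#'
#' Mann-Whitney statistic: the probability a random case scores above a
#' random control, with half credit for ties.
#'
#' @param scores Numeric vector.
#' @param y Binary labels (1 = case) or status strings.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, y) {
  y <- as_binary_labels(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Independent route: trapezoidal integration of the empirical ROC curve,
# grouping tied scores (equivalent to the half-credit tie convention).
auroc_trapezoid <- function(scores, y) {
  y <- as_binary_labels(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUROC")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yy <- y[o]
  cuts <- cumsum(!duplicated(s))
  tp <- tapply(yy, cuts, sum)
  fp <- tapply(1 - yy, cuts, sum)
  tpr <- c(0, cumsum(tp) / n1)
  fpr <- c(0, cumsum(fp) / n0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Fit an insomnia phenotyping model by adaptive-LASSO logistic regression
#'
#' Stage one fits an unpenalized logistic regression for pilot
#' coefficients (falling back to a ridge-stabilized pilot under separation
#' or non-convergence, with a warning). Stage two solves the L1-penalized
#' problem with per-covariate penalty weights `1/|pilot|^gamma`, the
#' penalty strength chosen by `cv_folds`-fold cross-validated deviance
#' over the regularization path. Covariates with zero final coefficient
#' are dropped. The returned model carries no threshold until
#' [select_threshold()] calibrates one.
#'
#' @param features Data frame with `patient_id` and covariate columns.
#' @param labels Data frame (`patient_id`, `status`) or binary vector
#'   aligned with `features` rows.
#' @param config A `train_config`.
#' @return An object of class `c("insomnia_fit", "insomnia_model")`;
#'   additional fields: `pilot` (pilot coefficients), `lambda`, `se`
#'   (standard errors from an unpenalized refit on the selected support),
#'   `n`, `subset_covariates`.
#' @seealso [predict.insomnia_model()], [select_threshold()]
#' @export
fit_insomnia_model <- function(features, labels, config = train_config()) {
  stopifnot(is.data.frame(features), inherits(config, "train_config"))
  covs <- subset_covariates(config$variable_subset)
  miss <- setdiff(covs, names(features))
  if (length(miss)) stop("features lack column(s): ", paste(miss, collapse = ", "))
  y <- as_binary_labels(labels, features$patient_id)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  if (nrow(features) < 10L) stop("need at least 10 labeled rows to fit")
  X <- as.matrix(features[covs])
  storage.mode(X) <- "double"

  # stage 1: pilot
  pilot_fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  pilot <- pilot_fit$coefficients[-1]
  names(pilot) <- covs
  # aliased columns (e.g. constant covariates) get NA pilots: no pilot
  # information, maximal penalty weight, but not evidence of separation
  aliased <- !is.finite(pilot)
  pilot[aliased] <- 0
  separated <- !pilot_fit$converged || any(abs(pilot[!aliased]) > 50)
  if (separated) {
    warning("pilot logistic regression unstable (separation?); ",
            "using ridge-stabilized pilot")
    set.seed(config$seed)
    ridge <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                               standardize = FALSE, nfolds = config$cv_folds)
    pilot <- as.numeric(stats::coef(ridge, s = "lambda.min"))[-1]
    names(pilot) <- covs
  }

  if (length(covs) == 1L) {
    # nothing to select; the pilot ML fit is the model
    fit_coef <- pilot
    intercept <- if (separated) {
      as.numeric(stats::coef(ridge, s = "lambda.min"))[1]
    } else pilot_fit$coefficients[1]
    lambda <- 0
  } else {
    w <- 1 / pmax(abs(pilot), 1e-8)^config$adaptive_gamma
    set.seed(config$seed)
    foldid <- sample(rep_len(seq_len(config$cv_folds), length(y)))
    cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                               penalty.factor = w, standardize = FALSE,
                               foldid = foldid, type.measure = "deviance")
    beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
    intercept <- beta[1]
    fit_coef <- beta[-1]
    names(fit_coef) <- covs
    lambda <- cvfit$lambda.min
  }

  keep <- fit_coef != 0
  selected <- fit_coef[keep]

  # post-selection unpenalized refit for standard errors
  se <- NULL
  if (any(keep)) {
    refit <- suppressWarnings(
      stats::glm(y ~ ., data = data.frame(y = y, X[, keep, drop = FALSE]),
                 family = stats::binomial()))
    se_all <- summary(refit)$coefficients[, "Std. Error"]
    se <- se_all[-1]
    names(se) <- names(selected)
  }

  model <- insomnia_model(intercept = intercept, coefficients = selected,
                          threshold = NA_real_,
                          variable_subset = config$variable_subset)
  model$pilot <- pilot
  model$lambda <- lambda
  model$se <- se
  model$n <- length(y)
  model$subset_covariates <- covs
  class(model) <- c("insomnia_fit", "insomnia_model")
  model
}

#' @export
print.insomnia_fit <- function(x, ...) {
  cat("Adaptive-LASSO insomnia phenotyping fit (n = ", x$n, ", subset = ",
      x$variable_subset, ")\n", sep = "")
  cat(length(x$coefficients), "of", length(x$subset_covariates),
      "offered covariates selected; lambda =", signif(x$lambda, 4), "\n")
  NextMethod()
}

#' @export
summary.insomnia_fit <- function(object, ...) {
  tab <- data.frame(coefficient = unname(object$coefficients),
                    std_error = if (is.null(object$se)) NA_real_
                                else unname(object$se[names(object$coefficients)]),
                    odds_ratio = exp(unname(object$coefficients)),
                    row.names = names(object$coefficients))
  structure(list(model = object, table = tab), class = "summary.insomnia_fit")
}

#' @export
print.summary.insomnia_fit <- function(x, ...) {
  print(x$model)
  cat("\nSelected covariates (post-selection refit standard errors):\n")
  print(signif(x$table, 6))
  invisible(x)
}

#' Calibrate the probability threshold to a target specificity
#'
#' Chooses the smallest candidate cut point whose specificity on the
#' validation negatives reaches the target, where candidates are the
#' observed validation probabilities plus a point just above the maximum
#' (classification is positive at probability >= threshold). Achieved
#' specificity and sensitivity are attached to the returned model.
#'
#' @param model An `insomnia_model` or `insomnia_fit`.
#' @param features Validation feature data frame.
#' @param labels Validation labels.
#' @param target_specificity Target, default 0.97.
#' @return The model with `threshold` set and fields
#'   `achieved_specificity`, `achieved_sensitivity` filled.
#' @export
select_threshold <- function(model, features, labels,
                             target_specificity = 0.97) {
  y <- as_binary_labels(labels, features$patient_id)
  if (!any(y == 0L)) stop("validation set contains no negatives")
  p <- predict(model, features, type = "response")
  neg <- p[y == 0L]
  n_neg <- length(neg)
  above_max <- min(1 - 1e-12, max(p) + 1e-9)
  if (target_specificity > 0 && n_neg < 1 / (1 - target_specificity)) {
    warning("too few negatives (", n_neg, ") to resolve specificity ",
            target_specificity, "; returning a threshold above the maximum ",
            "observed probability")
    thr <- above_max
  } else {
    candidates <- sort(unique(c(p, above_max)))
    spec <- vapply(candidates, function(t) mean(neg < t), numeric(1))
    ok <- which(spec >= target_specificity)
    thr <- candidates[ok[1]]
  }
  model$threshold <- thr
  model$achieved_specificity <- mean(neg < thr)
  model$achieved_sensitivity <- if (any(y == 1L)) mean(p[y == 1L] >= thr)
                                else NA_real_
  model
}

#' Bootstrap confidence interval for the validation AUROC
#'
#' Percentile 2.5/97.5 bounds over patient-resampled replicates; a
#' replicate that draws a single class is redrawn.
#'
#' @param model An `insomnia_model`.
#' @param features Validation feature data frame.
#' @param labels Validation labels.
#' @param reps Bootstrap replicates, default 1000.
#' @param seed Integer seed.
#' @return List with `auroc`, `ci_low`, `ci_high`, `reps`.
#' @export
bootstrap_auroc_ci <- function(model, features, labels, reps = 1000L,
                               seed = 1L) {
  y <- as_binary_labels(labels, features$patient_id)
  if (length(unique(y)) < 2L) stop("both classes required")
  p <- predict(model, features, type = "response")
  point <- auroc(p, y)
  set.seed(as.integer(seed))
  n <- length(y)
  stat <- numeric(reps)
  for (r in seq_len(reps)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
    }
    stat[r] <- auroc(p[idx], y[idx])
  }
  ci <- unname(stats::quantile(stat, c(0.025, 0.975), type = 7))
  list(auroc = point, ci_low = ci[1], ci_high = ci[2], reps = reps)
}

#' Permutation overfitting check
#'
#' Repeatedly re-splits the training set into sub-derivation and
#' sub-validation parts at the configured fraction, refits the full
#' adaptive-LASSO protocol on the sub-derivation part, and scores the
#' held-out part. A mean sub-validation AUROC close to the external
#' validation AUROC indicates the protocol is not overfitting.
#'
#' @param features Training feature data frame.
#' @param labels Training labels.
#' @param config A `train_config` (`overfit_permutations` controls the
#'   number of sub-splits; `seed` makes the whole check deterministic).
#' @return List with `mean_auroc`, `se` (`NA` for a single permutation),
#'   `aurocs`.
#' @export
overfitting_check <- function(features, labels, config = train_config()) {
  y <- as_binary_labels(labels, features$patient_id)
  R <- config$overfit_permutations
  aucs <- numeric(R)
  for (r in seq_len(R)) {
    sub_seed <- (config$seed + 7919L * r) %% .Machine$integer.max
    sp <- split_train_validation(features$patient_id, y,
                                 fraction = config$train_fraction,
                                 seed = sub_seed)
    tr <- features$patient_id %in% sp$train
    cfg_r <- config
    cfg_r$seed <- sub_seed
    fit <- fit_insomnia_model(features[tr, , drop = FALSE], y[tr], cfg_r)
    p <- predict(fit, features[!tr, , drop = FALSE], type = "response")
    aucs[r] <- auroc(p, y[!tr])
  }
  list(mean_auroc = mean(aucs),
       se = if (R > 1L) stats::sd(aucs) / sqrt(R) else NA_real_,
       aurocs = aucs)
}

#' Run the full protocol for each variable-subset configuration
#'
#' Splits once, then per subset fits the adaptive LASSO on the training
#' part, calibrates the threshold, and bootstraps the validation AUROC —
#' all on identical splits so the subsets are directly comparable.
#'
#' @param features Labeled feature data frame.
#' @param labels Labels for every row of `features`.
#' @param config A `train_config` (its `variable_subset` is ignored).
#' @param subsets Subset names to compare.
#' @return List with `table` (data frame: subset, auroc, ci_low, ci_high,
#'   threshold, achieved specificity/sensitivity) and `models` (named list
#'   of calibrated fits).
#' @export
compare_subsets <- function(features, labels, config = train_config(),
                            subsets = names(VARIABLE_SUBSETS)) {
  y <- as_binary_labels(labels, features$patient_id)
  sp <- split_train_validation(features$patient_id, y,
                               fraction = config$train_fraction,
                               seed = config$seed)
  tr <- features$patient_id %in% sp$train
  rows <- list(); models <- list()
  for (sub in subsets) {
    cfg <- config
    cfg$variable_subset <- sub
    fit <- fit_insomnia_model(features[tr, , drop = FALSE], y[tr], cfg)
    fit <- select_threshold(fit, features[!tr, , drop = FALSE], y[!tr],
                            config$target_specificity)
    bs <- bootstrap_auroc_ci(fit, features[!tr, , drop = FALSE], y[!tr],
                             reps = config$bootstrap_reps, seed = config$seed)
    rows[[sub]] <- data.frame(
      subset = sub, auroc = bs$auroc, ci_low = bs$ci_low,
      ci_high = bs$ci_high, threshold = fit$threshold,
      specificity = fit$achieved_specificity,
      sensitivity = fit$achieved_sensitivity,
      stringsAsFactors = FALSE)
    models[[sub]] <- fit
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, models = models)
}
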