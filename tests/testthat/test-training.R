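test_that("stratified split is exact, seeded, and floors the training share", {
  ids <- sprintf("p%03d", 1:493)
  y <- rep(c("insomnia", "no_insomnia"), c(226, 267))
  sp <- split_train_validation(ids, y, fraction = 2 / 3, seed = 4)
  expect_identical(length(sp$train),
                   as.integer(floor(2 / 3 * 226) + floor(2 / 3 * 267)))
  expect_identical(sort(c(sp$train, sp$validation)), sort(ids))
  expect_length(intersect(sp$train, sp$validation), 0L)
  # class balance is preserved within rounding
  ytr <- y[match(sp$train, ids)]
  expect_identical(sum(ytr == "insomnia"), as.integer(floor(2 / 3 * 226)))
  # determinism
  expect_identical(sp, split_train_validation(ids, y, fraction = 2 / 3, seed = 4))
  # tiny case and the single-class error
  sp3 <- split_train_validation(c("a", "b", "c"), c(1L, 1L, 0L),
                                fraction = 2 / 3, seed = 1)
  expect_length(sp3$train, 1L)  # floor(2/3*2) + floor(2/3*1)
  expect_error(split_train_validation(ids, rep("insomnia", 493)),
               "both classes")
})

test_that("rank and trapezoid AUROC agree, with half-credit ties", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:120, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(round(runif(n), 2))  # duplicates force tie handling
    a1 <- auroc(s, y)
    a2 <- insomniaphen:::auroc_trapezoid(s, y)
    expect_equal(a1, a2, tolerance = 1e-10)
  }
  # tiny hand case: scores 1,2,2,3 with labels 0,0,1,1 -> (1 + 0.5 + 2)/4
  expect_equal(auroc(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
})

test_that("AUROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  y <- rbinom(200, 1, 0.5)
  s <- rnorm(200) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(auroc(s, y), ref, tolerance = 1e-12)
})

test_that("label-independent scores give a null AUROC near 0.5", {
  set.seed(8)
  n1 <- 250; n0 <- 250
  y <- rep(c(1L, 0L), c(n1, n0))
  a <- auroc(rnorm(500), y)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))  # Mann-Whitney null SE
  expect_lt(abs(a - 0.5), 3 * se)
})

test_that("adaptive LASSO recovers the generating model at n = 5000", {
  sim <- simulate_from_model(published_model(), n = 5000, seed = 11)
  fit <- fit_insomnia_model(sim$features, sim$labels, train_config(seed = 11))
  truth <- coef(published_model())[-1]
  # all seven selected with the correct (positive) sign
  expect_setequal(names(fit$coefficients), names(truth))
  expect_true(all(fit$coefficients > 0))
  # and each within 3 estimated standard errors of its generating value
  z <- abs(fit$coefficients[names(truth)] - truth) / fit$se[names(truth)]
  expect_true(all(z < 3))
})

test_that("a pure-noise covariate is usually excluded by the penalty", {
  # append noise to a *subset* fit by hijacking an unused covariate slot:
  # signal lives in sleep notes only; joint codes are label-independent noise
  dropped <- 0L
  for (s in 1:10) {
    set.seed(1000 + s)
    n <- 1200
    x_sig <- rpois(n, 1)
    x_noise <- rpois(n, 2)
    p <- 1 / (1 + exp(-(-1.5 + 2 * x_sig)))
    y <- rbinom(n, 1, p)
    feats <- data.frame(patient_id = sprintf("q%04d", 1:n),
                        n_sleep_notes = x_sig, n_joint_codes = x_noise,
                        n_insomnia_codes = 0L, n_anxdep_codes = 0L,
                        n_psych_notes = 0L, n_insomnia_rx = 0L,
                        n_emr_facts = 0L)
    fit <- fit_insomnia_model(feats, y, train_config(seed = 1000 + s))
    if (!("n_joint_codes" %in% names(fit$coefficients))) dropped <- dropped + 1L
  }
  expect_gte(dropped, 8L)  # selection consistency: >= 80% of replicates
})

test_that("degenerate fits error out cleanly", {
  sim <- simulate_from_model(n = 100, seed = 5)
  expect_error(fit_insomnia_model(sim$features, rep(1L, 100), train_config()),
               "both classes")
  expect_error(fit_insomnia_model(sim$features[1:5, ], c(0, 1, 0, 1, 0),
                                  train_config()), "at least 10")
})

test_that("threshold selection anchors specificity at the target", {
  sim <- simulate_from_model(n = 3000, seed = 17)
  fit <- select_threshold(published_model(), sim$features, sim$labels,
                          target_specificity = 0.97)
  # recount specificity directly from classifications at the new threshold
  y <- sim$labels$status == "insomnia"
  cls <- predict(fit, sim$features, type = "class")
  spec <- mean(!cls[!y])
  expect_gte(spec, 0.97)
  expect_lte(spec, 1)
  expect_equal(fit$achieved_specificity, spec, tolerance = 1e-12)
  # target 0 -> minimum observed probability: everything classifies positive
  fit0 <- select_threshold(published_model(), sim$features, sim$labels,
                           target_specificity = 0)
  expect_true(all(predict(fit0, sim$features, type = "class")))
  # too few negatives to resolve the target -> warning + max threshold
  few <- sim$features[c(which(y)[1:20], which(!y)[1:3]), ]
  fl <- sim$labels[match(few$patient_id, sim$labels$patient_id), ]
  expect_warning(ft <- select_threshold(published_model(), few, fl, 0.97),
                 "too few negatives")
  expect_gte(ft$threshold, max(predict(ft, few, type = "response")))
})

test_that("bootstrap CI brackets the point AUROC and nails separation", {
  sim <- simulate_from_model(n = 400, seed = 23)
  bs <- bootstrap_auroc_ci(published_model(), sim$features, sim$labels,
                           reps = 400, seed = 23)
  expect_lte(bs$ci_low, bs$auroc)
  expect_gte(bs$ci_high, bs$auroc)
  # perfectly separated scores
  feats <- data.frame(patient_id = sprintf("s%02d", 1:40),
                      n_sleep_notes = rep(c(5L, 0L), each = 20),
                      n_insomnia_codes = 0L, n_anxdep_codes = 0L,
                      n_psych_notes = 0L, n_insomnia_rx = 0L,
                      n_joint_codes = 0L, n_emr_facts = 0L)
  ylab <- rep(c("insomnia", "no_insomnia"), each = 20)
  bs2 <- bootstrap_auroc_ci(published_model(), feats,
                            data.frame(patient_id = feats$patient_id,
                                       status = ylab), reps = 100, seed = 1)
  expect_identical(bs2$auroc, 1)
  expect_identical(c(bs2$ci_low, bs2$ci_high), c(1, 1))
})

test_that("overfitting check is deterministic and degenerates gracefully", {
  sim <- simulate_from_model(n = 400, seed = 29)
  cfg <- train_config(overfit_permutations = 5, seed = 29)
  a <- overfitting_check(sim$features, sim$labels, cfg)
  b <- overfitting_check(sim$features, sim$labels, cfg)
  expect_identical(a$mean_auroc, b$mean_auroc)
  one <- overfitting_check(sim$features, sim$labels,
                           train_config(overfit_permutations = 1, seed = 29))
  expect_true(is.na(one$se))
})

test_that("well-specified data shows no overfit: sub-validation tracks validation", {
  sim <- simulate_from_model(n = 1800, seed = 37)
  cfg <- train_config(overfit_permutations = 15, seed = 37)
  sp <- split_train_validation(sim$features$patient_id, sim$labels,
                               fraction = 2 / 3, seed = 37)
  tr <- sim$features$patient_id %in% sp$train
  fit <- fit_insomnia_model(sim$features[tr, ], sim$labels, cfg)
  ext <- auroc(predict(fit, sim$features[!tr, ], type = "response"),
               sim$labels$status[match(sim$features$patient_id[!tr],
                                       sim$labels$patient_id)])
  oc <- overfitting_check(sim$features[tr, ],
                          sim$labels[match(sim$features$patient_id[tr],
                                           sim$labels$patient_id), ], cfg)
  expect_lt(abs(oc$mean_auroc - ext), 0.05)
})

test_that("subset comparison respects planted information ordering", {
  sim <- simulate_corpus(sim_config(n_patients = 900, seed = 41))
  feats <- extract_features_corpus(sim$corpus)
  cfg <- train_config(bootstrap_reps = 50, overfit_permutations = 2, seed = 41)
  cmp <- compare_subsets(feats, sim$truth, cfg)
  tab <- cmp$table
  expect_setequal(tab$subset,
                  c("icd_only", "structured_only", "unstructured_only", "combined"))
  a <- function(s) tab$auroc[tab$subset == s]
  # notes carry the dominant planted signal; codes are sparse in cases
  expect_gte(a("combined"), a("unstructured_only") - 0.02)
  expect_gte(a("combined"), a("structured_only") - 0.02)
  expect_gte(a("unstructured_only"), a("icd_only") - 0.02)
  expect_true(all(tab$ci_low <= tab$auroc & tab$auroc <= tab$ci_high))
  # deterministic under the master seed
  cmp2 <- compare_subsets(feats, sim$truth, cfg)
  expect_identical(tab, cmp2$table)
})
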