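test_that("ROC worked examples", {
  expect_identical(roc_auc(c(3, 2, 1), c(1, 1, 0))$auc, 1)
  expect_identical(roc_auc(rep(5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  # one concordant, one discordant pair
  expect_identical(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "positive and one negative")
})

test_that("trapezoid AUC equals the Mann-Whitney statistic", {
  set.seed(71)
  for (i in 1:25) {
    n1 <- sample(3:30, 1); n0 <- sample(3:30, 1)
    scores <- c(rnorm(n1, 1), rnorm(n0))        # tie-free a.s.
    labels <- c(rep(1, n1), rep(0, n0))
    u <- unname(wilcox.test(scores[labels == 1], scores[labels == 0],
                            exact = FALSE)$statistic)
    expect_equal(roc_auc(scores, labels)$auc, u / (n1 * n0),
                 tolerance = 1e-12)
  }
  # with ties, ties count one half (pair-counting oracle)
  scores <- c(1, 2, 2, 3); labels <- c(0, 0, 1, 1)
  pairs <- expand.grid(p = which(labels == 1), n = which(labels == 0))
  mw <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                    ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(scores, labels)$auc, mw, tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(72)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, plogis(scores))
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("tpr and fpr are non-decreasing along descending thresholds", {
  set.seed(73)
  roc <- roc_auc(rnorm(100), rbinom(100, 1, 0.4))
  expect_false(is.unsorted(roc$tpr))
  expect_false(is.unsorted(roc$fpr))
  expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
})

test_that("a noise-free model separates survival at the horizon perfectly", {
  co <- strong_cohort(seed = 25, noise_sd = 0, intercept = 1500,
                      censor_fraction = 0.3)
  tr <- prepare_training(co)
  fit <- run_search(tr$led, tr$la, tr$ranking, gamma_config(D = 3))
  horizon <- median(tr$la)
  roc <- survival_roc(fit, tr$led, co$clinical, horizon = horizon)
  expect_equal(roc$auc, 1)
})

test_that("constant predictions give chance-level survival AUC", {
  co <- strong_cohort(seed = 26, censor_fraction = 0.2)
  tr <- prepare_training(co)
  fit <- fit_survival_model(tr$led, tr$la, integer(0))  # intercept only
  roc <- survival_roc(fit, tr$led, co$clinical, horizon = median(tr$la))
  expect_equal(roc$auc, 0.5)   # all scores tie
})

test_that("indeterminate censored patients are excluded at the horizon", {
  cl <- data.frame(
    submitter_id = c("a", "b", "c", "d"),
    vital_status = c("dead", "alive", "alive", "dead"),
    days_to_death = c(1000, NA, NA, 3000),
    days_to_last_follow_up = c(NA, 500, 2500, NA))
  led <- matrix(c(1, 2, 3, 4), 4,
                dimnames = list(c("a", "b", "c", "d"), "G1"))
  la <- c(a = 1000, b = 500, c = 2500, d = 3000)
  fit <- fit_survival_model(led, la, 1L)
  roc <- survival_roc(fit, led, cl, horizon = 1825)
  # b is alive with follow-up inside the horizon: indeterminate
  expect_identical(roc$n_excluded, 1L)
  expect_identical(roc$n_used, 3L)
})

test_that("LOOCV with an oracle scorer is perfect and calls it once per pair", {
  universe <- expand.grid(lncrna = sprintf("L%02d", 1:20),
                          disease = "prostate", stringsAsFactors = FALSE)
  pairs <- universe[c(2, 5, 9, 14), ]
  calls <- 0L
  oracle <- function(train, uni) {
    calls <<- calls + 1L
    as.numeric(uni$lncrna %in% pairs$lncrna)
  }
  roc <- loocv_association(pairs, universe, oracle)
  expect_identical(roc$auc, 1)
  expect_identical(calls, nrow(pairs))
  expect_identical(roc$n_folds, nrow(pairs))
})

test_that("LOOCV with random scores sits at chance level", {
  set.seed(74)
  universe <- expand.grid(lncrna = sprintf("L%03d", 1:100),
                          disease = "prostate", stringsAsFactors = FALSE)
  pairs <- universe[sample(100, 20), ]
  aucs <- replicate(30, {
    loocv_association(pairs, universe,
                      function(train, uni) runif(nrow(uni)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("model-based scores rank planted associations near the top", {
  co <- strong_cohort(seed = 27)
  tr <- prepare_training(co)
  fit <- run_search(tr$led, tr$la, tr$ranking, gamma_config())
  universe <- data.frame(lncrna = tr$ranking$transcript_ids,
                         disease = "prostate")
  pairs <- data.frame(lncrna = co$truth$causal_ids, disease = "prostate")
  pairs <- pairs[pairs$lncrna %in% universe$lncrna, ]
  roc <- loocv_association(pairs, universe,
                           model_association_scorer(fit, tr$led))
  expect_gt(roc$auc, 0.9)
})

test_that("scorer failures are reported with the offending fold", {
  universe <- data.frame(lncrna = c("a", "b", "c"), disease = "d")
  pairs <- universe[1:2, ]
  expect_error(
    loocv_association(pairs, universe,
                      function(train, uni) stop("boom")),
    "fold 1")
})
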