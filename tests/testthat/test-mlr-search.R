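test_that("initial selection seeds ultra-significant candidates", {
  p <- c(rep(1e-15, 107), seq(1e-10, 1e-4, length.out = 13))
  x0 <- initialize_selection(make_ranking(p))
  expect_identical(which(x0 == 1L), 1:107)
  expect_identical(sum(x0), 107L)
  # vacuous cutoff sets every bit
  expect_identical(sum(initialize_selection(make_ranking(p), 1)), 120L)
})

test_that("an empty seed falls back to the smallest-P candidates with a warning", {
  p <- seq(1e-6, 1e-3, length.out = 120)
  expect_warning(x0 <- initialize_selection(make_ranking(p)), "falling back")
  expect_identical(which(x0 == 1L), 1:12)   # max(10, 120/10)
  p2 <- seq(1e-6, 1e-3, length.out = 30)
  expect_warning(x02 <- initialize_selection(make_ranking(p2)), "falling back")
  expect_identical(which(x02 == 1L), 1:10)
})

test_that("the stagnation kick flips the leading block only on stagnation", {
  x <- c(1L, 0L, 1L, 0L)
  expect_identical(stagnation_kick(x, x, 3), c(0L, 1L, 0L, 0L))
  y <- c(0L, 0L, 1L, 0L)
  expect_identical(stagnation_kick(x, y, 3), x)   # differ at position 1
  # kick then correct respects the population cap
  set.seed(61)
  for (i in 1:10) {
    v <- sample(0:1, 30, replace = TRUE)
    theta <- sample(1:15, 1)
    kicked <- gamma_correct(stagnation_kick(v, v, theta), theta)
    expect_lte(sum(kicked), theta)
  }
})

test_that("a zero-iteration search reduces to stepwise of the seed set", {
  co <- strong_cohort(seed = 23, n_tumor = 60, n_normal = 25,
                      n_transcripts = 40, n_differential = 10, n_causal = 3)
  tr <- prepare_training(co)
  fit <- run_search(tr$led, tr$la, tr$ranking, gamma_config(D = 0))
  x0 <- initialize_selection(tr$ranking)
  sw <- stepwise_select(which(x0 == 1L), tr$led, tr$la)
  expect_identical(fit$selected_idx, sw$reduced_set)
  expect_equal(fit$aic_optimal, sw$aic, tolerance = 1e-10)
})

test_that("residual degrees of freedom follow n - delta - 1", {
  set.seed(62)
  led <- matrix(rlnorm(176 * 60), 176,
                dimnames = list(sprintf("T%03d", 1:176),
                                sprintf("G%03d", 1:60)))
  la <- rnorm(176, 1500, 300)
  fit <- fit_survival_model(led, la, 1:60)
  expect_identical(fit$residual_df, 115L)
  expect_identical(fit$delta, 60L)
  expect_length(fit$coefficients, 61L)
})

test_that("the search recovers a strongly planted sparse signal", {
  co <- strong_cohort(seed = 7)
  tr <- prepare_training(co)
  fit <- run_search(tr$led, tr$la, tr$ranking, gamma_config())
  recovered <- mean(co$truth$causal_ids %in% fit$selected_ids)
  expect_gte(recovered, 0.9)
  se <- summary(fit$fit)$coefficients[co$truth$causal_ids, 2]
  dev <- abs(fit$coefficients[co$truth$causal_ids] -
             co$truth$coefficients)
  expect_true(all(dev <= 3 * se))
})

test_that("the bulletin-board AIC is non-increasing over iterations", {
  co <- strong_cohort(seed = 29, n_tumor = 80, n_normal = 30,
                      n_transcripts = 60, n_differential = 15, n_causal = 4)
  tr <- prepare_training(co)
  fit <- run_search(tr$led, tr$la, tr$ranking, gamma_config())
  expect_true(all(diff(fit$trace$best_aic) <= 0))
  expect_lte(fit$aic_optimal, fit$trace$stepwise_aic[1L])
})

test_that("fitted residuals are orthogonal to every selected column", {
  co <- strong_cohort(seed = 33, n_tumor = 70, n_normal = 30,
                      n_transcripts = 50, n_differential = 12, n_causal = 3)
  tr <- prepare_training(co)
  fit <- run_search(tr$led, tr$la, tr$ranking, gamma_config(D = 5))
  r <- resid(fit$fit)
  for (id in fit$selected_ids) {
    col <- tr$led[, id]
    expect_lt(abs(sum(r * col)) / (sqrt(sum(r^2)) * sqrt(sum(col^2)) + 1e-30),
              1e-8)
  }
})

test_that("collinear selected columns are dropped before the final fit", {
  set.seed(63)
  led <- matrix(rlnorm(50 * 3), 50,
                dimnames = list(sprintf("T%02d", 1:50), c("A", "B", "C")))
  led[, "C"] <- led[, "A"]
  la <- 100 + 20 * led[, "A"] + rnorm(50)
  expect_warning(fit <- fit_survival_model(led, la, 1:3), "collinear")
  expect_identical(fit$dropped, "C")
  expect_identical(fit$delta, 2L)
})

test_that("overall model significance behaves at the extremes", {
  set.seed(64)
  led <- matrix(rnorm(50), 50, dimnames = list(sprintf("T%02d", 1:50), "G1"))
  la_perfect <- 10 + 3 * led[, 1] + rnorm(50, sd = 1e-8)
  fit <- fit_survival_model(led, la_perfect, 1L)
  expect_lt(model_significance(fit), 1e-12)
  la_noise <- rnorm(50)
  fit0 <- fit_survival_model(led, la_noise, integer(0))
  expect_true(is.na(model_significance(fit0)))   # intercept-only: no F test
})

test_that("search inputs are validated", {
  co <- strong_cohort(seed = 3, n_tumor = 30, n_normal = 15,
                      n_transcripts = 20, n_differential = 6, n_causal = 2)
  tr <- prepare_training(co)
  expect_error(run_search(tr$led, tr$la[-1], tr$ranking, gamma_config()),
               "length")
  expect_error(run_search(tr$led[, rev(seq_len(ncol(tr$led)))], tr$la,
                          tr$ranking, gamma_config()),
               "ranked candidates")
})

test_that("predictions require the selected transcripts", {
  co <- strong_cohort(seed = 3, n_tumor = 30, n_normal = 15,
                      n_transcripts = 20, n_differential = 6, n_causal = 2)
  tr <- prepare_training(co)
  fit <- suppressWarnings(run_search(tr$led, tr$la, tr$ranking,
                                     gamma_config(D = 2)))
  pred <- predict(fit, tr$led)
  expect_length(pred, nrow(tr$led))
  expect_error(predict(fit, tr$led[, 0, drop = FALSE]), "lacks")
})
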