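#' Configuration of the Gamma subset search
#'
#' @param D maximal Gamma iterations (default 10).
#' @param init_threshold P-value cutoff seeding the initial selection
#'   (default \code{1e-12}): every candidate below it starts active, and
#'   the retention cap \eqn{\theta} is set to that initial count.
#' @param schedule decay schedule name, see [decay_coefficient()].
#' @param lookup optional explicit per-iteration decay values for
#'   \code{schedule = "lookup"}.
#' @return An object of class \code{"gamma_config"}.
#' @export
gamma_config <- function(D = 10, init_threshold = 1e-12,
                         schedule = "tanh", lookup = NULL) {
  if (!is.numeric(D) || length(D) != 1L || D < 0 || D != floor(D))
    stop_input("`D` must be a nonnegative integer")
  if (!is.numeric(init_threshold) || init_threshold <= 0 ||
      init_threshold > 1)
    stop_input("`init_threshold` must be in (0, 1]")
  structure(list(D = as.integer(D), init_threshold = init_threshold,
                 schedule = schedule, lookup = lookup),
            class = "gamma_config")
}

#' Seed the selection vector from ultra-significant candidates
#'
#' Bit \eqn{j} of the initial selection \eqn{X^0} is set when candidate
#' \eqn{G_j}'s differential-expression P value falls below
#' \code{init_threshold} (default \eqn{10^{-12}}).  If no candidate
#' qualifies, the search still needs a non-empty seed: the
#' \eqn{\max(10, \lceil C/10 \rceil)} smallest-P candidates are used
#' instead, with a warning.
#'
#' @param ranking a \code{candidate_ranking} (P ascending).
#' @param init_threshold seeding P cutoff.
#' @return Integer 0/1 vector over the ranked candidates.
#' @export
initialize_selection <- function(ranking, init_threshold = 1e-12) {
  stopifnot(inherits(ranking, "candidate_ranking"))
  C <- length(ranking$transcript_ids)
  if (C == 0L) stop_input("ranking is empty; nothing to search")
  bits <- as.integer(ranking$p_values < init_threshold)
  if (sum(bits) == 0L) {
    k <- min(C, max(10L, ceiling(C / 10)))
    warning("no candidate below the seeding threshold ", init_threshold,
            "; falling back to the ", k, " smallest-P candidates",
            call. = FALSE)
    bits[seq_len(k)] <- 1L   # ranking is P-ascending
  }
  bits
}

#' Escape a stagnated selection by flipping its leading block
#'
#' If the leading \eqn{\theta} bits of the current vector equal those of
#' the previous iteration's vector, the search has stalled in its most
#' significant block; those \eqn{\theta} positions are bitwise inverted to
#' force the search elsewhere.  Otherwise the vector is returned
#' unchanged.  (Callers apply the Gamma correction afterward.)
#'
#' @param x_current,x_previous 0/1 selection vectors of equal length.
#' @param theta size of the leading block compared and flipped.
#' @return The (possibly kicked) current selection vector.
#' @export
stagnation_kick <- function(x_current, x_previous, theta) {
  x_current <- check_selection(x_current)
  x_previous <- check_selection(x_previous)
  if (length(x_current) != length(x_previous))
    stop_input("selection vectors must have equal length")
  theta <- min(as.integer(theta), length(x_current))
  if (theta < 1) return(x_current)
  head_idx <- seq_len(theta)
  if (all(x_current[head_idx] == x_previous[head_idx]))
    x_current[head_idx] <- 1L - x_current[head_idx]
  x_current
}

#' Search for the transcript subset best predicting survival
#'
#' Runs the full subset search: seed the selection from
#' ultra-significant candidates (retention cap \eqn{\theta} = seed size),
#' then for \eqn{d = 1, \ldots, D} apply the Gamma operation (windowed
#' bitwise inversion with moving center and decaying width), a stagnation
#' kick, the Gamma correction, and a bidirectional stepwise-AIC reduction
#' of the active set.  A best-so-far bulletin board keeps the reduced set
#' with the smallest AIC seen; stepwise results never overwrite the
#' vector the Gamma operation acts on, only the bulletin board.  After
#' \eqn{D} rounds the winning subset is fitted by OLS, giving the
#' coefficient vector \eqn{\Theta} used for survival prediction and
#' association scoring.
#'
#' The search contains no randomness: identical inputs give identical
#' results.
#'
#' @param led training expression matrix from [build_led()] (rows =
#'   tumor samples sorted by ID, columns = P-ranked candidates).
#' @param la survival response from [build_survival_vector()], ordered as
#'   \code{rownames(led)}.
#' @param ranking the \code{candidate_ranking} that ordered the columns.
#' @param config a [gamma_config()].
#' @return A fitted model of class \code{"mlr_model"} (see
#'   [fit_survival_model()]) with extra fields: \code{aic_optimal} (best
#'   stepwise AIC) and \code{trace} (per-iteration data frame: iteration,
#'   center, xi, clipped range, post-correction population, stepwise AIC,
#'   best AIC so far).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_normal = 20, n_tumor = 60,
#'                                       n_transcripts = 40,
#'                                       n_differential = 10, n_causal = 3,
#'                                       effect_size = 4, noise_sd = 25))
#' rk <- differential_screen(cohort$normal, cohort$tumor)
#' led <- build_led(cohort$tumor, rk)
#' la <- build_survival_vector(cohort$clinical, rownames(led))
#' fit <- run_search(led, la, rk, gamma_config(D = 4))
#' fit$selected_ids
#' @export
run_search <- function(led, la, ranking, config = gamma_config()) {
  stopifnot(inherits(config, "gamma_config"),
            inherits(ranking, "candidate_ranking"))
  n <- nrow(led)
  if (length(la) != n)
    stop_input("`la` length (", length(la),
               ") must equal the training-matrix row count (", n, ")")
  if (!identical(colnames(led), ranking$transcript_ids))
    stop_input("training-matrix columns must be the ranked candidates, in order")
  C <- ncol(led)
  D <- config$D

  clamp_active <- function(active) {
    if (length(active) >= n - 2) {
      warning("active set (", length(active), ") reaches n - 2; ",
              "truncated to the ", n - 3, " smallest-P members",
              call. = FALSE)
      active <- sort(active)[seq_len(n - 3)]
    }
    active
  }

  x0 <- initialize_selection(ranking, config$init_threshold)
  theta <- sum(x0)

  sw0 <- stepwise_select(clamp_active(which(x0 == 1L)), led, la)
  best_set <- sw0$reduced_set
  best_aic <- sw0$aic
  msg("d=0: seed population ", theta, ", stepwise AIC ",
      format(best_aic, digits = 8))

  trace <- list()
  trace[[1L]] <- data.frame(d = 0L, center = NA_real_, xi = NA_real_,
                            range_lo = NA_integer_, range_hi = NA_integer_,
                            population = theta, stepwise_aic = sw0$aic,
                            best_aic = best_aic)

  x_prev <- x0
  x_cur <- x0
  d <- 1L
  while (d <= D) {
    center <- variation_center(C, D, d)
    xi <- decay_coefficient(D, d, config$schedule, config$lookup)
    range <- tryCatch(variation_range(center, xi, C),
                      mlrldacp_degenerate_range = function(cond) {
                        msg("d=", d, ": ", conditionMessage(cond),
                            "; iteration skipped")
                        NULL
                      })
    if (is.null(range)) {
      trace[[d + 1L]] <- data.frame(d = d, center = center, xi = xi,
                                    range_lo = NA_integer_,
                                    range_hi = NA_integer_,
                                    population = sum(x_cur),
                                    stepwise_aic = NA_real_,
                                    best_aic = best_aic)
      d <- d + 1L
      next
    }
    x_new <- gamma_operate(x_cur, range)
    x_new <- stagnation_kick(x_new, x_prev, theta)
    x_new <- gamma_correct(x_new, theta)
    x_prev <- x_cur
    x_cur <- x_new

    active <- which(x_cur == 1L)
    sw_aic <- NA_real_
    if (length(active)) {
      sw <- stepwise_select(clamp_active(active), led, la)
      sw_aic <- sw$aic
      if (sw$aic < best_aic) {
        best_aic <- sw$aic
        best_set <- sw$reduced_set
      }
    }
    msg("d=", d, ": center ", center, ", xi ", format(xi, digits = 4),
        ", range [", range[1L], ",", range[2L], "], population ",
        length(active), ", stepwise AIC ", format(sw_aic, digits = 8))
    trace[[d + 1L]] <- data.frame(d = d, center = center, xi = xi,
                                  range_lo = range[1L],
                                  range_hi = range[2L],
                                  population = length(active),
                                  stepwise_aic = sw_aic,
                                  best_aic = best_aic)
    d <- d + 1L
  }

  if (length(best_set) > n - 2) {
    warning("optimal set larger than n - 2; truncated to the ", n - 2,
            " smallest-P members", call. = FALSE)
    best_set <- sort(best_set)[seq_len(n - 2)]
  }
  model <- fit_survival_model(led, la, best_set)
  model$aic_optimal <- best_aic
  model$theta <- theta
  model$trace <- do.call(rbind, trace)
  model
}

#' Fit the final survival regression on a selected transcript subset
#'
#' Ordinary least squares of survival days on the selected expression
#' columns, with intercept.  Collinear columns are dropped (with a
#' warning, IDs recorded in \code{$dropped}) before the final fit so every
#' reported coefficient is estimable.
#'
#' @param led training expression matrix.
#' @param la survival response vector.
#' @param selected integer column indices of the selected subset (may be
#'   empty: intercept-only model).
#' @return An object of class \code{"mlr_model"}:
#'   \describe{
#'     \item{selected_ids}{transcript IDs of the fitted subset.}
#'     \item{selected_idx}{their column indices in \code{led}.}
#'     \item{delta}{number of fitted transcripts.}
#'     \item{coefficients}{named vector: intercept then one coefficient
#'       per selected transcript (survival-days per expression unit).}
#'     \item{residual_se, residual_df}{residual standard error (days) on
#'       \eqn{n - \Delta - 1} degrees of freedom.}
#'     \item{model_p}{overall regression F-test P value.}
#'     \item{aic}{AIC of the fit.}
#'     \item{dropped}{IDs dropped for collinearity.}
#'     \item{fit}{the underlying \code{lm} object.}
#'   }
#' @export
fit_survival_model <- function(led, la, selected) {
  selected <- sort(unique(as.integer(selected)))
  n <- nrow(led)
  stopifnot(length(la) == n)
  if (length(selected) > n - 2)
    stop_input("cannot fit ", length(selected), " transcripts on ", n,
               " samples (need delta <= n - 2)")
  ids <- colnames(led)[selected]
  dat <- as.data.frame(led[, selected, drop = FALSE])
  names(dat) <- ids
  dat$.la <- as.numeric(la)
  fit <- stats::lm(.la ~ ., data = dat)
  aliased <- is.na(stats::coef(fit))
  dropped <- character(0)
  if (any(aliased)) {
    dropped <- intersect(names(stats::coef(fit))[aliased], ids)
    warning("dropping collinear column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    keep <- setdiff(ids, dropped)
    selected <- selected[ids %in% keep]
    ids <- keep
    dat <- dat[, c(ids, ".la"), drop = FALSE]
    fit <- stats::lm(.la ~ ., data = dat)
  }
  s <- summary(fit)
  structure(list(selected_ids = ids, selected_idx = selected,
                 delta = length(ids),
                 coefficients = stats::coef(fit),
                 residual_se = s$sigma,
                 residual_df = fit$df.residual,
                 model_p = model_f_pvalue(s),
                 aic = stats::AIC(fit),
                 dropped = dropped, fit = fit),
            class = "mlr_model")
}

model_f_pvalue <- function(s) {
  fs <- s$fstatistic
  if (is.null(fs)) return(NA_real_)
  unname(stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
}

#' Overall significance of the fitted survival regression
#'
#' The overall F test of the regression (all transcript coefficients
#' jointly zero), reported alongside the residual standard error on
#' \eqn{n - \Delta - 1} degrees of freedom.
#'
#' @param model an \code{"mlr_model"}.
#' @return The overall P value (\code{NA} for an intercept-only model).
#' @export
model_significance <- function(model) {
  stopifnot(inherits(model, "mlr_model"))
  if (model$residual_df <= 0)
    stop_input("model has no residual degrees of freedom")
  model$model_p
}

#' Predict survival days for expression profiles
#'
#' @param object an \code{"mlr_model"}.
#' @param newdata expression matrix containing the model's selected
#'   transcript columns.
#' @param ... unused.
#' @return Numeric vector of predicted survival days.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  absent <- setdiff(object$selected_ids, colnames(newdata))
  if (length(absent))
    stop_input("newdata lacks selected transcript(s): ",
               paste(absent, collapse = ", "))
  dat <- as.data.frame(newdata[, object$selected_ids, drop = FALSE])
  names(dat) <- object$selected_ids
  unname(stats::predict(object$fit, newdata = dat))
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("Survival regression on %d selected transcript(s)\n", x$delta))
  cat(sprintf("  residual SE %.4g on %d degrees of freedom\n",
              x$residual_se, x$residual_df))
  if (!is.na(x$model_p))
    cat(sprintf("  overall F-test P = %.4g\n", x$model_p))
  if (!is.null(x$aic_optimal))
    cat(sprintf("  best stepwise AIC %.2f\n", x$aic_optimal))
  invisible(x)
}

#' Write the fitted coefficient table and diagnostics
#'
#' The coefficient table lists the intercept and one row per selected
#' transcript; the diagnostics block reports residual standard error,
#' residual degrees of freedom, and the overall P value.
#'
#' @param model an \code{"mlr_model"}.
#' @param path output TSV path.
#' @export
write_coefficients <- function(model, path) {
  cf <- model$coefficients
  df <- data.frame(serial = c("Intercept",
                              sprintf("X%d", model$selected_idx)),
                   transcript_id = c("---------", model$selected_ids),
                   coefficient = sprintf("%.15g", unname(cf)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
write_diagnostics <- function(model, path) {
  df <- data.frame(residual_standard_error = sprintf("%.15g", model$residual_se),
                   residual_df = model$residual_df,
                   p_value = sprintf("%.15g", model$model_p),
                   aic = sprintf("%.15g", model$aic))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
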