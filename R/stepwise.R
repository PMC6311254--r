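#' Gaussian AIC of an ordinary-least-squares survival regression
#'
#' Fits the survival response on the given expression columns by OLS (with
#' intercept) and returns the Akaike information criterion under the full
#' Gaussian-likelihood convention:
#' \deqn{AIC = n \ln(2\pi \, RSS/n) + n + 2(k + 2)}
#' with \eqn{k} predictors plus intercept plus the noise variance as free
#' parameters.  This matches \code{stats::AIC} on an \code{lm} fit, so
#' logged values are comparable across software; only differences matter
#' for selection.  Smaller is better.
#'
#' Rank-deficient designs are handled by pivoting: collinear columns are
#' dropped with a warning and \eqn{k} is the effective rank.
#'
#' @param design numeric matrix of predictor columns (no intercept column;
#'   0 columns = intercept-only model).
#' @param response numeric response vector (survival days).
#' @return The AIC value (\code{-Inf} if the fit is exact).
#' @examples
#' y <- rnorm(30)
#' model_aic(matrix(rnorm(30), ncol = 1), y)
#' @export
model_aic <- function(design, response) {
  if (is.null(dim(design))) design <- as.matrix(design)
  n <- length(response)
  stopifnot(nrow(design) == n)
  if (ncol(design) >= n - 1)
    stop_input("number of predictors must be < n - 1")
  X <- cbind(`(Intercept)` = rep(1, n), design)
  fit <- stats::lm.fit(X, response)
  if (fit$rank < ncol(X))
    warning("design is rank-deficient; ", ncol(X) - fit$rank,
            " collinear column(s) dropped", call. = FALSE)
  k <- fit$rank - 1L
  rss <- sum(fit$residuals^2)
  n * log(2 * pi * rss / n) + n + 2 * (k + 2)
}

#' Bidirectional stepwise-AIC reduction of a candidate component set
#'
#' Alternates a forward phase (repeatedly add the candidate whose
#' inclusion most decreases the AIC, while any addition strictly decreases
#' it) and a backward phase (repeatedly remove the active component whose
#' exclusion most decreases the AIC), tracked by two flags — one per
#' direction — each reset whenever the opposite direction succeeds.  The
#' loop terminates only when both directions stall in succession; since
#' every accepted move strictly decreases the AIC and the subset lattice
#' is finite, termination is guaranteed.  Ties are broken toward the
#' smaller component index.
#'
#' "Significant effect" is operationalised as "the move strictly decreases
#' AIC": AIC is the search's sole quality measure.
#'
#' @param candidates integer vector of candidate column indices into
#'   \code{led} (the active set the search proposes).
#' @param led training expression matrix (samples x ranked candidates).
#' @param la survival response vector (length \code{nrow(led)}).
#' @return A list of class \code{"stepwise_result"}:
#'   \describe{
#'     \item{reduced_set}{surviving component indices (sorted).}
#'     \item{aic}{AIC of the regression on the surviving components.}
#'     \item{history}{data frame of moves: action (\code{add}/
#'       \code{remove}), component, AIC after the move.}
#'   }
#' @export
stepwise_select <- function(candidates, led, la) {
  candidates <- sort(unique(as.integer(candidates)))
  n <- length(la)
  stopifnot(nrow(led) == n)
  if (length(candidates) == 0L) stop_input("`candidates` must be non-empty")
  if (any(candidates < 1L | candidates > ncol(led)))
    stop_input("candidate indices outside the training matrix columns")
  if (length(candidates) >= n - 2)
    stop_input("need fewer candidates than n - 2 (",
               length(candidates), " >= ", n - 2, ")")

  aic_of <- function(set) {
    suppressWarnings(model_aic(led[, set, drop = FALSE], la))
  }

  temp <- integer(0)
  aic_cur <- aic_of(temp)
  history <- list()
  flag_add <- 0L; flag_remove <- 0L

  repeat {
    # forward phase: best-first additions while AIC strictly improves
    repeat {
      pool <- setdiff(candidates, temp)
      if (length(pool) == 0L) { flag_add <- 1L; break }
      aics <- vapply(pool, function(j) aic_of(c(temp, j)), numeric(1))
      best <- which.min(aics)   # ties resolve to the smaller index
      if (aics[best] < aic_cur) {
        temp <- c(temp, pool[best])
        aic_cur <- aics[best]
        flag_add <- 0L; flag_remove <- 0L
        history[[length(history) + 1L]] <-
          data.frame(action = "add", component = pool[best], aic = aic_cur)
      } else { flag_add <- 1L; break }
    }
    if (flag_add == 1L && flag_remove == 1L) break
    # backward phase: best-first removals while AIC strictly improves
    repeat {
      if (length(temp) == 0L) { flag_remove <- 1L; break }
      aics <- vapply(seq_along(temp),
                     function(i) aic_of(temp[-i]), numeric(1))
      ord <- order(aics, temp)  # tie toward the smaller component index
      best <- ord[1L]
      if (aics[best] < aic_cur) {
        history[[length(history) + 1L]] <-
          data.frame(action = "remove", component = temp[best],
                     aic = aics[best])
        temp <- temp[-best]
        aic_cur <- aics[best]
        flag_add <- 0L; flag_remove <- 0L
      } else { flag_remove <- 1L; break }
    }
    if (flag_add == 1L && flag_remove == 1L) break
  }

  structure(list(reduced_set = sort(temp), aic = aic_cur,
                 history = if (length(history)) do.call(rbind, history)
                           else data.frame(action = character(0),
                                           component = integer(0),
                                           aic = numeric(0))),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("Stepwise reduction: %d component(s) retained, AIC %.2f\n",
              length(x$reduced_set), x$aic))
  invisible(x)
}
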