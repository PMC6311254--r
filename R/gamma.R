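#' The Gamma operation: a windowed bitwise variation operator
#'
#' The search over candidate transcript subsets is driven by a deterministic
#' variation operator acting on a binary inclusion vector \eqn{X} of length
#' \eqn{C(X)} (one bit per P-ranked candidate; bit \eqn{j} = 1 means
#' transcript \eqn{G_j} is active).  Each iteration \eqn{d} of at most
#' \eqn{D} rounds flips all bits inside a window centred at
#' \code{variation_center(C, D, d)} whose half-width
#' \eqn{\xi(d) \cdot C/2} shrinks with the decay coefficient
#' \code{decay_coefficient(D, d)}.  After each flip, a Gamma correction caps
#' the active set at \eqn{\theta} bits, keeping the lowest-index (most
#' significant) ones.
#'
#' @name gamma-operation
#' @keywords internal
NULL

#' Variation center of the d-th Gamma iteration
#'
#' The window centers alternate around the vector midpoint \eqn{C/2} and
#' spread outward by one step of \eqn{C/D} per pair of iterations:
#' \eqn{C/2} at \eqn{d = 1}, then
#' \eqn{C/2 + (C/D)(-1)^{d-1}\lfloor d/2 \rfloor} for \eqn{d \ge 2}.
#' Over a full run the centers are evenly distributed on both sides of the
#' midpoint so every candidate position falls under the window of some
#' iteration.
#'
#' @param C length of the selection vector (number of ranked candidates).
#' @param D maximal number of iterations.
#' @param d current iteration, in \code{1:D}.
#' @return The (possibly fractional) center position.
#' @examples
#' variation_center(50, 10, 2)  # 20
#' variation_center(50, 10, 9)  # 45
#' @export
variation_center <- function(C, D, d) {
  stopifnot(is.numeric(C), is.numeric(D), is.numeric(d), length(d) == 1L)
  if (d < 1 || d > D || d != floor(d))
    stop_input("`d` must be an integer in [1, D]; got ", d)
  if (d == 1) return(C / 2)
  C / 2 + (C / D) * (-1)^(d - 1) * floor(d / 2)
}

#' Decay coefficient controlling the variation window width
#'
#' The decay coefficient \eqn{\xi(d) \in (0, 1]} shrinks the flip window as
#' the search proceeds: wide, exploratory windows early (\eqn{\xi} close to
#' 1 at \eqn{d = 1}) and narrow, refining windows late, with a hard floor
#' of exactly 0.1 at the final iteration and from \eqn{d \ge 10} on.
#'
#' Three schedules are available:
#' \describe{
#'   \item{\code{"tanh"}}{(default) \eqn{\tanh(2 (D - d) / (D + 1))} for
#'     \eqn{d \le 9}; starts above 0.9 and decreases strictly.}
#'   \item{\code{"tanh75"}}{\eqn{\tanh(0.75 (D - d) / (D + 1))}; a gentler
#'     alternative parameterisation.}
#'   \item{\code{"lookup"}}{explicit per-iteration values supplied via
#'     \code{lookup}; entry \code{d} is used for \eqn{d \le 9}.}
#' }
#'
#' @param D maximal number of iterations.
#' @param d current iteration (\eqn{d \ge 1}).
#' @param schedule one of \code{"tanh"}, \code{"tanh75"}, \code{"lookup"}.
#' @param lookup numeric vector of per-iteration values for
#'   \code{schedule = "lookup"}.
#' @return \eqn{\xi(d)}, a value in \eqn{(0, 1]}.
#' @examples
#' decay_coefficient(10, 10)  # 0.1 exactly
#' decay_coefficient(10, 1)   # ~0.927
#' @export
decay_coefficient <- function(D, d, schedule = c("tanh", "tanh75", "lookup"),
                              lookup = NULL) {
  stopifnot(is.numeric(D), is.numeric(d), length(d) == 1L)
  if (d < 1 || d != floor(d)) stop_input("`d` must be an integer >= 1; got ", d)
  if (is.character(schedule)) {
    schedule <- tryCatch(match.arg(schedule),
                         error = function(e) stop_input(
                           "unknown decay schedule: ", schedule[1L]))
  } else {
    stop_input("unknown decay schedule")
  }
  # hard floor: final iteration (and everything from d = 10 on) is 0.1
  if (d >= 10 || d >= D) return(0.1)
  switch(schedule,
    tanh   = tanh(2 * (D - d) / (D + 1)),
    tanh75 = tanh(0.75 * (D - d) / (D + 1)),
    lookup = {
      if (is.null(lookup) || length(lookup) < d)
        stop_input("`lookup` schedule requires a value for iteration ", d)
      lookup[[d]]
    })
}

#' Variation range of a Gamma iteration
#'
#' The raw window is \eqn{[center - \xi C/2,\; center + \xi C/2 - 1]};
#' endpoints are rounded to the nearest integer and the window is clipped
#' to the valid index range \eqn{[1, C]}.  Parts of the raw window falling
#' outside \eqn{[1, C]} "overflow" and are discarded.
#'
#' @param center window center (from [variation_center()]).
#' @param xi decay coefficient in \eqn{(0, 1]}.
#' @param C selection-vector length.
#' @return Integer vector \code{c(lo, hi)}, the inclusive clipped window.
#'   If the clipped window is empty, signals a condition of class
#'   \code{"mlrldacp_degenerate_range"} (callers skip the iteration).
#' @examples
#' variation_range(20, 0.8, 50)   # c(1, 39)
#' variation_range(45, 0.16, 50)  # c(41, 48)
#' @export
variation_range <- function(center, xi, C) {
  stopifnot(is.numeric(center), is.numeric(xi), is.numeric(C))
  if (xi <= 0 || xi > 1) stop_input("`xi` must be in (0, 1]; got ", xi)
  lo <- round(center - xi * C / 2)
  hi <- round(center + xi * C / 2 - 1)
  lo <- max(lo, 1)
  hi <- min(hi, C)
  if (lo > hi) {
    cond <- structure(
      class = c("mlrldacp_degenerate_range", "error", "condition"),
      list(message = sprintf(
        "variation range empty after clipping (center=%g, xi=%g, C=%g)",
        center, xi, C), call = sys.call(-1)))
    stop(cond)
  }
  c(as.integer(lo), as.integer(hi))
}

#' Bitwise inversion within a variation range
#'
#' Flips every bit of the selection vector whose index lies inside the
#' inclusive window \code{range}; bits outside are untouched.  The operator
#' is an involution: applying the same window twice restores the input.
#'
#' @param x integer/numeric 0/1 selection vector.
#' @param range inclusive index window \code{c(lo, hi)} within
#'   \code{[1, length(x)]}.
#' @return The flipped selection vector (the input is not modified).
#' @examples
#' gamma_operate(c(1, 1, 0, 0, 1), c(2, 4))  # 1 0 1 1 1
#' @export
gamma_operate <- function(x, range) {
  x <- check_selection(x)
  stopifnot(length(range) == 2L)
  lo <- range[[1L]]; hi <- range[[2L]]
  if (lo < 1 || hi > length(x) || lo > hi)
    stop_input("range [", lo, ", ", hi, "] outside [1, ", length(x), "]")
  idx <- lo:hi
  x[idx] <- 1L - x[idx]
  x
}

#' Gamma correction: cap the active set at theta bits
#'
#' After a bitwise inversion the active set may exceed the retention cap
#' \eqn{\theta}.  Only the \eqn{\theta} one-bits of smallest index remain
#' valid (positions are ordered by ascending differential-expression P, so
#' smallest index = most significant candidate); all later one-bits are
#' reset to 0.  Idempotent, and never increases the population count.
#'
#' @param x 0/1 selection vector.
#' @param theta retention cap (\eqn{\ge 1}).
#' @return The corrected selection vector.
#' @examples
#' gamma_correct(c(1, 1, 0, 0, 1, 0, 1), 2)  # keeps positions 1, 2
#' @export
gamma_correct <- function(x, theta) {
  x <- check_selection(x)
  stopifnot(is.numeric(theta), length(theta) == 1L)
  if (theta < 1) stop_input("`theta` must be >= 1; got ", theta)
  ones <- which(x == 1L)
  if (length(ones) > theta) x[ones[-seq_len(theta)]] <- 0L
  x
}

# Validate and canonicalise a 0/1 selection vector.
check_selection <- function(x) {
  if (!is.numeric(x) && !is.integer(x) && !is.logical(x))
    stop_input("selection vector must be numeric 0/1")
  x <- as.integer(x)
  if (anyNA(x) || any(x != 0L & x != 1L))
    stop_input("selection vector entries must all be 0 or 1")
  x
}
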