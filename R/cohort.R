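#' Specify a synthetic two-group lncRNA cohort
#'
#' Describes a simulated cohort with the statistical structure the survival
#' regression assumes: two sample groups (normal / tumor) whose expression
#' differs for a planted subset of transcripts, and a tumor survival time
#' generated as a sparse linear combination of a causal transcript subset
#' plus Gaussian noise.  Expression values are drawn log-normal (baseline
#' meanlog 1, sdlog 0.5) so they are nonnegative, like RPKM-style
#' quantities.
#'
#' Defaults mirror a prostate-cancer-sized cohort: 44 normal and 176 tumor
#' samples, 600 simulated transcripts of which 481 carry a true group mean
#' shift.
#'
#' @param n_normal,n_tumor sample counts per group.
#' @param n_transcripts total transcripts simulated.
#' @param n_differential transcripts with a true group mean shift
#'   (\code{n_causal <= n_differential <= n_transcripts}).
#' @param n_causal transcripts with nonzero true survival coefficient
#'   (causal transcripts are a subset of the differential ones).
#' @param effect_size group mean shift, in expression units.
#' @param true_coefficients numeric vector of length \code{n_causal}:
#'   causal-effect weights in survival-days per expression unit.  Default:
#'   magnitudes evenly spaced in [50, 150] with alternating sign.
#' @param intercept baseline survival time in days.
#' @param noise_sd survival-noise standard deviation in days.
#' @param censor_fraction fraction of tumor samples marked alive.
#' @param seed integer RNG seed.
#' @return An object of class \code{"cohort_spec"}.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_normal = 44, n_tumor = 176, n_transcripts = 600,
                        n_differential = 481, n_causal = 8,
                        effect_size = 2, true_coefficients = NULL,
                        intercept = 2000, noise_sd = 100,
                        censor_fraction = 0.4, seed = 1L) {
  spec <- list(n_normal = n_normal, n_tumor = n_tumor,
               n_transcripts = n_transcripts,
               n_differential = n_differential, n_causal = n_causal,
               effect_size = effect_size,
               true_coefficients = true_coefficients,
               intercept = intercept, noise_sd = noise_sd,
               censor_fraction = censor_fraction, seed = as.integer(seed))
  counts <- c("n_normal", "n_tumor", "n_transcripts")
  for (nm in counts)
    if (!is.numeric(spec[[nm]]) || length(spec[[nm]]) != 1L || spec[[nm]] < 1)
      stop_input("invalid cohort spec: `", nm, "` must be a positive count")
  for (nm in c("n_differential", "n_causal"))
    if (!is.numeric(spec[[nm]]) || spec[[nm]] < 0)
      stop_input("invalid cohort spec: `", nm, "` must be a nonnegative count")
  if (spec$n_causal > spec$n_differential)
    stop_input("invalid cohort spec: n_causal <= n_differential violated")
  if (spec$n_differential > spec$n_transcripts)
    stop_input("invalid cohort spec: n_differential <= n_transcripts violated")
  if (spec$censor_fraction < 0 || spec$censor_fraction > 1)
    stop_input("invalid cohort spec: censor_fraction must lie in [0, 1]")
  if (spec$noise_sd < 0)
    stop_input("invalid cohort spec: noise_sd must be >= 0")
  if (is.null(spec$true_coefficients)) {
    if (spec$n_causal > 0) {
      mag <- seq(50, 150, length.out = spec$n_causal)
      spec$true_coefficients <- mag * (-1)^(seq_len(spec$n_causal) - 1)
    } else {
      spec$true_coefficients <- numeric(0)
    }
  }
  if (length(spec$true_coefficients) != spec$n_causal)
    stop_input("invalid cohort spec: true_coefficients length must equal n_causal")
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  samples:      %d normal / %d tumor\n", x$n_normal, x$n_tumor))
  cat(sprintf("  transcripts:  %d total, %d differential, %d causal\n",
              x$n_transcripts, x$n_differential, x$n_causal))
  cat(sprintf("  effect size:  %g expression units; noise sd %g days\n",
              x$effect_size, x$noise_sd))
  cat(sprintf("  censoring:    %g alive fraction; seed %d\n",
              x$censor_fraction, x$seed))
  invisible(x)
}

#' Generate a synthetic expression + clinical cohort
#'
#' Draws normal and tumor expression matrices, plants a group mean shift of
#' \code{effect_size} on the differential transcripts, and generates tumor
#' survival as \eqn{intercept + \sum_j \beta_j \cdot expr_{ij} + N(0,
#' noise\_sd)}, floored at 1 day.  A \code{censor_fraction} of tumor
#' samples is marked \code{alive} (follow-up time recorded, death time
#' blank); the rest are \code{dead} (death time recorded, follow-up blank).
#' Censoring is assigned independently of survival time, mirroring a
#' response-style treatment of follow-up time for alive patients.
#'
#' Identical seeds give bit-identical output; the caller's RNG stream is
#' left undisturbed.
#'
#' @param spec a [cohort_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{normal, tumor}{expression matrices (samples x transcripts)
#'       with sample IDs as rownames and transcript IDs as colnames.}
#'     \item{clinical}{data frame with columns \code{submitter_id},
#'       \code{vital_status}, \code{days_to_death},
#'       \code{days_to_last_follow_up} (missing values \code{NA}).}
#'     \item{truth}{ground truth: \code{differential_ids},
#'       \code{causal_ids}, \code{coefficients} (named by causal transcript
#'       ID), \code{intercept}.}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_normal = 5, n_tumor = 10,
#'                                       n_transcripts = 20,
#'                                       n_differential = 6, n_causal = 2))
#' dim(cohort$tumor)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  with_seed(spec$seed, {
    n_t <- spec$n_tumor; n_n <- spec$n_normal; M <- spec$n_transcripts
    transcript_ids <- sprintf("LNC%04d", seq_len(M))
    tumor_ids  <- sprintf("TS-%04d", seq_len(n_t))
    normal_ids <- sprintf("NS-%04d", seq_len(n_n))

    normal <- matrix(stats::rlnorm(n_n * M, meanlog = 1, sdlog = 0.5),
                     nrow = n_n, dimnames = list(normal_ids, transcript_ids))
    tumor  <- matrix(stats::rlnorm(n_t * M, meanlog = 1, sdlog = 0.5),
                     nrow = n_t, dimnames = list(tumor_ids, transcript_ids))

    diff_idx <- sort(sample.int(M, spec$n_differential))
    causal_idx <- sort(sample(diff_idx, spec$n_causal))
    tumor[, diff_idx] <- tumor[, diff_idx] + spec$effect_size

    la_true <- rep(spec$intercept, n_t)
    if (spec$n_causal > 0)
      la_true <- la_true +
        drop(tumor[, causal_idx, drop = FALSE] %*% spec$true_coefficients)
    la <- la_true + stats::rnorm(n_t, sd = spec$noise_sd)
    la <- pmax(round(la, 3), 1)

    n_alive <- round(spec$censor_fraction * n_t)
    alive <- rep(FALSE, n_t)
    alive[sample.int(n_t, n_alive)] <- TRUE
    clinical <- data.frame(
      submitter_id = tumor_ids,
      vital_status = ifelse(alive, "alive", "dead"),
      days_to_death = ifelse(alive, NA_real_, la),
      days_to_last_follow_up = ifelse(alive, la, NA_real_),
      stringsAsFactors = FALSE)

    list(normal = normal, tumor = tumor, clinical = clinical,
         truth = list(differential_ids = transcript_ids[diff_idx],
                      causal_ids = transcript_ids[causal_idx],
                      coefficients = stats::setNames(
                        spec$true_coefficients, transcript_ids[causal_idx]),
                      intercept = spec$intercept))
  })
}

#' Write a generated cohort to plain-text files
#'
#' Emits the expression matrices and clinical table as UTF-8 TSV (blank
#' cell = missing) plus a ground-truth sidecar JSON, so downstream stages
#' and tests never re-derive the planted signal from the data.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return Invisibly, a named character vector of the written paths
#'   (\code{normal}, \code{tumor}, \code{clinical}, \code{truth}).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(normal = file.path(dir, "expression_normal.tsv"),
             tumor = file.path(dir, "expression_tumor.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$normal, paths[["normal"]])
  write_expression(cohort$tumor, paths[["tumor"]])
  write_clinical(cohort$clinical, paths[["clinical"]])
  truth <- cohort$truth
  truth$coefficients <- as.list(truth$coefficients)  # keep names in JSON
  jsonlite::write_json(truth, paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
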