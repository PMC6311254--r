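#' Survival distribution coefficients for one clinical record
#'
#' Maps a patient's vital status to the pair \eqn{(\alpha, \beta)} that
#' selects which clinical time field contributes to the survival response:
#' dead \eqn{\Rightarrow (1, 0)} (days to death counts), alive
#' \eqn{\Rightarrow (0, 1)} (days to last follow-up counts).  Status is
#' matched case-insensitively.
#'
#' @param vital_status \code{"dead"} or \code{"alive"} (any case).
#' @return Named numeric vector \code{c(alpha = , beta = )}.
#' @examples
#' survival_coefficients("dead")   # c(alpha = 1, beta = 0)
#' survival_coefficients("Alive")  # c(alpha = 0, beta = 1)
#' @export
survival_coefficients <- function(vital_status) {
  stopifnot(length(vital_status) == 1L)
  status <- tolower(trimws(as.character(vital_status)))
  if (status == "dead")  return(c(alpha = 1, beta = 0))
  if (status == "alive") return(c(alpha = 0, beta = 1))
  stop_input("unrecognized vital_status: \"", vital_status, "\"")
}

#' Build the survival response vector from clinical records
#'
#' For each sample, the survival response (in days) is
#' \eqn{Dd \cdot \alpha + Dl \cdot \beta}: days to death for dead
#' patients, days to last follow-up for alive patients.  Follow-up time is
#' used directly as the response for alive patients — no censoring model.
#' Blank/missing clinical time cells are read as 0 (the convention of
#' TCGA-style exports, where the field not applying to the patient's
#' status is blank).
#'
#' @param clinical clinical data frame (see [read_clinical()]).
#' @param sample_order character vector of sample IDs giving the output
#'   order (typically the expression-matrix rownames).
#' @return Named numeric vector of survival days, ordered as
#'   \code{sample_order}; all entries strictly positive.
#' @examples
#' cl <- data.frame(submitter_id = c("a", "b"),
#'                  vital_status = c("dead", "alive"),
#'                  days_to_death = c(730, NA),
#'                  days_to_last_follow_up = c(NA, 1100))
#' build_survival_vector(cl, c("a", "b"))
#' @export
build_survival_vector <- function(clinical, sample_order) {
  stopifnot(is.data.frame(clinical), is.character(sample_order))
  if (anyDuplicated(clinical$submitter_id)) {
    dup <- unique(clinical$submitter_id[duplicated(clinical$submitter_id)])
    stop_input("duplicate clinical record(s) for: ",
               paste(dup, collapse = ", "))
  }
  missing <- setdiff(sample_order, clinical$submitter_id)
  if (length(missing))
    stop_input("no clinical record for sample(s): ",
               paste(missing, collapse = ", "))
  rows <- match(sample_order, clinical$submitter_id)
  dd <- clinical$days_to_death[rows]
  dl <- clinical$days_to_last_follow_up[rows]
  dd[is.na(dd)] <- 0
  dl[is.na(dl)] <- 0
  la <- vapply(seq_along(rows), function(i) {
    ab <- survival_coefficients(clinical$vital_status[rows[i]])
    dd[i] * ab[["alpha"]] + dl[i] * ab[["beta"]]
  }, numeric(1))
  bad <- la <= 0
  if (any(bad))
    stop_input("nonpositive survival time for sample(s): ",
               paste(sample_order[bad], collapse = ", "),
               " (the time field matching vital_status must be positive)")
  stats::setNames(la, sample_order)
}

#' Write the survival response vector to TSV
#'
#' Columns: \code{submitter_id}, \code{survival_days},
#' \code{event_indicator} (1 = dead, 0 = alive).
#'
#' @param la named survival vector from [build_survival_vector()].
#' @param clinical the clinical data frame (for the event indicator).
#' @param path output TSV path.
#' @export
write_survival <- function(la, clinical, path) {
  rows <- match(names(la), clinical$submitter_id)
  df <- data.frame(submitter_id = names(la), survival_days = unname(la),
                   event_indicator =
                     as.integer(tolower(clinical$vital_status[rows]) == "dead"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
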