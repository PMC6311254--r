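new_ranking <- function(transcript_ids, p_values) {
  stopifnot(length(transcript_ids) == length(p_values))
  structure(list(transcript_ids = transcript_ids, p_values = p_values),
            class = "candidate_ranking")
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat(sprintf("Candidate ranking: %d transcripts (P ascending)\n",
              length(x$transcript_ids)))
  if (length(x$transcript_ids)) {
    k <- min(5L, length(x$transcript_ids))
    cat(sprintf("  %s: P = %.3g\n", x$transcript_ids[seq_len(k)],
                x$p_values[seq_len(k)]), sep = "")
    if (length(x$transcript_ids) > k) cat("  ...\n")
  }
  invisible(x)
}

#' Screen transcripts for differential expression between groups
#'
#' Tests each shared transcript for a normal-vs-tumor expression
#' difference, retains those with raw \eqn{P < \alpha} (no
#' multiple-testing correction — the candidate list is filtered on the raw
#' P value), and orders them by ascending P.  Ties on P are broken by
#' transcript ID so the resulting ranking \eqn{G_1, G_2, \ldots} is total
#' and reproducible — the downstream subset search operates on these
#' positions.
#'
#' The default test is two-sided Welch's unequal-variance t test on the
#' raw expression quantities; a Wilcoxon rank-sum alternative is
#' selectable.  A transcript constant in both groups at the same value
#' cannot discriminate and is assigned \eqn{P = 1} (never selected); one
#' constant in both groups at different values has an unbounded t
#' statistic and is assigned \eqn{P = 0}.
#'
#' @param normal,tumor expression matrices (samples x transcripts) sharing
#'   the same transcript columns.
#' @param alpha retention threshold on the raw P value, in (0, 1).
#'   Default 0.001.
#' @param test \code{"welch"} (default) or \code{"wilcoxon"}.
#' @return A \code{candidate_ranking}: \code{transcript_ids} ordered by
#'   ascending P with matching \code{p_values}.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_normal = 10, n_tumor = 20,
#'                                       n_transcripts = 30,
#'                                       n_differential = 5, n_causal = 2,
#'                                       effect_size = 4))
#' differential_screen(cohort$normal, cohort$tumor)
#' @export
differential_screen <- function(normal, tumor, alpha = 0.001,
                                test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(is.matrix(normal), is.matrix(tumor))
  if (!identical(sort(colnames(normal)), sort(colnames(tumor))))
    stop_input("normal and tumor matrices must share the same transcript set")
  if (alpha <= 0 || alpha >= 1) stop_input("`alpha` must be in (0, 1)")
  tumor <- tumor[, colnames(normal), drop = FALSE]

  p <- vapply(seq_len(ncol(normal)), function(j) {
    a <- normal[, j]; b <- tumor[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: no within-group variance; P by mean comparison
      p_j <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      msg("transcript ", colnames(normal)[j],
          ": zero variance in both groups; P set to ", p_j)
      return(p_j)
    }
    if (test == "welch")
      stats::t.test(b, a, var.equal = FALSE)$p.value
    else
      stats::wilcox.test(b, a, exact = FALSE)$p.value
  }, numeric(1))

  keep <- which(p < alpha)
  ids <- colnames(normal)[keep]
  ord <- order(p[keep], ids)
  new_ranking(ids[ord], p[keep][ord])
}

#' Assemble the training expression matrix from ranked candidates
#'
#' Builds the training matrix used by the subset search: tumor-sample rows
#' sorted by ascending sample ID, columns restricted and reordered to the
#' ranking order (so column \eqn{j} is candidate \eqn{G_j}).
#'
#' @param tumor tumor expression matrix (samples x transcripts).
#' @param ranking a \code{candidate_ranking} from [differential_screen()].
#' @return Numeric matrix with rows sorted by sample ID and columns in
#'   ranking order.
#' @export
build_led <- function(tumor, ranking) {
  stopifnot(is.matrix(tumor), inherits(ranking, "candidate_ranking"))
  absent <- setdiff(ranking$transcript_ids, colnames(tumor))
  if (length(absent))
    stop_input("ranked transcript(s) absent from tumor matrix: ",
               paste(absent, collapse = ", "))
  tumor[order(rownames(tumor)), ranking$transcript_ids, drop = FALSE]
}
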