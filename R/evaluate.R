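#' ROC curve and AUC of a binary scoring
#'
#' Sweeps all distinct score values as descending thresholds, computing
#' the true-positive rate \eqn{TPR = TP/(TP+FN)} and false-positive rate
#' \eqn{FPR = FP/(FP+TN)} at each, and integrates the curve by the
#' trapezoid rule.  With this construction the AUC equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, ties counting one half.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels 0/1 labels, same length.
#' @return An object of class \code{"roc_curve"}: \code{thresholds}
#'   (descending distinct cutoffs), \code{tpr}, \code{fpr} (each
#'   including the (0,0) origin), and \code{auc}.
#' @examples
#' roc_auc(c(3, 2, 1), c(1, 1, 0))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (anyNA(scores) || anyNA(labels))
    stop_input("scores and labels must not contain NA")
  if (!all(labels %in% c(0L, 1L)))
    stop_input("labels must be 0/1")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_input("need at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at each distinct threshold (predict positive if
  # score >= threshold)
  last_of_run <- which(diff(s) != 0)
  cut_idx <- c(last_of_run, length(s))
  tp <- cumsum(y)[cut_idx]
  fp <- cumsum(1L - y)[cut_idx]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = s[cut_idx], tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d threshold(s), AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Fixed-horizon survival ROC of a fitted model
#'
#' Evaluates how well the model's predicted survival time separates
#' patients by their event status at a fixed horizon (default 5 years =
#' 1825 days).  A patient is labelled positive (event) if dead within the
#' horizon, negative if observed event-free beyond it (death or follow-up
#' after the horizon).  Patients alive with follow-up shorter than the
#' horizon are indeterminate at that horizon and are excluded.  The score
#' is the negated predicted survival time, so shorter predicted survival
#' ranks as higher risk.
#'
#' @param model an \code{"mlr_model"}.
#' @param led expression matrix with the model's transcripts.
#' @param clinical clinical data frame covering \code{rownames(led)}.
#' @param horizon evaluation horizon in days (default 1825).
#' @return A \code{"roc_curve"} with extra fields \code{n_used} and
#'   \code{n_excluded}.
#' @export
survival_roc <- function(model, led, clinical, horizon = 1825) {
  stopifnot(inherits(model, "mlr_model"), horizon > 0)
  ids <- rownames(led)
  rows <- match(ids, clinical$submitter_id)
  if (anyNA(rows))
    stop_input("no clinical record for sample(s): ",
               paste(ids[is.na(rows)], collapse = ", "))
  status <- tolower(clinical$vital_status[rows])
  dd <- clinical$days_to_death[rows]
  dl <- clinical$days_to_last_follow_up[rows]
  dead <- status == "dead"
  time <- ifelse(dead, dd, dl)
  label <- ifelse(dead & time <= horizon, 1L,
                  ifelse(time > horizon, 0L, NA_integer_))
  keep <- !is.na(label)
  if (!any(keep)) stop_input("no determinate patients at horizon ", horizon)
  pred <- predict(model, led[keep, , drop = FALSE])
  roc <- roc_auc(-pred, label[keep])
  roc$n_used <- sum(keep)
  roc$n_excluded <- sum(!keep)
  roc
}

#' Leave-one-out cross-validation over known association pairs
#'
#' For each known lncRNA-disease pair in turn: remove it from the
#' training associations, invoke the scorer on the remainder, and record
#' the held-out pair's score as a positive alongside the scores of every
#' never-known candidate pair as negatives.  The pooled scores give one
#' ROC/AUC summarising how highly the method re-ranks withheld true
#' associations among unknown candidates.
#'
#' @param pairs data frame of known associations: columns \code{lncrna},
#'   \code{disease} (at least 2 rows, no duplicates).
#' @param universe data frame of all candidate pairs (same columns);
#'   must contain every known pair.
#' @param scorer \code{function(train_pairs, universe)} returning one
#'   numeric score per universe row (larger = more associated).
#' @return A \code{"roc_curve"} with extra field \code{n_folds}.
#' @export
loocv_association <- function(pairs, universe, scorer) {
  stopifnot(is.data.frame(pairs), is.data.frame(universe),
            is.function(scorer))
  pairs <- pairs[, c("lncrna", "disease")]
  universe <- universe[, c("lncrna", "disease")]
  if (anyDuplicated(pairs)) stop_input("duplicate known pairs")
  if (anyDuplicated(universe)) stop_input("duplicate universe pairs")
  key <- function(df) paste(df$lncrna, df$disease, sep = "\r")
  pos_at <- match(key(pairs), key(universe))
  if (anyNA(pos_at))
    stop_input("known pair(s) missing from the universe: ",
               paste(key(pairs)[is.na(pos_at)], collapse = "; "))
  n <- nrow(pairs)
  if (n < 2L) stop_input("need at least 2 known pairs for LOOCV")
  neg_at <- setdiff(seq_len(nrow(universe)), pos_at)
  if (length(neg_at) == 0L)
    stop_input("universe contains no never-known pairs to rank against")

  scores <- numeric(0); labels <- integer(0)
  for (i in seq_len(n)) {
    s <- tryCatch(scorer(pairs[-i, , drop = FALSE], universe),
                  error = function(e) stop_input(
                    "scorer failed on fold ", i, " (held-out ",
                    pairs$lncrna[i], " / ", pairs$disease[i], "): ",
                    conditionMessage(e)))
    if (length(s) != nrow(universe))
      stop_input("scorer must return one score per universe row (fold ",
                 i, ")")
    scores <- c(scores, s[pos_at[i]], s[neg_at])
    labels <- c(labels, 1L, rep(0L, length(neg_at)))
  }
  roc <- roc_auc(scores, labels)
  roc$n_folds <- n
  roc
}

#' Association scorer from a fitted survival model
#'
#' Converts the fitted regression into per-lncRNA association scores for
#' a single disease: each selected transcript scores the absolute
#' standardised coefficient \eqn{|\Theta_j| \cdot sd(g_j)} (its effect on
#' predicted survival in days per one-SD change of expression);
#' unselected transcripts score 0.  The returned function has the scorer
#' signature required by [loocv_association()] and ignores the training
#' pairs — the evidence comes from the survival regression, not from the
#' association list itself.
#'
#' @param model an \code{"mlr_model"}.
#' @param led the expression matrix the model was fitted on.
#' @return \code{function(train_pairs, universe)} returning one score
#'   per universe row, keyed by the universe's \code{lncrna} column.
#' @export
model_association_scorer <- function(model, led) {
  stopifnot(inherits(model, "mlr_model"), is.matrix(led))
  sds <- apply(led[, model$selected_ids, drop = FALSE], 2, stats::sd)
  theta <- model$coefficients[model$selected_ids]
  weight <- stats::setNames(abs(theta) * sds, model$selected_ids)
  function(train_pairs, universe) {
    s <- weight[universe$lncrna]
    s[is.na(s)] <- 0
    unname(s)
  }
}

#' Write ROC points and an AUC summary
#'
#' @param roc a \code{"roc_curve"}.
#' @param points_path output TSV of (threshold, fpr, tpr) points.
#' @param summary_path output JSON with the AUC (and counts if present).
#' @export
write_roc <- function(roc, points_path, summary_path = NULL) {
  df <- data.frame(threshold = c(NA, roc$thresholds),
                   fpr = roc$fpr, tpr = roc$tpr)
  utils::write.table(df, points_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(summary_path)) {
    out <- list(auc = roc$auc)
    for (f in c("n_used", "n_excluded", "n_folds"))
      if (!is.null(roc[[f]])) out[[f]] <- roc[[f]]
    jsonlite::write_json(out, summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(points_path)
}
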