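#' Build an AUC-weighted voting ensemble
#'
#' @param members List of `signature_model`s.
#' @param weights Numeric AUC weights in \[0, 1\], one per member (use
#'   [fit_weights()] to compute them on a labelled cohort).
#' @param consensus_threshold Fraction of members that must share the
#'   majority outcome for a sample's prediction to be flagged as a
#'   consensus call (default 0.75).
#' @return An `ensemble_model`.
#' @export
ensemble_model <- function(members, weights,
                           consensus_threshold = 0.75) {
  if (length(members) != length(weights))
    stop("one weight per member required")
  if (length(members) == 0L) stop("ensemble needs >= 1 member")
  if (any(!is.finite(weights))) stop("weights must be finite")
  structure(list(members = members, weights = as.numeric(weights),
                 consensus_threshold = consensus_threshold),
            class = "ensemble_model")
}

#' Compute AUC weights for ensemble members on a labelled cohort
#'
#' Each member's weight is the rank-based AUC of its decision values on
#' the cohort, so better-ranking members dominate the vote.
#'
#' @param members List of `signature_model`s.
#' @param matrix Cohort expression matrix.
#' @param truth Factor sensitive/resistant named by sample.
#' @param consensus_threshold Passed to [ensemble_model()].
#' @return An `ensemble_model` with fitted weights.
#' @export
fit_weights <- function(members, matrix, truth,
                        consensus_threshold = 0.75) {
  if (is.data.frame(truth))
    truth <- stats::setNames(as.character(truth$label), truth$sample)
  truth <- factor(truth[colnames(matrix)],
                  levels = c("sensitive", "resistant"))
  if (nlevels(droplevels(truth)) < 2L)
    stop("AUC weights undefined: cohort truth has a single class")
  w <- vapply(members, function(m) {
    pr <- predict(m, matrix)
    rank_auc(pr$decision, truth)
  }, 0)
  ensemble_model(members, w, consensus_threshold)
}

#' Predict with an AUC-weighted ensemble
#'
#' Each member votes +1 (resistant) or -1 (sensitive) per sample; the
#' weighted sum of votes decides: > 0 resistant, < 0 sensitive. An exact
#' zero is called resistant with a warning (the conservative default: a
#' non-response call). A sample is a consensus call when at least
#' `consensus_threshold` of members agree on the majority outcome.
#'
#' @param ensemble An `ensemble_model`.
#' @param matrix Cohort expression matrix.
#' @return Data frame: `sample`, `label`, `weighted_sum`,
#'   `consensus_flag`.
#' @export
ensemble_predict <- function(ensemble, matrix) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  votes <- vapply(seq_along(ensemble$members), function(i) {
    pr <- tryCatch(predict(ensemble$members[[i]], matrix),
                   error = function(e)
                     stop("ensemble member ", i, " failed: ",
                          conditionMessage(e), call. = FALSE))
    ifelse(pr$label == "resistant", 1, -1)
  }, numeric(ncol(matrix)))
  votes <- matrix(votes, nrow = ncol(matrix))
  wsum <- as.numeric(votes %*% ensemble$weights)
  if (any(wsum == 0))
    warning(sum(wsum == 0), " sample(s) with an exactly-zero weighted sum ",
            "called resistant")
  label <- factor(ifelse(wsum > 0, "resistant",
                         ifelse(wsum < 0, "sensitive", "resistant")),
                  levels = c("sensitive", "resistant"))
  maj_frac <- apply(votes, 1L, function(v) max(mean(v > 0), mean(v < 0)))
  data.frame(sample = colnames(matrix), label = label,
             weighted_sum = wsum,
             consensus_flag = maj_frac >= ensemble$consensus_threshold,
             stringsAsFactors = FALSE)
}

#' @export
predict.ensemble_model <- function(object, matrix, ...) {
  ensemble_predict(object, matrix)
}

#' Score an ensemble with a consensus/non-consensus split
#'
#' @param ensemble An `ensemble_model`.
#' @param matrix Cohort expression matrix.
#' @param truth Factor sensitive/resistant named by sample.
#' @return List with the overall `report` plus `consensus` and
#'   `non_consensus` sub-reports (NULL when a stratum is empty).
#' @export
score_ensemble <- function(ensemble, matrix, truth) {
  pr <- ensemble_predict(ensemble, matrix)
  if (is.data.frame(truth))
    truth <- stats::setNames(as.character(truth$label), truth$sample)
  rep_all <- score_predictions(
    data.frame(sample = pr$sample, label = pr$label,
               decision = pr$weighted_sum), truth[pr$sample])
  sub <- function(flag) {
    idx <- pr$consensus_flag == flag
    if (!any(idx)) return(NULL)
    score_predictions(
      data.frame(sample = pr$sample[idx], label = pr$label[idx],
                 decision = pr$weighted_sum[idx]),
      truth[pr$sample[idx]])
  }
  list(report = rep_all, consensus = sub(TRUE), non_consensus = sub(FALSE),
       predictions = pr)
}
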