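#' Predict drug response for a cohort
#'
#' Applies a trained signature to an expression matrix (after probe
#' collapsing and quantile normalization onto the training scale). The
#' decision value's sign gives the label: positive = resistant,
#' negative/zero = sensitive. Decision values are returned for AUC and
#' ensemble weighting.
#'
#' @param object A `signature_model`.
#' @param matrix Expression matrix (genes x samples) containing every
#'   model feature.
#' @param ... Unused.
#' @return Data frame with columns `sample`, `label` (factor
#'   sensitive/resistant) and `decision`.
#' @export
predict.signature_model <- function(object, matrix, ...) {
  validate_expression_matrix(matrix)
  miss <- setdiff(object$features, rownames(matrix))
  if (length(miss))
    stop("matrix is missing signature feature(s): ",
         paste(miss, collapse = ", "))
  x <- t(matrix[object$features, , drop = FALSE])
  if (anyNA(x))
    stop("NaN/NA expression for signature gene(s) in sample(s): ",
         paste(rownames(x)[rowSums(is.na(x)) > 0], collapse = ", "))
  d <- svm_decision(object$decision_params, x)
  data.frame(sample = colnames(matrix), label = decision_to_label(d),
             decision = d, stringsAsFactors = FALSE)
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the common
#' convention of 0 when any denominator factor is 0 (e.g. a single-class
#' prediction). Positive class = resistant.
#'
#' @param tp,fn,tn,fp Non-negative integer confusion counts.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(tp, fn, tn, fp) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Rank-based AUC of decision values
#'
#' Probability that a resistant sample's decision value exceeds a
#' sensitive one's, with midrank handling of ties (the Mann-Whitney
#' statistic). Orientation: higher decision values should mean resistant.
#'
#' @param decision Numeric decision values.
#' @param truth Factor sensitive/resistant.
#' @return AUC in \[0, 1\]; `NA` if either class is absent.
#' @export
rank_auc <- function(decision, truth) {
  truth <- factor(truth, levels = c("sensitive", "resistant"))
  n1 <- sum(truth == "resistant"); n0 <- sum(truth == "sensitive")
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(decision, ties.method = "average")
  (sum(r[truth == "resistant"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score predictions against observed labels
#'
#' Builds the confusion matrix (positive class = resistant), the per-class
#' and overall accuracies, MCC and AUC; optionally the same report per
#' group (e.g. sex strata).
#'
#' @param predictions Data frame from [predict.signature_model()] (columns
#'   `sample`, `label`, optionally `decision`), or a factor of predicted
#'   labels named by sample.
#' @param truth Factor sensitive/resistant named by sample, or a
#'   two-column data frame (`sample`, `label`).
#' @param groups Optional factor/character named by sample for stratified
#'   sub-reports.
#' @return A `validation_report` list: `tp`, `fn`, `tn`, `fp`,
#'   `sensitive_acc`, `resistant_acc`, `overall_acc`, `mcc`, `auc`, `n`,
#'   and `group_reports` when groups are given.
#' @export
score_predictions <- function(predictions, truth, groups = NULL) {
  if (is.data.frame(predictions)) {
    pred <- stats::setNames(as.character(predictions$label),
                            predictions$sample)
    decision <- if ("decision" %in% names(predictions))
      stats::setNames(predictions$decision, predictions$sample) else NULL
  } else {
    pred <- stats::setNames(as.character(predictions), names(predictions))
    decision <- NULL
  }
  if (is.data.frame(truth))
    truth <- stats::setNames(as.character(truth$label), truth$sample)
  tr <- stats::setNames(as.character(truth), names(truth))
  if (is.null(names(tr)) || is.null(names(pred))) {
    if (length(tr) != length(pred))
      stop("prediction/truth length mismatch and no sample names")
    names(tr) <- names(pred) <- seq_along(tr)
  }
  if (!setequal(names(tr), names(pred)))
    stop("prediction and truth sample sets differ")
  pred <- pred[names(tr)]
  if (!is.null(decision)) decision <- decision[names(tr)]

  build <- function(idx) {
    p <- pred[idx]; t <- tr[idx]
    tp <- sum(p == "resistant" & t == "resistant")
    fn <- sum(p == "sensitive" & t == "resistant")
    tn <- sum(p == "sensitive" & t == "sensitive")
    fp <- sum(p == "resistant" & t == "sensitive")
    n_res <- tp + fn; n_sen <- tn + fp
    list(tp = tp, fn = fn, tn = tn, fp = fp,
         sensitive_acc = if (n_sen) tn / n_sen else NA_real_,
         resistant_acc = if (n_res) tp / n_res else NA_real_,
         overall_acc = (tp + tn) / (n_res + n_sen),
         mcc = mcc(tp, fn, tn, fp),
         auc = if (!is.null(decision))
           rank_auc(decision[idx], factor(t, c("sensitive", "resistant")))
           else NA_real_,
         n = n_res + n_sen)
  }
  rep <- build(names(tr))
  if (!is.null(groups)) {
    grp <- groups[names(tr)]
    rep$group_reports <- lapply(split(names(tr), grp), build)
  }
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("MCC %.2f | Sensitive %s | Resistant %s | Overall %s (n = %d)\n",
              x$mcc, pct(x$sensitive_acc), pct(x$resistant_acc),
              pct(x$overall_acc), x$n))
  if (!is.null(x$group_reports))
    for (g in names(x$group_reports)) {
      cat("  ", g, ": ", sep = "")
      print(x$group_reports[[g]])
    }
  invisible(x)
}

pct <- function(p) if (is.na(p)) "NA" else sprintf("%d%%", round(100 * p))

#' Select the best model by MCC
#'
#' MCC is the primary selection metric because the validation cohorts are
#' imbalanced; ties are broken by higher overall accuracy, then by fewer
#' signature genes.
#'
#' @param reports List of `validation_report`s, one per model.
#' @param models Optional parallel list of `signature_model`s (for the
#'   feature-count tie-break).
#' @return Index of the selected model in `reports`.
#' @export
select_best <- function(reports, models = NULL) {
  if (length(reports) == 0L) stop("no reports to select from")
  m <- vapply(reports, `[[`, 0, "mcc")
  oa <- vapply(reports, `[[`, 0, "overall_acc")
  nf <- if (is.null(models)) rep(0L, length(reports)) else
    vapply(models, function(x) length(x$features), 0L)
  ord <- order(-m, -oa, nf)
  ord[1L]
}

#' Leave-one-gene-out importance of signature features
#'
#' For each gene in a signature, refits the SVM at the model's (C, sigma)
#' without that gene and reports the change in training criterion and in
#' test-cohort overall accuracy and MCC. A gene whose removal RAISES test
#' MCC is flagged as a candidate machine-learning false positive.
#'
#' @param model A `signature_model` with >= 2 features.
#' @param train_matrix,train_labels The training panel and labels.
#' @param test_matrix,test_truth The validation cohort and labels.
#' @param k,seed Passed to [cv_criterion()] for the retrained criterion.
#' @return Data frame with one row per gene: `gene`, `delta_criterion`,
#'   `delta_overall_acc`, `delta_mcc`, `candidate_false_positive`; the
#'   attribute `baseline` holds the full-model report.
#' @export
loo_gene_importance <- function(model, train_matrix, train_labels,
                                test_matrix, test_truth,
                                k = 5L, seed = 1L) {
  if (length(model$features) < 2L)
    stop("leave-one-out importance needs a model with >= 2 features")
  base_crit <- cv_criterion(model$features, train_matrix, train_labels,
                            model$C, model$sigma, model$criterion,
                            k = k, seed = seed)
  base_rep <- score_predictions(predict(model, test_matrix), test_truth)
  rows <- lapply(model$features, function(g) {
    feats <- setdiff(model$features, g)
    crit <- cv_criterion(feats, train_matrix, train_labels,
                         model$C, model$sigma, model$criterion,
                         k = k, seed = seed)
    xy <- align_features(train_matrix, train_labels, feats)
    sub <- new_signature_model(
      features = feats, C = model$C, sigma = model$sigma,
      decision_params = fit_gaussian_svm(xy$x, xy$y, model$C, model$sigma),
      criterion = model$criterion, criterion_value = crit,
      condition = model$condition, seed = model$seed)
    rep <- score_predictions(predict(sub, test_matrix), test_truth)
    data.frame(gene = g,
               delta_criterion = crit - base_crit,
               delta_overall_acc = rep$overall_acc - base_rep$overall_acc,
               delta_mcc = rep$mcc - base_rep$mcc,
               candidate_false_positive = rep$mcc > base_rep$mcc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- base_rep
  out
}

#' Write a validation report table
#'
#' Columns follow the conventional layout: MCC, then sensitive-, resistant-
#' and overall accuracy (nearest percent), plus the raw confusion counts.
#'
#' @param reports Named list of `validation_report`s.
#' @param path Output path.
#' @export
write_validation_report <- function(reports, path) {
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, MCC = round(r$mcc, 2L),
               Sensitive = round(100 * r$sensitive_acc),
               Resistant = round(100 * r$resistant_acc),
               Overall = round(100 * r$overall_acc),
               tp = r$tp, fn = r$fn, tn = r$tn, fp = r$fp,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
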