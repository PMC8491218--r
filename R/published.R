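#' Published validation statistics for six TKI signature models
#'
#' Per-class accuracies, MCC and overall accuracy of the best curated and
#' pathway-extended SVM signature for each tyrosine kinase inhibitor, as
#' reported on the clinical validation cohorts (GEO series GSE61676,
#' GSE109211, GSE33658, GSE66399, GSE14671 and GSE51305), together with
#' each cohort's sensitive/resistant class sizes. Shipped so the summary
#' arithmetic relating per-class accuracy, MCC and overall accuracy can be
#' recomputed from first principles.
#'
#' @return Data frame with columns `drug`, `model` (curated /
#'   pathway_extended), `n_sensitive`, `n_resistant`, `acc_sensitive`,
#'   `acc_resistant` (percent), `mcc`, `overall` (percent).
#' @export
published_validation_stats <- function() {
  path <- system.file("extdata", "tki_validation_published.tsv",
                      package = "pesig", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reconstruct integer confusion counts from per-class accuracies
#'
#' Given a cohort's class sizes and the reported per-class accuracies (in
#' percent), recovers the confusion matrix by rounding accuracy times
#' class size to the nearest integer (positive class = resistant).
#'
#' @param n_sensitive,n_resistant Class sizes.
#' @param acc_sensitive,acc_resistant Per-class accuracies in percent.
#' @return List with `tp`, `fn`, `tn`, `fp`.
#' @export
reconstruct_confusion <- function(n_sensitive, n_resistant,
                                  acc_sensitive, acc_resistant) {
  tp <- round(n_resistant * acc_resistant / 100)
  tn <- round(n_sensitive * acc_sensitive / 100)
  list(tp = tp, fn = n_resistant - tp, tn = tn, fp = n_sensitive - tn)
}
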