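#' Collapse multiple probes per gene to one row
#'
#' When a platform measures a gene with several probes, the per-sample mean
#' of all probe rows sharing a symbol becomes that gene's expression value.
#' Rows with unique symbols pass through unchanged.
#'
#' @param x Numeric matrix, features x samples, rownames = symbols (possibly
#'   duplicated).
#' @return Matrix with one row per symbol, rows ordered by first appearance.
#' @export
collapse_probes <- function(x) {
  validate_expression_matrix(x)
  sym <- rownames(x)
  if (!anyDuplicated(sym)) return(x)
  first <- unique(sym)
  counts <- table(sym)[first]
  out <- rowsum(x, group = sym, reorder = FALSE) / as.vector(counts)
  rownames(out) <- first
  out[first, , drop = FALSE]
}

#' Mean-quantile reference vector of a matrix
#'
#' The sorted per-sample value vectors averaged position-wise: the target
#' distribution quantile normalization maps every sample onto.
#'
#' @param x Numeric matrix, features x samples.
#' @return Sorted numeric vector of length `nrow(x)`.
#' @export
reference_quantiles <- function(x) {
  validate_expression_matrix(x)
  rowMeans(apply(x, 2L, sort))
}

#' Quantile-normalize a matrix, optionally against an external reference
#'
#' Every sample's values are replaced by the reference quantiles at their
#' within-sample ranks, so all samples share one distribution while each
#' sample's ordering is preserved. With `reference = NULL` the reference is
#' the matrix's own mean-quantile vector (the classic algorithm). Passing
#' the training panel's [reference_quantiles()] maps a validation cohort
#' onto the training scale, where the SVM decision function is calibrated.
#' Ties within a sample receive the mean of the implicated reference
#' quantiles (midranks).
#'
#' @param x Numeric matrix, features x samples, >=2 samples unless a
#'   reference is supplied.
#' @param reference Optional sorted numeric vector; length must equal
#'   `nrow(x)` unless `interpolate = TRUE`.
#' @param interpolate Allow a reference of different length, mapped by
#'   linear interpolation on the quantile scale.
#' @return Normalized matrix with the dimnames of `x`.
#' @export
quantile_normalize <- function(x, reference = NULL, interpolate = FALSE) {
  validate_expression_matrix(x)
  if (is.null(reference)) {
    if (ncol(x) < 2L)
      stop("need >=2 samples or an explicit reference distribution")
    reference <- reference_quantiles(x)
  } else {
    if (is.matrix(reference)) reference <- reference_quantiles(reference)
    reference <- sort(reference)
    if (length(reference) != nrow(x)) {
      if (!interpolate)
        stop("reference length (", length(reference),
             ") != feature count (", nrow(x),
             "); set interpolate = TRUE to map through quantiles")
      p <- (seq_len(nrow(x)) - 0.5) / nrow(x)
      reference <- stats::quantile(reference, probs = p, names = FALSE,
                                   type = 7L)
    }
  }
  out <- apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    # midrank -> mean of the tied positions' reference quantiles
    lo <- floor(r); frac <- r - lo
    v <- reference[lo]
    up <- pmin(lo + 1L, length(reference))
    v + frac * (reference[up] - v)
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Dichotomize GI50 values into sensitive/resistant labels
#'
#' The per-drug median GI50 is the default threshold separating sensitive
#' from resistant cell lines. When two or more samples tie exactly at the
#' median, the median no longer splits the panel cleanly; the threshold then
#' moves to the observed GI50 value whose gap to the next larger sorted
#' value is maximal (the widest natural break). GI50 is on a -log10 molar
#' scale, so under the default polarity a value at or above threshold
#' (inhibition at lower concentration) is called sensitive.
#'
#' @param responses Data frame with columns `sample` and `gi50`, or a named
#'   numeric vector of GI50 values.
#' @param polarity `"high_value_sensitive"` (default, -log10 molar scale) or
#'   `"high_value_resistant"`.
#' @param method `"auto"` (median unless tied at the median), `"median"`, or
#'   `"max_gap"` to force the widest-break rule.
#' @return List with `labels` (factor sensitive/resistant named by sample)
#'   and `rule` (list: method actually used, threshold, polarity).
#' @export
dichotomize_gi50 <- function(responses,
                             polarity = c("high_value_sensitive",
                                          "high_value_resistant"),
                             method = c("auto", "median", "max_gap")) {
  polarity <- match.arg(polarity)
  method <- match.arg(method)
  if (is.data.frame(responses)) {
    gi50 <- stats::setNames(responses$gi50, responses$sample)
  } else gi50 <- responses
  gi50 <- gi50[is.finite(gi50)]
  if (length(gi50) < 4L) stop("need >=4 finite GI50 values to dichotomize")
  if (length(unique(gi50)) == 1L)
    stop("degenerate GI50 vector: all values equal, no split possible")
  med <- stats::median(gi50)
  tied <- sum(gi50 == med) >= 2L
  use_gap <- switch(method, auto = tied, median = FALSE, max_gap = TRUE)
  if (use_gap) {
    s <- sort(unique(gi50))
    gaps <- diff(s)
    threshold <- s[which.max(gaps)]
    used <- "max_gap"
  } else {
    threshold <- med
    used <- "median"
  }
  hi_sens <- polarity == "high_value_sensitive"
  sens <- if (hi_sens) gi50 >= threshold else gi50 < threshold
  if (use_gap && !hi_sens) sens <- gi50 <= threshold
  if (use_gap && hi_sens) sens <- gi50 > threshold
  labels <- factor(ifelse(sens, "sensitive", "resistant"),
                   levels = c("sensitive", "resistant"))
  names(labels) <- names(gi50)
  if (!all(c("sensitive", "resistant") %in% labels))
    stop("degenerate split: one class empty at threshold ", threshold)
  list(labels = labels,
       rule = list(method = used, threshold = threshold,
                   polarity = polarity))
}
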