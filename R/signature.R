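#' The (C, sigma) hyperparameter grid
#'
#' Both the box constraint C and the Gaussian kernel scale sigma range over
#' decades from 1 to 100,000; only pairs with C >= sigma are kept, giving
#' 21 combinations. Order is ascending sigma within ascending C.
#'
#' @return Data frame with columns `C` and `sigma` (21 rows).
#' @export
build_grid <- function() {
  vals <- 10^(0:5)
  g <- expand.grid(sigma = vals, C = vals)[, c("C", "sigma")]
  g <- g[g$C >= g$sigma, ]
  g <- g[order(g$C, g$sigma), ]
  rownames(g) <- NULL
  g
}

# ---- internal: Gaussian-kernel SVM with a portable decision function ----

# Gaussian kernel matrix between row-sample matrices a and b:
# K(u, v) = exp(-gamma * ||u - v||^2), gamma = 1 / sigma^2
# (kernel-scale convention: exp(-(||u-v|| / sigma)^2)).
kernel_cross <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# Fit a two-class Gaussian SVM; labels are a factor sensitive/resistant.
# Features are standardized with training-derived centre/scale, and the
# decision function is re-expressed in portable parameters oriented so
# that positive decision values mean resistant.
fit_gaussian_svm <- function(x, y, C, sigma) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- factor(y, levels = c("sensitive", "resistant"))
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present to train an SVM")
  center <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = center, scale = scl)
  gamma <- 1 / sigma^2
  fit <- e1071::svm(x = xs, y = y, scale = FALSE, type = "C-classification",
                    kernel = "radial", gamma = gamma, cost = C)
  sv <- fit$SV
  coefs <- as.numeric(fit$coefs)
  rho <- fit$rho
  # e1071's decision value is positive for its internally-first label;
  # orient so positive = resistant.
  first <- fit$levels[fit$labels[1L]]
  if (identical(first, "sensitive")) {
    coefs <- -coefs
    rho <- -rho
  }
  list(center = stats::setNames(center, colnames(x)),
       scale = stats::setNames(scl, colnames(x)),
       gamma = gamma, rho = rho, coefs = coefs, sv = sv)
}

# Decision values from portable parameters; positive = resistant.
svm_decision <- function(params, x) {
  xs <- scale(x[, names(params$center), drop = FALSE],
              center = params$center, scale = params$scale)
  k <- kernel_cross(xs, params$sv, params$gamma)
  as.numeric(k %*% params$coefs - params$rho)
}

decision_to_label <- function(d) {
  factor(ifelse(d > 0, "resistant", "sensitive"),
         levels = c("sensitive", "resistant"))
}

# Stratified k-fold assignment: within each class, samples are shuffled
# under the seed and dealt round-robin into folds.
stratified_folds <- function(y, k, seed) {
  if (k < 2L) stop("k must be >= 2")
  mins <- min(table(y))
  if (k > mins)
    stop("k = ", k, " exceeds the smaller class size (", mins,
         "); lower k to at most ", mins)
  fold <- integer(length(y))
  rng <- local({ set.seed(seed); lapply(levels(factor(y)), function(l) {
    idx <- which(y == l)
    sample(idx)
  })})
  for (idx in rng) fold[idx] <- rep_len(seq_len(k), length(idx))
  fold
}

#' Cross-validated training criterion for a feature set
#'
#' Stratified k-fold estimate of either the misclassification rate or the
#' log loss of a Gaussian-kernel SVM on the training panel. For log loss,
#' a logistic (Platt-style) map from decision value to class probability is
#' fitted on each fold's training portion, since a margin classifier emits
#' no probabilities natively; probabilities are clipped to
#' \[1e-15, 1 - 1e-15\].
#'
#' @param features Gene symbols to use as features.
#' @param matrix Expression matrix (genes x samples).
#' @param labels Factor sensitive/resistant, named by sample or in column
#'   order.
#' @param C,sigma SVM hyperparameters.
#' @param criterion `"misclassification"` or `"log_loss"`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @return Non-negative scalar criterion value.
#' @export
cv_criterion <- function(features, matrix, labels, C, sigma,
                         criterion = c("misclassification", "log_loss"),
                         k = 5L, seed = 1L) {
  criterion <- match.arg(criterion)
  xy <- align_features(matrix, labels, features)
  x <- xy$x; y <- xy$y
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present in the training labels")
  fold <- stratified_folds(y, k, seed)
  err <- 0L; ll <- 0
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    params <- fit_gaussian_svm(x[tr, , drop = FALSE], y[tr], C, sigma)
    d_te <- svm_decision(params, x[te, , drop = FALSE])
    if (criterion == "misclassification") {
      err <- err + sum(decision_to_label(d_te) != y[te])
    } else {
      d_tr <- svm_decision(params, x[tr, , drop = FALSE])
      p_te <- platt_probability(d_tr, y[tr], d_te)
      p_true <- ifelse(y[te] == "resistant", p_te, 1 - p_te)
      p_true <- pmin(pmax(p_true, 1e-15), 1 - 1e-15)
      ll <- ll - sum(log(p_true))
    }
  }
  if (criterion == "misclassification") err / length(y) else ll / length(y)
}

# Logistic map of decision values to P(resistant), fitted on training
# decision values; degenerate (separable) fits fall back to a steep
# sigmoid, which log-loss clipping keeps finite.
platt_probability <- function(d_train, y_train, d_new) {
  df <- data.frame(y = as.integer(y_train == "resistant"), d = d_train)
  fit <- suppressWarnings(stats::glm(y ~ d, family = stats::binomial(),
                                     data = df))
  eta <- stats::coef(fit)[1L] + stats::coef(fit)[2L] * d_new
  eta[is.na(eta)] <- 0
  1 / (1 + exp(-pmin(pmax(eta, -700), 700)))
}

align_features <- function(matrix, labels, features) {
  validate_expression_matrix(matrix)
  features <- toupper(features)
  miss <- setdiff(features, rownames(matrix))
  if (length(miss))
    stop("feature(s) missing from matrix: ", paste(miss, collapse = ", "))
  if (!is.null(names(labels))) {
    common <- intersect(colnames(matrix), names(labels))
    if (length(common) < length(labels) || length(common) < ncol(matrix))
      stop("sample mismatch between matrix and labels")
    labels <- labels[colnames(matrix)]
  } else if (length(labels) != ncol(matrix)) {
    stop("labels length != sample count and no names to match")
  }
  y <- factor(labels, levels = c("sensitive", "resistant"))
  if (anyNA(y)) stop("labels must be sensitive/resistant")
  list(x = t(matrix[features, , drop = FALSE]), y = y)
}

new_signature_model <- function(features, C, sigma, decision_params,
                                criterion, criterion_value,
                                condition = "curated", seed = NA_integer_,
                                trajectory = NULL) {
  structure(list(features = features, C = C, sigma = sigma,
                 decision_params = decision_params, criterion = criterion,
                 criterion_value = criterion_value, condition = condition,
                 seed = seed, trajectory = trajectory),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Gaussian-kernel SVM gene signature\n")
  cat(sprintf("  features (%d): %s\n", length(x$features),
              paste(x$features, collapse = ", ")))
  cat(sprintf("  C = %g, sigma = %g\n", x$C, x$sigma))
  cat(sprintf("  training %s = %.4g (condition %s, seed %s)\n",
              x$criterion, x$criterion_value, x$condition, x$seed))
  invisible(x)
}

#' Forward feature selection of a gene signature
#'
#' Greedy construction of a feature list at fixed (C, sigma): every round,
#' each remaining candidate is evaluated appended to the current list via
#' [cv_criterion()]; the candidate with the lowest criterion is accepted
#' only if it strictly lowers the incumbent value, and the loop stops when
#' no candidate improves. The order in which candidates are evaluated each
#' round is randomized by the seed; ties on the criterion are broken in
#' favour of the first-encountered candidate in that order. The returned
#' model is refitted on the full panel with the selected features.
#'
#' @param pool Candidate gene symbols (the qualified set).
#' @param matrix Expression matrix (genes x samples).
#' @param labels Factor sensitive/resistant.
#' @param C,sigma SVM hyperparameters.
#' @param criterion `"misclassification"` or `"log_loss"`.
#' @param k Folds for [cv_criterion()].
#' @param seed Integer seed (candidate order and fold assignment).
#' @param tolerance Minimum improvement required to accept a feature
#'   (default 0: strict decrease).
#' @param condition Condition tag stored in the model (provenance).
#' @return A `signature_model`; its `trajectory` field records the
#'   criterion after each accepted feature.
#' @export
forward_select <- function(pool, matrix, labels, C, sigma,
                           criterion = c("misclassification", "log_loss"),
                           k = 5L, seed = 1L, tolerance = 0,
                           condition = "curated") {
  criterion <- match.arg(criterion)
  pool <- unique(toupper(pool))
  if (length(pool) == 0L) stop("empty candidate pool")
  remaining <- pool
  selected <- character()
  best <- Inf
  trajectory <- numeric()
  round_i <- 0L
  while (length(remaining) > 0L) {
    round_i <- round_i + 1L
    order_seed <- seed + 10000L * round_i
    cand <- local({ set.seed(order_seed); sample(remaining) })
    vals <- vapply(cand, function(g)
      cv_criterion(c(selected, g), matrix, labels, C, sigma, criterion,
                   k = k, seed = seed), 0)
    i <- which.min(vals)           # first-encountered wins ties
    if (vals[i] < best - tolerance && vals[i] < best) {
      selected <- c(selected, cand[i])
      remaining <- setdiff(remaining, cand[i])
      best <- unname(vals[i])
      trajectory <- c(trajectory, best)
      if (best == 0) break
    } else break
  }
  xy <- align_features(matrix, labels, selected)
  params <- fit_gaussian_svm(xy$x, xy$y, C, sigma)
  new_signature_model(features = selected, C = C, sigma = sigma,
                      decision_params = params, criterion = criterion,
                      criterion_value = best, condition = condition,
                      seed = seed, trajectory = trajectory)
}

#' Derive signatures over the full (C, sigma) grid
#'
#' Runs [forward_select()] once per grid pair on the SVM-eligible genes of
#' a qualified set (GE-passing genes; CN-only correlates are excluded
#' because validation cohorts lack copy-number data). Pathway-extended
#' signatures with fewer than two genes are dropped from the returned list
#' (kept in the `audit` attribute); curated-only runs are exempt from the
#' two-gene floor.
#'
#' @param qualified A `qualified_gene_set`, or a character vector of
#'   symbols (then treated as a curated pool unless `pathway_extended`
#'   says otherwise).
#' @param matrix Expression matrix.
#' @param labels Factor sensitive/resistant.
#' @param criterion `"misclassification"` or `"log_loss"`.
#' @param seed Integer seed.
#' @param k Folds.
#' @param grid Hyperparameter grid (default [build_grid()]).
#' @param pathway_extended Logical; is this a pathway-extended pool (two-
#'   gene floor applies)? Default: deduced from the qualified set's
#'   condition (depth > 0).
#' @return List of `signature_model`s (possibly empty, with a warning);
#'   attribute `audit` holds the excluded short models.
#' @export
derive_signatures <- function(qualified, matrix, labels,
                              criterion = c("misclassification", "log_loss"),
                              seed = 1L, k = 5L, grid = build_grid(),
                              pathway_extended = NULL) {
  criterion <- match.arg(criterion)
  if (inherits(qualified, "qualified_gene_set")) {
    cond <- attr(qualified, "condition")
    pool <- qualified$gene[qualified$svm_eligible]
    if (is.null(pathway_extended)) pathway_extended <- cond$max_depth > 0L
    cond_tag <- as.character(cond$id)
  } else {
    pool <- as.character(qualified)
    if (is.null(pathway_extended)) pathway_extended <- FALSE
    cond_tag <- "curated"
  }
  if (length(pool) == 0L) stop("qualified set has no SVM-eligible genes")
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    models[[i]] <- forward_select(pool, matrix, labels,
                                  C = grid$C[i], sigma = grid$sigma[i],
                                  criterion = criterion, k = k, seed = seed,
                                  condition = cond_tag)
  }
  keep <- !pathway_extended |
    vapply(models, function(m) length(m$features) >= 2L, TRUE)
  audit <- models[!keep]
  models <- models[keep]
  if (length(models) == 0L)
    warning("all grid models excluded by the two-gene floor; ",
            "see the audit attribute")
  attr(models, "audit") <- audit
  models
}
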