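#' Multiple-factor-analysis correlation angle between a gene and GI50
#'
#' Relates one gene's expression (and optionally its copy number) to drug
#' GI50 across a cell-line panel as an angle on the MFA correlation circle:
#' ~0 degrees for direct correlation, ~180 degrees for inverse. The gene's
#' variables form one group and GI50 the other; each column is standardized
#' and each group is weighted by the inverse of its first singular value, so
#' neither block dominates the global decomposition. Variables are then
#' placed on the circle by their correlations with the first two global
#' dimensions, and the angle is the planar angle between a gene variable's
#' position and the GI50 position. With a single gene variable the angle
#' reduces analytically to `acos` of the Pearson correlation, which is used
#' directly in that case.
#'
#' @param gene_vars Numeric vector (GE only) or matrix with one column per
#'   gene variable (e.g. columns GE and CN), samples in rows.
#' @param outcome Numeric GI50 vector, same length/rows.
#' @return Data frame with one row per gene variable: `variable`, `angle`
#'   (degrees in \[0, 180\]), `direction` (`direct` if angle <= 90 else
#'   `inverse`).
#' @export
mfa_angle <- function(gene_vars, outcome) {
  if (is.vector(gene_vars)) gene_vars <- matrix(gene_vars,
                                                dimnames = list(NULL, "GE"))
  if (is.null(colnames(gene_vars)))
    colnames(gene_vars) <- paste0("V", seq_len(ncol(gene_vars)))
  n <- nrow(gene_vars)
  if (length(outcome) != n) stop("outcome length != number of samples")
  if (n < 3L) stop("need >=3 samples for an angle estimate")
  if (stats::sd(outcome) == 0) stop("degenerate outcome: constant GI50")
  sds <- apply(gene_vars, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate variable(s): ",
         paste(colnames(gene_vars)[sds == 0], collapse = ", "))

  if (ncol(gene_vars) == 1L) {
    r <- stats::cor(gene_vars[, 1L], outcome)
    ang <- acos(max(-1, min(1, r))) * 180 / pi
    return(data.frame(variable = colnames(gene_vars), angle = ang,
                      direction = ifelse(ang <= 90, "direct", "inverse"),
                      stringsAsFactors = FALSE))
  }

  z <- scale(cbind(gene_vars, .outcome = outcome))
  grp <- c(rep(1L, ncol(gene_vars)), 2L)
  w <- numeric(length(grp))
  for (g in 1:2) {
    block <- z[, grp == g, drop = FALSE]
    d1 <- svd(block, nu = 0L, nv = 0L)$d[1L]
    w[grp == g] <- 1 / d1
  }
  zw <- sweep(z, 2L, w, `*`)
  dec <- svd(zw, nu = 2L, nv = 0L)
  scores <- dec$u %*% diag(dec$d[1:2], 2L, 2L)
  coords <- stats::cor(z, scores)         # variables on the correlation circle
  out_xy <- coords[nrow(coords), ]
  angs <- vapply(seq_len(ncol(gene_vars)), function(j) {
    v <- coords[j, ]
    cosang <- sum(v * out_xy) / sqrt(sum(v^2) * sum(out_xy^2))
    acos(max(-1, min(1, cosang))) * 180 / pi
  }, 0)
  data.frame(variable = colnames(gene_vars), angle = angs,
             direction = ifelse(angs <= 90, "direct", "inverse"),
             stringsAsFactors = FALSE)
}

#' Does an angle pass a correlation threshold?
#'
#' A gene qualifies when its angle lies within `theta` degrees of full
#' direct (0) or full inverse (180) correlation.
#'
#' @param angle Numeric angle(s) in degrees.
#' @param theta Threshold in degrees (10 or 20 in the standard conditions).
#' @return Logical vector.
#' @export
angle_pass <- function(angle, theta) {
  angle <= theta | angle >= 180 - theta
}

#' Angle table for a list of genes against GI50
#'
#' Computes the MFA correlation angle of every requested gene's expression
#' (and copy number, when a CN matrix is given and carries the gene)
#' against the GI50 vector. Genes absent from the expression matrix, or
#' with constant values, are skipped and reported. When CN is available for
#' a gene, GE and CN enter one two-variable group and both receive a record
#' from the same decomposition.
#'
#' @param matrix Expression matrix (genes x samples), probe-collapsed.
#' @param cn Optional copy-number matrix on the same samples.
#' @param gi50 Numeric GI50 vector named by sample, or in matrix column
#'   order.
#' @param genes Character vector of symbols to score.
#' @return Data frame (`angle_table`) with columns `gene`, `source`
#'   (GE/CN), `angle`, `direction`, `node_distance` (NA, filled during
#'   pathway expansion), ordered by gene symbol; attribute `skipped` is a
#'   data frame of skipped genes and reasons.
#' @export
angle_table <- function(matrix, cn = NULL, gi50, genes) {
  validate_expression_matrix(matrix)
  if (!is.null(names(gi50))) {
    miss <- setdiff(colnames(matrix), names(gi50))
    if (length(miss))
      stop("GI50 missing for sample(s): ", paste(miss, collapse = ", "))
    gi50 <- gi50[colnames(matrix)]
  } else if (length(gi50) != ncol(matrix)) {
    stop("GI50 length != sample count and no names to match")
  }
  genes <- unique(toupper(genes))
  recs <- list(); skipped <- list()
  for (g in sort(genes)) {
    if (!(g %in% rownames(matrix))) {
      skipped[[g]] <- "absent from expression matrix"
      next
    }
    ge <- matrix[g, ]
    if (stats::sd(ge) == 0) {
      skipped[[g]] <- "constant expression"
      next
    }
    vars <- cbind(GE = ge)
    if (!is.null(cn) && g %in% rownames(cn)) {
      cnv <- cn[g, colnames(matrix)]
      if (stats::sd(cnv) > 0) vars <- cbind(vars, CN = cnv)
    }
    a <- mfa_angle(vars, gi50)
    recs[[g]] <- data.frame(gene = g, source = a$variable, angle = a$angle,
                            direction = a$direction,
                            node_distance = NA_integer_,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(), source = character(), angle = numeric(),
               direction = character(), node_distance = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(
    gene = names(skipped), reason = unlist(skipped, use.names = FALSE),
    stringsAsFactors = FALSE)
  class(out) <- c("angle_table", class(out))
  out
}

#' Write an angle table as tab-delimited text
#'
#' @param records An `angle_table` (or qualified-set data frame).
#' @param path Output path.
#' @export
write_angle_table <- function(records, path) {
  df <- as.data.frame(records)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render an MFA correlation circle
#'
#' Draws the unit circle with the outcome (GI50) ray at 0 degrees and one
#' ray per gene variable at its correlation angle; direct-correlating genes
#' point near the outcome ray, inverse ones near 180 degrees.
#'
#' @param records Data frame with columns `gene` (or `variable`) and
#'   `angle`.
#' @param outcome_label Label for the outcome ray.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
render_correlation_circle <- function(records, outcome_label = "GI50",
                                      path) {
  if (nrow(records) == 0L) stop("no records to render")
  lab <- if ("gene" %in% names(records)) records$gene else records$variable
  grDevices::png(path, width = 720, height = 720)
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25),
                 asp = 1, xlab = "Dim 1", ylab = "Dim 2",
                 main = "MFA correlation circle")
  th <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(cos(th), sin(th), col = "grey60")
  graphics::arrows(0, 0, 1, 0, length = 0.08, col = "red", lwd = 2)
  graphics::text(1.12, 0, outcome_label, col = "red")
  a <- records$angle * pi / 180
  graphics::arrows(0, 0, cos(a), sin(a), length = 0.06, col = "steelblue")
  graphics::text(1.12 * cos(a), 1.12 * sin(a), lab, cex = 0.7)
  invisible(path)
}
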