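#' Specification for synthetic pipeline fixtures
#'
#' Defines a self-contained study: a cell-line training panel with genes
#' planted to correlate with GI50, an interaction network with curated
#' seeds and planted one-node/two-node chains, and a patient validation
#' cohort with class-shifted signature genes. Defaults mirror a realistic
#' desk-scale study: a 48-cell-line panel, GI50 spanning 3.0-6.5 on the
#' -log10 molar scale, and a 1:3 sensitive:resistant patient cohort.
#'
#' Planted genes are constructed so their in-sample Pearson correlation
#' with GI50 equals `planted_r` exactly (half direct, half inverse): the
#' generator residualizes the noise against GI50 before mixing, so the
#' planted angle is `acos(planted_r)` up to MFA arithmetic, not merely in
#' expectation. Background genes are independent noise.
#'
#' @param n_cell_lines Training panel size (default 48).
#' @param n_patients Validation cohort size (default 40).
#' @param n_genes Total genes in the universe (default 60).
#' @param n_curated Curated seed genes, all planted (default 4).
#' @param n_chains Planted seed -> one-node -> two-node chains (default 2;
#'   adds 2 planted genes each).
#' @param planted_r Target in-sample |Pearson r| with GI50 (default 0.95).
#' @param gi50_range Range of GI50 (-log10 molar, default c(3.0, 6.5)).
#' @param edge_density Background edge probability among non-planted pairs
#'   (default 0.02).
#' @param alias_fraction Fraction of gene symbols given a deprecated alias
#'   in the generated alias table (default 0.2).
#' @param effect_size Patient-cohort class separation for signature genes,
#'   in noise-SD units (default 2).
#' @param noise_sd Expression noise SD (default 1).
#' @param imbalance Sensitive:resistant patient ratio (default c(1, 3)).
#' @param probe_dup_fraction Fraction of cohort genes emitted as two
#'   probes (default 0.3).
#' @param n_cn_only Genes given GI50-correlated copy number but noise
#'   expression, to exercise the CN-only exclusion (default 2).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cell_lines = 48L, n_patients = 40L,
                           n_genes = 60L, n_curated = 4L, n_chains = 2L,
                           planted_r = 0.95, gi50_range = c(3.0, 6.5),
                           edge_density = 0.02, alias_fraction = 0.2,
                           effect_size = 2, noise_sd = 1,
                           imbalance = c(1, 3), probe_dup_fraction = 0.3,
                           n_cn_only = 2L, seed = 1L) {
  n_planted <- n_curated + 2L * n_chains
  if (n_planted + n_cn_only > n_genes)
    stop("planted + CN-only gene count exceeds n_genes")
  if (planted_r <= 0 || planted_r >= 1)
    stop("planted_r must lie strictly between 0 and 1")
  genes <- sprintf("G%03d", seq_len(n_genes))
  curated <- genes[seq_len(n_curated)]
  chain1 <- genes[n_curated + seq_len(n_chains)]
  chain2 <- genes[n_curated + n_chains + seq_len(n_chains)]
  cn_only <- if (n_cn_only > 0L)
    genes[n_planted + seq_len(n_cn_only)] else character()
  planted <- c(curated, chain1, chain2)
  dir <- rep(c(1, -1), length.out = length(planted))
  structure(list(
    n_cell_lines = n_cell_lines, n_patients = n_patients,
    n_genes = n_genes, genes = genes, curated = curated,
    chains = data.frame(seed = curated[seq_len(n_chains)],
                        one_node = chain1, two_node = chain2,
                        stringsAsFactors = FALSE),
    planted = planted,
    planted_direction = stats::setNames(dir, planted),
    cn_only = cn_only, planted_r = planted_r, gi50_range = gi50_range,
    edge_density = edge_density, alias_fraction = alias_fraction,
    effect_size = effect_size, noise_sd = noise_sd,
    imbalance = imbalance, probe_dup_fraction = probe_dup_fraction,
    seed = as.integer(seed)), class = "synthetic_spec")
}

# Per-gene baseline expression shared by the panel and the cohort: the
# generator emulates cohorts already calibrated at the gene level, with
# quantile normalization left to absorb sample-level distribution shifts.
gene_baselines <- function(spec) {
  set.seed(spec$seed + 11L)
  stats::setNames(stats::rnorm(spec$n_genes, 7, 1), spec$genes)
}

# Mix noise into the standardized outcome so the realized sample
# correlation is exactly r * sign.
planted_vector <- function(outcome_std, r, sign, noise) {
  res <- stats::residuals(stats::lm(noise ~ outcome_std))
  res <- res / stats::sd(res)
  v <- sign * r * outcome_std + sqrt(1 - r^2) * res
  v / stats::sd(v)
}

#' Generate a synthetic cell-line training panel
#'
#' GI50 is drawn uniformly over the spec's range. Planted genes mix the
#' standardized GI50 vector with orthogonalized noise so that their
#' in-sample correlation is exactly +/- `planted_r`; remaining genes are
#' independent Gaussian noise around gene-specific baselines. Genes listed
#' as CN-only get a GI50-correlated copy-number row and noise expression.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `expression` (genes x cell lines), `cn` (copy-number
#'   matrix for the CN-only genes, or NULL), and `responses` (data frame
#'   sample/gi50).
#' @export
make_cell_line_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  baseline <- gene_baselines(spec)
  set.seed(spec$seed)
  n <- spec$n_cell_lines
  cells <- sprintf("CL%02d", seq_len(n))
  gi50 <- stats::runif(n, spec$gi50_range[1L], spec$gi50_range[2L])
  g_std <- as.numeric(scale(gi50))
  expr <- matrix(NA_real_, spec$n_genes, n,
                 dimnames = list(spec$genes, cells))
  for (g in spec$genes) {
    noise <- stats::rnorm(n)
    if (g %in% spec$planted) {
      v <- planted_vector(g_std, spec$planted_r,
                          spec$planted_direction[[g]], noise)
      expr[g, ] <- baseline[[g]] + spec$noise_sd * v
    } else {
      expr[g, ] <- baseline[[g]] + spec$noise_sd * noise
    }
  }
  cn <- NULL
  if (length(spec$cn_only)) {
    cn <- matrix(NA_real_, length(spec$cn_only), n,
                 dimnames = list(spec$cn_only, cells))
    for (g in spec$cn_only) {
      v <- planted_vector(g_std, spec$planted_r, 1, stats::rnorm(n))
      cn[g, ] <- 2 + 0.5 * v
    }
  }
  list(expression = expr, cn = cn,
       responses = data.frame(sample = cells, gi50 = gi50,
                              stringsAsFactors = FALSE))
}

#' Generate a synthetic interaction network and alias table
#'
#' Plants the spec's curated -> one-node -> two-node chains as guaranteed
#' edges, adds random background edges among the remaining pairs at
#' `edge_density`, and emits an alias table mapping a fraction of symbols
#' to fake deprecated aliases (symbol with suffix `-OLD`), so alias
#' substitution and association verification are exercised end-to-end.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `network` (an `interaction_network`) and `aliases`
#'   (an `alias_map`).
#' @export
make_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  chain_edges <- rbind(
    data.frame(from = spec$chains$seed, to = spec$chains$one_node,
               stringsAsFactors = FALSE),
    data.frame(from = spec$chains$one_node, to = spec$chains$two_node,
               stringsAsFactors = FALSE))
  # background edges among pairs not touching the planted chain genes,
  # so traversal outcomes are governed by the angle filter alone
  bg_nodes <- setdiff(spec$genes, c(spec$chains$one_node,
                                    spec$chains$two_node))
  pairs <- utils::combn(bg_nodes, 2L)
  pick <- stats::runif(ncol(pairs)) < spec$edge_density
  bg <- data.frame(from = pairs[1L, pick], to = pairs[2L, pick],
                   stringsAsFactors = FALSE)
  edges <- rbind(chain_edges, bg)
  edges$itype <- "interacts-with"
  net <- interaction_network(edges)
  n_alias <- floor(spec$alias_fraction * spec$n_genes)
  aliased <- sample(spec$genes, n_alias)
  aliases <- alias_map(c(paste0(aliased, "-OLD"), spec$genes),
                       c(aliased, spec$genes))
  list(network = net, aliases = aliases)
}

#' Generate a synthetic patient validation cohort
#'
#' Two outcome classes at the spec's imbalance; each signature gene's mean
#' is shifted between classes by `effect_size` noise-SD units, in the
#' direction matching its training-panel correlation (direct genes high in
#' sensitive patients under the default polarity). A fraction of genes is
#' emitted as two probe rows sharing the gene symbol, and an optional
#' group covariate (e.g. sex) can modulate the effect of one designated
#' gene.
#'
#' @param spec A `synthetic_spec`.
#' @param signature_genes Genes to separate between classes (default: the
#'   spec's planted genes).
#' @param directions Named vector of +1 (direct: high expression in
#'   sensitive patients) / -1 per signature gene; defaults to the spec's
#'   planted directions (+1 for unknown genes).
#' @param effect_size Class separation in noise-SD units; default from the
#'   spec.
#' @param group_gene Optional gene whose effect is halved in group "M" and
#'   amplified in group "F".
#' @return List with `expression` (probe-level rows, duplicated symbols),
#'   `responses` (sample/label data frame) and `groups` (factor M/F named
#'   by sample).
#' @export
make_patient_cohort <- function(spec, signature_genes = spec$planted,
                                directions = NULL,
                                effect_size = spec$effect_size,
                                group_gene = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  baseline <- gene_baselines(spec)
  set.seed(spec$seed + 2L)
  n <- spec$n_patients
  pts <- sprintf("PT%02d", seq_len(n))
  n_sens <- max(1L, round(n * spec$imbalance[1L] / sum(spec$imbalance)))
  label <- factor(c(rep("sensitive", n_sens), rep("resistant", n - n_sens)),
                  levels = c("sensitive", "resistant"))
  groups <- factor(sample(c("M", "F"), n, replace = TRUE))
  names(groups) <- pts
  if (is.null(directions)) {
    directions <- stats::setNames(rep(1, length(signature_genes)),
                                  signature_genes)
    known <- intersect(signature_genes, names(spec$planted_direction))
    directions[known] <- spec$planted_direction[known]
  }
  half <- effect_size * spec$noise_sd / 2
  gene_rows <- lapply(spec$genes, function(g) {
    mu <- rep(baseline[[g]], n)
    if (g %in% signature_genes) {
      shift <- ifelse(label == "sensitive", half, -half) * directions[[g]]
      if (!is.null(group_gene) && g == group_gene)
        shift <- shift * ifelse(groups == "M", 0.5, 1.5)
      mu <- mu + shift
    }
    mu + stats::rnorm(n, 0, spec$noise_sd)
  })
  names(gene_rows) <- spec$genes
  dup <- spec$genes[stats::runif(spec$n_genes) < spec$probe_dup_fraction]
  rows <- list(); rnames <- character()
  for (g in spec$genes) {
    if (g %in% dup) {
      rows[[length(rows) + 1L]] <- gene_rows[[g]] + stats::rnorm(n, 0, 0.1)
      rows[[length(rows) + 1L]] <- gene_rows[[g]] + stats::rnorm(n, 0, 0.1)
      rnames <- c(rnames, g, g)
    } else {
      rows[[length(rows) + 1L]] <- gene_rows[[g]]
      rnames <- c(rnames, g)
    }
  }
  expr <- do.call(rbind, rows)
  dimnames(expr) <- list(rnames, pts)
  list(expression = expr,
       responses = data.frame(sample = pts, label = label,
                              stringsAsFactors = FALSE),
       groups = groups)
}
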