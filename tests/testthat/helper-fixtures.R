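# Shared fixture builders. All randomness is seeded by the caller.

# Small expression matrix with named genes/samples.
toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}

# Write a tab-delimited expression file and return its path.
write_expr_file <- function(mat, path = tempfile(fileext = ".tsv")) {
  write_expression_matrix(mat, path)
  path
}

# A separable two-class training fixture: `n_inform` informative genes
# whose class means sit +/- delta/2 apart (in SD units), plus noise genes.
planted_classification_fixture <- function(n = 40, n_inform = 1,
                                           n_noise = 9, delta = 6,
                                           seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("sensitive", "resistant"), length.out = n),
              levels = c("sensitive", "resistant"))
  genes <- c(sprintf("INF%02d", seq_len(n_inform)),
             sprintf("NSE%02d", seq_len(n_noise)))
  x <- matrix(rnorm(length(genes) * n), length(genes), n,
              dimnames = list(genes, sprintf("S%02d", seq_len(n))))
  shift <- ifelse(y == "resistant", delta / 2, -delta / 2)
  for (g in seq_len(n_inform)) x[g, ] <- x[g, ] + shift
  names(y) <- colnames(x)
  list(x = x, y = y)
}

# Tiny chain network A-B-C (+ an off-chain edge D-E).
chain_network <- function() {
  interaction_network(data.frame(
    from = c("A", "B", "D"), to = c("B", "C", "E"),
    itype = "interacts-with"))
}

# Panel whose genes have prescribed exact in-sample correlation with GI50;
# r values named by gene, others noise.
correlated_panel <- function(r_by_gene, n_noise = 0, n = 30, seed = 1) {
  set.seed(seed)
  gi50 <- runif(n, 3, 6.5)
  g_std <- as.numeric(scale(gi50))
  genes <- c(names(r_by_gene),
             if (n_noise) sprintf("NZ%02d", seq_len(n_noise)))
  x <- matrix(NA_real_, length(genes), n,
              dimnames = list(genes, sprintf("CL%02d", seq_len(n))))
  for (g in names(r_by_gene)) {
    e <- rnorm(n)
    res <- residuals(lm(e ~ g_std)); res <- res / sd(res)
    r <- r_by_gene[[g]]
    x[g, ] <- r * g_std + sqrt(1 - r^2) * res
  }
  for (g in setdiff(genes, names(r_by_gene))) x[g, ] <- rnorm(n)
  list(x = x, gi50 = setNames(gi50, colnames(x)))
}

# Independent brute-force BFS oracle for layered pathway expansion:
# passing() is a predicate; traversal never passes through failing genes.
bfs_expand_oracle <- function(seeds, edges, passing, max_depth) {
  nbr <- function(g) unique(c(edges$to[edges$from == g],
                              edges$from[edges$to == g]))
  dist <- list()
  frontier <- character()
  for (s in unique(seeds)) {
    if (passing(s)) { dist[[s]] <- 0L; frontier <- c(frontier, s) }
  }
  seen <- unique(seeds)
  d <- 0L
  while (d < max_depth && length(frontier)) {
    d <- d + 1L
    cand <- setdiff(unique(unlist(lapply(frontier, nbr))), seen)
    seen <- c(seen, cand)
    frontier <- Filter(passing, cand)
    for (g in frontier) dist[[g]] <- d
  }
  dist
}
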