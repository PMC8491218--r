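test_that("the six conditions pair depths 0/1/2 with 10/20 degrees", {
  tab <- preselection_conditions()
  expect_equal(tab$max_depth, c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_equal(tab$theta, c(10, 20, 10, 20, 10, 20))
  expect_error(preselection_conditions(7), "1..6")
})

test_that("alias substitution replaces, reports and de-duplicates", {
  m <- alias_map(c("PNP", "DBP", "OLDX"), c("NP", "GC", "GC"))
  r <- substitute_aliases(c("pnp", "TP53", "DBP", "OLDX"), m)
  expect_equal(r$genes, c("NP", "TP53", "GC"))
  expect_true(r$report$duplicate[r$report$input == "OLDX"])
  expect_false(all(r$report$known))
  # identity on an all-approved list
  r2 <- substitute_aliases(c("NP", "GC"), m)
  expect_equal(r2$genes, c("NP", "GC"))
})

test_that("association verification removes pairs absent from the network", {
  net <- interaction_network(data.frame(
    from = c("GC", "GC", "GC", "GC"),
    to = c("HNF1A", "CYP11B1", "CYP27B1", "PIK3R3")))
  pairs <- data.frame(parent = c("GC", "GC", "GC", "GC"),
                      child = c("CNN1", "CA3", "HNF1A", "CYP27B1"),
                      stringsAsFactors = FALSE)
  v <- verify_associations(pairs, net)
  expect_setequal(v$removed$child, c("CNN1", "CA3"))
  expect_setequal(v$retained$child, c("HNF1A", "CYP27B1"))
  e <- verify_associations(pairs[0, ], net)
  expect_equal(nrow(e$retained), 0L)
  expect_equal(nrow(e$removed), 0L)
})

make_chain_panel <- function(r_by_gene, seed = 1) {
  correlated_panel(r_by_gene, n_noise = 0, n = 30, seed = seed)
}

test_that("expansion follows the chain and records distances and parents", {
  fix <- make_chain_panel(c(A = 0.97, B = 0.96, C = 0.95))
  net <- chain_network()
  qs <- expand_gene_set("A", net, fix$x, NULL, fix$gi50, condition = 6)
  expect_equal(qs$gene, c("A", "B", "C"))
  expect_equal(qs$node_distance, 0:2)
  expect_equal(qs$parents, c("", "A", "B"))
})

test_that("traversal never passes through a failing gene", {
  # B fails the 20-degree threshold; C must be excluded even though it
  # would pass on its own
  fix <- make_chain_panel(c(A = 0.97, B = 0.10, C = 0.95))
  net <- chain_network()
  qs <- expand_gene_set("A", net, fix$x, NULL, fix$gi50, condition = 6)
  expect_equal(qs$gene, "A")
  # agreement with an independent BFS oracle on the same predicate
  tab <- angle_table(fix$x, NULL, fix$gi50, c("A", "B", "C"))
  passing <- function(g) angle_pass(tab$angle[tab$gene == g], 20)
  edges <- data.frame(from = c("A", "B"), to = c("B", "C"))
  want <- bfs_expand_oracle("A", edges, passing, max_depth = 2)
  expect_setequal(qs$gene, names(want))
})

test_that("depth-0 conditions return a subset of the seeds", {
  fix <- make_chain_panel(c(A = 0.97, B = 0.96, C = 0.95))
  net <- chain_network()
  qs <- expand_gene_set(c("A", "B"), net, fix$x, NULL, fix$gi50,
                        condition = 2)
  expect_true(all(qs$gene %in% c("A", "B")))
  expect_true(all(qs$node_distance == 0L))
})

test_that("failing curated genes stay in the audit but not the set", {
  fix <- make_chain_panel(c(A = 0.97, B = 0.10))
  net <- chain_network()
  qs <- expand_gene_set(c("A", "B"), net, fix$x, NULL, fix$gi50,
                        condition = 2)
  expect_equal(qs$gene, "A")
  audit <- attr(qs, "audit")
  expect_true("B" %in% audit$gene)
  expect_false(audit$pass[audit$gene == "B"])
})

test_that("an all-failing seed layer warns and yields an empty set", {
  fix <- make_chain_panel(c(A = 0.05))
  net <- chain_network()
  expect_warning(
    qs <- expand_gene_set("A", net, fix$x, NULL, fix$gi50, condition = 6),
    "no gene passed")
  expect_equal(nrow(qs), 0L)
})

random_expansion_fixture <- function(seed) {
  set.seed(seed)
  genes <- sprintf("R%02d", 1:15)
  r <- setNames(runif(15, -1, 1) * 0.999, genes)
  fix <- correlated_panel(r, n_noise = 0, n = 30, seed = seed + 100)
  pairs <- t(combn(genes, 2))
  pick <- runif(nrow(pairs)) < 0.15
  net <- interaction_network(data.frame(from = pairs[pick, 1],
                                        to = pairs[pick, 2]))
  list(fix = fix, net = net, seeds = genes[1:3])
}

test_that("qualified sets grow monotonically in theta and depth", {
  for (s in 1:5) {
    fx <- random_expansion_fixture(s)
    got <- lapply(1:6, function(i)
      suppressWarnings(expand_gene_set(fx$seeds, fx$net, fx$fix$x, NULL,
                                       fx$fix$gi50, condition = i))$gene)
    # theta monotonicity at equal depth
    expect_true(all(got[[1]] %in% got[[2]]))
    expect_true(all(got[[3]] %in% got[[4]]))
    expect_true(all(got[[5]] %in% got[[6]]))
    # depth monotonicity at equal theta
    expect_true(all(got[[1]] %in% got[[3]]))
    expect_true(all(got[[3]] %in% got[[5]]))
    expect_true(all(got[[2]] %in% got[[4]]))
    expect_true(all(got[[4]] %in% got[[6]]))
  }
})

test_that("every recruited gene has a passing adjacent parent one layer up", {
  for (s in 1:5) {
    fx <- random_expansion_fixture(s + 50)
    qs <- suppressWarnings(
      expand_gene_set(fx$seeds, fx$net, fx$fix$x, NULL, fx$fix$gi50,
                      condition = 6))
    deeper <- qs[qs$node_distance > 0L, , drop = FALSE]
    for (i in seq_len(nrow(deeper))) {
      parents <- strsplit(deeper$parents[i], ",")[[1]]
      expect_gt(length(parents), 0)
      for (p in parents) {
        expect_true(has_edge(fx$net, p, deeper$gene[i]))
        prow <- qs[qs$gene == p, ]
        expect_equal(prow$node_distance, deeper$node_distance[i] - 1L)
        expect_true(prow$pass)
      }
    }
    # distances are minimal: no qualified gene is listed twice
    expect_false(anyDuplicated(qs$gene) > 0)
  }
})

test_that("expansion is deterministic and run_conditions covers ids 1-6", {
  fx <- random_expansion_fixture(99)
  a <- suppressWarnings(run_conditions(fx$seeds, fx$net, fx$fix$x, NULL,
                                       fx$fix$gi50))
  b <- suppressWarnings(run_conditions(fx$seeds, fx$net, fx$fix$x, NULL,
                                       fx$fix$gi50))
  expect_equal(names(a), paste0("condition_", 1:6))
  for (i in 1:6) expect_equal(as.data.frame(a[[i]]), as.data.frame(b[[i]]))
  for (i in 1:6)
    expect_equal(attr(a[[i]], "condition")$id,
                 preselection_conditions(i)$id)
})

test_that("aliases are substituted in seeds and network before traversal", {
  fix <- make_chain_panel(c(A = 0.97, B = 0.96, C = 0.95))
  # network written with deprecated names for A and C
  net <- interaction_network(data.frame(from = c("A-OLD", "B"),
                                        to = c("B", "C-OLD")))
  m <- alias_map(c("A-OLD", "C-OLD", "A", "B", "C"),
                 c("A", "C", "A", "B", "C"))
  qs <- expand_gene_set("A-OLD", net, fix$x, NULL, fix$gi50, condition = 6,
                        aliases = m)
  expect_equal(qs$gene, c("A", "B", "C"))
})

test_that("CN-only correlates pass and traverse but are SVM-ineligible", {
  fix <- make_chain_panel(c(A = 0.97, C = 0.95))
  set.seed(42)
  bmat <- matrix(rnorm(30), 1, 30, dimnames = list("B", colnames(fix$x)))
  x <- rbind(fix$x, bmat)
  # B's expression is noise, but its copy number tracks GI50
  g_std <- as.numeric(scale(fix$gi50))
  e <- rnorm(30); res <- residuals(lm(e ~ g_std)); res <- res / sd(res)
  cn <- matrix(2 + 0.5 * (0.97 * g_std + sqrt(1 - 0.97^2) * res), 1, 30,
               dimnames = list("B", colnames(fix$x)))
  net <- chain_network()
  qs <- expand_gene_set("A", net, x, cn, fix$gi50, condition = 6)
  expect_setequal(qs$gene, c("A", "B", "C"))
  expect_false(qs$svm_eligible[qs$gene == "B"])
  expect_true(qs$pass[qs$gene == "B"])
  expect_true(qs$svm_eligible[qs$gene == "C"])
})
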