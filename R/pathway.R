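#' The six standard preselection conditions
#'
#' Each condition pairs a maximum pathway depth with an angular threshold:
#' conditions 1-2 score curated genes only (depth 0) at 10 and 20 degrees;
#' 3-4 add one-node distant genes; 5-6 add two-node distant genes.
#'
#' @param id Condition identifier 1-6, or `NULL` for the full table.
#' @return For a single id, a list with `id`, `max_depth`, `theta`;
#'   otherwise a data frame of all six.
#' @export
preselection_conditions <- function(id = NULL) {
  tab <- data.frame(id = 1:6,
                    max_depth = rep(0:2, each = 2L),
                    theta = rep(c(10, 20), 3L))
  if (is.null(id)) return(tab)
  if (!id %in% tab$id) stop("condition id must be in 1..6, got ", id)
  as.list(tab[tab$id == id, ])
}

#' Substitute deprecated aliases with approved symbols
#'
#' Applies an alias map to a gene list, de-duplicating symbols that
#' collide after substitution (two aliases of one gene). The report lists
#' every substitution made, symbols not found in the map (kept verbatim),
#' and duplicates removed.
#'
#' @param genes Character vector of symbols.
#' @param aliases An `alias_map`, or `NULL` for a no-op.
#' @return List with `genes` (resolved, unique, input order) and `report`
#'   (data frame: input, resolved, known, duplicate).
#' @export
substitute_aliases <- function(genes, aliases = NULL) {
  genes <- toupper(genes)
  if (is.null(aliases)) {
    rep <- data.frame(input = genes, resolved = genes, known = NA,
                      duplicate = duplicated(genes),
                      stringsAsFactors = FALSE)
    return(list(genes = unique(genes), report = rep))
  }
  res <- resolve_alias(aliases, genes)
  res$duplicate <- duplicated(res$resolved)
  list(genes = unique(res$resolved), report = res)
}

#' Audit parent-child gene associations against the interaction network
#'
#' A pathway-expansion step may report a recruited gene whose link to its
#' parent arose from a stale alias rather than a real interaction. Each
#' (parent, child) pair is checked for an edge in the network; pairs with
#' no edge are removed and returned separately for audit.
#'
#' @param pairs Data frame with columns `parent`, `child` (symbols).
#' @param network An `interaction_network`.
#' @return List with `retained` and `removed` data frames.
#' @export
verify_associations <- function(pairs, network) {
  if (nrow(pairs) == 0L)
    return(list(retained = pairs, removed = pairs))
  ok <- mapply(function(p, c) has_edge(network, p, c),
               pairs$parent, pairs$child)
  list(retained = pairs[ok, , drop = FALSE],
       removed = pairs[!ok, , drop = FALSE])
}

#' Expand a curated gene set through the interaction network
#'
#' Breadth-layered traversal under one preselection condition. Layer 0:
#' the curated seeds are scored by [angle_table()] and filtered by
#' [angle_pass()]. Each further layer (up to the condition's `max_depth`)
#' takes the network neighbours of the previous layer's PASSING genes,
#' drops genes already assigned a smaller distance, and scores and filters
#' them identically. Genes failing the threshold are dead ends: the
#' traversal never passes through them, and curated genes that fail are
#' excluded from the qualified set (they remain in the audit table).
#' A gene's node distance is the minimum distance at which it was
#' recruited, and its parents are the passing previous-layer genes it
#' shares an edge with.
#'
#' Genes whose CN (but not GE) correlates with GI50 still pass and are
#' traversed through, but are flagged ineligible for SVM features, since
#' validation cohorts carry no copy-number data.
#'
#' @param seeds Curated symbols (after alias substitution).
#' @param network An `interaction_network` (alias-resolved node names).
#' @param matrix Probe-collapsed expression matrix.
#' @param cn Optional copy-number matrix.
#' @param gi50 GI50 vector (named by sample or in column order).
#' @param condition Condition id 1-6 or a list from
#'   [preselection_conditions()].
#' @param aliases Optional `alias_map` applied to seeds and network node
#'   names before traversal.
#' @param max_neighbors Optional cap on the number of neighbours recruited
#'   per gene (hub control); `Inf` by default.
#' @param angle_cache Optional environment used to memoize per-gene angle
#'   records across conditions.
#' @return A `qualified_gene_set`: data frame with one row per passing
#'   gene (`gene`, `node_distance`, `angle_ge`, `angle_cn`, `direction`,
#'   `parents` (comma-joined), `svm_eligible`), plus attributes `condition`,
#'   `audit` (all scored genes incl. failures), `pairs` (parent-child
#'   edges used), and `skipped`.
#' @export
expand_gene_set <- function(seeds, network, matrix, cn = NULL, gi50,
                            condition, aliases = NULL,
                            max_neighbors = Inf, angle_cache = NULL) {
  if (is.numeric(condition)) condition <- preselection_conditions(condition)
  stopifnot(all(c("id", "max_depth", "theta") %in% names(condition)))
  theta <- condition$theta
  if (length(seeds) == 0L) stop("empty curated seed list")

  if (!is.null(aliases)) {
    seeds <- substitute_aliases(seeds, aliases)$genes
    network <- rename_network_nodes(network, aliases)
  } else seeds <- unique(toupper(seeds))

  if (is.null(angle_cache)) angle_cache <- new.env(parent = emptyenv())
  score <- function(genes) {
    todo <- genes[!vapply(genes, exists, TRUE, envir = angle_cache)]
    if (length(todo)) {
      tab <- angle_table(matrix, cn, gi50, todo)
      sk <- attr(tab, "skipped")
      for (g in todo) {
        rows <- tab[tab$gene == g, , drop = FALSE]
        reason <- sk$reason[sk$gene == g]
        assign(g, list(rows = rows,
                       skip = if (length(reason)) reason[1L] else NA_character_),
               envir = angle_cache)
      }
    }
    invisible(NULL)
  }

  gene_row <- function(g, d, parents, rows) {
    ge <- rows$angle[rows$source == "GE"]
    cnv <- rows$angle[rows$source == "CN"]
    ge_pass <- length(ge) == 1L && angle_pass(ge, theta)
    cn_pass <- length(cnv) == 1L && angle_pass(cnv, theta)
    data.frame(gene = g, node_distance = d,
               angle_ge = if (length(ge)) ge else NA_real_,
               angle_cn = if (length(cnv)) cnv else NA_real_,
               direction = if (length(ge)) rows$direction[rows$source == "GE"][1L]
                           else rows$direction[1L],
               parents = paste(parents, collapse = ","),
               pass = ge_pass || cn_pass,
               svm_eligible = ge_pass,
               stringsAsFactors = FALSE)
  }

  audit <- list(); qualified <- list(); pairs <- list(); skipped <- list()
  assigned <- character()   # every gene ever scored (any layer)
  frontier <- character()   # passing genes of the previous layer

  layer_genes <- sort(unique(seeds))
  for (d in 0:condition$max_depth) {
    if (d > 0L) {
      if (length(frontier) == 0L) break
      nb <- lapply(frontier, function(p) {
        v <- network_neighbors(network, p)
        if (is.finite(max_neighbors) && length(v) > max_neighbors)
          v <- v[seq_len(max_neighbors)]
        v
      })
      names(nb) <- frontier
      layer_genes <- sort(setdiff(unique(unlist(nb)), assigned))
    }
    if (length(layer_genes) == 0L) break
    score(layer_genes)
    new_frontier <- character()
    for (g in layer_genes) {
      entry <- get(g, envir = angle_cache)
      rows <- entry$rows
      if (nrow(rows) == 0L) {
        skipped[[g]] <- entry$skip
        assigned <- c(assigned, g)
        next
      }
      parents <- if (d == 0L) character() else
        frontier[vapply(frontier, function(p) g %in% network_neighbors(network, p), TRUE)]
      row <- gene_row(g, d, parents, rows)
      audit[[g]] <- row
      assigned <- c(assigned, g)
      if (row$pass) {
        qualified[[g]] <- row
        new_frontier <- c(new_frontier, g)
        for (p in parents)
          pairs[[paste(p, g)]] <- data.frame(parent = p, child = g,
                                             stringsAsFactors = FALSE)
      }
    }
    frontier <- new_frontier
  }

  empty <- data.frame(gene = character(), node_distance = integer(),
                      angle_ge = numeric(), angle_cn = numeric(),
                      direction = character(), parents = character(),
                      pass = logical(), svm_eligible = logical(),
                      stringsAsFactors = FALSE)
  qset <- if (length(qualified))
    do.call(rbind, c(qualified, list(make.row.names = FALSE))) else empty
  audit_df <- if (length(audit))
    do.call(rbind, c(audit, list(make.row.names = FALSE))) else empty
  ord <- order(qset$node_distance, qset$gene)
  qset <- qset[ord, , drop = FALSE]
  rownames(qset) <- NULL
  if (nrow(qset) == 0L)
    warning("no gene passed the angle threshold at layer 0 for condition ",
            condition$id)
  pair_df <- if (length(pairs))
    do.call(rbind, c(pairs, list(make.row.names = FALSE))) else
    data.frame(parent = character(), child = character(),
               stringsAsFactors = FALSE)
  ver <- verify_associations(pair_df, network)
  attr(qset, "condition") <- condition
  attr(qset, "audit") <- audit_df
  attr(qset, "pairs") <- ver$retained
  attr(qset, "removed_pairs") <- ver$removed
  attr(qset, "skipped") <- data.frame(
    gene = names(skipped), reason = unlist(skipped, use.names = FALSE),
    stringsAsFactors = FALSE)
  class(qset) <- c("qualified_gene_set", class(qset))
  qset
}

rename_network_nodes <- function(network, aliases) {
  nm <- igraph::V(network)$name
  res <- resolve_alias(aliases, nm)
  g <- igraph::set_vertex_attr(network, "name", value = res$resolved)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  class(g) <- c("interaction_network", class(g))
  g
}

#' Run all six preselection conditions
#'
#' One [expand_gene_set()] call per condition, sharing a single per-gene
#' angle cache so each gene is scored once.
#'
#' @inheritParams expand_gene_set
#' @return Named list (`condition_1` ... `condition_6`) of
#'   `qualified_gene_set` objects.
#' @export
run_conditions <- function(seeds, network, matrix, cn = NULL, gi50,
                           aliases = NULL, max_neighbors = Inf) {
  cache <- new.env(parent = emptyenv())
  if (!is.null(aliases)) {
    seeds <- substitute_aliases(seeds, aliases)$genes
    network <- rename_network_nodes(network, aliases)
    aliases <- NULL
  }
  out <- lapply(1:6, function(i)
    expand_gene_set(seeds, network, matrix, cn, gi50,
                    condition = preselection_conditions(i),
                    max_neighbors = max_neighbors, angle_cache = cache))
  names(out) <- paste0("condition_", 1:6)
  out
}

#' Write a qualified gene set (and its audit trail) to disk
#'
#' @param qset A `qualified_gene_set`.
#' @param path Output path for the qualified table; the audit and
#'   removed-association tables are written alongside with suffixes
#'   `.audit.tsv` and `.removed.tsv`.
#' @export
write_qualified_set <- function(qset, path) {
  utils::write.table(as.data.frame(qset), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(attr(qset, "audit"),
                     paste0(path, ".audit.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(attr(qset, "removed_pairs"),
                     paste0(path, ".removed.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
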