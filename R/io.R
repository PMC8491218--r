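#' Read a tab-delimited expression matrix
#'
#' Reads a features-by-samples matrix of log-scale expression (or copy
#' number) values. The first column holds gene or probe identifiers, the
#' header row holds sample identifiers. Gene symbols are uppercased on
#' ingest so they can be matched against interaction networks and alias
#' tables, which mix cases in the wild. Duplicate feature identifiers
#' (multiple probes per gene) are retained; collapse them later with
#' [collapse_probes()].
#'
#' @param path Path to a tab-delimited text file.
#' @param missing Character vector of tokens to be read as missing values.
#' @param drop_missing If `TRUE` (default), features with any missing value
#'   are dropped with a warning; such genes cannot take part in the angle
#'   or SVM computations.
#' @return A numeric matrix (features x samples) with uppercased rownames.
#' @export
read_expression_matrix <- function(path, missing = c("NA", ""),
                                   drop_missing = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L)
    stop("expression file must have a feature-id column and >=1 sample column: ",
         path)
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  feature_ids <- toupper(trimws(raw[[1L]]))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals %in% missing] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]],
                 feature_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  dimnames(num) <- list(feature_ids, sample_ids)
  if (drop_missing && anyNA(num)) {
    drop <- rowSums(is.na(num)) > 0L
    warning(sum(drop), " feature(s) with missing values dropped: ",
            paste(utils::head(unique(feature_ids[drop]), 5L), collapse = ", "),
            if (sum(drop) > 5L) ", ..." else "")
    num <- num[!drop, , drop = FALSE]
  }
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to a tab-delimited file
#'
#' @param x Numeric matrix as returned by [read_expression_matrix()].
#' @param path Output path.
#' @param id_column Name for the feature-id column in the header.
#' @export
write_expression_matrix <- function(x, path, id_column = "gene") {
  validate_expression_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry feature rownames and sample colnames")
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers")
  invisible(x)
}

#' Read a per-sample response table
#'
#' Two-column tab-delimited file: sample identifier, then either a numeric
#' GI50 value (-log10 molar; training panels) or a binary label
#' sensitive/resistant (validation cohorts). The column type is detected
#' from the header name unless `type` is given.
#'
#' @param path Path to the table.
#' @param type `"auto"`, `"gi50"` or `"label"`.
#' @return A data frame with columns `sample` and either `gi50` (numeric) or
#'   `label` (factor with levels sensitive, resistant).
#' @export
read_response_table <- function(path, type = c("auto", "gi50", "label")) {
  type <- match.arg(type)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("response table needs two columns: ", path)
  sample <- trimws(raw[[1L]])
  if (anyDuplicated(sample))
    stop("duplicate sample identifiers in response table: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  value <- trimws(raw[[2L]])
  if (type == "auto") {
    type <- if (grepl("label|response|outcome", tolower(colnames(raw)[2L])))
      "label" else "gi50"
  }
  if (type == "gi50") {
    gi50 <- suppressWarnings(as.numeric(value))
    if (anyNA(gi50))
      stop("non-numeric GI50 for sample(s): ",
           paste(sample[is.na(gi50)], collapse = ", "))
    data.frame(sample = sample, gi50 = gi50, stringsAsFactors = FALSE)
  } else {
    lab <- tolower(value)
    ok <- lab %in% c("sensitive", "resistant")
    if (!all(ok))
      stop("labels must be sensitive/resistant; offending sample(s): ",
           paste(sample[!ok], collapse = ", "))
    data.frame(sample = sample,
               label = factor(lab, levels = c("sensitive", "resistant")),
               stringsAsFactors = FALSE)
  }
}

#' Read a curated gene list
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' ignored. Symbols are uppercased.
#'
#' @param path Path to the list.
#' @return Character vector of unique symbols in file order.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(toupper(lines))
}

#' Read a pathway interaction network in SIF format
#'
#' Parses the 3-column PathwayCommons dialect (participant A, interaction
#' type, participant B) into an undirected gene-symbol graph. Symbols are
#' uppercased; self-loops are dropped; duplicate edges are merged, keeping
#' the union of their interaction-type tags.
#'
#' @param path Path to the SIF file.
#' @param types Optional include-list of interaction types; other lines are
#'   skipped. Default keeps all types.
#' @return An `interaction_network` object (an igraph graph with an
#'   `itype` edge attribute).
#' @export
read_sif <- function(path, types = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop("SIF line ", which(nf != 3L)[1L], " has ", nf[nf != 3L][1L],
         " column(s), expected 3")
  a <- toupper(trimws(vapply(parts, `[[`, "", 1L)))
  itype <- trimws(vapply(parts, `[[`, "", 2L))
  b <- toupper(trimws(vapply(parts, `[[`, "", 3L)))
  if (!is.null(types)) {
    keep <- itype %in% types
    a <- a[keep]; b <- b[keep]; itype <- itype[keep]
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]; itype <- itype[keep]
  # canonical unordered key so A-B and B-A merge
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  tags <- vapply(split(itype, key), function(t)
    paste(sort(unique(t)), collapse = ";"), "")
  ek <- unique(key)
  em <- do.call(rbind, strsplit(ek, "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1L], to = em[, 2L], itype = unname(tags[ek]),
               stringsAsFactors = FALSE),
    directed = FALSE)
  class(g) <- c("interaction_network", class(g))
  g
}

#' Build an interaction network from an edge data frame
#'
#' @param edges Data frame with columns `from`, `to` and optionally `itype`.
#' @return An `interaction_network` object.
#' @export
interaction_network <- function(edges) {
  edges$from <- toupper(edges$from)
  edges$to <- toupper(edges$to)
  if (is.null(edges$itype)) edges$itype <- "interacts-with"
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  lo <- pmin(edges$from, edges$to); hi <- pmax(edges$from, edges$to)
  edges <- edges[!duplicated(paste(lo, hi, sep = "\r")), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  class(g) <- c("interaction_network", class(g))
  g
}

#' Test whether an undirected edge exists between two symbols
#'
#' @param network An `interaction_network`.
#' @param a,b Gene symbols (case-insensitive).
#' @return Logical scalar; `FALSE` if either node is absent.
#' @export
has_edge <- function(network, a, b) {
  a <- toupper(a); b <- toupper(b)
  verts <- igraph::V(network)$name
  if (!(a %in% verts) || !(b %in% verts)) return(FALSE)
  igraph::are_adjacent(network, a, b)
}

#' Neighbours of a gene symbol in the network
#'
#' @param network An `interaction_network`.
#' @param gene Gene symbol (case-insensitive).
#' @return Character vector of neighbouring symbols (empty if absent).
#' @export
network_neighbors <- function(network, gene) {
  gene <- toupper(gene)
  if (!(gene %in% igraph::V(network)$name)) return(character())
  sort(igraph::neighbors(network, gene)$name)
}

#' Read a gene alias table
#'
#' Two-column tab-delimited file mapping a (possibly deprecated) alias to
#' its approved symbol. Both columns are uppercased. Approved symbols are
#' added as identity entries so the map is total on its own range. An alias
#' mapped to two different approved symbols is a fatal conflict: silently
#' picking one is exactly how spurious pathway associations arise.
#'
#' @param path Path to the table.
#' @return An `alias_map`: named character vector, `names` = alias,
#'   value = approved symbol.
#' @export
read_alias_map <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("alias table needs two columns: ", path)
  alias <- toupper(trimws(raw[[1L]]))
  approved <- toupper(trimws(raw[[2L]]))
  alias_map(alias, approved)
}

#' Construct an alias map from vectors
#'
#' @param alias Character vector of aliases.
#' @param approved Parallel vector of approved symbols.
#' @return An `alias_map` object.
#' @export
alias_map <- function(alias, approved) {
  alias <- toupper(alias); approved <- toupper(approved)
  dup <- split(approved, alias)
  conf <- names(dup)[vapply(dup, function(v) length(unique(v)) > 1L, TRUE)]
  if (length(conf))
    stop("alias '", conf[1L], "' maps to multiple approved symbols: ",
         paste(unique(dup[[conf[1L]]]), collapse = ", "))
  map <- vapply(dup, `[[`, "", 1L)
  ident <- setdiff(unique(unname(map)), names(map))
  map <- c(map, stats::setNames(ident, ident))
  structure(map, class = "alias_map")
}

#' Resolve symbols through an alias map
#'
#' Unknown symbols are returned unchanged and flagged.
#'
#' @param map An `alias_map`.
#' @param symbols Character vector of symbols to resolve.
#' @return Data frame with columns `input`, `resolved`, `known` (logical:
#'   was the symbol present in the map).
#' @export
resolve_alias <- function(map, symbols) {
  symbols <- toupper(symbols)
  known <- symbols %in% names(map)
  resolved <- symbols
  resolved[known] <- unname(unclass(map)[symbols[known]])
  data.frame(input = symbols, resolved = resolved, known = known,
             stringsAsFactors = FALSE)
}

# ---- signature model serialization (versioned plain text) ----

SIGNATURE_FORMAT <- "pesig_signature_v1"

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write a trained signature model to a versioned plain-text file
#'
#' The file stores the ordered feature list, the (C, sigma) pair, the
#' trained decision-function state (support vectors, coefficients, offset,
#' feature centring/scaling), the training criterion and provenance
#' (condition, seed), with full double precision, so a read-back model
#' reproduces predictions exactly.
#'
#' @param model A `signature_model` from [forward_select()].
#' @param path Output path.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  dp <- model$decision_params
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(SIGNATURE_FORMAT)
  w("features\t", paste(model$features, collapse = ","))
  w("C\t", fmt_num(model$C))
  w("sigma\t", fmt_num(model$sigma))
  w("criterion\t", model$criterion)
  w("criterion_value\t", fmt_num(model$criterion_value))
  w("condition\t", as.character(model$condition))
  w("seed\t", as.character(model$seed))
  w("center\t", paste(fmt_num(dp$center), collapse = ","))
  w("scale\t", paste(fmt_num(dp$scale), collapse = ","))
  w("gamma\t", fmt_num(dp$gamma))
  w("rho\t", fmt_num(dp$rho))
  w("coefs\t", paste(fmt_num(dp$coefs), collapse = ","))
  w("sv\t", nrow(dp$sv), "\t", ncol(dp$sv))
  for (i in seq_len(nrow(dp$sv)))
    w(paste(fmt_num(dp$sv[i, ]), collapse = ","))
  w("end")
  invisible(path)
}

#' Read a signature model written by [write_signature()]
#'
#' @param path Path to a signature file.
#' @return A `signature_model`.
#' @export
read_signature <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || lines[1L] != SIGNATURE_FORMAT) {
    if (length(lines) >= 1L && grepl("^pesig_signature_", lines[1L]))
      stop("unsupported signature file version: ", lines[1L])
    stop("not a pesig signature file: ", path)
  }
  if (lines[length(lines)] != "end")
    stop("truncated signature file (missing end marker): ", path)
  body <- lines[-c(1L, length(lines))]
  kv <- strsplit(body, "\t", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("signature file missing field '", k, "': ", path)
    kv[[i]]
  }
  nums <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])
  svhdr <- get("sv")
  nr <- as.integer(svhdr[2L]); nc <- as.integer(svhdr[3L])
  svstart <- match("sv", keys) + 1L
  if (length(body) < svstart + nr - 1L)
    stop("truncated signature file (support-vector block short): ", path)
  sv <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) sv[i, ] <- nums(body[svstart + i - 1L])
  features <- strsplit(get("features")[2L], ",", fixed = TRUE)[[1L]]
  colnames(sv) <- features
  dp <- list(center = stats::setNames(nums(get("center")[2L]), features),
             scale = stats::setNames(nums(get("scale")[2L]), features),
             gamma = as.numeric(get("gamma")[2L]),
             rho = as.numeric(get("rho")[2L]),
             coefs = nums(get("coefs")[2L]),
             sv = sv)
  new_signature_model(
    features = features,
    C = as.numeric(get("C")[2L]),
    sigma = as.numeric(get("sigma")[2L]),
    decision_params = dp,
    criterion = get("criterion")[2L],
    criterion_value = as.numeric(get("criterion_value")[2L]),
    condition = get("condition")[2L],
    seed = as.integer(get("seed")[2L]))
}
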