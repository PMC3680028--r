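#' Read an undirected PPI network from a tab/whitespace-separated edge list
#'
#' Each non-comment line names one interaction: two protein IDs and an
#' optional numeric weight (`idA<TAB>idB[<TAB>weight]`; any whitespace
#' separates columns). Protein IDs are opaque, case-sensitive strings.
#' Duplicate lines — including reversed duplicates — collapse to a single
#' edge (the last weight seen wins) and self-loops are dropped; both events
#' are reported via `message()`.
#'
#' @param path path to a text file, or a connection.
#' @param comment lines whose first non-blank character starts with this
#'   prefix are skipped (default `"#"`).
#' @return an undirected simple [igraph::graph] with vertex names; edges
#'   carry a `weight` attribute when the file has a third column.
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path, comment = "#") {
  lines <- trimws(readLines(path))
  keep <- nzchar(lines) & !startsWith(lines, comment)
  lineno <- which(keep)
  toks <- strsplit(lines[keep], "[ \t]+")
  ntok <- lengths(toks)
  if (any(ntok < 2L)) {
    stop("malformed edge list: line ", lineno[which(ntok < 2L)[1L]],
         " has a single token", call. = FALSE)
  }
  from <- vapply(toks, `[`, character(1L), 1L)
  to <- vapply(toks, `[`, character(1L), 2L)
  df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (any(ntok >= 3L)) {
    wtok <- vapply(toks, function(t) if (length(t) >= 3L) t[3L] else NA_character_,
                   character(1L))
    w <- suppressWarnings(as.numeric(wtok))
    bad <- which(!is.na(wtok) & is.na(w))
    if (length(bad)) {
      stop("weight is not numeric on line ", lineno[bad[1L]], call. = FALSE)
    }
    if (any(!is.na(w) & (!is.finite(w) | w < 0))) {
      stop("edge weights must be finite and non-negative", call. = FALSE)
    }
    df$weight <- w
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  n_loop <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(weight = function(x) x[length(x)]))
  if (n_loop) message(n_loop, " self-loop(s) dropped")
  if (n_multi) message(n_multi, " duplicate edge(s) collapsed (last weight kept)")
  g
}

#' Write a network as a sorted tab-separated edge list
#'
#' One edge per line with endpoints in lexicographic order, rows sorted, and
#' the `weight` edge attribute (if any) as a third column with six decimals.
#' Reading the file back with [read_edge_list()] reproduces the node and edge
#' sets (isolated vertices cannot be represented in an edge list).
#'
#' @param network an undirected igraph with vertex names.
#' @param path output file path or connection.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  el <- canonical_edges(network)
  if (nrow(el)) {
    ord <- order(el[, 1L], el[, 2L], method = "radix")
    el <- el[ord, , drop = FALSE]
    if ("weight" %in% igraph::edge_attr_names(network)) {
      w <- igraph::E(network)$weight[ord]
      out <- sprintf("%s\t%s\t%.6f", el[, 1L], el[, 2L], w)
    } else {
      out <- sprintf("%s\t%s", el[, 1L], el[, 2L])
    }
  } else {
    out <- character(0L)
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a complex catalog
#'
#' A `complex_set` is an ordered list of protein-ID sets, optionally named.
#' Within-complex membership is a set: duplicate IDs are collapsed.
#'
#' @param complexes a list of character vectors (each non-empty).
#' @param labels optional character vector of per-complex names.
#' @return an object of class `complex_set` (a list of character vectors).
#' @export
complex_set <- function(complexes, labels = NULL) {
  complexes <- lapply(complexes, function(x) unique(as.character(x)))
  if (any(lengths(complexes) == 0L)) {
    stop("every complex must contain at least one protein", call. = FALSE)
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(complexes))
    names(complexes) <- labels
  }
  structure(complexes, class = "complex_set")
}

#' Coerce to a complex catalog
#' @param x a `complex_set` or a plain list of character vectors.
#' @return a `complex_set`.
#' @export
as_complex_set <- function(x) {
  if (inherits(x, "complex_set")) x else complex_set(x)
}

#' @export
print.complex_set <- function(x, ...) {
  cat("complex_set with", length(x), "complex(es); sizes:",
      if (length(x)) paste(range(lengths(x)), collapse = "-") else "none", "\n")
  invisible(x)
}

#' Drop exact-duplicate complexes
#'
#' Keeps the first occurrence (in catalog order) of every distinct protein
#' set.
#'
#' @param x a `complex_set`.
#' @return a deduplicated `complex_set`.
#' @export
dedup_complexes <- function(x) {
  x <- as_complex_set(x)
  keys <- vapply(x, function(s) paste(sort_ids(s), collapse = "\r"), character(1L))
  keep <- !duplicated(keys)
  complex_set(unclass(x)[keep], labels = names(x)[keep])
}

#' Read a complex catalog (one complex per line)
#'
#' Lines hold whitespace-separated protein IDs; blank lines and `#` comments
#' are skipped. Duplicate IDs within a line are collapsed with a warning.
#'
#' @param path path to a text file or a connection.
#' @param labeled if `TRUE`, the first column of each line is the complex
#'   name rather than a member.
#' @return a `complex_set`.
#' @export
read_complexes <- function(path, labeled = FALSE) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(complex_set(list()))
  toks <- strsplit(lines, "[ \t]+")
  labels <- NULL
  if (labeled) {
    labels <- vapply(toks, `[`, character(1L), 1L)
    toks <- lapply(toks, `[`, -1L)
    if (any(lengths(toks) == 0L)) {
      stop("labeled catalog line has a name but no members", call. = FALSE)
    }
  }
  n_dup <- sum(lengths(toks) - vapply(toks, function(t) length(unique(t)), integer(1L)))
  if (n_dup) warning(n_dup, " duplicate protein ID(s) within complexes collapsed")
  complex_set(toks, labels = labels)
}

#' Write a complex catalog
#'
#' Complexes are written one per line (members sorted lexicographically),
#' ordered by decreasing size then lexicographic membership, so two runs
#' producing the same catalog write byte-identical files.
#'
#' @param x a `complex_set` (or coercible).
#' @param path output file path or connection.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(x, path) {
  x <- as_complex_set(x)
  rows <- vapply(x, function(s) paste(sort_ids(s), collapse = "\t"), character(1L))
  ord <- order(-lengths(x), rows, method = "radix")
  writeLines(rows[ord], path)
  invisible(path)
}

#' Neighborhood graph of a seed protein
#'
#' The subgraph induced on the seed's neighbors; the seed itself is excluded.
#'
#' @param network an undirected igraph with vertex names.
#' @param seed a protein ID present in the network.
#' @return an object of class `neighborhood_graph`: a list with `seed`,
#'   `members` (neighbor IDs) and `graph` (the induced igraph).
#' @export
neighborhood_subgraph <- function(network, seed) {
  seed <- as.character(seed)
  if (!seed %in% igraph::V(network)$name) {
    stop("unknown seed protein: ", seed, call. = FALSE)
  }
  members <- names(igraph::neighbors(network, seed))
  structure(
    list(seed = seed, members = members,
         graph = igraph::induced_subgraph(network, members)),
    class = "neighborhood_graph")
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  cat("neighborhood of", x$seed, "-", length(x$members), "member(s),",
      igraph::ecount(x$graph), "member edge(s)\n")
  invisible(x)
}

#' Summary statistics of a PPI network
#'
#' @param network an undirected igraph.
#' @return a one-row data frame: node count, edge count, density
#'   \eqn{2|E| / (N(N-1))}, average of per-node local clustering
#'   coefficients (nodes of degree < 2 contribute 0), mean degree, and the
#'   number of isolated (degree-0) proteins.
#' @export
network_stats <- function(network) {
  n <- igraph::vcount(network)
  m <- igraph::ecount(network)
  deg <- igraph::degree(network)
  cc <- if (n == 0L) 0 else igraph::transitivity(network, type = "localaverage",
                                                 isolates = "zero")
  if (is.nan(cc)) cc <- 0
  data.frame(
    n_nodes = n,
    n_edges = m,
    density = if (n < 2L) 0 else 2 * m / (n * (n - 1)),
    clustering = cc,
    mean_degree = if (n == 0L) 0 else mean(deg),
    n_isolated = sum(deg == 0L))
}
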