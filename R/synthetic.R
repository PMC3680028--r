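#' Five-protein toy network for the reliability stage
#'
#' Nodes `1..5` with edges (1,2), (1,3), (2,3), (2,4), (1,4), (3,5): the
#' edge (1,2) sits in two triangles, (3,5) in none, making the network the
#' minimal worked example of common-neighbor support. After one PE
#' iteration from the uniform 0.5 prior, (1,2) scores 7/16, the four
#' triangle edges 1/4, and (3,5) scores 0 and is removed by the filter.
#'
#' @return an undirected igraph with 5 vertices and 6 edges.
#' @export
toy_reliability_network <- function() {
  igraph::graph_from_edgelist(
    base::matrix(c("1", "2",
                   "1", "3",
                   "2", "3",
                   "2", "4",
                   "1", "4",
                   "3", "5"), ncol = 2L, byrow = TRUE),
    directed = FALSE)
}

#' Six-protein toy network for the detection stage
#'
#' Nodes `1..6` with 12 edges. Protein 1's neighborhood graph has 5 members
#' with 7 member edges; member 5 has the unique minimum member-degree 2,
#' after its removal members 3 and 4 tie at degree 2, and the surviving
#' 3-member sets score c = 1/3. With rejoin threshold t = 0.5 the detected
#' complex around seed 1 is \{1, 2, 3, 4, 6\}.
#'
#' @return an undirected igraph with 6 vertices and 12 edges.
#' @export
toy_detection_network <- function() {
  igraph::graph_from_edgelist(
    base::matrix(c("1", "2",
                   "1", "3",
                   "1", "4",
                   "1", "5",
                   "1", "6",
                   "2", "3",
                   "2", "4",
                   "2", "6",
                   "3", "6",
                   "4", "6",
                   "3", "5",
                   "4", "5"), ncol = 2L, byrow = TRUE),
    directed = FALSE)
}

absent_pairs <- function(network) {
  vn <- sort_ids(igraph::V(network)$name)
  if (length(vn) < 2L) {
    return(base::matrix(character(0L), ncol = 2L))
  }
  pairs <- t(combn(vn, 2L))
  have <- edge_key(pairs[, 1L], pairs[, 2L]) %in%
    edge_key(canonical_edges(network)[, 1L], canonical_edges(network)[, 2L])
  pairs[!have, , drop = FALSE]
}

#' Add uniformly random spurious interactions
#'
#' Samples `count` currently-absent, non-self pairs among the existing
#' proteins and adds them as edges: the standard noise-injection experiment
#' for testing robustness of complex detection. Reproducible from
#' `rng_seed`.
#'
#' @param network an undirected igraph with vertex names.
#' @param count number of edges to add.
#' @param rng_seed integer seed.
#' @return the network with `count` extra edges.
#' @export
add_random_edges <- function(network, count, rng_seed) {
  stopifnot(count >= 0, count == round(count))
  if (count == 0) return(network)
  pool <- absent_pairs(network)
  if (count > nrow(pool)) {
    stop("count exceeds the number of absent node pairs (", nrow(pool), ")",
         call. = FALSE)
  }
  pick <- withr::with_seed(rng_seed, sample.int(nrow(pool), count))
  igraph::add_edges(network, as.vector(t(pool[pick, , drop = FALSE])))
}

#' Remove uniformly random interactions
#'
#' @param network an undirected igraph.
#' @param count number of edges to remove (at most the edge count).
#' @param rng_seed integer seed.
#' @return the network with `count` fewer edges; vertices are kept.
#' @export
remove_random_edges <- function(network, count, rng_seed) {
  stopifnot(count >= 0, count == round(count))
  m <- igraph::ecount(network)
  if (count > m) {
    stop("count exceeds the number of edges (", m, ")", call. = FALSE)
  }
  if (count == 0) return(network)
  pick <- withr::with_seed(rng_seed, sample.int(m, count))
  igraph::delete_edges(network, pick)
}

#' Generate a planted-complex benchmark network
#'
#' Plants `n_complexes` disjoint vertex groups with dense within-group
#' wiring (each pair present with probability `p_in`), embeds them among
#' `n_background` extra proteins, wires every remaining pair (background
#' and cross-group) with probability `p_out`, and finally injects
#' `noise_edges` uniformly random spurious edges. The planted groups are
#' the ground-truth catalog. Everything is a pure function of the
#' parameters and `rng_seed`.
#'
#' @param n_complexes number of planted complexes (default 10).
#' @param size_range integer range of complex sizes, minimum 4 (default
#'   `c(5, 8)`).
#' @param p_in within-complex edge probability (default 0.9).
#' @param n_background number of background proteins (default 40).
#' @param p_out background/cross-complex edge probability (default 0.01).
#' @param noise_edges extra uniformly random edges (default 0).
#' @param rng_seed integer seed.
#' @return an object of class `planted_benchmark`: list with `network`
#'   (igraph), `truth` (`complex_set`) and `params`.
#' @export
planted_complex_network <- function(n_complexes = 10, size_range = c(5, 8),
                                    p_in = 0.9, n_background = 40,
                                    p_out = 0.01, noise_edges = 0,
                                    rng_seed = 1) {
  stopifnot(n_complexes >= 1, length(size_range) == 2L,
            size_range[1L] >= 4, size_range[2L] >= size_range[1L],
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            n_background >= 0, noise_edges >= 0)
  res <- withr::with_seed(rng_seed, {
    sizes <- sample(seq(size_range[1L], size_range[2L]), n_complexes,
                    replace = TRUE)
    groups <- lapply(seq_len(n_complexes), function(i) {
      sprintf("C%02d_%02d", i, seq_len(sizes[i]))
    })
    bg <- if (n_background) sprintf("B%03d", seq_len(n_background)) else character(0L)
    nodes <- c(unlist(groups), bg)
    within_all <- do.call(rbind, lapply(groups, function(g) t(combn(g, 2L))))
    within <- within_all[runif(nrow(within_all)) < p_in, , drop = FALSE]
    all_pairs <- t(combn(nodes, 2L))
    in_key <- edge_key(within_all[, 1L], within_all[, 2L])
    outside <- all_pairs[!edge_key(all_pairs[, 1L], all_pairs[, 2L]) %in% in_key, ,
                         drop = FALSE]
    outside <- outside[runif(nrow(outside)) < p_out, , drop = FALSE]
    edges <- rbind(within, outside)
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1L], to = edges[, 2L], stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
    list(network = g, groups = groups, noise_seed = sample.int(2^30, 1L))
  })
  g <- res$network
  if (noise_edges > 0) g <- add_random_edges(g, noise_edges, res$noise_seed)
  structure(
    list(network = g,
         truth = complex_set(res$groups),
         params = list(n_complexes = n_complexes, size_range = size_range,
                       p_in = p_in, n_background = n_background,
                       p_out = p_out, noise_edges = noise_edges,
                       rng_seed = rng_seed)),
    class = "planted_benchmark")
}

#' @export
print.planted_benchmark <- function(x, ...) {
  cat("planted_benchmark:", length(x$truth), "complex(es),",
      igraph::vcount(x$network), "proteins,",
      igraph::ecount(x$network), "interactions (seed",
      x$params$rng_seed, ")\n")
  invisible(x)
}
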