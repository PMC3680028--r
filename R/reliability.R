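new_reliability_matrix <- function(edges, p, k, method) {
  structure(list(edges = edges, p = as.numeric(p), k = as.integer(k),
                 method = method),
            class = "reliability_matrix")
}

#' @export
print.reliability_matrix <- function(x, ...) {
  cat("reliability_matrix (", x$method, "), ", nrow(x$edges),
      " edge(s), iteration k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Look up edge reliabilities
#'
#' Returns the stored reliability for each `(u, v)` pair; pairs that are not
#' edges of the scored network have probability 0 by convention.
#'
#' @param matrix a `reliability_matrix` from [pe_score()], [pe_initialize()]
#'   or [adjstcd_score()].
#' @param u,v protein ID vectors (recycled to common length).
#' @return numeric vector of reliabilities in `[0, 1]`.
#' @export
reliability <- function(matrix, u, v) {
  stopifnot(inherits(matrix, "reliability_matrix"))
  keys <- edge_key(matrix$edges[, 1L], matrix$edges[, 2L])
  i <- match(edge_key(as.character(u), as.character(v)), keys)
  out <- matrix$p[i]
  out[is.na(i)] <- 0
  out
}

# dense symmetric probability matrix over the network's vertex order;
# dense is deliberate: the update indexes rows edge-by-edge
prob_matrix <- function(matrix, network) {
  vn <- igraph::V(network)$name
  n <- length(vn)
  i <- match(matrix$edges[, 1L], vn)
  j <- match(matrix$edges[, 2L], vn)
  if (anyNA(i) || anyNA(j)) {
    stop("reliability matrix refers to proteins absent from the network",
         call. = FALSE)
  }
  P <- base::matrix(0, n, n)
  P[cbind(i, j)] <- matrix$p
  P[cbind(j, i)] <- matrix$p
  list(P = P, i = i, j = j)
}

check_coverage <- function(matrix, network) {
  if (nrow(matrix$edges) != igraph::ecount(network)) {
    stop("reliability matrix does not cover the network's edge set",
         call. = FALSE)
  }
}

#' Initialize the PE reliability matrix
#'
#' Every interaction starts at probability 0.5 (the prior that an observed
#' edge is genuine); non-edges carry probability 0 wherever referenced.
#'
#' @param network an undirected igraph with vertex names.
#' @return a `reliability_matrix` at iteration `k = 0`.
#' @export
pe_initialize <- function(network) {
  el <- canonical_edges(network)
  new_reliability_matrix(el, rep(0.5, nrow(el)), 0L, "pe")
}

#' One synchronous PE update
#'
#' For each edge `(i, j)` the new reliability is
#' \deqn{p_{ij} = 1 - \prod_l (1 - p_{il} \, p_{jl})}
#' over the common neighbors `l` of `i` and `j`, every right-hand value
#' taken from the previous iteration (Jacobi-style update). An edge with no
#' common neighbor gets the empty product 1, hence reliability 0: only
#' triangles "support" an interaction.
#'
#' @param matrix the current `reliability_matrix`.
#' @param network the network the matrix was computed on.
#' @return a `reliability_matrix` with the iteration counter advanced.
#' @export
pe_iterate <- function(matrix, network) {
  stopifnot(inherits(matrix, "reliability_matrix"))
  check_coverage(matrix, network)
  pm <- prob_matrix(matrix, network)
  adj <- lapply(igraph::as_adj_list(network), as.integer)
  p_new <- numeric(nrow(matrix$edges))
  for (e in seq_along(p_new)) {
    common <- intersect(adj[[pm$i[e]]], adj[[pm$j[e]]])
    if (length(common)) {
      p_new[e] <- 1 - prod(1 - pm$P[pm$i[e], common] * pm$P[pm$j[e], common])
    }
  }
  new_reliability_matrix(matrix$edges, p_new, matrix$k + 1L, matrix$method)
}

#' PE-measure of interaction reliability
#'
#' Initializes every edge at 0.5 and applies `k` synchronous updates of
#' [pe_iterate()]. `k = 2` is the working default: further iterations bring
#' no practical change in filtering behavior.
#'
#' @param network an undirected igraph with vertex names.
#' @param k number of iterations (integer >= 1, default 2).
#' @return a `reliability_matrix` with method `"pe"`.
#' @seealso [filter_unreliable()], [adjstcd_score()]
#' @export
pe_score <- function(network, k = 2) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be an integer >= 1", call. = FALSE)
  }
  m <- pe_initialize(network)
  for (s in seq_len(k)) m <- pe_iterate(m, network)
  m
}

#' Per-protein average edge reliability
#'
#' @param matrix a `reliability_matrix` covering the network's edges.
#' @param network the scored network.
#' @return named numeric vector: for each protein of degree >= 1, the
#'   arithmetic mean reliability of its incident edges. Isolated proteins
#'   have no entry.
#' @export
node_average <- function(matrix, network) {
  stopifnot(inherits(matrix, "reliability_matrix"))
  check_coverage(matrix, network)
  el <- matrix$edges
  if (!nrow(el)) return(stats::setNames(numeric(0L), character(0L)))
  ends <- c(el[, 1L], el[, 2L])
  pp <- rep(matrix$p, 2L)
  s <- tapply(pp, ends, sum)
  cnt <- tapply(pp, ends, length)
  avg <- as.numeric(s / cnt)
  names(avg) <- names(s)
  avg
}

#' Remove unreliable interactions
#'
#' Scanning every protein, an edge `(i, l)` is unreliable when its
#' reliability is strictly below the average reliability of either
#' endpoint's incident edges. Averages are computed once on the unfiltered
#' network and all removals applied at once; ties (reliability equal to the
#' average) survive. Proteins are never removed and may become isolated.
#'
#' @param network the scored network.
#' @param matrix a `reliability_matrix` covering its edges.
#' @return an igraph over the same vertex set whose surviving edges carry
#'   their reliability in the `weight` attribute.
#' @export
filter_unreliable <- function(network, matrix) {
  stopifnot(inherits(matrix, "reliability_matrix"))
  check_coverage(matrix, network)
  el <- matrix$edges
  vdf <- data.frame(name = igraph::V(network)$name, stringsAsFactors = FALSE)
  if (!nrow(el)) return(network)
  avg <- node_average(matrix, network)
  drop <- matrix$p < avg[el[, 1L]] | matrix$p < avg[el[, 2L]]
  keep <- which(!drop)
  igraph::graph_from_data_frame(
    data.frame(from = el[keep, 1L], to = el[keep, 2L],
               weight = matrix$p[keep], stringsAsFactors = FALSE),
    directed = FALSE, vertices = vdf)
}

#' CD-distance between two proteins
#'
#' \eqn{CD(u, v) = 1 - 2 |N_u \cap N_v| / (|N_u| + |N_v|)}, where the
#' neighbor sets exclude the protein itself. Small for protein pairs whose
#' neighborhoods largely coincide.
#'
#' @param network an undirected igraph with vertex names.
#' @param u,v protein IDs.
#' @return the distance in `[0, 1]`.
#' @export
cd_distance <- function(network, u, v) {
  nu <- names(igraph::neighbors(network, as.character(u)))
  nv <- names(igraph::neighbors(network, as.character(v)))
  if (length(nu) + length(nv) == 0L) {
    stop("CD-distance undefined: both proteins are isolated", call. = FALSE)
  }
  1 - 2 * length(intersect(nu, nv)) / (length(nu) + length(nv))
}

#' Degree-adjusted common-neighbor similarity (AdjstCD)
#'
#' \eqn{2 |N_u \cap N_v| / (\max(|N_u|, N_{avg}) + \max(|N_v|, N_{avg}))}
#' with \eqn{N_{avg}} the mean degree over all proteins of the network
#' (isolated ones included). The `max` floor keeps sparsely-connected
#' proteins from looking spuriously similar.
#'
#' @inheritParams cd_distance
#' @return similarity in `[0, 1]`; 0 on an edgeless network.
#' @export
adjstcd <- function(network, u, v) {
  nu <- names(igraph::neighbors(network, as.character(u)))
  nv <- names(igraph::neighbors(network, as.character(v)))
  n_avg <- mean(igraph::degree(network))
  den <- max(length(nu), n_avg) + max(length(nv), n_avg)
  if (den == 0) return(0)
  2 * length(intersect(nu, nv)) / den
}

#' Iterated AdjstCD edge reliability
#'
#' Starting from the adjacency indicator `w^0`, each step replaces the
#' weight of edge `(u, v)` by
#' \deqn{w^k(u,v) = \frac{\sum_{x \in N_u \cap N_v} (w^{k-1}(x,u) + w^{k-1}(x,v))}
#'   {\max(\sum_{x \in N_u} w^{k-1}(x,u), \bar w^{k-1}) +
#'    \max(\sum_{x \in N_v} w^{k-1}(x,v), \bar w^{k-1})}}
#' with \eqn{\bar w^{k-1}} the total weight incident to a protein averaged
#' over all N proteins. The first step reproduces [adjstcd()] exactly.
#' Updates are synchronous.
#'
#' @param network an undirected igraph with vertex names.
#' @param k number of iterations (integer >= 1, default 2).
#' @return a `reliability_matrix` with method `"adjstcd"`.
#' @export
adjstcd_score <- function(network, k = 2) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be an integer >= 1", call. = FALSE)
  }
  el <- canonical_edges(network)
  m <- new_reliability_matrix(el, rep(1, nrow(el)), 0L, "adjstcd")
  if (!nrow(el)) { m$k <- as.integer(k); return(m) }
  vn <- igraph::V(network)$name
  n <- length(vn)
  i <- match(el[, 1L], vn)
  j <- match(el[, 2L], vn)
  adj <- lapply(igraph::as_adj_list(network), as.integer)
  W <- base::matrix(0, n, n)
  W[cbind(i, j)] <- 1
  W[cbind(j, i)] <- 1
  for (s in seq_len(k)) {
    inc <- rowSums(W)            # weights are supported on edges only
    w_avg <- sum(W) / n
    w_new <- numeric(nrow(el))
    for (e in seq_along(w_new)) {
      common <- intersect(adj[[i[e]]], adj[[j[e]]])
      if (!length(common)) next
      num <- sum(W[common, i[e]] + W[common, j[e]])
      den <- max(inc[i[e]], w_avg) + max(inc[j[e]], w_avg)
      if (den > 0) w_new[e] <- num / den
    }
    W[] <- 0
    W[cbind(i, j)] <- w_new
    W[cbind(j, i)] <- w_new
  }
  new_reliability_matrix(el, w_new, as.integer(k), "adjstcd")
}
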