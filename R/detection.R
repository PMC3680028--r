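#' Weighted clustering coefficient of a neighborhood graph
#'
#' \deqn{c = \frac{2 \, N_{3cliques}}{N_i^2 (N_i - 1)}}
#' where \eqn{N_i} is the number of neighborhood members (seed excluded) and
#' \eqn{N_{3cliques}} counts the 3-cliques through the seed — equivalently,
#' the edges among the members. The coefficient is bounded above by
#' \eqn{1 / N_i}, so denser *and smaller* member sets score higher, which is
#' what drives the peeling loop toward near-cliques.
#'
#' @param neigh a `neighborhood_graph` from [neighborhood_subgraph()] with
#'   at least 2 members.
#' @return the coefficient, a real in `[0, 1]`.
#' @export
wcc <- function(neigh) {
  stopifnot(inherits(neigh, "neighborhood_graph"))
  n <- length(neigh$members)
  if (n < 2L) {
    stop("weighted clustering coefficient undefined for fewer than 2 members",
         call. = FALSE)
  }
  2 * igraph::ecount(neigh$graph) / (n^2 * (n - 1))
}

#' Peel a neighborhood graph down to three members
#'
#' Records the member set, 3-clique count and weighted clustering
#' coefficient of the initial neighborhood, then repeatedly removes the
#' member with the minimum degree *within the member-induced subgraph*
#' (the seed does not contribute to degrees) together with its incident
#' edges, recording after each removal, until exactly 3 members remain.
#' Minimum-degree ties are broken lexicographically (`"lex"`, the
#' reproducible default) or uniformly at random (`"random"`, drawing from
#' R's RNG stream). The step maximizing the coefficient is marked; on a tie
#' the earliest (largest) subgraph wins.
#'
#' @param neigh a `neighborhood_graph` with at least 3 members.
#' @param tie_break `"lex"` or `"random"`.
#' @return an object of class `peel_trace`: list with `seed`, `members`
#'   (list of ID vectors per step), `n_3cliques`, `c` (numeric vectors) and
#'   `argmax` (index of the best step).
#' @export
peel <- function(neigh, tie_break = c("lex", "random")) {
  stopifnot(inherits(neigh, "neighborhood_graph"))
  tie_break <- match.arg(tie_break)
  g <- neigh$graph
  if (igraph::vcount(g) < 3L) {
    stop("peeling needs a neighborhood of at least 3 members", call. = FALSE)
  }
  members <- list()
  ntri <- integer()
  cval <- numeric()
  step <- 0L
  repeat {
    step <- step + 1L
    n <- igraph::vcount(g)
    m <- igraph::ecount(g)
    members[[step]] <- sort_ids(igraph::V(g)$name)
    ntri[step] <- m
    cval[step] <- 2 * m / (n^2 * (n - 1))
    if (n <= 3L) break
    deg <- igraph::degree(g)
    cand <- names(deg)[deg == min(deg)]
    victim <- if (length(cand) == 1L) {
      cand
    } else if (tie_break == "lex") {
      sort_ids(cand)[1L]
    } else {
      sample(cand, 1L)
    }
    g <- igraph::delete_vertices(g, victim)
  }
  structure(list(seed = neigh$seed, members = members, n_3cliques = ntri,
                 c = cval, argmax = which.max(cval)),
            class = "peel_trace")
}

#' @export
print.peel_trace <- function(x, ...) {
  cat("peel_trace for seed", x$seed, "-", length(x$c), "step(s), best c =",
      format(x$c[x$argmax]), "at", length(x$members[[x$argmax]]), "members\n")
  invisible(x)
}

#' Extract the core complex around a seed protein
#'
#' Runs [peel()] on the seed's neighborhood graph and returns the seed plus
#' the member set of the step with the highest weighted clustering
#' coefficient. Seeds of degree < 3 have no peelable neighborhood and yield
#' `NULL`.
#'
#' @param network an undirected igraph with vertex names.
#' @param seed a protein ID.
#' @param tie_break passed to [peel()].
#' @return `NULL`, or a list with `seed`, `core` (ID set including the
#'   seed), `c_core`, `neigh` (the `neighborhood_graph`) and `trace`.
#' @export
extract_core <- function(network, seed, tie_break = c("lex", "random")) {
  tie_break <- match.arg(tie_break)
  seed <- as.character(seed)
  neigh <- neighborhood_subgraph(network, seed)
  if (length(neigh$members) < 3L) return(NULL)
  trace <- peel(neigh, tie_break)
  best <- trace$argmax
  list(seed = seed,
       core = sort_ids(c(seed, trace$members[[best]])),
       c_core = trace$c[best],
       neigh = neigh,
       trace = trace)
}

#' Rejoin neighborhood proteins to a core complex
#'
#' Every *original* neighborhood member outside the core joins when it
#' interacts with strictly more than a fraction `t` of the core proteins
#' (core size includes the seed). The decision is a single pass against the
#' pre-rejoin core: newly joined proteins do not recruit further.
#'
#' @param network the full network (adjacency is judged here).
#' @param neigh the seed's `neighborhood_graph`.
#' @param core the core ID set from [extract_core()].
#' @param t rejoin threshold in `[0, 1]`; default 0.3.
#' @return the complex member set (core plus rejoined proteins), sorted.
#' @export
rejoin <- function(network, neigh, core, t = 0.3) {
  stopifnot(inherits(neigh, "neighborhood_graph"), t >= 0, t <= 1)
  cand <- setdiff(neigh$members, core)
  if (length(cand)) {
    frac <- vapply(cand, function(p) {
      length(intersect(names(igraph::neighbors(network, p)), core)) / length(core)
    }, numeric(1L))
    cand <- cand[frac > t]
  }
  sort_ids(c(core, cand))
}

#' Detect protein complexes in a PPI network
#'
#' Runs [extract_core()] and [rejoin()] with every protein of degree >= 3
#' as the seed, keeps complexes with at least `min_size` members, and drops
#' exact duplicates (first seed in lexicographic order wins). Run on the
#' reliability-filtered topology for the full two-stage method (see
#' [run_pipeline()]); the clustering coefficient itself uses only edge
#' counts, never weights.
#'
#' @param network an undirected igraph with vertex names.
#' @param t rejoin threshold (default 0.3).
#' @param min_size minimum complex size reported (default 4).
#' @param tie_break `"lex"` (deterministic default) or `"random"`.
#' @param rng_seed optional integer seeding the RNG for `"random"`
#'   tie-breaking, making randomized runs reproducible.
#' @return a `complex_set`; attribute `"meta"` holds a data frame with the
#'   seed, core coefficient and size of each retained complex.
#' @export
detect_complexes <- function(network, t = 0.3, min_size = 4,
                             tie_break = c("lex", "random"), rng_seed = NULL) {
  tie_break <- match.arg(tie_break)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  deg <- igraph::degree(network)
  seeds <- sort_ids(names(deg)[deg >= 3])
  out <- list()
  meta <- list()
  seen <- character(0L)
  for (s in seeds) {
    res <- extract_core(network, s, tie_break)
    if (is.null(res)) next
    members <- rejoin(network, res$neigh, res$core, t)
    if (length(members) < min_size) next
    key <- paste(members, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- members
    meta[[length(meta) + 1L]] <- data.frame(
      seed = s, c_core = res$c_core, size = length(members),
      stringsAsFactors = FALSE)
  }
  cs <- complex_set(out)
  attr(cs, "meta") <- if (length(meta)) do.call(rbind, meta) else
    data.frame(seed = character(0L), c_core = numeric(0L), size = integer(0L))
  cs
}
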