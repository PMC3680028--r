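test_that("PE initialization puts 0.5 on every edge and nothing elsewhere", {
  g <- toy_reliability_network()
  m <- pe_initialize(g)
  expect_equal(nrow(m$edges), 6)
  expect_true(all(m$p == 0.5))
  expect_equal(m$k, 0L)
  expect_equal(reliability(m, "1", "5"), 0)  # non-edge -> 0

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(nrow(pe_initialize(empty)$edges), 0)

  single <- igraph::graph_from_edgelist(cbind("a", "b"), directed = FALSE)
  expect_equal(pe_initialize(single)$p, 0.5)
})

test_that("one PE iteration reproduces the worked five-protein example", {
  g <- toy_reliability_network()
  m <- pe_score(g, k = 1)
  expect_equal(reliability(m, "1", "2"), 7 / 16)
  for (e in list(c("1", "3"), c("2", "3"), c("2", "4"), c("1", "4"))) {
    expect_equal(reliability(m, e[1], e[2]), 1 / 4)
  }
  expect_equal(reliability(m, "3", "5"), 0)
  # a second iteration keeps the structural zero
  expect_equal(reliability(pe_score(g, k = 2), "3", "5"), 0)
})

test_that("PE on a triangle gives 1/4 everywhere after one step", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("x", "y", "z")
  m <- pe_score(tri, k = 1)
  expect_true(all(abs(m$p - 0.25) < 1e-15))
})

test_that("pe_score composes pe_initialize with synchronous pe_iterate", {
  g <- random_network(25, 0.15, 7)
  manual <- pe_iterate(pe_initialize(g), g)
  auto <- pe_score(g, k = 1)
  expect_equal(manual$p, auto$p)
  expect_equal(manual$k, 1L)
  expect_error(pe_score(g, k = 0), "k must be")
})

test_that("PE equals the naive oracle edge by edge on random graphs", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- random_network(sample(10:40, 1), 0.2, seed + 100)
    A <- adjacency_of(g)
    vn <- igraph::V(g)$name
    P <- A * 0.5
    m <- pe_initialize(g)
    for (k in 1:2) {
      P <- naive_pe_step(A, P)
      m <- pe_iterate(m, g)
      i <- match(m$edges[, 1], vn)
      j <- match(m$edges[, 2], vn)
      expect_equal(m$p, P[cbind(i, j)], tolerance = 1e-12)
    }
  }
})

test_that("PE values stay in [0,1], symmetric, and zero off triangles", {
  for (seed in 1:5) {
    g <- random_network(30, 0.12, seed)
    for (k in 1:3) {
      m <- pe_score(g, k)
      expect_true(all(m$p >= 0 & m$p <= 1))
      # symmetry of the lookup
      expect_equal(reliability(m, m$edges[, 1], m$edges[, 2]),
                   reliability(m, m$edges[, 2], m$edges[, 1]))
      # edges in no triangle are 0 at every k >= 1
      tri <- igraph::count_triangles(g)
      vn <- igraph::V(g)$name
      no_common <- vapply(seq_len(nrow(m$edges)), function(e) {
        nu <- names(igraph::neighbors(g, m$edges[e, 1]))
        nv <- names(igraph::neighbors(g, m$edges[e, 2]))
        length(intersect(nu, nv)) == 0
      }, logical(1))
      expect_true(all(m$p[no_common] == 0))
    }
  }
})

test_that("per-protein averages are plain means of incident reliabilities", {
  g <- toy_reliability_network()
  m <- pe_score(g, k = 1)
  avg <- node_average(m, g)
  expect_equal(avg[["3"]], (1 / 4 + 1 / 4 + 0) / 3)
  expect_equal(avg[["1"]], (7 / 16 + 1 / 4 + 1 / 4) / 3)

  # uniform weights: every average equals the weight; isolated nodes absent
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("x", "y", "z")
  m0 <- pe_initialize(tri)
  expect_true(all(node_average(m0, tri) == 0.5))
})

test_that("the filter removes below-average edges from either endpoint", {
  g <- toy_reliability_network()
  m <- pe_score(g, k = 1)
  gf <- filter_unreliable(g, m)
  expect_false(igraph::are_adjacent(gf, "3", "5"))   # the noise edge goes
  expect_equal(igraph::vcount(gf), 5)                # proteins are kept
  expect_true("weight" %in% igraph::edge_attr_names(gf))

  # ties survive: uniform initialization removes nothing
  m0 <- pe_initialize(g)
  expect_equal(igraph::ecount(filter_unreliable(g, m0)), 6)

  # star with one zero-weight edge: only the zero edge goes
  star <- igraph::graph_from_edgelist(
    rbind(c("c", "a"), c("c", "b"), c("c", "d")), directed = FALSE)
  ms <- pewcc:::new_reliability_matrix(pewcc:::canonical_edges(star),
                                       c(0.4, 0.4, 0), 1L, "pe")
  stopifnot(identical(ms$edges[, 2], c("c", "c", "d")))  # row "c d" carries 0
  gf2 <- filter_unreliable(star, ms)
  expect_false(igraph::are_adjacent(gf2, "c", "d"))
  expect_true(igraph::are_adjacent(gf2, "a", "c"))
  expect_true(igraph::are_adjacent(gf2, "b", "c"))
})

test_that("the filter never removes an edge maximal at both endpoints", {
  for (seed in 1:8) {
    g <- random_network(25, 0.2, seed)
    m <- pe_score(g, 2)
    gf <- filter_unreliable(g, m)
    vn <- igraph::V(g)$name
    # per-node incident maximum
    node_max <- sapply(vn, function(v) {
      nb <- names(igraph::neighbors(g, v))
      if (!length(nb)) return(NA_real_)
      max(reliability(m, rep(v, length(nb)), nb))
    })
    for (e in seq_len(nrow(m$edges))) {
      u <- m$edges[e, 1]; v <- m$edges[e, 2]
      if (m$p[e] == node_max[[u]] && m$p[e] == node_max[[v]]) {
        expect_true(igraph::are_adjacent(gf, u, v))
      }
    }
  }
})

test_that("CD-distance follows its closed form", {
  g <- toy_reliability_network()
  # identical neighbor sets -> 0
  twin <- igraph::graph_from_edgelist(
    rbind(c("u", "a"), c("u", "b"), c("v", "a"), c("v", "b")),
    directed = FALSE)
  expect_equal(cd_distance(twin, "u", "v"), 0)
  # disjoint neighborhoods -> 1
  path <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("c", "d")), directed = FALSE)
  expect_equal(cd_distance(path, "a", "c"), 1)
  # |Nu|=3, |Nv|=5, overlap 2 -> 0.5
  gg <- igraph::graph_from_edgelist(rbind(
    c("u", "x1"), c("u", "x2"), c("u", "x3"),
    c("v", "x1"), c("v", "x2"), c("v", "y1"), c("v", "y2"), c("v", "y3")),
    directed = FALSE)
  expect_equal(cd_distance(gg, "u", "v"), 0.5)
  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("p", "q")
  expect_error(cd_distance(iso, "p", "q"), "isolated")
})

test_that("AdjstCD uses the degree floor at the network mean", {
  g <- toy_reliability_network()
  # degrees of 1 and 2 are 3, mean degree 2.4, overlap {3,4}
  expect_equal(adjstcd(g, "1", "2"), 2 * 2 / (3 + 3))
  # disjoint neighborhoods (N_4 = {1,2}, N_5 = {3}) -> 0
  expect_equal(adjstcd(g, "4", "5"), 0)
  # regular graph: every degree equals the mean, so max() is inactive
  ring <- igraph::make_full_graph(4)
  igraph::V(ring)$name <- letters[1:4]
  expect_equal(adjstcd(ring, "a", "b"), 2 * 2 / (3 + 3))
})

test_that("iterated AdjstCD matches adjstcd at k=1 and the oracle at k=2", {
  g <- random_network(20, 0.25, 3)
  m1 <- adjstcd_score(g, k = 1)
  direct <- vapply(seq_len(nrow(m1$edges)), function(e) {
    adjstcd(g, m1$edges[e, 1], m1$edges[e, 2])
  }, numeric(1))
  expect_equal(m1$p, direct, tolerance = 1e-12)

  for (seed in c(11, 12)) {
    g <- random_network(15, 0.3, seed)
    A <- adjacency_of(g)
    vn <- igraph::V(g)$name
    for (k in 1:3) {
      m <- adjstcd_score(g, k = k)
      W <- naive_adjstcd_iterate(A, k)
      i <- match(m$edges[, 1], vn)
      j <- match(m$edges[, 2], vn)
      expect_equal(m$p, W[cbind(i, j)], tolerance = 1e-12)
      expect_true(all(m$p >= 0 & m$p <= 1))
    }
  }
  expect_error(adjstcd_score(g, 0), "k must be")
})
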