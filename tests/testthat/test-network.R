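# Network construction and the six social-network traits, checked against
# hand-worked examples and exhaustive brute-force oracles.

graph_from_edges <- function(roster, ...) {
  e <- list(...)
  edges <- if (length(e) == 0) {
    data.frame(animal_a = character(0), animal_b = character(0),
               weight_s = numeric(0))
  } else {
    do.call(rbind, lapply(e, function(x)
      data.frame(animal_a = x[[1]], animal_b = x[[2]],
                 weight_s = as.numeric(x[[3]]), stringsAsFactors = FALSE)))
  }
  build_pen_graph(roster, edges)
}

test_that("fight aggregation sums unordered dyads within pens", {
  rec <- data.frame(pen_id = c("P1", "P1", "P2"),
                    animal_a = c("A", "B", "X"),
                    animal_b = c("B", "A", "Y"),
                    duration_s = c(10, 5, 7), stringsAsFactors = FALSE)
  agg <- aggregate_fights(rec)
  expect_equal(nrow(agg), 2L)
  expect_equal(agg$weight_s[agg$pen_id == "P1"], 15)
  expect_equal(agg$weight_s[agg$pen_id == "P2"], 7)
  expect_equal(nrow(aggregate_fights(rec[0, ])), 0L)
})

test_that("graphs carry the full roster with isolated non-fighters", {
  g <- graph_from_edges(c("A", "B", "C"), list("A", "B", 15))
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(unname(igraph::degree(g)["C"]), 0)

  g18 <- build_pen_graph(paste0("a", 1:18),
                         data.frame(animal_a = character(0),
                                    animal_b = character(0),
                                    weight_s = numeric(0)))
  expect_equal(igraph::vcount(g18), 18L)
  expect_error(graph_from_edges(c("A", "B"), list("A", "Z", 3)), "roster")
})

test_that("hand-worked trait values on path, triangle and star graphs", {
  # path A-B-C, unit weights
  gp <- graph_from_edges(c("A", "B", "C"), list("A", "B", 1), list("B", "C", 1))
  expect_equal(unname(degree_centrality(gp)[c("A", "B")]), c(0.5, 1.0))
  expect_equal(unname(betweenness_centrality(gp)[["B"]]), 1.0)
  expect_equal(unname(closeness_centrality(gp)[c("B", "A")]), c(1, 2 / 3))

  # triangle: complete graph values
  gt <- graph_from_edges(c("A", "B", "C"), list("A", "B", 2),
                         list("B", "C", 2), list("A", "C", 2))
  expect_equal(unname(degree_centrality(gt)), rep(1, 3))
  expect_equal(unname(betweenness_centrality(gt)), rep(0, 3))
  expect_equal(unname(eigenvector_centrality(gt)), rep(1, 3))
  expect_equal(unname(clustering_coefficient(gt)), rep(1, 3))

  # weighted path: closeness(B) with costs 4 and 1
  gw <- graph_from_edges(c("A", "B", "C"), list("A", "B", 4), list("B", "C", 1))
  expect_equal(unname(closeness_centrality(gw)[["B"]]), 2 / 5)
  expect_equal(unname(weighted_degree(gw)[["B"]]), 5)

  # star with 3 leaves: closed-form eigenvector leaf/center ratio 1/sqrt(3)
  gs <- graph_from_edges(c("O", "A", "B", "C"), list("O", "A", 1),
                         list("O", "B", 1), list("O", "C", 1))
  ev <- eigenvector_centrality(gs)
  expect_equal(unname(ev[["O"]]), 1)
  expect_equal(unname(ev[c("A", "B", "C")]), rep(1 / sqrt(3), 3),
               tolerance = 1e-8)
  expect_equal(unname(clustering_coefficient(gs)[["O"]]), 0)

  # two disjoint dyads: Wasserman-Faust corrected closeness 1/3
  gd <- graph_from_edges(c("A", "B", "C", "D"), list("A", "B", 1),
                         list("C", "D", 1))
  expect_equal(unname(closeness_centrality(gd)[["A"]]), 1 / 3)

  # neighbour set {a,b,c} with one edge among them: clustering 1/3
  gc <- graph_from_edges(c("v", "a", "b", "c"), list("v", "a", 1),
                         list("v", "b", 1), list("v", "c", 1),
                         list("a", "b", 1))
  expect_equal(unname(clustering_coefficient(gc)[["v"]]), 1 / 3)
})

test_that("all six traits match brute-force oracles on random graphs", {
  set.seed(421)
  for (rep in 1:60) {
    n <- sample(3:7, 1)
    edges <- random_edge_df(n, p = runif(1, 0.2, 0.9))
    ids <- paste0("v", seq_len(n))
    g <- build_pen_graph(ids, edges)
    W <- edge_df_to_adj(ids, edges)

    expect_equal(unname(degree_centrality(g)), unname(rowSums(W > 0)) / (n - 1))
    expect_equal(unname(weighted_degree(g)), unname(rowSums(W)))
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(W),
                 tolerance = 1e-9)
    expect_equal(unname(closeness_centrality(g)), oracle_closeness(W),
                 tolerance = 1e-9)
    expect_equal(unname(eigenvector_centrality(g)), oracle_eigenvector(W),
                 tolerance = 1e-7)
    expect_equal(unname(clustering_coefficient(g)), oracle_clustering(W))
  }
})

test_that("trait invariants: range, isolation, monotonicity, equivariance", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    edges <- random_edge_df(n, p = 0.5)
    ids <- paste0("v", seq_len(n))
    g <- build_pen_graph(ids, edges)
    tr <- sna_traits(g)

    expect_true(all(tr$degree >= 0 & tr$degree <= 1))
    expect_true(all(tr$betweenness >= 0 & tr$betweenness <= 1 + 1e-12))
    expect_true(all(tr$eigenvector >= 0 & tr$eigenvector <= 1 + 1e-12))
    expect_true(all(tr$clustering >= 0 & tr$clustering <= 1))
    expect_true(all(tr$weighted_degree >= 0 & tr$closeness >= 0))
    # sqrt transform is elementwise
    for (v in sna_trait_names())
      expect_equal(tr[[paste0("t_", v)]]^2, tr[[v]], tolerance = 1e-12)

    # isolation: remove all edges of the first vertex that has any
    if (nrow(edges) > 0) {
      v <- edges$animal_a[1]
      e2 <- edges[edges$animal_a != v & edges$animal_b != v, , drop = FALSE]
      tr2 <- sna_traits(build_pen_graph(ids, e2))
      row <- tr2[tr2$animal == v, sna_trait_names()]
      expect_equal(unname(unlist(row)), rep(0, 6))
    }

    # permutation equivariance: relabeling permutes rows identically
    perm <- sample(ids)
    map <- setNames(perm, ids)
    e3 <- edges
    e3$animal_a <- unname(map[edges$animal_a])
    e3$animal_b <- unname(map[edges$animal_b])
    tr3 <- sna_traits(build_pen_graph(perm, e3))
    for (v in sna_trait_names()) {
      orig <- setNames(tr[[v]], map[tr$animal])
      expect_equal(orig[tr3$animal], setNames(tr3[[v]], tr3$animal),
                   tolerance = 1e-9)
    }
  }

  # monotonicity of degree/strength in added incident edges
  set.seed(17)
  ids <- paste0("v", 1:6)
  edges <- random_edge_df(6, p = 0.4)
  g1 <- build_pen_graph(ids, edges)
  free <- utils::combn(ids, 2)
  have <- paste(pmin(edges$animal_a, edges$animal_b),
                pmax(edges$animal_a, edges$animal_b))
  open <- which(!paste(free[1, ], free[2, ]) %in% have)
  k <- open[1]
  edges2 <- rbind(edges, data.frame(animal_a = free[1, k],
                                    animal_b = free[2, k], weight_s = 3))
  g2 <- build_pen_graph(ids, edges2)
  expect_true(all(degree_centrality(g2) >= degree_centrality(g1)))
  expect_true(all(weighted_degree(g2) >= weighted_degree(g1)))
})

test_that("compute_sna_traits covers every roster member per pen", {
  st <- small_study(seed = 3)
  tr <- compute_sna_traits(st$fights, st$animals)
  expect_equal(nrow(tr), nrow(st$animals))
  expect_setequal(tr$animal, st$animals$animal)
  # all-isolated pen yields all-zero vectors
  quiet <- setdiff(unique(st$animals$pen_id), unique(st$fights$pen_id))
  if (length(quiet) > 0) {
    rows <- tr[tr$pen_id == quiet[1], sna_trait_names()]
    expect_true(all(rows == 0))
  }
  # degenerate single-animal pen errors
  expect_error(sna_traits(build_pen_graph("A", data.frame(
    animal_a = character(0), animal_b = character(0),
    weight_s = numeric(0)))), "degenerate")
})
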