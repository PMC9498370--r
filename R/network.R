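# Per-pen weighted aggression networks and the six social-network traits.
#
# Edges are weighted by the total duration (seconds) of reciprocal fights
# between a pair of pen mates. For the path-based centralities (betweenness,
# closeness) the weights are interpreted as path costs by default: a longer
# total fight makes the tie "longer", which is the default convention of
# igraph's shortest-path machinery. An inverse-duration alternative is
# available via `weight_mode = "inverse"`.

#' Aggregate raw fight records into per-pen dyad weights
#'
#' Sums durations over all rows that refer to the same unordered pair in the
#' same pen.
#'
#' @param records Fight record data frame (see [read_fight_records()]).
#' @return Data frame `pen_id,animal_a,animal_b,weight_s` with one row per
#'   unordered dyad per pen; the pair is stored in lexicographic order.
#' @export
aggregate_fights <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(pen_id = character(0), animal_a = character(0),
                      animal_b = character(0), weight_s = numeric(0),
                      stringsAsFactors = FALSE))
  lo <- pmin(records$animal_a, records$animal_b)
  hi <- pmax(records$animal_a, records$animal_b)
  key <- paste(records$pen_id, lo, hi, sep = "\r")
  agg <- tapply(records$duration_s, key, sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    pen_id = vapply(parts, `[`, "", 1L),
    animal_a = vapply(parts, `[`, "", 2L),
    animal_b = vapply(parts, `[`, "", 3L),
    weight_s = as.numeric(agg),
    stringsAsFactors = FALSE
  )
  out[order(out$pen_id, out$animal_a, out$animal_b), , drop = FALSE]
}

#' Build a pen's weighted aggression graph
#'
#' The graph contains the full pen roster as vertices, including animals
#' that never fought (isolated nodes), so that every animal receives a trait
#' score. Edge weights are total fight durations in seconds.
#'
#' @param roster Character vector of the pen's animal ids.
#' @param dyads Data frame with columns `animal_a,animal_b,weight_s` for this
#'   pen (e.g. a subset of [aggregate_fights()] output).
#' @return An undirected `igraph` graph with a `weight` edge attribute.
#' @export
build_pen_graph <- function(roster, dyads) {
  if (anyDuplicated(roster)) stop("duplicate animal ids in roster")
  if (nrow(dyads) > 0L) {
    unknown <- setdiff(c(dyads$animal_a, dyads$animal_b), roster)
    if (length(unknown) > 0L)
      stop("dyad member(s) not in roster: ", paste(unknown, collapse = ", "))
    if (any(dyads$animal_a == dyads$animal_b)) stop("self-loop dyad")
    if (any(dyads$weight_s <= 0)) stop("non-positive dyad weight")
    key <- paste(pmin(dyads$animal_a, dyads$animal_b),
                 pmax(dyads$animal_a, dyads$animal_b))
    if (anyDuplicated(key)) stop("duplicate dyad: aggregate first")
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(roster), name = as.character(roster))
  if (nrow(dyads) > 0L) {
    g <- igraph::add_edges(g, rbind(dyads$animal_a, dyads$animal_b),
                           weight = dyads$weight_s)
  }
  g
}

#' Degree centrality (normalized)
#'
#' Number of distinct opponents divided by the maximum possible, n - 1.
#'
#' @param g Weighted aggression graph.
#' @return Named numeric vector in \[0, 1\], one entry per vertex.
#' @export
degree_centrality <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) stop("degenerate pen: need at least 2 animals")
  igraph::degree(g) / (n - 1)
}

#' Weighted degree (strength)
#'
#' Sum of the durations of all fights the animal was involved in, seconds.
#'
#' @param g Weighted aggression graph.
#' @return Named numeric vector, >= 0.
#' @export
weighted_degree <- function(g) {
  igraph::strength(g, weights = igraph::E(g)$weight)
}

#' Betweenness centrality (normalized, weighted)
#'
#' Fraction of all-pairs weighted shortest paths that pass through the
#' vertex, with fractional credit over equally short paths, normalized by
#' `(n-1)(n-2)/2`. Edge weights act as path costs (`weight_mode = "cost"`)
#' or as inverted affinities (`weight_mode = "inverse"`, cost = 1/weight).
#'
#' @param g Weighted aggression graph.
#' @param weight_mode `"cost"` (default) or `"inverse"`.
#' @return Named numeric vector in \[0, 1\].
#' @export
betweenness_centrality <- function(g, weight_mode = c("cost", "inverse")) {
  n <- igraph::vcount(g)
  if (n < 3L) return(stats::setNames(numeric(n), igraph::V(g)$name))
  igraph::betweenness(g, weights = path_costs(g, weight_mode), normalized = TRUE)
}

#' Closeness centrality (Wasserman-Faust corrected)
#'
#' For a vertex reaching `m` other vertices at total weighted distance `S`,
#' the score is `((m/S) * m) / (n - 1)`: the within-component closeness
#' `m/S` scaled by the fraction of the network that is reachable. On a
#' connected graph this reduces to the classic `(n - 1) / S`; isolated
#' vertices score 0.
#'
#' @param g Weighted aggression graph.
#' @param weight_mode `"cost"` (default) or `"inverse"`.
#' @return Named numeric vector, >= 0.
#' @export
closeness_centrality <- function(g, weight_mode = c("cost", "inverse")) {
  n <- igraph::vcount(g)
  if (n < 2L) stop("degenerate pen: need at least 2 animals")
  D <- igraph::distances(g, weights = path_costs(g, weight_mode))
  diag(D) <- Inf
  vapply(seq_len(n), function(v) {
    d <- D[v, ]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0L) return(0)
    (r / sum(d[reach])) * (r / (n - 1))
  }, numeric(1)) |> stats::setNames(igraph::V(g)$name)
}

#' Eigenvector centrality of the weighted adjacency matrix
#'
#' Leading-eigenvector score computed by shifted power iteration on the
#' symmetric weighted adjacency matrix, rescaled so the maximum score is 1.
#' The shift (largest row sum) makes the iteration converge on bipartite-like
#' components where the unshifted spectrum is symmetric. In disconnected
#' graphs the score is carried by the component with the largest leading
#' eigenvalue; other components decay towards 0, and isolated vertices score
#' exactly 0.
#'
#' @param g Weighted aggression graph.
#' @param tol Convergence tolerance on the sup-norm change (default 1e-12,
#'   conservative so that scores are accurate well beyond 1e-9 even when the
#'   spectral gap is small).
#' @param max_iter Iteration cap (default 50000).
#' @return Named numeric vector in \[0, 1\].
#' @export
eigenvector_centrality <- function(g, tol = 1e-12, max_iter = 50000L) {
  n <- igraph::vcount(g)
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g) > 0) "weight" else NULL,
                                             sparse = FALSE))
  nm <- igraph::V(g)$name
  if (all(W == 0)) return(stats::setNames(numeric(n), nm))
  shift <- max(rowSums(W))
  M <- W + diag(shift, n)
  active <- rowSums(W) > 0
  v <- as.numeric(active)
  v <- v / sqrt(sum(v^2))
  for (it in seq_len(max_iter)) {
    v_new <- M %*% v
    v_new <- as.numeric(v_new) / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      v[!active] <- 0
      v <- abs(v)
      return(stats::setNames(v / max(v), nm))
    }
    v <- v_new
  }
  stop("eigenvector centrality: power iteration failed to converge in ",
       max_iter, " steps")
}

#' Local clustering coefficient
#'
#' Proportion of an animal's opponents that also fought each other, out of
#' all possible opponent pairs. Computed on the unweighted topology by
#' default; `mode = "barrat"` gives the Barrat et al. weighted
#' generalization. Vertices with fewer than two opponents score 0.
#'
#' @param g Weighted aggression graph.
#' @param mode `"binary"` (default) or `"barrat"`.
#' @return Named numeric vector in \[0, 1\].
#' @export
clustering_coefficient <- function(g, mode = c("binary", "barrat")) {
  mode <- match.arg(mode)
  nm <- igraph::V(g)$name
  x <- if (mode == "binary") {
    igraph::transitivity(g, type = "local", isolates = "zero")
  } else {
    igraph::transitivity(g, type = "barrat", isolates = "zero",
                         weights = igraph::E(g)$weight)
  }
  x[is.na(x)] <- 0
  stats::setNames(x, nm)
}

#' All six social-network traits for one pen graph
#'
#' @param g Weighted aggression graph (from [build_pen_graph()]).
#' @param weight_mode Path-cost convention for betweenness/closeness.
#' @param clustering_mode `"binary"` or `"barrat"`.
#' @return Data frame with one row per animal: `animal`, the six raw traits
#'   (`degree`, `weighted_degree`, `betweenness`, `closeness`, `eigenvector`,
#'   `clustering`) and their square-root transforms (`t_` prefix).
#' @export
sna_traits <- function(g, weight_mode = c("cost", "inverse"),
                       clustering_mode = c("binary", "barrat")) {
  raw <- data.frame(
    animal = igraph::V(g)$name,
    degree = as.numeric(degree_centrality(g)),
    weighted_degree = as.numeric(weighted_degree(g)),
    betweenness = as.numeric(betweenness_centrality(g, weight_mode)),
    closeness = as.numeric(closeness_centrality(g, weight_mode)),
    eigenvector = as.numeric(eigenvector_centrality(g)),
    clustering = as.numeric(clustering_coefficient(g, clustering_mode)),
    stringsAsFactors = FALSE
  )
  for (tr in sna_trait_names()) raw[[paste0("t_", tr)]] <- sqrt(raw[[tr]])
  raw
}

#' Names of the six social-network traits
#' @return Character vector.
#' @export
sna_trait_names <- function() {
  c("degree", "weighted_degree", "betweenness", "closeness", "eigenvector",
    "clustering")
}

#' Compute social-network traits for every pen
#'
#' End-to-end: aggregates fight records, builds one weighted graph per pen
#' over the full roster (non-fighters included as isolated nodes) and scores
#' every animal. Skewed raw scores are square-root transformed into the
#' `t_`-prefixed columns, which are the responses of the genetic analysis.
#'
#' @param records Fight records (see [read_fight_records()]).
#' @param animals Animal metadata (see [read_animal_metadata()]).
#' @param weight_mode,clustering_mode Passed to [sna_traits()].
#' @return Data frame: `animal`, `pen_id`, six raw and six transformed trait
#'   columns, in roster order within pen.
#' @export
compute_sna_traits <- function(records, animals,
                               weight_mode = c("cost", "inverse"),
                               clustering_mode = c("binary", "barrat")) {
  rosters <- pen_rosters(animals)
  dyads <- aggregate_fights(records)
  out <- lapply(names(rosters), function(pen) {
    dd <- dyads[dyads$pen_id == pen, , drop = FALSE]
    g <- build_pen_graph(rosters[[pen]], dd)
    tr <- sna_traits(g, weight_mode, clustering_mode)
    cbind(tr[1], pen_id = pen, tr[-1], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export per-pen edge lists
#'
#' @param records Fight records.
#' @param path Output CSV path (`pen_id,animal_a,animal_b,weight_s`).
#' @return Invisibly, the path.
#' @export
export_edge_lists <- function(records, path) {
  write_csv_plain(aggregate_fights(records), path)
}

path_costs <- function(g, weight_mode = c("cost", "inverse")) {
  weight_mode <- match.arg(weight_mode)
  if (igraph::ecount(g) == 0L) return(NULL)
  w <- igraph::E(g)$weight
  if (any(w < 0)) stop("negative edge weight")
  if (weight_mode == "inverse") 1 / w else w
}
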