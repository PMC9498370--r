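# Independent brute-force oracles and small fixture builders used across the
# test files. Everything here is deliberately naive (enumeration, dense
# linear algebra) and shares no code with the package internals.

# random weighted graph as an edge data frame over vertices v1..vn
random_edge_df <- function(n, p = 0.5, wmax = 10) {
  ids <- paste0("v", seq_len(n))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(animal_a = pairs[1, keep], animal_b = pairs[2, keep],
             weight_s = stats::runif(sum(keep), 0.5, wmax),
             stringsAsFactors = FALSE)
}

edge_df_to_adj <- function(ids, edges) {
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(edges))) {
    W[edges$animal_a[k], edges$animal_b[k]] <- edges$weight_s[k]
    W[edges$animal_b[k], edges$animal_a[k]] <- edges$weight_s[k]
  }
  W
}

# Floyd-Warshall all-pairs shortest path costs
oracle_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, W, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# enumerate all simple paths between s and t (indices), return list of
# vertex sequences
all_simple_paths_idx <- function(W, s, t) {
  n <- nrow(W)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (u in seq_len(n)) {
      if (W[v, u] > 0 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(s)
  out
}

path_cost <- function(W, path) {
  if (length(path) < 2L) return(0)
  sum(W[cbind(path[-length(path)], path[-1])])
}

# betweenness by exhaustive shortest-path enumeration, fractional credit,
# normalized by (n-1)(n-2)/2
oracle_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      paths <- all_simple_paths_idx(W, s, t)
      if (length(paths) == 0L) next
      costs <- vapply(paths, function(p) path_cost(W, p), numeric(1))
      best <- min(costs)
      sp <- paths[costs <= best + tol * max(1, best)]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(sp, function(p) v %in% p, logical(1)))
        bc[v] <- bc[v] + through / length(sp)
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# closeness with the reachable-fraction (Wasserman-Faust) correction
oracle_closeness <- function(W) {
  n <- nrow(W)
  D <- oracle_distances(W)
  diag(D) <- Inf
  vapply(seq_len(n), function(v) {
    d <- D[v, ]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (r / sum(d[is.finite(d)])) * (r / (n - 1))
  }, numeric(1))
}

# eigenvector centrality via dense symmetric eigendecomposition
oracle_eigenvector <- function(W) {
  if (all(W == 0)) return(numeric(nrow(W)))
  e <- eigen(W, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  v[rowSums(W) == 0] <- 0
  v / max(v)
}

oracle_clustering <- function(W) {
  n <- nrow(W)
  A <- (W > 0) * 1
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
}

# small pedigree helpers -----------------------------------------------------

ped_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(animal = m[, 1], sire = m[, 2], dam = m[, 3],
             stringsAsFactors = FALSE)
}

# random valid pedigree: n animals, each non-founder picks parents among
# earlier animals
random_pedigree <- function(n, p_founder = 0.3) {
  sire <- dam <- integer(n)
  for (i in seq_len(n)) {
    if (i > 2 && stats::runif(1) > p_founder) {
      sire[i] <- sample.int(i - 1L, 1)
      dam[i] <- sample.int(i - 1L, 1)
      if (dam[i] == sire[i]) dam[i] <- 0L
    }
  }
  as_pedigree(data.frame(animal = seq_len(n), sire = sire, dam = dam))
}

# compact simulated study used by several test files
small_study <- function(seed = 5) {
  cfg <- sim_config(n_sires = 8, n_dams = 24, n_offspring = 120, n_pens = 12,
                    pen_size = 10, n_pedigree = 200, n_gsires = 10,
                    n_gdams = 20, n_batches = 3, n_lines = 3)
  simulate_study(cfg, seed = seed)
}
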