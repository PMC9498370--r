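# Pedigree handling: topological sorting, inbreeding, the additive
# (numerator) relationship matrix A, and Henderson's sparse A-inverse.

#' Construct a pedigree object from an animal/sire/dam table
#'
#' Validates the three-column pedigree, applies a stable topological sort
#' (parents before offspring, ties broken by input order) and recodes ids to
#' consecutive integers 1..n. Unknown parents are coded 0; empty strings and
#' NA are accepted as synonyms.
#'
#' @param df Data frame with columns `animal`, `sire`, `dam` (labels may be
#'   arbitrary strings or numbers).
#' @return An object of class `pedigree`: a data frame with integer columns
#'   `id`, `sire`, `dam` (0 = unknown) and character `label`, sorted so
#'   parents precede offspring.
#' @export
as_pedigree <- function(df) {
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree needs columns animal, sire, dam")
  an <- as.character(df$animal)
  si <- normalize_parent(df$sire)
  da <- normalize_parent(df$dam)
  if (any(is.na(an) | an == "" | an == "0"))
    stop("invalid animal id (empty or 0) in pedigree")
  dup <- an[duplicated(an)]
  if (length(dup) > 0L)
    stop("duplicated animal row(s) in pedigree: ", paste(unique(dup), collapse = ", "))
  known <- unique(c(si, da)); known <- known[!is.na(known)]
  phantom <- setdiff(known, an)
  if (length(phantom) > 0L) {
    # parents that never get their own row become founders
    an <- c(phantom, an)
    si <- c(rep(NA_character_, length(phantom)), si)
    da <- c(rep(NA_character_, length(phantom)), da)
  }
  n <- length(an)
  idx <- stats::setNames(seq_len(n), an)
  sire_i <- ifelse(is.na(si), 0L, idx[si])
  dam_i <- ifelse(is.na(da), 0L, idx[da])

  ord <- topo_sort_pedigree(sire_i, dam_i)
  rank <- integer(n); rank[ord] <- seq_len(n)
  ped <- data.frame(
    id = seq_len(n),
    sire = ifelse(sire_i[ord] == 0L, 0L, rank[pmax(sire_i[ord], 1L)]),
    dam = ifelse(dam_i[ord] == 0L, 0L, rank[pmax(dam_i[ord], 1L)]),
    label = an[ord],
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree", "data.frame")
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

# Kahn's algorithm, stable: among ready nodes, original order is preserved.
# Detects cycles (an animal that is its own ancestor).
topo_sort_pedigree <- function(sire, dam) {
  n <- length(sire)
  children <- vector("list", n)
  indeg <- integer(n)
  for (i in seq_len(n)) {
    for (p in c(sire[i], dam[i])) {
      if (p > 0L) {
        children[[p]] <- c(children[[p]], i)
        indeg[i] <- indeg[i] + 1L
      }
    }
  }
  ready <- which(indeg == 0L)  # ascending = original file order
  out <- integer(0)
  while (length(ready) > 0L) {
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- sort(c(ready, ch))
    }
  }
  if (length(out) < n)
    stop("pedigree contains a cycle (an animal is its own ancestor)")
  out
}

#' Number of animals in a pedigree
#' @param ped A `pedigree` object.
#' @return Integer count.
#' @export
n_animals <- function(ped) nrow(ped)

#' Inbreeding coefficients from a pedigree
#'
#' Computes per-animal inbreeding F, either by the Meuwissen-Luo algorithm
#' (default; O(n) memory, suitable for thousands of animals) or from the
#' diagonal of the tabular relationship matrix. The two must agree exactly.
#'
#' @param ped A `pedigree` object (sorted; see [as_pedigree()]).
#' @param method `"meuwissen"` or `"tabular"`.
#' @return Numeric vector F with `F[i] = A[i,i] - 1`.
#' @export
inbreeding <- function(ped, method = c("meuwissen", "tabular")) {
  method <- match.arg(method)
  check_sorted(ped)
  if (method == "tabular") {
    A <- relationship_matrix(ped)
    return(unname(diag(A)) - 1)
  }
  meuwissen_luo_f(ped$sire, ped$dam)
}

# Meuwissen & Luo (1992): computes F animal by animal by tracing each
# animal's ancestor list and accumulating within-animal additive variance
# contributions. L[j] is the path coefficient from ancestor j to animal i;
# D[j] the within-family (Mendelian) variance of j.
meuwissen_luo_f <- function(sire, dam, ret_d = FALSE) {
  n <- length(sire)
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    Fs <- if (s > 0L) F[s] else -1
    Fd <- if (d > 0L) F[d] else -1
    D[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (s == 0L || d == 0L) { F[i] <- 0; next }
    L <- numeric(i)
    L[i] <- 1
    fi <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      fi <- fi + L[j]^2 * D[j]
      sj <- sire[j]; dj <- dam[j]
      if (sj > 0L) L[sj] <- L[sj] + 0.5 * L[j]
      if (dj > 0L) L[dj] <- L[dj] + 0.5 * L[j]
    }
    F[i] <- fi - 1
  }
  if (ret_d) list(F = F, D = D) else F
}

#' Additive genetic relationship matrix (tabular method)
#'
#' Builds the dense numerator relationship matrix A by the tabular
#' recursion: for animal i with parents s, d,
#' `a[i,j] = 0.5 * (a[j,s] + a[j,d])` for j < i and
#' `a[i,i] = 1 + 0.5 * a[s,d]`, terms for unknown parents dropped.
#' Intended for pedigrees small enough to hold densely; the MCMC machinery
#' uses [ainverse()] instead.
#'
#' @param ped A sorted `pedigree` object.
#' @return Dense symmetric matrix with dimnames = pedigree labels.
#' @export
relationship_matrix <- function(ped) {
  check_sorted(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else numeric(i - 1L)
      ad_ <- if (d > 0L) A[j, d] else numeric(i - 1L)
      A[j, i] <- 0.5 * (as_ + ad_)
      A[i, j] <- A[j, i]
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped$label, ped$label)
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules with
#' inbreeding: each animal contributes `alpha = 1/d` to a small block over
#' {animal, sire, dam}, where `d = 0.5 - 0.25 (F_s + F_d)` is the Mendelian
#' sampling variance (with `F = -1` for an unknown parent, giving d = 1 for
#' two unknown and 0.75 for one unknown, non-inbred parent). Never forms
#' dense A, so it scales to pedigrees of thousands of animals.
#'
#' @param ped A sorted `pedigree` object.
#' @param f Optional precomputed inbreeding vector (from [inbreeding()]).
#' @return A symmetric sparse matrix (`Matrix::dsCMatrix`).
#' @export
ainverse <- function(ped, f = NULL) {
  check_sorted(ped)
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding(ped)
  stopifnot(length(f) == n)
  # triplet accumulation; each animal adds at most 9 entries
  cap <- 9L * n
  ii <- integer(cap); jj <- integer(cap); xx <- numeric(cap)
  k <- 0L
  put <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    Fs <- if (s > 0L) f[s] else -1
    Fd <- if (d > 0L) f[d] else -1
    alpha <- 1 / (0.5 - 0.25 * (Fs + Fd))
    put(i, i, alpha)
    for (p in c(s, d)) {
      if (p > 0L) {
        put(i, p, -alpha / 2); put(p, i, -alpha / 2)
        put(p, p, alpha / 4)
      }
    }
    if (s > 0L && d > 0L) {
      put(s, d, alpha / 4); put(d, s, alpha / 4)
    }
  }
  M <- Matrix::sparseMatrix(i = ii[seq_len(k)], j = jj[seq_len(k)],
                            x = xx[seq_len(k)], dims = c(n, n),
                            dimnames = list(ped$label, ped$label))
  Matrix::forceSymmetric(M)
}

#' Export inbreeding and A-inverse triplets for inspection
#'
#' @param ped A sorted `pedigree` object.
#' @param dir Output directory.
#' @return Invisibly, the file paths written (`inbreeding.csv`,
#'   `ainverse_triplets.csv`).
#' @export
export_kinship <- function(ped, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- inbreeding(ped)
  p1 <- file.path(dir, "inbreeding.csv")
  write_csv_plain(data.frame(animal = ped$label, F = f), p1)
  Ai <- as(as(ainverse(ped, f), "generalMatrix"), "TsparseMatrix")
  p2 <- file.path(dir, "ainverse_triplets.csv")
  write_csv_plain(data.frame(row = ped$label[Ai@i + 1L],
                             col = ped$label[Ai@j + 1L],
                             value = Ai@x), p2)
  invisible(c(p1, p2))
}

check_sorted <- function(ped) {
  if (!inherits(ped, "pedigree"))
    stop("expected a 'pedigree' object (see as_pedigree)")
  bad <- ped$sire >= ped$id & ped$sire > 0 | ped$dam >= ped$id & ped$dam > 0
  if (any(bad))
    stop("pedigree not sorted: parent does not precede offspring at row ",
         which(bad)[1])
  invisible(ped)
}
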