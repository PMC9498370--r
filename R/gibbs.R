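# Bayesian animal model y = Xb + Za + Wc + e fitted by Gibbs sampling.
#
# b: fixed effects (genetic line, sex, batch, mixing-weight covariate),
# a: additive genetic effects with a ~ N(0, A (x) G0) structured by the
#    pedigree relationship matrix (entering via its sparse inverse),
# c: common environmental pen effects, iid across pens,
# e: residual. Univariate (t = 1) and bivariate (t = 2) models share one
# sampler; bivariate records missing one trait are kept via residual
# conditional data augmentation.

#' MCMC configuration for the Gibbs sampler
#'
#' The full-scale default (1,000,000 iterations, 100,000 burn-in, thinning
#' lag 20) matches common practice for pedigree animal models; the
#' [gibbs_config_test()] preset (20,000 / 2,000 / 10) is used throughout the
#' test suite so that chains finish in seconds while remaining long enough
#' for stable posterior means.
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before saving.
#' @param thin Save every `thin`-th post-burn-in draw.
#' @param seed Integer seed (optional; forwarded to `set.seed`).
#' @return A `gibbs_config` list.
#' @export
gibbs_config <- function(n_iter = 1000000L, burn_in = 100000L, thin = 20L,
                         seed = NULL) {
  stopifnot(burn_in < n_iter, thin >= 1L)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed),
            class = "gibbs_config")
}

#' Reduced-run preset for testing
#' @inheritParams gibbs_config
#' @return A `gibbs_config` list.
#' @export
gibbs_config_test <- function(n_iter = 20000L, burn_in = 2000L, thin = 10L,
                              seed = NULL) {
  gibbs_config(n_iter, burn_in, thin, seed)
}

#' Inverse-Wishart priors for the covariance components
#'
#' The default is the flat (uniform) prior on each covariance matrix,
#' expressed in inverse-Wishart form as degrees of freedom `-(t + 1)` and a
#' zero scale, so that the full conditional of e.g. G0 is
#' `InvWishart(q - t - 1, a' A^-1 a)` — the likelihood alone. This is the
#' standard "flat priors for the covariance components" choice for animal
#' models. Informative alternatives (larger `nu`, nonzero `s`) can be
#' supplied for small or degenerate data sets. Beware that a seemingly
#' vague proper prior such as `nu = t + 1` with tiny `s` concentrates its
#' mass near zero variance and can dominate weakly identified partitions.
#'
#' @param t Number of traits (1 or 2).
#' @param nu Prior degrees of freedom (same for G0, C0, R0 by default).
#' @param s Diagonal prior scale.
#' @return List with `nu_g, S_g, nu_c, S_c, nu_r, S_r`.
#' @export
default_priors <- function(t, nu = -(t + 1), s = 0) {
  S <- diag(s, t)
  list(nu_g = nu, S_g = S, nu_c = nu, S_c = S, nu_r = nu, S_r = S)
}

#' Assemble the design of the animal model
#'
#' Builds the stacked response, the fixed-effect design matrix with corner
#' (reference-level) constraints and a centered covariate, and the index
#' maps into the pedigree and pen levels. Rows missing every requested trait
#' are dropped; in bivariate models rows missing exactly one trait are kept
#' and flagged for data augmentation.
#'
#' @param data Data frame with one row per phenotyped animal: `animal`,
#'   `pen_id`, the fixed-effect columns and the trait columns.
#' @param traits Character vector of 1 or 2 response column names.
#' @param ped The `pedigree` object covering all phenotyped animals.
#' @param fixed Factor columns fitted as fixed effects.
#' @param covariate Numeric covariate column (centered), or `NULL`.
#' @return A `design_assembly` list: `Y` (n x t), `obs` (logical n x t),
#'   `X`, `animal_idx`, `pen_idx`, `pen_levels`, `traits`.
#' @export
assemble_design <- function(data, traits, ped,
                            fixed = c("line", "sex", "batch"),
                            covariate = "mixing_weight_kg") {
  stopifnot(length(traits) %in% 1:2)
  miss <- setdiff(c(traits, fixed, covariate, "animal", "pen_id"), names(data))
  if (length(miss) > 0L)
    stop("missing column(s) in data: ", paste(miss, collapse = ", "))

  Y <- as.matrix(data[traits])
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0L
  if (!any(keep)) stop("all responses missing")
  if (length(traits) == 1L) keep <- obs[, 1]
  data <- data[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  Y[!obs] <- 0

  fml_terms <- character(0)
  for (fc in fixed) {
    data[[fc]] <- droplevels(factor(data[[fc]]))
    tab <- table(data[[fc]])
    if (any(tab == 1L))
      warning("factor '", fc, "' has level(s) with a single observation: ",
              paste(names(tab)[tab == 1L], collapse = ", "))
    if (nlevels(data[[fc]]) > 1L) fml_terms <- c(fml_terms, fc)
  }
  if (!is.null(covariate)) {
    data[[covariate]] <- data[[covariate]] - mean(data[[covariate]], na.rm = TRUE)
    fml_terms <- c(fml_terms, covariate)
  }
  fml <- stats::as.formula(paste("~", paste(c("1", fml_terms), collapse = " + ")))
  X <- stats::model.matrix(fml, data = data)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design is rank deficient")

  animal_idx <- match(as.character(data$animal), ped$label)
  if (anyNA(animal_idx))
    stop("animal(s) not in pedigree: ",
         paste(utils::head(data$animal[is.na(animal_idx)], 5), collapse = ", "))
  pen_f <- factor(data$pen_id)

  structure(list(Y = Y, obs = obs, X = X,
                 animal_idx = animal_idx,
                 pen_idx = as.integer(pen_f),
                 pen_levels = levels(pen_f),
                 traits = traits),
            class = "design_assembly")
}

#' Run the Gibbs sampler for one model
#'
#' @param assembly A `design_assembly` from [assemble_design()].
#' @param ainv Sparse A-inverse over the full pedigree (from [ainverse()]).
#' @param priors Prior list (default: [default_priors()] for the trait count).
#' @param config A `gibbs_config`.
#' @param update_location If `FALSE`, the location effects (b, a, c) are
#'   frozen at `a_init`/`c_init`/zero and only the covariance components are
#'   drawn from their inverse-Wishart full conditionals — used to validate
#'   conjugacy against the analytic distribution.
#' @param a_init,c_init Optional starting values for the genetic and pen
#'   effects (matrices q x t and n_pens x t).
#' @return An `mcmc_chain` object: `draws` (matrix, one row per saved draw,
#'   columns `G0_11[,G0_12,G0_22],C0_...,R0_...`), `a_mean` (posterior mean
#'   breeding values), `traits`, and the configuration used.
#' @export
gibbs_run <- function(assembly, ainv, priors = NULL, config = gibbs_config(),
                      update_location = TRUE, a_init = NULL, c_init = NULL) {
  t <- ncol(assembly$Y)
  q <- nrow(ainv)
  npen <- length(assembly$pen_levels)
  if (max(assembly$animal_idx) > q)
    stop("A-inverse does not cover all animals in the design")
  if (is.null(priors)) priors <- default_priors(t)
  if (is.null(a_init)) a_init <- matrix(0, q, t)
  if (is.null(c_init)) c_init <- matrix(0, npen, t)

  v0 <- pmax(apply(assembly$Y, 2, stats::var), 1e-8) / 3
  G0 <- diag(v0, t); C0 <- diag(v0, t); R0 <- diag(v0, t)

  M <- as(as(Matrix::forceSymmetric(ainv), "generalMatrix"), "CsparseMatrix")

  if (!is.null(config$seed)) set.seed(config$seed)
  res <- gibbs_sampler_cpp(
    Y = assembly$Y, obs = matrix(as.integer(assembly$obs), nrow(assembly$obs)),
    X = assembly$X,
    animal = assembly$animal_idx - 1L, pen = assembly$pen_idx - 1L,
    Ap = M@p, Ai = M@i, Ax = M@x, q = q, npen = npen,
    nu_g = priors$nu_g, S_g = as.matrix(priors$S_g),
    nu_c = priors$nu_c, S_c = as.matrix(priors$S_c),
    nu_r = priors$nu_r, S_r = as.matrix(priors$S_r),
    G0 = G0, C0 = C0, R0 = R0,
    n_iter = config$n_iter, burn_in = config$burn_in, thin = config$thin,
    update_location = update_location,
    a_init = a_init, c_init = c_init)

  tri <- if (t == 1L) "11" else c("11", "12", "22")
  colnames(res$draws) <- c(paste0("G0_", tri), paste0("C0_", tri),
                           paste0("R0_", tri))
  structure(list(draws = res$draws, a_mean = res$a_mean,
                 traits = assembly$traits, config = config, priors = priors),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat("mcmc_chain:", paste(x$traits, collapse = " x "),
      "|", nrow(x$draws), "saved draws\n")
  print(round(colMeans(x$draws), 5))
  invisible(x)
}

#' Fit all univariate and bivariate models of the analysis
#'
#' Runs one univariate chain per trait in `traits`, one bivariate chain per
#' pair within `traits` (all 15 pairs for the six network traits), and one
#' bivariate chain for each trait crossed with each column of
#' `partner_traits` (6 x 8 = 48 network-by-performance models in the full
#' analysis). Per-model seeds are derived deterministically from the master
#' seed, so the whole set is reproducible.
#'
#' @param data Merged data frame (see [assemble_design()]).
#' @param traits Primary trait columns.
#' @param ped Pedigree object.
#' @param ainv Sparse A-inverse (computed from `ped` if `NULL`).
#' @param partner_traits Optional second trait set for cross pairs.
#' @param pairs If `FALSE`, univariate chains only.
#' @param config Shared `gibbs_config`; its `seed` seeds the whole set.
#' @param ... Passed to [assemble_design()].
#' @return Named list of `mcmc_chain` objects (`"trait"` for univariate,
#'   `"a:b"` for bivariate).
#' @export
run_all_models <- function(data, traits, ped, ainv = NULL,
                           partner_traits = character(0), pairs = TRUE,
                           config = gibbs_config_test(), ...) {
  if (is.null(ainv)) ainv <- ainverse(ped)
  models <- lapply(traits, function(tr) tr)
  if (pairs && length(traits) > 1L) {
    cmb <- utils::combn(traits, 2, simplify = FALSE)
    models <- c(models, cmb)
  }
  for (tr in traits)
    for (pt in partner_traits) models <- c(models, list(c(tr, pt)))
  names(models) <- vapply(models, paste, "", collapse = ":")

  master <- if (is.null(config$seed)) 1L else config$seed
  set.seed(master)
  seeds <- sample.int(.Machine$integer.max - 1L, length(models))

  out <- vector("list", length(models))
  names(out) <- names(models)
  for (i in seq_along(models)) {
    cfg <- config; cfg$seed <- seeds[i]
    asm <- assemble_design(data, models[[i]], ped, ...)
    out[[i]] <- gibbs_run(asm, ainv, config = cfg)
  }
  out
}

#' Write a chain's saved draws to CSV
#'
#' @param chain An `mcmc_chain`.
#' @param path Output CSV path (`iter` plus one column per covariance
#'   element).
#' @return Invisibly, the path.
#' @export
write_chain <- function(chain, path) {
  df <- data.frame(iter = seq_len(nrow(chain$draws)), chain$draws,
                   check.names = FALSE)
  write_csv_plain(df, path)
}
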