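# Synthetic study generator: pedigree, pen structure, latent aggressiveness,
# fight networks and phenotypes with known ground truth. The defaults
# emulate the design of the commercial-herd study the pipeline targets:
# 900 focal pigs (450 females, 450 castrates), progeny of 116 sires and 391
# dams inside a pedigree of ~4100 animals, housed in 50 single-sex pens of
# 18 across 9 batches, with 9 genetic lines.

#' Configuration of the synthetic study
#'
#' @param n_sires,n_dams Parents of the focal generation (defaults 116/391).
#' @param n_offspring Focal animals with records (default 900).
#' @param pen_size,n_pens Pen structure (defaults 18 and 50; their product
#'   must equal `n_offspring`).
#' @param n_batches Mixing-day batches (default 9).
#' @param n_lines Genetic lines, inherited from the sire (default 9).
#' @param n_pedigree Target total pedigree size (default 4104); the gap
#'   beyond grandparents + parents + offspring is filled with non-phenotyped
#'   relatives (additional progeny of the founder generation).
#' @param n_gsires,n_gdams Founder grandparents available as parents of the
#'   sire/dam generation.
#' @param mixing_weight_mean,mixing_weight_sd Body weight at mixing, kg
#'   (defaults 30 and 4; pigs were mixed at about 10 weeks of age).
#' @param fight Fight-model parameters, see [fight_params()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sires = 116L, n_dams = 391L, n_offspring = 900L,
                       pen_size = 18L, n_pens = 50L, n_batches = 9L,
                       n_lines = 9L, n_pedigree = 4104L,
                       n_gsires = 80L, n_gdams = 260L,
                       mixing_weight_mean = 30, mixing_weight_sd = 4,
                       fight = fight_params()) {
  if (n_pens * pen_size != n_offspring)
    stop("n_pens * pen_size must equal n_offspring")
  structure(as.list(environment()), class = "sim_config")
}

#' Parameters of the fight-network generator
#'
#' Fights are generated dyad by dyad within a pen: a reciprocal fight occurs
#' with probability `plogis(alpha + lambda * (u_i + u_j))`, where `u` is the
#' latent aggressiveness of the pair; if it occurs, its total duration is
#' `LogNormal(mu + kappa * (u_i + u_j), sigma)` seconds, floored at 1 s
#' (shorter exchanges do not count as reciprocal fights). Latent
#' aggressiveness is `u = a_u + environmental noise`, with `a_u` a breeding
#' value of unit genetic variance simulated down the pedigree and the noise
#' variance set by `u_h2`. The defaults produce sparse right-skewed networks
#' (most dyads never fight; a minority of long fights), the regime the
#' square-root transform of the network traits is designed for.
#'
#' @param alpha Logit-scale intercept of fight incidence (default -4.4).
#' @param lambda Genetic loading on incidence (default 0.6).
#' @param mu Log-scale mean of fight duration (default 2.5, median ~12 s).
#' @param kappa Genetic loading on duration (default 0.3).
#' @param sigma Log-scale SD of duration (default 1).
#' @param u_h2 Heritability of latent aggressiveness (default 0.5).
#' @return A `fight_params` list.
#' @export
fight_params <- function(alpha = -4.4, lambda = 0.6, mu = 2.5, kappa = 0.3,
                         sigma = 1, u_h2 = 0.5) {
  stopifnot(u_h2 > 0, u_h2 <= 1)
  structure(as.list(environment()), class = "fight_params")
}

#' Simulate a three-generation pedigree
#'
#' Founder grandparents, a sire/dam generation descended from them, the
#' focal offspring, and enough additional founder-generation progeny
#' ("relatives without records") to reach the target pedigree size. Dams are
#' each mated to one randomly assigned sire and offspring are allocated to
#' dams at random, so litter sizes average `n_offspring / n_dams`.
#'
#' @param cfg A `sim_config`.
#' @param seed Integer seed.
#' @return A `pedigree` object with a `role` attribute
#'   (`founder`/`parent`/`relative`/`offspring`, aligned with rows) and an
#'   `offspring` attribute holding the focal labels in birth order.
#' @export
simulate_pedigree <- function(cfg, seed) {
  set.seed(seed)
  gs <- paste0("GS", seq_len(cfg$n_gsires))
  gd <- paste0("GD", seq_len(cfg$n_gdams))
  founders <- c(gs, gd)

  n_parents <- cfg$n_sires + cfg$n_dams
  sires <- paste0("S", seq_len(cfg$n_sires))
  dams <- paste0("D", seq_len(cfg$n_dams))
  par_gs <- sample(gs, n_parents, replace = TRUE)
  par_gd <- sample(gd, n_parents, replace = TRUE)

  n_extra <- max(0L, cfg$n_pedigree - length(founders) - n_parents -
                   cfg$n_offspring)
  extras <- if (n_extra > 0L) paste0("R", seq_len(n_extra)) else character(0)
  ex_gs <- sample(gs, n_extra, replace = TRUE)
  ex_gd <- sample(gd, n_extra, replace = TRUE)

  off <- sprintf("P%04d", seq_len(cfg$n_offspring))
  dam_sire <- sample(sires, cfg$n_dams, replace = TRUE)  # one mate per dam
  off_dam <- sample(dams, cfg$n_offspring, replace = TRUE)
  off_sire <- dam_sire[match(off_dam, dams)]

  df <- data.frame(
    animal = c(founders, sires, dams, extras, off),
    sire = c(rep("0", length(founders)), par_gs[seq_len(cfg$n_sires)],
             par_gs[cfg$n_sires + seq_len(cfg$n_dams)], ex_gs, off_sire),
    dam = c(rep("0", length(founders)), par_gd[seq_len(cfg$n_sires)],
            par_gd[cfg$n_sires + seq_len(cfg$n_dams)], ex_gd, off_dam),
    stringsAsFactors = FALSE
  )
  ped <- as_pedigree(df)
  role <- rep("relative", nrow(ped))
  role[ped$label %in% founders] <- "founder"
  role[ped$label %in% c(sires, dams)] <- "parent"
  role[ped$label %in% off] <- "offspring"
  attr(ped, "role") <- role
  attr(ped, "offspring") <- off
  attr(ped, "sire_of") <- stats::setNames(dam_sire, dams)
  ped
}

#' Simulate breeding values down a pedigree
#'
#' Founders draw `a ~ N(0, G0)`; every non-founder is the parent average
#' plus a Mendelian sampling deviation `m ~ N(0, d_i * G0)` with
#' `d_i = 0.5 - 0.25 * (F_s + F_d)` (unknown parents contribute `F = -1`),
#' so the simulated values have covariance `A (x) G0` by construction.
#'
#' @param ped A sorted `pedigree` object.
#' @param G0 Genetic covariance matrix (t x t; a scalar is accepted).
#' @param seed Integer seed.
#' @return Matrix n x t of breeding values, rownames = pedigree labels.
#' @export
simulate_breeding_values <- function(ped, G0, seed) {
  set.seed(seed)
  G0 <- as.matrix(G0)
  t <- ncol(G0)
  n <- nrow(ped)
  a <- matrix(0, n, t, dimnames = list(ped$label, NULL))
  if (all(G0 == 0)) return(a)
  L <- chol(G0)
  fd <- meuwissen_luo_f(ped$sire, ped$dam, ret_d = TRUE)
  z <- matrix(stats::rnorm(n * t), n, t) %*% L
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    pa <- numeric(t)
    if (s > 0L) pa <- pa + 0.5 * a[s, ]
    if (d > 0L) pa <- pa + 0.5 * a[d, ]
    a[i, ] <- pa + sqrt(fd$D[i]) * z[i, ]
  }
  a
}

#' Assign focal animals to pens, batches, lines and sexes
#'
#' Half the offspring are female and half castrates; pens are single-sex
#' (25 of each at the defaults) and batches are contiguous groups of pens
#' mixed on the same day. The genetic line is inherited from the sire (sires
#' are spread round-robin over the lines), and body weight at mixing is
#' drawn from a truncated normal.
#'
#' @param ped Pedigree from [simulate_pedigree()].
#' @param cfg A `sim_config`.
#' @param seed Integer seed.
#' @return Animal metadata data frame
#'   (`animal,pen_id,line,sex,batch,mixing_weight_kg`).
#' @export
assign_pens <- function(ped, cfg, seed) {
  set.seed(seed)
  off <- attr(ped, "offspring")
  n <- length(off)
  if (n %% cfg$pen_size != 0L) stop("offspring count not divisible by pen size")
  if (n %% 2L != 0L) stop("offspring count must be even (two sexes)")

  sex <- sample(rep(c("female", "castrate"), each = n %/% 2L))
  names(sex) <- off
  pens_per_sex <- cfg$n_pens %/% 2L
  pen_id <- character(n); names(pen_id) <- off
  for (sx in c("female", "castrate")) {
    ids <- sample(off[sex == sx])
    pens <- paste0(ifelse(sx == "female", "F", "C"),
                   sprintf("%02d", seq_len(pens_per_sex)))
    pen_id[ids] <- rep(pens, each = cfg$pen_size)
  }
  pen_levels <- sort(unique(pen_id))
  batch_of_pen <- stats::setNames(
    paste0("B", as.integer(cut(seq_along(pen_levels), cfg$n_batches))),
    sample(pen_levels))  # batches group pens mixed the same day

  sire_line <- stats::setNames(
    paste0("L", rep_len(seq_len(cfg$n_lines), cfg$n_sires)),
    paste0("S", seq_len(cfg$n_sires)))
  sire_of <- ped$sire[match(off, ped$label)]
  line <- sire_line[ped$label[sire_of]]

  w <- stats::rnorm(n, cfg$mixing_weight_mean, cfg$mixing_weight_sd)
  while (any(w <= 0))
    w[w <= 0] <- stats::rnorm(sum(w <= 0), cfg$mixing_weight_mean,
                              cfg$mixing_weight_sd)

  data.frame(animal = off, pen_id = unname(pen_id[off]),
             line = unname(line), sex = unname(sex[off]),
             batch = unname(batch_of_pen[pen_id[off]]),
             mixing_weight_kg = w, stringsAsFactors = FALSE)
}

#' Simulate a pen-structured fight network
#'
#' @param animals Animal metadata (pen assignments).
#' @param u Named vector of latent aggressiveness, one entry per animal.
#' @param params A `fight_params` list.
#' @param seed Integer seed.
#' @return Fight record data frame (`pen_id,animal_a,animal_b,duration_s`),
#'   one row per fighting dyad.
#' @export
simulate_fight_network <- function(animals, u, params = fight_params(), seed) {
  set.seed(seed)
  rosters <- pen_rosters(animals)
  rows <- list()
  for (pen in names(rosters)) {
    ids <- rosters[[pen]]
    if (length(ids) < 2L) next
    pr <- utils::combn(ids, 2)
    us <- u[pr[1, ]] + u[pr[2, ]]
    p <- stats::plogis(params$alpha + params$lambda * us)
    hit <- stats::runif(ncol(pr)) < p
    if (!any(hit)) next
    dur <- pmax(1, stats::rlnorm(sum(hit), params$mu + params$kappa * us[hit],
                                 params$sigma))
    rows[[pen]] <- data.frame(pen_id = pen, animal_a = pr[1, hit],
                              animal_b = pr[2, hit], duration_s = dur,
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(pen_id = character(0), animal_a = character(0),
                      animal_b = character(0), duration_s = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate phenotypes under the animal model
#'
#' Assembles `y = Xb + Za + Wc + e` exactly: fixed effects are drawn once
#' per level from `N(0, b_sd^2)` (plus a covariate slope on centered mixing
#' weight), pen effects from `N(0, C0)`, residuals from `N(0, R0)`.
#'
#' @param animals Animal metadata.
#' @param a Breeding-value matrix for the focal animals (rows = pedigree
#'   labels, from [simulate_breeding_values()]).
#' @param G0,C0,R0 True covariance components (t x t or scalars).
#' @param seed Integer seed.
#' @param b_sd SD of the fixed line/sex/batch effects (default 0.25 on the
#'   trait's own scale).
#' @param beta_weight Covariate slope per kg (default 0).
#' @param trait_names Column names of the output traits.
#' @return List: `data` (animals + trait columns), `truth` (the true b, c
#'   and variance components).
#' @export
simulate_phenotypes <- function(animals, a, G0, C0, R0, seed,
                                b_sd = 0.25, beta_weight = 0,
                                trait_names = NULL) {
  set.seed(seed)
  G0 <- as.matrix(G0); C0 <- as.matrix(C0); R0 <- as.matrix(R0)
  t <- ncol(G0)
  n <- nrow(animals)
  if (is.null(trait_names)) trait_names <- paste0("y", seq_len(t))

  av <- a[animals$animal, , drop = FALSE]

  draw_effects <- function(levels) {
    m <- matrix(stats::rnorm(length(levels) * t, 0, b_sd), ncol = t,
                dimnames = list(levels, NULL))
    m
  }
  b_line <- draw_effects(unique(animals$line))
  b_sex <- draw_effects(unique(animals$sex))
  b_batch <- draw_effects(unique(animals$batch))
  pens <- unique(animals$pen_id)
  cmat <- if (all(C0 == 0)) matrix(0, length(pens), t)
          else matrix(stats::rnorm(length(pens) * t), length(pens), t) %*% chol(C0)
  rownames(cmat) <- pens
  e <- if (all(R0 == 0)) matrix(0, n, t)
       else matrix(stats::rnorm(n * t), n, t) %*% chol(R0)

  wcen <- animals$mixing_weight_kg - mean(animals$mixing_weight_kg)
  y <- b_line[animals$line, , drop = FALSE] +
       b_sex[animals$sex, , drop = FALSE] +
       b_batch[animals$batch, , drop = FALSE] +
       outer(wcen, rep(beta_weight, t)) +
       av + cmat[animals$pen_id, , drop = FALSE] + e

  out <- animals
  for (k in seq_len(t)) out[[trait_names[k]]] <- y[, k]
  list(data = out,
       truth = list(G0 = G0, C0 = C0, R0 = R0, b_line = b_line, b_sex = b_sex,
                    b_batch = b_batch, beta_weight = beta_weight,
                    c = cmat, a = av))
}

#' Simulate a complete synthetic study
#'
#' One call produces everything the pipeline consumes: pedigree, pen/batch
#' metadata, a latent-aggressiveness-driven fight network, and performance
#' phenotypes, together with the ground truth that generated them.
#' Performance traits are simulated on the published descriptive scale (test
#' and lifetime daily gain in g/d, feed intake in g/d, weights in kg, back
#' fat and loin depth in mm), each under the animal model with moderate
#' heritability.
#'
#' @param cfg A `sim_config`.
#' @param seed Master seed; sub-stage seeds are derived deterministically.
#' @param perf_h2,perf_c2 Variance ratios of the simulated performance
#'   traits (defaults 0.3 and 0.05).
#' @return List with `ped`, `animals`, `fights`, `performance`, `u` (latent
#'   aggressiveness), `a_u` (its genetic part), `config`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1L,
                           perf_h2 = 0.3, perf_c2 = 0.05) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 6)
  ped <- simulate_pedigree(cfg, seeds[1])
  animals <- assign_pens(ped, cfg, seeds[2])

  fp <- cfg$fight
  a_u <- simulate_breeding_values(ped, matrix(1), seeds[3])[, 1]
  set.seed(seeds[4])
  sig_env <- sqrt(1 / fp$u_h2 - 1)
  u <- a_u[animals$animal] + stats::rnorm(nrow(animals), 0, sig_env)
  names(u) <- animals$animal
  fights <- simulate_fight_network(animals, u, fp, seeds[5])

  # performance traits on the published descriptive scale
  perf_means <- c(TDG = 887.5, LDG = 695.9, DFI = 2280, FE = 0.39,
                  FBW = 120.1, HCW = 94.1, BF = 18.0, LD = 62.2)
  perf_sds <- c(TDG = 117.4, LDG = 75.1, DFI = 290, FE = 0.05,
                FBW = 12.0, HCW = 9.0, BF = 4.3, LD = 8.9)
  set.seed(seeds[6])
  pseeds <- sample.int(.Machine$integer.max - 1L, 2 * length(perf_means))
  perf <- data.frame(animal = animals$animal, stringsAsFactors = FALSE)
  for (k in seq_along(perf_means)) {
    vp <- perf_sds[k]^2
    ak <- simulate_breeding_values(ped, matrix(vp * perf_h2), pseeds[2 * k - 1])
    sim <- simulate_phenotypes(animals, ak, G0 = vp * perf_h2,
                               C0 = vp * perf_c2,
                               R0 = vp * (1 - perf_h2 - perf_c2),
                               seed = pseeds[2 * k],
                               b_sd = 0.25 * perf_sds[k])
    perf[[names(perf_means)[k]]] <- sim$data$y1 + perf_means[k]
  }

  list(ped = ped, animals = animals, fights = fights, performance = perf,
       u = u, a_u = a_u, config = cfg)
}

#' Write a simulated study to the standard input CSVs
#'
#' @param study Output of [simulate_study()].
#' @param dir Directory to write `pedigree.csv`, `animals.csv`,
#'   `fights.csv`, `performance.csv` and `ground_truth.csv` into.
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ped <- study$ped
  lab <- function(i) ifelse(i == 0L, "0", ped$label[pmax(i, 1L)])
  paths <- c(
    pedigree = file.path(dir, "pedigree.csv"),
    animals = file.path(dir, "animals.csv"),
    fights = file.path(dir, "fights.csv"),
    performance = file.path(dir, "performance.csv"),
    truth = file.path(dir, "ground_truth.csv")
  )
  write_csv_plain(data.frame(animal = ped$label, sire = lab(ped$sire),
                             dam = lab(ped$dam)), paths["pedigree"])
  write_csv_plain(study$animals, paths["animals"])
  write_csv_plain(study$fights, paths["fights"])
  write_csv_plain(study$performance, paths["performance"])
  write_csv_plain(data.frame(animal = study$animals$animal,
                             u = unname(study$u[study$animals$animal]),
                             a_u = unname(study$a_u[study$animals$animal])),
                  paths["truth"])
  invisible(paths)
}
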