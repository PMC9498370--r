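# Synthetic-data generator: pedigree construction, breeding values, pen
# assignment, fight networks and phenotypes.

test_that("simulated pedigree matches the configured study design", {
  cfg <- sim_config()
  ped <- simulate_pedigree(cfg, seed = 1)
  expect_equal(nrow(ped), 4104)
  role <- attr(ped, "role")
  expect_equal(sum(role == "offspring"), 900)
  expect_equal(sum(role == "parent"), 116 + 391)
  # every offspring has both parents inside the pedigree
  off <- which(role == "offspring")
  expect_true(all(ped$sire[off] > 0 & ped$dam[off] > 0))
  # distinct sires/dams actually used
  expect_lte(length(unique(ped$sire[off])), 116)
  expect_equal(length(unique(ped$dam[off])) <= 391, TRUE)
  # determinism
  ped2 <- simulate_pedigree(cfg, seed = 1)
  expect_identical(ped$label, ped2$label)
  expect_identical(ped$sire, ped2$sire)
})

test_that("breeding values follow the pedigree covariance structure", {
  # founder-only: variance matches G0
  ped <- as_pedigree(data.frame(animal = 1:10000, sire = 0, dam = 0))
  a <- simulate_breeding_values(ped, matrix(1), seed = 2)
  expect_equal(var(a[, 1]), 1, tolerance = 0.05)

  # zero genetic variance -> all zero
  expect_true(all(simulate_breeding_values(ped, matrix(0), seed = 3) == 0))

  # parent-offspring covariance ~ 0.5 G0 over many trios
  n <- 6000
  trio <- data.frame(animal = seq_len(3 * n), sire = 0, dam = 0)
  trio$sire[2 * n + seq_len(n)] <- seq_len(n)
  trio$dam[2 * n + seq_len(n)] <- n + seq_len(n)
  pedt <- as_pedigree(trio)
  at <- simulate_breeding_values(pedt, matrix(1), seed = 4)
  expect_equal(cov(at[seq_len(n), 1], at[2 * n + seq_len(n), 1]), 0.5,
               tolerance = 0.06)
  # offspring variance also 1 under non-inbred parents
  expect_equal(var(at[2 * n + seq_len(n), 1]), 1, tolerance = 0.06)
})

test_that("pen assignment is single-sex, balanced and batch-structured", {
  cfg <- sim_config()
  ped <- simulate_pedigree(cfg, seed = 5)
  for (s in 1:3) {
    an <- assign_pens(ped, cfg, seed = s)
    expect_equal(nrow(an), 900)
    expect_equal(sum(an$sex == "female"), 450)
    expect_equal(length(unique(an$pen_id)), 50)
    expect_true(all(table(an$pen_id) == 18))
    mixed <- tapply(an$sex, an$pen_id, function(x) length(unique(x)))
    expect_true(all(mixed == 1))
    expect_equal(length(unique(an$batch)), 9)
    expect_lte(length(unique(an$line)), 9)
    expect_true(all(an$mixing_weight_kg > 0))
  }
})

test_that("fight incidence follows the logistic model in the null case", {
  cfg <- sim_config()
  ped <- simulate_pedigree(cfg, seed = 6)
  an <- assign_pens(ped, cfg, seed = 6)
  u <- setNames(rnorm(nrow(an)), an$animal)

  # lambda = kappa = 0: density = plogis(alpha), binomial check
  fp <- fight_params(alpha = -2, lambda = 0, kappa = 0)
  f <- simulate_fight_network(an, u, fp, seed = 7)
  n_dyads <- 50 * choose(18, 2)
  phat <- nrow(f) / n_dyads
  p0 <- plogis(-2)
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / n_dyads))
  expect_true(all(f$duration_s >= 1))

  # alpha -> -Inf: empty network
  f0 <- simulate_fight_network(an, u, fight_params(alpha = -50), seed = 8)
  expect_equal(nrow(f0), 0L)

  # positive genetic loading: aggressive animals accumulate weighted degree
  fpos <- simulate_fight_network(an, u, fight_params(alpha = -3, lambda = 1,
                                                     kappa = 0.5), seed = 9)
  tr <- compute_sna_traits(fpos, an)
  rho <- cor(u[tr$animal], tr$weighted_degree, method = "spearman")
  expect_gt(rho, 0.2)

  # determinism
  f1 <- simulate_fight_network(an, u, fp, seed = 7)
  expect_identical(f, f1)
})

test_that("phenotypes follow y = Xb + Za + Wc + e", {
  st <- small_study(seed = 13)
  a <- simulate_breeding_values(st$ped, matrix(0.4), 131)

  # noise-free limit: y equals the breeding value exactly
  sim0 <- simulate_phenotypes(st$animals, a, 0.4, 0, 0, seed = 132, b_sd = 0)
  expect_equal(sim0$data$y1, unname(a[st$animals$animal, 1]))

  # intraclass correlation within pens ~ c2 when animals are unrelated
  ped <- as_pedigree(data.frame(animal = sprintf("U%04d", 1:2000),
                                sire = 0, dam = 0))
  an <- data.frame(animal = ped$label,
                   pen_id = rep(sprintf("p%03d", 1:100), each = 20),
                   line = "L1", sex = "female", batch = "B1",
                   mixing_weight_kg = 30)
  au <- simulate_breeding_values(ped, matrix(0), 133)
  simc <- simulate_phenotypes(an, au, 0, 0.3, 0.7, seed = 134, b_sd = 0)
  y <- simc$data$y1
  pen_means <- tapply(y, an$pen_id, mean)
  between <- var(pen_means) - 0.7 / 20     # bias-correct the within part
  expect_equal(between / (between + 0.7), 0.3, tolerance = 0.25)

  # determinism
  simr <- simulate_phenotypes(st$animals, a, 0.4, 0.1, 0.5, seed = 135)
  simr2 <- simulate_phenotypes(st$animals, a, 0.4, 0.1, 0.5, seed = 135)
  expect_identical(simr$data, simr2$data)
})

test_that("simulate_study writes a consistent, readable input set", {
  st <- small_study(seed = 14)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  an <- read_animal_metadata(file.path(dir, "animals.csv"))
  expect_equal(nrow(an), 120)
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(nrow(ped), nrow(st$ped))
  fights <- read_fight_records(file.path(dir, "fights.csv"), pen_rosters(an))
  expect_equal(nrow(fights), nrow(st$fights))
  perf <- read_performance(file.path(dir, "performance.csv"))
  expect_equal(names(perf), c("animal", perf_trait_names()))
  expect_true(all(is.finite(perf$TDG)))
})
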