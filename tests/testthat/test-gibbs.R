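# Animal-model machinery: design assembly, reproducibility and the sampler's
# behaviour on constructed data. Full-scale parameter recovery lives in
# test-acceptance.R; these tests run on a compact study.

test_that("design assembly applies corner constraints and centers the covariate", {
  st <- small_study(seed = 5)
  a <- simulate_breeding_values(st$ped, matrix(0.3), 51)
  sim <- simulate_phenotypes(st$animals, a, 0.3, 0.1, 0.6, seed = 52)
  asm <- assemble_design(sim$data, "y1", st$ped)

  # intercept + (3-1) lines + (2-1) sex + (3-1) batches + covariate
  expect_equal(ncol(asm$X), 1 + 2 + 1 + 2 + 1)
  expect_equal(nrow(asm$X), 120)
  expect_equal(mean(asm$X[, "mixing_weight_kg"]), 0, tolerance = 1e-10)
  expect_equal(qr(asm$X)$rank, ncol(asm$X))

  # 900-record full design: 1 + 8 lines + 1 sex + 8 batches + 1 covariate
  st2 <- simulate_study(sim_config(), seed = 6)
  a2 <- simulate_breeding_values(st2$ped, matrix(0.3), 61)
  sim2 <- simulate_phenotypes(st2$animals, a2, 0.3, 0.1, 0.6, seed = 62)
  asm2 <- assemble_design(sim2$data, "y1", st2$ped)
  expect_equal(ncol(asm2$X), 19)

  sim$data$y1 <- NA_real_
  expect_error(assemble_design(sim$data, "y1", st$ped), "missing")
})

test_that("identical seed and config give bit-identical chains", {
  st <- small_study(seed = 7)
  a <- simulate_breeding_values(st$ped, matrix(0.3), 71)
  sim <- simulate_phenotypes(st$animals, a, 0.3, 0.1, 0.6, seed = 72)
  asm <- assemble_design(sim$data, "y1", st$ped)
  ai <- ainverse(st$ped)
  cfg <- gibbs_config(n_iter = 3000, burn_in = 500, thin = 5, seed = 99)
  ch1 <- gibbs_run(asm, ai, config = cfg)
  ch2 <- gibbs_run(asm, ai, config = cfg)
  expect_identical(ch1$draws, ch2$draws)
  cfg2 <- cfg; cfg2$seed <- 100
  ch3 <- gibbs_run(asm, ai, config = cfg2)
  expect_false(identical(ch1$draws, ch3$draws))
  # saved draw count honours the thinning arithmetic
  expect_equal(nrow(ch1$draws), (3000 - 500) / 5)
})

test_that("frozen-location variance draws follow the analytic inverse Wishart", {
  st <- small_study(seed = 8)
  a <- simulate_breeding_values(st$ped, matrix(0.35), 81)
  sim <- simulate_phenotypes(st$animals, a, 0.35, 0.1, 0.55, seed = 82)
  asm <- assemble_design(sim$data, "y1", st$ped)
  ai <- ainverse(st$ped)
  q <- nrow(ai); npen <- length(asm$pen_levels)
  set.seed(83)
  a_init <- matrix(rnorm(q, 0, 0.5), q, 1)
  c_init <- matrix(rnorm(npen, 0, 0.3), npen, 1)
  ch <- gibbs_run(asm, ai,
                  config = gibbs_config(n_iter = 10000, burn_in = 0,
                                        thin = 1, seed = 84),
                  update_location = FALSE, a_init = a_init, c_init = c_init)
  SS <- as.numeric(t(a_init) %*% ai %*% a_init)
  # x ~ IW_1(q - 2, SS)  <=>  SS / x ~ chi-square(q - 2)
  ks <- ks.test(SS / ch$draws[, "G0_11"], "pchisq", df = q - 2)
  expect_gt(ks$p.value, 0.01)
  ksc <- ks.test(sum(c_init^2) / ch$draws[, "C0_11"], "pchisq", df = npen - 2)
  expect_gt(ksc$p.value, 0.01)
})

test_that("tight informative priors dominate a degenerate all-zero response", {
  st <- small_study(seed = 9)
  d <- st$animals
  d$y1 <- 0
  asm <- assemble_design(d, "y1", st$ped)
  pri <- default_priors(1, nu = 200, s = 200 * 0.02)
  ch <- gibbs_run(asm, ainverse(st$ped), priors = pri,
                  config = gibbs_config(n_iter = 4000, burn_in = 1000,
                                        thin = 3, seed = 91))
  # every component shrinks to the prior scale (~0.02 / each), so Vp stays tiny
  expect_lt(mean(derive_ratios(ch)$Vp), 0.1)
})

test_that("run_all_models produces the expected chain set deterministically", {
  st <- small_study(seed = 10)
  G0 <- diag(c(0.3, 0.3)); C0 <- diag(c(0.1, 0.1)); R0 <- diag(c(0.6, 0.6))
  a <- simulate_breeding_values(st$ped, G0, 101)
  sim <- simulate_phenotypes(st$animals, a, G0, C0, R0, seed = 102)
  cfg <- gibbs_config(n_iter = 600, burn_in = 100, thin = 5, seed = 7)
  chains <- run_all_models(sim$data, c("y1", "y2"), st$ped, config = cfg,
                           partner_traits = "mixing_weight_kg")
  # 2 univariate + 1 pair + 2 cross models
  expect_setequal(names(chains),
                  c("y1", "y2", "y1:y2", "y1:mixing_weight_kg",
                    "y2:mixing_weight_kg"))
  chains2 <- run_all_models(sim$data, c("y1", "y2"), st$ped, config = cfg,
                            partner_traits = "mixing_weight_kg")
  expect_identical(chains$`y1:y2`$draws, chains2$`y1:y2`$draws)
  # univariate-only mode
  uni <- run_all_models(sim$data, c("y1", "y2"), st$ped, config = cfg,
                        pairs = FALSE)
  expect_equal(names(uni), c("y1", "y2"))
})

test_that("bivariate records missing one trait are retained by augmentation", {
  st <- small_study(seed = 12)
  G0 <- matrix(c(0.3, 0.15, 0.15, 0.3), 2)
  a <- simulate_breeding_values(st$ped, G0, 121)
  sim <- simulate_phenotypes(st$animals, a, G0, diag(c(0.1, 0.1)),
                             diag(c(0.6, 0.6)), seed = 122)
  d <- sim$data
  d$y2[1:30] <- NA
  asm <- assemble_design(d, c("y1", "y2"), st$ped)
  expect_equal(nrow(asm$Y), 120)          # nothing dropped
  expect_equal(sum(!asm$obs[, 2]), 30)
  ch <- gibbs_run(asm, ainverse(st$ped),
                  config = gibbs_config(n_iter = 2000, burn_in = 500,
                                        thin = 5, seed = 123))
  r <- derive_ratios(ch)
  expect_true(all(is.finite(r$rg)))
  expect_true(all(abs(r$rg) <= 1))
})
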