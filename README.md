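# snaherit

Quantitative genetics of social-network behaviour traits derived from
dyadic fight records in group-housed pigs.

When unfamiliar pigs are mixed into a new pen they fight to establish
dominance, which damages welfare and performance. Social network analysis
(SNA) turns the observed reciprocal fights of a pen into a weighted graph —
animals as nodes, edges weighted by total fight duration in seconds — and
scores each animal's role in the pen's aggression with six traits: degree
centrality, weighted degree (strength), betweenness, closeness, eigenvector
centrality and the local clustering coefficient. If those scores are
heritable, and not antagonistically correlated with production traits, they
are candidates for selective breeding against harmful aggression.

`snaherit` implements that full analysis as a reusable, tested pipeline for
geneticists working with pen-level behaviour data:

- **Networks and traits** — per-pen weighted aggression graphs over the
  full roster (non-fighters enter as isolated nodes and score zero), the
  six SNA traits with explicit normalization conventions, and their
  square-root transforms.
- **Kinship** — inbreeding coefficients (Meuwissen–Luo), the additive
  relationship matrix **A** by the tabular method, and Henderson's sparse
  **A**⁻¹ built directly from the pedigree.
- **Genetic model** — univariate and bivariate Bayesian animal models

  y = Xb + Za + Wc + e,&nbsp;&nbsp; a ~ N(0, A ⊗ G₀),&nbsp; c ~ N(0, I ⊗ C₀),&nbsp; e ~ N(0, I ⊗ R₀)

  fitted by Gibbs sampling (Rcpp core; single-site Gaussian conditionals
  for b, a, c and inverse-Wishart conditionals for G₀, C₀, R₀, flat priors
  by default). Fixed effects: genetic line, sex, batch, and body weight at
  mixing as a covariate. Bivariate records missing one trait are kept by
  residual-conditional data augmentation.
- **Posterior summaries** — per-draw heritability h² = σ²ₐ/(σ²ₐ+σ²c+σ²ₑ),
  common-pen effect c², phenotypic variance Vp, genetic correlations
  r_g = σₐ₁₂/√(σ²ₐ₁σ²ₐ₂), shortest-window HPD95% intervals, a Geweke
  convergence diagnostic, effective sample sizes, and Spearman phenotypic
  correlations.
- **Synthetic studies** — a generator that emulates the target study design
  (900 focal pigs from 116 sires and 391 dams in a 4104-animal pedigree, 50
  single-sex pens of 18 across 9 batches) with heritable latent
  aggressiveness driving sparse weighted fight networks, so every stage can
  be validated against known ground truth.

## Worked example

Simulate a compact study, estimate the heritability of square-root
weighted degree, and summarize:

```r
library(snaherit)

cfg <- sim_config(n_sires = 8, n_dams = 24, n_offspring = 120, n_pens = 12,
                  pen_size = 10, n_pedigree = 200, n_gsires = 10,
                  n_gdams = 20, n_batches = 3, n_lines = 3)
st  <- simulate_study(cfg, seed = 1)

traits <- compute_sna_traits(st$fights, st$animals)
d   <- merge(st$animals, traits[c("animal", "t_weighted_degree")], by = "animal")
asm <- assemble_design(d, "t_weighted_degree", st$ped)
ch  <- gibbs_run(asm, ainverse(st$ped), config = gibbs_config_test(seed = 2))
summarize_univariate(ch)[c("trait", "h2_mean", "h2_lo", "h2_hi", "c2_mean")]
```

```
              trait   h2_mean     h2_lo     h2_hi    c2_mean
1 t_weighted_degree 0.4823617 0.1406304 0.9571063 0.09213326
```

The posterior mean heritability of transformed weighted degree in this
small simulated herd is 0.48, but the HPD95% interval (0.14, 0.96) is very
wide: 120 animals from 8 sires carry little information about a variance
ratio, which is exactly why the interval matters more than the point
estimate at this scale. At the full study scale (900 records, 116 sires)
the same pipeline recovers simulated heritabilities to within about ±0.1
with far tighter intervals — see the methods vignette.

The complete analysis (6 univariate + 15 SNA-pair + 48 SNA×performance
bivariate models, summary tables, Spearman matrix, chain files, manifest)
runs with one call:

```r
run_pipeline(fights = "fights.csv", animals = "animals.csv",
             pedigree = "pedigree.csv", performance = "performance.csv",
             out_dir = "out", config = gibbs_config_test(seed = 1))
report("out")
```

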