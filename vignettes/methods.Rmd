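---
title: "Methods: network traits of pen aggression and their genetic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network traits of pen aggression and their genetic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mixing unfamiliar pigs triggers fighting. A pen's 24 hours of post-mixing
reciprocal fights — pairs of animals, each pair's total fight duration in
seconds — define a weighted undirected graph per pen, and each animal's
position in that graph is summarized by six social-network traits. The
scientific questions are quantitative-genetic: how heritable are these
traits, how large is the shared-pen environmental effect, and how are they
genetically correlated with each other and with production traits? This
vignette documents the modelling choices, defaults, numerical details and
limitations of the package's answer to those questions.

## Network traits

Each pen's graph contains the **full roster**: animals that never fought are
isolated nodes and legitimately score zero on all six traits. This is not a
missing-data convention — a pig that avoided all fights is a real, and from
a breeding perspective desirable, phenotype; dropping such animals would
both bias the traits upward and hide exactly the animals of interest.

For a pen of $n$ animals, writing $w_{ij} \ge 0$ for the total fight
duration of pair $(i,j)$:

* **Degree centrality**: number of distinct opponents, normalized by $n-1$.
* **Weighted degree (strength)**: $\sum_j w_{ij}$, in seconds.
* **Betweenness**: fraction of all-pairs weighted shortest paths passing
  through the animal (fractional credit across equally short paths),
  normalized by $(n-1)(n-2)/2$.
* **Closeness**: for an animal reaching $m$ others at total shortest-path
  cost $S$, the score is $(m/S)\cdot m/(n-1)$ — the within-component
  closeness scaled by the reachable fraction (the Wasserman–Faust
  correction). On a connected graph this is the classic $(n-1)/S$; an
  isolated animal scores 0. Without the correction closeness is undefined
  or discontinuous on the disconnected graphs that sparse fight networks
  produce routinely.
* **Eigenvector centrality**: leading-eigenvector score of the weighted
  adjacency matrix, rescaled to a maximum of 1. It is computed by power
  iteration after adding a diagonal shift equal to the largest row sum.
  The shift leaves eigenvectors unchanged but makes the dominant
  eigenvalue strictly largest in magnitude, so the iteration also
  converges on bipartite-like components (a star graph, for instance, has
  spectrum symmetric about zero and defeats unshifted power iteration).
  Tolerance is $10^{-12}$ on the sup-norm change with a 50,000-step cap —
  deliberately conservative so scores are accurate to well below $10^{-9}$
  even when the spectral gap is small. In disconnected graphs the score is
  carried by the component with the largest leading eigenvalue; other
  components decay to zero, which should be kept in mind when comparing
  animals across components of the same pen.
* **Clustering coefficient**: the fraction of an animal's opponent pairs
  that also fought each other, computed on the unweighted topology
  (definition: a *proportion of connections*); a duration-weighted variant
  (Barrat) is available via `clustering_mode = "barrat"`. Animals with
  fewer than two opponents score 0.

**Path costs.** Betweenness and closeness need a travel cost per edge. The
default treats the fight duration itself as the cost (`weight_mode =
"cost"`), which is the default behaviour of the graph library this field
uses for these analyses; `weight_mode = "inverse"` (cost $=1/w$, long
fights = strong ties = short distances) is provided because both
conventions appear in the animal-network literature. The choice changes
the meaning of "close": under the default, an animal is close if it can be
reached through *short* fights.

All six traits are strongly right-skewed in sparse fight networks (most
animals fight little or not at all), so the square-root transform of each
raw trait (`t_` columns) is what enters the genetic analysis. All raw
traits are nonnegative, so no shift is needed.

## Kinship

The additive relationship matrix $A$ is built by the tabular recursion,
inbreeding by the Meuwissen–Luo algorithm (verified to equal the tabular
diagonal exactly), and $A^{-1}$ directly by Henderson's rules with
inbreeding: animal $i$ with parents $s,d$ contributes
$\alpha_i = 1/(0.5 - 0.25(F_s + F_d))$ to a $3\times 3$ block over
$\{i,s,d\}$, with $F=-1$ for an unknown parent. $A$ is never inverted
densely: at a pedigree of 4104 animals the sparse construction is what
makes the Gibbs sampler's genetic updates cheap. Unknown parents are
unrelated phantom founders; genetic groups are out of scope. The pedigree
is sorted by a stable topological sort (ties broken by input order) so
matrix indices are reproducible run to run.

## The animal model and its sampler

For one or two traits,

$$y = Xb + Za + Wc + e, \qquad
a \sim N(0,\,A \otimes G_0),\quad c \sim N(0,\,I \otimes C_0),\quad
e \sim N(0,\,I \otimes R_0).$$

Fixed effects are genetic line, sex and batch (corner constraints,
first level as reference — variance components are invariant to this
choice) plus centered body weight at mixing as a covariate. Random
effects are the additive genetic effect of every pedigree animal and an
iid common-pen effect.

The Gibbs sampler (Rcpp) cycles per iteration: single-site Gaussian draws
for every fixed-effect coefficient, every animal's breeding value (using
only its $A^{-1}$ row, so a sweep costs $O(\mathrm{nnz}(A^{-1}))$), and
every pen effect; then inverse-Wishart draws
$G_0 \mid a \sim \mathrm{IW}(q + \nu_g,\, a'A^{-1}a + S_g)$ and analogous
conditionals for $C_0$ (pens) and $R_0$ (records). All randomness flows
from R's RNG, so a seed makes chains bit-reproducible. Single-site
location sampling was chosen for simplicity and verifiability; it mixes
adequately at this scale (effective sample sizes of several hundred from
the test preset), and block updates would be an optimization, not a
correctness change.

**Priors.** The default is the flat prior on each covariance matrix,
expressed as $\nu = -(t+1)$, $S = 0$, giving conditional degrees of
freedom $q - t - 1$. A caution from this package's own validation: the
superficially "vague" proper prior $\mathrm{IW}(t+1,\ \varepsilon I)$ with
tiny $\varepsilon$ is *not* a flat limit — its density is
$\propto |G|^{-(t+1)}$ with essentially all mass below $\varepsilon$, and
on data where the variance partition is weakly identified it pushes
components to zero hard enough to collapse the chain into a degenerate
$h^2 \to 1$ state (observed with two independent sampler implementations
before the default was corrected). Informative priors remain available
through `default_priors(t, nu, s)` and are the right tool for degenerate
inputs (e.g. a constant response).

**Missing bivariate records.** Rows missing both traits are dropped; rows
missing one trait are kept and the missing residual is drawn each
iteration from its conditional given the observed trait's residual and the
current $R_0$ (data augmentation), so trait pairs with different
missingness patterns use all available records.

**MCMC settings.** The full-scale preset is 1,000,000 iterations, 100,000
burn-in, thinning 20. The test preset — used throughout the test suite and
the validation script — is 20,000/2,000/10, which at the emulated study
scale (900 records, pedigree 4104) runs in roughly ten seconds per
univariate chain and yields posterior means stable to well within the
tolerances being tested. Convergence is monitored with a Geweke z-score
(first 10% vs last 50%, spectral variance at frequency zero from an
AIC-selected AR fit) and effective sample size; any accepted MCMC
diagnostic would serve, and this one was chosen for being standard,
self-contained and testable (calibrated on iid chains, triggered by
injected trends).

## Posterior summaries

$h^2$, $c^2$, $V_p$ and correlations are computed **per draw** and then
summarized, never from posterior-mean components — ratios of means are not
means of ratios, and the per-draw route preserves the full posterior
uncertainty that the HPD intervals report. The HPD95% interval is the
shortest window over the sorted draws containing $\lceil 0.95 n\rceil$
points (leftmost on ties), exact for unimodal empirical posteriors. A
correlation is flagged significant when its HPD95% excludes zero, with a
boundary exactly at zero counting as inclusion. Phenotypic associations
use Spearman rank correlations (average ranks for ties, pairwise-complete)
— deliberately rank-based, so they are identical for raw and square-root
transformed traits.

## The synthetic study generator

Because the real data are proprietary, the generator reproduces the study
*design* as its defaults: 900 focal animals (450 female, 450 castrate),
progeny of 116 sires and 391 dams; 50 single-sex pens of 18 across 9
batches; 9 genetic lines inherited from the sire; mixing weight
$\sim N(30, 4^2)$ kg truncated positive (pigs mixed at about ten weeks).
The pedigree has founder grandparents and a parent generation; since
unique grandparents alone cannot reach the reported pedigree size of 4104,
the gap is filled with founder-generation progeny — relatives without
records, as real pedigrees contain. Breeding values descend the pedigree
as parent average plus Mendelian sampling with variance
$(0.5 - 0.25(F_s+F_d))\,G_0$, so their covariance is $A \otimes G_0$ by
construction.

**Fight model.** The observation process is modelled generatively (the
source study recorded fights but did not model them): each within-pen dyad
fights with probability $\mathrm{logit}^{-1}(\alpha + \lambda(u_i+u_j))$
and, if it fights, for a total duration
$\mathrm{LogNormal}(\mu + \kappa(u_i+u_j), \sigma)$ seconds floored at 1 s
(sub-second exchanges do not count as reciprocal fights). The latent
aggressiveness $u$ is a unit-variance breeding value plus independent
noise with heritability `u_h2`. Defaults
($\alpha=-4.4, \lambda=0.6, \mu=2.5, \kappa=0.3, \sigma=1, u_{h^2}=0.5$)
were fixed once to reproduce the published descriptive character of the
transformed traits — means near 0.10/2.3/0.02/0.15 for transformed degree,
weighted degree, closeness and eigenvector centrality, about two-thirds
structural zeros, right-skewed durations — and are not tuned to any
estimation outcome. The heritability this induces in the network traits
themselves is *emergent* (posterior means around 0.08–0.19 for transformed
weighted degree across seeds) and is asserted in tests only
qualitatively: its HPD95% lower bound exceeds zero.

What the generator does **not** emulate: dominance-hierarchy dynamics,
winner/loser effects, temporal bout structure, litter-environment effects
(litters appear only through the pedigree), or attacker/receiver
asymmetry. Passing tests on this generator therefore demonstrate that the
estimation machinery is correct under the stated model, not that the model
captures all structure of real pens.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route: the six
traits against exhaustive brute force (all-simple-path enumeration,
Floyd–Warshall, dense eigendecomposition, direct counting) on hundreds of
random graphs of up to 7 nodes; kinship against textbook cases and dense
inversion on random pedigrees of up to 200 animals; the variance sampler
against its analytic inverse-Wishart conditional with location effects
frozen (Kolmogorov–Smirnov); and the full estimator by parameter recovery
at study scale — truth $(h^2, c^2) = (0.35, 0.10)$ recovered within
$\pm 0.10$ with HPD95% coverage in at least 4 of 5 seeds, a null
($\sigma^2_a = 0$) posterior mean $h^2$ below 0.05, a dominant pen
scenario ($c^2 = 0.80$) recovered within $\pm 0.10$, a bivariate
$r_g = -0.8$ recovered within $\pm 0.15$, and a trait duplicated with
small jitter forced above 0.9. One seed in five at study scale can
legitimately miss the $\pm 0.10$ band: the per-seed posterior SD of $h^2$
at this design is itself about 0.08–0.10 (confirmed by extending one such
chain tenfold — the posterior, not the chain, was off-center), which is
why the recovery criterion is framed over seeds rather than per seed.

## Known limitations

* Closeness and clustering depend strongly on pen-level structure; their
  genetic analysis inherits that fragility (the emulated study itself
  reports $c^2 = 0.80$ for closeness).
* The sampler supports at most two traits; the analysis is a series of
  univariate and bivariate models, not a joint multi-trait fit, so
  correlation estimates from different pairs need not form a positive
  definite matrix.
* No maternal, litter or dominance genetic effects; no genomic
  relationships; no multiple-testing adjustment across the 63 bivariate
  models (matching the analysis being emulated).
* Bivariate genetic correlations from 900 records are weakly identified;
  HPD intervals spanning most of $[-1, 1]$ are the honest norm, and the
  significance flag, not the point estimate, is the reportable result.
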