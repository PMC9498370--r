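# Posterior summaries: variance ratios per draw, highest posterior density
# intervals, convergence diagnostics, and Spearman phenotypic correlations.

#' Per-draw variance ratios and correlations from a chain
#'
#' Computes the derived quantities draw by draw (never from posterior-mean
#' components, so the full posterior uncertainty is preserved). For a
#' univariate chain: heritability `h2 = s2a / (s2a + s2c + s2e)`, common pen
#' effect `c2 = s2c / Vp` and phenotypic variance `Vp`. For a bivariate
#' chain additionally the genetic, pen and residual correlations of the
#' trait pair, plus each trait's own h2.
#'
#' @param chain An `mcmc_chain` from [gibbs_run()].
#' @return Data frame with one row per saved draw.
#' @export
derive_ratios <- function(chain) {
  d <- chain$draws
  t <- length(chain$traits)
  if (nrow(d) == 0L) stop("empty chain")
  if (t == 1L) {
    vp <- d[, "G0_11"] + d[, "C0_11"] + d[, "R0_11"]
    if (any(vp <= 0)) stop("zero total variance in a draw")
    data.frame(h2 = d[, "G0_11"] / vp, c2 = d[, "C0_11"] / vp, Vp = vp)
  } else {
    vp1 <- d[, "G0_11"] + d[, "C0_11"] + d[, "R0_11"]
    vp2 <- d[, "G0_22"] + d[, "C0_22"] + d[, "R0_22"]
    if (any(vp1 <= 0) || any(vp2 <= 0)) stop("zero total variance in a draw")
    data.frame(
      h2_1 = d[, "G0_11"] / vp1,
      h2_2 = d[, "G0_22"] / vp2,
      rg = d[, "G0_12"] / sqrt(d[, "G0_11"] * d[, "G0_22"]),
      rc = d[, "C0_12"] / sqrt(d[, "C0_11"] * d[, "C0_22"]),
      re = d[, "R0_12"] / sqrt(d[, "R0_11"] * d[, "R0_22"]),
      Vp_1 = vp1, Vp_2 = vp2
    )
  }
}

#' Highest posterior density interval
#'
#' Shortest contiguous window over the sorted samples that contains
#' `ceiling(mass * n)` points; the leftmost window is returned on ties.
#' Exact for unimodal empirical posteriors.
#'
#' @param samples Numeric vector of posterior draws (at least 100).
#' @param mass Target probability mass (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 100L) stop("need at least 100 samples for an HPD interval")
  stopifnot(mass > 0, mass <= 1)
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)  # which.min returns the first (leftmost) minimum
  c(x[i], x[i + m - 1L])
}

#' Does an interval exclude zero?
#'
#' The convention of the analysis: a correlation is declared significant
#' when its HPD95 interval does not include zero; a boundary exactly at zero
#' counts as inclusion.
#'
#' @param lower,upper Interval bounds, `lower <= upper`.
#' @return Logical.
#' @export
significance_flag <- function(lower, upper) {
  stopifnot(all(lower <= upper))
  lower > 0 | upper < 0
}

#' Geweke convergence diagnostic
#'
#' Z-score comparing the mean of the first `frac1` of the chain with the
#' mean of the last `frac2`, using spectral density estimates of the
#' variance at frequency zero (autoregressive fit) so autocorrelation is
#' accounted for. |z| well above 2-3 indicates the chain has not reached
#' stationarity.
#'
#' @param samples Numeric chain (at least 1000 samples).
#' @param frac1,frac2 Window fractions (defaults 0.1 and 0.5).
#' @return The z score.
#' @export
geweke_diagnostic <- function(samples, frac1 = 0.1, frac2 = 0.5) {
  n <- length(samples)
  if (n < 1000L) stop("need at least 1000 samples")
  if (stats::var(samples) == 0) stop("degenerate (constant) chain")
  x1 <- samples[seq_len(floor(frac1 * n))]
  x2 <- samples[(n - floor(frac2 * n) + 1L):n]
  s1 <- spectrum0_ar(x1)
  s2 <- spectrum0_ar(x2)
  if (!is.finite(s1) || !is.finite(s2) || s1 <= 0 || s2 <= 0)
    stop("degenerate spectral density estimate")
  (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
}

# Spectral density at frequency zero via an AIC-selected AR fit.
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  fit <- try(stats::ar(x, aic = TRUE, order.max = min(50L, length(x) %/% 4L)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(v)
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Effective sample size of a chain
#'
#' `n * var(x) / spectral density at 0`, capped at n.
#'
#' @param samples Numeric chain.
#' @return Effective number of independent draws.
#' @export
effective_size <- function(samples) {
  s0 <- spectrum0_ar(samples)
  if (s0 <= 0) return(0)
  min(length(samples), length(samples) * stats::var(samples) / s0)
}

#' Spearman rank correlation matrix
#'
#' Pairwise-complete Spearman correlations with average ranks for ties, the
#' standard choice for the skewed network traits. Columns with fewer than 3
#' complete pairs against a partner, or zero rank variance, yield NA.
#'
#' @param data Data frame holding the trait columns.
#' @param columns Character vector of column names to correlate.
#' @return Symmetric matrix of Spearman rho with the columns as dimnames.
#' @export
spearman_matrix <- function(data, columns) {
  miss <- setdiff(columns, names(data))
  if (length(miss) > 0L) stop("column(s) not found: ", paste(miss, collapse = ", "))
  k <- length(columns)
  R <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  for (i in seq_len(k)) {
    R[i, i] <- 1
    xi <- data[[columns[i]]]
    if (i == k) next
    for (j in seq.int(i + 1L, k)) {
      xj <- data[[columns[j]]]
      ok <- !is.na(xi) & !is.na(xj)
      if (sum(ok) < 3L) next
      if (stats::var(rank(xi[ok])) == 0 || stats::var(rank(xj[ok])) == 0) next
      R[i, j] <- R[j, i] <- stats::cor(xi[ok], xj[ok], method = "spearman")
    }
  }
  R
}

#' Summarize a univariate chain into an h2/c2/Vp table row
#'
#' @param chain Univariate `mcmc_chain`.
#' @param trait Label for the output row (defaults to the chain's trait).
#' @return One-row data frame: posterior means, HPD95 bounds for h2, c2 and
#'   Vp, posterior SD of h2, Geweke z and effective sample size of the
#'   genetic variance chain.
#' @export
summarize_univariate <- function(chain, trait = chain$traits[1]) {
  r <- derive_ratios(chain)
  h <- hpd_interval(r$h2); cc <- hpd_interval(r$c2); v <- hpd_interval(r$Vp)
  data.frame(
    trait = trait,
    h2_mean = mean(r$h2), h2_sd = stats::sd(r$h2), h2_lo = h[1], h2_hi = h[2],
    c2_mean = mean(r$c2), c2_lo = cc[1], c2_hi = cc[2],
    Vp_mean = mean(r$Vp), Vp_lo = v[1], Vp_hi = v[2],
    geweke_z = if (nrow(chain$draws) >= 1000)
      geweke_diagnostic(chain$draws[, "G0_11"]) else NA_real_,
    ess_va = effective_size(chain$draws[, "G0_11"]),
    stringsAsFactors = FALSE
  )
}

#' Summarize a bivariate chain into a genetic-correlation row
#'
#' @param chain Bivariate `mcmc_chain`.
#' @return One-row data frame: trait pair, posterior mean/SD of the genetic
#'   correlation, HPD95 bounds and the HPD-excludes-zero flag.
#' @export
summarize_bivariate <- function(chain) {
  r <- derive_ratios(chain)
  h <- hpd_interval(r$rg)
  data.frame(
    trait_a = chain$traits[1], trait_b = chain$traits[2],
    rg_mean = mean(r$rg), rg_sd = stats::sd(r$rg),
    rg_lo = h[1], rg_hi = h[2],
    significant = significance_flag(h[1], h[2]),
    stringsAsFactors = FALSE
  )
}
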