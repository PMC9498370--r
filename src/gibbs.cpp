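// Single-site Gibbs sampler for the linear animal model
//   y = Xb + Za + Wc + e,   a ~ N(0, A (x) G0), c ~ N(0, I (x) C0),
//   e ~ N(0, I (x) R0)
// for t = 1 or 2 traits. Location effects are sampled from their scalar /
// 2x2 Gaussian full conditionals derived from the mixed-model equations;
// the (co)variance matrices G0, C0, R0 are sampled from their inverse
// Wishart full conditionals. A-inverse enters through its sparse
// column-compressed representation, so the cost per sweep is O(nnz(Ainv)).
//
// All randomness comes from R's RNG (unif_rand/norm_rand family), so
// set.seed() in R makes runs bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat riwish_cpp(double df, const arma::mat& S) {
  // Draw from InvWishart(df, S): W ~ Wishart(df, S^-1) by Bartlett, return W^-1
  const int t = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat B(t, t, arma::fill::zeros);
  for (int i = 0; i < t; ++i) {
    B(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) B(i, j) = norm_rand();
  }
  arma::mat LB = L * B;
  arma::mat W = LB * LB.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// Draw x ~ N(P^-1 r, P^-1) for t<=2 without heap allocation.
static inline void draw_gaussian_site(int t, const double* P, const double* r,
                                      double* out) {
  if (t == 1) {
    double sd = 1.0 / std::sqrt(P[0]);
    out[0] = r[0] / P[0] + sd * norm_rand();
  } else {
    // 2x2: Cholesky P = L L^T, mean = P^-1 r, draw mean + L^-T z
    double l11 = std::sqrt(P[0]);
    double l21 = P[1] / l11;
    double d = P[3] - l21 * l21;
    if (d <= 0) stop("non-positive-definite conditional precision");
    double l22 = std::sqrt(d);
    // solve L w = r ; L^T m = w
    double w1 = r[0] / l11;
    double w2 = (r[1] - l21 * w1) / l22;
    double m2 = w2 / l22;
    double m1 = (w1 - l21 * m2) / l11;
    double z1 = norm_rand(), z2 = norm_rand();
    // x = m + L^-T z : solve L^T u = z
    double u2 = z2 / l22;
    double u1 = (z1 - l21 * u2) / l11;
    out[0] = m1 + u1;
    out[1] = m2 + u2;
  }
}

// [[Rcpp::export]]
List gibbs_sampler_cpp(arma::mat Y, arma::imat obs, arma::mat X,
                       IntegerVector animal, IntegerVector pen,
                       IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                       int q, int npen,
                       double nu_g, arma::mat S_g,
                       double nu_c, arma::mat S_c,
                       double nu_r, arma::mat S_r,
                       arma::mat G0, arma::mat C0, arma::mat R0,
                       int n_iter, int burn_in, int thin,
                       bool update_location,
                       arma::mat a_init, arma::mat c_init) {
  const int n = Y.n_rows;
  const int t = Y.n_cols;
  const int p = X.n_cols;
  if (t > 2) stop("at most 2 traits supported");
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");

  arma::mat b(p, t, arma::fill::zeros);
  arma::mat a = a_init;           // q x t
  arma::mat cc = c_init;          // npen x t
  arma::mat E(n, t);              // record-level residuals (augmented)

  // initialize missing entries of Y at 0 residual contribution
  for (int r = 0; r < n; ++r)
    for (int m = 0; m < t; ++m)
      E(r, m) = obs(r, m) ? (Y(r, m) - a(animal[r], m) - cc(pen[r], m)) : 0.0;
  // subtract Xb (b = 0 initially, nothing to do)

  // precompute record lists per animal and per pen
  std::vector< std::vector<int> > rec_of_animal(q), rec_of_pen(npen);
  for (int r = 0; r < n; ++r) {
    rec_of_animal[animal[r]].push_back(r);
    rec_of_pen[pen[r]].push_back(r);
  }
  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  arma::mat Ginv = arma::inv_sympd(G0);
  arma::mat Cinv = arma::inv_sympd(C0);
  arma::mat Rinv = arma::inv_sympd(R0);

  const int n_saved = (n_iter - burn_in) / thin;
  const int tc = t * (t + 1) / 2;   // stored lower-tri elements per matrix
  arma::mat out(n_saved, 3 * tc);
  arma::mat a_mean(q, t, arma::fill::zeros);
  int saved = 0;

  bool any_missing = false;
  for (int r = 0; r < n && !any_missing; ++r)
    for (int m = 0; m < t; ++m) if (!obs(r, m)) any_missing = true;

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();

    if (any_missing && t == 2) {
      // residual-conditional data augmentation for single-missing records
      double r00 = R0(0, 0), r01 = R0(0, 1), r11 = R0(1, 1);
      for (int r = 0; r < n; ++r) {
        if (obs(r, 0) && obs(r, 1)) continue;
        if (!obs(r, 0) && !obs(r, 1)) stop("record with both traits missing");
        int mis = obs(r, 0) ? 1 : 0;
        int ob = 1 - mis;
        double vo = ob == 0 ? r00 : r11;
        double vm = mis == 0 ? r00 : r11;
        double mu = r01 / vo * E(r, ob);
        double v = vm - r01 * r01 / vo;
        E(r, mis) = mu + std::sqrt(v) * norm_rand();
      }
    }

    if (update_location) {
      // ---- fixed effects, scalar site updates (flat prior) ----
      for (int m = 0; m < t; ++m) {
        for (int j = 0; j < p; ++j) {
          if (xtx(j) <= 0) continue;
          double num = 0.0;
          const double bjm = b(j, m);
          for (int r = 0; r < n; ++r) {
            double x = X(r, j);
            if (x == 0.0) continue;
            double s = Rinv(m, m) * (E(r, m) + x * bjm);
            for (int m2 = 0; m2 < t; ++m2)
              if (m2 != m) s += Rinv(m, m2) * E(r, m2);
            num += x * s;
          }
          double prec = Rinv(m, m) * xtx(j);
          double newb = num / prec + norm_rand() / std::sqrt(prec);
          double delta = newb - bjm;
          if (delta != 0.0)
            for (int r = 0; r < n; ++r)
              if (X(r, j) != 0.0) E(r, m) -= X(r, j) * delta;
          b(j, m) = newb;
        }
      }

      // ---- animal (breeding value) effects, site updates over pedigree ----
      double P[4], rhs[2], anew[2];
      for (int i = 0; i < q; ++i) {
        // s_off = sum_{j != i} Ainv_ij a_j ; aii = Ainv_ii
        double aii = 0.0, soff0 = 0.0, soff1 = 0.0;
        for (int k = Ap[i]; k < Ap[i + 1]; ++k) {
          int j = Ai[k];
          double v = Ax[k];
          if (j == i) { aii = v; continue; }
          soff0 += v * a(j, 0);
          if (t == 2) soff1 += v * a(j, 1);
        }
        const std::vector<int>& recs = rec_of_animal[i];
        const int ni = recs.size();
        // precision = ni * Rinv + aii * Ginv
        P[0] = ni * Rinv(0, 0) + aii * Ginv(0, 0);
        if (t == 2) {
          P[1] = ni * Rinv(0, 1) + aii * Ginv(0, 1);
          P[3] = ni * Rinv(1, 1) + aii * Ginv(1, 1);
        }
        // rhs = Rinv * sum_r (E_r + a_i) - Ginv * soff
        double s0 = 0.0, s1 = 0.0;
        for (int rr = 0; rr < ni; ++rr) {
          int r = recs[rr];
          s0 += E(r, 0) + a(i, 0);
          if (t == 2) s1 += E(r, 1) + a(i, 1);
        }
        rhs[0] = Rinv(0, 0) * s0 - Ginv(0, 0) * soff0;
        if (t == 2) {
          rhs[0] += Rinv(0, 1) * s1 - Ginv(0, 1) * soff1;
          rhs[1] = Rinv(1, 0) * s0 + Rinv(1, 1) * s1
                 - Ginv(1, 0) * soff0 - Ginv(1, 1) * soff1;
        }
        draw_gaussian_site(t, P, rhs, anew);
        double d0 = anew[0] - a(i, 0);
        double d1 = t == 2 ? anew[1] - a(i, 1) : 0.0;
        for (int rr = 0; rr < ni; ++rr) {
          int r = recs[rr];
          E(r, 0) -= d0;
          if (t == 2) E(r, 1) -= d1;
        }
        a(i, 0) = anew[0];
        if (t == 2) a(i, 1) = anew[1];
      }

      // ---- pen effects ----
      for (int pidx = 0; pidx < npen; ++pidx) {
        const std::vector<int>& recs = rec_of_pen[pidx];
        const int ni = recs.size();
        P[0] = ni * Rinv(0, 0) + Cinv(0, 0);
        if (t == 2) {
          P[1] = ni * Rinv(0, 1) + Cinv(0, 1);
          P[3] = ni * Rinv(1, 1) + Cinv(1, 1);
        }
        double s0 = 0.0, s1 = 0.0;
        for (int rr = 0; rr < ni; ++rr) {
          int r = recs[rr];
          s0 += E(r, 0) + cc(pidx, 0);
          if (t == 2) s1 += E(r, 1) + cc(pidx, 1);
        }
        rhs[0] = Rinv(0, 0) * s0;
        if (t == 2) {
          rhs[0] += Rinv(0, 1) * s1;
          rhs[1] = Rinv(1, 0) * s0 + Rinv(1, 1) * s1;
        }
        draw_gaussian_site(t, P, rhs, anew);
        double d0 = anew[0] - cc(pidx, 0);
        double d1 = t == 2 ? anew[1] - cc(pidx, 1) : 0.0;
        for (int rr = 0; rr < ni; ++rr) {
          int r = recs[rr];
          E(r, 0) -= d0;
          if (t == 2) E(r, 1) -= d1;
        }
        cc(pidx, 0) = anew[0];
        if (t == 2) cc(pidx, 1) = anew[1];
      }
    }

    // ---- variance components ----
    // G0 | a  ~ IW(q + nu_g, a' Ainv a + S_g)
    arma::mat Qa(t, t, arma::fill::zeros);
    for (int i = 0; i < q; ++i) {
      double s0 = 0.0, s1 = 0.0;
      for (int k = Ap[i]; k < Ap[i + 1]; ++k) {
        int j = Ai[k];
        s0 += Ax[k] * a(j, 0);
        if (t == 2) s1 += Ax[k] * a(j, 1);
      }
      Qa(0, 0) += a(i, 0) * s0;
      if (t == 2) {
        Qa(0, 1) += a(i, 0) * s1;
        Qa(1, 1) += a(i, 1) * s1;
      }
    }
    if (t == 2) Qa(1, 0) = Qa(0, 1);
    G0 = riwish_cpp(q + nu_g, Qa + S_g);

    // C0 | c ~ IW(npen + nu_c, c'c + S_c)
    C0 = riwish_cpp(npen + nu_c, cc.t() * cc + S_c);

    // R0 | e ~ IW(n + nu_r, e'e + S_r)
    R0 = riwish_cpp(n + nu_r, E.t() * E + S_r);

    if (!G0.is_finite() || !C0.is_finite() || !R0.is_finite())
      stop("divergent chain: non-finite covariance draw at iteration %d", iter);

    Ginv = arma::inv_sympd(arma::symmatu(G0));
    Cinv = arma::inv_sympd(arma::symmatu(C0));
    Rinv = arma::inv_sympd(arma::symmatu(R0));

    if (iter > burn_in && (iter - burn_in) % thin == 0 && saved < n_saved) {
      int col = 0;
      for (int m2 = 0; m2 < t; ++m2)
        for (int m1 = m2; m1 < t; ++m1) out(saved, col++) = G0(m1, m2);
      for (int m2 = 0; m2 < t; ++m2)
        for (int m1 = m2; m1 < t; ++m1) out(saved, col++) = C0(m1, m2);
      for (int m2 = 0; m2 < t; ++m2)
        for (int m1 = m2; m1 < t; ++m1) out(saved, col++) = R0(m1, m2);
      a_mean += a;
      ++saved;
    }
  }
  if (saved > 0) a_mean /= saved;

  return List::create(_["draws"] = out, _["a_mean"] = a_mean,
                      _["b_last"] = b, _["c_last"] = cc);
}
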