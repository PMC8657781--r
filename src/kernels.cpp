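#include <Rcpp.h>
#include <complex>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

// Stratonovich-Heun integrator for the delay-coupled Stuart-Landau network
//   dz_j = {lam + i*omega_j - |z_j|^2} z_j dt
//        + K * sum_k A_jk {z_k(t - tau_jk) - alpha z_j} dt + beta dW_j
// Delays are given in integration steps; history before t = 0 is the held
// initial state. The same complex Wiener increment (sd beta*sqrt(dt) per
// component) enters predictor and corrector. Output is decimated to every
// `decim`-th step after discarding the first `n_discard` steps.
// [[Rcpp::export]]
ComplexMatrix sl_integrate_cpp(const IntegerMatrix& adj,
                               const IntegerMatrix& delay_steps,
                               const NumericVector& omega,
                               double lam, double K, double alpha, double beta,
                               double dt, int n_steps, int n_discard, int decim,
                               const ComplexVector& z0) {
  const int n = adj.nrow();
  std::vector< std::vector<int> > nbr(n), dly(n);
  int maxd = 0;
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < n; ++k)
      if (adj(j, k) != 0 && j != k) {
        nbr[j].push_back(k);
        dly[j].push_back(delay_steps(j, k));
        if (delay_steps(j, k) > maxd) maxd = delay_steps(j, k);
      }
  const int L = maxd + 2;  // ring buffer length
  std::vector<cplx> hist((size_t)n * L);
  std::vector<cplx> z(n), zp(n), f0(n), f1(n), xi(n);
  for (int j = 0; j < n; ++j) {
    z[j] = cplx(z0[j].r, z0[j].i);
    for (int s = 0; s < L; ++s) hist[(size_t)s * n + j] = z[j];
  }
  const int n_keep = (n_steps - n_discard) / decim;
  ComplexMatrix out(n, n_keep);
  const double sq = std::sqrt(dt);
  int col = 0;
  for (int t = 0; t < n_steps; ++t) {
    // drift at the current state, delayed terms evaluated at time t
    for (int j = 0; j < n; ++j) {
      const cplx zj = z[j];
      cplx loc = (cplx(lam, omega[j]) - std::norm(zj)) * zj;
      cplx cpl(0.0, 0.0);
      const std::vector<int>& nb = nbr[j];
      const std::vector<int>& dl = dly[j];
      for (size_t e = 0; e < nb.size(); ++e) {
        const int d = dl[e];
        const cplx zk = (d == 0)
          ? z[nb[e]]
          : hist[(size_t)(((t - d) % L + L) % L) * n + nb[e]];
        cpl += zk - alpha * zj;
      }
      f0[j] = loc + K * cpl;
      xi[j] = beta * sq * cplx(norm_rand(), norm_rand());
      zp[j] = zj + f0[j] * dt + xi[j];
    }
    // corrector drift at the predicted state, delayed terms at time t + 1
    for (int j = 0; j < n; ++j) {
      const cplx zj = zp[j];
      cplx loc = (cplx(lam, omega[j]) - std::norm(zj)) * zj;
      cplx cpl(0.0, 0.0);
      const std::vector<int>& nb = nbr[j];
      const std::vector<int>& dl = dly[j];
      for (size_t e = 0; e < nb.size(); ++e) {
        const int d = dl[e];
        const cplx zk = (d == 0)
          ? zp[nb[e]]
          : hist[(size_t)(((t + 1 - d) % L + L) % L) * n + nb[e]];
        cpl += zk - alpha * zj;
      }
      f1[j] = loc + K * cpl;
    }
    bool bad = false;
    for (int j = 0; j < n; ++j) {
      z[j] += 0.5 * (f0[j] + f1[j]) * dt + xi[j];
      hist[(size_t)((t + 1) % L) * n + j] = z[j];
      const double a2 = std::norm(z[j]);
      if (!std::isfinite(a2) || a2 > 1e12) bad = true;
    }
    if (bad)
      stop("Stuart-Landau integration diverged at t = %.4f s (lambda = %.3f, K = %.3f)",
           (t + 1) * dt, lam, K);
    const int rel = t + 1 - n_discard;
    if (rel > 0 && rel % decim == 0 && col < n_keep) {
      for (int j = 0; j < n; ++j) {
        out(j, col).r = z[j].real();
        out(j, col).i = z[j].imag();
      }
      ++col;
    }
  }
  return out;
}

static inline int factorial_i(int m) {
  int f = 1;
  for (int i = 2; i <= m; ++i) f *= i;
  return f;
}

// Ordinal-pattern symbolization: each channel/time position maps to the
// Lehmer code of the rank order of (x_t, x_{t+tau}, ..., x_{t+(m-1)tau}).
// Ties are broken by temporal order (the earlier sample ranks lower).
// Codes run 0 .. m!-1.
// [[Rcpp::export]]
IntegerMatrix symbolize_cpp(const NumericMatrix& x, int m, int tau) {
  const int n = x.nrow(), S = x.ncol();
  const int span = (m - 1) * tau;
  const int ns = S - span;
  if (ns < 1) stop("signal too short for symbol size m = %d, lag tau = %d", m, tau);
  std::vector<int> fact(m);
  for (int i = 0; i < m; ++i) fact[i] = factorial_i(m - 1 - i);
  IntegerMatrix sym(n, ns);
  std::vector<double> v(m);
  for (int ch = 0; ch < n; ++ch) {
    for (int t = 0; t < ns; ++t) {
      for (int i = 0; i < m; ++i) v[i] = x(ch, t + i * tau);
      int code = 0;
      for (int i = 0; i < m - 1; ++i) {
        int l = 0;
        for (int j = i + 1; j < m; ++j)
          if (v[j] < v[i]) ++l;  // strict: equal later samples rank higher
        code += l * fact[i];
      }
      sym(ch, t) = code;
    }
  }
  return sym;
}

static double smi_from_counts(const std::vector<int>& joint, int M, int ntot) {
  std::vector<double> px(M, 0.0), py(M, 0.0);
  for (int a = 0; a < M; ++a)
    for (int b = 0; b < M; ++b) {
      px[a] += joint[a * M + b];
      py[b] += joint[a * M + b];
    }
  const double N = (double)ntot;
  double mi = 0.0;
  for (int a = 0; a < M; ++a) {
    if (px[a] == 0.0) continue;
    for (int b = 0; b < M; ++b) {
      const double c = joint[a * M + b];
      if (c > 0.0) mi += (c / N) * std::log(c * N / (px[a] * py[b]));
    }
  }
  return mi / std::log((double)M);
}

// Plug-in symbolic mutual information between two symbol sequences,
// normalized by log(m!).
// [[Rcpp::export]]
double smi_cpp(const IntegerVector& xs, const IntegerVector& ys, int m) {
  if (xs.size() != ys.size()) stop("symbol sequences must have equal length");
  const int M = factorial_i(m);
  const int ntot = xs.size();
  if (ntot < 1) stop("empty symbol sequence");
  std::vector<int> joint((size_t)M * M, 0);
  for (int t = 0; t < ntot; ++t) {
    const int a = xs[t], b = ys[t];
    if (a < 0 || a >= M || b < 0 || b >= M) stop("symbol out of range 0..m!-1");
    ++joint[a * M + b];
  }
  return smi_from_counts(joint, M, ntot);
}

// Mean pairwise SMI per window. `sym` is channels x symbol-positions; each
// window uses symbol positions start .. start + n_sym - 1 (0-based starts).
// [[Rcpp::export]]
NumericVector window_mean_smi_cpp(const IntegerMatrix& sym,
                                  const IntegerVector& starts,
                                  int n_sym, int m) {
  const int n = sym.nrow();
  const int M = factorial_i(m);
  const int nw = starts.size();
  NumericVector out(nw);
  std::vector<int> joint((size_t)M * M);
  for (int w = 0; w < nw; ++w) {
    const int s0 = starts[w];
    if (s0 < 0 || s0 + n_sym > sym.ncol())
      stop("window exceeds symbol sequence length");
    double acc = 0.0;
    int npair = 0;
    for (int a = 0; a < n - 1; ++a) {
      for (int b = a + 1; b < n; ++b) {
        std::fill(joint.begin(), joint.end(), 0);
        for (int t = 0; t < n_sym; ++t)
          ++joint[sym(a, s0 + t) * M + sym(b, s0 + t)];
        acc += smi_from_counts(joint, M, n_sym);
        ++npair;
      }
    }
    out[w] = acc / npair;
  }
  return out;
}

// Full pairwise SMI matrix for one window of symbol positions.
// [[Rcpp::export]]
NumericMatrix smi_matrix_cpp(const IntegerMatrix& sym, int start, int n_sym, int m) {
  const int n = sym.nrow();
  const int M = factorial_i(m);
  if (start < 0 || start + n_sym > sym.ncol())
    stop("window exceeds symbol sequence length");
  NumericMatrix out(n, n);
  std::vector<int> joint((size_t)M * M);
  for (int a = 0; a < n; ++a) {
    for (int b = a; b < n; ++b) {
      std::fill(joint.begin(), joint.end(), 0);
      for (int t = 0; t < n_sym; ++t)
        ++joint[sym(a, start + t) * M + sym(b, start + t)];
      const double v = smi_from_counts(joint, M, n_sym);
      out(a, b) = v;
      out(b, a) = v;
    }
  }
  return out;
}

static void average_ranks(const std::vector<double>& v, std::vector<double>& r,
                          std::vector<int>& idx) {
  const int n = v.size();
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&v](int a, int b) { return v[a] < v[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
    const double rk = 0.5 * (i + j) + 1.0;  // average rank, 1-based
    for (int k = i; k <= j; ++k) r[idx[k]] = rk;
    i = j + 1;
  }
}

// Instantaneous Spearman correlation between a fixed per-unit score (already
// rank-transformed, e.g. node degree ranks) and each column of `amp`.
// [[Rcpp::export]]
NumericVector inst_spearman_cpp(const NumericMatrix& amp,
                                const NumericVector& score_rank) {
  const int n = amp.nrow(), T = amp.ncol();
  if (score_rank.size() != n) stop("score length must match row count");
  double sm = 0.0, sv = 0.0;
  for (int j = 0; j < n; ++j) sm += score_rank[j];
  sm /= n;
  for (int j = 0; j < n; ++j) sv += (score_rank[j] - sm) * (score_rank[j] - sm);
  NumericVector out(T);
  if (sv <= 0.0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  std::vector<double> v(n), r(n);
  std::vector<int> idx(n);
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < n; ++j) v[j] = amp(j, t);
    average_ranks(v, r, idx);
    double rm = 0.0;
    for (int j = 0; j < n; ++j) rm += r[j];
    rm /= n;
    double sxy = 0.0, sxx = 0.0;
    for (int j = 0; j < n; ++j) {
      sxy += (r[j] - rm) * (score_rank[j] - sm);
      sxx += (r[j] - rm) * (r[j] - rm);
    }
    out[t] = (sxx > 0.0) ? sxy / std::sqrt(sxx * sv) : NA_REAL;
  }
  return out;
}
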