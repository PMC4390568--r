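// Haplotype-cluster HMM on unphased genotypes (fastPHASE-style).
//
// Hidden state at SNP s: the ordered pair (k, l) of clusters carried by the
// two chromosomes. Each chromosome evolves independently with kernel
//   P(k -> k') = (1 - r_s) * delta(k, k') + r_s * alpha_{k', s}
// and the genotype emission couples the pair through independent
// Bernoulli(theta) allele draws. All quantities are kept in scaled
// probability space (per-SNP normalization), so transitions cost O(K^2) per
// SNP via the rank-one structure of the kernel, and all E-step accumulators
// (allele counts, occupancies, jump counts) are exact, giving a monotone EM.
//
// Parameter rows (theta, alpha) are cached per SNP in small dense buffers:
// the matrices are S x K and column-strided access inside the K^2 loops
// dominates runtime otherwise.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct HmmView {
  const double *theta, *alpha, *r;
  int S, K;
};

static inline void snp_rows(const HmmView& m, int s, double* th, double* al) {
  for (int k = 0; k < m.K; ++k) {
    th[k] = m.theta[s + (size_t)m.S * k];
    al[k] = m.alpha[s + (size_t)m.S * k];
  }
}

static inline void emission(int g, int K, const double* th, double* E) {
  if (g < 0) {
    for (int i = 0; i < K * K; ++i) E[i] = 1.0;
    return;
  }
  for (int l = 0; l < K; ++l) {
    double tl = th[l];
    for (int k = 0; k < K; ++k) {
      double tk = th[k];
      E[k + K * l] = g == 0 ? (1 - tk) * (1 - tl)
                   : (g == 1 ? tk * (1 - tl) + (1 - tk) * tl : tk * tl);
    }
  }
}

// Scaled forward pass. F: S blocks of K*K. Returns log-likelihood.
static double forward_pass(const int* g, const HmmView& m,
                           std::vector<double>& F, std::vector<double>& scal) {
  int K = m.K, S = m.S;
  std::vector<double> buf(K * K), E(K * K), th(K), al(K), colsum(K), rowsum(K);
  double loglik = 0.0;
  for (int s = 0; s < S; ++s) {
    double* Fs = &F[(size_t)s * K * K];
    snp_rows(m, s, th.data(), al.data());
    emission(g[s], K, th.data(), E.data());
    if (s == 0) {
      for (int l = 0; l < K; ++l)
        for (int k = 0; k < K; ++k)
          Fs[k + K * l] = al[k] * al[l] * E[k + K * l];
    } else {
      const double* Fp = &F[(size_t)(s - 1) * K * K];
      double rs = m.r[s];
      for (int l = 0; l < K; ++l) {
        double cs = 0.0;
        for (int k = 0; k < K; ++k) cs += Fp[k + K * l];
        colsum[l] = cs;
      }
      for (int l = 0; l < K; ++l)
        for (int k = 0; k < K; ++k)
          buf[k + K * l] = (1 - rs) * Fp[k + K * l] + rs * al[k] * colsum[l];
      for (int k = 0; k < K; ++k) {
        double v = 0.0;
        for (int l = 0; l < K; ++l) v += buf[k + K * l];
        rowsum[k] = v;
      }
      for (int l = 0; l < K; ++l)
        for (int k = 0; k < K; ++k)
          Fs[k + K * l] = ((1 - rs) * buf[k + K * l] + rs * al[l] * rowsum[k]) *
            E[k + K * l];
    }
    double c = 0.0;
    for (int i = 0; i < K * K; ++i) c += Fs[i];
    if (!(c > 0.0) || !std::isfinite(c))
      stop("numerical underflow in forward pass at SNP %d", s + 1);
    for (int i = 0; i < K * K; ++i) Fs[i] /= c;
    scal[s] = c;
    loglik += std::log(c);
  }
  return loglik;
}

// One backward step from s+1 to s, in place on B; M gets E_{s+1} o B_{s+1}.
static void backward_step(const HmmView& m, int K, double rs, double csp1,
                          const double* al, const double* E,
                          std::vector<double>& B, std::vector<double>& M,
                          std::vector<double>& buf) {
  for (int i = 0; i < K * K; ++i) M[i] = E[i] * B[i];
  for (int l = 0; l < K; ++l) {
    double w = 0.0;
    for (int k = 0; k < K; ++k) w += al[k] * M[k + K * l];
    for (int k = 0; k < K; ++k)
      buf[k + K * l] = (1 - rs) * M[k + K * l] + rs * w;
  }
  for (int k = 0; k < K; ++k) {
    double v = 0.0;
    for (int l = 0; l < K; ++l) v += al[l] * buf[k + K * l];
    for (int l = 0; l < K; ++l)
      B[k + K * l] = ((1 - rs) * buf[k + K * l] + rs * v) / csp1;
  }
}

// [[Rcpp::export]]
List hmm_forward_backward_cpp(IntegerVector dosages, NumericMatrix theta,
                              NumericMatrix alpha, NumericVector r) {
  int S = dosages.size(), K = theta.ncol();
  HmmView m{REAL(theta), REAL(alpha), REAL(r), S, K};
  std::vector<int> g(S);
  for (int s = 0; s < S; ++s)
    g[s] = IntegerVector::is_na(dosages[s]) ? -1 : dosages[s];
  std::vector<double> F((size_t)S * K * K), scal(S);
  double loglik = forward_pass(g.data(), m, F, scal);
  std::vector<double> B(K * K, 1.0), M(K * K), buf(K * K), E(K * K),
    th(K), al(K);
  int P = K * (K + 1) / 2;
  NumericMatrix post(S, P);
  for (int s = S - 1; s >= 0; --s) {
    if (s < S - 1) {
      snp_rows(m, s + 1, th.data(), al.data());
      emission(g[s + 1], K, th.data(), E.data());
      backward_step(m, K, m.r[s + 1], scal[s + 1], al.data(), E.data(),
                    B, M, buf);
    }
    const double* Fs = &F[(size_t)s * K * K];
    double tot = 0.0;
    for (int i = 0; i < K * K; ++i) tot += Fs[i] * B[i];
    int idx = 0;
    for (int k = 0; k < K; ++k)
      for (int l = k; l < K; ++l) {
        double v = Fs[k + K * l] * B[k + K * l];
        if (l != k) v += Fs[l + K * k] * B[l + K * k];
        post(s, idx++) = v / tot;
      }
  }
  return List::create(_["pair_posterior"] = post, _["loglik"] = loglik);
}

// Full EM fit; dosage is N x S (NA = missing). The log-likelihood trace
// records the objective of the parameters entering each iteration, so it
// is non-decreasing. Memberships (expected chromosome counts per cluster,
// N x (S*K), cluster index fastest) come from a final E-only pass.
// [[Rcpp::export]]
List hmm_em_cpp(IntegerMatrix dosage, NumericMatrix theta0,
                NumericMatrix alpha0, NumericVector r0,
                int n_iter, double tol, double theta_floor) {
  int N = dosage.nrow(), S = dosage.ncol(), K = theta0.ncol();
  NumericMatrix theta = clone(theta0), alpha = clone(alpha0);
  NumericVector r = clone(r0);
  const int* dos = INTEGER(dosage);
  std::vector<double> F((size_t)S * K * K), scal(S);
  std::vector<double> B(K * K), M(K * K), buf(K * K), G(K * K), E(K * K),
    th(K), al(K), gcol(K), wtab(K * K);
  std::vector<int> g(S);
  std::vector<double> ll_trace;
  NumericMatrix member(N, S * K);

  for (int iter = 0; iter <= n_iter; ++iter) {
    HmmView m{REAL(theta), REAL(alpha), REAL(r), S, K};
    std::vector<double> acc_alt((size_t)S * K, 0.0), occ((size_t)S * K, 0.0);
    std::vector<double> jump((size_t)S * K, 0.0);
    double loglik = 0.0;
    bool last = (iter == n_iter);

    for (int i = 0; i < N; ++i) {
      for (int s = 0; s < S; ++s) {
        int d = dos[i + (size_t)N * s];
        g[s] = (d == NA_INTEGER) ? -1 : d;
      }
      loglik += forward_pass(g.data(), m, F, scal);
      std::fill(B.begin(), B.end(), 1.0);
      for (int s = S - 1; s >= 0; --s) {
        if (s < S - 1) {
          snp_rows(m, s + 1, th.data(), al.data());
          emission(g[s + 1], K, th.data(), E.data());
          backward_step(m, K, m.r[s + 1], scal[s + 1], al.data(), E.data(),
                        B, M, buf);
        }
        snp_rows(m, s, th.data(), al.data());
        const double* Fs = &F[(size_t)s * K * K];
        double tot = 0.0;
        for (int ii = 0; ii < K * K; ++ii) tot += Fs[ii] * B[ii];
        // expected alt-allele share carried by the chromosome in cluster k
        // given the pair (k, l) and the genotype
        for (int l = 0; l < K; ++l) {
          double tl = th[l];
          for (int k = 0; k < K; ++k) {
            double tk = th[k], w;
            switch (g[s]) {
            case 0: w = 0.0; break;
            case 2: w = 1.0; break;
            case 1: {
              double e1 = tk * (1 - tl) + (1 - tk) * tl;
              w = e1 > 0 ? tk * (1 - tl) / e1 : 0.5;
              break;
            }
            default: w = tk;
            }
            wtab[k + K * l] = w;
          }
        }
        for (int k = 0; k < K; ++k) {
          double occk = 0.0, altk = 0.0;
          for (int l = 0; l < K; ++l) {
            double gam = Fs[k + K * l] * B[k + K * l] / tot;
            occk += gam;
            altk += gam * wtab[k + K * l];
          }
          occ[k + (size_t)K * s] += 2.0 * occk;
          acc_alt[k + (size_t)K * s] += 2.0 * altk;
          if (last) member(i, k + K * s) = 2.0 * occk;
        }
        // expected jumps into each cluster over interval (s-1 -> s);
        // chromosome 2 contributes identically by symmetry of gamma.
        if (s > 0 && !last) {
          const double* Fp = &F[(size_t)(s - 1) * K * K];
          double rs = m.r[s];
          if (rs > 0.0) {
            emission(g[s], K, th.data(), E.data());
            for (int ii = 0; ii < K * K; ++ii) M[ii] = E[ii] * B[ii] / scal[s];
            for (int k = 0; k < K; ++k) {
              double rsum = 0.0;
              for (int l = 0; l < K; ++l) rsum += Fp[k + K * l];
              for (int lp = 0; lp < K; ++lp)
                G[k + K * lp] = (1 - rs) * Fp[k + K * lp] + rs * rsum * al[lp];
            }
            for (int lp = 0; lp < K; ++lp) {
              double cs = 0.0;
              for (int k = 0; k < K; ++k) cs += G[k + K * lp];
              gcol[lp] = cs;
            }
            for (int kp = 0; kp < K; ++kp) {
              double acc = 0.0;
              for (int lp = 0; lp < K; ++lp) acc += M[kp + K * lp] * gcol[lp];
              jump[kp + (size_t)K * s] += 2.0 * rs * al[kp] * acc;
            }
          }
        }
      }
    }

    ll_trace.push_back(loglik);
    if (last) break;
    if (iter > 0 && tol > 0) {
      double prev = ll_trace[iter - 1];
      if (std::fabs(loglik - prev) <= tol * std::fabs(prev)) n_iter = iter + 1;
    }

    double twoN = 2.0 * N;
    for (int s = 0; s < S; ++s) {
      for (int k = 0; k < K; ++k) {
        double o = occ[k + (size_t)K * s];
        if (o > 1e-12) {
          double t = acc_alt[k + (size_t)K * s] / o;
          theta(s, k) = std::min(std::max(t, theta_floor), 1.0 - theta_floor);
        }
      }
      if (s == 0) {
        for (int k = 0; k < K; ++k) alpha(0, k) = occ[k] / twoN;
      } else {
        double jt = 0.0;
        for (int k = 0; k < K; ++k) jt += jump[k + (size_t)K * s];
        r[s] = std::min(std::max(jt / twoN, 0.0), 1.0 - 1e-12);
        if (jt > 1e-12)
          for (int k = 0; k < K; ++k) alpha(s, k) = jump[k + (size_t)K * s] / jt;
      }
      double asum = 0.0;
      for (int k = 0; k < K; ++k) {
        if (alpha(s, k) < 1e-6) alpha(s, k) = 1e-6;
        asum += alpha(s, k);
      }
      for (int k = 0; k < K; ++k) alpha(s, k) /= asum;
    }
  }

  return List::create(
    _["theta"] = theta, _["alpha"] = alpha, _["r"] = r,
    _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["membership"] = member);
}
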