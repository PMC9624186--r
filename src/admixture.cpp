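#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler for the Pritchard admixture model with independent
// symmetric-Dirichlet allele-frequency priors.
//
// geno:      n x 2L integer matrix of dense allele indices (0-based),
//            NA_INTEGER for missing gene copies; columns 2l, 2l+1 are the
//            two copies at locus l.
// nalleles:  J_l per locus (dense code space per locus).
// All randomness goes through R's RNG so set.seed() upstream makes runs
// exactly reproducible.

// Marsaglia-Tsang (2000) gamma generator driven by R's RNG; much faster
// than R::rgamma inside the sweep loops, still exactly seed-reproducible.
static double rgamma_mt(double shape) {
  if (shape < 1.0) {
    // boost: G(a) = G(a+1) * U^(1/a)
    double u = unif_rand();
    return rgamma_mt(shape + 1.0) * std::pow(u, 1.0 / shape);
  }
  const double d = shape - 1.0 / 3.0;
  const double c = 1.0 / std::sqrt(9.0 * d);
  for (;;) {
    double x, v;
    do { x = norm_rand(); v = 1.0 + c * x; } while (v <= 0.0);
    v = v * v * v;
    double u = unif_rand();
    double x2 = x * x;
    if (u < 1.0 - 0.0331 * x2 * x2) return d * v;
    if (std::log(u) < 0.5 * x2 + d * (1.0 - v + std::log(v))) return d * v;
  }
}

static double rgamma_guard(double shape) {
  // gamma draws with tiny shapes underflow to 0; the Dirichlet draw
  // renormalises, we only need to avoid an all-zero vector and log(0)
  double g = rgamma_mt(shape);
  if (g < 1e-300) g = 1e-300;
  return g;
}

// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix geno, IntegerVector nalleles,
                         int K, double lambda, double alpha0,
                         bool infer_alpha, double alpha_max, double alpha_sd,
                         int burnin, int reps, int thin) {
  const int n = geno.nrow();
  const int L = nalleles.size();
  const int C = 2 * L; // gene copies per individual
  if (geno.ncol() != C) stop("geno must have 2 * length(nalleles) columns");
  if (K < 1) stop("K must be >= 1");

  // state
  std::vector<int> z(n * C, -1);          // cluster of each gene copy
  NumericMatrix Q(n, K);
  std::vector<NumericMatrix> P(L);        // K x J_l
  for (int l = 0; l < L; ++l) P[l] = NumericMatrix(K, nalleles[l]);
  double alpha = alpha0;

  // init: Z uniform, P from prior, Q uniform
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < C; ++c)
      if (geno(i, c) != NA_INTEGER)
        z[i * C + c] = (int)(unif_rand() * K) % K;
  for (int l = 0; l < L; ++l) {
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < nalleles[l]; ++j) { P[l](k, j) = rgamma_guard(lambda); s += P[l](k, j); }
      for (int j = 0; j < nalleles[l]; ++j) P[l](k, j) /= s;
    }
  }
  std::fill(Q.begin(), Q.end(), 1.0 / K);

  const int total = burnin + reps;
  const int nsave = (thin > 0) ? reps / thin : 0;
  NumericVector lnl_trace(nsave);
  NumericVector alpha_trace(nsave);
  NumericMatrix Qsum(n, K);
  std::vector<NumericMatrix> Psum(L);
  for (int l = 0; l < L; ++l) Psum[l] = NumericMatrix(K, nalleles[l]);
  int saved = 0;

  std::vector<double> prob(K);
  // allele counts per (locus, k, j) and copy counts per (i, k)
  std::vector<std::vector<double> > acnt(L);
  for (int l = 0; l < L; ++l) acnt[l].assign(K * nalleles[l], 0.0);
  NumericMatrix qcnt(n, K);

  for (int it = 0; it < total; ++it) {
    // --- update Z | Q, P and collect counts
    for (int l = 0; l < L; ++l) std::fill(acnt[l].begin(), acnt[l].end(), 0.0);
    std::fill(qcnt.begin(), qcnt.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int col = 2 * l + c;
          int a = geno(i, col);
          if (a == NA_INTEGER) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) { prob[k] = Q(i, k) * P[l](k, a); s += prob[k]; }
          int knew = K - 1;
          if (s > 0) {
            double u = unif_rand() * s, acc = 0.0;
            for (int k = 0; k < K; ++k) { acc += prob[k]; if (u <= acc) { knew = k; break; } }
          } else {
            knew = (int)(unif_rand() * K) % K;
          }
          z[i * C + col] = knew;
          acnt[l][knew * nalleles[l] + a] += 1.0;
          qcnt(i, knew) += 1.0;
        }
      }
    }
    // --- update P | Z (conjugate Dirichlet)
    for (int l = 0; l < L; ++l) {
      int J = nalleles[l];
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < J; ++j) {
          double g = rgamma_guard(lambda + acnt[l][k * J + j]);
          P[l](k, j) = g; s += g;
        }
        for (int j = 0; j < J; ++j) P[l](k, j) /= s;
      }
    }
    // --- update Q | Z (conjugate Dirichlet)
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) { double g = rgamma_guard(alpha + qcnt(i, k)); Q(i, k) = g; s += g; }
      for (int k = 0; k < K; ++k) Q(i, k) /= s;
    }
    // --- update alpha | Q (Metropolis, uniform prior on (0, alpha_max])
    if (infer_alpha && K > 1) {
      double aprop = alpha + norm_rand() * alpha_sd;
      if (aprop > 0 && aprop <= alpha_max) {
        double slog = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) slog += std::log(Q(i, k));
        double lr = n * (R::lgammafn(K * aprop) - K * R::lgammafn(aprop)
                       - R::lgammafn(K * alpha) + K * R::lgammafn(alpha))
                  + (aprop - alpha) * slog;
        if (lr >= 0 || unif_rand() < std::exp(lr)) alpha = aprop;
      }
    }
    // --- record thinned post-burn-in samples
    if (it >= burnin && thin > 0 && ((it - burnin + 1) % thin == 0) && saved < nsave) {
      double lnl = 0.0;
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a == NA_INTEGER) continue;
            double m = 0.0;
            for (int k = 0; k < K; ++k) m += Q(i, k) * P[l](k, a);
            lnl += std::log(m);
          }
      lnl_trace[saved] = lnl;
      alpha_trace[saved] = alpha;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < K; ++k)
          for (int j = 0; j < nalleles[l]; ++j) Psum[l](k, j) += P[l](k, j);
      ++saved;
    }
  }

  if (saved == 0) stop("no post-burn-in samples recorded; increase reps or lower thin");
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { Qsum(i, k) /= saved; s += Qsum(i, k); }
    for (int k = 0; k < K; ++k) Qsum(i, k) /= s;
  }
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm(K, nalleles[l]);
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < nalleles[l]; ++j) { pm(k, j) = Psum[l](k, j) / saved; s += pm(k, j); }
      for (int j = 0; j < nalleles[l]; ++j) pm(k, j) /= s;
    }
    Pout[l] = pm;
  }
  return List::create(_["Q"] = Qsum, _["P"] = Pout,
                      _["lnl_trace"] = lnl_trace, _["alpha_trace"] = alpha_trace,
                      _["n_samples"] = saved);
}
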