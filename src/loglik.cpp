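// FFT-inversion likelihood core for the bivariate latent-confounder model.
// The joint characteristic function of a SNP's (beta_x, beta_y) is the
// product of three spike-and-slab signal components (confounder, X, Y) and
// a bivariate Gaussian noise component; it is real and positive because
// every component is symmetric around zero. The density is recovered on a
// regular grid by FFT inversion and SNP contributions are bilinearly
// interpolated on the log-density, weighted by the restricted LD-score
// weights.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// log CF term of one spike-and-slab signal component at squared argument
// t2: M * log1p(-pi_k * pi_trait * (1 - (1 + sigma_k^2 sigma_t^2 t2)^{-1/2}));
// for the tiny mixture products typical of per-SNP LD profiles the
// second-order expansion of log1p is exact to ~1e-15 relative.
static inline double log_cf_ss(double t2, double pik, double pit,
                               double s2prod, double M) {
  if (pit <= 0.0 || s2prod <= 0.0) return 0.0;
  const double z = pik * pit * (1.0 - 1.0 / std::sqrt(1.0 + s2prod * t2));
  if (z < 1e-5) return -M * (z + 0.5 * z * z);
  return M * log1p(-z);
}

// [[Rcpp::export]]
double cpp_loglik_pair(const arma::vec& bx, const arma::vec& by,
                       const arma::vec& wt, const arma::uvec& bin,
                       const arma::vec& bin_pi, const arma::vec& bin_sigma,
                       double pix, double piy, double piu,
                       double h2x, double h2y, double tx, double ty,
                       double axy, double ayx,
                       double ix, double iy, double ixy,
                       double nx, double ny, double M,
                       int N, double Lx, double Ly, double floor_log) {
  const double D = 1.0 - axy * ayx;
  if (std::abs(D) < 1e-6) return -1e15;
  const double s2x = (pix > 0) ? h2x / (M * pix) : 0.0;
  const double s2y = (piy > 0) ? h2y / (M * piy) : 0.0;
  const double s2u = (piu > 0) ? 1.0 / (M * piu) : 0.0;

  const double dx = 2.0 * Lx / N, dy = 2.0 * Ly / N;
  const double dv = 2.0 * M_PI / (N * dx), dw = 2.0 * M_PI / (N * dy);
  vec v(N), w(N);
  for (int m = 0; m < N; ++m) {
    v(m) = (m - N / 2) * dv;
    w(m) = (m - N / 2) * dw;
  }
  // frequency-lattice quantities shared by all bins
  mat Au2(N, N), Ax2(N, N), Ay2(N, N), noise_log(N, N), sgn(N, N);
  const double cux = (tx + ayx * ty) / D, cuy = (ty + axy * tx) / D;
  const double nvar_x = ix / nx, nvar_y = iy / ny;
  const double ncov = ixy / std::sqrt(nx * ny);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < N; ++m) {
      const double au = v(m) * cux + w(n) * cuy;
      const double ax = (v(m) + axy * w(n)) / D;
      const double ay = (w(n) + ayx * v(m)) / D;
      Au2(m, n) = au * au;
      Ax2(m, n) = ax * ax;
      Ay2(m, n) = ay * ay;
      noise_log(m, n) = -0.5 * nvar_x * v(m) * v(m) -
                        0.5 * nvar_y * w(n) * w(n) - ncov * v(m) * w(n);
      sgn(m, n) = ((m + n) % 2 == 0) ? 1.0 : -1.0;
    }
  }
  const double cell = dv * dw / (4.0 * M_PI * M_PI);
  const double floor_dens = std::exp(floor_log);

  // group SNPs by bin so each bin's grid is built once
  const uword B = bin_pi.n_elem;
  std::vector<std::vector<uword>> members(B);
  for (uword k = 0; k < bin.n_elem; ++k) members[bin(k)].push_back(k);

  // cells where the noise CF alone is < exp(-60) contribute nothing to
  // the density (the signal CFs are bounded by 1); skip them
  std::vector<uword> active;
  active.reserve((uword)N * N);
  for (uword c = 0; c < (uword)(N * N); ++c)
    if (noise_log(c) > -60.0) active.push_back(c);

  double ll = 0.0;
  mat re(N, N), logf(N, N);
  for (uword b = 0; b < B; ++b) {
    if (members[b].empty()) continue;
    const double pik = bin_pi(b), sk2 = bin_sigma(b) * bin_sigma(b);
    re.zeros();
    for (uword ci = 0; ci < active.size(); ++ci) {
      const uword c = active[ci];
      const double lg = log_cf_ss(Au2(c), pik, piu, sk2 * s2u, M) +
                        log_cf_ss(Ax2(c), pik, pix, sk2 * s2x, M) +
                        log_cf_ss(Ay2(c), pik, piy, sk2 * s2y, M) +
                        noise_log(c);
      re(c) = std::exp(lg) * sgn(c);
    }
    cx_mat phi(re, mat(N, N, fill::zeros));
    mat f = real(fft2(phi)) % sgn * cell;
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        logf(i, j) = std::log(std::max(f(i, j), floor_dens));

    for (uword idx = 0; idx < members[b].size(); ++idx) {
      const uword k = members[b][idx];
      const double gx = (bx(k) + Lx) / dx, gy = (by(k) + Ly) / dy;
      const int j0 = (int)std::floor(gx), l0 = (int)std::floor(gy);
      double val;
      if (j0 < 0 || j0 >= N - 1 || l0 < 0 || l0 >= N - 1) {
        val = floor_log;
      } else {
        const double fx = gx - j0, fy = gy - l0;
        val = (1 - fx) * (1 - fy) * logf(j0, l0) +
              fx * (1 - fy) * logf(j0 + 1, l0) +
              (1 - fx) * fy * logf(j0, l0 + 1) +
              fx * fy * logf(j0 + 1, l0 + 1);
      }
      ll += wt(k) * val;
    }
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_loglik_single(const arma::vec& beta, const arma::vec& wt,
                         const arma::uvec& bin,
                         const arma::vec& bin_pi, const arma::vec& bin_sigma,
                         double pi_t, double h2, double intercept,
                         double n, double M,
                         int N, double L, double floor_log) {
  const double s2t = (pi_t > 0) ? h2 / (M * pi_t) : 0.0;
  const double dx = 2.0 * L / N;
  const double dv = 2.0 * M_PI / (N * dx);
  vec v(N), sgn(N);
  for (int m = 0; m < N; ++m) {
    v(m) = (m - N / 2) * dv;
    sgn(m) = (m % 2 == 0) ? 1.0 : -1.0;
  }
  const double nvar = intercept / n;
  const double cell = dv / (2.0 * M_PI);
  const double floor_dens = std::exp(floor_log);

  const uword B = bin_pi.n_elem;
  std::vector<std::vector<uword>> members(B);
  for (uword k = 0; k < bin.n_elem; ++k) members[bin(k)].push_back(k);

  double ll = 0.0;
  for (uword b = 0; b < B; ++b) {
    if (members[b].empty()) continue;
    const double pik = bin_pi(b), sk2 = bin_sigma(b) * bin_sigma(b);
    vec lg(N);
    for (int m = 0; m < N; ++m)
      lg(m) = log_cf_ss(v(m) * v(m), pik, pi_t, sk2 * s2t, M) -
              0.5 * nvar * v(m) * v(m);
    cx_vec phi(exp(lg) % sgn, vec(N, fill::zeros));
    vec f = real(fft(phi)) % sgn * cell;
    vec logf(N);
    for (int m = 0; m < N; ++m)
      logf(m) = std::log(std::max(f(m), floor_dens));

    for (uword idx = 0; idx < members[b].size(); ++idx) {
      const uword k = members[b][idx];
      const double gx = (beta(k) + L) / dx;
      const int j0 = (int)std::floor(gx);
      double val;
      if (j0 < 0 || j0 >= N - 1) {
        val = floor_log;
      } else {
        const double fx = gx - j0;
        val = (1 - fx) * logf(j0) + fx * logf(j0 + 1);
      }
      ll += wt(k) * val;
    }
  }
  return ll;
}
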