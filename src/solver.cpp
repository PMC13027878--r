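// First-order coupled k-space pseudospectral solver for the lossless
// homogeneous 2D wave equation, with a split-field PML, staggered spatial
// grids and the k-space dispersion correction kappa = sinc(c k dt / 2).
// Initial-value problem: p(0) = p0, dp/dt(0) = 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec fft_wavenumbers(int n, double dx) {
  vec k(n);
  for (int i = 0; i < n; ++i) {
    double f = (i <= (n - 1) / 2) ? (double)i : (double)(i - n);
    k(i) = 2.0 * datum::pi * f / (n * dx);
  }
  return k;
}

// Blackman taper over the (fftshifted) spectrum, as commonly applied to
// the initial pressure to limit staircasing-induced high-k ringing.
static vec blackman_k(int n) {
  vec w(n);
  for (int i = 0; i < n; ++i) {
    int s = (i + n / 2) % n;  // shifted position, DC at n/2
    double u = (double)s / (double)(n - 1);
    w(i) = 0.42 - 0.5 * std::cos(2.0 * datum::pi * u) +
           0.08 * std::cos(4.0 * datum::pi * u);
  }
  return w;
}

// exp(-alpha dt/2) absorption factor per grid line; quartic ramp inside
// the PML of `pml_size` points on each edge.
static vec pml_factor(int n, int pml_size, double pml_alpha, double c0,
                      double dx, double dt, double offset) {
  vec f(n, fill::ones);
  if (pml_size <= 0) return f;
  for (int i = 0; i < n; ++i) {
    double pos = (double)i + offset;
    double edge = std::min(pos, (double)(n - 1) - pos);
    if (edge < pml_size) {
      double x = (pml_size - edge) / (double)pml_size;
      double a = pml_alpha * (c0 / dx) * std::pow(x, 4);
      f(i) = std::exp(-a * dt / 2.0);
    }
  }
  return f;
}

// [[Rcpp::export(name = ".kspace_solve_2d")]]
arma::mat kspace_solve_2d(const arma::mat& p0, double dx, double c0,
                          double rho0, double dt, int n_record,
                          int record_every, const arma::mat& sensor_xy,
                          int pml_size, double pml_alpha, bool smooth_p0) {
  const int N = p0.n_rows;
  if ((int)p0.n_cols != N) Rcpp::stop("p0 must be square");
  if (c0 * dt / dx >= 1.0) Rcpp::stop("unstable time step (CFL >= 1)");
  const int n_sensors = sensor_xy.n_rows;

  vec k1 = fft_wavenumbers(N, dx);
  mat KX = repmat(k1, 1, N);        // x along rows
  mat KY = repmat(k1.t(), N, 1);    // y along cols
  mat K = sqrt(KX % KX + KY % KY);

  // k-space correction sinc(c k dt / 2)
  mat kappa(N, N);
  for (uword i = 0; i < kappa.n_elem; ++i) {
    double a = c0 * K(i) * dt / 2.0;
    kappa(i) = (a == 0.0) ? 1.0 : std::sin(a) / a;
  }

  // staggered-grid derivative operators (multiplicative, in k-space)
  cx_mat Dxp(N, N), Dxm(N, N), Dyp(N, N), Dym(N, N);
  const cx_double I(0.0, 1.0);
  for (uword i = 0; i < Dxp.n_elem; ++i) {
    cx_double sx = std::exp(I * (KX(i) * dx / 2.0));
    cx_double sy = std::exp(I * (KY(i) * dx / 2.0));
    Dxp(i) = I * KX(i) * kappa(i) * sx;
    Dxm(i) = I * KX(i) * kappa(i) / sx;
    Dyp(i) = I * KY(i) * kappa(i) * sy;
    Dym(i) = I * KY(i) * kappa(i) / sy;
  }

  // PML absorption factors (x varies along rows, y along cols)
  vec px = pml_factor(N, pml_size, pml_alpha, c0, dx, dt, 0.0);
  vec pxs = pml_factor(N, pml_size, pml_alpha, c0, dx, dt, 0.5);
  vec py = px, pys = pxs;
  mat PX = repmat(px, 1, N), PXS = repmat(pxs, 1, N);
  mat PY = repmat(py.t(), N, 1), PYS = repmat(pys.t(), N, 1);

  // initial pressure (optionally spectrally smoothed)
  mat p = p0;
  if (smooth_p0) {
    vec w = blackman_k(N);
    cx_mat P = fft2(cx_mat(p, zeros(N, N)));
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i) P(i, j) *= w(i) * w(j);
    p = real(ifft2(P));
  }

  mat rhox = p / (2.0 * c0 * c0), rhoy = rhox;
  mat ux(N, N, fill::zeros), uy(N, N, fill::zeros);

  mat sino(n_sensors, n_record, fill::zeros);
  // precompute bilinear interpolation weights for sensor positions
  ivec i0(n_sensors), j0(n_sensors);
  vec wi(n_sensors), wj(n_sensors);
  const double half = (N - 1) / 2.0;
  for (int s = 0; s < n_sensors; ++s) {
    double fi = sensor_xy(s, 0) / dx + half;  // row index (x)
    double fj = sensor_xy(s, 1) / dx + half;  // col index (y)
    if (fi < 0 || fi > N - 1 || fj < 0 || fj > N - 1)
      Rcpp::stop("sensor outside computational domain");
    i0(s) = std::min((int)std::floor(fi), N - 2);
    j0(s) = std::min((int)std::floor(fj), N - 2);
    wi(s) = fi - i0(s);
    wj(s) = fj - j0(s);
  }

  const int n_steps = n_record * record_every;
  int rec = 0;
  bool first = true;
  cx_mat buf(N, N);

  for (int t = 0; t < n_steps; ++t) {
    if (t % record_every == 0 && rec < n_record) {
      for (int s = 0; s < n_sensors; ++s) {
        int i = i0(s), j = j0(s);
        double a = wi(s), b = wj(s);
        sino(s, rec) = (1 - a) * (1 - b) * p(i, j) + a * (1 - b) * p(i + 1, j) +
                       (1 - a) * b * p(i, j + 1) + a * b * p(i + 1, j + 1);
      }
      ++rec;
    }

    // velocity update (first update is a half step: u lives at t + dt/2)
    buf = fft2(cx_mat(p, zeros(N, N)));
    mat dpdx = real(ifft2(cx_mat(Dxp % buf)));
    mat dpdy = real(ifft2(cx_mat(Dyp % buf)));
    double fac = first ? dt / 2.0 : dt;
    first = false;
    ux = PXS % (PXS % ux - (fac / rho0) * dpdx);
    uy = PYS % (PYS % uy - (fac / rho0) * dpdy);

    // density (split-field) and pressure update
    buf = fft2(cx_mat(ux, zeros(N, N)));
    mat duxdx = real(ifft2(cx_mat(Dxm % buf)));
    buf = fft2(cx_mat(uy, zeros(N, N)));
    mat duydy = real(ifft2(cx_mat(Dym % buf)));
    rhox = PX % (PX % rhox - dt * rho0 * duxdx);
    rhoy = PY % (PY % rhoy - dt * rho0 * duydy);
    p = c0 * c0 * (rhox + rhoy);
  }

  return sino;
}
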