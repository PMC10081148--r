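// Core numerical kernels: centred 2D FFT pair, the spatio-temporally
// regularised objective/gradient and its gradient-descent loop, the monotone
// deformation matcher, and two small image-processing primitives.
//
// Conventions shared with the R layer (see R/fourier.R):
//   * spatial and frequency arrays are "centred": DC sits at 0-based index
//     n/2 along each axis; kforward/kinverse below are the unnormalised DFT
//     conjugated by the corresponding fftshift permutations, so that
//     kinverse(kforward(x)) == x and the adjoint of kforward is
//     n_elem * kinverse.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline cx_mat fftshift2(const cx_mat& x) {
  return shift(shift(x, (sword)(x.n_rows / 2), 0), (sword)(x.n_cols / 2), 1);
}
static inline cx_mat ifftshift2(const cx_mat& x) {
  return shift(shift(x, -(sword)(x.n_rows / 2), 0), -(sword)(x.n_cols / 2), 1);
}

// For even sizes the shift conjugation is a checkerboard modulation:
//   K[k] = (-1)^{c1+c2} S o fft2(S o m),  S[i,j] = (-1)^{i+j},
// which avoids four circular-shift copies per transform.
static mat checkerboard(uword n1, uword n2) {
  mat S(n1, n2);
  for (uword j = 0; j < n2; ++j)
    for (uword i = 0; i < n1; ++i)
      S(i, j) = ((i + j) & 1u) ? -1.0 : 1.0;
  return S;
}

static inline cx_mat kforward(const cx_mat& m) {
  if (m.n_rows % 2 || m.n_cols % 2) return fftshift2(fft2(ifftshift2(m)));
  mat S = checkerboard(m.n_rows, m.n_cols);
  double sgn = (((m.n_rows / 2 + m.n_cols / 2) & 1u) ? -1.0 : 1.0);
  return (S % fft2(S % m)) * sgn;
}
static inline cx_mat kinverse(const cx_mat& d) {
  if (d.n_rows % 2 || d.n_cols % 2) return fftshift2(ifft2(ifftshift2(d)));
  mat S = checkerboard(d.n_rows, d.n_cols);
  double sgn = (((d.n_rows / 2 + d.n_cols / 2) & 1u) ? -1.0 : 1.0);
  return (S % ifft2(S % d)) * sgn;
}

// [[Rcpp::export(name = ".cpp_kforward")]]
arma::cx_mat cpp_kforward(const arma::cx_mat& m) { return kforward(m); }

// [[Rcpp::export(name = ".cpp_kinverse")]]
arma::cx_mat cpp_kinverse(const arma::cx_mat& d) { return kinverse(d); }

// Objective components given the Fourier transforms Fm of every frame.
// Fused explicit loops: these run every iteration of the descent.
static vec objective_terms(const cx_cube& m, const cx_cube& Fm,
                           const cx_cube& d, const cube& W,
                           double a1, double a2, double eps) {
  double fid = 0.0, tem = 0.0, tv = 0.0;
  const uword T = m.n_slices, n1 = m.n_rows, n2 = m.n_cols;
  for (uword t = 0; t < T; ++t) {
    const cx_double* Fp = Fm.slice_memptr(t);
    const cx_double* dp = d.slice_memptr(t);
    const double* Wp = W.slice_memptr(t);
    const uword nn = n1 * n2;
    double fs = 0.0;
    for (uword q = 0; q < nn; ++q)
      fs += std::norm(Wp[q] * Fp[q] - dp[q]);
    fid += fs / (double)nn;  // orthonormal-DFT units
    const cx_double* mp = m.slice_memptr(t);
    for (uword j = 0; j < n2; ++j)
      for (uword i = 0; i < n1; ++i) {
        const uword q = j * n1 + i;
        cx_double dx = (i + 1 < n1) ? mp[q + 1] - mp[q] : cx_double(0, 0);
        cx_double dy = (j + 1 < n2) ? mp[q + n1] - mp[q] : cx_double(0, 0);
        tv += std::sqrt(std::norm(dx) + std::norm(dy) + eps);
      }
    if (t + 1 < T) {
      const cx_double* np = m.slice_memptr(t + 1);
      for (uword q = 0; q < nn; ++q) tem += std::norm(np[q] - mp[q]);
    }
  }
  vec out(4);
  out(0) = fid;
  out(1) = a1 * tem;
  out(2) = a2 * tv;
  out(3) = out(0) + out(1) + out(2);
  return out;
}

static cx_cube gradient_cube(const cx_cube& m, const cx_cube& Fm,
                             const cx_cube& d, const cube& W,
                             double a1, double a2, double eps) {
  const uword T = m.n_slices, n1 = m.n_rows, n2 = m.n_cols;
  cx_cube g(size(m));
  cx_mat px(n1, n2), py(n1, n2), r(n1, n2);
  for (uword t = 0; t < T; ++t) {
    // fidelity: 2 F^H (W o (W o Fm - d)),  F^H = nn * kinverse
    {
      const cx_double* Fp = Fm.slice_memptr(t);
      const cx_double* dp = d.slice_memptr(t);
      const double* Wp = W.slice_memptr(t);
      cx_double* rp = r.memptr();
      for (uword q = 0; q < n1 * n2; ++q)
        rp[q] = Wp[q] * (Wp[q] * Fp[q] - dp[q]);
    }
    g.slice(t) = 2.0 * kinverse(r);  // 2 F_u^H r_u in orthonormal units
    // TV: a2 * (Dx^T(dx/s) + Dy^T(dy/s)) with the shared complex denominator
    const cx_double* mp = m.slice_memptr(t);
    cx_double* pxp = px.memptr();
    cx_double* pyp = py.memptr();
    for (uword j = 0; j < n2; ++j)
      for (uword i = 0; i < n1; ++i) {
        const uword q = j * n1 + i;
        cx_double dx = (i + 1 < n1) ? mp[q + 1] - mp[q] : cx_double(0, 0);
        cx_double dy = (j + 1 < n2) ? mp[q + n1] - mp[q] : cx_double(0, 0);
        double s = std::sqrt(std::norm(dx) + std::norm(dy) + eps);
        pxp[q] = dx / s;
        pyp[q] = dy / s;
      }
    cx_double* gp = g.slice_memptr(t);
    for (uword j = 0; j < n2; ++j)
      for (uword i = 0; i < n1; ++i) {
        const uword q = j * n1 + i;
        cx_double div = -pxp[q] - pyp[q];
        if (i > 0) div += pxp[q - 1];
        if (j > 0) div += pyp[q - n1];
        gp[q] += a2 * div;
      }
    // temporal: forward differences in t, one-sided at the ends
    if (t + 1 < T) g.slice(t) -= 2.0 * a1 * (m.slice(t + 1) - m.slice(t));
    if (t > 0)     g.slice(t) += 2.0 * a1 * (m.slice(t) - m.slice(t - 1));
  }
  return g;
}

static cx_cube forward_all(const cx_cube& m) {
  cx_cube Fm(size(m));
  for (uword t = 0; t < m.n_slices; ++t) Fm.slice(t) = kforward(m.slice(t));
  return Fm;
}

// [[Rcpp::export(name = ".cpp_objective")]]
arma::vec cpp_objective(const arma::cx_cube& m, const arma::cx_cube& d,
                        const arma::cube& W, double a1, double a2, double eps) {
  return objective_terms(m, forward_all(m), d, W, a1, a2, eps);
}

// [[Rcpp::export(name = ".cpp_gradient")]]
arma::cx_cube cpp_gradient(const arma::cx_cube& m, const arma::cx_cube& d,
                           const arma::cube& W, double a1, double a2, double eps) {
  return gradient_cube(m, forward_all(m), d, W, a1, a2, eps);
}

// Largest-eigenvalue estimate of the fidelity Hessian 2 F^H W F by power
// iteration.  The all-ones start image is a k-space delta at DC; radial
// sampling always measures DC, so it has a component along the top eigenspace.
// [[Rcpp::export(name = ".cpp_fidelity_lipschitz")]]
double cpp_fidelity_lipschitz(const arma::cube& W, int iters) {
  const uword n1 = W.n_rows, n2 = W.n_cols, T = W.n_slices;
  cx_cube x(n1, n2, T, fill::ones);
  double lam = 2.0;
  for (int it = 0; it < iters; ++it) {
    cx_cube y(size(x));
    for (uword t = 0; t < T; ++t)
      y.slice(t) = 2.0 * kinverse(W.slice(t) % kforward(x.slice(t)));
    double ny = norm(vectorise(y), 2), nx = norm(vectorise(x), 2);
    if (ny < 1e-300 || nx < 1e-300) break;
    lam = ny / nx;
    x = y / ny;
  }
  return lam;
}

// Gradient descent with optional backtracking: halve the step whenever the
// objective would increase, and let it recover geometrically (capped at the
// initial step) after accepted iterations, so one locally stiff event — e.g.
// the smoothed-TV curvature spike where a gradient magnitude dips below
// sqrt(eps) — does not clamp the whole run.  Monotone descent is enforced at
// every iteration either way.  Returns the final complex series, the
// objective trace (length n_iter + 1, including the initial point) and the
// final step.
// [[Rcpp::export(name = ".cpp_descend")]]
Rcpp::List cpp_descend(const arma::cx_cube& d, const arma::cube& W,
                       double a1, double a2, double eps,
                       int n_iter, double tau, bool backtracking) {
  const uword T = d.n_slices;
  cx_cube m(size(d));
  for (uword t = 0; t < T; ++t) m.slice(t) = kinverse(d.slice(t));  // zero-filled init
  cx_cube Fm = forward_all(m);
  vec trace(n_iter + 1);
  vec terms = objective_terms(m, Fm, d, W, a1, a2, eps);
  trace(0) = terms(3);
  const double tau0 = tau;
  for (int k = 1; k <= n_iter; ++k) {
    cx_cube g = gradient_cube(m, Fm, d, W, a1, a2, eps);
    cx_cube cand = m - tau * g;
    cx_cube Fc = forward_all(cand);
    vec ct = objective_terms(cand, Fc, d, W, a1, a2, eps);
    if (backtracking) {
      int guard = 0;
      while (ct(3) > terms(3) && guard < 60) {
        tau *= 0.5;
        cand = m - tau * g;
        Fc = forward_all(cand);
        ct = objective_terms(cand, Fc, d, W, a1, a2, eps);
        ++guard;
      }
      if (guard == 0) tau = std::min(tau * 1.1, tau0);
    }
    if (!ct.is_finite())
      Rcpp::stop("objective became non-finite at iteration %d", k);
    m = cand; Fm = Fc; terms = ct;
    trace(k) = terms(3);
  }
  return Rcpp::List::create(
    Rcpp::Named("m") = m,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("terms") = terms,
    Rcpp::Named("tau") = tau);
}

// Monotone correspondence between two magnitude profiles by dynamic
// programming: minimise sum_i (a[i] - b[j(i)])^2 + lambda * (j(i) - i)^2 over
// non-decreasing maps with j(0)=0, j(c)=c (DC pin, c = n/2) and j(n-1)=n-1;
// ties broken towards the identity (minimal sum |j(i)-i|).  The lambda term
// keeps the field a small deformation; the caller scales it with the data.
// Returns 1-based indices.
// [[Rcpp::export(name = ".cpp_deformation_dp")]]
Rcpp::List cpp_deformation_dp(const arma::vec& a, const arma::vec& b,
                              double lambda) {
  const int n = a.n_elem;
  const int c = n / 2;
  const double INF = datum::inf;
  mat D(n, n, fill::value(INF));   // primary cost
  mat Tt(n, n, fill::value(INF));  // tie cost
  imat from(n, n, fill::value(-1));
  auto lo = [&](int i) { return i == 0 ? 0 : (i <= c ? 0 : c); };
  auto hi = [&](int i) { return i == n - 1 ? n - 1 : (i < c ? c : n - 1); };
  auto pin = [&](int i, int j) {
    if (i == 0 && j != 0) return false;
    if (i == c && j != c) return false;
    if (i == n - 1 && j != n - 1) return false;
    return true;
  };
  D(0, 0) = (a(0) - b(0)) * (a(0) - b(0));
  Tt(0, 0) = 0.0;
  for (int i = 1; i < n; ++i) {
    double bd = INF, bt = INF; int bj = -1;
    for (int j = lo(i); j <= hi(i); ++j) {
      // admit predecessors with j' <= j from row i-1
      if (j >= lo(i - 1)) {
        int jp = std::min(j, hi(i - 1));
        for (int q = (bj < 0 ? lo(i - 1) : jp); q <= jp; ++q) {
          if (!std::isfinite(D(i - 1, q))) continue;
          if (D(i - 1, q) < bd || (D(i - 1, q) == bd && Tt(i - 1, q) < bt)) {
            bd = D(i - 1, q); bt = Tt(i - 1, q); bj = q;
          }
        }
      }
      if (!pin(i, j) || bj < 0) continue;
      double loc = (a(i) - b(j)) * (a(i) - b(j)) +
                   lambda * (double)((j - i) * (j - i));
      D(i, j) = bd + loc;
      Tt(i, j) = bt + std::abs((double)(j - i));
      from(i, j) = bj;
    }
  }
  Rcpp::IntegerVector j(n);
  int cur = n - 1;
  j[n - 1] = n;  // 1-based
  for (int i = n - 1; i >= 1; --i) {
    cur = from(i, cur);
    j[i - 1] = cur + 1;
  }
  return Rcpp::List::create(Rcpp::Named("j") = j,
                            Rcpp::Named("cost") = D(n - 1, n - 1),
                            Rcpp::Named("tie") = Tt(n - 1, n - 1));
}

// 2D median filter, odd window, borders mirrored across the array edge.
// [[Rcpp::export(name = ".cpp_median_filter")]]
arma::mat cpp_median_filter(const arma::mat& x, int k) {
  const int n1 = x.n_rows, n2 = x.n_cols, h = k / 2;
  mat out(n1, n2);
  std::vector<double> buf(k * k);
  auto ref = [](int p, int n) {
    if (p < 0) p = -p - 1;
    if (p >= n) p = 2 * n - 1 - p;
    return p;
  };
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      int c = 0;
      for (int dj = -h; dj <= h; ++dj)
        for (int di = -h; di <= h; ++di)
          buf[c++] = x(ref(i + di, n1), ref(j + dj, n2));
      std::nth_element(buf.begin(), buf.begin() + c / 2, buf.begin() + c);
      out(i, j) = buf[c / 2];
    }
  return out;
}

// Valid-region 2D convolution (for the SSIM Gaussian window).
// [[Rcpp::export(name = ".cpp_conv2_valid")]]
arma::mat cpp_conv2_valid(const arma::mat& x, const arma::mat& kern) {
  mat full = conv2(x, kern);
  const uword r0 = kern.n_rows - 1, c0 = kern.n_cols - 1;
  return full.submat(r0, c0, x.n_rows - 1, x.n_cols - 1);
}
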