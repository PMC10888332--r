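#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Accumulate Gaussian-modulated echoes of one plane-wave transmit into an
// RF frame (n_samples x n_elements). Each scatterer carries its own
// amplitude, carrier frequency and spectral width (attenuation and form
// factor are folded into those in closed form by the R caller). The
// Gaussian envelope and the carrier are evaluated with multiplicative
// recurrences so the inner loop is transcendental-free.
// [[Rcpp::export]]
NumericMatrix cpp_add_echoes(int n_samples, double fs,
                             NumericVector elem_x,
                             NumericVector sx, NumericVector sz,
                             NumericVector t_tx, NumericVector c_path,
                             NumericVector amp, NumericVector fc,
                             NumericVector sig_f) {
  const int n_elem = elem_x.size();
  const int n_scat = sx.size();
  NumericMatrix rf(n_samples, n_elem);
  const double dt = 1.0 / fs;
  const double two_pi = 2.0 * M_PI;

  for (int e = 0; e < n_elem; ++e) {
    double* col = &rf(0, e);
    const double ex = elem_x[e];
    for (int s = 0; s < n_scat; ++s) {
      const double dxs = sx[s] - ex;
      const double r = std::sqrt(dxs * dxs + sz[s] * sz[s]);
      const double t0 = t_tx[s] + r / c_path[s];
      const double sig_t = 1.0 / (two_pi * sig_f[s]);
      const double half = 4.0 * sig_t;
      int k0 = (int)std::ceil((t0 - half) * fs);
      int k1 = (int)std::floor((t0 + half) * fs);
      if (k0 < 0) k0 = 0;
      if (k1 > n_samples - 1) k1 = n_samples - 1;
      if (k1 < k0) continue;
      // cylindrical spreading on receive; transmit is an unfocused plane
      const double a = amp[s] / std::sqrt(std::max(r, 1e-4));
      const double ts = k0 * dt - t0;            // time rel. echo center
      const double inv2s2 = 1.0 / (2.0 * sig_t * sig_t);
      double env = std::exp(-ts * ts * inv2s2);
      double m = std::exp(-(2.0 * ts * dt + dt * dt) * inv2s2);
      const double w = std::exp(-2.0 * dt * dt * inv2s2);
      const double ang0 = two_pi * fc[s] * ts;
      double cr = std::cos(ang0), ci = std::sin(ang0);
      const double dang = two_pi * fc[s] * dt;
      const double rc = std::cos(dang), rs = std::sin(dang);
      for (int k = k0; k <= k1; ++k) {
        col[k] += a * env * cr;
        env *= m; m *= w;
        const double cr2 = cr * rc - ci * rs;
        ci = cr * rs + ci * rc;
        cr = cr2;
      }
    }
  }
  return rf;
}

// Delay-and-sum beamforming of analytic (complex) plane-wave channel data
// onto a pixel grid, one image per steering angle. Geometry matches the
// forward model: the transmit wavefront leaves the zero-delay element
// (lateral position x0) and propagates at the refracted angle implied by
// the assumed speed; receive is the direct element-to-pixel path.
// re/im: n_samples x n_elem x n_angles (flattened, column-major).
// Returns complex images as a list of two arrays nz x nx x n_angles.
// [[Rcpp::export]]
List cpp_das(NumericVector re, NumericVector im,
             int n_samples, int n_elem, int n_angles,
             NumericVector elem_x, NumericVector angles_rad,
             NumericVector x0_angle, double fs, double c_assumed,
             double c_ref, NumericVector px, NumericVector pz) {
  const int nx = px.size(), nz = pz.size();
  NumericVector out_re(nz * nx * n_angles), out_im(nz * nx * n_angles);

  for (int a = 0; a < n_angles; ++a) {
    const double th = angles_rad[a];
    const double sth = std::sin(th);
    double sin_med = c_assumed * sth / c_ref;
    if (sin_med > 1.0) sin_med = 1.0;
    if (sin_med < -1.0) sin_med = -1.0;
    const double cos_med = std::sqrt(1.0 - sin_med * sin_med);
    const double x0 = x0_angle[a];
    const long off_a = (long)a * n_samples * n_elem;
    for (int j = 0; j < nx; ++j) {
      const double x = px[j];
      for (int i = 0; i < nz; ++i) {
        const double z = pz[i];
        const double t_tx = (x - x0) * sth / c_ref + z * cos_med / c_assumed;
        double acc_r = 0.0, acc_i = 0.0;
        for (int e = 0; e < n_elem; ++e) {
          const double dx = x - elem_x[e];
          const double t = t_tx + std::sqrt(dx * dx + z * z) / c_assumed;
          const double u = t * fs;
          const int k = (int)u;
          if (k < 0 || k >= n_samples - 1) continue;
          const double fr = u - k;
          const long idx = off_a + (long)e * n_samples + k;
          acc_r += (1.0 - fr) * re[idx] + fr * re[idx + 1];
          acc_i += (1.0 - fr) * im[idx] + fr * im[idx + 1];
        }
        const long o = (long)a * nz * nx + (long)j * nz + i;
        out_re[o] = acc_r;
        out_im[o] = acc_i;
      }
    }
  }
  return List::create(_["re"] = out_re, _["im"] = out_im);
}

// im2col gather for batched feature maps stored as (H*W*B) x C matrices
// (rows pixel-fastest then batch). idx: P x 9 plane indices (0 = padded).
// Output: (P*B) x (9*C).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericMatrix x, IntegerMatrix idx, int HW,
                         int B) {
  const int C = x.ncol();
  const int P = idx.nrow();
  NumericMatrix M(P * B, 9 * C);
  const double* xp = x.begin();
  double* mp = M.begin();
  for (int k = 0; k < 9; ++k) {
    const int* ik = &idx(0, k);
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (long)c * HW * B;
      double* mc = mp + ((long)(k * C + c)) * P * B;
      for (int b = 0; b < B; ++b) {
        const double* xb = xc + (long)b * HW;
        double* mb = mc + (long)b * P;
        for (int q = 0; q < P; ++q) {
          const int r = ik[q];
          mb[q] = r > 0 ? xb[r - 1] : 0.0;
        }
      }
    }
  }
  return M;
}

// transpose of cpp_im2col: scatter-add (P*B) x (9*C) back to (H*W*B) x C
// [[Rcpp::export]]
NumericMatrix cpp_col2im(NumericMatrix dM, IntegerMatrix idx, int HW,
                         int B) {
  const int P = idx.nrow();
  const int C = dM.ncol() / 9;
  NumericMatrix dx(HW * B, C);
  const double* mp = dM.begin();
  double* xp = dx.begin();
  for (int k = 0; k < 9; ++k) {
    const int* ik = &idx(0, k);
    for (int c = 0; c < C; ++c) {
      double* xc = xp + (long)c * HW * B;
      const double* mc = mp + ((long)(k * C + c)) * P * B;
      for (int b = 0; b < B; ++b) {
        double* xb = xc + (long)b * HW;
        const double* mb = mc + (long)b * P;
        for (int q = 0; q < P; ++q) {
          const int r = ik[q];
          if (r > 0) xb[r - 1] += mb[q];
        }
      }
    }
  }
  return dx;
}

// batched row gather by plane index (nearest-neighbour upsampling)
// [[Rcpp::export]]
NumericMatrix cpp_gather_rows(NumericMatrix x, IntegerVector idx, int HW,
                              int B) {
  const int C = x.ncol();
  const int P = idx.size();
  NumericMatrix y(P * B, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (long)c * HW * B;
    double* yc = y.begin() + (long)c * P * B;
    for (int b = 0; b < B; ++b)
      for (int q = 0; q < P; ++q)
        yc[b * P + q] = xc[(long)b * HW + idx[q] - 1];
  }
  return y;
}

// transpose of cpp_gather_rows: scatter-add rows back
// [[Rcpp::export]]
NumericMatrix cpp_scatter_rows(NumericMatrix dy, IntegerVector idx,
                               int HW, int B) {
  const int C = dy.ncol();
  const int P = idx.size();
  NumericMatrix dx(HW * B, C);
  for (int c = 0; c < C; ++c) {
    double* xc = dx.begin() + (long)c * HW * B;
    const double* yc = dy.begin() + (long)c * P * B;
    for (int b = 0; b < B; ++b)
      for (int q = 0; q < P; ++q)
        xc[(long)b * HW + idx[q] - 1] += yc[b * P + q];
  }
  return dx;
}
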