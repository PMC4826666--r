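// Synthetic linear-array RF simulation and RF cross-correlation tracking.
//
// RF model: separable convolutional point-spread function. Each scatterer
// contributes amplitude x lateral Gaussian beam weight x Gaussian-modulated
// cosine pulse along the axial (beam) direction. Depth-to-sample mapping is
// y = k * axial_step with axial_step = c / (2 fs).

#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".simulate_rf_core")]]
arma::mat simulate_rf_core(const arma::vec& x_mm, const arma::vec& y_mm,
                           const arma::vec& amp, int n_samples, int n_lines,
                           double x0_mm, double pitch_um, double axial_step_um,
                           double sigma_lat_um, double sigma_ax_um,
                           double carrier_per_um) {
  arma::mat rf(n_samples, n_lines, arma::fill::zeros);
  const double lat_cut = 3.5 * sigma_lat_um, ax_cut = 4.0 * sigma_ax_um;
  const int ns = x_mm.n_elem;
  for (int s = 0; s < ns; ++s) {
    const double xs = (x_mm[s] - x0_mm) * 1000.0;  // um from first line
    const double ys = y_mm[s] * 1000.0;            // um depth
    const double a = amp[s];
    int l0 = (int)std::ceil((xs - lat_cut) / pitch_um);
    int l1 = (int)std::floor((xs + lat_cut) / pitch_um);
    if (l0 < 0) l0 = 0;
    if (l1 > n_lines - 1) l1 = n_lines - 1;
    if (l0 > l1) continue;
    int k0 = (int)std::ceil((ys - ax_cut) / axial_step_um);
    int k1 = (int)std::floor((ys + ax_cut) / axial_step_um);
    if (k0 < 0) k0 = 0;
    if (k1 > n_samples - 1) k1 = n_samples - 1;
    if (k0 > k1) continue;
    for (int l = l0; l <= l1; ++l) {
      const double dx = l * pitch_um - xs;
      const double wl = a * std::exp(-dx * dx / (2 * sigma_lat_um * sigma_lat_um));
      double* col = rf.colptr(l);
      for (int k = k0; k <= k1; ++k) {
        const double dy = k * axial_step_um - ys;
        col[k] += wl * std::exp(-dy * dy / (2 * sigma_ax_um * sigma_ax_um)) *
                  std::cos(2 * M_PI * carrier_per_um * dy);
      }
    }
  }
  return rf;
}

namespace {

// zero-mean NCC of tmpl against all fully-overlapping positions in search
arma::mat ncc_direct(const arma::mat& tmpl, const arma::mat& search) {
  const int ta = tmpl.n_rows, tl = tmpl.n_cols;
  const int sa = search.n_rows, sl = search.n_cols;
  const int na = sa - ta + 1, nl = sl - tl + 1;
  arma::mat out(na, nl);
  const double nt = (double)ta * tl;
  const double tmean = arma::accu(tmpl) / nt;
  arma::mat t0 = tmpl - tmean;
  const double tss = arma::accu(t0 % t0);
  for (int j = 0; j < nl; ++j) {
    for (int i = 0; i < na; ++i) {
      const arma::mat sub = search.submat(i, j, i + ta - 1, j + tl - 1);
      const double smean = arma::accu(sub) / nt;
      double num = 0, sss = 0;
      for (int c = 0; c < tl; ++c)
        for (int r = 0; r < ta; ++r) {
          const double sv = sub(r, c) - smean;
          num += t0(r, c) * sv;
          sss += sv * sv;
        }
      const double den = std::sqrt(tss * sss);
      out(i, j) = den > 0 ? num / den : 0.0;
    }
  }
  return out;
}

arma::mat ncc_fft(const arma::mat& tmpl, const arma::mat& search) {
  const int ta = tmpl.n_rows, tl = tmpl.n_cols;
  const int sa = search.n_rows, sl = search.n_cols;
  const int na = sa - ta + 1, nl = sl - tl + 1;
  const double nt = (double)ta * tl;
  const double tmean = arma::accu(tmpl) / nt;
  arma::mat t0 = tmpl - tmean;
  const double tss = arma::accu(t0 % t0);

  auto next_sz = [](int n) { int p = 1; while (p < n) p <<= 1; return p; };
  const int fa = next_sz(sa), fl = next_sz(sl);
  arma::mat pt(fa, fl, arma::fill::zeros), ps(fa, fl, arma::fill::zeros);
  pt.submat(0, 0, ta - 1, tl - 1) = t0;
  ps.submat(0, 0, sa - 1, sl - 1) = search;
  arma::cx_mat corr = arma::ifft2(arma::conj(arma::fft2(pt)) % arma::fft2(ps));

  // integral images for local sums of search and search^2
  arma::mat I1(sa + 1, sl + 1, arma::fill::zeros), I2(sa + 1, sl + 1, arma::fill::zeros);
  for (int j = 0; j < sl; ++j)
    for (int i = 0; i < sa; ++i) {
      const double v = search(i, j);
      I1(i + 1, j + 1) = v + I1(i, j + 1) + I1(i + 1, j) - I1(i, j);
      I2(i + 1, j + 1) = v * v + I2(i, j + 1) + I2(i + 1, j) - I2(i, j);
    }
  arma::mat out(na, nl);
  for (int j = 0; j < nl; ++j)
    for (int i = 0; i < na; ++i) {
      const double s1 = I1(i + ta, j + tl) - I1(i, j + tl) - I1(i + ta, j) + I1(i, j);
      const double s2 = I2(i + ta, j + tl) - I2(i, j + tl) - I2(i + ta, j) + I2(i, j);
      const double num = corr(i, j).real();  // sum t0 * s
      const double sss = s2 - s1 * s1 / nt;
      const double den = std::sqrt(tss * sss);
      out(i, j) = den > 0 ? num / den : 0.0;
    }
  return out;
}

// Lanczos-3 along rows (axial, where the RF carrier lives: a 6-tap
// windowed sinc keeps the carrier phase error below ~0.006 samples, where
// linear/cubic kernels distort it by ~0.04), linear across lines (the
// lateral profile is envelope-smooth)
double interp_rf(const arma::mat& m, double r, double c) {
  const int nr = m.n_rows, nc = m.n_cols;
  if (r < 2) r = 2;
  if (r > nr - 4) r = nr - 4;
  if (c < 0) c = 0;
  if (c > nc - 1) c = nc - 1;
  const int r1 = (int)std::floor(r), c0 = (int)std::floor(c);
  const int c1 = std::min(c0 + 1, nc - 1);
  const double t = r - r1, fc = c - c0;
  double h[6], hs = 0;
  for (int k = -2; k <= 3; ++k) {
    const double x = t - k;
    double v;
    if (std::abs(x) < 1e-12) v = 1.0;
    else if (std::abs(x) >= 3.0) v = 0.0;
    else v = (std::sin(M_PI * x) / (M_PI * x)) *
             (std::sin(M_PI * x / 3) / (M_PI * x / 3));
    h[k + 2] = v; hs += v;
  }
  double va = 0, vb = 0;
  for (int k = -2; k <= 3; ++k) {
    va += h[k + 2] * m(r1 + k, c0);
    vb += h[k + 2] * m(r1 + k, c1);
  }
  va /= hs; vb /= hs;
  return va * (1 - fc) + vb * fc;
}

double bilinear(const arma::mat& m, double r, double c) {
  const int nr = m.n_rows, nc = m.n_cols;
  if (r < 0) r = 0;
  if (r > nr - 1) r = nr - 1;
  if (c < 0) c = 0;
  if (c > nc - 1) c = nc - 1;
  const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  const int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
  const double fr = r - r0, fc = c - c0;
  return m(r0, c0) * (1 - fr) * (1 - fc) + m(r1, c0) * fr * (1 - fc) +
         m(r0, c1) * (1 - fr) * fc + m(r1, c1) * fr * fc;
}

double parab(double cm, double cp, double cc) {
  const double den = cm - 2 * cc + cp;
  if (den >= -1e-12) return 0.0;  // flat or non-concave triple
  double d = 0.5 * (cm - cp) / den;
  if (d > 0.5) d = 0.5;
  if (d < -0.5) d = -0.5;
  return d;
}

} // namespace

// [[Rcpp::export(name = ".ncc_surface_core")]]
arma::mat ncc_surface_core(const arma::mat& tmpl, const arma::mat& search,
                           bool use_fft) {
  return use_fft ? ncc_fft(tmpl, search) : ncc_direct(tmpl, search);
}

// One block-matching iteration on a kernel grid.
//
// cy, cx: kernel center positions (0-based samples / lines).
// init_ax, init_lat: initial displacement estimates (samples / lines) on the
// same grid. mode: 1 = integer lag, 2 = integer lag with offset rounding,
// 3 = local alignment (fractional warp of the post window by the current
// estimate) plus parabolic subsample refinement.
// [[Rcpp::export(name = ".track_grid")]]
List track_grid(const arma::mat& pre, const arma::mat& post,
                const arma::ivec& cy, const arma::ivec& cx,
                const arma::mat& init_ax, const arma::mat& init_lat,
                int ta, int tl, int sa, int sl, int mode, bool use_fft) {
  const int nry = cy.n_elem, nrx = cx.n_elem;
  const int nsamp = pre.n_rows, nlin = pre.n_cols;
  arma::mat est_ax(nry, nrx), est_lat(nry, nrx), qual(nry, nrx, arma::fill::zeros);
  est_ax.fill(arma::datum::nan); est_lat.fill(arma::datum::nan);

  for (int gj = 0; gj < nrx; ++gj) {
    for (int gi = 0; gi < nry; ++gi) {
      const int y = cy[gi], x = cx[gj];
      const int ty0 = y - ta / 2, tx0 = x - tl / 2;
      if (ty0 < 0 || tx0 < 0 || ty0 + ta > nsamp || tx0 + tl > nlin) continue;
      const arma::mat tmpl = pre.submat(ty0, tx0, ty0 + ta - 1, tx0 + tl - 1);

      const double ia = init_ax(gi, gj), il = init_lat(gi, gj);
      const double oy = std::isfinite(ia) ? ia : 0.0;
      const double ox = std::isfinite(il) ? il : 0.0;

      if (mode < 3) {
        int sy0 = ty0 + (int)std::lround(oy) - (sa - ta) / 2;
        int sx0 = tx0 + (int)std::lround(ox) - (sl - tl) / 2;
        if (sy0 < 0) sy0 = 0;
        if (sx0 < 0) sx0 = 0;
        if (sy0 + sa > nsamp) sy0 = nsamp - sa;
        if (sx0 + sl > nlin) sx0 = nlin - sl;
        if (sy0 < 0 || sx0 < 0) continue;
        const arma::mat srch = post.submat(sy0, sx0, sy0 + sa - 1, sx0 + sl - 1);
        arma::mat cc = use_fft ? ncc_fft(tmpl, srch) : ncc_direct(tmpl, srch);
        int bi = 0, bj = 0; double bv = -2, bmag = 1e18;
        for (int j = 0; j < (int)cc.n_cols; ++j)
          for (int i = 0; i < (int)cc.n_rows; ++i) {
            const double dy = sy0 + i - ty0, dx = sx0 + j - tx0;
            const double mag = std::abs(dy) + std::abs(dx);
            if (cc(i, j) > bv + 1e-12 ||
                (std::abs(cc(i, j) - bv) <= 1e-12 && mag < bmag)) {
              bv = cc(i, j); bi = i; bj = j; bmag = mag;
            }
          }
        est_ax(gi, gj) = sy0 + bi - ty0;
        est_lat(gi, gj) = sx0 + bj - tx0;
        qual(gi, gj) = bv;
      } else {
        // local alignment: resample the post frame at template positions
        // shifted by the current (fractional) estimate, correlate over the
        // residual lag range and refine with parabolic interpolation; the
        // warp-correlate cycle is repeated so the parabola is evaluated at
        // a near-zero residual, where it is unbiased for band-pass RF
        double uy = oy, ux = ox, bv = -2;
        const int ry = (sa - ta) / 2, rx = (sl - tl) / 2;
        const int wa = ta + 2 * ry, wl = tl + 2 * rx;
        arma::mat warp(wa, wl);
        for (int sub = 0; sub < 3; ++sub) {
          for (int c = 0; c < wl; ++c)
            for (int r = 0; r < wa; ++r)
              warp(r, c) = interp_rf(post, ty0 - ry + r + uy, tx0 - rx + c + ux);
          arma::mat cc = ncc_direct(tmpl, warp);
          int bi = 0, bj = 0; double bmag = 1e18; bv = -2;
          for (int j = 0; j < (int)cc.n_cols; ++j)
            for (int i = 0; i < (int)cc.n_rows; ++i) {
              const double mag = std::abs(i - ry) + std::abs(j - rx);
              if (cc(i, j) > bv + 1e-12 ||
                  (std::abs(cc(i, j) - bv) <= 1e-12 && mag < bmag)) {
                bv = cc(i, j); bi = i; bj = j; bmag = mag;
              }
            }
          double dy = bi - ry, dx = bj - rx;
          // a numerically perfect match needs no subsample refinement
          const bool perfect = bv > 1.0 - 1e-12;
          if (!perfect && bi > 0 && bi < (int)cc.n_rows - 1)
            dy += parab(cc(bi - 1, bj), cc(bi + 1, bj), cc(bi, bj));
          if (!perfect && bj > 0 && bj < (int)cc.n_cols - 1)
            dx += parab(cc(bi, bj - 1), cc(bi, bj + 1), cc(bi, bj));
          uy += dy; ux += dx;
          if (std::abs(dy) < 1e-3 && std::abs(dx) < 1e-3) break;
        }
        est_ax(gi, gj) = uy;
        est_lat(gi, gj) = ux;
        qual(gi, gj) = bv;
      }
    }
  }
  return List::create(_["ax"] = est_ax, _["lat"] = est_lat, _["corr"] = qual);
}

// component-wise k x k median filter with reflect padding; NaNs are ignored
// within each window (a window of all NaNs yields NaN)
// [[Rcpp::export(name = ".median_filter2")]]
arma::mat median_filter2(const arma::mat& m, int k) {
  const int nr = m.n_rows, nc = m.n_cols, h = k / 2;
  arma::mat out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)k * k);
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj)
        for (int di = -h; di <= h; ++di) {
          const double v = m(refl(i + di, nr), refl(j + dj, nc));
          if (std::isfinite(v)) buf.push_back(v);
        }
      if (buf.empty()) { out(i, j) = arma::datum::nan; continue; }
      const size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
        med = 0.5 * (med + buf[mid - 1]);
      }
      out(i, j) = med;
    }
  return out;
}
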