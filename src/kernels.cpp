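// Compiled kernels: differential projector assembly (CSR), Kaczmarz row-action
// sweeps, isotropic TV descent, and the BM3D collaborative-filtering core.
//
// Geometry convention (used package-wide):
//   image pixel (i = row, j = col), 0-based here; x = j - (nc-1)/2,
//   y = -(i - (nr-1)/2) so +y points up while rows grow downward.
//   A view angle theta is the detector-axis direction measured CCW from +x:
//   detector axis u = (cos t, sin t), ray direction d = (-sin t, cos t),
//   detector coordinate of a point: s = x cos t + y sin t.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Joseph-style interpolated line integral for the ray at (theta, s).
// Appends (linear pixel index, weight) pairs; driving axis chosen from the
// dominant ray direction so each driven line contributes two bilinear taps.
static void joseph_row(double ct, double st, double s, int nr, int nc,
                       std::vector<int>& idx, std::vector<double>& val) {
  idx.clear(); val.clear();
  const double cx = 0.5 * (nc - 1), cy = 0.5 * (nr - 1);
  const double dx = -st, dy = ct;  // ray direction
  if (std::fabs(dx) >= std::fabs(dy)) {
    const double w = 1.0 / std::fabs(dx);  // path length per unit x
    for (int j = 0; j < nc; ++j) {
      const double xc = j - cx;
      const double t = (xc - s * ct) / dx;
      const double y = s * st + t * dy;
      const double rf = cy - y;
      const int i0 = (int)std::floor(rf);
      const double f = rf - i0;
      if (i0 >= 0 && i0 < nr && f < 1.0) { idx.push_back(i0 * nc + j); val.push_back(w * (1.0 - f)); }
      if (i0 + 1 >= 0 && i0 + 1 < nr && f > 0.0) { idx.push_back((i0 + 1) * nc + j); val.push_back(w * f); }
    }
  } else {
    const double w = 1.0 / std::fabs(dy);
    for (int i = 0; i < nr; ++i) {
      const double y = cy - i;
      const double t = (y - s * st) / dy;
      const double x = s * ct + t * dx;
      const double cf = x + cx;
      const int j0 = (int)std::floor(cf);
      const double f = cf - j0;
      if (j0 >= 0 && j0 < nc && f < 1.0) { idx.push_back(i * nc + j0); val.push_back(w * (1.0 - f)); }
      if (j0 + 1 >= 0 && j0 + 1 < nc && f > 0.0) { idx.push_back(i * nc + j0 + 1); val.push_back(w * f); }
    }
  }
}

// Assemble the linearly partial-derivative matrix B in CSR form.
// Row (view v, bin k) = [A(s_k + ds/2) - A(s_k - ds/2)] / ds where A(s) is the
// Joseph line-integral row: a transverse central difference of half-pixel
// pitch realized as the difference of adjacent interpolation rows.
// [[Rcpp::export]]
List build_diff_operator_cpp(NumericVector angles, int n_det, double det_spacing,
                             int nr, int nc) {
  const int nv = angles.size();
  const R_xlen_t n_rays = (R_xlen_t)nv * n_det;
  std::vector<int> P; P.reserve(n_rays + 1); P.push_back(0);
  std::vector<int> J;
  std::vector<double> X;
  std::vector<double> RN2; RN2.reserve(n_rays);
  J.reserve((size_t)n_rays * 3 * std::max(nr, nc) / 2);
  X.reserve((size_t)n_rays * 3 * std::max(nr, nc) / 2);

  std::vector<int> ia, ib;
  std::vector<double> va, vb;
  std::vector<std::pair<int, double>> merged;
  const double c0 = 0.5 * (n_det);  // midpoint m_k = (k - n_det/2) * ds

  for (int v = 0; v < nv; ++v) {
    const double ct = std::cos(angles[v]), st = std::sin(angles[v]);
    // midpoint row m_0 first, then roll through bins
    joseph_row(ct, st, (0 - c0) * det_spacing, nr, nc, ia, va);
    for (int k = 0; k < n_det; ++k) {
      joseph_row(ct, st, (k + 1 - c0) * det_spacing, nr, nc, ib, vb);
      merged.clear();
      for (size_t q = 0; q < ib.size(); ++q) merged.push_back({ib[q],  vb[q] / det_spacing});
      for (size_t q = 0; q < ia.size(); ++q) merged.push_back({ia[q], -va[q] / det_spacing});
      std::sort(merged.begin(), merged.end(),
                [](const std::pair<int,double>& a, const std::pair<int,double>& b){ return a.first < b.first; });
      double rn2 = 0.0;
      size_t q = 0;
      while (q < merged.size()) {
        int pix = merged[q].first;
        double acc = merged[q].second;
        ++q;
        while (q < merged.size() && merged[q].first == pix) { acc += merged[q].second; ++q; }
        if (acc != 0.0) { J.push_back(pix); X.push_back(acc); rn2 += acc * acc; }
      }
      P.push_back((int)J.size());
      RN2.push_back(rn2);
      ia.swap(ib); va.swap(vb);
    }
  }
  return List::create(_["p"] = IntegerVector(P.begin(), P.end()),
                      _["j"] = IntegerVector(J.begin(), J.end()),
                      _["x"] = NumericVector(X.begin(), X.end()),
                      _["row_norm2"] = NumericVector(RN2.begin(), RN2.end()));
}

// y_hat = B x for CSR B.
// [[Rcpp::export]]
NumericVector csr_matvec_cpp(IntegerVector p, IntegerVector j, NumericVector x,
                             NumericVector img) {
  const R_xlen_t nr = p.size() - 1;
  NumericVector out(nr);
  const int* pp = INTEGER(p); const int* jj = INTEGER(j);
  const double* xx = REAL(x); const double* im = REAL(img);
  for (R_xlen_t i = 0; i < nr; ++i) {
    double acc = 0.0;
    for (int q = pp[i]; q < pp[i + 1]; ++q) acc += xx[q] * im[jj[q]];
    out[i] = acc;
  }
  return out;
}

// Relaxed Kaczmarz sweeps over rays in the given order (0-based indices).
// Rays with zero norm are skipped; optional nonnegativity clamp at sweep end.
// [[Rcpp::export]]
NumericVector kaczmarz_sweep_cpp(IntegerVector p, IntegerVector j, NumericVector bx,
                                 NumericVector row_norm2, NumericVector y,
                                 NumericVector x0, double beta, int nsweeps,
                                 bool clamp, IntegerVector order) {
  NumericVector x = clone(x0);
  double* xv = REAL(x);
  const int* pp = INTEGER(p); const int* jj = INTEGER(j);
  const double* bb = REAL(bx); const double* rn = REAL(row_norm2);
  const double* yy = REAL(y); const int* ord = INTEGER(order);
  const R_xlen_t n_ord = order.size();
  const R_xlen_t npix = x.size();
  for (int s = 0; s < nsweeps; ++s) {
    for (R_xlen_t t = 0; t < n_ord; ++t) {
      const int i = ord[t];
      if (rn[i] <= 0.0) continue;
      double acc = 0.0;
      for (int q = pp[i]; q < pp[i + 1]; ++q) acc += bb[q] * xv[jj[q]];
      const double c = beta * (yy[i] - acc) / rn[i];
      for (int q = pp[i]; q < pp[i + 1]; ++q) xv[jj[q]] += c * bb[q];
    }
    if (clamp) for (R_xlen_t q = 0; q < npix; ++q) if (xv[q] < 0.0) xv[q] = 0.0;
  }
  return x;
}

// Gradient descent on smoothed isotropic TV, forward differences.
// [[Rcpp::export]]
NumericMatrix tv_descent_cpp(NumericMatrix xin, double step, int nsub, double eps) {
  const int nr = xin.nrow(), nc = xin.ncol();
  NumericMatrix x = clone(xin);
  NumericMatrix g(nr, nc);
  for (int it = 0; it < nsub; ++it) {
    std::fill(g.begin(), g.end(), 0.0);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        const double dh = (j + 1 < nc) ? x(i, j + 1) - x(i, j) : 0.0;
        const double dv = (i + 1 < nr) ? x(i + 1, j) - x(i, j) : 0.0;
        const double nrm = std::sqrt(dh * dh + dv * dv + eps * eps);
        g(i, j) -= (dh + dv) / nrm;
        if (j + 1 < nc) g(i, j + 1) += dh / nrm;
        if (i + 1 < nr) g(i + 1, j) += dv / nrm;
      }
    }
    for (int q = 0; q < nr * nc; ++q) x[q] -= step * g[q];
  }
  return x;
}

// ---------------- BM3D ----------------

static void make_dct_matrix(int N, std::vector<double>& D) {
  D.assign((size_t)N * N, 0.0);
  const double pi = M_PI;
  for (int k = 0; k < N; ++k) {
    const double a = (k == 0) ? std::sqrt(1.0 / N) : std::sqrt(2.0 / N);
    for (int j = 0; j < N; ++j)
      D[(size_t)k * N + j] = a * std::cos(pi * (2 * j + 1) * k / (2.0 * N));
  }
}

// C = D * B * D^T for an N x N block; row-accumulation ordering keeps every
// inner loop contiguous so the compiler can vectorize
static void dct2_block(const std::vector<double>& D, int N,
                       const double* B, double* C, std::vector<double>& tmp) {
  tmp.assign((size_t)N * N, 0.0);
  for (int k = 0; k < N; ++k) {
    double* trow = &tmp[(size_t)k * N];
    for (int m = 0; m < N; ++m) {
      const double d = D[(size_t)k * N + m];
      const double* brow = &B[(size_t)m * N];
      for (int j = 0; j < N; ++j) trow[j] += d * brow[j];
    }
  }
  for (int k = 0; k < N; ++k)
    for (int l = 0; l < N; ++l) {
      double acc = 0.0;
      const double* trow = &tmp[(size_t)k * N];
      const double* drow = &D[(size_t)l * N];
      for (int m = 0; m < N; ++m) acc += trow[m] * drow[m];
      C[(size_t)k * N + l] = acc;
    }
}

// B = D^T * C * D
static void idct2_block(const std::vector<double>& D, int N,
                        const double* C, double* B, std::vector<double>& tmp) {
  tmp.assign((size_t)N * N, 0.0);
  for (int k = 0; k < N; ++k) {
    const double* crow = &C[(size_t)k * N];
    const double* drow = &D[(size_t)k * N];
    for (int m = 0; m < N; ++m) {
      const double d = drow[m];
      double* trow = &tmp[(size_t)m * N];
      for (int l = 0; l < N; ++l) trow[l] += d * crow[l];
    }
  }
  std::fill(B, B + (size_t)N * N, 0.0);
  for (int m = 0; m < N; ++m) {
    double* brow = &B[(size_t)m * N];
    const double* trow = &tmp[(size_t)m * N];
    for (int l = 0; l < N; ++l) {
      const double t = trow[l];
      const double* drow = &D[(size_t)l * N];
      for (int n = 0; n < N; ++n) brow[n] += t * drow[n];
    }
  }
}

// Ordered orthonormal Haar transform of length P (power of 2), in place.
static void haar_fwd(double* v, int P, double* scratch) {
  const double s2 = std::sqrt(0.5);
  int len = P;
  while (len > 1) {
    const int h = len / 2;
    for (int m = 0; m < h; ++m) {
      scratch[m]     = (v[2 * m] + v[2 * m + 1]) * s2;
      scratch[h + m] = (v[2 * m] - v[2 * m + 1]) * s2;
    }
    std::copy(scratch, scratch + len, v);
    len = h;
  }
}

static void haar_inv(double* v, int P, double* scratch) {
  const double s2 = std::sqrt(0.5);
  int len = 2;
  while (len <= P) {
    const int h = len / 2;
    for (int m = 0; m < h; ++m) {
      scratch[2 * m]     = (v[m] + v[h + m]) * s2;
      scratch[2 * m + 1] = (v[m] - v[h + m]) * s2;
    }
    std::copy(scratch, scratch + len, v);
    len *= 2;
  }
}

static std::vector<int> block_grid(int n, int N, int stride) {
  std::vector<int> g;
  for (int p = 0; p + N <= n; p += stride) g.push_back(p);
  if (g.empty() || g.back() != n - N) g.push_back(n - N);
  return g;
}

// Full BM3D hard-threshold filter: block matching on the stride grid,
// 2-D DCT + 1-D Haar collaborative filtering, similarity-weighted aggregation.
// The group's global DC coefficient is exempt from thresholding so constants
// pass through unchanged.
// [[Rcpp::export]]
NumericMatrix bm3d_core_cpp(NumericMatrix img, int N, int stride, int search,
                            double tau, int maxG, double hardth, double sigma,
                            bool weighted_agg) {
  const int nr = img.nrow(), nc = img.ncol();
  if (nr < N || nc < N) stop("image smaller than block size");
  std::vector<int> gr = block_grid(nr, N, stride);
  std::vector<int> gc = block_grid(nc, N, stride);
  const int nGr = (int)gr.size(), nGc = (int)gc.size();
  const int NN = N * N;

  std::vector<double> D;
  make_dct_matrix(N, D);

  // precompute spatial blocks (row-major within block) and their 2-D DCTs
  std::vector<double> blocks((size_t)nGr * nGc * NN);
  std::vector<double> coefs((size_t)nGr * nGc * NN);
  std::vector<double> tmp;
  for (int gi = 0; gi < nGr; ++gi)
    for (int gj = 0; gj < nGc; ++gj) {
      double* B = &blocks[((size_t)gi * nGc + gj) * NN];
      for (int a = 0; a < N; ++a)
        for (int b = 0; b < N; ++b)
          B[a * N + b] = img(gr[gi] + a, gc[gj] + b);
      dct2_block(D, N, B, &coefs[((size_t)gi * nGc + gj) * NN], tmp);
    }

  NumericMatrix num(nr, nc), den(nr, nc);
  const double thr = hardth * sigma;

  std::vector<std::pair<double, long long>> cand;  // (distance, scan key)
  std::vector<double> stackc, scratch, outblk;
  for (int gi = 0; gi < nGr; ++gi) {
    for (int gj = 0; gj < nGc; ++gj) {
      const double* RB = &blocks[((size_t)gi * nGc + gj) * NN];
      cand.clear();
      for (int gi2 = 0; gi2 < nGr; ++gi2) {
        if (std::abs(gr[gi2] - gr[gi]) > search) continue;
        for (int gj2 = 0; gj2 < nGc; ++gj2) {
          if (std::abs(gc[gj2] - gc[gj]) > search) continue;
          const double* CB = &blocks[((size_t)gi2 * nGc + gj2) * NN];
          const bool is_ref = (gi2 == gi && gj2 == gj);
          // partial sums only grow, so exceeding the threshold early is final
          const double lim = tau * NN;
          double d = 0.0;
          bool out = false;
          for (int q = 0; q < NN; ) {
            const int stop = std::min(q + 16, NN);
            for (; q < stop; ++q) { const double e = RB[q] - CB[q]; d += e * e; }
            if (!is_ref && d > lim) { out = true; break; }
          }
          if (is_ref || !out)
            cand.push_back({is_ref ? -1.0 : d / NN, (long long)gi2 * nGc + gj2});
        }
      }
      std::stable_sort(cand.begin(), cand.end());
      int s = (int)cand.size();
      if (s > maxG) s = maxG;
      int P = 1; while (P < s) P <<= 1;

      // stack the member DCT coefficients; pad by repeating the last member
      stackc.assign((size_t)P * NN, 0.0);
      for (int k = 0; k < P; ++k) {
        const long long key = cand[std::min(k, s - 1)].second;
        std::copy(&coefs[(size_t)key * NN], &coefs[(size_t)key * NN] + NN, &stackc[(size_t)k * NN]);
      }
      // Haar along the stack per coefficient position
      scratch.assign(std::max(P, NN), 0.0);
      std::vector<double> col(P);
      long long nhar = 0;
      for (int q = 0; q < NN; ++q) {
        for (int k = 0; k < P; ++k) col[k] = stackc[(size_t)k * NN + q];
        haar_fwd(col.data(), P, scratch.data());
        for (int k = 0; k < P; ++k) {
          const bool is_dc = (q == 0 && k == 0);
          if (!is_dc && std::fabs(col[k]) < thr) col[k] = 0.0;
          if (col[k] != 0.0) ++nhar;
        }
        haar_inv(col.data(), P, scratch.data());
        for (int k = 0; k < P; ++k) stackc[(size_t)k * NN + q] = col[k];
      }
      const double w = (sigma > 0.0 && nhar > 0) ? 1.0 / (sigma * sigma * (double)nhar) : 1.0;

      // inverse DCT of the true members, aggregate
      outblk.assign(NN, 0.0);
      for (int k = 0; k < s; ++k) {
        idct2_block(D, N, &stackc[(size_t)k * NN], outblk.data(), tmp);
        const long long key = cand[k].second;
        const int br = gr[(int)(key / nGc)], bc = gc[(int)(key % nGc)];
        for (int a = 0; a < N; ++a)
          for (int b = 0; b < N; ++b) {
            const double vv = outblk[a * N + b];
            num(br + a, bc + b) += w * vv;
            den(br + a, bc + b) += weighted_agg ? w : (vv != 0.0 ? 1.0 : 0.0);
          }
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (int q = 0; q < nr * nc; ++q) out[q] = (den[q] > 0.0) ? num[q] / den[q] : 0.0;
  return out;
}
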