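// Matrix-free kernels for the scalar-potential finite-difference system.
//
// Nodes are voxel corners on an (ndx, ndy, ndz) lattice, column-major.
// Edge conductances are stored per axis: Sx(p,q,r) couples node (p,q,r) to
// (p+1,q,r), dims (ndx-1, ndy, ndz); similarly Sy, Sz. The operator is the
// weighted graph Laplacian A = D - S (SPD on head nodes up to the constant
// nullspace); air nodes have zero diagonal and are skipped everywhere.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

#define IDX(p, q, r, n1, n2) ((p) + (n1) * ((q) + (n2) * (r)))

static inline double neighbor_sum(const double* phi,
                                  const double* Sx, const double* Sy, const double* Sz,
                                  int p, int q, int r,
                                  int ndx, int ndy, int ndz) {
  double s = 0.0;
  if (p > 0)       s += Sx[IDX(p - 1, q, r, ndx - 1, ndy)] * phi[IDX(p - 1, q, r, ndx, ndy)];
  if (p < ndx - 1) s += Sx[IDX(p,     q, r, ndx - 1, ndy)] * phi[IDX(p + 1, q, r, ndx, ndy)];
  if (q > 0)       s += Sy[IDX(p, q - 1, r, ndx, ndy - 1)] * phi[IDX(p, q - 1, r, ndx, ndy)];
  if (q < ndy - 1) s += Sy[IDX(p, q,     r, ndx, ndy - 1)] * phi[IDX(p, q + 1, r, ndx, ndy)];
  if (r > 0)       s += Sz[IDX(p, q, r - 1, ndx, ndy)]     * phi[IDX(p, q, r - 1, ndx, ndy)];
  if (r < ndz - 1) s += Sz[IDX(p, q, r,     ndx, ndy)]     * phi[IDX(p, q, r + 1, ndx, ndy)];
  return s;
}

// One SOR sweep (lexicographic; reverse = backward ordering). Modifies phi
// in place: the caller owns phi and must not share it.
// [[Rcpp::export]]
void spfd_sweep(NumericVector phi, NumericVector Sx, NumericVector Sy,
                NumericVector Sz, NumericVector diagv, NumericVector rhs,
                IntegerVector nd, double omega, bool reverse) {
  const int ndx = nd[0], ndy = nd[1], ndz = nd[2];
  double* ph = phi.begin();
  const double *sx = Sx.begin(), *sy = Sy.begin(), *sz = Sz.begin();
  const double *dg = diagv.begin(), *b = rhs.begin();
  if (!reverse) {
    for (int r = 0; r < ndz; ++r)
      for (int q = 0; q < ndy; ++q)
        for (int p = 0; p < ndx; ++p) {
          const int i = IDX(p, q, r, ndx, ndy);
          const double d = dg[i];
          if (d <= 0.0) continue;
          const double s = neighbor_sum(ph, sx, sy, sz, p, q, r, ndx, ndy, ndz);
          ph[i] = (1.0 - omega) * ph[i] + omega * (b[i] + s) / d;
        }
  } else {
    for (int r = ndz - 1; r >= 0; --r)
      for (int q = ndy - 1; q >= 0; --q)
        for (int p = ndx - 1; p >= 0; --p) {
          const int i = IDX(p, q, r, ndx, ndy);
          const double d = dg[i];
          if (d <= 0.0) continue;
          const double s = neighbor_sum(ph, sx, sy, sz, p, q, r, ndx, ndy, ndz);
          ph[i] = (1.0 - omega) * ph[i] + omega * (b[i] + s) / d;
        }
  }
}

// A * phi with A = D - S (zero on air nodes).
// [[Rcpp::export]]
NumericVector spfd_apply(NumericVector phi, NumericVector Sx, NumericVector Sy,
                         NumericVector Sz, NumericVector diagv, IntegerVector nd) {
  const int ndx = nd[0], ndy = nd[1], ndz = nd[2];
  NumericVector out(phi.size());
  const double* ph = phi.begin();
  const double *sx = Sx.begin(), *sy = Sy.begin(), *sz = Sz.begin();
  const double* dg = diagv.begin();
  double* o = out.begin();
  for (int r = 0; r < ndz; ++r)
    for (int q = 0; q < ndy; ++q)
      for (int p = 0; p < ndx; ++p) {
        const int i = IDX(p, q, r, ndx, ndy);
        const double d = dg[i];
        if (d <= 0.0) { o[i] = 0.0; continue; }
        const double s = neighbor_sum(ph, sx, sy, sz, p, q, r, ndx, ndy, ndz);
        o[i] = d * ph[i] - s;
      }
  return out;
}

// Full-weighting restriction of a node field to the factor-2 coarse lattice.
// Weights are 1 / 2^(#off-axes) (sum 8), the transpose of trilinear
// interpolation, which keeps injected-current (integral) quantities
// consistent across levels.
// [[Rcpp::export]]
NumericVector mg_restrict(NumericVector fine, IntegerVector nd_f, IntegerVector nd_c) {
  const int fx = nd_f[0], fy = nd_f[1], fz = nd_f[2];
  const int cx = nd_c[0], cy = nd_c[1], cz = nd_c[2];
  NumericVector coarse((double)cx * cy * cz);
  const double* f = fine.begin();
  double* c = coarse.begin();
  for (int R = 0; R < cz; ++R)
    for (int Q = 0; Q < cy; ++Q)
      for (int P = 0; P < cx; ++P) {
        double acc = 0.0;
        for (int dr = -1; dr <= 1; ++dr) {
          const int r = 2 * R + dr; if (r < 0 || r >= fz) continue;
          for (int dq = -1; dq <= 1; ++dq) {
            const int q = 2 * Q + dq; if (q < 0 || q >= fy) continue;
            for (int dp = -1; dp <= 1; ++dp) {
              const int p = 2 * P + dp; if (p < 0 || p >= fx) continue;
              const double w = 1.0 / (1 << ((dp != 0) + (dq != 0) + (dr != 0)));
              acc += w * f[IDX(p, q, r, fx, fy)];
            }
          }
        }
        c[IDX(P, Q, R, cx, cy)] = acc;
      }
  return coarse;
}

// Add the trilinear prolongation of a coarse correction to the fine field,
// restricted to fine head nodes (diag > 0). Modifies phi in place.
// [[Rcpp::export]]
void mg_prolong_add(NumericVector phi, NumericVector coarse, NumericVector diag_f,
                    IntegerVector nd_f, IntegerVector nd_c) {
  const int fx = nd_f[0], fy = nd_f[1], fz = nd_f[2];
  const int cx = nd_c[0], cy = nd_c[1];
  double* ph = phi.begin();
  const double* c = coarse.begin();
  const double* dg = diag_f.begin();
  for (int r = 0; r < fz; ++r) {
    const int R0 = r / 2, R1 = (r + 1) / 2;  // equal when r even
    for (int q = 0; q < fy; ++q) {
      const int Q0 = q / 2, Q1 = (q + 1) / 2;
      for (int p = 0; p < fx; ++p) {
        const int i = IDX(p, q, r, fx, fy);
        if (dg[i] <= 0.0) continue;
        const int P0 = p / 2, P1 = (p + 1) / 2;
        double v = 0.0;
        v += c[IDX(P0, Q0, R0, cx, cy)];
        v += c[IDX(P1, Q0, R0, cx, cy)];
        v += c[IDX(P0, Q1, R0, cx, cy)];
        v += c[IDX(P1, Q1, R0, cx, cy)];
        v += c[IDX(P0, Q0, R1, cx, cy)];
        v += c[IDX(P1, Q0, R1, cx, cy)];
        v += c[IDX(P0, Q1, R1, cx, cy)];
        v += c[IDX(P1, Q1, R1, cx, cy)];
        ph[i] += 0.125 * v;
      }
    }
  }
}

// Number of 6-connected components among head nodes (edges with S > 0).
// [[Rcpp::export]]
int spfd_n_components(NumericVector Sx, NumericVector Sy, NumericVector Sz,
                      NumericVector diagv, IntegerVector nd) {
  const int ndx = nd[0], ndy = nd[1], ndz = nd[2];
  const R_xlen_t n = diagv.size();
  const double *sx = Sx.begin(), *sy = Sy.begin(), *sz = Sz.begin();
  const double* dg = diagv.begin();
  std::vector<char> seen(n, 0);
  std::vector<int> stack;
  int ncomp = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (seen[start] || dg[start] <= 0.0) continue;
    ++ncomp;
    stack.push_back((int)start);
    seen[start] = 1;
    while (!stack.empty()) {
      const int i = stack.back(); stack.pop_back();
      const int p = i % ndx, q = (i / ndx) % ndy, r = i / (ndx * ndy);
      int nb[6]; double sc[6]; int k = 0;
      if (p > 0)       { nb[k] = i - 1;         sc[k++] = sx[IDX(p - 1, q, r, ndx - 1, ndy)]; }
      if (p < ndx - 1) { nb[k] = i + 1;         sc[k++] = sx[IDX(p,     q, r, ndx - 1, ndy)]; }
      if (q > 0)       { nb[k] = i - ndx;       sc[k++] = sy[IDX(p, q - 1, r, ndx, ndy - 1)]; }
      if (q < ndy - 1) { nb[k] = i + ndx;       sc[k++] = sy[IDX(p, q,     r, ndx, ndy - 1)]; }
      if (r > 0)       { nb[k] = i - ndx * ndy; sc[k++] = sz[IDX(p, q, r - 1, ndx, ndy)]; }
      if (r < ndz - 1) { nb[k] = i + ndx * ndy; sc[k++] = sz[IDX(p, q, r,     ndx, ndy)]; }
      for (int t = 0; t < k; ++t) {
        if (sc[t] > 0.0 && !seen[nb[t]] && dg[nb[t]] > 0.0) {
          seen[nb[t]] = 1;
          stack.push_back(nb[t]);
        }
      }
    }
  }
  return ncomp;
}
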