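#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Explicit finite-difference stepper for the 2D diffusion equation
// dC/dt = D (Cxx + Cyy) on a regular grid with spacing dx (same in x and y).
//
// Boundary conditions:
//   x = 0  (source edge): source_bc = 0 -> Dirichlet at source_value
//                         source_bc = 1 -> no-flux (mirror ghost)
//   x = L  (sink edge):   sink_bc = 0 -> Robin, flux out = k * C (mass-transfer
//                                        coefficient k in um/s; ghost node
//                                        C_{N+1} = C_{N-1} - 2 dx (k/D) C_N)
//                         sink_bc = 1 -> Dirichlet 0
//                         sink_bc = 2 -> no-flux
//   long walls (y):       always no-flux (mirror ghost)
//
// Snapshots are recorded at the requested step counts (sorted, may include 0).
// Returns an nx x ny x nsnap array.
// [[Rcpp::export]]
NumericVector diffusion_run_cpp(NumericMatrix C0, double r, double dx,
                                double k_over_D, double source_value,
                                int source_bc, int sink_bc,
                                IntegerVector snapshot_steps) {
  const int nx = C0.nrow(), ny = C0.ncol();
  const int nsnap = snapshot_steps.size();
  NumericVector out(Dimension(nx, ny, nsnap));
  std::vector<double> cur(nx * ny), nxt(nx * ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) cur[i + j * nx] = C0(i, j);

  if (source_bc == 0)
    for (int j = 0; j < ny; ++j) cur[0 + j * nx] = source_value;
  if (sink_bc == 1)
    for (int j = 0; j < ny; ++j) cur[nx - 1 + j * nx] = 0.0;

  long max_step = 0;
  for (int s = 0; s < nsnap; ++s)
    if (snapshot_steps[s] > max_step) max_step = snapshot_steps[s];

  int snap_idx = 0;
  const double robin = 2.0 * dx * k_over_D;

  for (long step = 0; step <= max_step; ++step) {
    while (snap_idx < nsnap && snapshot_steps[snap_idx] == step) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          out[i + j * nx + (R_xlen_t)snap_idx * nx * ny] = cur[i + j * nx];
      ++snap_idx;
    }
    if (step == max_step) break;

    for (int j = 0; j < ny; ++j) {
      const int jm = (j == 0) ? 1 : j - 1;       // mirror ghosts on walls
      const int jp = (j == ny - 1) ? ny - 2 : j + 1;
      const double* cm = &cur[jm * nx];
      const double* cc = &cur[j * nx];
      const double* cp = &cur[jp * nx];
      double* nn = &nxt[j * nx];
      for (int i = 1; i < nx - 1; ++i)
        nn[i] = cc[i] + r * (cc[i - 1] + cc[i + 1] + cm[i] + cp[i]
                             - 4.0 * cc[i]);
      if (source_bc == 0) nn[0] = source_value;
      else nn[0] = cc[0] + r * (2.0 * cc[1] + cm[0] + cp[0] - 4.0 * cc[0]);
      const int e = nx - 1;
      if (sink_bc == 1) nn[e] = 0.0;
      else {
        const double right = (sink_bc == 2) ? cc[e - 1]
                                            : cc[e - 1] - robin * cc[e];
        nn[e] = cc[e] + r * (cc[e - 1] + right + cm[e] + cp[e] - 4.0 * cc[e]);
      }
    }
    cur.swap(nxt);
  }
  return out;
}

// 8-connected component labeling of a binary mask. Labels are assigned
// contiguously (1..n) in raster scan order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pr = p % nr, pc = p / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          const int qc = pc + dc;
          if (qc < 0 || qc >= nc) continue;
          for (int dr = -1; dr <= 1; ++dr) {
            const int qr = pr + dr;
            if (qr < 0 || qr >= nr || (dr == 0 && dc == 0)) continue;
            if (mask(qr, qc) && !lab(qr, qc)) {
              lab(qr, qc) = next;
              stack.push_back(qr + qc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// 3x3 median filter with replicated borders.
// [[Rcpp::export]]
NumericMatrix median3x3_cpp(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double v[9];
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int n = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        int qc = c + dc; qc = qc < 0 ? 0 : (qc >= nc ? nc - 1 : qc);
        for (int dr = -1; dr <= 1; ++dr) {
          int qr = r + dr; qr = qr < 0 ? 0 : (qr >= nr ? nr - 1 : qr);
          v[n++] = x(qr, qc);
        }
      }
      std::nth_element(v, v + 4, v + 9);
      out(r, c) = v[4];
    }
  }
  return out;
}
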