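#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Sequential minimal optimization for the binary soft-margin SVM dual:
//   min_a 0.5 a'Qa - e'a,  Q_ij = y_i y_j K_ij,  0 <= a_i <= C,  sum a_i y_i = 0.
// Maximal-violating-pair working-set selection; stops when the KKT gap
// m(a) - M(a) drops below tol. Returns alpha, the bias b (decision value is
// sum_i a_i y_i K(x_i, x) + b) and the dual objective sum(a) - 0.5 a'Qa.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double tol,
               int max_iter) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G = Qa - e
  int iter = 0;
  double m_up = 0.0, m_low = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    // select i maximizing -y_i G_i over I_up, j minimizing over I_low
    int i = -1, j = -1;
    m_up = -R_PosInf;
    m_low = R_PosInf;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > m_up) { m_up = v; i = t; }
      if (low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low <= tol) break;
    // analytic step along d with d_i = y_i, d_j = -y_j, which preserves
    // the equality constraint; curvature along d is K_ii + K_jj - 2 K_ij
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 1e-12) quad = 1e-12;
    double step = (m_up - m_low) / quad;
    // clamp the step so both multipliers stay inside the box
    double hi = step;
    hi = std::min(hi, y[i] > 0 ? C - alpha[i] : alpha[i]);
    hi = std::min(hi, y[j] > 0 ? alpha[j] : C - alpha[j]);
    if (hi <= 0) break;  // numerically no room to move
    double di = y[i] * hi, dj = -y[j] * hi;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(i, t) * di + y[j] * K(j, t) * dj);
    alpha[i] += di;
    alpha[j] += dj;
  }
  // recompute final violating-pair bounds for b
  m_up = -R_PosInf; m_low = R_PosInf;
  for (int t = 0; t < n; ++t) {
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    double v = -y[t] * G[t];
    if (up && v > m_up) m_up = v;
    if (low && v < m_low) m_low = v;
  }
  double b = (m_up + m_low) / 2.0;
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] - 0.5 * alpha[t] * (G[t] + 1.0);
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["objective"] = obj,
                      _["iterations"] = iter, _["kkt_gap"] = m_up - m_low);
}

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 6-connected flood fill over the TRUE voxels of `accept` starting at the
// 1-based linear seed indices. Returns a logical vector marking the grown
// region.
// [[Rcpp::export(name = ".flood_fill6")]]
LogicalVector flood_fill6(LogicalVector accept, IntegerVector dim,
                          IntegerVector seeds) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(accept.size(), false);
  std::queue<int> q;
  for (int s = 0; s < seeds.size(); ++s) {
    int v = seeds[s] - 1;
    if (v >= 0 && v < accept.size() && accept[v] && !out[v]) {
      out[v] = true;
      q.push(v);
    }
  }
  while (!q.empty()) {
    int v = q.front(); q.pop();
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int w = idx3(xx, yy, zz, nx, ny);
      if (accept[w] && !out[w]) { out[w] = true; q.push(w); }
    }
  }
  return out;
}

// 6-connected component labeling of the TRUE voxels; labels 1..k in order of
// first (column-major) encounter, 0 elsewhere.
// [[Rcpp::export(name = ".label_components6")]]
IntegerVector label_components6(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (int v = 0; v < mask.size(); ++v) {
    if (!mask[v] || lab[v]) continue;
    lab[v] = ++next;
    q.push(v);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      int x = u % nx, y = (u / nx) % ny, z = u / (nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = idx3(xx, yy, zz, nx, ny);
        if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
      }
    }
  }
  return lab;
}
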