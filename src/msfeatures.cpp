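// Multiscale per-point covariance eigenfeatures with uniform-grid radius
// search. Each scale is the DIAMETER of the search sphere; the vertical-range
// feature uses an XY cylinder of the same diameter, unbounded in Z.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>

// [[Rcpp::depends(RcppArmadillo)]]

namespace {

// 3D (or 2D with iz = 0) cell key packed into a 64-bit integer.
inline long long cell_key(long long ix, long long iy, long long iz) {
  // offset to keep components non-negative within 21 bits
  const long long off = 1LL << 20;
  return ((ix + off) << 42) | ((iy + off) << 21) | (iz + off);
}

struct Grid {
  double cell;
  bool use_z;
  std::unordered_map<long long, std::vector<int> > cells;

  Grid(const arma::mat& P, double cell_size, bool with_z)
      : cell(cell_size), use_z(with_z) {
    const int n = P.n_rows;
    cells.reserve(static_cast<size_t>(n));
    for (int i = 0; i < n; ++i) {
      long long ix = (long long)std::floor(P(i, 0) / cell);
      long long iy = (long long)std::floor(P(i, 1) / cell);
      long long iz = use_z ? (long long)std::floor(P(i, 2) / cell) : 0;
      cells[cell_key(ix, iy, iz)].push_back(i);
    }
  }

  // indices of points within `radius` of point q (3D sphere or XY disc)
  void query(const arma::mat& P, int q, double radius,
             std::vector<int>& out) const {
    out.clear();
    const double r2 = radius * radius;
    long long ix = (long long)std::floor(P(q, 0) / cell);
    long long iy = (long long)std::floor(P(q, 1) / cell);
    long long iz = use_z ? (long long)std::floor(P(q, 2) / cell) : 0;
    long long zlo = use_z ? iz - 1 : 0, zhi = use_z ? iz + 1 : 0;
    for (long long cx = ix - 1; cx <= ix + 1; ++cx)
      for (long long cy = iy - 1; cy <= iy + 1; ++cy)
        for (long long cz = zlo; cz <= zhi; ++cz) {
          auto it = cells.find(cell_key(cx, cy, cz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            double dx = P(j, 0) - P(q, 0);
            double dy = P(j, 1) - P(q, 1);
            double d2 = dx * dx + dy * dy;
            if (use_z) {
              double dz = P(j, 2) - P(q, 2);
              d2 += dz * dz;
            }
            if (d2 <= r2) out.push_back(j);
          }
        }
  }
};

// type-7 quantile (linear interpolation between order statistics) on a
// sorted vector
inline double quantile7(const std::vector<double>& z, double p) {
  const int n = (int)z.size();
  if (n == 1) return z[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return z[n - 1];
  return z[lo] + (h - lo) * (z[lo + 1] - z[lo]);
}

}  // namespace

// [[Rcpp::export(name = ".ms_extract_cpp")]]
Rcpp::NumericMatrix ms_extract_cpp(const arma::mat& coords,
                                   const arma::vec& diameters,
                                   int min_neighbors) {
  const int n = coords.n_rows;
  const int s = diameters.n_elem;
  Rcpp::NumericMatrix out(n, 5 * s);

  std::vector<int> nb;
  std::vector<double> zcol;
  const double rad2deg = 180.0 / M_PI;

  for (int sc = 0; sc < s; ++sc) {
    const double r = diameters(sc) / 2.0;
    Grid g3(coords, r, true);
    Grid g2(coords, r, false);
    const int base = 5 * sc;

    for (int i = 0; i < n; ++i) {
      g3.query(coords, i, r, nb);
      const int m = (int)nb.size();

      double L = 0.0, PL = 0.0, SPH = 0.0, HOR = 0.0;
      if (m >= min_neighbors) {
        // two-pass centered covariance, 1/m normalization
        arma::vec mean(3, arma::fill::zeros);
        for (int j : nb) mean += coords.row(j).t();
        mean /= m;
        arma::mat C(3, 3, arma::fill::zeros);
        for (int j : nb) {
          arma::vec d = coords.row(j).t() - mean;
          C += d * d.t();
        }
        C /= m;
        arma::vec ev;
        arma::mat V;
        arma::eig_sym(ev, V, C);  // ascending
        double l1 = std::max(ev(2), 0.0);
        double l2 = std::max(ev(1), 0.0);
        double l3 = std::max(ev(0), 0.0);
        if (l1 > 0.0) {
          L = (l1 - l2) / l1;
          PL = (l2 - l3) / l1;
          SPH = l3 / l1;
          double vz = std::min(std::fabs(V(2, 0)), 1.0);  // v3 = smallest
          HOR = std::acos(vz) * rad2deg;
        }
      }

      out(i, base + 0) = L;
      out(i, base + 1) = PL;
      out(i, base + 2) = SPH;
      out(i, base + 3) = HOR;
    }

    // vertical-extent feature: XY-cylinder neighborhoods
    std::vector<int> cyl;
    for (int i = 0; i < n; ++i) {
      g2.query(coords, i, r, cyl);
      zcol.clear();
      zcol.reserve(cyl.size());
      for (int j : cyl) zcol.push_back(coords(j, 2));
      std::sort(zcol.begin(), zcol.end());
      out(i, base + 4) = quantile7(zcol, 0.95) - quantile7(zcol, 0.05);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".radius_neighbors_cpp")]]
Rcpp::List radius_neighbors_cpp(const arma::mat& coords, double radius,
                                bool xy_only) {
  const int n = coords.n_rows;
  Grid g(coords, radius, !xy_only);
  Rcpp::List res(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    g.query(coords, i, radius, nb);
    std::sort(nb.begin(), nb.end());
    Rcpp::IntegerVector v(nb.size());
    for (size_t k = 0; k < nb.size(); ++k) v[k] = nb[k] + 1;  // 1-based
    res[i] = v;
  }
  return res;
}
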