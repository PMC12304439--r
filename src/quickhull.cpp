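// Incremental (beneath-beyond) convex hull in d dimensions.
//
// Point sets here are small (tens of species embedded on 2-6 PCoA axes), but
// hull volumes sit inside the null-model loop, so they are computed hundreds
// of thousands of times per analysis; that is why this lives in C++.
//
// Facets are (d-1)-simplices (d vertex indices). Points within `eps` of a
// facet's hyperplane are treated as non-visible, so degenerate inputs
// (coplanar subsets) never create zero-area facets; a fully degenerate input
// (affine rank < d) is reported via status so the caller can drop to a lower
// dimensionality.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>

using namespace Rcpp;

typedef std::vector<double> vec;

// determinant by Gaussian elimination with partial pivoting (n <= 8 here)
static double det_ge(std::vector<vec> a) {
  int n = a.size();
  double det = 1.0;
  for (int c = 0; c < n; ++c) {
    int piv = c;
    for (int r = c + 1; r < n; ++r)
      if (std::fabs(a[r][c]) > std::fabs(a[piv][c])) piv = r;
    if (a[piv][c] == 0.0) return 0.0;
    if (piv != c) { std::swap(a[piv], a[c]); det = -det; }
    det *= a[c][c];
    for (int r = c + 1; r < n; ++r) {
      double f = a[r][c] / a[c][c];
      for (int k = c; k < n; ++k) a[r][k] -= f * a[c][k];
    }
  }
  return det;
}

struct Facet {
  std::vector<int> v;   // d vertex indices
  vec normal;           // outward unit-ish normal
  double offset;        // dot(normal, x) = offset on the plane
};

class Hull {
public:
  int n, d;
  const double *pts;    // column-major n x d
  double eps;
  std::vector<Facet> facets;
  vec interior;
  int status;           // 0 ok, 1 degenerate (affine rank < d)

  Hull(const double *p, int n_, int d_) : n(n_), d(d_), pts(p), status(0) {
    double scale = 0.0;
    for (int i = 0; i < n * d; ++i) scale = std::max(scale, std::fabs(pts[i]));
    eps = 1e-9 * (scale > 0 ? scale : 1.0);
    build();
  }

  double coord(int i, int k) const { return pts[k * n + i]; }

  // generalized cross product: normal to span of rows of (d-1) x d matrix
  vec nullvec(const std::vector<vec> &edges) {
    vec nrm(d);
    for (int j = 0; j < d; ++j) {
      std::vector<vec> sub(d - 1, vec(d - 1));
      for (int r = 0; r < d - 1; ++r) {
        int cc = 0;
        for (int c = 0; c < d; ++c)
          if (c != j) sub[r][cc++] = edges[r][c];
      }
      nrm[j] = ((j % 2) ? -1.0 : 1.0) * det_ge(sub);
    }
    return nrm;
  }

  void make_facet(std::vector<int> verts) {
    std::vector<vec> edges(d - 1, vec(d));
    for (int r = 0; r < d - 1; ++r)
      for (int c = 0; c < d; ++c)
        edges[r][c] = coord(verts[r + 1], c) - coord(verts[0], c);
    vec nrm = nullvec(edges);
    double len = 0.0;
    for (int c = 0; c < d; ++c) len += nrm[c] * nrm[c];
    len = std::sqrt(len);
    if (len <= 0) return;  // degenerate facet, skip
    double off = 0.0, side = 0.0;
    for (int c = 0; c < d; ++c) { nrm[c] /= len; off += nrm[c] * coord(verts[0], c); }
    for (int c = 0; c < d; ++c) side += nrm[c] * interior[c];
    if (side > off) {          // flip outward
      for (int c = 0; c < d; ++c) nrm[c] = -nrm[c];
      off = -off;
    }
    Facet f; f.v = verts; f.normal = nrm; f.offset = off;
    facets.push_back(f);
  }

  void build() {
    // greedy affinely independent start: d+1 points spanning the space
    std::vector<int> init;
    init.push_back(0);
    std::vector<vec> basis;  // orthonormalized edge directions
    for (int step = 0; step < d; ++step) {
      int best = -1; double bestres = eps;
      for (int i = 0; i < n; ++i) {
        vec r(d);
        for (int c = 0; c < d; ++c) r[c] = coord(i, c) - coord(init[0], c);
        for (size_t b = 0; b < basis.size(); ++b) {
          double dp = 0.0;
          for (int c = 0; c < d; ++c) dp += r[c] * basis[b][c];
          for (int c = 0; c < d; ++c) r[c] -= dp * basis[b][c];
        }
        double len = 0.0;
        for (int c = 0; c < d; ++c) len += r[c] * r[c];
        len = std::sqrt(len);
        if (len > bestres) { bestres = len; best = i; }
      }
      if (best < 0) { status = 1; return; }
      init.push_back(best);
      vec r(d);
      for (int c = 0; c < d; ++c) r[c] = coord(best, c) - coord(init[0], c);
      for (size_t b = 0; b < basis.size(); ++b) {
        double dp = 0.0;
        for (int c = 0; c < d; ++c) dp += r[c] * basis[b][c];
        for (int c = 0; c < d; ++c) r[c] -= dp * basis[b][c];
      }
      double len = 0.0;
      for (int c = 0; c < d; ++c) len += r[c] * r[c];
      len = std::sqrt(len);
      for (int c = 0; c < d; ++c) r[c] /= len;
      basis.push_back(r);
    }

    interior.assign(d, 0.0);
    for (int j = 0; j <= d; ++j)
      for (int c = 0; c < d; ++c) interior[c] += coord(init[j], c) / (d + 1);

    // initial simplex facets: all d-subsets of init
    for (int drop = 0; drop <= d; ++drop) {
      std::vector<int> verts;
      for (int j = 0; j <= d; ++j)
        if (j != drop) verts.push_back(init[j]);
      make_facet(verts);
    }

    std::vector<bool> used(n, false);
    for (int j = 0; j <= d; ++j) used[init[j]] = true;
    for (int i = 0; i < n; ++i) {
      if (used[i]) continue;
      add_point(i);
    }
  }

  void add_point(int p) {
    std::vector<char> visible(facets.size(), 0);
    bool any = false;
    for (size_t f = 0; f < facets.size(); ++f) {
      double s = -facets[f].offset;
      for (int c = 0; c < d; ++c) s += facets[f].normal[c] * coord(p, c);
      if (s > eps) { visible[f] = 1; any = true; }
    }
    if (!any) return;  // interior or on-boundary point

    // horizon ridges: (d-1)-subsets of visible facets' vertices that are not
    // shared between two visible facets
    std::map<std::vector<int>, int> ridge_count;
    for (size_t f = 0; f < facets.size(); ++f) {
      if (!visible[f]) continue;
      for (int drop = 0; drop < d; ++drop) {
        std::vector<int> ridge;
        for (int j = 0; j < d; ++j)
          if (j != drop) ridge.push_back(facets[f].v[j]);
        std::sort(ridge.begin(), ridge.end());
        ridge_count[ridge]++;
      }
    }
    std::vector<Facet> kept;
    for (size_t f = 0; f < facets.size(); ++f)
      if (!visible[f]) kept.push_back(facets[f]);
    facets.swap(kept);
    for (std::map<std::vector<int>, int>::iterator it = ridge_count.begin();
         it != ridge_count.end(); ++it) {
      if (it->second != 1) continue;  // internal ridge
      std::vector<int> verts = it->first;
      verts.push_back(p);
      make_facet(verts);
    }
  }

  double volume() const {
    if (status != 0) return 0.0;
    double fact = 1.0;
    for (int k = 2; k <= d; ++k) fact *= k;
    double vol = 0.0;
    for (size_t f = 0; f < facets.size(); ++f) {
      std::vector<vec> m(d, vec(d));
      for (int r = 0; r < d; ++r)
        for (int c = 0; c < d; ++c)
          m[r][c] = coord(facets[f].v[r], c) - interior[c];
      vol += std::fabs(det_ge(m)) / fact;
    }
    return vol;
  }

  std::vector<int> vertices() const {
    std::vector<bool> isv(n, false);
    for (size_t f = 0; f < facets.size(); ++f)
      for (int j = 0; j < d; ++j) isv[facets[f].v[j]] = true;
    std::vector<int> out;
    for (int i = 0; i < n; ++i)
      if (isv[i]) out.push_back(i + 1);  // 1-based for R
    return out;
  }
};

// drop duplicate rows (within tol) before hull construction
static std::vector<int> unique_rows(const NumericMatrix &x, double tol) {
  int n = x.nrow(), d = x.ncol();
  std::vector<int> keep;
  for (int i = 0; i < n; ++i) {
    bool dup = false;
    for (size_t j = 0; j < keep.size() && !dup; ++j) {
      bool same = true;
      for (int c = 0; c < d; ++c)
        if (std::fabs(x(i, c) - x(keep[j], c)) > tol) { same = false; break; }
      dup = same;
    }
    if (!dup) keep.push_back(i);
  }
  return keep;
}

// [[Rcpp::export(name = ".cpp_convhull")]]
List cpp_convhull(NumericMatrix x) {
  int n = x.nrow(), d = x.ncol();
  if (n < d + 1)
    return List::create(_["status"] = 1, _["volume"] = 0.0,
                        _["vertices"] = IntegerVector(0));
  Hull h(REAL(x), n, d);
  if (h.status != 0)
    return List::create(_["status"] = 1, _["volume"] = 0.0,
                        _["vertices"] = IntegerVector(0));
  return List::create(_["status"] = 0, _["volume"] = h.volume(),
                      _["vertices"] = wrap(h.vertices()));
}

// Batch hull volumes for null-model draws: each column of `idx` holds 1-based
// row indices into `pool`; duplicates within a draw are removed first.
// Degenerate draws yield NA.
// [[Rcpp::export(name = ".cpp_hull_volumes")]]
NumericVector cpp_hull_volumes(NumericMatrix pool, IntegerMatrix idx) {
  int d = pool.ncol(), S = idx.nrow(), nsim = idx.ncol();
  NumericVector out(nsim);
  double scale = 0.0;
  for (int i = 0; i < pool.nrow() * d; ++i)
    scale = std::max(scale, std::fabs(pool[i]));
  double tol = 1e-12 * (scale > 0 ? scale : 1.0);
  std::vector<double> buf;
  for (int s = 0; s < nsim; ++s) {
    NumericMatrix sub(S, d);
    for (int r = 0; r < S; ++r)
      for (int c = 0; c < d; ++c)
        sub(r, c) = pool(idx(r, s) - 1, c);
    std::vector<int> keep = unique_rows(sub, tol);
    int m = keep.size();
    if (m < d + 1) { out[s] = NA_REAL; continue; }
    buf.assign((size_t)m * d, 0.0);
    for (int r = 0; r < m; ++r)
      for (int c = 0; c < d; ++c)
        buf[(size_t)c * m + r] = sub(keep[r], c);
    Hull h(&buf[0], m, d);
    out[s] = (h.status == 0) ? h.volume() : NA_REAL;
  }
  return out;
}
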