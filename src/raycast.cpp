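#include <Rcpp.h>
using namespace Rcpp;

// Count, for each point, how many ray directions hit an atom sphere
// within `range`.  A ray blocks when the entry distance along the ray
// (t - sqrt(r^2 - b^2)) is positive-side and at most `range`.
// [[Rcpp::export(name = ".raycast_counts")]]
IntegerVector raycast_counts(NumericMatrix points, NumericMatrix atoms,
                             NumericVector radii, NumericMatrix dirs,
                             double range) {
  const int np = points.nrow(), na = atoms.nrow(), nd = dirs.nrow();
  IntegerVector counts(np);
  std::vector<double> ax(na), ay(na), az(na), r2(na);
  for (int a = 0; a < na; ++a) {
    ax[a] = atoms(a, 0); ay[a] = atoms(a, 1); az[a] = atoms(a, 2);
    r2[a] = radii[a] * radii[a];
  }
  const double maxr = radii.size() ? *std::max_element(radii.begin(), radii.end()) : 0.0;
  const double reach2 = (range + maxr) * (range + maxr);
  std::vector<double> dx, dy, dz, d2;
  dx.reserve(na); dy.reserve(na); dz.reserve(na); d2.reserve(na);
  std::vector<int> aidx; aidx.reserve(na);
  for (int p = 0; p < np; ++p) {
    dx.clear(); dy.clear(); dz.clear(); d2.clear(); aidx.clear();
    const double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    for (int a = 0; a < na; ++a) {
      const double ddx = ax[a] - px, ddy = ay[a] - py, ddz = az[a] - pz;
      const double dd2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (dd2 <= reach2) {
        dx.push_back(ddx); dy.push_back(ddy); dz.push_back(ddz);
        d2.push_back(dd2); aidx.push_back(a);
      }
    }
    const int nn = (int)dx.size();
    if (!nn) continue;
    int blocked = 0;
    for (int k = 0; k < nd; ++k) {
      const double ux = dirs(k, 0), uy = dirs(k, 1), uz = dirs(k, 2);
      for (int a = 0; a < nn; ++a) {
        const double t = dx[a] * ux + dy[a] * uy + dz[a] * uz;
        if (t <= 0) continue;
        const double b2 = d2[a] - t * t;
        const double rr2 = r2[aidx[a]];
        if (b2 > rr2) continue;
        if (t - std::sqrt(rr2 - b2) <= range) { ++blocked; break; }
      }
    }
    counts[p] = blocked;
  }
  return counts;
}

// Row-wise minimum of a squared-distance computation between two
// coordinate sets, without materialising the full matrix.
// [[Rcpp::export(name = ".min_dist2")]]
NumericVector min_dist2(NumericMatrix p, NumericMatrix q) {
  const int np = p.nrow(), nq = q.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    const double px = p(i, 0), py = p(i, 1), pz = p(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nq; ++j) {
      const double dx = q(j, 0) - px, dy = q(j, 1) - py, dz = q(j, 2) - pz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = best;
  }
  return out;
}
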