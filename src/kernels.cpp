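#include <Rcpp.h>
using namespace Rcpp;

// Grid-probe void classification for one frame.
// A voxel is "free" if its centre is at least (vdw_i + probe) away from every
// atom i, and "buried" if at least min_hits of the supplied scan rays meet an
// atom (ray passes within vdw_i of the atom centre, with the entry point of
// the ray into the sphere no farther than ray_len from the voxel).
// Returns 0 = clash, 1 = free but exposed, 2 = void (free and buried).
// [[Rcpp::export]]
IntegerVector cpp_classify_voxels(NumericMatrix vox, NumericMatrix atoms,
                                  NumericVector vdw, double probe,
                                  NumericMatrix rays, double ray_len,
                                  int min_hits) {
  const int nv = vox.nrow(), na = atoms.nrow(), nr = rays.nrow();
  IntegerVector out(nv);
  std::vector<double> ax(na), ay(na), az(na), rad2(na);
  double maxrad = 0.0;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int a = 0; a < na; ++a) {
    ax[a] = atoms(a, 0); ay[a] = atoms(a, 1); az[a] = atoms(a, 2);
    const double r = vdw[a] + probe; rad2[a] = r * r;
    if (vdw[a] > maxrad) maxrad = vdw[a];
    if (ax[a] < lo[0]) lo[0] = ax[a];
    if (ay[a] < lo[1]) lo[1] = ay[a];
    if (az[a] < lo[2]) lo[2] = az[a];
  }
  // cell list over the atoms so each voxel only gathers nearby atoms
  const double h = 3.4;
  const double reach = ray_len + maxrad;
  const double reach2 = reach * reach;
  const int span = (int)std::ceil(reach / h);
  int ncell[3];
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int a = 0; a < na; ++a) {
    if (ax[a] > hi[0]) hi[0] = ax[a];
    if (ay[a] > hi[1]) hi[1] = ay[a];
    if (az[a] > hi[2]) hi[2] = az[a];
  }
  for (int d = 0; d < 3; ++d)
    ncell[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / h) + 1);
  std::vector<std::vector<int> > cells((size_t)ncell[0] * ncell[1] * ncell[2]);
  for (int a = 0; a < na; ++a) {
    int ix = std::min(ncell[0] - 1, std::max(0, (int)((ax[a] - lo[0]) / h)));
    int iy = std::min(ncell[1] - 1, std::max(0, (int)((ay[a] - lo[1]) / h)));
    int iz = std::min(ncell[2] - 1, std::max(0, (int)((az[a] - lo[2]) / h)));
    cells[((size_t)ix * ncell[1] + iy) * ncell[2] + iz].push_back(a);
  }
  std::vector<int> near_idx; near_idx.reserve(2048);

  for (int v = 0; v < nv; ++v) {
    const double x = vox(v, 0), y = vox(v, 1), z = vox(v, 2);
    bool clash = false;
    near_idx.clear();
    const int cx = (int)std::floor((x - lo[0]) / h);
    const int cy = (int)std::floor((y - lo[1]) / h);
    const int cz = (int)std::floor((z - lo[2]) / h);
    for (int ix = std::max(0, cx - span);
         ix <= std::min(ncell[0] - 1, cx + span) && !clash; ++ix)
      for (int iy = std::max(0, cy - span);
           iy <= std::min(ncell[1] - 1, cy + span) && !clash; ++iy)
        for (int iz = std::max(0, cz - span);
             iz <= std::min(ncell[2] - 1, cz + span) && !clash; ++iz) {
          const std::vector<int> &cell =
            cells[((size_t)ix * ncell[1] + iy) * ncell[2] + iz];
          for (size_t q = 0; q < cell.size(); ++q) {
            const int a = cell[q];
            const double dx = ax[a] - x, dy = ay[a] - y, dz = az[a] - z;
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < rad2[a]) { clash = true; break; }
            if (d2 <= reach2) near_idx.push_back(a);
          }
        }
    if (clash) { out[v] = 0; continue; }
    int hits = 0;
    for (int r = 0; r < nr && hits < min_hits; ++r) {
      const double ux = rays(r, 0), uy = rays(r, 1), uz = rays(r, 2);
      bool hit = false;
      for (size_t k = 0; k < near_idx.size(); ++k) {
        const int a = near_idx[k];
        const double dx = ax[a] - x, dy = ay[a] - y, dz = az[a] - z;
        const double t = dx * ux + dy * uy + dz * uz;   // projection on ray
        if (t <= 0.0) continue;
        const double p2 = dx * dx + dy * dy + dz * dz - t * t;
        const double v2 = vdw[a] * vdw[a];
        if (p2 > v2) continue;
        const double entry = t - std::sqrt(v2 - p2);
        if (entry <= ray_len) { hit = true; break; }
      }
      if (hit) ++hits;
    }
    out[v] = (hits >= min_hits) ? 2 : 1;
  }
  return out;
}

// Minimum Euclidean distance from each query point to a reference point set.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix pts, NumericMatrix ref) {
  const int np = pts.nrow(), nr = ref.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    double best = R_PosInf;
    for (int r = 0; r < nr; ++r) {
      const double dx = ref(r, 0) - x, dy = ref(r, 1) - y, dz = ref(r, 2) - z;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// TRUE for points lying within (vdw_i + probe) of any atom i (early exit).
// [[Rcpp::export]]
LogicalVector cpp_clash(NumericMatrix pts, NumericMatrix atoms,
                        NumericVector vdw, double probe) {
  const int np = pts.nrow(), na = atoms.nrow();
  LogicalVector out(np);
  for (int p = 0; p < np; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    bool clash = false;
    for (int a = 0; a < na && !clash; ++a) {
      const double r = vdw[a] + probe;
      const double dx = atoms(a, 0) - x;
      if (dx > r || dx < -r) continue;
      const double dy = atoms(a, 1) - y, dz = atoms(a, 2) - z;
      if (dx * dx + dy * dy + dz * dz < r * r) clash = true;
    }
    out[p] = clash;
  }
  return out;
}
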