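#include <Rcpp.h>
using namespace Rcpp;

// Software triangle rasterizer with z-buffer.
//
// Inputs are screen-space vertex coordinates (pixels) and camera-space
// depths; faces are 1-based triangle index triples. Pixel (r, c) of the
// H x W output samples the point (c - 0.5, r - 0.5) in screen coordinates.
// Depth is interpolated affinely in screen space, which is exact at the
// vertices (all the baking step relies on). Faces with any vertex at or
// behind the camera are skipped (the camera orbits outside the scan, so
// nothing legitimately crosses the near plane). Both triangle windings are
// rasterized (no back-face culling).
//
// Returns per-pixel: depth (Inf = background), 1-based face id (0 =
// background), and the first two barycentric weights (b3 = 1 - b1 - b2).

// [[Rcpp::export]]
List cpp_rasterize(NumericVector px, NumericVector py, NumericVector pz,
                   IntegerMatrix faces, int width, int height) {
  NumericMatrix depth(height, width);
  IntegerMatrix face(height, width);
  NumericMatrix b1(height, width), b2(height, width);
  std::fill(depth.begin(), depth.end(), R_PosInf);

  const double near = 1e-9;
  int M = faces.nrow();
  for (int m = 0; m < M; ++m) {
    int i0 = faces(m, 0) - 1, i1 = faces(m, 1) - 1, i2 = faces(m, 2) - 1;
    double z0 = pz[i0], z1 = pz[i1], z2 = pz[i2];
    if (z0 <= near || z1 <= near || z2 <= near) continue;
    double x0 = px[i0], y0 = py[i0];
    double x1 = px[i1], y1 = py[i1];
    double x2 = px[i2], y2 = py[i2];
    double den = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(den) < 1e-12) continue;

    double minx = std::min(x0, std::min(x1, x2));
    double maxx = std::max(x0, std::max(x1, x2));
    double miny = std::min(y0, std::min(y1, y2));
    double maxy = std::max(y0, std::max(y1, y2));
    int c0 = std::max(0, (int)std::floor(minx + 0.5));
    int c1 = std::min(width - 1, (int)std::floor(maxx + 0.5));
    int r0 = std::max(0, (int)std::floor(miny + 0.5));
    int r1 = std::min(height - 1, (int)std::floor(maxy + 0.5));

    for (int r = r0; r <= r1; ++r) {
      double sy = r + 0.5;
      for (int c = c0; c <= c1; ++c) {
        double sx = c + 0.5;
        double wa = ((x1 - sx) * (y2 - sy) - (x2 - sx) * (y1 - sy)) / den;
        double wb = ((x2 - sx) * (y0 - sy) - (x0 - sx) * (y2 - sy)) / den;
        double wc = 1.0 - wa - wb;
        if (wa < 0 || wb < 0 || wc < 0) continue;
        double z = wa * z0 + wb * z1 + wc * z2;
        if (z < depth(r, c)) {
          depth(r, c) = z;
          face(r, c) = m + 1;
          b1(r, c) = wa;
          b2(r, c) = wb;
        }
      }
    }
  }
  return List::create(_["depth"] = depth, _["face"] = face,
                      _["b1"] = b1, _["b2"] = b2);
}

// Brute-force nearest neighbour between small point clouds (tooth- and
// rugae-patch sized; an index structure would not pay for itself here).
// Returns 1-based indices into `ref` and squared distances.

// [[Rcpp::export]]
List cpp_nearest(NumericMatrix query, NumericMatrix ref) {
  int n = query.nrow(), m = ref.nrow();
  IntegerVector idx(n);
  NumericVector d2(n);
  for (int i = 0; i < n; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    int bestj = 0;
    for (int j = 0; j < m; ++j) {
      double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bestj = j; }
    }
    idx[i] = bestj + 1;
    d2[i] = best;
  }
  return List::create(_["index"] = idx, _["dist2"] = d2);
}
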