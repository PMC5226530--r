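#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 2D prominence-based maxima (ImageJ Find-Maxima "noise tolerance" semantics).
//
// A candidate is a pixel >= all 8 neighbours. A candidate c is reported iff
// the 8-connected flood region {q : v(q) > v(c) - prominence} containing c
//   (i) contains no pixel strictly brighter than c,
//  (ii) does not cover the whole image (peak-to-boundary drop < prominence),
// (iii) c has the smallest linear index among equal-valued candidates in it.
// Implemented by processing candidates in (value desc, index asc) order and
// claiming flooded pixels; the declarative rule above is what tests check.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_find_maxima_2d(NumericMatrix img, double prominence) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<int> cand;
  cand.reserve(64);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      bool ismax = true;
      for (int dj = -1; dj <= 1 && ismax; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (img(ii, jj) > v) { ismax = false; break; }
        }
      if (ismax) cand.push_back(i + nr * j);
    }
  }
  std::sort(cand.begin(), cand.end(), [&](int a, int b) {
    double va = img[a], vb = img[b];
    if (va != vb) return va > vb;
    return a < b;
  });
  std::vector<char> claimed(n, 0), visited(n, 0);
  std::vector<int> region;
  std::vector<int> out;
  for (int c : cand) {
    if (claimed[c]) continue;
    double vc = img[c];
    double thr = vc - prominence;
    region.clear();
    std::queue<int> q;
    q.push(c);
    visited[c] = 1;
    region.push_back(c);
    bool bad = false;
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int pi = p % nr, pj = p / nr;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          int ii = pi + di, jj = pj + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          int pp = ii + nr * jj;
          if (visited[pp]) continue;
          double vp = img[pp];
          if (!(vp > thr)) continue;
          if (vp > vc) bad = true;
          if (claimed[pp]) { bad = true; visited[pp] = 1; region.push_back(pp); continue; }
          visited[pp] = 1;
          region.push_back(pp);
          q.push(pp);
        }
    }
    if ((int)region.size() == n) bad = true;  // flat within prominence
    for (int p : region) { claimed[p] = 1; visited[p] = 0; }
    if (!bad) out.push_back(c);
  }
  IntegerMatrix res(out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    res(k, 0) = out[k] % nr + 1;  // row, 1-based
    res(k, 1) = out[k] / nr + 1;  // col
  }
  return res;
}

// ---------------------------------------------------------------------------
// 26-connected labeling of a logical 3D array (dims z, y, x).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int pz = p % nz, py = (p / nz) % ny, px = p / (nz * ny);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            int zz = pz + dz, yy = py + dy, xx = px + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            int pp = zz + nz * (yy + ny * xx);
            if (mask[pp] && !lab[pp]) { lab[pp] = next; q.push(pp); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Level-descending synchronous flooding from seed peaks (26-connectivity).
//
// Thresholds descend from the brightest peak towards `floor` in steps of
// `step`. At each level, growth proceeds in synchronous sweeps: every
// unassigned voxel with intensity >= level that touches exactly one region
// (through non-frozen voxels, state taken before the sweep) joins it; a voxel
// touching two or more regions is assigned to the region whose seed peak is
// physically nearer (tie: brighter peak, then lower label) and frozen, so it
// does not conduct further growth. Synchronous updates make the result
// independent of voxel iteration order.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_flood_regions(NumericVector img, IntegerVector dims,
                       IntegerVector peakIdx,  // 0-based linear seeds
                       NumericVector peakVal,
                       double floorLevel, double step,
                       NumericVector voxelSize,  // dz, dy, dx (um)
                       LogicalVector allowed) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  const int npk = peakIdx.size();
  const double dz = voxelSize[0], dy = voxelSize[1], dx = voxelSize[2];
  IntegerVector lab(n, 0);
  LogicalVector frozen(n, false);
  std::vector<double> pz(npk), py(npk), px(npk);
  double topLevel = R_NegInf;
  for (int k = 0; k < npk; ++k) {
    int p = peakIdx[k];
    lab[p] = k + 1;
    pz[k] = p % nz; py[k] = (p / nz) % ny; px[k] = p / (nz * ny);
    if (peakVal[k] > topLevel) topLevel = peakVal[k];
  }
  if (npk == 0) {
    lab.attr("dim") = dims;
    return List::create(_["labels"] = lab, _["frozen"] = frozen);
  }
  // perimeter: unassigned allowed voxels adjacent to >=1 labelled non-frozen voxel
  std::vector<int> perim;
  std::vector<char> inPerim(n, 0);
  auto addNbrsToPerim = [&](int p) {
    int zz0 = p % nz, yy0 = (p / nz) % ny, xx0 = p / (nz * ny);
    for (int ddx = -1; ddx <= 1; ++ddx)
      for (int ddy = -1; ddy <= 1; ++ddy)
        for (int ddz = -1; ddz <= 1; ++ddz) {
          if (!ddx && !ddy && !ddz) continue;
          int zz = zz0 + ddz, yy = yy0 + ddy, xx = xx0 + ddx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          int pp = zz + nz * (yy + ny * xx);
          if (!lab[pp] && allowed[pp] && !inPerim[pp]) {
            inPerim[pp] = 1;
            perim.push_back(pp);
          }
        }
  };
  for (int k = 0; k < npk; ++k) addNbrsToPerim(peakIdx[k]);

  std::vector<int> sweep, swLab;
  std::vector<char> swFrozen;
  for (double level = topLevel; level >= floorLevel; level -= step) {
    for (;;) {
      sweep.clear(); swLab.clear(); swFrozen.clear();
      // collect candidates and their decisions from the pre-sweep state
      for (int p : perim) {
        if (lab[p] || img[p] < level) continue;
        int zz0 = p % nz, yy0 = (p / nz) % ny, xx0 = p / (nz * ny);
        int l1 = 0, l2 = 0;
        for (int ddx = -1; ddx <= 1; ++ddx)
          for (int ddy = -1; ddy <= 1; ++ddy)
            for (int ddz = -1; ddz <= 1; ++ddz) {
              if (!ddx && !ddy && !ddz) continue;
              int zz = zz0 + ddz, yy = yy0 + ddy, xx = xx0 + ddx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
              int pp = zz + nz * (yy + ny * xx);
              int l = lab[pp];
              if (!l || frozen[pp]) continue;
              if (!l1) l1 = l;
              else if (l != l1 && (!l2 || l < l2)) {
                if (l < l1) { if (!l2 || l1 < l2) l2 = l1; l1 = l; }
                else l2 = l;
              }
            }
        if (!l1) continue;  // only frozen contact: not assignable
        if (!l2) {
          sweep.push_back(p); swLab.push_back(l1); swFrozen.push_back(0);
        } else {
          // contested: nearest peak among all touching labels
          int best = 0; double bestd = R_PosInf; double bestv = R_NegInf;
          for (int ddx = -1; ddx <= 1; ++ddx)
            for (int ddy = -1; ddy <= 1; ++ddy)
              for (int ddz = -1; ddz <= 1; ++ddz) {
                if (!ddx && !ddy && !ddz) continue;
                int zz = zz0 + ddz, yy = yy0 + ddy, xx = xx0 + ddx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
                int pp = zz + nz * (yy + ny * xx);
                int l = lab[pp];
                if (!l || frozen[pp] || l == best) continue;
                int k = l - 1;
                double az = (zz0 - pz[k]) * dz, ay = (yy0 - py[k]) * dy,
                       ax = (xx0 - px[k]) * dx;
                double d = az * az + ay * ay + ax * ax;
                if (d < bestd - 1e-12 ||
                    (std::abs(d - bestd) <= 1e-12 &&
                     (peakVal[k] > bestv ||
                      (peakVal[k] == bestv && l < best)))) {
                  best = l; bestd = d; bestv = peakVal[k];
                }
              }
          sweep.push_back(p); swLab.push_back(best); swFrozen.push_back(1);
        }
      }
      if (sweep.empty()) break;
      for (size_t s = 0; s < sweep.size(); ++s) {
        int p = sweep[s];
        lab[p] = swLab[s];
        frozen[p] = swFrozen[s] != 0;
        inPerim[p] = 0;
      }
      for (size_t s = 0; s < sweep.size(); ++s)
        if (!swFrozen[s]) addNbrsToPerim(sweep[s]);
      // compact perimeter
      size_t w = 0;
      for (size_t s = 0; s < perim.size(); ++s)
        if (inPerim[perim[s]]) perim[w++] = perim[s];
      perim.resize(w);
    }
  }
  lab.attr("dim") = dims;
  frozen.attr("dim") = dims;
  return List::create(_["labels"] = lab, _["frozen"] = frozen);
}

// ---------------------------------------------------------------------------
// Separable 3D convolution with 1D kernels (replicate border), dims (z,y,x).
// ---------------------------------------------------------------------------

static void conv_axis(std::vector<double>& v, const std::vector<double>& k,
                      int nz, int ny, int nx, int axis) {
  int len[3] = {nz, ny, nx};
  int stride[3] = {1, nz, nz * ny};
  int na = len[axis], sa = stride[axis];
  int half = ((int)k.size() - 1) / 2;
  std::vector<double> line(na);
  int nOther = nz * ny * nx / na;
  // iterate over all lines along `axis`
  int o1 = (axis == 0) ? ny : nz;            // first other dim length
  int s1 = (axis == 0) ? nz : 1;             // its stride
  int s2 = (axis == 2) ? nz : nz * ny;       // second other stride
  int o2 = nOther / o1;
  for (int b = 0; b < o2; ++b) {
    for (int a = 0; a < o1; ++a) {
      int base = a * s1 + b * s2;
      for (int i = 0; i < na; ++i) line[i] = v[base + i * sa];
      for (int i = 0; i < na; ++i) {
        double acc = 0;
        for (int j = -half; j <= half; ++j) {
          int ii = i + j;
          if (ii < 0) ii = 0;
          if (ii >= na) ii = na - 1;
          acc += line[ii] * k[j + half];
        }
        v[base + i * sa] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sep_conv3d(NumericVector img, IntegerVector dims,
                             NumericVector kz, NumericVector ky,
                             NumericVector kx) {
  std::vector<double> v(img.begin(), img.end());
  int nz = dims[0], ny = dims[1], nx = dims[2];
  if (kz.size() > 1) conv_axis(v, std::vector<double>(kz.begin(), kz.end()), nz, ny, nx, 0);
  if (ky.size() > 1) conv_axis(v, std::vector<double>(ky.begin(), ky.end()), nz, ny, nx, 1);
  if (kx.size() > 1) conv_axis(v, std::vector<double>(kx.begin(), kx.end()), nz, ny, nx, 2);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Spatial kernels: cumulative ordered pair counts and nearest neighbours.
// Points are (n x 3) matrices of physical coordinates in um.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_pair_counts(NumericMatrix A, NumericMatrix B,
                              NumericVector r, bool autoMode) {
  const int na = A.nrow(), nb = B.nrow(), nr = r.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = r[k] * r[k];
  std::vector<double> hist(nr + 1, 0.0);
  for (int i = 0; i < na; ++i) {
    double x = A(i, 0), y = A(i, 1), z = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      if (autoMode && i == j) continue;
      double dx = x - B(j, 0), dy = y - B(j, 1), dz = z - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      // first r index with r2 >= d2
      int lo = std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin();
      hist[lo] += 1.0;
    }
  }
  NumericVector out(nr);
  double acc = 0;
  for (int k = 0; k < nr; ++k) { acc += hist[k]; out[k] = acc; }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix A, NumericMatrix B, bool autoMode) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double x = A(i, 0), y = A(i, 1), z = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      if (autoMode && i == j) continue;
      double dx = x - B(j, 0), dy = y - B(j, 1), dz = z - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
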