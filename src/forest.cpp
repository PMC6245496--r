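#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Voxel indices are 0-based throughout; reads outside the volume clamp to
// the nearest edge voxel so every voxel can be routed and can vote.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double read_clamped(const double *ch, const int *dim,
                                  int x, int y, int z) {
  x = clampi(x, 0, dim[0] - 1);
  y = clampi(y, 0, dim[1] - 1);
  z = clampi(z, 0, dim[2] - 1);
  return ch[(size_t)x + (size_t)dim[0] * ((size_t)y + (size_t)dim[1] * z)];
}

// [[Rcpp::export(name = "cp_sobel")]]
List cp_sobel(NumericVector data, IntegerVector dim) {
  const int dx = dim[0], dy = dim[1], dz = dim[2];
  const int d3[3] = {dx, dy, dz};
  const double *src = data.begin();
  const double deriv[3] = {-1.0, 0.0, 1.0};
  const double smooth[3] = {1.0, 2.0, 1.0};
  NumericVector gx(data.size()), gy(data.size()), gz(data.size()),
      gm(data.size());
  for (int z = 0; z < dz; ++z)
    for (int y = 0; y < dy; ++y)
      for (int x = 0; x < dx; ++x) {
        double sx = 0, sy = 0, sz = 0;
        for (int k = -1; k <= 1; ++k)
          for (int j = -1; j <= 1; ++j)
            for (int i = -1; i <= 1; ++i) {
              double v = read_clamped(src, d3, x + i, y + j, z + k);
              sx += v * deriv[i + 1] * smooth[j + 1] * smooth[k + 1];
              sy += v * smooth[i + 1] * deriv[j + 1] * smooth[k + 1];
              sz += v * smooth[i + 1] * smooth[j + 1] * deriv[k + 1];
            }
        size_t idx = (size_t)x + (size_t)dx * ((size_t)y + (size_t)dy * z);
        gx[idx] = sx;
        gy[idx] = sy;
        gz[idx] = sz;
        gm[idx] = std::sqrt(sx * sx + sy * sy + sz * sz);
      }
  return List::create(Named("grad_x") = gx, Named("grad_y") = gy,
                      Named("grad_z") = gz, Named("grad_mag") = gm);
}

// ---------------------------------------------------------------------------
// Tree growing

struct PatchSet {
  std::vector<const double *> chan;  // [vol * n_chan + c]
  std::vector<const int *> dims;     // per volume
  int n_chan;
  const int *vol_id;                 // per patch (0-based)
  const int *cx, *cy, *cz;           // patch centers, 0-based voxels
  const int *label;
  const double *off;                 // n x k, column-major
  int n, k;
  double feat(int patch, int ch, int ox, int oy, int oz) const {
    int v = vol_id[patch];
    return read_clamped(chan[(size_t)v * n_chan + ch], dims[v],
                        cx[patch] + ox, cy[patch] + oy, cz[patch] + oz);
  }
};

struct TreeBuild {
  std::vector<int> channel, ax, ay, az, bx, by, bz, left, right, is_leaf,
      n_samples, off_start, off_count;
  std::vector<double> thr, cl;
  std::vector<double> leaf_off;  // row-major rows of k
  int k;
};

// class-label uncertainty: -|A| * sum_c p(c|A) ln p(c|A)
static double u1_of(int n, int nobj) {
  if (n == 0) return 0.0;
  double u = 0.0;
  double p1 = (double)nobj / n, p0 = 1.0 - p1;
  if (p1 > 0) u += p1 * std::log(p1);
  if (p0 > 0) u += p0 * std::log(p0);
  return -n * u;
}

// offset uncertainty: sum over object patches of squared deviation from the
// object mean, summed across offset components
static double u2_of(const PatchSet &ps, const std::vector<int> &idx,
                    const std::vector<char> &side, char which) {
  int k = ps.k;
  std::vector<double> s(k, 0.0), ss(k, 0.0);
  int nobj = 0;
  for (size_t t = 0; t < idx.size(); ++t) {
    if (side[t] != which) continue;
    int i = idx[t];
    if (ps.label[i] != 1) continue;
    ++nobj;
    for (int c = 0; c < k; ++c) {
      double v = ps.off[i + (size_t)c * ps.n];
      s[c] += v;
      ss[c] += v * v;
    }
  }
  if (nobj == 0) return 0.0;
  double u = 0.0;
  for (int c = 0; c < k; ++c) u += ss[c] - s[c] * s[c] / nobj;
  return u < 0 ? 0.0 : u;
}

static int grow_node(const PatchSet &ps, TreeBuild &tb,
                     std::vector<int> &idx, int depth, int max_depth,
                     int min_samples, int n_tests, int n_thresholds,
                     int patch_half) {
  int node = (int)tb.channel.size();
  tb.channel.push_back(-1);
  tb.ax.push_back(0); tb.ay.push_back(0); tb.az.push_back(0);
  tb.bx.push_back(0); tb.by.push_back(0); tb.bz.push_back(0);
  tb.thr.push_back(0.0);
  tb.left.push_back(0); tb.right.push_back(0);
  tb.is_leaf.push_back(0);
  tb.n_samples.push_back((int)idx.size());
  tb.cl.push_back(0.0);
  tb.off_start.push_back(0); tb.off_count.push_back(0);

  int n = (int)idx.size();
  int nobj = 0;
  for (int t = 0; t < n; ++t) nobj += (ps.label[idx[t]] == 1);

  std::vector<char> all_side(n, 0);  // helper for whole-node U2
  bool pure_bg = (nobj == 0);
  bool pure_obj = (nobj == n);
  double node_u2 = pure_bg ? 0.0 : u2_of(ps, idx, all_side, 0);
  bool stop = depth >= max_depth || n < min_samples || pure_bg ||
              (pure_obj && node_u2 < 1e-12);

  double best_score = std::numeric_limits<double>::infinity();
  int b_ch = -1, b_ax = 0, b_ay = 0, b_az = 0, b_bx = 0, b_by = 0, b_bz = 0;
  double b_thr = 0.0;
  std::vector<char> b_side(n, 0);

  if (!stop) {
    // randomized objective per node: U1 or U2 (U1 forced with <2 object patches)
    bool use_u2 = (nobj >= 2) && (unif_rand() < 0.5);
    if (pure_obj) use_u2 = true;       // U1 cannot discriminate a pure node
    std::vector<double> diff(n);
    std::vector<char> side(n);
    for (int t = 0; t < n_tests; ++t) {
      int ch = (int)std::floor(unif_rand() * ps.n_chan);
      if (ch >= ps.n_chan) ch = ps.n_chan - 1;
      int oax = (int)std::floor(unif_rand() * (2 * patch_half + 1)) - patch_half;
      int oay = (int)std::floor(unif_rand() * (2 * patch_half + 1)) - patch_half;
      int oaz = (int)std::floor(unif_rand() * (2 * patch_half + 1)) - patch_half;
      int obx = (int)std::floor(unif_rand() * (2 * patch_half + 1)) - patch_half;
      int oby = (int)std::floor(unif_rand() * (2 * patch_half + 1)) - patch_half;
      int obz = (int)std::floor(unif_rand() * (2 * patch_half + 1)) - patch_half;
      double dmin = std::numeric_limits<double>::infinity(), dmax = -dmin;
      for (int t2 = 0; t2 < n; ++t2) {
        int i = idx[t2];
        double d = ps.feat(i, ch, oax, oay, oaz) - ps.feat(i, ch, obx, oby, obz);
        diff[t2] = d;
        if (d < dmin) dmin = d;
        if (d > dmax) dmax = d;
      }
      if (!(dmax > dmin)) continue;  // constant feature difference
      for (int j = 0; j < n_thresholds; ++j) {
        double thr = dmin + unif_rand() * (dmax - dmin);
        int nl = 0, nr = 0, nlobj = 0, nrobj = 0;
        for (int t2 = 0; t2 < n; ++t2) {
          // test fires (1, right child) iff value_a - value_b > threshold
          side[t2] = diff[t2] > thr ? 1 : 0;
          if (side[t2]) { ++nr; nrobj += (ps.label[idx[t2]] == 1); }
          else { ++nl; nlobj += (ps.label[idx[t2]] == 1); }
        }
        if (nl == 0 || nr == 0) continue;
        double score;
        if (use_u2)
          score = u2_of(ps, idx, side, 0) + u2_of(ps, idx, side, 1);
        else
          score = u1_of(nl, nlobj) + u1_of(nr, nrobj);
        if (score < best_score) {
          best_score = score;
          b_ch = ch; b_ax = oax; b_ay = oay; b_az = oaz;
          b_bx = obx; b_by = oby; b_bz = obz; b_thr = thr;
          b_side = side;
        }
      }
    }
  }

  if (stop || b_ch < 0) {  // leaf: store C_L and object-patch offsets
    tb.is_leaf[node] = 1;
    tb.cl[node] = n > 0 ? (double)nobj / n : 0.0;
    tb.off_start[node] = (int)(tb.leaf_off.size() / ps.k);
    tb.off_count[node] = nobj;
    for (int t = 0; t < n; ++t) {
      int i = idx[t];
      if (ps.label[i] != 1) continue;
      for (int c = 0; c < ps.k; ++c)
        tb.leaf_off.push_back(ps.off[i + (size_t)c * ps.n]);
    }
    return node;
  }

  std::vector<int> lidx, ridx;
  for (int t = 0; t < n; ++t)
    (b_side[t] ? ridx : lidx).push_back(idx[t]);
  idx.clear(); idx.shrink_to_fit();
  tb.channel[node] = b_ch;
  tb.ax[node] = b_ax; tb.ay[node] = b_ay; tb.az[node] = b_az;
  tb.bx[node] = b_bx; tb.by[node] = b_by; tb.bz[node] = b_bz;
  tb.thr[node] = b_thr;
  int l = grow_node(ps, tb, lidx, depth + 1, max_depth, min_samples, n_tests,
                    n_thresholds, patch_half);
  int r = grow_node(ps, tb, ridx, depth + 1, max_depth, min_samples, n_tests,
                    n_thresholds, patch_half);
  tb.left[node] = l + 1;   // 1-based for R
  tb.right[node] = r + 1;
  return node;
}

// stacks: list over volumes, each a list of numeric channel vectors
// dims: n_vols x 3 integer matrix
// [[Rcpp::export(name = "cp_grow_tree")]]
List cp_grow_tree(List stacks, IntegerMatrix dims, IntegerVector vol_id,
                  IntegerMatrix centers, IntegerVector labels,
                  NumericMatrix offsets, int patch_half, int max_depth,
                  int min_samples, int n_tests, int n_thresholds) {
  int n_vols = stacks.size();
  if (n_vols == 0) stop("empty training set");
  int n_chan = ((List)stacks[0]).size();
  PatchSet ps;
  ps.n_chan = n_chan;
  ps.chan.resize((size_t)n_vols * n_chan);
  std::vector<std::vector<int>> dimstore(n_vols, std::vector<int>(3));
  ps.dims.resize(n_vols);
  for (int v = 0; v < n_vols; ++v) {
    List st = stacks[v];
    if (st.size() != n_chan) stop("inconsistent channel counts across volumes");
    for (int c = 0; c < n_chan; ++c)
      ps.chan[(size_t)v * n_chan + c] = NumericVector(st[c]).begin();
    for (int j = 0; j < 3; ++j) dimstore[v][j] = dims(v, j);
    ps.dims[v] = dimstore[v].data();
  }
  ps.n = centers.nrow();
  ps.k = offsets.ncol();
  if (ps.n == 0) stop("no training patches");
  std::vector<int> cx(ps.n), cy(ps.n), cz(ps.n);
  for (int i = 0; i < ps.n; ++i) {
    cx[i] = centers(i, 0); cy[i] = centers(i, 1); cz[i] = centers(i, 2);
  }
  ps.cx = cx.data(); ps.cy = cy.data(); ps.cz = cz.data();
  ps.vol_id = vol_id.begin();
  ps.label = labels.begin();
  ps.off = offsets.begin();

  TreeBuild tb;
  tb.k = ps.k;
  std::vector<int> idx(ps.n);
  for (int i = 0; i < ps.n; ++i) idx[i] = i;
  grow_node(ps, tb, idx, 0, max_depth, min_samples, n_tests, n_thresholds,
            patch_half);

  int m = (int)(tb.leaf_off.size() / ps.k);
  NumericMatrix loff(m, ps.k);
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < ps.k; ++c)
      loff(r, c) = tb.leaf_off[(size_t)r * ps.k + c];
  return List::create(
      Named("channel") = wrap(tb.channel), Named("ax") = wrap(tb.ax),
      Named("ay") = wrap(tb.ay), Named("az") = wrap(tb.az),
      Named("bx") = wrap(tb.bx), Named("by") = wrap(tb.by),
      Named("bz") = wrap(tb.bz), Named("threshold") = wrap(tb.thr),
      Named("left") = wrap(tb.left), Named("right") = wrap(tb.right),
      Named("is_leaf") = wrap(tb.is_leaf), Named("cl") = wrap(tb.cl),
      Named("n_samples") = wrap(tb.n_samples),
      Named("off_start") = wrap(tb.off_start),
      Named("off_count") = wrap(tb.off_count), Named("leaf_off") = loff);
}

struct FlatTree {
  const int *channel, *ax, *ay, *az, *bx, *by, *bz, *left, *right, *is_leaf,
      *off_start, *off_count;
  const double *thr, *cl, *leaf_off;
  int n_leaf_rows, k;
};

static FlatTree flatten(List tree) {
  FlatTree t;
  t.channel = IntegerVector(tree["channel"]).begin();
  t.ax = IntegerVector(tree["ax"]).begin();
  t.ay = IntegerVector(tree["ay"]).begin();
  t.az = IntegerVector(tree["az"]).begin();
  t.bx = IntegerVector(tree["bx"]).begin();
  t.by = IntegerVector(tree["by"]).begin();
  t.bz = IntegerVector(tree["bz"]).begin();
  t.left = IntegerVector(tree["left"]).begin();
  t.right = IntegerVector(tree["right"]).begin();
  t.is_leaf = IntegerVector(tree["is_leaf"]).begin();
  t.off_start = IntegerVector(tree["off_start"]).begin();
  t.off_count = IntegerVector(tree["off_count"]).begin();
  t.thr = NumericVector(tree["threshold"]).begin();
  t.cl = NumericVector(tree["cl"]).begin();
  NumericMatrix lo = tree["leaf_off"];
  t.leaf_off = lo.begin();
  t.n_leaf_rows = lo.nrow();
  t.k = lo.ncol();
  return t;
}

static inline int route_one(const FlatTree &t,
                            const std::vector<const double *> &chan,
                            const int *dim, int x, int y, int z) {
  int node = 0;
  while (!t.is_leaf[node]) {
    const double *ch = chan[t.channel[node]];
    double d = read_clamped(ch, dim, x + t.ax[node], y + t.ay[node],
                            z + t.az[node]) -
               read_clamped(ch, dim, x + t.bx[node], y + t.by[node],
                            z + t.bz[node]);
    node = (d > t.thr[node] ? t.right[node] : t.left[node]) - 1;
  }
  return node;
}

// Route voxel centers through one tree; returns 1-based node ids.
// [[Rcpp::export(name = "cp_route")]]
IntegerVector cp_route(List channels, IntegerVector dim, List tree,
                       IntegerMatrix centers) {
  FlatTree t = flatten(tree);
  int n_chan = channels.size();
  std::vector<const double *> chan(n_chan);
  for (int c = 0; c < n_chan; ++c)
    chan[c] = NumericVector(channels[c]).begin();
  int d3[3] = {dim[0], dim[1], dim[2]};
  int n = centers.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = route_one(t, chan, d3, centers(i, 0), centers(i, 1),
                       centers(i, 2)) + 1;
  return out;
}

// Generalized Hough voting over a rectangular region [lo, hi] (0-based,
// inclusive). Every voxel on the stride lattice is routed through every
// tree; leaves with C_L >= tau deposit weight C_L / |D_L| at p - d for each
// stored offset d (nearest voxel); votes landing outside the region are
// dropped.
// [[Rcpp::export(name = "cp_cast_votes")]]
List cp_cast_votes(List channels, IntegerVector dim, List trees,
                   IntegerVector lo, IntegerVector hi, int stride,
                   double tau) {
  int n_chan = channels.size();
  std::vector<const double *> chan(n_chan);
  for (int c = 0; c < n_chan; ++c)
    chan[c] = NumericVector(channels[c]).begin();
  int d3[3] = {dim[0], dim[1], dim[2]};
  int rx = hi[0] - lo[0] + 1, ry = hi[1] - lo[1] + 1, rz = hi[2] - lo[2] + 1;
  if (rx <= 0 || ry <= 0 || rz <= 0) stop("empty voting region");
  std::vector<FlatTree> ft;
  for (int t = 0; t < trees.size(); ++t) ft.push_back(flatten(trees[t]));
  NumericVector acc((size_t)rx * ry * rz);
  long long examined = 0;
  for (int z = lo[2]; z <= hi[2]; z += stride)
    for (int y = lo[1]; y <= hi[1]; y += stride)
      for (int x = lo[0]; x <= hi[0]; x += stride) {
        ++examined;
        for (size_t ti = 0; ti < ft.size(); ++ti) {
          const FlatTree &t = ft[ti];
          int node = route_one(t, chan, d3, x, y, z);
          double cl = t.cl[node];
          int cnt = t.off_count[node];
          if (cl < tau || cnt == 0) continue;
          double w = cl / cnt;
          // leaf_off is an R matrix (column-major), rows off_start..off_start+cnt-1
          const double *off = t.leaf_off;
          const size_t nr = (size_t)t.n_leaf_rows;
          const size_t r0 = (size_t)t.off_start[node];
          for (int j = 0; j < cnt; ++j) {
            size_t r = r0 + j;
            int qx = (int)std::lround(x - off[r]);
            int qy = (int)std::lround(y - off[r + nr]);
            int qz = (int)std::lround(z - off[r + 2 * nr]);
            if (qx < lo[0] || qx > hi[0] || qy < lo[1] || qy > hi[1] ||
                qz < lo[2] || qz > hi[2])
              continue;
            acc[(size_t)(qx - lo[0]) +
                (size_t)rx * ((size_t)(qy - lo[1]) +
                              (size_t)ry * (qz - lo[2]))] += w;
          }
        }
      }
  return List::create(Named("acc") = acc,
                      Named("examined") = (double)examined);
}
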