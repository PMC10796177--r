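#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &par, int i) {
  while (par[i] != i) {
    par[i] = par[par[i]];
    i = par[i];
  }
  return i;
}

static void uf_union(std::vector<int> &par, int a, int b) {
  int ra = uf_find(par, a), rb = uf_find(par, b);
  if (ra != rb) par[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labelling of a logical matrix.
// connectivity: 4 or 8. Labels are 1..n in raster-scan order of first pixel.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> par;
  par.reserve(1024);
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int up = (r > 0 && mask(r - 1, c)) ? lab(r - 1, c) : 0;
      int lf = (c > 0 && mask(r, c - 1)) ? lab(r, c - 1) : 0;
      int ul = 0, ll = 0;
      if (connectivity == 8) {
        ul = (r > 0 && c > 0 && mask(r - 1, c - 1)) ? lab(r - 1, c - 1) : 0;
        ll = (r < H - 1 && c > 0 && mask(r + 1, c - 1)) ? lab(r + 1, c - 1) : 0;
      }
      int cand[4] = {up, lf, ul, ll};
      int assigned = 0;
      for (int k = 0; k < 4; ++k)
        if (cand[k] > 0) assigned = assigned ? std::min(assigned, cand[k]) : cand[k];
      if (!assigned) {
        par.push_back(next);
        assigned = ++next;
      } else {
        for (int k = 0; k < 4; ++k)
          if (cand[k] > 0) uf_union(par, assigned - 1, cand[k] - 1);
      }
      lab(r, c) = assigned;
    }
  }
  // Resolve equivalences, relabel densely in raster order (columns outer loop
  // above, so re-scan row-major for stable ids).
  std::vector<int> remap(next + 1, 0);
  int nfinal = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int l = lab(r, c);
      if (!l) continue;
      int root = uf_find(par, l - 1) + 1;
      if (!remap[root]) remap[root] = ++nfinal;
      lab(r, c) = remap[root];
    }
  }
  lab.attr("n") = nfinal;
  return lab;
}

// Outer boundary of one labelled component, traced along pixel cracks so the
// polygon encloses exactly the component's pixels (plus any holes). Vertices
// are 0-based (x = column, y = row) lattice corners; pixel (r, c) occupies
// [c, c+1) x [r, r+1). The region is kept on the right of the walk; the
// ambiguous checkerboard corner is resolved as connected (8-connectivity).
// [[Rcpp::export(name = ".trace_outer_cpp")]]
IntegerMatrix trace_outer_cpp(IntegerMatrix lab, int id) {
  const int H = lab.nrow(), W = lab.ncol();
  int r0 = -1, c0 = -1;
  for (int r = 0; r < H && r0 < 0; ++r)
    for (int c = 0; c < W; ++c)
      if (lab(r, c) == id) { r0 = r; c0 = c; break; }
  if (r0 < 0) stop("label not present in matrix");

  auto in = [&](int r, int c) {
    return r >= 0 && r < H && c >= 0 && c < W && lab(r, c) == id;
  };
  // Directions: 0=R(+x), 1=D(+y), 2=L(-x), 3=U(-y)
  const int dx[4] = {1, 0, -1, 0};
  const int dy[4] = {0, 1, 0, -1};
  int x = c0, y = r0, d = 0; // start at top-left corner of seed pixel, going right
  const int xs = x, ys = y, ds = d;
  std::vector<int> vx, vy;
  long guard = 0, maxsteps = 8L * (long)(H + 2) * (W + 2);
  do {
    vx.push_back(x);
    vy.push_back(y);
    x += dx[d];
    y += dy[d];
    // pixels ahead-left / ahead-right of travel direction at the new corner
    int la = 0, ra = 0;
    switch (d) {
    case 0: la = in(y - 1, x);     ra = in(y, x);         break;
    case 1: la = in(y, x);         ra = in(y, x - 1);     break;
    case 2: la = in(y, x - 1);     ra = in(y - 1, x - 1); break;
    case 3: la = in(y - 1, x - 1); ra = in(y - 1, x);     break;
    }
    if (la && ra)
      d = (d + 3) % 4;            // turn left
    else if (la && !ra)
      d = (d + 3) % 4;            // checkerboard: keep 8-connected, turn left
    else if (!la && ra)
      ;                           // straight
    else
      d = (d + 1) % 4;            // turn right
    if (++guard > maxsteps) stop("contour tracing failed to terminate");
  } while (!(x == xs && y == ys && d == ds));

  // Drop collinear runs.
  int n = (int)vx.size();
  std::vector<int> keep;
  for (int i = 0; i < n; ++i) {
    int p = (i + n - 1) % n, q = (i + 1) % n;
    long ax = vx[i] - vx[p], ay = vy[i] - vy[p];
    long bx = vx[q] - vx[i], by = vy[q] - vy[i];
    if (ax * by - ay * bx != 0) keep.push_back(i);
  }
  IntegerMatrix out((int)keep.size(), 2);
  for (int i = 0; i < (int)keep.size(); ++i) {
    out(i, 0) = vx[keep[i]];
    out(i, 1) = vy[keep[i]];
  }
  colnames(out) = CharacterVector::create("x", "y");
  return out;
}
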