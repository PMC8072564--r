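#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-neighbourhood in ring order: consecutive entries are mutually adjacent,
// even indices are the 4-neighbours. (dr, dc) offsets.
static const int RDR[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int RDC[8] = {1, 1, 0, -1, -1, -1, 0, 1};

// Simple-point test for (8-foreground, 4-background) digital topology.
// ring[i] = occupancy of neighbour i in ring order. A pixel is simple iff
// the ring holds exactly one circular run of foreground and exactly one
// circular run of background that touches a 4-neighbour (even index).
static bool simple_point(const int ring[8]) {
  int fg_runs = 0;
  for (int i = 0; i < 8; ++i) {
    if (ring[i] == 1 && ring[(i + 7) % 8] == 0) ++fg_runs;
  }
  if (fg_runs != 1) return false;
  int start = -1;
  for (int i = 0; i < 8; ++i) if (ring[i] == 1) { start = i; break; }
  int bg_edge_runs = 0;
  bool in_run = false, run_has_edge = false;
  for (int k = 1; k <= 8; ++k) {
    int i = (start + k) % 8;
    if (ring[i] == 0) {
      if (!in_run) { in_run = true; run_has_edge = false; }
      if (i % 2 == 0) run_has_edge = true;
    } else if (in_run) {
      if (run_has_edge) ++bg_edge_runs;
      in_run = false;
    }
  }
  return bg_edge_runs == 1;
}

static inline int fg_at(const IntegerMatrix &fg, int r, int c, int nr, int nc) {
  if (r < 0 || c < 0 || r >= nr || c >= nc) return 0;
  return fg(r, c) != 0 ? 1 : 0;
}

// Exact Euclidean feature transform (Felzenszwalb-Huttenlocher): for every
// pixel, the squared distance to — and location of — the nearest
// background pixel; the image border counts as background.
static void feature_transform(const IntegerMatrix &mask,
                              std::vector<double> &d2,
                              std::vector<int> &featR,
                              std::vector<int> &featC) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  // per-column nearest background row (two scans; border row = background)
  std::vector<int> nbr((size_t)nr * nc);
  for (int c = 0; c < nc; ++c) {
    int last = -1;
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) last = r;
      nbr[(size_t)c * nr + r] = last;
    }
    int nxt = nr;
    for (int r = nr - 1; r >= 0; --r) {
      if (!mask(r, c)) nxt = r;
      int &bst = nbr[(size_t)c * nr + r];
      int dUp = bst < 0 ? r + 1 : r - bst;  // border at row -1
      int dDn = nxt - r;                    // border at row nr
      if (dDn < dUp) bst = nxt;
      else if (bst < 0) bst = -1;           // keep border-above marker
    }
  }
  std::vector<double> f(nc + 2), z(nc + 3);
  std::vector<int> v(nc + 2), frow(nc + 2);
  for (int r = 0; r < nr; ++r) {
    // candidate columns: real columns plus virtual border columns -1, nc
    int m = 0;
    std::vector<int> cols(nc + 2);
    for (int c = -1; c <= nc; ++c) {
      double fc;
      int fr;
      if (c < 0 || c >= nc) { fc = 0.0; fr = r; }
      else {
        int b = nbr[(size_t)c * nr + r];
        int du = b < 0 ? r + 1 : (b <= r ? r - b : 0);
        // nbr already resolved to the nearer of up/down (or border)
        du = b < 0 ? r + 1 : std::abs(r - b);
        fc = (double)du * du;
        fr = b < 0 ? -1 : b;
      }
      cols[m] = c;
      f[m] = fc;
      frow[m] = fr;
      ++m;
    }
    // lower envelope over candidates
    std::vector<int> vv(m);
    std::vector<double> zz(m + 1);
    int k = 0;
    vv[0] = 0;
    zz[0] = -INF;
    zz[1] = INF;
    for (int q = 1; q < m; ++q) {
      double s;
      while (true) {
        int p = vv[k];
        double xp = cols[p], xq = cols[q];
        s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2 * xq - 2 * xp);
        if (s <= zz[k]) { --k; } else break;
      }
      ++k;
      vv[k] = q;
      zz[k] = s;
      zz[k + 1] = INF;
    }
    k = 0;
    for (int c = 0; c < nc; ++c) {
      while (zz[k + 1] < c) ++k;
      int p = vv[k];
      double dx = c - cols[p];
      size_t idx = (size_t)c * nr + r;
      d2[idx] = dx * dx + f[p];
      featR[idx] = frow[p];
      featC[idx] = cols[p];
    }
  }
}

// Homotopic thinning guided by the Euclidean distance transform: simple
// non-endpoint pixels are removed in increasing EDT order (ties broken by
// linear index), which keeps the surviving curve centred on the medial
// ridge. Anchor pixels are never removed. A pixel is an anchor when its
// nearest-boundary feature point and that of one of its foreground
// neighbours subtend a wide angle (>= 75 degrees) and are well separated
// (> 2.9 px): the theta-medial-axis criterion, which detects genuine
// medial ridges (features on opposing boundary walls) while rejecting
// boundary-staircase and EDT-facet artefacts (features close together on
// one wall). Two-pixel-thick anchor plateaus are demoted to a single row
// by an asymmetric axis rule.
// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(IntegerMatrix mask, NumericMatrix dist) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix fg = clone(mask);
  std::vector<double> d2((size_t)nr * nc);
  std::vector<int> featR((size_t)nr * nc), featC((size_t)nr * nc);
  feature_transform(mask, d2, featR, featC);
  const double cosTheta = std::cos(75.0 * M_PI / 180.0);
  const double minSep2 = 2.9 * 2.9;
  std::vector<char> anchor((size_t)nr * nc, 0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!fg(r, c)) continue;
      size_t ip = (size_t)c * nr + r;
      double ur = featR[ip] - r, uc = featC[ip] - c;
      double un = std::sqrt(ur * ur + uc * uc);
      for (int i = 0; i < 8; ++i) {
        int rq = r + RDR[i], cq = c + RDC[i];
        if (rq < 0 || cq < 0 || rq >= nr || cq >= nc || !fg(rq, cq)) continue;
        size_t iq = (size_t)cq * nr + rq;
        double dfr = featR[iq] - featR[ip], dfc = featC[iq] - featC[ip];
        if (dfr * dfr + dfc * dfc <= minSep2) continue;
        double vr = featR[iq] - r, vc = featC[iq] - c;
        double vn = std::sqrt(vr * vr + vc * vc);
        if (ur * vr + uc * vc < cosTheta * un * vn) {
          // anchor only the larger-disk side of the pair (index as tie
          // break), keeping the protected zone thin so the final parallel
          // thinning does not retract band ends
          if (d2[ip] > d2[iq] ||
              (d2[ip] == d2[iq] && ip < iq)) {
            anchor[ip] = 1;
            break;
          }
        }
      }
    }
  }
  typedef std::pair<double, int> QE;  // (EDT priority, linear index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (fg(r, c)) pq.push(QE(dist(r, c), c * nr + r));
  int ring[8];
  while (!pq.empty()) {
    int idx = pq.top().second;
    pq.pop();
    int r = idx % nr, c = idx / nr;
    if (!fg(r, c) || anchor[(size_t)idx]) continue;
    int nnb = 0;
    for (int i = 0; i < 8; ++i) {
      ring[i] = fg_at(fg, r + RDR[i], c + RDC[i], nr, nc);
      nnb += ring[i];
    }
    if (nnb < 2) continue;           // endpoint or isolated: keep
    if (!simple_point(ring)) continue;
    fg(r, c) = 0;
    for (int i = 0; i < 8; ++i) {
      int rr = r + RDR[i], cc = c + RDC[i];
      if (rr >= 0 && cc >= 0 && rr < nr && cc < nc && fg(rr, cc))
        pq.push(QE(dist(rr, cc), cc * nr + rr));
    }
  }
  // Stage 2: the protected medial zone is 2-4 px thick where features
  // straddle a ridge; parallel Guo-Hall thinning reduces it to a 1-px
  // curve without nibbling band ends (template-based, end-preserving).
  std::vector<int> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!fg(r, c)) continue;
          int p2 = fg_at(fg, r - 1, c, nr, nc);
          int p3 = fg_at(fg, r - 1, c + 1, nr, nc);
          int p4 = fg_at(fg, r, c + 1, nr, nc);
          int p5 = fg_at(fg, r + 1, c + 1, nr, nc);
          int p6 = fg_at(fg, r + 1, c, nr, nc);
          int p7 = fg_at(fg, r + 1, c - 1, nr, nc);
          int p8 = fg_at(fg, r, c - 1, nr, nc);
          int p9 = fg_at(fg, r - 1, c - 1, nr, nc);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int mcond = sub == 0 ? ((p6 | p7 | (!p9)) & p8)
                               : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && mcond == 0)
            del.push_back(c * nr + r);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t i = 0; i < del.size(); ++i)
          fg[del[i]] = 0;
      }
    }
  }
  return fg;
}

// 8-connected component labelling (two-pass union-find). Labels are
// consecutive 1..N in row-major order of first occurrence.
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  // scan column-major (R storage); previously visited 8-neighbours:
  // (r-1,c-1), (r,c-1), (r+1,c-1), (r-1,c)
  static const int PDR[4] = {-1, 0, 1, -1};
  static const int PDC[4] = {-1, -1, -1, 0};
  std::vector<int> find_buf;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int nbl[4];
      for (int i = 0; i < 4; ++i) {
        nbl[i] = 0;
        int rr = r + PDR[i], cc = c + PDC[i];
        if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
        int l = lab(rr, cc);
        if (l) {
          while (parent[l] != l) l = parent[l];
          nbl[i] = l;
          if (best == 0 || l < best) best = l;
        }
      }
      if (best == 0) {
        int nl = (int)parent.size();
        parent.push_back(nl);
        lab(r, c) = nl;
      } else {
        lab(r, c) = best;
        for (int i = 0; i < 4; ++i)
          if (nbl[i] && nbl[i] != best) parent[nbl[i]] = best;
      }
    }
  }
  // resolve + relabel consecutively by first occurrence (column-major scan)
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (!l) continue;
      while (parent[l] != l) l = parent[l];
      if (!remap[l]) remap[l] = ++next;
      lab(r, c) = remap[l];
    }
  }
  return lab;
}

static inline bool has_witness(double px, double py, double pr,
                               const NumericVector &kx,
                               const NumericVector &ky,
                               const NumericVector &kr, double eps,
                               bool strictLarger) {
  int nk = kx.size();
  for (int j = 0; j < nk; ++j) {
    if (strictLarger && kr[j] <= pr) continue;
    double dx = px - kx[j], dy = py - ky[j];
    if (std::sqrt(dx * dx + dy * dy) + pr - kr[j] < eps) return true;
  }
  return false;
}

// Admissibility of a candidate tail removal under witnessed containment.
// Every candidate point must have a direct witness among the kept points:
// a strictly larger maximal disk whose eps-inflation contains the
// candidate's disk (|p - q| + r_p - r_q < eps); the strictness protects
// constant-radius trunks from creeping erosion. Previously removed points
// that may have been witnessed by a candidate must stay within the
// 2*eps-inflation of some kept disk — the allowance for material of an
// unbranched feature, whose extent is below 2*eps by the pruning rule.
// [[Rcpp::export(name = ".cpp_prune_ok")]]
bool cpp_prune_ok(NumericVector px, NumericVector py, NumericVector pr,
                  NumericVector ox, NumericVector oy, NumericVector orr,
                  NumericVector kx, NumericVector ky, NumericVector kr,
                  double eps) {
  int np = px.size(), no = ox.size();
  for (int i = 0; i < np; ++i)
    if (!has_witness(px[i], py[i], pr[i], kx, ky, kr, eps, true))
      return false;
  for (int i = 0; i < no; ++i) {
    // re-check any previously removed point whose 2*eps witness could have
    // been among the candidates (any radius: chains may pass through
    // same-size disks)
    bool dep = false;
    for (int j = 0; j < np; ++j) {
      double dx = ox[i] - px[j], dy = oy[i] - py[j];
      if (std::sqrt(dx * dx + dy * dy) + orr[i] - pr[j] < 2 * eps) {
        dep = true;
        break;
      }
    }
    if (dep && !has_witness(ox[i], oy[i], orr[i], kx, ky, kr, 2 * eps,
                            false))
      return false;
  }
  return true;
}
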