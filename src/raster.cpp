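#include <Rcpp.h>
using namespace Rcpp;

// Guo-Hall thinning of a binary image to an 8-connected one-pixel
// skeleton. Chosen over Zhang-Suen because the latter deletes two-pixel
// wide diagonal strips outright (thick diagonal strokes erode to nothing).
// Input/output: logical matrix, TRUE = foreground. Border pixels are
// treated as background so index arithmetic never leaves the matrix.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix a(clone(img));
  for (int j = 0; j < nc; ++j) { a(0, j) = false; a(nr - 1, j) = false; }
  for (int i = 0; i < nr; ++i) { a(i, 0) = false; a(i, nc - 1) = false; }

  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 1; j < nc - 1; ++j) {
        for (int i = 1; i < nr - 1; ++i) {
          if (!a(i, j)) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = a(i - 1, j),     p3 = a(i - 1, j + 1), p4 = a(i, j + 1);
          int p5 = a(i + 1, j + 1), p6 = a(i + 1, j),     p7 = a(i + 1, j - 1);
          int p8 = a(i, j - 1),     p9 = a(i - 1, j - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          if (C != 1) continue;
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          if (N < 2 || N > 3) continue;
          int m = pass == 0 ? ((p6 | p7 | (!p9)) & p8)
                            : ((p2 | p3 | (!p5)) & p4);
          if (m != 0) continue;
          kill.push_back(i + nr * j);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k) a[kill[k]] = false;
      }
    }
  }
  return a;
}

// Stamp a polyline into a numeric image with a circular pen, writing
// max(current, value). Points are given in pixel units (1-based, row/col);
// the pen centre is interpolated every half pixel along the polyline.
// [[Rcpp::export]]
NumericMatrix cpp_stamp_polyline(NumericMatrix img, NumericMatrix pts,
                                 double radius, double value) {
  int nr = img.nrow(), nc = img.ncol(), np = pts.nrow();
  if (np == 0) return img;
  double r2 = radius * radius;
  int ir = (int)std::ceil(radius);
  auto stamp = [&](double cr, double cc) {
    int r0 = std::max(0, (int)std::floor(cr) - ir - 1);
    int r1 = std::min(nr - 1, (int)std::ceil(cr) + ir);
    int c0 = std::max(0, (int)std::floor(cc) - ir - 1);
    int c1 = std::min(nc - 1, (int)std::ceil(cc) + ir);
    for (int j = c0; j <= c1; ++j) {
      double dc = (j + 1) - cc;            // pixel centre, 1-based
      for (int i = r0; i <= r1; ++i) {
        double dr = (i + 1) - cr;
        if (dr * dr + dc * dc <= r2 && img(i, j) < value) img(i, j) = value;
      }
    }
  };
  stamp(pts(0, 0), pts(0, 1));
  for (int p = 1; p < np; ++p) {
    double ar = pts(p - 1, 0), ac = pts(p - 1, 1);
    double br = pts(p, 0),     bc = pts(p, 1);
    double len = std::sqrt((br - ar) * (br - ar) + (bc - ac) * (bc - ac));
    int nstep = std::max(1, (int)std::ceil(len / 0.5));
    for (int s = 1; s <= nstep; ++s) {
      double t = (double)s / nstep;
      stamp(ar + t * (br - ar), ac + t * (bc - ac));
    }
  }
  return img;
}

// Separable Gaussian blur with reflected borders.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double ksum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += k[i + radius];
  }
  for (double &v : k) v /= ksum;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  auto reflect = [](int i, int n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
    return i;
  };
  for (int j = 0; j < nc; ++j) {       // vertical pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -radius; d <= radius; ++d) {
        acc += k[d + radius] * img(reflect(i + d, nr), j);
      }
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < nc; ++j) {       // horizontal pass
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -radius; d <= radius; ++d) {
        acc += k[d + radius] * tmp(i, reflect(j + d, nc));
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher):
// for every pixel, squared distance to the nearest TRUE pixel. Pixels of
// an all-FALSE image get a large finite value.
static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   std::vector<int> &v, std::vector<double> &z, int n) {
  int kk = 0;
  v[0] = 0;
  z[0] = -1e20; z[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[kk]] + v[kk] * (double)v[kk])) /
          (2.0 * q - 2.0 * v[kk]);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = 1e20;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    d[q] = (q - v[kk]) * (double)(q - v[kk]) + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix g(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int j = 0; j < nc; ++j) {       // columns first
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? 0.0 : 1e18;
    edt_1d(f, d, v, z, nr);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  for (int i = 0; i < nr; ++i) {       // then rows
    for (int j = 0; j < nc; ++j) f[j] = g(i, j);
    edt_1d(f, d, v, z, nc);
    for (int j = 0; j < nc; ++j) g(i, j) = d[j];
  }
  return g;
}

// Trace polyline edges of a skeleton between node clusters.
// skel: one-pixel skeleton; cid: cluster id per node pixel (0 elsewhere).
// Walks follow degree-2 runs, preferring continuations that are not
// adjacent to the previous pixel (avoids staircase backtracking); a dead
// end closes the edge at a new synthetic single-pixel cluster; rings
// (components with no node pixel) get a synthetic node and are traced as
// self-loops. Returns edge endpoints, polylines (1-based row/col), and
// any synthetic cluster pixels (id, row, col).
// [[Rcpp::export]]
List cpp_trace_edges(LogicalMatrix skel, IntegerMatrix cid_in, int n_clust) {
  int nr = skel.nrow(), nc = skel.ncol();
  IntegerMatrix cid(clone(cid_in));
  LogicalMatrix visited(nr, nc);
  std::vector<int> e_a, e_b;
  std::vector< std::vector<int> > e_pts;   // interleaved r1,c1,r2,c2,...
  std::vector<int> synth;                  // id, r, c triples
  std::set< std::pair<int,int> > direct_seen;

  const int OR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int OC[8] = { 0, 0,-1, 1, -1,  1,-1, 1};

  // collect pixels per cluster id
  std::vector< std::vector<int> > cpx(n_clust + 1);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (cid(i, j) > 0) cpx[cid(i, j)].push_back(i + nr * j);

  int next_clust = n_clust;

  auto walk = [&](int pr, int pc, int qr, int qc, int start_cid) {
    std::vector<int> pts;
    pts.push_back(pr); pts.push_back(pc);
    pts.push_back(qr); pts.push_back(qc);
    visited(qr, qc) = true;
    int prev_r = pr, prev_c = pc, cur_r = qr, cur_c = qc;
    while (true) {
      int term_r = -1, term_c = -1, best_r = -1, best_c = -1;
      int best_score = 1 << 30;
      for (int o = 0; o < 8; ++o) {
        int rr = cur_r + OR[o], cc = cur_c + OC[o];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (!skel(rr, cc)) continue;
        if (rr == prev_r && cc == prev_c) continue;
        int c2 = cid(rr, cc);
        if (c2 > 0) {
          if (c2 == start_cid && (int)pts.size() <= 6) continue;
          if (term_r < 0) { term_r = rr; term_c = cc; }
        } else if (!visited(rr, cc)) {
          int score = (o >= 4 ? 1 : 0) +
            ((std::abs(rr - prev_r) <= 1 && std::abs(cc - prev_c) <= 1) ? 2 : 0);
          if (score < best_score) { best_score = score; best_r = rr; best_c = cc; }
        }
      }
      if (term_r >= 0) {
        pts.push_back(term_r); pts.push_back(term_c);
        e_a.push_back(start_cid);
        e_b.push_back(cid(term_r, term_c));
        e_pts.push_back(pts);
        return;
      }
      if (best_r < 0) {   // dead end: synthesise an endpoint cluster here
        ++next_clust;
        cid(cur_r, cur_c) = next_clust;
        synth.push_back(next_clust);
        synth.push_back(cur_r + 1);
        synth.push_back(cur_c + 1);
        e_a.push_back(start_cid);
        e_b.push_back(next_clust);
        e_pts.push_back(pts);
        return;
      }
      visited(best_r, best_c) = true;
      pts.push_back(best_r); pts.push_back(best_c);
      prev_r = cur_r; prev_c = cur_c;
      cur_r = best_r; cur_c = best_c;
    }
  };

  for (int ci = 1; ci <= n_clust; ++ci) {
    for (size_t p = 0; p < cpx[ci].size(); ++p) {
      int pr = cpx[ci][p] % nr, pc = cpx[ci][p] / nr;
      for (int o = 0; o < 8; ++o) {
        int qr = pr + OR[o], qc = pc + OC[o];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (!skel(qr, qc)) continue;
        int qcid = cid(qr, qc);
        if (qcid > 0) {
          if (qcid > ci) {
            auto key = std::make_pair(ci, qcid);
            if (direct_seen.insert(key).second) {
              e_a.push_back(ci); e_b.push_back(qcid);
              std::vector<int> pts = {pr, pc, qr, qc};
              e_pts.push_back(pts);
            }
          }
          continue;
        }
        if (visited(qr, qc)) continue;
        walk(pr, pc, qr, qc, ci);
      }
    }
  }

  // rings: skeleton pixels never visited and not in any cluster
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!skel(i, j) || visited(i, j) || cid(i, j) > 0) continue;
      ++next_clust;
      cid(i, j) = next_clust;
      synth.push_back(next_clust);
      synth.push_back(i + 1);
      synth.push_back(j + 1);
      for (int o = 0; o < 8; ++o) {
        int qr = i + OR[o], qc = j + OC[o];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (!skel(qr, qc) || cid(qr, qc) > 0 || visited(qr, qc)) continue;
        walk(i, j, qr, qc, next_clust);
      }
    }
  }

  int n_e = e_a.size();
  List pts_out(n_e);
  for (int e = 0; e < n_e; ++e) {
    int np = e_pts[e].size() / 2;
    IntegerMatrix m(np, 2);
    for (int p = 0; p < np; ++p) {
      m(p, 0) = e_pts[e][2 * p] + 1;       // 1-based rows
      m(p, 1) = e_pts[e][2 * p + 1] + 1;
    }
    pts_out[e] = m;
  }
  IntegerMatrix synth_out(synth.size() / 3, 3);
  for (size_t k = 0; k < synth.size() / 3; ++k) {
    synth_out(k, 0) = synth[3 * k];
    synth_out(k, 1) = synth[3 * k + 1];
    synth_out(k, 2) = synth[3 * k + 2];
  }
  return List::create(_["a"] = wrap(e_a), _["b"] = wrap(e_b),
                      _["pts"] = pts_out, _["synthetic"] = synth_out);
}

// 8-neighbour count of TRUE pixels for every pixel of a logical matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_neighbour_count(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!img(i, j)) { out(i, j) = 0; continue; }
      int n = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          int ii = i + di, jj = j + dj;
          if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && img(ii, jj)) ++n;
        }
      }
      out(i, j) = n;
    }
  }
  return out;
}
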