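// Low-level compute kernels for the 3D U-Net and geometry code.
//
// Tensor convention: a feature map on an (X, Y, Z) grid with C channels is
// stored as an N x C matrix (N = X*Y*Z), voxel index n = i + X*(j + Y*k),
// all 0-based here (R side is 1-based and converts).
//
// Convolutions are 3x3x3 with zero ("same") padding, implemented as 27
// shifted GEMMs: y += shift_o(x) * W_o with W_o the (Cin x Cout) slice of
// the kernel at spatial offset o.

#include <RcppArmadillo.h>
#include <map>
#include <utility>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void gather_shift(const arma::mat& x, int X, int Y, int Z,
                                int di, int dj, int dk, arma::mat& out) {
  // out(n, c) = x(n shifted by (di,dj,dk), c), zero outside the grid.
  const int C = x.n_cols;
  out.zeros();
  const int i0 = std::max(0, -di), i1 = std::min(X, X - di);
  const int j0 = std::max(0, -dj), j1 = std::min(Y, Y - dj);
  const int k0 = std::max(0, -dk), k1 = std::min(Z, Z - dk);
  if (i0 >= i1 || j0 >= j1 || k0 >= k1) return;
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = out.colptr(c);
    for (int k = k0; k < k1; ++k) {
      const int ks = k + dk;
      for (int j = j0; j < j1; ++j) {
        const int js = j + dj;
        const double* s = src + (i0 + di) + (size_t)X * (js + (size_t)Y * ks);
        double* d = dst + i0 + (size_t)X * (j + (size_t)Y * k);
        std::copy(s, s + (i1 - i0), d);
      }
    }
  }
}

static inline void scatter_shift_add(const arma::mat& g, int X, int Y, int Z,
                                     int di, int dj, int dk, arma::mat& out) {
  // out(n shifted, c) += g(n, c); the adjoint of gather_shift.
  const int C = g.n_cols;
  const int i0 = std::max(0, -di), i1 = std::min(X, X - di);
  const int j0 = std::max(0, -dj), j1 = std::min(Y, Y - dj);
  const int k0 = std::max(0, -dk), k1 = std::min(Z, Z - dk);
  if (i0 >= i1 || j0 >= j1 || k0 >= k1) return;
  for (int c = 0; c < C; ++c) {
    const double* src = g.colptr(c);
    double* dst = out.colptr(c);
    for (int k = k0; k < k1; ++k) {
      const int ks = k + dk;
      for (int j = j0; j < j1; ++j) {
        const int js = j + dj;
        double* d = dst + (i0 + di) + (size_t)X * (js + (size_t)Y * ks);
        const double* s = src + i0 + (size_t)X * (j + (size_t)Y * k);
        for (int i = 0; i < i1 - i0; ++i) d[i] += s[i];
      }
    }
  }
}

static inline arma::mat kernel_slice(const arma::mat& W, int o, int Cin, int Cout) {
  // W is (27*Cin) x Cout with row index o + 27*ci (R array dim (3,3,3,Cin,Cout)).
  arma::mat Wo(Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      Wo(ci, co) = W(o + 27 * ci, co);
  return Wo;
}

// [[Rcpp::export(name = ".cv_fwd")]]
arma::mat cv_fwd(const arma::mat& x, IntegerVector xd, const arma::mat& W,
                 const arma::vec& b) {
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int Cin = x.n_cols, Cout = W.n_cols;
  arma::mat y(x.n_rows, Cout);
  y.each_row() = b.t();
  arma::mat buf(x.n_rows, Cin);        // reused per offset: cache-resident
  for (int o = 0; o < 27; ++o) {
    const int di = o % 3 - 1, dj = (o / 3) % 3 - 1, dk = o / 9 - 1;
    gather_shift(x, X, Y, Z, di, dj, dk, buf);
    y += buf * kernel_slice(W, o, Cin, Cout);
  }
  return y;
}

// [[Rcpp::export(name = ".cv_bwd")]]
List cv_bwd(const arma::mat& x, IntegerVector xd, const arma::mat& W,
            const arma::mat& gy) {
  const int X = xd[0], Y = xd[1], Z = xd[2];
  const int Cin = x.n_cols, Cout = W.n_cols;
  arma::mat gx(x.n_rows, Cin, arma::fill::zeros);
  arma::mat gW(27 * Cin, Cout);
  arma::mat buf(x.n_rows, Cin), gbuf(x.n_rows, Cin);
  arma::mat gWo(Cin, Cout);
  for (int o = 0; o < 27; ++o) {
    const int di = o % 3 - 1, dj = (o / 3) % 3 - 1, dk = o / 9 - 1;
    gather_shift(x, X, Y, Z, di, dj, dk, buf);
    gWo = buf.t() * gy;                              // Cin x Cout
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        gW(o + 27 * ci, co) = gWo(ci, co);
    gbuf = gy * kernel_slice(W, o, Cin, Cout).t();   // N x Cin, buffer reused
    scatter_shift_add(gbuf, X, Y, Z, di, dj, dk, gx);
  }
  arma::vec gb = arma::sum(gy, 0).t();
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export(name = ".mp_fwd")]]
List mp_fwd(const arma::mat& x, IntegerVector xd) {
  // 2x2x2 max pooling; records the argmax voxel index (0-based) per output.
  const int X = xd[0], Y = xd[1], Z = xd[2], C = x.n_cols;
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const size_t No = (size_t)Xo * Yo * Zo;
  arma::mat y(No, C);
  IntegerMatrix idx(No, C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = y.colptr(c);
    for (int k = 0; k < Zo; ++k)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i) {
          double best = -1e300; size_t barg = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                size_t n = (2 * i + di) + (size_t)X * ((2 * j + dj) + (size_t)Y * (2 * k + dk));
                if (src[n] > best) { best = src[n]; barg = n; }
              }
          size_t no = i + (size_t)Xo * (j + (size_t)Yo * k);
          dst[no] = best;
          idx(no, c) = (int)barg;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".mp_bwd")]]
arma::mat mp_bwd(const arma::mat& gy, IntegerMatrix idx, int Nin) {
  const int C = gy.n_cols;
  arma::mat gx(Nin, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* g = gy.colptr(c);
    double* d = gx.colptr(c);
    for (size_t n = 0; n < gy.n_rows; ++n) d[idx(n, c)] += g[n];
  }
  return gx;
}

// [[Rcpp::export(name = ".up_fwd")]]
arma::mat up_fwd(const arma::mat& x, IntegerVector xd) {
  // 2x2x2 nearest upsampling by element repetition.
  const int X = xd[0], Y = xd[1], Z = xd[2], C = x.n_cols;
  const int Xo = 2 * X, Yo = 2 * Y;
  arma::mat y((size_t)Xo * Yo * 2 * Z, C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = y.colptr(c);
    for (int k = 0; k < 2 * Z; ++k)
      for (int j = 0; j < 2 * Y; ++j)
        for (int i = 0; i < 2 * X; ++i)
          dst[i + (size_t)Xo * (j + (size_t)Yo * k)] =
            src[(i / 2) + (size_t)X * ((j / 2) + (size_t)Y * (k / 2))];
  }
  return y;
}

// [[Rcpp::export(name = ".up_bwd")]]
arma::mat up_bwd(const arma::mat& gy, IntegerVector yd) {
  // Adjoint of repetition: sum each 2x2x2 block.
  const int Xo = yd[0], Yo = yd[1], Zo = yd[2], C = gy.n_cols;
  const int X = Xo / 2, Y = Yo / 2, Z = Zo / 2;
  arma::mat gx((size_t)X * Y * Z, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* g = gy.colptr(c);
    double* d = gx.colptr(c);
    for (int k = 0; k < Zo; ++k)
      for (int j = 0; j < Yo; ++j)
        for (int i = 0; i < Xo; ++i)
          d[(i / 2) + (size_t)X * ((j / 2) + (size_t)Y * (k / 2))] +=
            g[i + (size_t)Xo * (j + (size_t)Yo * k)];
  }
  return gx;
}

// [[Rcpp::export(name = ".nn_min_dists")]]
arma::vec nn_min_dists(const arma::mat& A, const arma::mat& B) {
  // For each row (point) of A, the distance to its nearest neighbour in B.
  const size_t n = A.n_rows, m = B.n_rows;
  arma::vec out(n);
  for (size_t i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = 1e300;
    for (size_t j = 0; j < m; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// [[Rcpp::export(name = ".cc_label26")]]
IntegerVector cc_label26(IntegerVector mask, IntegerVector dims) {
  // 26-connected component labelling of a binary voxel grid (BFS).
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t N = (size_t)X * Y * Z;
  IntegerVector lab(N, 0);
  std::vector<size_t> queue;
  int next = 0;
  for (size_t s = 0; s < N; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      size_t n = queue.back(); queue.pop_back();
      const int i = n % X, j = (n / X) % Y, k = n / ((size_t)X * Y);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= X || jj < 0 || jj >= Y || kk < 0 || kk >= Z) continue;
            const size_t nn = ii + (size_t)X * (jj + (size_t)Y * kk);
            if (mask[nn] != 0 && lab[nn] == 0) { lab[nn] = next; queue.push_back(nn); }
          }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Iso-surface extraction by marching over the Freudenthal (6-tetrahedra)
// decomposition of each grid cell. Field values sit at voxel centers;
// interpolated surface vertices are keyed by the grid edge they lie on, so
// shared edges between tetrahedra/cells produce shared mesh vertices and the
// surface is watertight by construction.

struct MTState {
  std::map<std::pair<size_t, size_t>, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

static int edge_point(MTState& st, size_t a, size_t b,
                      const double* f, double iso,
                      int X, int Y, const double* sp, const double* org) {
  if (a > b) std::swap(a, b);
  auto key = std::make_pair(a, b);
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  const double fa = f[a], fb = f[b];
  const double t = (iso - fa) / (fb - fa);
  const double ai = a % X, aj = (a / X) % Y, ak = a / ((size_t)X * Y);
  const double bi = b % X, bj = (b / X) % Y, bk = b / ((size_t)X * Y);
  st.vx.push_back(org[0] + sp[0] * (ai + t * (bi - ai)));
  st.vy.push_back(org[1] + sp[1] * (aj + t * (bj - aj)));
  st.vz.push_back(org[2] + sp[2] * (ak + t * (bk - ak)));
  const int id = (int)st.vx.size() - 1;
  st.edge_vertex[key] = id;
  return id;
}

static void emit_tri(MTState& st, int a, int b, int c,
                     double ix, double iy, double iz) {
  // Orient the triangle so its normal points away from the interior point
  // (ix, iy, iz), i.e. outward from the >= iso region.
  const double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
  const double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
  const double wx = st.vx[c] - ax, wy = st.vy[c] - ay, wz = st.vz[c] - az;
  const double nx = uy * wz - uz * wy;
  const double ny = uz * wx - ux * wz;
  const double nz = ux * wy - uy * wx;
  const double cx = (ax + st.vx[b] + st.vx[c]) / 3.0 - ix;
  const double cy = (ay + st.vy[b] + st.vy[c]) / 3.0 - iy;
  const double cz = (az + st.vz[b] + st.vz[c]) / 3.0 - iz;
  if (nx * cx + ny * cy + nz * cz >= 0) {
    st.tri.push_back(a); st.tri.push_back(b); st.tri.push_back(c);
  } else {
    st.tri.push_back(a); st.tri.push_back(c); st.tri.push_back(b);
  }
}

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector field, IntegerVector dims, double iso,
                NumericVector spacing, NumericVector origin) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const double* f = field.begin();
  const double* sp = spacing.begin();
  const double* org = origin.begin();
  MTState st;
  // Freudenthal: the six axis-order paths from corner 0 to corner 7.
  static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  const size_t sx = 1, sy = (size_t)X, sz = (size_t)X * Y;
  const size_t step[3] = {sx, sy, sz};
  for (int k = 0; k + 1 < Z; ++k)
    for (int j = 0; j + 1 < Y; ++j)
      for (int i = 0; i + 1 < X; ++i) {
        const size_t c0 = i + (size_t)X * (j + (size_t)Y * k);
        // quick reject: all 8 corners same side
        bool any_in = false, any_out = false;
        for (int d = 0; d < 8; ++d) {
          const size_t v = c0 + (d & 1 ? sx : 0) + (d & 2 ? sy : 0) + (d & 4 ? sz : 0);
          (f[v] >= iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int p = 0; p < 6; ++p) {
          size_t v[4];
          v[0] = c0;
          v[1] = v[0] + step[perms[p][0]];
          v[2] = v[1] + step[perms[p][1]];
          v[3] = v[2] + step[perms[p][2]];
          int inside[4], nin = 0;
          for (int d = 0; d < 4; ++d) inside[d] = f[v[d]] >= iso;
          for (int d = 0; d < 4; ++d) nin += inside[d];
          if (nin == 0 || nin == 4) continue;
          // interior reference point: centroid of inside corners
          double ix = 0, iy = 0, iz = 0; int cnt = 0;
          for (int d = 0; d < 4; ++d) if (inside[d]) {
            ix += org[0] + sp[0] * (double)(v[d] % X);
            iy += org[1] + sp[1] * (double)((v[d] / X) % Y);
            iz += org[2] + sp[2] * (double)(v[d] / ((size_t)X * Y));
            ++cnt;
          }
          ix /= cnt; iy /= cnt; iz /= cnt;
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int d = 0; d < 4; ++d) (inside[d] ? in_idx[ni++] : out_idx[no++]) = d;
          if (nin == 1 || nin == 3) {
            const int apex = (nin == 1) ? in_idx[0] : out_idx[0];
            int e[3], m = 0;
            for (int d = 0; d < 4; ++d) if (d != apex)
              e[m++] = edge_point(st, v[apex], v[d], f, iso, X, Y, sp, org);
            emit_tri(st, e[0], e[1], e[2], ix, iy, iz);
          } else {  // nin == 2: four crossed edges -> quad -> two triangles
            const int a = in_idx[0], b = in_idx[1], c = out_idx[0], d = out_idx[1];
            const int pac = edge_point(st, v[a], v[c], f, iso, X, Y, sp, org);
            const int pad = edge_point(st, v[a], v[d], f, iso, X, Y, sp, org);
            const int pbc = edge_point(st, v[b], v[c], f, iso, X, Y, sp, org);
            const int pbd = edge_point(st, v[b], v[d], f, iso, X, Y, sp, org);
            emit_tri(st, pac, pad, pbd, ix, iy, iz);
            emit_tri(st, pac, pbd, pbc, ix, iy, iz);
          }
        }
      }
  const int nv = (int)st.vx.size();
  NumericMatrix V(nv, 3);
  for (int q = 0; q < nv; ++q) { V(q,0) = st.vx[q]; V(q,1) = st.vy[q]; V(q,2) = st.vz[q]; }
  const int nf = (int)st.tri.size() / 3;
  IntegerMatrix Fm(nf, 3);
  for (int q = 0; q < nf; ++q) {  // 1-based indices for R
    Fm(q,0) = st.tri[3*q] + 1; Fm(q,1) = st.tri[3*q+1] + 1; Fm(q,2) = st.tri[3*q+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}
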