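// Numeric kernels: im2col convolution, 2x2 max pooling, 2x2 transposed
// convolution, 26-connected 3D component labelling, exact anisotropic
// Euclidean distance transform, and trilinear/nearest volume resampling.
//
// Array layouts follow R's column-major convention throughout:
//   feature maps  : H x W x C x N   (rows, cols, channels, batch)
//   volumes       : nz x ny x nx    (slice, row, col)

#include <RcppArmadillo.h>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector make4d(int a, int b, int c, int d) {
  NumericVector v((std::size_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector make4d_int(int a, int b, int c, int d) {
  IntegerVector v((std::size_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// ---------------------------------------------------------------------------
// im2col / col2im for 3x3 same-padding convolution.
// Kt is (H*W) x (C*9); column r = c*9 + dj*3 + di holds x(i+di-1, j+dj-1, c)
// for output pixel p = i + j*H (zero outside the slice).
// ---------------------------------------------------------------------------

static void im2col3(const arma::cube& x, arma::mat& Kt) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  Kt.zeros();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int r = c * 9 + dj * 3 + di;
        const int oi = di - 1, oj = dj - 1;
        double* col = Kt.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int js = j + oj;
          if (js < 0 || js >= W) continue;
          const double* src = x.slice_colptr(c, js);
          double* dst = col + (std::size_t)j * H;
          const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
          for (int i = i0; i < i1; ++i) dst[i] = src[i + oi];
        }
      }
    }
  }
}

static void col2im3(const arma::mat& G, arma::cube& gx) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int r = c * 9 + dj * 3 + di;
        const int oi = di - 1, oj = dj - 1;
        const double* col = G.colptr(r);
        for (int j = 0; j < W; ++j) {
          const int js = j + oj;
          if (js < 0 || js >= W) continue;
          double* dst = gx.slice_colptr(c, js);
          const double* src = col + (std::size_t)j * H;
          const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
          for (int i = i0; i < i1; ++i) dst[i + oi] += src[i];
        }
      }
    }
  }
}

static arma::mat weights3_as_mat(const NumericVector& w, int C, int Co) {
  // w dims: 3 x 3 x C x Co  ->  (C*9) x Co with row order matching im2col3
  arma::mat Wm(C * 9, Co);
  const double* wp = w.begin();
  for (int o = 0; o < Co; ++o)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          Wm(c * 9 + dj * 3 + di, o) =
            wp[di + 3 * dj + 9 * (std::size_t)c + 9 * (std::size_t)C * o];
  return Wm;
}

// [[Rcpp::export(".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Co = wd[3];
  if (wd[0] != 3 || wd[1] != 3 || wd[2] != C)
    stop("conv2d: weight dims do not match input channels");
  arma::mat Wm = weights3_as_mat(w, C, Co);
  arma::rowvec bv(b.begin(), Co);

  NumericVector y = make4d(H, W, Co, N);
  arma::mat Kt(H * W, C * 9);
  for (int n = 0; n < N; ++n) {
    const arma::cube xn(const_cast<double*>(x.begin()) +
                        (std::size_t)n * H * W * C, H, W, C, false, true);
    im2col3(xn, Kt);
    arma::mat Ym = Kt * Wm;            // (H*W) x Co
    Ym.each_row() += bv;
    std::copy(Ym.begin(), Ym.end(), y.begin() + (std::size_t)n * H * W * Co);
  }
  return y;
}

// [[Rcpp::export(".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Co = wd[3];
  arma::mat Wm = weights3_as_mat(w, C, Co);

  NumericVector gx = make4d(H, W, C, N);
  arma::mat gWm(C * 9, Co, arma::fill::zeros);
  arma::rowvec gb(Co, arma::fill::zeros);
  arma::mat Kt(H * W, C * 9);

  for (int n = 0; n < N; ++n) {
    const arma::cube xn(const_cast<double*>(x.begin()) +
                        (std::size_t)n * H * W * C, H, W, C, false, true);
    const arma::mat Gy(const_cast<double*>(gy.begin()) +
                       (std::size_t)n * H * W * Co, H * W, Co, false, true);
    im2col3(xn, Kt);
    gWm += Kt.t() * Gy;
    gb += arma::sum(Gy, 0);
    arma::mat Gcol = Gy * Wm.t();      // (H*W) x (C*9)
    arma::cube gxn(gx.begin() + (std::size_t)n * H * W * C, H, W, C,
                   false, true);
    col2im3(Gcol, gxn);
  }

  NumericVector gw = make4d(3, 3, C, Co);
  double* gwp = gw.begin();
  for (int o = 0; o < Co; ++o)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          gwp[di + 3 * dj + 9 * (std::size_t)c + 9 * (std::size_t)C * o] =
            gWm(c * 9 + dj * 3 + di, o);
  NumericVector gbv(Co);
  std::copy(gb.begin(), gb.end(), gbv.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gbv);
}

// ---------------------------------------------------------------------------
// 2x2 max pooling, stride 2 (H and W must be even).
// ---------------------------------------------------------------------------

// [[Rcpp::export(".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4d(Ho, Wo, C, N);
  IntegerVector idx = make4d_int(Ho, Wo, C, N); // flat index into H*W plane
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (std::size_t s = 0; s < (std::size_t)C * N; ++s) {
    const double* plane = xp + s * H * W;
    double* yplane = yp + s * Ho * Wo;
    int* iplane = ip + s * Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int best = 2 * i + (2 * j) * H;
        double bv = plane[best];
        const int cand[3] = {2 * i + 1 + (2 * j) * H,
                             2 * i + (2 * j + 1) * H,
                             2 * i + 1 + (2 * j + 1) * H};
        for (int k = 0; k < 3; ++k)
          if (plane[cand[k]] > bv) { bv = plane[cand[k]]; best = cand[k]; }
        yplane[i + j * Ho] = bv;
        iplane[i + j * Ho] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector gy, IntegerVector idx,
                               int H, int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector gx = make4d(H, W, C, N);
  const double* gp = gy.begin();
  const int* ip = idx.begin();
  double* xp = gx.begin();
  for (std::size_t s = 0; s < (std::size_t)C * N; ++s) {
    const double* gplane = gp + s * Ho * Wo;
    const int* iplane = ip + s * Ho * Wo;
    double* xplane = xp + s * H * W;
    for (int k = 0; k < Ho * Wo; ++k) xplane[iplane[k]] += gplane[k];
  }
  return gx;
}

// ---------------------------------------------------------------------------
// 2x2 transposed convolution, stride 2 (the decoder's up-convolution).
// w dims: 2 x 2 x Cin x Cout;  y(2i+di, 2j+dj, o) = sum_c x(i,j,c) w(di,dj,c,o)
// ---------------------------------------------------------------------------

// [[Rcpp::export(".cpp_upconv2_fwd")]]
NumericVector cpp_upconv2_fwd(NumericVector x, NumericVector w,
                              NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Co = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = make4d(Ho, Wo, Co, N);

  // Wsub[di][dj]: C x Co
  arma::mat Wsub[2][2];
  const double* wp = w.begin();
  for (int di = 0; di < 2; ++di)
    for (int dj = 0; dj < 2; ++dj) {
      arma::mat m(C, Co);
      for (int o = 0; o < Co; ++o)
        for (int c = 0; c < C; ++c)
          m(c, o) = wp[di + 2 * dj + 4 * (std::size_t)c + 4 * (std::size_t)C * o];
      Wsub[di][dj] = m;
    }

  for (int n = 0; n < N; ++n) {
    const arma::mat Xm(const_cast<double*>(x.begin()) +
                       (std::size_t)n * H * W * C, H * W, C, false, true);
    double* yn = y.begin() + (std::size_t)n * Ho * Wo * Co;
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj) {
        arma::mat Ym = Xm * Wsub[di][dj]; // (H*W) x Co
        for (int o = 0; o < Co; ++o) {
          const double* src = Ym.colptr(o);
          double* dsto = yn + (std::size_t)o * Ho * Wo;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              dsto[(2 * i + di) + (2 * j + dj) * Ho] = src[i + j * H];
        }
      }
    const double* bp = b.begin();
    for (int o = 0; o < Co; ++o) {
      double* dsto = yn + (std::size_t)o * Ho * Wo;
      for (int k = 0; k < Ho * Wo; ++k) dsto[k] += bp[o];
    }
  }
  return y;
}

// [[Rcpp::export(".cpp_upconv2_bwd")]]
List cpp_upconv2_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Co = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;

  arma::mat Wsub[2][2], gWsub[2][2];
  const double* wp = w.begin();
  for (int di = 0; di < 2; ++di)
    for (int dj = 0; dj < 2; ++dj) {
      arma::mat m(C, Co);
      for (int o = 0; o < Co; ++o)
        for (int c = 0; c < C; ++c)
          m(c, o) = wp[di + 2 * dj + 4 * (std::size_t)c + 4 * (std::size_t)C * o];
      Wsub[di][dj] = m;
      gWsub[di][dj] = arma::mat(C, Co, arma::fill::zeros);
    }

  NumericVector gx = make4d(H, W, C, N);
  NumericVector gb(Co);
  arma::mat Gsub(H * W, Co);

  for (int n = 0; n < N; ++n) {
    const arma::mat Xm(const_cast<double*>(x.begin()) +
                       (std::size_t)n * H * W * C, H * W, C, false, true);
    arma::mat gXm(gx.begin() + (std::size_t)n * H * W * C, H * W, C,
                  false, true);
    const double* gyn = gy.begin() + (std::size_t)n * Ho * Wo * Co;
    for (int o = 0; o < Co; ++o) {
      const double* g = gyn + (std::size_t)o * Ho * Wo;
      double acc = 0;
      for (int k = 0; k < Ho * Wo; ++k) acc += g[k];
      gb[o] += acc;
    }
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj) {
        for (int o = 0; o < Co; ++o) {
          const double* g = gyn + (std::size_t)o * Ho * Wo;
          double* dst = Gsub.colptr(o);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              dst[i + j * H] = g[(2 * i + di) + (2 * j + dj) * Ho];
        }
        gWsub[di][dj] += Xm.t() * Gsub;
        gXm += Gsub * Wsub[di][dj].t();
      }
  }

  NumericVector gw = make4d(2, 2, C, Co);
  double* gwp = gw.begin();
  for (int di = 0; di < 2; ++di)
    for (int dj = 0; dj < 2; ++dj)
      for (int o = 0; o < Co; ++o)
        for (int c = 0; c < C; ++c)
          gwp[di + 2 * dj + 4 * (std::size_t)c + 4 * (std::size_t)C * o] =
            gWsub[di][dj](c, o);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// 26-connected component labelling of a 3D binary mask.
// ---------------------------------------------------------------------------

// [[Rcpp::export(".cpp_label3d")]]
IntegerVector cpp_label3d(IntegerVector mask) {
  IntegerVector md = mask.attr("dim");
  const int n1 = md[0], n2 = md[1], n3 = md[2];
  const std::size_t total = (std::size_t)n1 * n2 * n3;
  IntegerVector lab(Dimension(n1, n2, n3));
  const int* mp = mask.begin();
  int* lp = lab.begin();
  int next = 0;
  std::vector<std::size_t> stack;
  for (std::size_t s = 0; s < total; ++s) {
    if (!mp[s] || lp[s]) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lp[s] = next;
    while (!stack.empty()) {
      const std::size_t v = stack.back();
      stack.pop_back();
      const int i = v % n1, j = (v / n1) % n2, k = v / ((std::size_t)n1 * n2);
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= n3) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= n2) continue;
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int ii = i + di;
            if (ii < 0 || ii >= n1) continue;
            const std::size_t u =
              ii + (std::size_t)n1 * (jj + (std::size_t)n2 * kk);
            if (mp[u] && !lp[u]) { lp[u] = next; stack.push_back(u); }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact anisotropic squared Euclidean distance transform
// (Felzenszwalb-Huttenlocher lower envelope of parabolas, per axis).
// Returns distance in physical units to the nearest foreground voxel centre.
// ---------------------------------------------------------------------------

static const double DT_INF = 1e30;

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 double s, std::vector<int>& v, std::vector<double>& z) {
  const double NEG_INF = -std::numeric_limits<double>::infinity();
  const double POS_INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = NEG_INF;   // true infinities: finite intersections never reach them
  z[1] = POS_INF;
  for (int q = 1; q < n; ++q) {
    const double fq = f[q] + (q * s) * (q * s);
    double sint;
    while (true) {
      const double fv = f[v[k]] + (v[k] * s) * (v[k] * s);
      sint = (fq - fv) / (2.0 * s * (q - v[k]));
      if (sint <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = POS_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q * s) ++k;
    const double diff = (q - v[k]) * s;
    d[q] = diff * diff + f[v[k]];
  }
}

// [[Rcpp::export(".cpp_edt3d")]]
NumericVector cpp_edt3d(IntegerVector mask, NumericVector spacing) {
  IntegerVector md = mask.attr("dim");
  const int n1 = md[0], n2 = md[1], n3 = md[2];
  const std::size_t total = (std::size_t)n1 * n2 * n3;
  NumericVector out(Dimension(n1, n2, n3));
  double* op = out.begin();
  const int* mp = mask.begin();
  for (std::size_t s = 0; s < total; ++s) op[s] = mp[s] ? 0.0 : DT_INF;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1), spacing[0]
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      double* line = op + (std::size_t)n1 * (j + (std::size_t)n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = line[i];
      dt1d(f, d, n1, spacing[0], v, z);
      for (int i = 0; i < n1; ++i) line[i] = d[i];
    }
  // axis 2 (stride n1), spacing[1]
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      double* base = op + i + (std::size_t)n1 * n2 * k;
      for (int j = 0; j < n2; ++j) f[j] = base[(std::size_t)j * n1];
      dt1d(f, d, n2, spacing[1], v, z);
      for (int j = 0; j < n2; ++j) base[(std::size_t)j * n1] = d[j];
    }
  // axis 3 (stride n1*n2), spacing[2]
  const std::size_t s3 = (std::size_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      double* base = op + i + (std::size_t)n1 * j;
      for (int k = 0; k < n3; ++k) f[k] = base[(std::size_t)k * s3];
      dt1d(f, d, n3, spacing[2], v, z);
      for (int k = 0; k < n3; ++k) base[(std::size_t)k * s3] = d[k];
    }

  for (std::size_t s = 0; s < total; ++s)
    op[s] = (op[s] >= DT_INF) ? R_PosInf : std::sqrt(op[s]);
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear / nearest-neighbour resampling onto a new grid.
// Output voxel centre k (0-based) sits at physical position k * out_spacing
// along each axis; input index = position / in_spacing, clamped at the edges.
// ---------------------------------------------------------------------------

// [[Rcpp::export(".cpp_resample3d")]]
NumericVector cpp_resample3d(NumericVector x, IntegerVector dims_out,
                             NumericVector sp_in, NumericVector sp_out,
                             bool nearest) {
  IntegerVector xd = x.attr("dim");
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2];
  const int m1 = dims_out[0], m2 = dims_out[1], m3 = dims_out[2];
  NumericVector y(Dimension(m1, m2, m3));
  const double* xp = x.begin();
  double* yp = y.begin();

  std::vector<int> i0_1(m1), i1_1(m1), i0_2(m2), i1_2(m2), i0_3(m3), i1_3(m3);
  std::vector<double> t1(m1), t2(m2), t3(m3);
  auto prep = [&](int m, int n, double si, double so, std::vector<int>& lo,
                  std::vector<int>& hi, std::vector<double>& t) {
    for (int k = 0; k < m; ++k) {
      double pos = (double)k * so / si;
      // snap to the lattice so identity resampling is exact
      if (std::fabs(pos - std::round(pos)) < 1e-9) pos = std::round(pos);
      if (nearest) {
        int idx = (int)std::floor(pos + 0.5);
        idx = std::min(std::max(idx, 0), n - 1);
        lo[k] = hi[k] = idx;
        t[k] = 0.0;
      } else {
        if (pos <= 0) { lo[k] = hi[k] = 0; t[k] = 0; }
        else if (pos >= n - 1) { lo[k] = hi[k] = n - 1; t[k] = 0; }
        else {
          lo[k] = (int)std::floor(pos);
          hi[k] = lo[k] + 1;
          t[k] = pos - lo[k];
        }
      }
    }
  };
  prep(m1, n1, sp_in[0], sp_out[0], i0_1, i1_1, t1);
  prep(m2, n2, sp_in[1], sp_out[1], i0_2, i1_2, t2);
  prep(m3, n3, sp_in[2], sp_out[2], i0_3, i1_3, t3);

  for (int k = 0; k < m3; ++k) {
    for (int j = 0; j < m2; ++j) {
      for (int i = 0; i < m1; ++i) {
        const double a = t1[i], bb = t2[j], c = t3[k];
        double val = 0;
        for (int dk = 0; dk < 2; ++dk) {
          const double wk = dk ? c : 1 - c;
          if (wk == 0) continue;
          const int zk = dk ? i1_3[k] : i0_3[k];
          for (int dj = 0; dj < 2; ++dj) {
            const double wj = dj ? bb : 1 - bb;
            if (wj == 0) continue;
            const int yj = dj ? i1_2[j] : i0_2[j];
            const std::size_t base =
              (std::size_t)n1 * (yj + (std::size_t)n2 * zk);
            for (int di = 0; di < 2; ++di) {
              const double wi = di ? a : 1 - a;
              if (wi == 0) continue;
              const int xi = di ? i1_1[i] : i0_1[i];
              val += wk * wj * wi * xp[base + xi];
            }
          }
        }
        yp[i + (std::size_t)m1 * (j + (std::size_t)m2 * k)] = val;
      }
    }
  }
  return y;
}
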