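// Low-level neural-network kernels: stride-1 same-padding 2-D convolution
// via im2col + GEMM, 2-D pooling, and an LSTM recurrence with full
// backpropagation through time. Array layouts are R column-major:
//   images   (H, W, C, N)
//   sequences (T, F, N)   -- time-major, F features per step
//   conv weights (kh, kw, Cin, Cout); flattened column index of the
//   im2col matrix is ki + kh*(kj + kw*c), matching the weight layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_same(const double* xn, int H, int W, int C,
                        int kh, int kw, arma::mat& M) {
  const int ph = kh / 2, pw = kw / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* Mcol = M.colptr(ki + kh * (kj + kw * c));
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - pw;
          double* Mj = Mcol + (size_t)j * H;
          if (jj < 0 || jj >= W) {
            std::fill(Mj, Mj + H, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)jj * H;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - ph;
            Mj[i] = (ii < 0 || ii >= H) ? 0.0 : xcol[ii];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(const NumericVector& x, const IntegerVector& xd,
                            const NumericVector& w, const IntegerVector& wd,
                            const NumericVector& b) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], K = wd[3];
  if (wd[2] != C) stop("conv2d: input channels (%d) do not match kernel (%d)", C, wd[2]);
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, K, false, true);
  const arma::rowvec bv(const_cast<double*>(b.begin()), K, false, true);
  NumericVector y((size_t)H * W * K * N);
  arma::mat M((size_t)H * W, (size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, M);
    arma::mat Yn(y.begin() + (size_t)n * H * W * K, (size_t)H * W, K, false, true);
    Yn = M * Wm;
    Yn.each_row() += bv;
  }
  y.attr("dim") = IntegerVector::create(H, W, K, N);
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(const NumericVector& x, const IntegerVector& xd,
                   const NumericVector& w, const IntegerVector& wd,
                   const NumericVector& dy) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], K = wd[3];
  const int ph = kh / 2, pw = kw / 2;
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, K, false, true);
  NumericVector dx((size_t)H * W * C * N);
  arma::mat dW((size_t)kh * kw * C, K, arma::fill::zeros);
  arma::rowvec db(K, arma::fill::zeros);
  arma::mat M((size_t)H * W, (size_t)kh * kw * C);
  arma::mat dM((size_t)H * W, (size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, M);
    const arma::mat dYn(const_cast<double*>(dy.begin()) + (size_t)n * H * W * K,
                        (size_t)H * W, K, false, true);
    dW += M.t() * dYn;
    db += arma::sum(dYn, 0);
    dM = dYn * Wm.t();
    // col2im scatter-add
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + (size_t)c * H * W;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const double* Mcol = dM.colptr(ki + kh * (kj + kw * c));
          for (int j = 0; j < W; ++j) {
            const int jj = j + kj - pw;
            if (jj < 0 || jj >= W) continue;
            const double* Mj = Mcol + (size_t)j * H;
            double* dxcol = dxc + (size_t)jj * H;
            for (int i = 0; i < H; ++i) {
              const int ii = i + ki - ph;
              if (ii >= 0 && ii < H) dxcol[ii] += Mj[i];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xd;
  NumericVector dWout(wrap(dW));
  dWout.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dW"] = dWout, _["db"] = NumericVector(wrap(db)));
}

// type: 0 = average, 1 = max. Pool cells of size (ph, pw) with matching
// stride; trailing rows/columns that do not fill a cell are dropped
// (floor division), as in the 95 -> 47 -> 23 -> 11 chain.
// [[Rcpp::export]]
List nn_pool2d_fwd(const NumericVector& x, const IntegerVector& xd,
                   int ph, int pw, int type) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / ph, Wo = W / pw;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector amax(type == 1 ? (size_t)Ho * Wo * C * N : 0);
  const double inv = 1.0 / (ph * pw);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++o) {
          if (type == 0) {
            double s = 0.0;
            for (int dj = 0; dj < pw; ++dj)
              for (int di = 0; di < ph; ++di)
                s += xc[(size_t)(j * pw + dj) * H + i * ph + di];
            y[o] = s * inv;
          } else {
            double best = -std::numeric_limits<double>::infinity();
            int besti = 0;
            for (int dj = 0; dj < pw; ++dj)
              for (int di = 0; di < ph; ++di) {
                const int idx = (j * pw + dj) * H + i * ph + di;
                if (xc[idx] > best) { best = xc[idx]; besti = idx; }
              }
            y[o] = best;
            amax[o] = besti;
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector nn_pool2d_bwd(const NumericVector& dy, const IntegerVector& xd,
                            int ph, int pw, int type, const IntegerVector& amax) {
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / ph, Wo = W / pw;
  NumericVector dx((size_t)H * W * C * N);
  const double inv = 1.0 / (ph * pw);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + (size_t)(n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++o) {
          if (type == 0) {
            const double g = dy[o] * inv;
            for (int dj = 0; dj < pw; ++dj)
              for (int di = 0; di < ph; ++di)
                dxc[(size_t)(j * pw + dj) * H + i * ph + di] += g;
          } else {
            dxc[amax[o]] += dy[o];
          }
        }
      }
    }
  }
  dx.attr("dim") = xd;
  return dx;
}

static inline arma::mat sigm(const arma::mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

// x: (T, F, N); Wx: F x 4U; Wh: U x 4U; b: 4U. Gate order i, f, g, o.
// Returns h_all (T, U, N) plus caches for BPTT.
// [[Rcpp::export]]
List nn_lstm_fwd(const NumericVector& x, const IntegerVector& xd,
                 const NumericMatrix& Wx, const NumericMatrix& Wh,
                 const NumericVector& b) {
  const int T = xd[0], F = xd[1], N = xd[2];
  const int U = Wh.nrow();
  const arma::mat WxA(const_cast<double*>(Wx.begin()), F, 4 * U, false, true);
  const arma::mat WhA(const_cast<double*>(Wh.begin()), U, 4 * U, false, true);
  const arma::rowvec bA(const_cast<double*>(b.begin()), 4 * U, false, true);
  NumericVector hall((size_t)T * U * N);
  NumericVector gates((size_t)N * 4 * U * T);  // activated gates, (N, 4U, T)
  NumericVector cstore((size_t)N * U * T);     // cell state, (N, U, T)
  arma::mat Xt(N, F), H(N, U, arma::fill::zeros), Cst(N, U, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    for (int f = 0; f < F; ++f)
      for (int n = 0; n < N; ++n)
        Xt(n, f) = x[t + (size_t)T * (f + (size_t)F * n)];
    arma::mat G = Xt * WxA + H * WhA;
    G.each_row() += bA;
    arma::mat gi = sigm(G.cols(0, U - 1));
    arma::mat gf = sigm(G.cols(U, 2 * U - 1));
    arma::mat gg = arma::tanh(G.cols(2 * U, 3 * U - 1));
    arma::mat go = sigm(G.cols(3 * U, 4 * U - 1));
    Cst = gf % Cst + gi % gg;
    H = go % arma::tanh(Cst);
    double* gt = gates.begin() + (size_t)t * N * 4 * U;
    std::copy(gi.begin(), gi.end(), gt);
    std::copy(gf.begin(), gf.end(), gt + (size_t)N * U);
    std::copy(gg.begin(), gg.end(), gt + (size_t)2 * N * U);
    std::copy(go.begin(), go.end(), gt + (size_t)3 * N * U);
    std::copy(Cst.begin(), Cst.end(), cstore.begin() + (size_t)t * N * U);
    for (int u = 0; u < U; ++u)
      for (int n = 0; n < N; ++n)
        hall[t + (size_t)T * (u + (size_t)U * n)] = H(n, u);
  }
  hall.attr("dim") = IntegerVector::create(T, U, N);
  return List::create(_["h"] = hall, _["gates"] = gates, _["c"] = cstore);
}

// dh: (T, U, N) upstream gradient on every step's hidden state (zero-filled
// except the last step when only the final state feeds forward).
// [[Rcpp::export]]
List nn_lstm_bwd(const NumericVector& x, const IntegerVector& xd,
                 const NumericMatrix& Wx, const NumericMatrix& Wh,
                 const NumericVector& gates, const NumericVector& cstore,
                 const NumericVector& hall, const NumericVector& dh) {
  const int T = xd[0], F = xd[1], N = xd[2];
  const int U = Wh.nrow();
  const arma::mat WxA(const_cast<double*>(Wx.begin()), F, 4 * U, false, true);
  const arma::mat WhA(const_cast<double*>(Wh.begin()), U, 4 * U, false, true);
  NumericVector dx((size_t)T * F * N);
  arma::mat dWx(F, 4 * U, arma::fill::zeros), dWh(U, 4 * U, arma::fill::zeros);
  arma::rowvec db(4 * U, arma::fill::zeros);
  arma::mat dHnext(N, U, arma::fill::zeros), dCnext(N, U, arma::fill::zeros);
  arma::mat Xt(N, F), Hprev(N, U), Cprev(N, U);
  for (int t = T - 1; t >= 0; --t) {
    const double* gt = gates.begin() + (size_t)t * N * 4 * U;
    const arma::mat gi(const_cast<double*>(gt), N, U, false, true);
    const arma::mat gf(const_cast<double*>(gt) + (size_t)N * U, N, U, false, true);
    const arma::mat gg(const_cast<double*>(gt) + (size_t)2 * N * U, N, U, false, true);
    const arma::mat go(const_cast<double*>(gt) + (size_t)3 * N * U, N, U, false, true);
    const arma::mat Ct(const_cast<double*>(cstore.begin()) + (size_t)t * N * U, N, U, false, true);
    if (t > 0) {
      const double* cp = cstore.begin() + (size_t)(t - 1) * N * U;
      std::copy(cp, cp + (size_t)N * U, Cprev.memptr());
      for (int u = 0; u < U; ++u)
        for (int n = 0; n < N; ++n)
          Hprev(n, u) = hall[(t - 1) + (size_t)T * (u + (size_t)U * n)];
    } else {
      Cprev.zeros();
      Hprev.zeros();
    }
    for (int f = 0; f < F; ++f)
      for (int n = 0; n < N; ++n)
        Xt(n, f) = x[t + (size_t)T * (f + (size_t)F * n)];
    arma::mat dH = dHnext;
    for (int u = 0; u < U; ++u)
      for (int n = 0; n < N; ++n)
        dH(n, u) += dh[t + (size_t)T * (u + (size_t)U * n)];
    const arma::mat tc = arma::tanh(Ct);
    arma::mat dO = dH % tc;
    arma::mat dC = dCnext + dH % go % (1.0 - tc % tc);
    arma::mat dI = dC % gg;
    arma::mat dF = dC % Cprev;
    arma::mat dG = dC % gi;
    arma::mat dpre(N, 4 * U);
    dpre.cols(0, U - 1) = dI % gi % (1.0 - gi);
    dpre.cols(U, 2 * U - 1) = dF % gf % (1.0 - gf);
    dpre.cols(2 * U, 3 * U - 1) = dG % (1.0 - gg % gg);
    dpre.cols(3 * U, 4 * U - 1) = dO % go % (1.0 - go);
    dWx += Xt.t() * dpre;
    dWh += Hprev.t() * dpre;
    db += arma::sum(dpre, 0);
    const arma::mat dXt = dpre * WxA.t();
    for (int f = 0; f < F; ++f)
      for (int n = 0; n < N; ++n)
        dx[t + (size_t)T * (f + (size_t)F * n)] = dXt(n, f);
    dHnext = dpre * WhA.t();
    dCnext = dC % gf;
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dWx"] = NumericMatrix(wrap(dWx)),
                      _["dWh"] = NumericMatrix(wrap(dWh)),
                      _["db"] = NumericVector(wrap(db)));
}

// In-place ADAM update over matching named lists. The caller owns the
// memory of params/m/v (they are duplicated once per training run), so
// updating through the proxies is safe.
// [[Rcpp::export]]
void nn_adam_update(List params, List m, List v, const List& grads,
                    double lr, double beta1, double beta2, int t, double eps) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  CharacterVector nms = grads.names();
  for (int k = 0; k < grads.size(); ++k) {
    const std::string nm = as<std::string>(nms[k]);
    NumericVector g = grads[nm];
    NumericVector pm = m[nm];
    NumericVector pv = v[nm];
    NumericVector pp = params[nm];
    const R_xlen_t n = g.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      pm[i] = beta1 * pm[i] + (1.0 - beta1) * g[i];
      pv[i] = beta2 * pv[i] + (1.0 - beta2) * g[i] * g[i];
      pp[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
    }
  }
}
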