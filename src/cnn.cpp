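// Small convolutional network for 24x24 grayscale nodule patches.
//
// Architecture (valid 3x3 convolutions, 2x2 max pooling):
//   24x24x1 -> conv(nf1) -> 22x22 -> conv(nf1) -> 20x20 -> pool -> 10x10
//           -> conv(nf2) ->  8x8  -> conv(nf2) ->  6x6  -> pool ->  3x3
//           -> flatten -> dropout -> dense(nd, ReLU) -> dropout -> sigmoid
//
// Convolutions are computed as im2col + gemm. Activation tensors are cubes
// of shape (H, W, B*C) with slice index b*C + c; the matching matrix layout
// is (Hout*Wout*B) x C with element (b*HW + j*Hout + i, c), so both
// directions of the reshape are contiguous memcpy per (b, c) block.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int KS = 3; // kernel side

// im2col for valid 3x3 convolution over a cube (H, W, B*C).
// Returns (Hout*Wout*B) x (C*9); column c*9 + dj*3 + di holds input pixel
// (i+di, j+dj) of channel c for every output location (i, j) of every image.
static mat im2col3(const cube& A, const int C) {
  const int H = A.n_rows, W = A.n_cols, B = A.n_slices / C;
  const int Hout = H - KS + 1, Wout = W - KS + 1, HW = Hout * Wout;
  mat out(static_cast<uword>(HW) * B, static_cast<uword>(C) * KS * KS);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < KS; ++dj)
      for (int di = 0; di < KS; ++di) {
        double* dst = out.colptr(c * KS * KS + dj * KS + di);
        for (int b = 0; b < B; ++b) {
          const uword s = static_cast<uword>(b) * C + c;
          for (int j = 0; j < Wout; ++j) {
            const double* src = &A(di, j + dj, s);
            std::memcpy(dst + static_cast<size_t>(b) * HW +
                            static_cast<size_t>(j) * Hout,
                        src, Hout * sizeof(double));
          }
        }
      }
  return out;
}

// Adjoint of im2col3: scatter-add column gradients back onto the input cube.
static cube col2im3(const mat& dcols, const int C, const int H, const int W,
                    const int B) {
  const int Hout = H - KS + 1, Wout = W - KS + 1, HW = Hout * Wout;
  cube dA(H, W, static_cast<uword>(B) * C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < KS; ++dj)
      for (int di = 0; di < KS; ++di) {
        const double* src = dcols.colptr(c * KS * KS + dj * KS + di);
        for (int b = 0; b < B; ++b) {
          const uword s = static_cast<uword>(b) * C + c;
          for (int j = 0; j < Wout; ++j) {
            double* dst = &dA(di, j + dj, s);
            const double* col = src + static_cast<size_t>(b) * HW +
                                static_cast<size_t>(j) * Hout;
            for (int i = 0; i < Hout; ++i) dst[i] += col[i];
          }
        }
      }
  return dA;
}

// (HW*B) x C activation matrix -> (Hout, Wout, B*C) cube.
static cube mat2cube(const mat& Z, const int Hout, const int Wout,
                     const int C) {
  const int HW = Hout * Wout, B = Z.n_rows / HW;
  cube A(Hout, Wout, static_cast<uword>(B) * C);
  for (int c = 0; c < C; ++c) {
    const double* src = Z.colptr(c);
    for (int b = 0; b < B; ++b)
      std::memcpy(A.slice_memptr(static_cast<uword>(b) * C + c),
                  src + static_cast<size_t>(b) * HW, HW * sizeof(double));
  }
  return A;
}

static mat cube2mat(const cube& A, const int C) {
  const int HW = A.n_rows * A.n_cols, B = A.n_slices / C;
  mat Z(static_cast<uword>(HW) * B, C);
  for (int c = 0; c < C; ++c) {
    double* dst = Z.colptr(c);
    for (int b = 0; b < B; ++b)
      std::memcpy(dst + static_cast<size_t>(b) * HW,
                  A.slice_memptr(static_cast<uword>(b) * C + c),
                  HW * sizeof(double));
  }
  return Z;
}

// 2x2 max pooling with stride 2; argmax stores the linear index into the
// input cube for the winning element of each pooled cell.
static cube maxpool2(const cube& A, uvec& argmax) {
  const int H = A.n_rows, W = A.n_cols, S = A.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube P(Ho, Wo, S);
  argmax.set_size(static_cast<uword>(Ho) * Wo * S);
  uword k = 0;
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double v, vmax = -datum::inf;
        uword imax = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const uword idx = static_cast<uword>(s) * H * W +
                              static_cast<uword>(2 * j + dj) * H +
                              (2 * i + di);
            v = A(idx);
            if (v > vmax) { vmax = v; imax = idx; }
          }
        P(i, j, s) = vmax;
        argmax(k++) = imax;
      }
  return P;
}

static cube unpool2(const cube& dP, const uvec& argmax, const int H,
                    const int W) {
  cube dA(H, W, dP.n_slices, fill::zeros);
  for (uword k = 0; k < argmax.n_elem; ++k) dA(argmax(k)) += dP(k);
  return dA;
}

struct Params {
  mat W1, W2, W3, W4, Wd, Wo;
  rowvec b1, b2, b3, b4;
  vec bd;
  double bo;
};

static Params unpack(const Rcpp::List& p) {
  Params q;
  q.W1 = Rcpp::as<mat>(p["W1"]); q.b1 = Rcpp::as<rowvec>(p["b1"]);
  q.W2 = Rcpp::as<mat>(p["W2"]); q.b2 = Rcpp::as<rowvec>(p["b2"]);
  q.W3 = Rcpp::as<mat>(p["W3"]); q.b3 = Rcpp::as<rowvec>(p["b3"]);
  q.W4 = Rcpp::as<mat>(p["W4"]); q.b4 = Rcpp::as<rowvec>(p["b4"]);
  q.Wd = Rcpp::as<mat>(p["Wd"]); q.bd = Rcpp::as<vec>(p["bd"]);
  q.Wo = Rcpp::as<mat>(p["Wo"]); q.bo = Rcpp::as<double>(p["bo"]);
  return q;
}

static Rcpp::List pack(const Params& q) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = q.W1, Rcpp::Named("b1") = q.b1,
      Rcpp::Named("W2") = q.W2, Rcpp::Named("b2") = q.b2,
      Rcpp::Named("W3") = q.W3, Rcpp::Named("b3") = q.b3,
      Rcpp::Named("W4") = q.W4, Rcpp::Named("b4") = q.b4,
      Rcpp::Named("Wd") = q.Wd, Rcpp::Named("bd") = q.bd,
      Rcpp::Named("Wo") = q.Wo, Rcpp::Named("bo") = q.bo);
}

// He-normal initialization, deterministic under seed.
// [[Rcpp::export(name = ".cnn_init")]]
Rcpp::List cnn_init(const int nf1, const int nf2, const int nd,
                    const int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> N(0.0, 1.0);
  auto he = [&](const int rows, const int cols, const int fan_in) {
    mat M(rows, cols);
    const double sd = std::sqrt(2.0 / fan_in);
    for (uword j = 0; j < M.n_cols; ++j)
      for (uword i = 0; i < M.n_rows; ++i) M(i, j) = sd * N(rng);
    return M;
  };
  Params q;
  q.W1 = he(9, nf1, 9);              // stored transposed: (C_in*9) x C_out
  q.W2 = he(nf1 * 9, nf1, nf1 * 9);
  q.W3 = he(nf1 * 9, nf2, nf1 * 9);
  q.W4 = he(nf2 * 9, nf2, nf2 * 9);
  const int flat = 3 * 3 * nf2;
  q.Wd = he(nd, flat, flat);
  q.Wo = he(1, nd, nd);
  q.b1 = rowvec(nf1, fill::zeros); q.b2 = rowvec(nf1, fill::zeros);
  q.b3 = rowvec(nf2, fill::zeros); q.b4 = rowvec(nf2, fill::zeros);
  q.bd = vec(nd, fill::zeros); q.bo = 0.0;
  return pack(q);
}

struct Fwd {
  mat cols1, cols2, cols3, cols4; // im2col caches
  mat Z1, Z2, Z3, Z4;             // post-ReLU conv activations, matrix form
  cube A2c, A4c;                  // post-ReLU cubes feeding the pools
  cube P1, P2;
  uvec am1, am2;
  mat Xf, Xfd, H, Hd;             // flat features, dropped, dense, dropped
  rowvec z;
  rowvec p;
};

// Forward pass over a batch cube X (24, 24, B). When train is true the two
// dropout masks (inverted dropout) are drawn from rng and returned in M1/M2.
static void forward(const Params& q, const cube& X, Fwd& f, const bool train,
                    const double drop, std::mt19937_64& rng, mat& M1,
                    mat& M2) {
  const int B = X.n_slices;
  const int nf1 = q.W1.n_cols, nf2 = q.W3.n_cols;
  f.cols1 = im2col3(X, 1);                          // (484B) x 9
  f.Z1 = f.cols1 * q.W1; f.Z1.each_row() += q.b1;   // (484B) x nf1
  f.Z1.clamp(0.0, datum::inf);
  cube A1c = mat2cube(f.Z1, 22, 22, nf1);
  f.cols2 = im2col3(A1c, nf1);
  f.Z2 = f.cols2 * q.W2; f.Z2.each_row() += q.b2;
  f.Z2.clamp(0.0, datum::inf);
  f.A2c = mat2cube(f.Z2, 20, 20, nf1);
  f.P1 = maxpool2(f.A2c, f.am1);                    // 10x10
  f.cols3 = im2col3(f.P1, nf1);
  f.Z3 = f.cols3 * q.W3; f.Z3.each_row() += q.b3;
  f.Z3.clamp(0.0, datum::inf);
  cube A3c = mat2cube(f.Z3, 8, 8, nf2);
  f.cols4 = im2col3(A3c, nf2);
  f.Z4 = f.cols4 * q.W4; f.Z4.each_row() += q.b4;
  f.Z4.clamp(0.0, datum::inf);
  f.A4c = mat2cube(f.Z4, 6, 6, nf2);
  f.P2 = maxpool2(f.A4c, f.am2);                    // 3x3
  const int flat = 9 * nf2;
  f.Xf.set_size(flat, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < nf2; ++c)
      std::memcpy(f.Xf.colptr(b) + 9 * c,
                  f.P2.slice_memptr(static_cast<uword>(b) * nf2 + c),
                  9 * sizeof(double));
  if (train && drop > 0) {
    std::bernoulli_distribution keep(1.0 - drop);
    auto mask = [&](const uword r, const uword c) {
      mat M(r, c);
      for (uword j = 0; j < c; ++j)
        for (uword i = 0; i < r; ++i)
          M(i, j) = keep(rng) ? 1.0 / (1.0 - drop) : 0.0;
      return M;
    };
    M1 = mask(flat, B);
    M2 = mask(q.Wd.n_rows, B);
    f.Xfd = f.Xf % M1;
  } else {
    f.Xfd = f.Xf;
  }
  f.H = q.Wd * f.Xfd; f.H.each_col() += q.bd;
  f.H.clamp(0.0, datum::inf);
  f.Hd = (train && drop > 0) ? mat(f.H % M2) : f.H;
  f.z = q.Wo * f.Hd + q.bo;
  f.p = 1.0 / (1.0 + exp(-f.z));
}

// [[Rcpp::export(name = ".cnn_forward")]]
Rcpp::List cnn_forward(const Rcpp::List& params, const arma::cube& X,
                       const bool features = false) {
  const Params q = unpack(params);
  Fwd f; mat M1, M2; std::mt19937_64 rng(0);
  forward(q, X, f, false, 0.0, rng, M1, M2);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("prob") = Rcpp::NumericVector(f.p.begin(), f.p.end()));
  if (features) out["features"] = mat(f.H.t()); // n x nd dense activations
  return out;
}

// One epoch of minibatch Adam on binary cross-entropy. X is the epoch's
// (already augmented, standardized) patch cube in presentation order.
// [[Rcpp::export(name = ".cnn_train_epoch")]]
Rcpp::List cnn_train_epoch(const Rcpp::List& params, Rcpp::List adam,
                           const arma::cube& X, const arma::vec& y,
                           const int batch_size, const double lr,
                           const double dropout, const int seed) {
  Params q = unpack(params);
  const int n = X.n_slices;
  const int nf1 = q.W1.n_cols, nf2 = q.W3.n_cols;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));

  // Adam state: flat vectors m and v spanning all parameters, plus step t.
  const uword npar = q.W1.n_elem + q.W2.n_elem + q.W3.n_elem + q.W4.n_elem +
                     q.Wd.n_elem + q.Wo.n_elem + q.b1.n_elem + q.b2.n_elem +
                     q.b3.n_elem + q.b4.n_elem + q.bd.n_elem + 1;
  vec m, v; int t;
  if (adam.size() == 0 || !adam.containsElementNamed("m")) {
    m = vec(npar, fill::zeros); v = vec(npar, fill::zeros); t = 0;
  } else {
    m = Rcpp::as<vec>(adam["m"]); v = Rcpp::as<vec>(adam["v"]);
    t = Rcpp::as<int>(adam["t"]);
  }
  const double b1a = 0.9, b2a = 0.999, eps = 1e-8;

  double loss_sum = 0.0;
  for (int start = 0; start < n; start += batch_size) {
    const int stop = std::min(start + batch_size, n) - 1;
    const int B = stop - start + 1;
    const cube Xb = X.slices(start, stop);
    const vec yb = y.subvec(start, stop);

    Fwd f; mat M1, M2;
    forward(q, Xb, f, true, dropout, rng, M1, M2);

    for (int i = 0; i < B; ++i) {
      const double pi = std::min(std::max(f.p(i), 1e-12), 1.0 - 1e-12);
      loss_sum -= yb(i) * std::log(pi) + (1 - yb(i)) * std::log(1 - pi);
    }

    // backward
    rowvec dz = (f.p - yb.t()) / B;
    mat dWo = dz * f.Hd.t();
    const double dbo = accu(dz);
    mat dH = q.Wo.t() * dz;
    if (dropout > 0) dH %= M2;
    dH %= conv_to<mat>::from(f.H > 0);
    mat dWd = dH * f.Xfd.t();
    vec dbd = sum(dH, 1);
    mat dXf = q.Wd.t() * dH;
    if (dropout > 0) dXf %= M1;

    cube dP2(3, 3, static_cast<uword>(B) * nf2);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < nf2; ++c)
        std::memcpy(dP2.slice_memptr(static_cast<uword>(b) * nf2 + c),
                    dXf.colptr(b) + 9 * c, 9 * sizeof(double));
    cube dA4 = unpool2(dP2, f.am2, 6, 6);
    mat dZ4 = cube2mat(dA4, nf2);
    dZ4 %= conv_to<mat>::from(f.Z4 > 0);
    mat dW4 = f.cols4.t() * dZ4;
    rowvec db4 = sum(dZ4, 0);
    cube dA3 = col2im3(dZ4 * q.W4.t(), nf2, 8, 8, B);
    mat dZ3 = cube2mat(dA3, nf2);
    dZ3 %= conv_to<mat>::from(f.Z3 > 0);
    mat dW3 = f.cols3.t() * dZ3;
    rowvec db3 = sum(dZ3, 0);
    cube dP1 = col2im3(dZ3 * q.W3.t(), nf1, 10, 10, B);
    cube dA2 = unpool2(dP1, f.am1, 20, 20);
    mat dZ2 = cube2mat(dA2, nf1);
    dZ2 %= conv_to<mat>::from(f.Z2 > 0);
    mat dW2 = f.cols2.t() * dZ2;
    rowvec db2 = sum(dZ2, 0);
    cube dA1 = col2im3(dZ2 * q.W2.t(), nf1, 22, 22, B);
    mat dZ1 = cube2mat(dA1, nf1);
    dZ1 %= conv_to<mat>::from(f.Z1 > 0);
    mat dW1 = f.cols1.t() * dZ1;
    rowvec db1 = sum(dZ1, 0);

    // Adam update over the concatenated gradient
    ++t;
    vec g(npar);
    uword off = 0;
    auto put = [&](const double* src, const uword len) {
      std::memcpy(g.memptr() + off, src, len * sizeof(double)); off += len;
    };
    put(dW1.memptr(), dW1.n_elem); put(dW2.memptr(), dW2.n_elem);
    put(dW3.memptr(), dW3.n_elem); put(dW4.memptr(), dW4.n_elem);
    put(dWd.memptr(), dWd.n_elem); put(dWo.memptr(), dWo.n_elem);
    put(db1.memptr(), db1.n_elem); put(db2.memptr(), db2.n_elem);
    put(db3.memptr(), db3.n_elem); put(db4.memptr(), db4.n_elem);
    put(dbd.memptr(), dbd.n_elem);
    g(off++) = dbo;

    m = b1a * m + (1 - b1a) * g;
    v = b2a * v + (1 - b2a) * square(g);
    const double corr =
        lr * std::sqrt(1 - std::pow(b2a, t)) / (1 - std::pow(b1a, t));
    vec step = corr * m / (sqrt(v) + eps);

    off = 0;
    auto take = [&](double* dst, const uword len) {
      for (uword i = 0; i < len; ++i) dst[i] -= step(off + i);
      off += len;
    };
    take(q.W1.memptr(), q.W1.n_elem); take(q.W2.memptr(), q.W2.n_elem);
    take(q.W3.memptr(), q.W3.n_elem); take(q.W4.memptr(), q.W4.n_elem);
    take(q.Wd.memptr(), q.Wd.n_elem); take(q.Wo.memptr(), q.Wo.n_elem);
    take(q.b1.memptr(), q.b1.n_elem); take(q.b2.memptr(), q.b2.n_elem);
    take(q.b3.memptr(), q.b3.n_elem); take(q.b4.memptr(), q.b4.n_elem);
    take(q.bd.memptr(), q.bd.n_elem);
    q.bo -= step(off);
  }

  return Rcpp::List::create(
      Rcpp::Named("params") = pack(q),
      Rcpp::Named("adam") = Rcpp::List::create(
          Rcpp::Named("m") = m, Rcpp::Named("v") = v, Rcpp::Named("t") = t),
      Rcpp::Named("loss") = loss_sum / n);
}
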