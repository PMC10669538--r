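// Convolutional primitives for the VGG-style autoencoder: im2col convolution
// with reflection padding, 2x2 max-pooling (ceil mode), nearest upsampling,
// plus the backward passes used by fixture training, and an 8-connected
// component labeller.  Layouts are column-major (H, W, C) cubes, matching R
// arrays; weight matrices are Cout x (k*k*Cin) with the kernel row index
// ordered di-fastest, then dj, then input channel.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace arma;
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect-101: -1 -> 1, n -> n-2 (n >= 2 assumed)
  if (i < 0) i = -i;
  if (i >= n) i = 2 * n - 2 - i;
  return i;
}

static mat im2col_reflect(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  const int R = k * k * C;
  mat X(R, (size_t)H * W);
  // fill each output column contiguously; rows ordered di-fastest, dj, c
  std::vector<int> ri(k), rj(k);
  for (int j = 0; j < W; ++j) {
    for (int dj = 0; dj < k; ++dj) rj[dj] = reflect_idx(j + dj - pad, W);
    for (int i = 0; i < H; ++i) {
      for (int di = 0; di < k; ++di) ri[di] = reflect_idx(i + di - pad, H);
      double* col = X.colptr((size_t)i + (size_t)j * H);
      for (int c = 0; c < C; ++c) {
        const mat& sl = x.slice(c);
        for (int dj = 0; dj < k; ++dj) {
          const double* src = sl.colptr(rj[dj]);
          for (int di = 0; di < k; ++di)
            col[(c * k + dj) * k + di] = src[ri[di]];
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::cube conv_fwd(const arma::cube& x, const arma::mat& Wm,
                    const arma::vec& b, int k, bool relu) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = Wm.n_rows;
  mat X = (k == 1) ? mat(x.memptr(), (size_t)H * W, x.n_slices).t()
                   : im2col_reflect(x, k);
  mat Y = Wm * X;          // Cout x HW
  Y.each_col() += b;
  if (relu) Y.transform([](double v) { return v > 0 ? v : 0.0; });
  cube out(H, W, Cout);
  mat Yt = Y.t();          // HW x Cout, contiguous per output channel
  std::memcpy(out.memptr(), Yt.memptr(), sizeof(double) * Yt.n_elem);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv_bwd(const arma::cube& x, const arma::mat& Wm,
                    const arma::cube& out, const arma::cube& gout,
                    int k, bool relu) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = Wm.n_rows;
  const int pad = (k - 1) / 2;
  mat X = (k == 1) ? mat(x.memptr(), (size_t)H * W, Cin).t()
                   : im2col_reflect(x, k);
  mat G(Cout, (size_t)H * W);
  for (int c = 0; c < Cout; ++c) {
    rowvec g = vectorise(gout.slice(c)).t();
    if (relu) {
      rowvec m = vectorise(out.slice(c)).t();
      g %= conv_to<rowvec>::from(m > 0);
    }
    G.row(c) = g;
  }
  mat gW = G * X.t();
  vec gb = sum(G, 1);
  mat GX = Wm.t() * G;     // (k*k*Cin) x HW
  cube gx(H, W, Cin, fill::zeros);
  if (k == 1) {
    for (int c = 0; c < Cin; ++c)
      gx.slice(c) = reshape(GX.row(c).t(), H, W);
  } else {
    for (int c = 0; c < Cin; ++c) {
      mat& gsl = gx.slice(c);
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          const int r = (c * k + dj) * k + di;
          for (int j = 0; j < W; ++j) {
            const int rj = reflect_idx(j + dj - pad, W);
            for (int i = 0; i < H; ++i) {
              const int ri = reflect_idx(i + di - pad, H);
              gsl(ri, rj) += GX(r, (size_t)i + (size_t)j * H);
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
Rcpp::List maxpool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  cube out(Ho, Wo, C);
  umat idx((size_t)Ho * Wo, C);   // linear (i + j*H) index of the max per window
  for (int c = 0; c < C; ++c) {
    const mat& sl = x.slice(c);
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double best = -datum::inf; uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          const int j = 2 * jo + dj; if (j >= W) continue;
          for (int di = 0; di < 2; ++di) {
            const int i = 2 * io + di; if (i >= H) continue;
            const double v = sl(i, j);
            if (v > best) { best = v; bi = (uword)i + (uword)j * H; }
          }
        }
        out(io, jo, c) = best;
        idx((size_t)io + (size_t)jo * Ho, c) = bi;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd(const arma::cube& gout, const arma::umat& idx,
                       int H, int W) {
  const int C = gout.n_slices;
  cube gx(H, W, C, fill::zeros);
  const int Ho = gout.n_rows, Wo = gout.n_cols;
  for (int c = 0; c < C; ++c) {
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        gx.slice(c)(idx((size_t)io + (size_t)jo * Ho, c)) += gout(io, jo, c);
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube upsample_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        out(i, j, c) = x(i / 2, j / 2, c);
  return out;
}

// [[Rcpp::export]]
arma::cube upsample_bwd(const arma::cube& gout) {
  const int H = gout.n_rows / 2, W = gout.n_cols / 2, C = gout.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i)
        gx(i / 2, j / 2, c) += gout(i, j, c);
  return gx;
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix label8(const Rcpp::LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second; q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
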