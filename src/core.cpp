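// Compiled primitives: im2col convolution (forward/backward), 2x2 max-pool,
// nearest-neighbour upsampling, priority-flood watershed and seeded region
// growing. All single-threaded and deterministic.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
#include <tuple>
using namespace Rcpp;

// im2col for 'same' zero-padded stride-1 convolution with odd kernel k.
// x: H x W x Cin cube -> (H*W) x (k*k*Cin) matrix, row-major over (row,col).
static arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  arma::mat cols(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int col = c * k * k + ki * k + kj;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + ki - p;
            if (si < 0 || si >= H) continue;
            cols(i + j * H, col) = x(si, sj, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
List conv2d_fwd(const arma::cube& x, const arma::mat& w, const arma::vec& b,
                int k) {
  arma::mat cols = im2col(x, k);
  arma::mat out = cols * w;           // (H*W) x Cout
  out.each_row() += b.t();
  arma::cube y(x.n_rows, x.n_cols, w.n_cols);
  std::memcpy(y.memptr(), out.memptr(), out.n_elem * sizeof(double));
  return List::create(_["out"] = y, _["cols"] = cols);
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& dy, const arma::mat& cols,
                const arma::mat& w, int k, int h, int wd, int cin) {
  arma::mat dy_m(const_cast<double*>(dy.memptr()), h * wd, w.n_cols, false);
  arma::mat dw = cols.t() * dy_m;
  arma::vec db = arma::sum(dy_m, 0).t();
  arma::mat dcols = dy_m * w.t();     // (H*W) x (k*k*Cin)
  // col2im scatter-add
  arma::cube dx(h, wd, cin, arma::fill::zeros);
  const int p = k / 2;
  for (int c = 0; c < cin; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int col = c * k * k + ki * k + kj;
        for (int j = 0; j < wd; ++j) {
          const int sj = j + kj - p;
          if (sj < 0 || sj >= wd) continue;
          for (int i = 0; i < h; ++i) {
            const int si = i + ki - p;
            if (si < 0 || si >= h) continue;
            dx(si, sj, c) += dcols(i + j * h, col);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  arma::cube y(H, W, C);
  arma::cube idx(H, W, C); // linear index into slice of argmax (stored as double)
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -1e300; double bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int r = 2 * i + di, cc = 2 * j + dj;
            const double v = x(r, cc, c);
            if (v > best) { best = v; bi = r + cc * x.n_rows; }
          }
        y(i, j, c) = best; idx(i, j, c) = bi;
      }
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& dy, const arma::cube& idx,
                        int h, int w) {
  arma::cube dx(h, w, dy.n_slices, arma::fill::zeros);
  for (unsigned c = 0; c < dy.n_slices; ++c)
    for (unsigned j = 0; j < dy.n_cols; ++j)
      for (unsigned i = 0; i < dy.n_rows; ++i)
        dx.slice(c)((arma::uword) idx(i, j, c)) += dy(i, j, c);
  return dx;
}

// [[Rcpp::export]]
arma::cube upsample2(const arma::cube& x) {
  arma::cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (unsigned c = 0; c < x.n_slices; ++c)
    for (unsigned j = 0; j < x.n_cols; ++j)
      for (unsigned i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, c);
        y(2*i, 2*j, c) = v; y(2*i+1, 2*j, c) = v;
        y(2*i, 2*j+1, c) = v; y(2*i+1, 2*j+1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& dy) {
  arma::cube dx(dy.n_rows / 2, dy.n_cols / 2, dy.n_slices);
  for (unsigned c = 0; c < dx.n_slices; ++c)
    for (unsigned j = 0; j < dx.n_cols; ++j)
      for (unsigned i = 0; i < dx.n_rows; ++i)
        dx(i, j, c) = dy(2*i, 2*j, c) + dy(2*i+1, 2*j, c) +
                      dy(2*i, 2*j+1, c) + dy(2*i+1, 2*j+1, c);
  return dx;
}

// Priority-flood from markers, ascending priority, 4-connectivity, restricted
// to mask. Ties resolved by insertion order (markers pushed row-major first),
// scan order), giving a deterministic result.
// [[Rcpp::export]]
IntegerMatrix watershed_flood(const NumericMatrix& priority,
                              const IntegerMatrix& markers,
                              const LogicalMatrix& mask) {
  const int H = priority.nrow(), W = priority.ncol();
  IntegerMatrix lab(H, W);
  typedef std::tuple<double, long, int, int> Item; // prio, order, r, c
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  long ord = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        pq.push(Item(priority(i, j), ord++, i, j));
      }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Item it = pq.top(); pq.pop();
    const int r = std::get<2>(it), c = std::get<3>(it);
    const int l = lab(r, c);
    for (int d = 0; d < 4; ++d) {
      const int nr = r + dr[d], nc = c + dc[d];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (!mask(nr, nc) || lab(nr, nc) != 0) continue;
      lab(nr, nc) = l;
      pq.push(Item(priority(nr, nc), ord++, nr, nc));
    }
  }
  return lab;
}

// Seeded region growing: each seed claims free pixels in order of Euclidean
// distance from its own seed scaled by a multiplicative cost field, up to a
// per-seed radius cap. 4-connected; deterministic (insertion-order ties).
// [[Rcpp::export]]
IntegerMatrix grow_regions(const IntegerVector& seed_r,
                           const IntegerVector& seed_c,
                           const LogicalMatrix& allowed,
                           const NumericVector& max_radius,
                           const NumericMatrix& cost) {
  const int H = allowed.nrow(), W = allowed.ncol(), n = seed_r.size();
  IntegerMatrix lab(H, W);
  typedef std::tuple<double, long, int, int, int> Item; // cost, ord, r, c, lab
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  long ord = 0;
  for (int s = 0; s < n; ++s) {
    const int r = seed_r[s], c = seed_c[s];
    if (r < 0 || r >= H || c < 0 || c >= W || !allowed(r, c)) continue;
    pq.push(Item(0.0, ord++, r, c, s + 1));
  }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Item it = pq.top(); pq.pop();
    const int r = std::get<2>(it), c = std::get<3>(it), l = std::get<4>(it);
    if (lab(r, c) != 0) continue;
    lab(r, c) = l;
    const double sr = seed_r[l - 1], sc = seed_c[l - 1];
    for (int d = 0; d < 4; ++d) {
      const int nr = r + dr[d], nc = c + dc[d];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (!allowed(nr, nc) || lab(nr, nc) != 0) continue;
      const double dist = std::sqrt((nr - sr) * (nr - sr) +
                                    (nc - sc) * (nc - sc));
      if (dist > max_radius[l - 1]) continue;
      pq.push(Item(dist * cost(nr, nc), ord++, nr, nc, l));
    }
  }
  return lab;
}
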