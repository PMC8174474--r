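// Stream-function / pressure network kernel.
//
// The surrogate is a fully-connected tanh network g(x, y, f, r) = (psi, p).
// The physics loss needs exact spatial derivatives of psi up to third order
// and of p up to first order, and the optimiser needs the gradient of the
// loss with respect to every weight and bias.  Both are computed here in
// closed form: the forward pass propagates ten "channels" per layer (the
// value and its partial derivatives in x and y up to order three) through
// the Faa di Bruno expansion of tanh, and the backward pass is the exact
// adjoint of that propagation.
//
// Channel order: 0 value, 1 d/dx, 2 d/dy, 3 xx, 4 xy, 5 yy,
//                6 xxx, 7 xxy, 8 xyy, 9 yyy.
//
// Channels are stacked row-wise into a (10 N) x width matrix so that each
// layer costs a single dgemm.  Inputs may be affinely rescaled for
// conditioning; the 1/scale factors enter through the seed values of the
// first-derivative channels, so all reported derivatives are with respect
// to the raw (mm) coordinates.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NCH = 10;

// The kernel churns through many MB-sized temporaries per evaluation; with
// glibc's default 128 KB mmap threshold every one becomes an mmap/munmap
// round trip.  Raising the threshold keeps freed blocks on the heap
// free-list, which is an order-of-magnitude win for full-batch training.
static void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 64 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 64 * 1024 * 1024);
    done = true;
  }
#endif
}

struct Net {
  std::vector<mat> W;
  std::vector<vec> b;
  int nlin;
};

static Net unpack(const vec& par, const ivec& sizes) {
  Net net;
  net.nlin = sizes.n_elem - 1;
  uword pos = 0;
  for (int l = 0; l < net.nlin; ++l) {
    uword nin = sizes[l], nout = sizes[l + 1];
    net.W.emplace_back(&par[pos], nout, nin);  // column-major copy
    pos += nout * nin;
    net.b.emplace_back(&par[pos], nout);
    pos += nout;
  }
  if (pos != par.n_elem) Rcpp::stop("parameter vector length mismatch");
  return net;
}

struct Cache {
  std::vector<mat> Ain;   // stacked input of each linear layer (moved in)
  std::vector<mat> Zs;    // stacked pre-activation per hidden layer
  std::vector<mat> T0s;   // tanh(Z value rows) per hidden layer
  mat O;                  // stacked output, (10 N) x 2
};

// Faa di Bruno propagation of the ten derivative channels through tanh,
// fused into one pass per column for memory locality.  Only tanh itself is
// stored for the backward pass; its higher derivatives are cheap algebra.
static void activate_channels(const mat& Z, mat& A, mat& T0, uword N) {
  const uword w = Z.n_cols;
  for (uword j = 0; j < w; ++j) {
    const double* z = Z.colptr(j);
    double* a = A.colptr(j);
    double* t0c = T0.colptr(j);
    for (uword i = 0; i < N; ++i) {
      const double z1 = z[N + i], z2 = z[2 * N + i], z3 = z[3 * N + i];
      const double z4 = z[4 * N + i], z5 = z[5 * N + i], z6 = z[6 * N + i];
      const double z7 = z[7 * N + i], z8 = z[8 * N + i], z9 = z[9 * N + i];
      const double t0 = std::tanh(z[i]);
      const double t1 = 1.0 - t0 * t0;
      const double t2 = -2.0 * t0 * t1;
      const double t3 = -2.0 * (t1 * t1 + t0 * t2);
      t0c[i] = t0;
      a[i] = t0;
      a[N + i] = t1 * z1;
      a[2 * N + i] = t1 * z2;
      a[3 * N + i] = t2 * z1 * z1 + t1 * z3;
      a[4 * N + i] = t2 * z1 * z2 + t1 * z4;
      a[5 * N + i] = t2 * z2 * z2 + t1 * z5;
      a[6 * N + i] = t3 * z1 * z1 * z1 + 3.0 * t2 * z1 * z3 + t1 * z6;
      a[7 * N + i] = t3 * z1 * z1 * z2 + t2 * (z3 * z2 + 2.0 * z1 * z4) + t1 * z7;
      a[8 * N + i] = t3 * z1 * z2 * z2 + t2 * (z5 * z1 + 2.0 * z2 * z4) + t1 * z8;
      a[9 * N + i] = t3 * z2 * z2 * z2 + 3.0 * t2 * z2 * z5 + t1 * z9;
    }
  }
}

// exact adjoint of activate_channels
static void activate_backward(const mat& Abar, const mat& Z, const mat& T0,
                              mat& Zbar, uword N) {
  const uword w = Z.n_cols;
  for (uword j = 0; j < w; ++j) {
    const double* ab = Abar.colptr(j);
    const double* z = Z.colptr(j);
    const double* t0c = T0.colptr(j);
    double* zb = Zbar.colptr(j);
    for (uword i = 0; i < N; ++i) {
      const double z1 = z[N + i], z2 = z[2 * N + i], z3 = z[3 * N + i];
      const double z4 = z[4 * N + i], z5 = z[5 * N + i], z6 = z[6 * N + i];
      const double z7 = z[7 * N + i], z8 = z[8 * N + i], z9 = z[9 * N + i];
      const double t0 = t0c[i];
      const double t1 = 1.0 - t0 * t0;
      const double t2 = -2.0 * t0 * t1;
      const double t3 = -2.0 * (t1 * t1 + t0 * t2);
      const double t4 = -2.0 * (3.0 * t1 * t2 + t0 * t3);
      const double a0 = ab[i], a1 = ab[N + i], a2 = ab[2 * N + i];
      const double a3 = ab[3 * N + i], a4 = ab[4 * N + i], a5 = ab[5 * N + i];
      const double a6 = ab[6 * N + i], a7 = ab[7 * N + i], a8 = ab[8 * N + i];
      const double a9 = ab[9 * N + i];

      zb[9 * N + i] = a9 * t1;
      zb[8 * N + i] = a8 * t1;
      zb[7 * N + i] = a7 * t1;
      zb[6 * N + i] = a6 * t1;
      zb[5 * N + i] = a5 * t1 + a9 * 3.0 * t2 * z2 + a8 * t2 * z1;
      zb[4 * N + i] = a4 * t1 + a7 * 2.0 * t2 * z1 + a8 * 2.0 * t2 * z2;
      zb[3 * N + i] = a3 * t1 + a6 * 3.0 * t2 * z1 + a7 * t2 * z2;
      zb[2 * N + i] = a2 * t1 + a4 * t2 * z1 + a5 * 2.0 * t2 * z2
        + a7 * (t3 * z1 * z1 + t2 * z3)
        + a8 * (2.0 * t3 * z1 * z2 + 2.0 * t2 * z4)
        + a9 * (3.0 * t3 * z2 * z2 + 3.0 * t2 * z5);
      zb[N + i] = a1 * t1 + a3 * 2.0 * t2 * z1 + a4 * t2 * z2
        + a6 * (3.0 * t3 * z1 * z1 + 3.0 * t2 * z3)
        + a7 * (2.0 * t3 * z1 * z2 + 2.0 * t2 * z4)
        + a8 * (t3 * z2 * z2 + t2 * z5);
      zb[i] = a0 * t1 + a1 * t2 * z1 + a2 * t2 * z2
        + a3 * (t3 * z1 * z1 + t2 * z3)
        + a4 * (t3 * z1 * z2 + t2 * z4)
        + a5 * (t3 * z2 * z2 + t2 * z5)
        + a6 * (t4 * z1 * z1 * z1 + 3.0 * t3 * z1 * z3 + t2 * z6)
        + a7 * (t4 * z1 * z1 * z2 + t3 * (z3 * z2 + 2.0 * z1 * z4) + t2 * z7)
        + a8 * (t4 * z1 * z2 * z2 + t3 * (z5 * z1 + 2.0 * z2 * z4) + t2 * z8)
        + a9 * (t4 * z2 * z2 * z2 + 3.0 * t3 * z2 * z5 + t2 * z9);
    }
  }
}

static void forward(const Net& net, const mat& X,
                    const vec& shift, const vec& scale,
                    const vec& out_scale, Cache& cc) {
  const uword N = X.n_rows;
  const uword nin = X.n_cols;
  mat A(NCH * N, nin, fill::zeros);
  for (uword c = 0; c < nin; ++c)
    A.col(c).subvec(0, N - 1) = (X.col(c) - shift[c]) / scale[c];
  A.col(0).subvec(N, 2 * N - 1).fill(1.0 / scale[0]);      // d/dx seed
  A.col(1).subvec(2 * N, 3 * N - 1).fill(1.0 / scale[1]);  // d/dy seed

  for (int l = 0; l < net.nlin; ++l) {
    mat Z = A * net.W[l].t();
    Z.rows(0, N - 1).each_row() += net.b[l].t();
    cc.Ain.push_back(std::move(A));
    if (l == net.nlin - 1) {
      cc.O = std::move(Z);
      for (uword c = 0; c < cc.O.n_cols; ++c) cc.O.col(c) *= out_scale[c];
      return;
    }
    const uword w = Z.n_cols;
    A.set_size(NCH * N, w);
    mat T0(N, w);
    activate_channels(Z, A, T0, N);
    cc.Zs.push_back(std::move(Z));
    cc.T0s.push_back(std::move(T0));
  }
}

// adjoint of the forward pass; Obar is (10 N) x n_out
static vec backward(const Net& net, const Cache& cc, const mat& Obar_scaled,
                    const vec& out_scale, const ivec& sizes) {
  const uword N = Obar_scaled.n_rows / NCH;
  std::vector<mat> gW(net.nlin);
  std::vector<rowvec> gb(net.nlin);

  mat Obar = Obar_scaled;
  for (uword c = 0; c < Obar.n_cols; ++c) Obar.col(c) *= out_scale[c];

  int l = net.nlin - 1;
  gW[l] = Obar.t() * cc.Ain[l];
  gb[l] = sum(Obar.rows(0, N - 1), 0);
  mat Abar = Obar * net.W[l];

  for (l = net.nlin - 2; l >= 0; --l) {
    mat Zbar(NCH * N, cc.Zs[l].n_cols);
    activate_backward(Abar, cc.Zs[l], cc.T0s[l], Zbar, N);
    gW[l] = Zbar.t() * cc.Ain[l];
    gb[l] = sum(Zbar.rows(0, N - 1), 0);
    if (l > 0) Abar = Zbar * net.W[l];
  }

  uword npar = 0;
  for (int k = 0; k < net.nlin; ++k)
    npar += (uword)sizes[k] * sizes[k + 1] + sizes[k + 1];
  vec g(npar);
  uword pos = 0;
  for (int k = 0; k < net.nlin; ++k) {
    g.subvec(pos, pos + gW[k].n_elem - 1) = vectorise(gW[k]);
    pos += gW[k].n_elem;
    g.subvec(pos, pos + gb[k].n_elem - 1) = gb[k].t();
    pos += gb[k].n_elem;
  }
  return g;
}

struct Fields {
  vec psi, p, u, v, ux, uy, vx, vy, px, py, r1, r2;
};

static Fields head_fields(const mat& O, uword N, double rho, double mu) {
  Fields F;
  F.psi = O.col(0).subvec(0, N - 1);
  vec psix = O.col(0).subvec(N, 2 * N - 1);
  vec psiy = O.col(0).subvec(2 * N, 3 * N - 1);
  vec psixx = O.col(0).subvec(3 * N, 4 * N - 1);
  vec psixy = O.col(0).subvec(4 * N, 5 * N - 1);
  vec psiyy = O.col(0).subvec(5 * N, 6 * N - 1);
  vec psixxx = O.col(0).subvec(6 * N, 7 * N - 1);
  vec psixxy = O.col(0).subvec(7 * N, 8 * N - 1);
  vec psixyy = O.col(0).subvec(8 * N, 9 * N - 1);
  vec psiyyy = O.col(0).subvec(9 * N, 10 * N - 1);
  F.p = O.col(1).subvec(0, N - 1);
  F.px = O.col(1).subvec(N, 2 * N - 1);
  F.py = O.col(1).subvec(2 * N, 3 * N - 1);

  F.u = psiy;          F.v = -psix;
  F.ux = psixy;        F.uy = psiyy;
  F.vx = -psixx;       F.vy = -psixy;
  vec lap_u = psixxy + psiyyy;
  vec lap_v = -(psixxx + psixyy);
  F.r1 = rho * (F.u % F.ux + F.v % F.uy) + F.px - mu * lap_u;
  F.r2 = rho * (F.u % F.vx + F.v % F.vy) + F.py - mu * lap_v;
  return F;
}

// [[Rcpp::export]]
arma::mat pinn_fields_cpp(const arma::vec& par, const arma::ivec& sizes,
                          const arma::mat& X, const arma::vec& shift,
                          const arma::vec& scale, const arma::vec& out_scale,
                          double rho, double mu) {
  tune_allocator();
  Net net = unpack(par, sizes);
  Cache cc;
  forward(net, X, shift, scale, out_scale, cc);
  Fields F = head_fields(cc.O, X.n_rows, rho, mu);
  mat out(X.n_rows, 6);
  out.col(0) = F.psi; out.col(1) = F.p;
  out.col(2) = F.u;   out.col(3) = F.v;
  out.col(4) = F.r1;  out.col(5) = F.r2;
  return out;
}

// [[Rcpp::export]]
Rcpp::List pinn_channels_cpp(const arma::vec& par, const arma::ivec& sizes,
                             const arma::mat& X, const arma::vec& shift,
                             const arma::vec& scale,
                             const arma::vec& out_scale) {
  tune_allocator();
  Net net = unpack(par, sizes);
  Cache cc;
  forward(net, X, shift, scale, out_scale, cc);
  const uword N = X.n_rows;
  mat psi(N, NCH), p(N, NCH);
  for (int c = 0; c < NCH; ++c) {
    psi.col(c) = cc.O.col(0).subvec(c * N, (c + 1) * N - 1);
    p.col(c) = cc.O.col(1).subvec(c * N, (c + 1) * N - 1);
  }
  return Rcpp::List::create(Rcpp::Named("psi") = psi, Rcpp::Named("p") = p);
}

// Weighted four-component loss and (optionally) its parameter gradient.
// Row masks select which points contribute to which component: wu rows
// carry velocity data U, wns rows the PDE residual, wbc rows the boundary
// target Gbc, wp rows the reference pressure pref.  Components are
// unnormalised sums of squares; the total is their alpha-weighted sum.
// [[Rcpp::export]]
Rcpp::List pinn_loss_cpp(const arma::vec& par, const arma::ivec& sizes,
                         const arma::mat& X, const arma::vec& shift,
                         const arma::vec& scale, const arma::vec& out_scale,
                         const arma::mat& U,
                         const arma::mat& Gbc, const arma::vec& pref,
                         const arma::vec& wu, const arma::vec& wns,
                         const arma::vec& wbc, const arma::vec& wp,
                         const arma::vec& alpha, double rho, double mu,
                         bool want_grad) {
  tune_allocator();
  Net net = unpack(par, sizes);
  Cache cc;
  forward(net, X, shift, scale, out_scale, cc);
  const uword N = X.n_rows;
  Fields F = head_fields(cc.O, N, rho, mu);

  vec eu1 = F.u - U.col(0), eu2 = F.v - U.col(1);
  vec eb1 = F.u - Gbc.col(0), eb2 = F.v - Gbc.col(1);
  vec ep = F.p - pref;
  double lu = accu(wu % (square(eu1) + square(eu2)));
  double lns = accu(wns % (square(F.r1) + square(F.r2)));
  double lbc = accu(wbc % (square(eb1) + square(eb2)));
  double lp = accu(wp % square(ep));
  double total = alpha[0] * lu + alpha[1] * lns + alpha[2] * lp + alpha[3] * lbc;

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("total") = total,
    Rcpp::Named("lu") = lu, Rcpp::Named("lns") = lns,
    Rcpp::Named("lp") = lp, Rcpp::Named("lbc") = lbc);
  if (!want_grad) return out;

  // adjoints of the head quantities
  vec r1b = 2.0 * alpha[1] * (wns % F.r1);
  vec r2b = 2.0 * alpha[1] * (wns % F.r2);
  vec du = 2.0 * alpha[0] * (wu % eu1) + 2.0 * alpha[3] * (wbc % eb1)
         + rho * (r1b % F.ux + r2b % F.vx);
  vec dv = 2.0 * alpha[0] * (wu % eu2) + 2.0 * alpha[3] * (wbc % eb2)
         + rho * (r1b % F.uy + r2b % F.vy);
  vec dux = rho * (r1b % F.u), duy = rho * (r1b % F.v);
  vec dvx = rho * (r2b % F.u), dvy = rho * (r2b % F.v);
  vec dp = 2.0 * alpha[2] * (wp % ep);

  mat Obar(NCH * N, 2, fill::zeros);
  // psi channels: u = psi_y, v = -psi_x and their derivatives
  Obar.col(0).subvec(N, 2 * N - 1) = -dv;                // psi_x
  Obar.col(0).subvec(2 * N, 3 * N - 1) = du;             // psi_y
  Obar.col(0).subvec(3 * N, 4 * N - 1) = -dvx;           // psi_xx
  Obar.col(0).subvec(4 * N, 5 * N - 1) = dux - dvy;      // psi_xy
  Obar.col(0).subvec(5 * N, 6 * N - 1) = duy;            // psi_yy
  Obar.col(0).subvec(6 * N, 7 * N - 1) = mu * r2b;       // psi_xxx
  Obar.col(0).subvec(7 * N, 8 * N - 1) = -mu * r1b;      // psi_xxy
  Obar.col(0).subvec(8 * N, 9 * N - 1) = mu * r2b;       // psi_xyy
  Obar.col(0).subvec(9 * N, 10 * N - 1) = -mu * r1b;     // psi_yyy
  // pressure channels
  Obar.col(1).subvec(0, N - 1) = dp;
  Obar.col(1).subvec(N, 2 * N - 1) = r1b;
  Obar.col(1).subvec(2 * N, 3 * N - 1) = r2b;

  out["grad"] = backward(net, cc, Obar, out_scale, sizes);
  return out;
}
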