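// Compact convolutional backbone for virtual-channel EEG decoding.
//
// Layer stack (input [B, 1, D, T]):
//   input batch-norm -> zero-pad (kt/2, kt/2-1) -> temporal conv (1 x kt) to F1
//   -> BN -> depthwise conv (D x 1, groups F1, multiplier 2) -> BN, ELU,
//   avg-pool (1 x p1), dropout -> zero-pad (ks/2-1, ks/2) -> depthwise temporal
//   conv (1 x ks, groups F2) -> pointwise (1 x 1) -> BN, ELU, avg-pool (1 x p2),
//   dropout -> channel attention (concat[GAP,GMP] 2F2 -> F2 -> F2/2 -> F2,
//   sigmoid gate) -> flatten -> dense hidden (no bias) + BN + ReLU + dropout
//   -> dense K.
//
// Convolutions and the pre-BN dense layer carry no bias (BN absorbs it).
// Activations are stored time-major (time runs down the rows, feature maps
// across the columns) so the temporal convolution reduces to one GEMM per
// trial over a contiguous im2col matrix. Forward/backward are hand-derived;
// Adam with bias correction. All randomness (init, dropout, shuffling)
// comes from an internal 64-bit generator so runs reproduce given a seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <string>

using namespace arma;

namespace {

struct Param {
  mat w, g, m, v;
  void init(uword r, uword c) {
    w.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};

// xorshift generator: identical streams across platforms
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t x = s;
    x ^= x << 13; x ^= x >> 7; x ^= x << 17;
    s = x;
    return x;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double unif(double lo, double hi) { return lo + (hi - lo) * unif(); }
};

const double BN_EPS = 1e-5;
const double BN_MOM = 0.1;

class Net {
public:
  // architecture
  int D, T, K, F1, mult, F2, kt, ks, p1, p2, hidden;
  double drop;
  int T1, T2, flat;
  int lpad1, lpad2;

  // parameters (W1 is kernel x maps; W2 rows are output maps)
  Param bn0g, bn0b, W1, bn1g, bn1b, W2, bn2g, bn2b,
        W3, W4, bn3g, bn3b, A1, a1b, A2, a2b, A3, a3b,
        W5, bn4g, bn4b, W6, b6;
  vec r0m, r0v, r1m, r1v, r2m, r2v, r3m, r3v, r4m, r4v;  // running stats

  RNG rng;
  int adam_t;

  // caches (populated by forward, consumed by backward); input is (T, D, B)
  bool cache_train;
  int B;
  cube xhat0;            // (T, D, B)
  double sd0;
  cube xhat1;            // (D*T, F1, B)  position-major rows, maps as cols
  vec sd1;
  cube xhat2, e2;        // (T, F2, B)
  vec sd2;
  cube q1, mask1;        // (T1, F2, B)
  cube z3;               // (T1, F2, B)
  cube xhat3, e3;        // (T1, F2, B)
  vec sd3;
  cube q2, mask2;        // (T2, F2, B)
  mat att_avg, att_mx, att_h1, att_h2, att_g;
  umat att_ix;
  mat fl;                // (flat, B), flat index = c*T2 + t
  mat xhat4, r4, mask3, rd;
  vec sd4;
  mat logits;

  Net(int D_, int T_, int K_, int F1_, int mult_, int kt_, int ks_,
      int p1_, int p2_, double drop_, int hidden_, uint64_t seed)
    : D(D_), T(T_), K(K_), F1(F1_), mult(mult_), F2(F1_ * mult_),
      kt(kt_), ks(ks_), p1(p1_), p2(p2_), hidden(hidden_), drop(drop_),
      rng(seed), adam_t(0), cache_train(false), B(0) {
    if (T < kt) Rcpp::stop("input length T (%d) must be >= temporal kernel (%d)", T, kt);
    T1 = T / p1;
    T2 = T1 / p2;
    if (T2 < 1) Rcpp::stop("input too short after pooling (T=%d)", T);
    flat = F2 * T2;
    lpad1 = kt / 2;            // (32, 31) for kt = 64
    lpad2 = ks / 2 - 1;        // (7, 8)  for ks = 16
    if (lpad2 < 0) lpad2 = 0;

    bn0g.init(1, 1); bn0b.init(1, 1);
    W1.init(kt, F1);
    bn1g.init(F1, 1); bn1b.init(F1, 1);
    W2.init(F2, D);
    bn2g.init(F2, 1); bn2b.init(F2, 1);
    W3.init(F2, ks);
    W4.init(F2, F2);
    bn3g.init(F2, 1); bn3b.init(F2, 1);
    int ah = F2, ah2 = std::max(1, F2 / 2);
    A1.init(ah, 2 * F2);  a1b.init(ah, 1);
    A2.init(ah2, ah);     a2b.init(ah2, 1);
    A3.init(F2, ah2);     a3b.init(F2, 1);
    W5.init(hidden, flat);
    bn4g.init(hidden, 1); bn4b.init(hidden, 1);
    W6.init(K, hidden);   b6.init(K, 1);

    r0m.zeros(1); r0v.ones(1);
    r1m.zeros(F1); r1v.ones(F1);
    r2m.zeros(F2); r2v.ones(F2);
    r3m.zeros(F2); r3v.ones(F2);
    r4m.zeros(hidden); r4v.ones(hidden);

    init_weights();
  }

  std::vector<Param*> params() {
    return { &bn0g, &bn0b, &W1, &bn1g, &bn1b, &W2, &bn2g, &bn2b,
             &W3, &W4, &bn3g, &bn3b, &A1, &a1b, &A2, &a2b, &A3, &a3b,
             &W5, &bn4g, &bn4b, &W6, &b6 };
  }
  std::vector<std::string> param_names() const {
    return { "bn0g", "bn0b", "W1", "bn1g", "bn1b", "W2", "bn2g", "bn2b",
             "W3", "W4", "bn3g", "bn3b", "A1", "a1b", "A2", "a2b", "A3", "a3b",
             "W5", "bn4g", "bn4b", "W6", "b6" };
  }

  void fill_unif(mat& w, double bound) {
    for (uword i = 0; i < w.n_elem; ++i) w(i) = rng.unif(-bound, bound);
  }

  void init_weights() {
    // fan-in uniform for weights, zeros for biases, BN scale 1 shift 0
    fill_unif(W1.w, 1.0 / std::sqrt((double)kt));
    fill_unif(W2.w, 1.0 / std::sqrt((double)D));
    fill_unif(W3.w, 1.0 / std::sqrt((double)ks));
    fill_unif(W4.w, 1.0 / std::sqrt((double)F2));
    fill_unif(A1.w, 1.0 / std::sqrt((double)(2 * F2)));
    fill_unif(A2.w, 1.0 / std::sqrt((double)A2.w.n_cols));
    fill_unif(A3.w, 1.0 / std::sqrt((double)A3.w.n_cols));
    fill_unif(W5.w, 1.0 / std::sqrt((double)flat));
    fill_unif(W6.w, 1.0 / std::sqrt((double)hidden));
    bn0g.w.ones(); bn1g.w.ones(); bn2g.w.ones(); bn3g.w.ones(); bn4g.w.ones();
    bn0b.w.zeros(); bn1b.w.zeros(); bn2b.w.zeros(); bn3b.w.zeros(); bn4b.w.zeros();
    a1b.w.zeros(); a2b.w.zeros(); a3b.w.zeros(); b6.w.zeros();
  }

  double n_parameters() {
    double n = 0;
    for (Param* p : params()) n += (double)p->w.n_elem;
    return n;
  }

  static double elu_deriv(double e) { return e > 0 ? 1.0 : e + 1.0; }

  // contiguous im2col: IC is (D*T, kt); rows d*T + t, column k holds
  // xpad(t + k, d) where xpad is the (T + kt - 1, D) zero-padded trial
  void im2col1(const mat& xpad, mat& IC) const {
    for (int d = 0; d < D; ++d) {
      const double* src = xpad.colptr(d);
      for (int k = 0; k < kt; ++k) {
        std::memcpy(IC.colptr(k) + (size_t)d * T, src + k, sizeof(double) * T);
      }
    }
  }

  // BN with statistics per column across all slices of a cube (train mode)
  // or from running stats (eval). Normalizes x in place to xhat.
  void bn_cols_forward(cube& x, vec& rm, vec& rv, vec& sd, bool train) {
    int F = (int)x.n_cols;
    double n = (double)(x.n_rows * x.n_slices);
    sd.set_size(F);
    for (int f = 0; f < F; ++f) {
      double m_, v_;
      if (train) {
        double s = 0, s2 = 0;
        for (uword b = 0; b < x.n_slices; ++b) {
          const vec c = x.slice(b).col(f);
          s += accu(c); s2 += dot(c, c);
        }
        m_ = s / n; v_ = s2 / n - m_ * m_;
        if (v_ < 0) v_ = 0;
        rm(f) = (1 - BN_MOM) * rm(f) + BN_MOM * m_;
        rv(f) = (1 - BN_MOM) * rv(f) + BN_MOM * v_ * n / std::max(1.0, n - 1);
      } else { m_ = rm(f); v_ = rv(f); }
      sd(f) = std::sqrt(v_ + BN_EPS);
      for (uword b = 0; b < x.n_slices; ++b)
        x.slice(b).col(f) = (x.slice(b).col(f) - m_) / sd(f);
    }
  }

  // backward through per-column BN; dy is transformed in place into dx
  void bn_cols_backward(cube& dy, const cube& xhat, Param& g, Param& b,
                        const vec& sd, bool train) {
    int F = (int)dy.n_cols;
    double n = (double)(dy.n_rows * dy.n_slices);
    for (int f = 0; f < F; ++f) {
      double gf = g.w(f);
      double sy = 0, syx = 0;
      for (uword bb = 0; bb < dy.n_slices; ++bb) {
        sy += accu(dy.slice(bb).col(f));
        syx += dot(dy.slice(bb).col(f), xhat.slice(bb).col(f));
      }
      g.g(f) += syx; b.g(f) += sy;
      if (train) {
        double s1 = gf * sy, s2 = gf * syx;
        for (uword bb = 0; bb < dy.n_slices; ++bb)
          dy.slice(bb).col(f) =
            (dy.slice(bb).col(f) * gf -
             (s1 + xhat.slice(bb).col(f) * s2) / n) / sd(f);
      } else {
        for (uword bb = 0; bb < dy.n_slices; ++bb)
          dy.slice(bb).col(f) *= gf / sd(f);
      }
    }
  }

  void fill_mask(cube& m, bool train) {
    if (train && drop > 0) {
      double keep = 1 - drop;
      for (uword i = 0; i < m.n_elem; ++i)
        m(i) = rng.unif() < keep ? 1.0 / keep : 0.0;
    } else m.ones();
  }

  // ------------------------------------------------------------------ forward
  // X: (T, D, B) -- time down the rows, channels across the columns
  void forward(const cube& X, bool train) {
    B = (int)X.n_slices;
    cache_train = train;

    // input BN (one feature map)
    double mu, var;
    if (train) {
      double n = (double)X.n_elem;
      mu = accu(X) / n;
      var = accu(square(X - mu)) / n;
      r0m(0) = (1 - BN_MOM) * r0m(0) + BN_MOM * mu;
      r0v(0) = (1 - BN_MOM) * r0v(0) + BN_MOM * var * n / std::max(1.0, n - 1);
    } else { mu = r0m(0); var = r0v(0); }
    sd0 = std::sqrt(var + BN_EPS);
    xhat0 = (X - mu) / sd0;
    double g0 = bn0g.w(0), b0 = bn0b.w(0);

    // temporal convolution via one GEMM per trial
    cube c1((uword)D * T, F1, B);
    {
      mat xpad(T + kt - 1, D);
      mat IC((uword)D * T, kt);
      for (int b = 0; b < B; ++b) {
        xpad.zeros();
        xpad.rows(lpad1, lpad1 + T - 1) = g0 * xhat0.slice(b) + b0;
        im2col1(xpad, IC);
        c1.slice(b) = IC * W1.w;               // (D*T, F1)
      }
    }

    bn_cols_forward(c1, r1m, r1v, sd1, train);
    xhat1 = std::move(c1);

    // depthwise convolution over the virtual-channel axis
    cube z2(T, F2, B);
    for (int b = 0; b < B; ++b) {
      for (int f = 0; f < F1; ++f) {
        mat Yf(xhat1.slice(b).colptr(f), T, D);  // copy view of column f
        Yf = bn1g.w(f) * Yf + bn1b.w(f);
        z2.slice(b).cols(f * mult, f * mult + mult - 1) =
          Yf * W2.w.rows(f * mult, f * mult + mult - 1).t();
      }
    }

    bn_cols_forward(z2, r2m, r2v, sd2, train);
    xhat2 = z2;
    e2 = z2;
    for (int f = 0; f < F2; ++f) {
      double gf = bn2g.w(f), bf = bn2b.w(f);
      for (int b = 0; b < B; ++b)
        e2.slice(b).col(f) = gf * xhat2.slice(b).col(f) + bf;
    }
    e2.transform([](double y) { return y > 0 ? y : std::expm1(y); });

    // avg-pool p1 + dropout
    cube P1(T1, F2, B);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F2; ++f) {
        const double* src = e2.slice(b).colptr(f);
        double* dst = P1.slice(b).colptr(f);
        for (int t = 0; t < T1; ++t) {
          double s = 0;
          for (int j = 0; j < p1; ++j) s += src[t * p1 + j];
          dst[t] = s / p1;
        }
      }
    mask1.set_size(T1, F2, B);
    fill_mask(mask1, train);
    q1 = P1 % mask1;

    // separable convolution: depthwise temporal, then pointwise
    z3.set_size(T1, F2, B);
    {
      vec padc(T1 + ks - 1);
      for (int b = 0; b < B; ++b) {
        for (int c = 0; c < F2; ++c) {
          padc.zeros();
          padc.subvec(lpad2, lpad2 + T1 - 1) = q1.slice(b).col(c);
          double* dst = z3.slice(b).colptr(c);
          const double* src = padc.memptr();
          for (int t = 0; t < T1; ++t) {
            double s = 0;
            for (int k = 0; k < ks; ++k) s += W3.w(c, k) * src[t + k];
            dst[t] = s;
          }
        }
      }
    }
    cube z4(T1, F2, B);
    for (int b = 0; b < B; ++b) z4.slice(b) = z3.slice(b) * W4.w.t();

    bn_cols_forward(z4, r3m, r3v, sd3, train);
    xhat3 = z4;
    e3 = z4;
    for (int f = 0; f < F2; ++f) {
      double gf = bn3g.w(f), bf = bn3b.w(f);
      for (int b = 0; b < B; ++b)
        e3.slice(b).col(f) = gf * xhat3.slice(b).col(f) + bf;
    }
    e3.transform([](double y) { return y > 0 ? y : std::expm1(y); });

    cube P2(T2, F2, B);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F2; ++f) {
        const double* src = e3.slice(b).colptr(f);
        double* dst = P2.slice(b).colptr(f);
        for (int t = 0; t < T2; ++t) {
          double s = 0;
          for (int j = 0; j < p2; ++j) s += src[t * p2 + j];
          dst[t] = s / p2;
        }
      }
    mask2.set_size(T2, F2, B);
    fill_mask(mask2, train);
    q2 = P2 % mask2;

    // channel attention
    att_avg.set_size(F2, B); att_mx.set_size(F2, B); att_ix.set_size(F2, B);
    for (int b = 0; b < B; ++b) {
      att_avg.col(b) = mean(q2.slice(b), 0).t();
      for (int c = 0; c < F2; ++c) {
        uword ix; att_mx(c, b) = q2.slice(b).col(c).max(ix); att_ix(c, b) = ix;
      }
    }
    mat z = join_cols(att_avg, att_mx);
    att_h1 = A1.w * z; att_h1.each_col() += a1b.w.col(0);
    att_h1.transform([](double x) { return x > 0 ? x : 0.0; });
    att_h2 = A2.w * att_h1; att_h2.each_col() += a2b.w.col(0);
    att_h2.transform([](double x) { return x > 0 ? x : 0.0; });
    att_g = A3.w * att_h2; att_g.each_col() += a3b.w.col(0);
    att_g.transform([](double x) { return 1.0 / (1.0 + std::exp(-x)); });

    fl.set_size(flat, B);
    for (int b = 0; b < B; ++b) {
      mat G = q2.slice(b);
      G.each_row() %= att_g.col(b).t();
      fl.col(b) = vectorise(G);               // index c*T2 + t
    }

    // classifier head
    mat u = W5.w * fl;
    sd4.set_size(hidden);
    xhat4.set_size(hidden, B);
    for (int f = 0; f < hidden; ++f) {
      double m_, v_;
      if (train) {
        m_ = mean(u.row(f)); v_ = mean(square(u.row(f) - m_));
        r4m(f) = (1 - BN_MOM) * r4m(f) + BN_MOM * m_;
        r4v(f) = (1 - BN_MOM) * r4v(f) + BN_MOM * v_ * B / std::max(1.0, (double)B - 1);
      } else { m_ = r4m(f); v_ = r4v(f); }
      sd4(f) = std::sqrt(v_ + BN_EPS);
      xhat4.row(f) = (u.row(f) - m_) / sd4(f);
    }
    r4 = xhat4;
    r4.each_col() %= bn4g.w.col(0);
    r4.each_col() += bn4b.w.col(0);
    r4.transform([](double x) { return x > 0 ? x : 0.0; });
    mask3.set_size(hidden, B);
    if (cache_train && drop > 0) {
      double keep = 1 - drop;
      for (uword i = 0; i < mask3.n_elem; ++i)
        mask3(i) = rng.unif() < keep ? 1.0 / keep : 0.0;
    } else mask3.ones();
    rd = r4 % mask3;
    logits = W6.w * rd;
    logits.each_col() += b6.w.col(0);
  }

  // ----------------------------------------------------------------- backward
  // dlogits: (K, B). Returns d(input) as (T, D, B) when want_dx.
  cube backward(const mat& dlogits, bool want_dx) {
    bool train = cache_train;

    W6.g += dlogits * rd.t();
    b6.g += sum(dlogits, 1);
    mat drd = W6.w.t() * dlogits;
    mat dr4 = drd % mask3;
    for (uword i = 0; i < dr4.n_elem; ++i) if (r4(i) <= 0) dr4(i) = 0;
    mat du(hidden, B);
    for (int f = 0; f < hidden; ++f) {
      double gf = bn4g.w(f);
      double sy = accu(dr4.row(f)), syx = accu(dr4.row(f) % xhat4.row(f));
      bn4g.g(f) += syx; bn4b.g(f) += sy;
      if (train)
        du.row(f) = (dr4.row(f) * gf - (gf * sy + xhat4.row(f) * (gf * syx)) / B) / sd4(f);
      else
        du.row(f) = dr4.row(f) * gf / sd4(f);
    }
    W5.g += du * fl.t();
    mat dfl = W5.w.t() * du;

    // attention backward
    cube dq2(T2, F2, B);
    mat dz_att(2 * F2, B);
    for (int b = 0; b < B; ++b) {
      mat dG(dfl.colptr(b), T2, F2);           // copy
      vec dgate(F2);
      for (int c = 0; c < F2; ++c)
        dgate(c) = dot(dG.col(c), q2.slice(b).col(c));
      dG.each_row() %= att_g.col(b).t();
      dq2.slice(b) = dG;
      vec ds = dgate % att_g.col(b) % (1 - att_g.col(b));
      A3.g += ds * att_h2.col(b).t();
      a3b.g += ds;
      vec dh2 = A3.w.t() * ds;
      for (uword i = 0; i < dh2.n_elem; ++i) if (att_h2(i, b) <= 0) dh2(i) = 0;
      A2.g += dh2 * att_h1.col(b).t();
      a2b.g += dh2;
      vec dh1 = A2.w.t() * dh2;
      for (uword i = 0; i < dh1.n_elem; ++i) if (att_h1(i, b) <= 0) dh1(i) = 0;
      A1.g += dh1 * join_cols(att_avg.col(b), att_mx.col(b)).t();
      a1b.g += dh1;
      dz_att.col(b) = A1.w.t() * dh1;
    }
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < F2; ++c) {
        dq2.slice(b).col(c) += dz_att(c, b) / T2;            // GAP path
        dq2.slice(b)(att_ix(c, b), c) += dz_att(F2 + c, b);  // GMP path
      }

    // dropout 2, pool 2, ELU, BN3
    cube dp2 = dq2 % mask2;
    cube de3(T1, F2, B, fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F2; ++f) {
        const double* src = dp2.slice(b).colptr(f);
        double* dst = de3.slice(b).colptr(f);
        for (int t = 0; t < T2; ++t)
          for (int j = 0; j < p2; ++j) dst[t * p2 + j] = src[t] / p2;
      }
    for (uword i = 0; i < de3.n_elem; ++i) de3(i) *= elu_deriv(e3(i));
    bn_cols_backward(de3, xhat3, bn3g, bn3b, sd3, train);   // -> dz4

    // pointwise + depthwise temporal conv backward
    cube dq1(T1, F2, B);
    {
      vec padc(T1 + ks - 1), dpadc(T1 + ks - 1);
      for (int b = 0; b < B; ++b) {
        W4.g += de3.slice(b).t() * z3.slice(b);
        mat dz3 = de3.slice(b) * W4.w;          // (T1, F2)
        for (int c = 0; c < F2; ++c) {
          padc.zeros();
          padc.subvec(lpad2, lpad2 + T1 - 1) = q1.slice(b).col(c);
          dpadc.zeros();
          const double* pc = padc.memptr();
          double* dpc = dpadc.memptr();
          const double* d3 = dz3.colptr(c);
          for (int k = 0; k < ks; ++k) {
            double acc = 0, wk = W3.w(c, k);
            for (int t = 0; t < T1; ++t) {
              acc += d3[t] * pc[t + k];
              dpc[t + k] += wk * d3[t];
            }
            W3.g(c, k) += acc;
          }
          dq1.slice(b).col(c) = dpadc.subvec(lpad2, lpad2 + T1 - 1);
        }
      }
    }

    // dropout 1, pool 1, ELU, BN2
    cube dp1 = dq1 % mask1;
    cube de2(T, F2, B, fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F2; ++f) {
        const double* src = dp1.slice(b).colptr(f);
        double* dst = de2.slice(b).colptr(f);
        for (int t = 0; t < T1; ++t)
          for (int j = 0; j < p1; ++j) dst[t * p1 + j] = src[t] / p1;
      }
    for (uword i = 0; i < de2.n_elem; ++i) de2(i) *= elu_deriv(e2(i));
    bn_cols_backward(de2, xhat2, bn2g, bn2b, sd2, train);   // -> dz2

    // depthwise (virtual-channel) convolution backward
    cube dy1((uword)D * T, F1, B);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F1; ++f) {
        mat Yf(xhat1.slice(b).colptr(f), T, D);
        Yf = bn1g.w(f) * Yf + bn1b.w(f);
        mat dz2f = de2.slice(b).cols(f * mult, f * mult + mult - 1); // (T, mult)
        W2.g.rows(f * mult, f * mult + mult - 1) += dz2f.t() * Yf;
        mat dYf = dz2f * W2.w.rows(f * mult, f * mult + mult - 1);   // (T, D)
        std::memcpy(dy1.slice(b).colptr(f), dYf.memptr(),
                    sizeof(double) * (size_t)D * T);
      }

    bn_cols_backward(dy1, xhat1, bn1g, bn1b, sd1, train);   // -> dc1

    // temporal convolution backward
    double g0 = bn0g.w(0), b0 = bn0b.w(0);
    cube dy0(T, D, B);
    {
      mat xpad(T + kt - 1, D), IC((uword)D * T, kt), dxpad(T + kt - 1, D);
      for (int b = 0; b < B; ++b) {
        xpad.zeros();
        xpad.rows(lpad1, lpad1 + T - 1) = g0 * xhat0.slice(b) + b0;
        im2col1(xpad, IC);
        W1.g += IC.t() * dy1.slice(b);
        mat dIC = dy1.slice(b) * W1.w.t();      // (D*T, kt)
        dxpad.zeros();
        for (int d = 0; d < D; ++d) {
          double* dst = dxpad.colptr(d);
          for (int k = 0; k < kt; ++k) {
            const double* src = dIC.colptr(k) + (size_t)d * T;
            for (int t = 0; t < T; ++t) dst[t + k] += src[t];
          }
        }
        dy0.slice(b) = dxpad.rows(lpad1, lpad1 + T - 1);
      }
    }

    // input BN backward
    double sy = 0, syx = 0;
    for (int b = 0; b < B; ++b) {
      sy += accu(dy0.slice(b));
      syx += accu(dy0.slice(b) % xhat0.slice(b));
    }
    bn0g.g(0) += syx; bn0b.g(0) += sy;
    if (!want_dx) return cube();
    cube dx(T, D, B);
    if (train) {
      double n = (double)((uword)D * T * B);
      for (int b = 0; b < B; ++b)
        dx.slice(b) = (dy0.slice(b) * g0 - (g0 * sy + xhat0.slice(b) * (g0 * syx)) / n) / sd0;
    } else {
      for (int b = 0; b < B; ++b)
        dx.slice(b) = dy0.slice(b) * g0 / sd0;
    }
    return dx;
  }

  void zero_grad() { for (Param* p : params()) p->g.zeros(); }

  void adam_step(double lr, double b1 = 0.9, double b2 = 0.999, double eps = 1e-8) {
    ++adam_t;
    double c1 = 1 - std::pow(b1, adam_t), c2 = 1 - std::pow(b2, adam_t);
    for (Param* p : params()) {
      p->m = b1 * p->m + (1 - b1) * p->g;
      p->v = b2 * p->v + (1 - b2) * square(p->g);
      p->w -= lr * (p->m / c1) / (sqrt(p->v / c2) + eps);
    }
  }

  double ce_loss(const ivec& y, mat& dlogits) {
    dlogits.set_size(K, B);
    double loss = 0;
    for (int b = 0; b < B; ++b) {
      vec l = logits.col(b);
      double mx = l.max();
      vec e = exp(l - mx);
      double se = accu(e);
      loss += -(l(y(b)) - mx - std::log(se));
      dlogits.col(b) = e / se;
      dlogits(y(b), b) -= 1.0;
    }
    dlogits /= B;
    return loss / B;
  }

  vec train_run(const cube& X, const ivec& y, int epochs, double lr,
                int batch, bool shuffle) {
    int N = (int)X.n_slices;
    vec losses(epochs, fill::zeros);
    std::vector<int> ord(N);
    for (int i = 0; i < N; ++i) ord[i] = i;
    for (int ep = 0; ep < epochs; ++ep) {
      if (shuffle)
        for (int i = N - 1; i > 0; --i) {
          int j = (int)(rng.next() % (uint64_t)(i + 1));
          std::swap(ord[i], ord[j]);
        }
      double tot = 0; int nb = 0;
      for (int s = 0; s < N; s += batch) {
        int e = std::min(N, s + batch);
        int bs = e - s;
        cube Xb(X.n_rows, X.n_cols, bs);
        ivec yb(bs);
        for (int i = 0; i < bs; ++i) {
          Xb.slice(i) = X.slice(ord[s + i]);
          yb(i) = y(ord[s + i]);
        }
        forward(Xb, true);
        mat dlog;
        double l = ce_loss(yb, dlog);
        tot += l * bs; nb += bs;
        if (!std::isfinite(l)) { losses(ep) = l; return losses.head(ep + 1); }
        zero_grad();
        backward(dlog, false);
        adam_step(lr);
      }
      losses(ep) = tot / nb;
      Rcpp::checkUserInterrupt();
    }
    return losses;
  }

  mat predict_logits(const cube& X, int chunk = 64) {
    int N = (int)X.n_slices;
    mat out(K, N);
    for (int s = 0; s < N; s += chunk) {
      int e = std::min(N, s + chunk);
      forward(X.slices(s, e - 1), false);
      out.cols(s, e - 1) = logits;
    }
    return out;
  }
};

}  // namespace

typedef Rcpp::XPtr<Net> NetPtr;

// [[Rcpp::export]]
SEXP net_create(int D, int T, int K, int F1, int mult, int kt, int ks,
                int p1, int p2, double dropout, int hidden, double seed) {
  Net* n = new Net(D, T, K, F1, mult, kt, ks, p1, p2, dropout, hidden,
                   (uint64_t)seed);
  return NetPtr(n, true);
}

// [[Rcpp::export]]
arma::vec net_train_run(SEXP ptr, const arma::cube& X, const arma::ivec& y,
                        int epochs, double lr, int batch, bool shuffle) {
  NetPtr n(ptr);
  return n->train_run(X, y, epochs, lr, batch, shuffle);
}

// [[Rcpp::export]]
arma::mat net_logits(SEXP ptr, const arma::cube& X) {
  NetPtr n(ptr);
  return n->predict_logits(X).t();  // (N, K)
}

// [[Rcpp::export]]
arma::mat net_embeddings(SEXP ptr, const arma::cube& X) {
  NetPtr n(ptr);
  int N = (int)X.n_slices;
  mat out(n->hidden, N);
  for (int s = 0; s < N; s += 64) {
    int e = std::min(N, s + 64);
    n->forward(X.slices(s, e - 1), false);
    out.cols(s, e - 1) = n->r4;   // post-ReLU, dropout off in eval mode
  }
  return out.t();
}

// [[Rcpp::export]]
Rcpp::List net_attention(SEXP ptr, const arma::cube& Fmaps) {
  // Fmaps: (F2, T', N) feature maps fed directly to the attention gate
  NetPtr n(ptr);
  int N = (int)Fmaps.n_slices, F2 = n->F2;
  int Tp = (int)Fmaps.n_cols;
  if ((int)Fmaps.n_rows != F2)
    Rcpp::stop("attention expects %d feature maps, got %d", F2, (int)Fmaps.n_rows);
  mat gates(F2, N);
  cube gated(F2, Tp, N);
  for (int b = 0; b < N; ++b) {
    vec avg = mean(Fmaps.slice(b), 1);
    vec mx = max(Fmaps.slice(b), 1);
    vec z = join_cols(avg, mx);
    vec h1 = n->A1.w * z + n->a1b.w.col(0);
    h1.transform([](double x) { return x > 0 ? x : 0.0; });
    vec h2 = n->A2.w * h1 + n->a2b.w.col(0);
    h2.transform([](double x) { return x > 0 ? x : 0.0; });
    vec g = n->A3.w * h2 + n->a3b.w.col(0);
    g.transform([](double x) { return 1.0 / (1.0 + std::exp(-x)); });
    gates.col(b) = g;
    gated.slice(b) = Fmaps.slice(b);
    gated.slice(b).each_col() %= g;
  }
  return Rcpp::List::create(Rcpp::Named("gates") = gates.t(),
                            Rcpp::Named("gated") = gated);
}

// [[Rcpp::export]]
arma::cube net_input_grad(SEXP ptr, const arma::cube& X, const arma::ivec& target) {
  // gradient of the target-class logit w.r.t. the input, eval mode; (T, D, N)
  NetPtr n(ptr);
  int N = (int)X.n_slices;
  cube out(X.n_rows, X.n_cols, N);
  for (int s = 0; s < N; s += 32) {
    int e = std::min(N, s + 32);
    int bs = e - s;
    n->forward(X.slices(s, e - 1), false);
    mat dlog(n->K, bs, fill::zeros);
    for (int i = 0; i < bs; ++i) dlog(target(s + i), i) = 1.0;
    n->zero_grad();
    out.slices(s, e - 1) = n->backward(dlog, true);
  }
  return out;
}

// [[Rcpp::export]]
double net_n_parameters(SEXP ptr) {
  NetPtr n(ptr);
  return n->n_parameters();
}

// [[Rcpp::export]]
Rcpp::List net_get_state(SEXP ptr) {
  NetPtr n(ptr);
  Rcpp::List out;
  std::vector<std::string> nm = n->param_names();
  std::vector<Param*> ps = n->params();
  for (size_t i = 0; i < ps.size(); ++i) out[nm[i]] = ps[i]->w;
  out["r0m"] = n->r0m; out["r0v"] = n->r0v;
  out["r1m"] = n->r1m; out["r1v"] = n->r1v;
  out["r2m"] = n->r2m; out["r2v"] = n->r2v;
  out["r3m"] = n->r3m; out["r3v"] = n->r3v;
  out["r4m"] = n->r4m; out["r4v"] = n->r4v;
  return out;
}

// [[Rcpp::export]]
void net_set_state(SEXP ptr, Rcpp::List state) {
  NetPtr n(ptr);
  std::vector<std::string> nm = n->param_names();
  std::vector<Param*> ps = n->params();
  for (size_t i = 0; i < ps.size(); ++i) {
    mat w = Rcpp::as<mat>(state[nm[i]]);
    if (w.n_rows != ps[i]->w.n_rows || w.n_cols != ps[i]->w.n_cols)
      Rcpp::stop("state dimension mismatch for %s", nm[i].c_str());
    ps[i]->w = w;
  }
  n->r0m = Rcpp::as<vec>(state["r0m"]); n->r0v = Rcpp::as<vec>(state["r0v"]);
  n->r1m = Rcpp::as<vec>(state["r1m"]); n->r1v = Rcpp::as<vec>(state["r1v"]);
  n->r2m = Rcpp::as<vec>(state["r2m"]); n->r2v = Rcpp::as<vec>(state["r2v"]);
  n->r3m = Rcpp::as<vec>(state["r3m"]); n->r3v = Rcpp::as<vec>(state["r3v"]);
  n->r4m = Rcpp::as<vec>(state["r4m"]); n->r4v = Rcpp::as<vec>(state["r4v"]);
}

// [[Rcpp::export]]
Rcpp::List net_loss_and_grad(SEXP ptr, const arma::cube& X, const arma::ivec& y,
                             bool train) {
  // single forward/backward without an optimizer step (used for checking)
  NetPtr n(ptr);
  n->forward(X, train);
  mat dlog;
  double l = n->ce_loss(y, dlog);
  n->zero_grad();
  cube dx = n->backward(dlog, true);
  Rcpp::List grads;
  std::vector<std::string> nm = n->param_names();
  std::vector<Param*> ps = n->params();
  for (size_t i = 0; i < ps.size(); ++i) grads[nm[i]] = ps[i]->g;
  return Rcpp::List::create(Rcpp::Named("loss") = l,
                            Rcpp::Named("grads") = grads,
                            Rcpp::Named("dx") = dx);
}

// [[Rcpp::export]]
double net_loss_only(SEXP ptr, const arma::cube& X, const arma::ivec& y,
                     bool train) {
  NetPtr n(ptr);
  n->forward(X, train);
  mat dlog;
  return n->ce_loss(y, dlog);
}
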