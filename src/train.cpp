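// Single-precision SGD training engine. Caffe-lineage networks of this
// family were trained in float32; the engine keeps the patch arrays,
// parameters, velocities and all activations resident as floats inside an
// external pointer, and processes one sample at a time so every activation
// buffer (~tens of KB) stays cache-hot.
//
// Activation planes carry a zero halo of P = max kernel radius, plus guard
// margins at both buffer ends, so the kernel column loop collapses to a
// 1-d row convolution: one sweep per (channel, kernel column) accumulates
// all s row taps in registers (template-specialized on s). Halos are
// re-zeroed after every write; guards are read-only and stay zero.
//
// Mini-batch index sequences are drawn by the R side (same RNG stream as
// the double-precision reference path), so the two paths see identical
// batch orders.

#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Full 2-d stencil in one plane sweep:
// y[i] += sum_{dc,dr} w[dr + S*dc] * x[i + dr + dc*Hp], taps in registers.
template <int S>
void stencil_acc(const float* __restrict__ x, float* __restrict__ y,
                 const float* __restrict__ w, size_t n, int Hp) {
  for (size_t i = 0; i < n; ++i) {
    float acc = 0;
#pragma GCC unroll 16
    for (int dc = 0; dc < S; ++dc) {
      const float* xc = x + i + (size_t)dc * Hp;
      const float* wc = w + (size_t)dc * S;
#pragma GCC unroll 16
      for (int dr = 0; dr < S; ++dr) acc += wc[dr] * xc[dr];
    }
    y[i] += acc;
  }
}

void stencil_acc_g(const float* __restrict__ x, float* __restrict__ y,
                   const float* __restrict__ w, size_t n, int Hp, int s) {
  switch (s) {
    case 1: stencil_acc<1>(x, y, w, n, Hp); break;
    case 3: stencil_acc<3>(x, y, w, n, Hp); break;
    case 5: stencil_acc<5>(x, y, w, n, Hp); break;
    case 7: stencil_acc<7>(x, y, w, n, Hp); break;
    case 9: stencil_acc<9>(x, y, w, n, Hp); break;
    case 11: stencil_acc<11>(x, y, w, n, Hp); break;
    default:
      for (size_t i = 0; i < n; ++i) {
        float acc = 0;
        for (int dc = 0; dc < s; ++dc)
          for (int dr = 0; dr < s; ++dr)
            acc += w[dr + (size_t)dc * s] * x[i + dr + (size_t)dc * Hp];
        y[i] += acc;
      }
  }
}

// acc[d] += sum_i x[i + d] * g[i], d = 0..S-1
template <int S>
void rowdot(const float* __restrict__ x, const float* __restrict__ g,
            float* __restrict__ acc, size_t n) {
  float a[S];
  for (int d = 0; d < S; ++d) a[d] = 0;
  for (size_t i = 0; i < n; ++i) {
    const float gv = g[i];
#pragma GCC unroll 16
    for (int d = 0; d < S; ++d) a[d] += x[i + d] * gv;
  }
  for (int d = 0; d < S; ++d) acc[d] += a[d];
}

void rowdot_g(const float* __restrict__ x, const float* __restrict__ g,
              float* __restrict__ acc, size_t n, int s) {
  switch (s) {
    case 1: rowdot<1>(x, g, acc, n); break;
    case 3: rowdot<3>(x, g, acc, n); break;
    case 5: rowdot<5>(x, g, acc, n); break;
    case 7: rowdot<7>(x, g, acc, n); break;
    case 9: rowdot<9>(x, g, acc, n); break;
    case 11: rowdot<11>(x, g, acc, n); break;
    default:
      for (size_t i = 0; i < n; ++i) {
        const float gv = g[i];
        for (int d = 0; d < s; ++d) acc[d] += x[i + d] * gv;
      }
  }
}

struct FLayer {
  int s, cin, cout;
  bool relu;
  std::vector<float> w, b, vw, vb, gw, gb;
  std::vector<float> act, gact;  // guarded padded activation / gradient
  float *actp, *gactp;           // plane base (past the guard)
};

struct Unit {
  int main_idx;
  std::vector<std::vector<int>> chains;
};

struct Trainer {
  int H, W, M, P;
  int Hp, Wp;
  size_t HWp, guard;
  std::vector<float> X, Y;
  std::vector<float> xpad;
  float* xpadp;
  std::vector<FLayer> layers;
  std::vector<Unit> units;
  int recon_idx;
  std::vector<std::vector<float>> fused, gfused;
  std::vector<float*> fusedp, gfusedp;
  std::vector<float> gy;
  float* gyp;
};

float* guarded_alloc(std::vector<float>& v, size_t planes_bytes,
                     size_t guard) {
  v.assign(planes_bytes + 2 * guard, 0.0f);
  return v.data() + guard;
}

void clear_halo(float* buf, int Hp, int Wp, int P, int C) {
  const size_t HWp = (size_t)Hp * Wp;
  for (int ci = 0; ci < C; ++ci) {
    float* pl = buf + (size_t)ci * HWp;
    for (int c = 0; c < P; ++c) {
      std::memset(pl + (size_t)c * Hp, 0, sizeof(float) * Hp);
      std::memset(pl + (size_t)(Wp - 1 - c) * Hp, 0, sizeof(float) * Hp);
    }
    for (int c = P; c < Wp - P; ++c) {
      float* col = pl + (size_t)c * Hp;
      for (int r = 0; r < P; ++r) col[r] = 0.0f;
      for (int r = Hp - P; r < Hp; ++r) col[r] = 0.0f;
    }
  }
}

void pconv_fwd(const Trainer* tr, const float* x, float* y, const float* w,
               const float* b, int cin, int cout, int s, bool relu) {
  const int hw = s / 2, Hp = tr->Hp;
  const size_t HWp = tr->HWp;
  for (int co = 0; co < cout; ++co) {
    float* yp = y + (size_t)co * HWp;
    const float bc = b[co];
    for (size_t i = 0; i < HWp; ++i) yp[i] = bc;
    for (int ci = 0; ci < cin; ++ci) {
      const float* xp = x + (size_t)ci * HWp;
      const float* wk = w + ((size_t)co * cin + ci) * s * s;
      // whole s x s kernel in one plane sweep
      stencil_acc_g(xp - (ptrdiff_t)hw * Hp - hw, yp, wk, HWp, Hp, s);
    }
    if (relu) {
      for (size_t i = 0; i < HWp; ++i) if (yp[i] < 0) yp[i] = 0;
    }
  }
  clear_halo(y, tr->Hp, tr->Wp, tr->P, cout);
}

// gy must be activation-masked with zero halo; gw/gb accumulate; gx (if
// non-null) accumulates, caller cleans its halo afterwards.
void pconv_bwd(const Trainer* tr, const float* x, const float* w,
               const float* gy, float* gx, float* gw, float* gb, int cin,
               int cout, int s) {
  const int hw = s / 2, Hp = tr->Hp;
  const size_t HWp = tr->HWp;
  float wrev[256];
  for (int co = 0; co < cout; ++co) {
    const float* gp = gy + (size_t)co * HWp;
    float acc = 0.0f;
    for (size_t i = 0; i < HWp; ++i) acc += gp[i];
    gb[co] += acc;
    for (int ci = 0; ci < cin; ++ci) {
      const float* xp = x + (size_t)ci * HWp;
      const float* wk = w + ((size_t)co * cin + ci) * s * s;
      float* gwk = gw + ((size_t)co * cin + ci) * s * s;
      for (int dc = 0; dc < s; ++dc) {
        rowdot_g(xp + (ptrdiff_t)(dc - hw) * Hp - hw, gp,
                 gwk + (size_t)dc * s, HWp, s);
      }
      if (gx) {
        // gx = gy convolved with the fully reversed kernel: one sweep
        for (int d = 0; d < s * s; ++d) wrev[d] = wk[s * s - 1 - d];
        stencil_acc_g(gp - (ptrdiff_t)hw * Hp - hw, gx + (size_t)ci * HWp,
                      wrev, HWp, Hp, s);
      }
    }
  }
}

void mask_relu(const float* __restrict__ act, const float* __restrict__ gin,
               float* __restrict__ gout, size_t n) {
  for (size_t i = 0; i < n; ++i) gout[i] = act[i] > 0 ? gin[i] : 0.0f;
}

void forward_sample(Trainer* tr) {
  const float* cur = tr->xpadp;
  for (size_t u = 0; u < tr->units.size(); ++u) {
    Unit& un = tr->units[u];
    FLayer& Lm = tr->layers[un.main_idx];
    pconv_fwd(tr, cur, Lm.actp, Lm.w.data(), Lm.b.data(), Lm.cin, Lm.cout,
              Lm.s, true);
    std::memcpy(tr->fusedp[u], Lm.actp,
                sizeof(float) * tr->HWp * Lm.cout);
    for (const std::vector<int>& chain : un.chains) {
      const float* z = cur;
      for (int k : chain) {
        FLayer& L = tr->layers[k];
        pconv_fwd(tr, z, L.actp, L.w.data(), L.b.data(), L.cin, L.cout,
                  L.s, L.relu);
        z = L.actp;
      }
      float* f = tr->fusedp[u];
      const size_t n = tr->HWp * Lm.cout;
      for (size_t i = 0; i < n; ++i) f[i] += z[i];
    }
    cur = tr->fusedp[u];
  }
  FLayer& Lr = tr->layers[tr->recon_idx];
  pconv_fwd(tr, cur, Lr.actp, Lr.w.data(), Lr.b.data(), Lr.cin, Lr.cout,
            Lr.s, false);
}

void backward_sample(Trainer* tr) {
  const int U = (int)tr->units.size();
  const size_t HWp = tr->HWp;
  FLayer& Lr = tr->layers[tr->recon_idx];
  const float* rin = U > 0 ? tr->fusedp[U - 1] : tr->xpadp;
  float* grin = U > 0 ? tr->gfusedp[U - 1] : nullptr;
  if (grin) std::memset(grin, 0, sizeof(float) * HWp * Lr.cin);
  pconv_bwd(tr, rin, Lr.w.data(), tr->gyp, grin, Lr.gw.data(),
            Lr.gb.data(), Lr.cin, Lr.cout, Lr.s);
  if (grin) clear_halo(grin, tr->Hp, tr->Wp, tr->P, Lr.cin);
  for (int u = U - 1; u >= 0; --u) {
    Unit& un = tr->units[u];
    FLayer& Lm = tr->layers[un.main_idx];
    const float* gout = tr->gfusedp[u];
    const float* uin = u > 0 ? tr->fusedp[u - 1] : tr->xpadp;
    float* gin = u > 0 ? tr->gfusedp[u - 1] : nullptr;
    if (gin) std::memset(gin, 0, sizeof(float) * HWp * Lm.cin);
    mask_relu(Lm.actp, gout, Lm.gactp, HWp * Lm.cout);
    pconv_bwd(tr, uin, Lm.w.data(), Lm.gactp, gin, Lm.gw.data(),
              Lm.gb.data(), Lm.cin, Lm.cout, Lm.s);
    for (const std::vector<int>& chain : un.chains) {
      const float* gz = gout;
      for (int ci = (int)chain.size() - 1; ci >= 0; --ci) {
        FLayer& L = tr->layers[chain[ci]];
        if (L.relu) {
          mask_relu(L.actp, gz, L.gactp, HWp * L.cout);
        } else if (gz != L.gactp) {
          std::memcpy(L.gactp, gz, sizeof(float) * HWp * L.cout);
        }
        const float* zin = ci > 0 ? tr->layers[chain[ci - 1]].actp : uin;
        if (ci > 0) {
          FLayer& Lp = tr->layers[chain[ci - 1]];
          std::memset(Lp.gactp, 0, sizeof(float) * HWp * Lp.cout);
          pconv_bwd(tr, zin, L.w.data(), L.gactp, Lp.gactp, L.gw.data(),
                    L.gb.data(), L.cin, L.cout, L.s);
          clear_halo(Lp.gactp, tr->Hp, tr->Wp, tr->P, Lp.cout);
          gz = Lp.gactp;
        } else {
          pconv_bwd(tr, zin, L.w.data(), L.gactp, gin, L.gw.data(),
                    L.gb.data(), L.cin, L.cout, L.s);
        }
      }
    }
    if (gin) clear_halo(gin, tr->Hp, tr->Wp, tr->P, Lm.cin);
  }
}

}  // namespace

// layers_meta: list of per-layer lists (s, cin, cout, relu, unit, kind,
// sub_id) in the package's fixed traversal order; kind: 0 main, 1 sub,
// 2 recon.
// [[Rcpp::export]]
SEXP cpp_trainer_new(List layers_meta, List params, NumericVector x_all,
                     NumericVector y_all, int H, int W) {
  Trainer* tr = new Trainer();
  tr->H = H;
  tr->W = W;
  const size_t HW = (size_t)H * W;
  tr->M = (int)(Rf_xlength(x_all) / (R_xlen_t)HW);
  tr->X.resize((size_t)tr->M * HW);
  tr->Y.resize((size_t)tr->M * HW);
  for (size_t i = 0; i < tr->X.size(); ++i) {
    tr->X[i] = (float)REAL(x_all)[i];
    tr->Y[i] = (float)REAL(y_all)[i];
  }
  const int nlay = layers_meta.size();
  int P = 1;
  for (int k = 0; k < nlay; ++k) {
    List m = layers_meta[k];
    const int s = as<int>(m["s"]);
    if (s > 15) stop("kernel size above 15 is not supported by the engine");
    P = std::max(P, s / 2);
  }
  tr->P = P;
  tr->Hp = H + 2 * P;
  tr->Wp = W + 2 * P;
  tr->HWp = (size_t)tr->Hp * tr->Wp;
  tr->guard = (size_t)P * (tr->Hp + 1);
  tr->xpadp = guarded_alloc(tr->xpad, tr->HWp, tr->guard);
  tr->layers.resize(nlay);
  int cur_unit = -1, cur_sub = -1;
  tr->recon_idx = -1;
  for (int k = 0; k < nlay; ++k) {
    List m = layers_meta[k];
    FLayer& L = tr->layers[k];
    L.s = as<int>(m["s"]);
    L.cin = as<int>(m["cin"]);
    L.cout = as<int>(m["cout"]);
    L.relu = as<bool>(m["relu"]);
    List p = params[k];
    NumericVector w = p["w"], b = p["b"];
    L.w.assign(w.begin(), w.end());
    L.b.assign(b.begin(), b.end());
    L.vw.assign(L.w.size(), 0.0f);
    L.vb.assign(L.b.size(), 0.0f);
    L.gw.resize(L.w.size());
    L.gb.resize(L.b.size());
    L.actp = guarded_alloc(L.act, tr->HWp * L.cout, tr->guard);
    L.gactp = guarded_alloc(L.gact, tr->HWp * L.cout, tr->guard);
    const int kind = as<int>(m["kind"]);
    const int unit = as<int>(m["unit"]);
    const int sub_id = as<int>(m["sub_id"]);
    if (kind == 0) {
      tr->units.push_back(Unit());
      tr->units.back().main_idx = k;
      cur_unit = (int)tr->units.size() - 1;
      cur_sub = -1;
    } else if (kind == 1) {
      if (unit - 1 != cur_unit) stop("layer metadata out of order");
      if (sub_id != cur_sub) {
        tr->units[cur_unit].chains.push_back(std::vector<int>());
        cur_sub = sub_id;
      }
      tr->units[cur_unit].chains.back().push_back(k);
    } else {
      tr->recon_idx = k;
    }
  }
  if (tr->recon_idx < 0) stop("missing reconstruction layer");
  tr->fused.resize(tr->units.size());
  tr->gfused.resize(tr->units.size());
  for (size_t u = 0; u < tr->units.size(); ++u) {
    const int cm = tr->layers[tr->units[u].main_idx].cout;
    tr->fusedp.push_back(guarded_alloc(tr->fused[u], tr->HWp * cm,
                                       tr->guard));
    tr->gfusedp.push_back(guarded_alloc(tr->gfused[u], tr->HWp * cm,
                                        tr->guard));
  }
  tr->gyp = guarded_alloc(tr->gy, tr->HWp, tr->guard);
  return XPtr<Trainer>(tr, true);
}

// Run the iterations whose 1-based sample indices are the columns of idx.
// Returns list(losses, diverged_at): diverged_at is the 1-based iteration
// within this chunk at which the loss became non-finite, or 0.
// [[Rcpp::export]]
List cpp_trainer_run(SEXP ptr, IntegerMatrix idx, double lr,
                     double momentum) {
  XPtr<Trainer> tr(ptr);
  const int B = idx.nrow(), K = idx.ncol();
  const int H = tr->H, W = tr->W, Hp = tr->Hp, P = tr->P;
  const size_t HW = (size_t)H * W;
  NumericVector losses(K);
  int diverged_at = 0;
  const float flr = (float)lr, fmom = (float)momentum;
  FLayer& Lr = tr->layers[tr->recon_idx];
  for (int it = 0; it < K; ++it) {
    for (FLayer& L : tr->layers) {
      std::fill(L.gw.begin(), L.gw.end(), 0.0f);
      std::fill(L.gb.begin(), L.gb.end(), 0.0f);
    }
    double loss = 0.0;
    const float inv_b = 1.0f / (float)B;
    for (int bi = 0; bi < B; ++bi) {
      const int m = idx(bi, it) - 1;
      if (m < 0 || m >= tr->M) stop("sample index out of range");
      const float* xs = tr->X.data() + (size_t)m * HW;
      const float* ys = tr->Y.data() + (size_t)m * HW;
      for (int c = 0; c < W; ++c) {
        std::memcpy(tr->xpadp + (size_t)(c + P) * Hp + P,
                    xs + (size_t)c * H, sizeof(float) * H);
      }
      forward_sample(tr);
      const float* pred = Lr.actp;
      double ssq = 0.0;
      for (int c = 0; c < W; ++c) {
        const float* pc = pred + (size_t)(c + P) * Hp + P;
        const float* yc = ys + (size_t)c * H;
        float* gc = tr->gyp + (size_t)(c + P) * Hp + P;
        for (int r = 0; r < H; ++r) {
          const float d = pc[r] - yc[r];
          gc[r] = d * inv_b;
          ssq += (double)d * d;
        }
      }
      loss += ssq;
      backward_sample(tr);
    }
    loss /= 2.0 * B;
    losses[it] = loss;
    if (!std::isfinite(loss)) {
      diverged_at = it + 1;
      break;
    }
    for (FLayer& L : tr->layers) {
      for (size_t i = 0; i < L.w.size(); ++i) {
        L.vw[i] = fmom * L.vw[i] - flr * L.gw[i];
        L.w[i] += L.vw[i];
      }
      for (size_t i = 0; i < L.b.size(); ++i) {
        L.vb[i] = fmom * L.vb[i] - flr * L.gb[i];
        L.b[i] += L.vb[i];
      }
    }
  }
  return List::create(_["losses"] = losses, _["diverged_at"] = diverged_at);
}

// Current parameters as double arrays, in layer order.
// [[Rcpp::export]]
List cpp_trainer_params(SEXP ptr) {
  XPtr<Trainer> tr(ptr);
  List out(tr->layers.size());
  for (size_t k = 0; k < tr->layers.size(); ++k) {
    FLayer& L = tr->layers[k];
    NumericVector w(L.w.size()), b(L.b.size());
    for (size_t i = 0; i < L.w.size(); ++i) w[i] = L.w[i];
    for (size_t i = 0; i < L.b.size(); ++i) b[i] = L.b[i];
    w.attr("dim") = IntegerVector::create(L.s, L.s, L.cin, L.cout);
    out[k] = List::create(_["w"] = w, _["b"] = b);
  }
  return out;
}
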