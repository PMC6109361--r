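// Shared shift-accumulate convolution primitives, templated on the real
// type: double for the reference path, float for the training engine.
#ifndef MFCNSR_KERNELS_H
#define MFCNSR_KERNELS_H

#include <algorithm>
#include <cstddef>

// y_plane += wv * x_plane shifted by (off_r, off_c), zero padding implied.
template <typename T>
inline void shift_axpy(const T* __restrict__ x, T* __restrict__ y, int H,
                       int W, int off_r, int off_c, T wv) {
  const int r0 = std::max(0, -off_r), r1 = std::min(H, H - off_r);
  const int c0 = std::max(0, -off_c), c1 = std::min(W, W - off_c);
  for (int c = c0; c < c1; ++c) {
    const T* __restrict__ src = x + (size_t)(c + off_c) * H + (r0 + off_r);
    T* __restrict__ dst = y + (size_t)c * H + r0;
    const int len = r1 - r0;
    for (int r = 0; r < len; ++r) dst[r] += wv * src[r];
  }
}

// sum over the valid region of x(shifted) .* g
template <typename T>
inline T shift_dot(const T* __restrict__ x, const T* __restrict__ g, int H,
                   int W, int off_r, int off_c) {
  const int r0 = std::max(0, -off_r), r1 = std::min(H, H - off_r);
  const int c0 = std::max(0, -off_c), c1 = std::min(W, W - off_c);
  T acc = 0;
  for (int c = c0; c < c1; ++c) {
    const T* __restrict__ src = x + (size_t)(c + off_c) * H + (r0 + off_r);
    const T* __restrict__ gp = g + (size_t)c * H + r0;
    const int len = r1 - r0;
    for (int r = 0; r < len; ++r) acc += src[r] * gp[r];
  }
  return acc;
}

// One convolution layer forward for a single sample (Cin planes -> Cout
// planes), zero same-padding, optional fused ReLU.
template <typename T>
inline void conv_sample_fwd(const T* x, T* y, const T* w, const T* b, int H,
                            int W, int Cin, int Cout, int s, bool relu) {
  const int hw = s / 2;
  const size_t HW = (size_t)H * W;
  for (int co = 0; co < Cout; ++co) {
    T* yplane = y + (size_t)co * HW;
    const T bc = b[co];
    for (size_t i = 0; i < HW; ++i) yplane[i] = bc;
    for (int ci = 0; ci < Cin; ++ci) {
      const T* xplane = x + (size_t)ci * HW;
      const T* wk = w + ((size_t)co * Cin + ci) * s * s;
      for (int dc = 0; dc < s; ++dc)
        for (int dr = 0; dr < s; ++dr)
          shift_axpy(xplane, yplane, H, W, dr - hw, dc - hw,
                     wk[(size_t)dc * s + dr]);
    }
    if (relu) {
      for (size_t i = 0; i < HW; ++i) if (yplane[i] < 0) yplane[i] = 0;
    }
  }
}

// Gradients for one sample. gy must already be activation-masked.
// Accumulates into gw/gb (caller zeroes once per batch); gx (if not null)
// must be zeroed by the caller and accumulates the input gradient.
template <typename T>
inline void conv_sample_bwd(const T* x, const T* w, const T* gy, T* gx,
                            T* gw, T* gb, int H, int W, int Cin, int Cout,
                            int s) {
  const int hw = s / 2;
  const size_t HW = (size_t)H * W;
  for (int co = 0; co < Cout; ++co) {
    const T* gplane = gy + (size_t)co * HW;
    T acc = 0;
    for (size_t i = 0; i < HW; ++i) acc += gplane[i];
    gb[co] += acc;
    for (int ci = 0; ci < Cin; ++ci) {
      const T* xplane = x + (size_t)ci * HW;
      const T* wk = w + ((size_t)co * Cin + ci) * s * s;
      T* gwk = gw + ((size_t)co * Cin + ci) * s * s;
      for (int dc = 0; dc < s; ++dc) {
        for (int dr = 0; dr < s; ++dr) {
          const int off_r = dr - hw, off_c = dc - hw;
          gwk[(size_t)dc * s + dr] +=
            shift_dot(xplane, gplane, H, W, off_r, off_c);
          if (gx) {
            shift_axpy(gplane, gx + (size_t)ci * HW, H, W, -off_r, -off_c,
                       wk[(size_t)dc * s + dr]);
          }
        }
      }
    }
  }
}

#endif
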