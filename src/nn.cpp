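// Forward and backward passes for the dilated 1D CNN.
//
// Activations are held in single-precision, time-major workspaces: channel
// c of a batch of N length-L samples is a contiguous run of L*N floats
// (sample-major). Parameters stay in double on the R side and are
// converted per call (they are tiny); gradients and batch statistics are
// accumulated in double. Convolutions use same (zero) padding within each
// sample and are computed as direct stencils over per-sample tiles, which
// beats im2col + gemm at the narrow channel counts used here. The forward
// pass keeps everything the backward pass needs in a NetCache handed back
// to R as an external pointer, so a full training step costs two C++
// calls.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#if defined(__SSE2__) || defined(_M_X64)
#include <emmintrin.h>
#define AFUQ_SSE2 1
#endif
using namespace Rcpp;

// R's default -O2 leaves the stencil loops partly unvectorized; the hot
// loops here are worth the extra optimization effort.
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3")
#endif

#ifdef AFUQ_SSE2
static inline float hsum4(__m128 v) {
  __m128 sh = _mm_add_ps(v, _mm_movehl_ps(v, v));
  sh = _mm_add_ss(sh, _mm_shuffle_ps(sh, sh, 1));
  return _mm_cvtss_f32(sh);
}
static inline double hsum2d(__m128d v) {
  return _mm_cvtsd_f64(_mm_add_sd(v, _mm_unpackhi_pd(v, v)));
}
#endif

struct BlockCache {
  std::vector<float> x_in;   // conv input
  std::vector<float> xhat;   // normalised conv output
  std::vector<uint8_t> mask; // ReLU * dropout survival
  std::vector<int> pool_src; // winning source row per pooled element
  std::vector<double> istd;  // per-channel 1/sd used in this pass
  int L_in = 0, L_out = 0, Cin = 0, Cout = 0, d = 0;
  bool pooled = false;
};

struct NetCache {
  int N = 0, L_final = 0, C_final = 0;
  double drop_scale = 1.0;
  std::vector<BlockCache> blocks;
  std::vector<double> G; // pooled features, (N x C_final), channel-major
  std::vector<double> p; // predicted probabilities
};

struct Rng64 { // xorshift128+, seeded from R's RNG for reproducibility
  uint64_t s0 = 88172645463325252ull, s1 = 362436069363025432ull;
  explicit Rng64(bool seed_from_r) {
    if (seed_from_r) {
      s0 = (uint64_t)(unif_rand() * 9007199254740992.0) | 1u;
      s1 = (uint64_t)(unif_rand() * 9007199254740992.0) | 1u;
    }
  }
  inline uint64_t next() {
    uint64_t t = s0;
    const uint64_t v = s1;
    s0 = v;
    t ^= t << 23;
    t ^= t >> 18;
    t ^= v ^ (v >> 5);
    s1 = t;
    return t + v;
  }
};

static inline int pooled_len(int L, int d) { return (L - d - 1) / 2 + 1; }

// conv same-padding stencil: Y[co] = b[co] + sum_{j,ci} W[co, j*Cin+ci] *
// shift(X[ci], (j - half)*d), per sample tile so everything stays in cache.
static void conv_fwd(const std::vector<float>& X, std::vector<float>& Y,
                     const std::vector<float>& W, const std::vector<float>& b,
                     int Cin, int Cout, int k, int L, int N, int d) {
  const int half = (k - 1) / 2;
  const size_t M = (size_t)L * N;
  for (int n = 0; n < N; ++n) {
    const size_t s = (size_t)n * L;
    for (int co = 0; co < Cout; ++co) {
      float* __restrict y = Y.data() + (size_t)co * M + s;
      const float bc = b[co];
      for (int l = 0; l < L; ++l) y[l] = bc;
      for (int j = 0; j < k; ++j) {
        const int off = (j - half) * d;
        const int lo = std::max(0, -off);
        const int hi = L - std::max(0, off);
        if (hi <= lo) continue;
        const int len = hi - lo;
        for (int ci = 0; ci < Cin; ++ci) {
          const float w = W[(size_t)co + (size_t)Cout * (j * Cin + ci)];
          if (w == 0.0f) continue;
          const float* __restrict xp = X.data() + (size_t)ci * M + s + lo + off;
          float* __restrict yp = y + lo;
          for (int i = 0; i < len; ++i) yp[i] += w * xp[i];
        }
      }
    }
  }
}

static void conv_bwd(const std::vector<float>& dY, const std::vector<float>& X,
                     const std::vector<float>& W, std::vector<float>& dX,
                     std::vector<double>& dW, std::vector<double>& db,
                     int Cin, int Cout, int k, int L, int N, int d) {
  const int half = (k - 1) / 2;
  const size_t M = (size_t)L * N;
  for (int n = 0; n < N; ++n) {
    const size_t s = (size_t)n * L;
    for (int co = 0; co < Cout; ++co) {
      const float* __restrict dy = dY.data() + (size_t)co * M + s;
#ifdef AFUQ_SSE2
      __m128 accb = _mm_setzero_ps();
      int l = 0;
      for (; l + 4 <= L; l += 4) accb = _mm_add_ps(accb, _mm_loadu_ps(dy + l));
      float a0 = hsum4(accb);
      for (; l < L; ++l) a0 += dy[l];
      db[co] += (double)a0;
#else
      float a0 = 0.0f, a1 = 0.0f;
      int l = 0;
      for (; l + 2 <= L; l += 2) { a0 += dy[l]; a1 += dy[l + 1]; }
      if (l < L) a0 += dy[l];
      db[co] += (double)a0 + (double)a1;
#endif
      for (int j = 0; j < k; ++j) {
        const int off = (j - half) * d;
        const int lo = std::max(0, -off);
        const int hi = L - std::max(0, off);
        if (hi <= lo) continue;
        const int len = hi - lo;
        for (int ci = 0; ci < Cin; ++ci) {
          const float w = W[(size_t)co + (size_t)Cout * (j * Cin + ci)];
          const float* __restrict xp = X.data() + (size_t)ci * M + s + lo + off;
          float* __restrict dxp = dX.data() + (size_t)ci * M + s + lo + off;
          const float* __restrict g = dy + lo;
          int i = 0;
#ifdef AFUQ_SSE2
          const __m128 wv = _mm_set1_ps(w);
          __m128 sw = _mm_setzero_ps();
          for (; i + 4 <= len; i += 4) {
            const __m128 gv = _mm_loadu_ps(g + i);
            sw = _mm_add_ps(sw, _mm_mul_ps(gv, _mm_loadu_ps(xp + i)));
            _mm_storeu_ps(dxp + i,
                          _mm_add_ps(_mm_loadu_ps(dxp + i), _mm_mul_ps(wv, gv)));
          }
          float sw0 = hsum4(sw);
          for (; i < len; ++i) {
            sw0 += g[i] * xp[i];
            dxp[i] += w * g[i];
          }
          dW[(size_t)co + (size_t)Cout * (j * Cin + ci)] += (double)sw0;
#else
          float sw0 = 0.0f, sw1 = 0.0f;
          for (; i + 2 <= len; i += 2) {
            sw0 += g[i] * xp[i];
            sw1 += g[i + 1] * xp[i + 1];
            dxp[i] += w * g[i];
            dxp[i + 1] += w * g[i + 1];
          }
          for (; i < len; ++i) {
            sw0 += g[i] * xp[i];
            dxp[i] += w * g[i];
          }
          dW[(size_t)co + (size_t)Cout * (j * Cin + ci)] +=
            (double)sw0 + (double)sw1;
#endif
        }
      }
    }
  }
}

static std::vector<float> as_float(const NumericVector& v) {
  std::vector<float> out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

// Full forward pass.
// mode: 0 = eval (running BN stats, no dropout), 1 = train (batch stats,
// dropout), 2 = mc (running stats, dropout active).
// [[Rcpp::export]]
List nn_fwd_cpp(const List& params, const List& config, const List& signals,
                int mode, bool keep_cache) {
  const IntegerVector channels = config["channels_per_block"];
  const IntegerVector dil = config["dilation_schedule"];
  const IntegerVector pool_blocks = config["pool_blocks"];
  const double rate = config["dropout_rate"];
  const int n_leads = config["n_leads"];
  const int k = config["kernel_size"];
  const int nb = channels.size();
  const bool training = mode == 1;
  const bool drop_on = (mode == 1 || mode == 2) && rate > 0.0;

  const int N = signals.size();
  const NumericMatrix first(as<NumericMatrix>(signals[0]));
  const int L0 = first.ncol();
  if (first.nrow() != n_leads) stop("signal lead count does not match config");

  std::vector<bool> pool_at(nb + 1, false);
  for (int i = 0; i < pool_blocks.size(); ++i) pool_at[pool_blocks[i]] = true;

  XPtr<NetCache> cache(new NetCache(), true);
  cache->N = N;
  cache->blocks.resize(nb);
  cache->drop_scale = drop_on ? 1.0 / (1.0 - rate) : 1.0;

  Rng64 rng(drop_on);
  // dropout decisions are drawn bytewise (8 per RNG draw, 1/256 rate
  // granularity): the survival test vectorizes and the generator runs
  // once per 8 activations
  const uint8_t thr8 = (uint8_t)std::min(255L, std::lround(rate * 256.0));
  std::vector<uint8_t> dmask;
  auto fill_dmask = [&](size_t total) {
    dmask.resize(total);
    size_t i = 0;
    for (; i + 8 <= total; i += 8) {
      uint64_t r = rng.next();
      for (int bb = 0; bb < 8; ++bb)
        dmask[i + bb] = ((uint8_t)(r >> (8 * bb)) >= thr8) ? 1 : 0;
    }
    if (i < total) {
      uint64_t r = rng.next();
      for (; i < total; ++i) {
        dmask[i] = ((uint8_t)r >= thr8) ? 1 : 0;
        r >>= 8;
      }
    }
  };

  // stack input signals time-major
  size_t M = (size_t)L0 * N;
  std::vector<float> A(M * n_leads);
  for (int n = 0; n < N; ++n) {
    const NumericMatrix sig(as<NumericMatrix>(signals[n]));
    if (sig.nrow() != n_leads || sig.ncol() != L0)
      stop("all signals in a batch must share the same shape");
    for (int c = 0; c < n_leads; ++c) {
      float* __restrict x = A.data() + (size_t)c * M + (size_t)n * L0;
      for (int l = 0; l < L0; ++l) x[l] = (float)sig(c, l);
    }
  }

  const List blocks = params["blocks"];
  List run_updates(training ? nb : 0);
  int L = L0;
  int Cin = n_leads;
  std::vector<float> Y;

  for (int i = 0; i < nb; ++i) {
    const List bp = blocks[i];
    const int Cout = channels[i];
    const int d = dil[i];
    BlockCache& bc = cache->blocks[i];
    bc.L_in = L;
    bc.Cin = Cin;
    bc.Cout = Cout;
    bc.d = d;

    const std::vector<float> W = as_float(bp["W"]);
    const std::vector<float> b = as_float(bp["b"]);
    M = (size_t)L * N;
    Y.resize(M * Cout); // conv_fwd overwrites every element (bias init)
    conv_fwd(A, Y, W, b, Cin, Cout, k, L, N, d);
    if (keep_cache) bc.x_in = std::move(A);

    // batch-norm statistics
    std::vector<double> mu(Cout), istd(Cout);
    if (training) {
      NumericVector bm(Cout), bv(Cout);
      for (int c = 0; c < Cout; ++c) {
        const float* __restrict y = Y.data() + (size_t)c * M;
        size_t t = 0;
#ifdef AFUQ_SSE2
        __m128d s0 = _mm_setzero_pd(), s1 = _mm_setzero_pd();
        __m128d q0 = _mm_setzero_pd(), q1 = _mm_setzero_pd();
        for (; t + 4 <= M; t += 4) {
          const __m128 f = _mm_loadu_ps(y + t);
          const __m128d lo = _mm_cvtps_pd(f);
          const __m128d hi = _mm_cvtps_pd(_mm_movehl_ps(f, f));
          s0 = _mm_add_pd(s0, lo);
          s1 = _mm_add_pd(s1, hi);
          q0 = _mm_add_pd(q0, _mm_mul_pd(lo, lo));
          q1 = _mm_add_pd(q1, _mm_mul_pd(hi, hi));
        }
        double sa = hsum2d(_mm_add_pd(s0, s1));
        double s2a = hsum2d(_mm_add_pd(q0, q1));
        for (; t < M; ++t) { sa += y[t]; s2a += (double)y[t] * y[t]; }
        const double m = sa / M;
        const double v = std::max(0.0, s2a / M - m * m);
#else
        double sa = 0.0, sb = 0.0, s2a = 0.0, s2b = 0.0;
        for (; t + 2 <= M; t += 2) {
          sa += y[t];      s2a += (double)y[t] * y[t];
          sb += y[t + 1];  s2b += (double)y[t + 1] * y[t + 1];
        }
        if (t < M) { sa += y[t]; s2a += (double)y[t] * y[t]; }
        const double m = (sa + sb) / M;
        const double v = std::max(0.0, (s2a + s2b) / M - m * m);
#endif
        mu[c] = m;
        istd[c] = 1.0 / std::sqrt(v + 1e-5);
        bm[c] = m;
        bv[c] = v;
      }
      run_updates[i] = List::create(_["mean"] = bm, _["var"] = bv);
    } else {
      const NumericVector rm = bp["run_mean"], rv = bp["run_var"];
      for (int c = 0; c < Cout; ++c) {
        mu[c] = rm[c];
        istd[c] = 1.0 / std::sqrt(rv[c] + 1e-5);
      }
    }
    if (keep_cache) bc.istd = istd;

    // fused normalise + scale/shift + ReLU + dropout
    const NumericVector gamma = bp["gamma"], beta = bp["beta"];
    if (keep_cache) {
      bc.xhat.resize(M * Cout);
      bc.mask.resize(M * Cout);
    }
    const float scale = (float)cache->drop_scale;
    if (drop_on) fill_dmask(M * Cout);
    std::vector<float> Anew(M * Cout);
    for (int c = 0; c < Cout; ++c) {
      const float* __restrict y = Y.data() + (size_t)c * M;
      float* __restrict a = Anew.data() + (size_t)c * M;
      float* __restrict xh = keep_cache ? bc.xhat.data() + (size_t)c * M : nullptr;
      uint8_t* __restrict mk = keep_cache ? bc.mask.data() + (size_t)c * M : nullptr;
      const uint8_t* __restrict dm = drop_on ? dmask.data() + (size_t)c * M : nullptr;
      const float m = (float)mu[c], is = (float)istd[c];
      const float g = (float)gamma[c], bt = (float)beta[c];
      size_t t = 0;
#ifdef AFUQ_SSE2
      {
        const __m128 mv = _mm_set1_ps(m), isv = _mm_set1_ps(is);
        const __m128 gv = _mm_set1_ps(g), btv = _mm_set1_ps(bt);
        const __m128 scv = _mm_set1_ps(scale), zv = _mm_setzero_ps();
        const __m128i z8 = _mm_setzero_si128();
        for (; t + 4 <= M; t += 4) {
          const __m128 hv = _mm_mul_ps(_mm_sub_ps(_mm_loadu_ps(y + t), mv), isv);
          const __m128 act = _mm_add_ps(_mm_mul_ps(gv, hv), btv);
          __m128 keep = _mm_cmpgt_ps(act, zv);
          if (drop_on) {
            int32_t mi;
            std::memcpy(&mi, dm + t, 4);
            const __m128i m32 = _mm_unpacklo_epi16(
              _mm_unpacklo_epi8(_mm_cvtsi32_si128(mi), z8), z8);
            keep = _mm_and_ps(keep,
                              _mm_castsi128_ps(_mm_cmpgt_epi32(m32, z8)));
          }
          _mm_storeu_ps(a + t, _mm_and_ps(keep, _mm_mul_ps(act, scv)));
          if (keep_cache) {
            _mm_storeu_ps(xh + t, hv);
            const __m128i one =
              _mm_srli_epi32(_mm_castps_si128(keep), 31); // 0/1 per lane
            const __m128i b8 =
              _mm_packus_epi16(_mm_packs_epi32(one, z8), z8);
            const int32_t mb = _mm_cvtsi128_si32(b8);
            std::memcpy(mk + t, &mb, 4);
          }
        }
      }
#endif
      for (; t < M; ++t) {
        const float h = (y[t] - m) * is;
        const float act = g * h + bt;
        const bool keep = (act > 0.0f) & (!drop_on || dm[t]);
        a[t] = keep ? act * scale : 0.0f;
        if (keep_cache) {
          xh[t] = h;
          mk[t] = keep ? 1 : 0;
        }
      }
    }

    // dilated max-pooling (window 2, stride 2) after selected blocks
    if (pool_at[i + 1]) {
      if (L - d < 1) stop("input too short for dilated pooling at block %d", i + 1);
      const int Lo = pooled_len(L, d);
      const size_t Mo = (size_t)Lo * N;
      std::vector<float> P(Mo * Cout);
      if (keep_cache) bc.pool_src.resize(Mo * Cout);
      for (int c = 0; c < Cout; ++c) {
        const float* __restrict x = Anew.data() + (size_t)c * M;
        float* __restrict y = P.data() + (size_t)c * Mo;
        int* __restrict sr = keep_cache ? bc.pool_src.data() + (size_t)c * Mo : nullptr;
        for (int n = 0; n < N; ++n) {
          const int bi = n * L, bo = n * Lo;
          for (int lo2 = 0; lo2 < Lo; ++lo2) {
            const int t1 = bi + 2 * lo2, t2 = t1 + d;
            const bool takea = x[t1] >= x[t2];
            y[bo + lo2] = takea ? x[t1] : x[t2];
            if (keep_cache) sr[bo + lo2] = takea ? t1 : t2;
          }
        }
      }
      bc.pooled = true;
      bc.L_out = Lo;
      A = std::move(P);
      L = Lo;
    } else {
      bc.L_out = L;
      A = std::move(Anew);
    }
    Cin = Cout;
  }

  // global average pooling + linear head + sigmoid
  M = (size_t)L * N;
  cache->L_final = L;
  cache->C_final = Cin;
  cache->G.assign((size_t)N * Cin, 0.0);
  for (int c = 0; c < Cin; ++c) {
    const float* __restrict x = A.data() + (size_t)c * M;
    for (int n = 0; n < N; ++n) {
      double s = 0.0;
      const float* __restrict xp = x + (size_t)n * L;
      for (int l = 0; l < L; ++l) s += xp[l];
      cache->G[(size_t)c * N + n] = s / L;
    }
  }

  const List head = params["head"];
  const NumericVector hw = head["w"];
  const double hb = as<double>(head["b"]);
  NumericVector p(N);
  cache->p.resize(N);
  for (int n = 0; n < N; ++n) {
    double z = hb;
    for (int c = 0; c < Cin; ++c) z += hw[c] * cache->G[(size_t)c * N + n];
    const double pr = 1.0 / (1.0 + std::exp(-z));
    p[n] = pr;
    cache->p[n] = pr;
  }

  return List::create(_["p"] = p, _["cache"] = cache,
                      _["run_updates"] = run_updates);
}

// Full backward pass for mean binary cross-entropy over the batch; the
// forward pass must have been run with keep_cache = TRUE in train mode.
// [[Rcpp::export]]
List nn_bwd_cpp(const List& params, const List& config, SEXP cache_ptr,
                const NumericVector& y) {
  XPtr<NetCache> cache(cache_ptr);
  const int N = cache->N;
  if (y.size() != N) stop("label length does not match cached batch");
  if (cache->blocks.empty()) stop("forward cache already consumed");
  const IntegerVector channels = config["channels_per_block"];
  const int k = config["kernel_size"];
  const int nb = channels.size();
  const List blocks = params["blocks"];
  const List head = params["head"];
  const NumericVector hw = head["w"];

  // head gradients
  const int Cf = cache->C_final;
  std::vector<double> dlogit(N);
  double dhb = 0.0;
  for (int n = 0; n < N; ++n) {
    dlogit[n] = (cache->p[n] - y[n]) / N;
    dhb += dlogit[n];
  }
  NumericVector dhw(Cf);
  for (int c = 0; c < Cf; ++c) {
    double s = 0.0;
    for (int n = 0; n < N; ++n) s += dlogit[n] * cache->G[(size_t)c * N + n];
    dhw[c] = s;
  }

  // gradient entering global average pooling
  int L = cache->L_final;
  size_t M = (size_t)L * N;
  std::vector<float> dX(M * Cf);
  for (int c = 0; c < Cf; ++c) {
    float* __restrict dx = dX.data() + (size_t)c * M;
    for (int n = 0; n < N; ++n) {
      const float v = (float)(dlogit[n] * hw[c] / L);
      float* __restrict xp = dx + (size_t)n * L;
      for (int l = 0; l < L; ++l) xp[l] = v;
    }
  }

  List grads_blocks(nb);
  const float scale = (float)cache->drop_scale;
  std::vector<float> dXin;

  for (int i = nb - 1; i >= 0; --i) {
    const BlockCache& bc = cache->blocks[i];
    const List bp = blocks[i];
    const int Cout = bc.Cout, Cin = bc.Cin;
    const size_t Min = (size_t)bc.L_in * N;

    // un-pool
    if (bc.pooled) {
      const size_t Mo = (size_t)bc.L_out * N;
      std::vector<float> dUp(Min * Cout, 0.0f);
      for (int c = 0; c < Cout; ++c) {
        const float* __restrict g = dX.data() + (size_t)c * Mo;
        const int* __restrict sr = bc.pool_src.data() + (size_t)c * Mo;
        float* __restrict d = dUp.data() + (size_t)c * Min;
        for (size_t t = 0; t < Mo; ++t) d[sr[t]] += g[t];
      }
      dX = std::move(dUp);
    }

    // fused ReLU/dropout + batch-norm backward (in place over dX)
    const NumericVector gamma = bp["gamma"];
    NumericVector dgamma(Cout), dbeta(Cout);
    for (int c = 0; c < Cout; ++c) {
      float* __restrict g = dX.data() + (size_t)c * Min;
      const float* __restrict h = bc.xhat.data() + (size_t)c * Min;
      const uint8_t* __restrict mk = bc.mask.data() + (size_t)c * Min;
      size_t t = 0;
#ifdef AFUQ_SSE2
      const __m128 sv = _mm_set1_ps(scale);
      const __m128i z8 = _mm_setzero_si128();
      __m128d sbv = _mm_setzero_pd(), sgv = _mm_setzero_pd();
      for (; t + 4 <= Min; t += 4) {
        int32_t mi;
        std::memcpy(&mi, mk + t, 4);
        const __m128i m32 =
          _mm_unpacklo_epi16(_mm_unpacklo_epi8(_mm_cvtsi32_si128(mi), z8), z8);
        const __m128 mf = _mm_cvtepi32_ps(m32); // 0.0f or 1.0f per lane
        const __m128 gm = _mm_mul_ps(_mm_mul_ps(_mm_loadu_ps(g + t), sv), mf);
        const __m128 pr = _mm_mul_ps(gm, _mm_loadu_ps(h + t));
        sbv = _mm_add_pd(sbv, _mm_cvtps_pd(gm));
        sbv = _mm_add_pd(sbv, _mm_cvtps_pd(_mm_movehl_ps(gm, gm)));
        sgv = _mm_add_pd(sgv, _mm_cvtps_pd(pr));
        sgv = _mm_add_pd(sgv, _mm_cvtps_pd(_mm_movehl_ps(pr, pr)));
      }
      double sb = hsum2d(sbv), sg = hsum2d(sgv);
      for (; t < Min; ++t) {
        const double g0 = mk[t] ? (double)g[t] * scale : 0.0;
        sb += g0; sg += g0 * h[t];
      }
#else
      double sb0 = 0.0, sb1 = 0.0, sg0 = 0.0, sg1 = 0.0;
      for (; t + 2 <= Min; t += 2) {
        const double g0 = mk[t] ? (double)g[t] * scale : 0.0;
        const double g1 = mk[t + 1] ? (double)g[t + 1] * scale : 0.0;
        sb0 += g0; sg0 += g0 * h[t];
        sb1 += g1; sg1 += g1 * h[t + 1];
      }
      if (t < Min) {
        const double g0 = mk[t] ? (double)g[t] * scale : 0.0;
        sb0 += g0; sg0 += g0 * h[t];
      }
      const double sb = sb0 + sb1, sg = sg0 + sg1;
#endif
      dbeta[c] = sb;
      dgamma[c] = sg;
      const float gam = (float)(double)gamma[c];
      const float s1 = (float)(sb * gamma[c] / (double)Min);
      const float s2 = (float)(sg * gamma[c] / (double)Min);
      const float is = (float)bc.istd[c];
      size_t u = 0;
#ifdef AFUQ_SSE2
      const __m128 gamv = _mm_set1_ps(gam), s1v = _mm_set1_ps(s1);
      const __m128 s2v = _mm_set1_ps(s2), isv = _mm_set1_ps(is);
      for (; u + 4 <= Min; u += 4) {
        int32_t mi;
        std::memcpy(&mi, mk + u, 4);
        const __m128i m32 =
          _mm_unpacklo_epi16(_mm_unpacklo_epi8(_mm_cvtsi32_si128(mi), z8), z8);
        const __m128 mf = _mm_cvtepi32_ps(m32);
        const __m128 gm = _mm_mul_ps(_mm_mul_ps(_mm_loadu_ps(g + u), sv), mf);
        const __m128 res = _mm_mul_ps(
          isv, _mm_sub_ps(_mm_sub_ps(_mm_mul_ps(gm, gamv), s1v),
                          _mm_mul_ps(_mm_loadu_ps(h + u), s2v)));
        _mm_storeu_ps(g + u, res);
      }
#endif
      for (; u < Min; ++u) {
        const float gm = mk[u] ? g[u] * scale : 0.0f;
        g[u] = is * (gm * gam - s1 - h[u] * s2);
      }
    }

    // conv backward
    const std::vector<float> W = as_float(bp["W"]);
    std::vector<double> dW((size_t)Cout * Cin * k, 0.0);
    std::vector<double> db(Cout, 0.0);
    dXin.assign(Min * Cin, 0.0f);
    conv_bwd(dX, bc.x_in, W, dXin, dW, db, Cin, Cout, k, bc.L_in, N, bc.d);

    NumericMatrix dWm(Cout, Cin * k);
    std::copy(dW.begin(), dW.end(), dWm.begin());
    NumericVector dbv(Cout);
    std::copy(db.begin(), db.end(), dbv.begin());
    grads_blocks[i] = List::create(_["W"] = dWm, _["b"] = dbv,
                                   _["gamma"] = dgamma, _["beta"] = dbeta);
    dX = std::move(dXin);
  }

  // Release the workspaces eagerly: they live on the C++ heap, so R's
  // garbage collector feels no pressure from them and would otherwise let
  // one ~100 MB cache per batch accumulate until memory runs out.
  std::vector<BlockCache>().swap(cache->blocks);
  std::vector<double>().swap(cache->G);

  NumericMatrix dhwm(1, Cf);
  std::copy(dhw.begin(), dhw.end(), dhwm.begin());
  return List::create(
    _["blocks"] = grads_blocks,
    _["head"] = List::create(_["w"] = dhwm, _["b"] = dhb)
  );
}
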