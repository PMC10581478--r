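#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of the coupled subcritical-Hopf network:
//   dz_i = [(lam_i - 1 + i*omega) z_i + 2 z_i |z_i|^2 - z_i |z_i|^4
//           + beta * sum_j A_ij (z_j - z_i)] dt + alpha dW_i
//   dlam_i = (lambda_base + lambda_ext(t) - lam_i - |z_i|^2) / tau dt
// with online hysteresis event detection on |z_i|.
//
// Forcing is zero-order hold on the grid (f_time, f_values); f_values has
// either one column (shared across nodes) or n_nodes columns. Times before
// f_time[0] take the first value, times past the end take the last.
// Events are onset times (upward crossing of onset_thr while in background);
// the background flag resets at the downward crossing of offset_thr.
// Onsets at t < 0 (burn-in) are discarded.
//
// Noise increments come from an internal xoshiro256++ generator (public
// domain, Blackman & Vigna) seeded from R's RNG stream, so set.seed()
// still governs reproducibility while the hot loop avoids the overhead of
// calling back into R's generator ~10^8 times per simulated day.

namespace {

struct Xoshiro256 {
  uint64_t s[4];
  static inline uint64_t rotl(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]
  inline double runif_oc() {
    return (double)((next() >> 11) + 1) * 0x1.0p-53;
  }
  // uniform on [0, 1)
  inline double runif_co() {
    return (double)(next() >> 11) * 0x1.0p-53;
  }
  // one pair of independent standard normals (Marsaglia polar method)
  inline void rnorm_pair(double &n1, double &n2) {
    double u, v, s;
    do {
      u = 2.0 * runif_co() - 1.0;
      v = 2.0 * runif_co() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s) / s);
    n1 = u * f;
    n2 = v * f;
  }
};

}  // namespace

// [[Rcpp::export]]
List hopf_simulate_cpp(int n_nodes, IntegerMatrix A, double omega, double beta,
                       double alpha, double tau, double lambda_base, double dt,
                       NumericVector f_time, NumericMatrix f_values,
                       double t_start, double t_end,
                       double onset_thr, double offset_thr,
                       bool record_traces, int trace_stride) {
  const int N = n_nodes;
  const R_xlen_t n_f = f_time.size();
  const bool shared_forcing = (f_values.ncol() == 1);
  if (!shared_forcing && f_values.ncol() != N)
    stop("forcing value matrix must have 1 or n_nodes columns");
  if (f_values.nrow() != n_f)
    stop("forcing time grid and value matrix differ in length");

  std::vector<double> re(N, 0.0), im(N, 0.0), lam(N, lambda_base);
  std::vector<double> fre(N), fim(N);
  std::vector<bool> in_event(N, false);
  std::vector<std::vector<double> > events(N);

  // adjacency lists (row i: targets j with A[i, j] == 1)
  std::vector<std::vector<int> > nb(N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (A(i, j) != 0) nb[i].push_back(j);

  const double sqdt = std::sqrt(dt);
  const R_xlen_t n_steps = (R_xlen_t)std::llround((t_end - t_start) / dt);

  std::vector<double> tr_t;
  std::vector<std::vector<double> > tr_re(N), tr_im(N), tr_lam(N);

  uint64_t seed64;
  {
    RNGScope rng;  // draw the stream seed from R's RNG
    const uint64_t hi = (uint64_t)std::floor(unif_rand() * 4294967296.0);
    const uint64_t lo = (uint64_t)std::floor(unif_rand() * 4294967296.0);
    seed64 = (hi << 32) | lo;
  }
  Xoshiro256 gen(seed64);

  R_xlen_t f_idx = 0;
  double t = t_start;

  for (R_xlen_t s = 0; s < n_steps; ++s, t = t_start + (double)(s) * dt) {
    // forcing lookup (zero-order hold; grid is sorted)
    while (f_idx + 1 < n_f && f_time[f_idx + 1] <= t) ++f_idx;

    // drift
    for (int i = 0; i < N; ++i) {
      const double r2 = re[i] * re[i] + im[i] * im[i];
      const double c = (lam[i] - 1.0) + 2.0 * r2 - r2 * r2;
      double cre = 0.0, cim = 0.0;
      for (size_t k = 0; k < nb[i].size(); ++k) {
        const int j = nb[i][k];
        cre += re[j] - re[i];
        cim += im[j] - im[i];
      }
      fre[i] = c * re[i] - omega * im[i] + beta * cre;
      fim[i] = c * im[i] + omega * re[i] + beta * cim;
    }

    // state update (noise after drift so all nodes see the same pre-step z)
    for (int i = 0; i < N; ++i) {
      double n1, n2;
      gen.rnorm_pair(n1, n2);
      re[i] += fre[i] * dt + alpha * n1 * sqdt;
      im[i] += fim[i] * dt + alpha * n2 * sqdt;
      const double r2 = re[i] * re[i] + im[i] * im[i];
      const double fext = shared_forcing ? f_values(f_idx, 0) : f_values(f_idx, i);
      lam[i] += dt / tau * (lambda_base + fext - lam[i] - r2);

      // hysteresis event detection on the updated amplitude
      const double amp = std::sqrt(r2);
      if (!in_event[i] && amp >= onset_thr) {
        in_event[i] = true;
        if (t >= 0.0) events[i].push_back(t);
      } else if (in_event[i] && amp <= offset_thr) {
        in_event[i] = false;
      }
    }

    if ((s & 0x3FF) == 0) {
      for (int i = 0; i < N; ++i)
        if (!R_finite(re[i]) || !R_finite(im[i]) || !R_finite(lam[i]))
          stop("non-finite state at step %td (t = %.3f s), node %d",
               (ptrdiff_t)s, t, i + 1);
    }

    if (record_traces && (s % trace_stride) == 0) {
      tr_t.push_back(t);
      for (int i = 0; i < N; ++i) {
        tr_re[i].push_back(re[i]);
        tr_im[i].push_back(im[i]);
        tr_lam[i].push_back(lam[i]);
      }
    }
  }

  List ev(N);
  for (int i = 0; i < N; ++i) ev[i] = wrap(events[i]);

  List out = List::create(_["events"] = ev,
                          _["final_re"] = wrap(re),
                          _["final_im"] = wrap(im),
                          _["final_lambda"] = wrap(lam));
  if (record_traces) {
    List tre(N), tim(N), tlam(N);
    for (int i = 0; i < N; ++i) {
      tre[i] = wrap(tr_re[i]);
      tim[i] = wrap(tr_im[i]);
      tlam[i] = wrap(tr_lam[i]);
    }
    out["trace_time"] = wrap(tr_t);
    out["trace_re"] = tre;
    out["trace_im"] = tim;
    out["trace_lambda"] = tlam;
  }
  return out;
}
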