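// Stochastic simulation engines: exact Gillespie (direct method) and
// Euler-Maruyama integration of the chemical Langevin equation for
// the three-species angiogenesis reaction network.
//
// The rate laws mirror the R implementations (log-space Hill forms).
// Randomness is fully self-contained: a splitmix64-seeded xoshiro256++
// stream per realization and an explicit Box-Muller transform, so
// ensembles are bit-reproducible for a given base seed regardless of
// platform or R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Params {
  double alpha, delta_N, K, b1, c1, a2, c2, delta_P, b3, a3, m3;
  double n, n1, n2, n3, n4, omega;
  bool conc_mode;
};

Params unpack(const List& par) {
  Params p;
  p.alpha = par["alpha"]; p.delta_N = par["delta_N"]; p.K = par["K"];
  p.b1 = par["b1"]; p.c1 = par["c1"]; p.a2 = par["a2"];
  p.c2 = par["c2"]; p.delta_P = par["delta_P"]; p.b3 = par["b3"];
  p.a3 = par["a3"]; p.m3 = par["m3"];
  p.n = par["n"]; p.n1 = par["n1"]; p.n2 = par["n2"];
  p.n3 = par["n3"]; p.n4 = par["n4"]; p.omega = par["omega"];
  p.conc_mode = as<std::string>(par["mode"]) == "concentration";
  return p;
}

inline double logistic(double z) {
  if (z >= 0.0) { double e = std::exp(-z); return 1.0 / (1.0 + e); }
  double e = std::exp(z); return e / (1.0 + e);
}
// u^m / (a^m + u^m), log-space
inline double hill_up(double u, double a, double m) {
  if (u <= 0.0) return 0.0;
  return logistic(m * (std::log(u) - std::log(a)));
}
inline double hill_down(double u, double a, double m) {
  if (u <= 0.0) return 1.0;
  return logistic(m * (std::log(a) - std::log(u)));
}

// channel rates with N, P, V in the parameters' native units; zero
// everywhere once N has been absorbed
inline void channel_rates(double N, double P, double V,
                          const Params& p, double* a) {
  if (N <= 0.0) { for (int i = 0; i < 6; ++i) a[i] = 0.0; return; }
  double E = V / N;
  double f1v = p.b1 * hill_up(E, std::pow(p.c1, 1.0 / p.n), p.n);
  double x = N / (p.K + f1v);
  a[0] = p.alpha * hill_down(x, 1.0, p.n1) * N;     // tumour birth
  a[1] = p.delta_N * hill_up(x, 1.0, p.n2) * N;     // tumour death
  a[2] = p.a2 / (1.0 + E / p.c2) * N;               // VEGF secretion
  a[3] = p.delta_P * P;                             // VEGF decay
  a[4] = p.b3 * hill_up(P, p.m3, p.n3) * V;         // vessel birth
  a[5] = p.a3 * hill_down(P, p.m3, p.n4) * V;       // vessel death
}

// ---- self-contained RNG ------------------------------------------------
inline std::uint64_t splitmix64(std::uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  std::uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  std::uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(std::uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  std::uint64_t next() {
    std::uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() {            // in (0, 1)
    return (static_cast<double>(next() >> 11) + 0.5) * 0x1.0p-53;
  }
  double norm() {            // Box-Muller
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    spare = r * std::sin(th); has_spare = true;
    return r * std::cos(th);
  }
};

inline std::uint64_t realization_seed(double base_seed, int idx) {
  std::uint64_t x = static_cast<std::uint64_t>(base_seed);
  x = x * 0x9E3779B97F4A7C15ULL + static_cast<std::uint64_t>(idx) + 1ULL;
  std::uint64_t tmp = x;
  return splitmix64(tmp);
}

}  // namespace

// Euler-Maruyama CLE for one realization.  State evolves in the
// parameters' native units (concentrations in concentration mode, in
// which case the diffusion carries the 1/sqrt(omega) prefactor).
// Absorption: a species whose update lands at or below `thr` is set
// to zero; N-absorption zeroes the whole system (state A), V-absorption
// is permanent (avascular trap).  States are recorded at `t_rec`
// (last-value carry for absorbed runs).
// [[Rcpp::export(name = ".cle_run")]]
List cle_run(List par, NumericVector y0, double t0, double t_end,
             double dt, NumericVector t_rec, double base_seed,
             int idx, double thr, double noise_scale) {
  Params p = unpack(par);
  if (dt <= 0.0) stop("dt must be positive");
  Rng rng(realization_seed(base_seed, idx));
  double N = y0[0], P = y0[1], V = y0[2];
  double pref = (p.conc_mode ? 1.0 / std::sqrt(p.omega) : 1.0)
                * noise_scale;
  int nrec = t_rec.size();
  NumericMatrix out(nrec, 3);
  int irec = 0;
  double a[6];
  bool avascular = (V <= thr);
  bool extinct = (N <= thr);
  double t_avascular = avascular ? t0 : NA_REAL;
  double t_extinct = extinct ? t0 : NA_REAL;
  if (avascular) V = 0.0;
  if (extinct) {
    N = 0.0; P = 0.0; V = 0.0;
    avascular = true;
    if (!R_finite(t_avascular)) t_avascular = t0;
  }

  long nsteps = static_cast<long>(std::ceil((t_end - t0) / dt));
  double t = t0;
  for (long step = 0; step <= nsteps; ++step) {
    while (irec < nrec && t_rec[irec] <= t + 1e-12 * std::max(1.0, t)) {
      out(irec, 0) = N; out(irec, 1) = P; out(irec, 2) = V;
      ++irec;
    }
    if (step == nsteps) break;
    double h = std::min(dt, t_end - t);
    if (h <= 0.0) break;
    channel_rates(N, P, V, p, a);
    double sq = std::sqrt(h);
    double dN = (a[0] - a[1]) * h
      + pref * std::sqrt(std::max(a[0] + a[1], 0.0)) * sq * rng.norm();
    double dP = (a[2] - a[3]) * h
      + pref * std::sqrt(std::max(a[2] + a[3], 0.0)) * sq * rng.norm();
    double dV = (a[4] - a[5]) * h
      + pref * std::sqrt(std::max(a[4] + a[5], 0.0)) * sq * rng.norm();
    N += dN; P += dP; V += dV;
    if (P < 0.0) P = 0.0;
    if (!avascular && V <= thr) {
      V = 0.0; avascular = true; t_avascular = t + h;
    }
    if (avascular) V = 0.0;
    if (!extinct && N <= thr) {
      N = 0.0; P = 0.0; V = 0.0;
      extinct = true; t_extinct = t + h;
      if (!avascular) { avascular = true; t_avascular = t + h; }
    }
    if (extinct) {
      t = t_end;                    // nothing further can happen
      break;
    }
    t += h;
  }
  while (irec < nrec) {
    out(irec, 0) = N; out(irec, 1) = P; out(irec, 2) = V;
    ++irec;
  }
  return List::create(_["states"] = out, _["extinct"] = extinct,
                      _["avascular"] = avascular,
                      _["t_extinct"] = t_extinct,
                      _["t_avascular"] = t_avascular,
                      _["final"] = NumericVector::create(N, P, V));
}

// Exact Gillespie realization over integer counts.  In concentration
// mode the propensities are omega * rate(counts / omega).  Recording
// is by last-value carry onto t_rec.
// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(List par, NumericVector y0, double t0, double t_end,
             NumericVector t_rec, double base_seed, int idx,
             double max_events) {
  Params p = unpack(par);
  Rng rng(realization_seed(base_seed, idx));
  double N = y0[0], P = y0[1], V = y0[2];
  const double om = p.conc_mode ? p.omega : 1.0;
  int nrec = t_rec.size();
  NumericMatrix out(nrec, 3);
  int irec = 0;
  double a[6], t = t0, events = 0.0;
  bool truncated = false;
  while (true) {
    channel_rates(N / om, P / om, V / om, p, a);
    double a0 = 0.0;
    for (int i = 0; i < 6; ++i) { a[i] *= om; a0 += a[i]; }
    double t_next = (a0 > 0.0) ? t - std::log(rng.unif()) / a0
                               : R_PosInf;
    while (irec < nrec && t_rec[irec] < std::min(t_next, t_end)) {
      out(irec, 0) = N; out(irec, 1) = P; out(irec, 2) = V;
      ++irec;
    }
    if (t_next >= t_end || a0 <= 0.0) break;
    t = t_next;
    double u = rng.unif() * a0, c = 0.0;
    int ch = 5;
    for (int i = 0; i < 6; ++i) { c += a[i]; if (u <= c) { ch = i; break; } }
    switch (ch) {
      case 0: N += 1; break; case 1: N -= 1; break;
      case 2: P += 1; break; case 3: P -= 1; break;
      case 4: V += 1; break; case 5: V -= 1; break;
    }
    if (++events >= max_events) { truncated = true; break; }
  }
  while (irec < nrec) {
    out(irec, 0) = N; out(irec, 1) = P; out(irec, 2) = V;
    ++irec;
  }
  return List::create(_["states"] = out,
                      _["extinct"] = (N <= 0.0),
                      _["avascular"] = (V <= 0.0),
                      _["events"] = events,
                      _["truncated"] = truncated,
                      _["final"] = NumericVector::create(N, P, V));
}

// Compiled right-hand side for deSolve: parameter vector order
// (alpha, delta_N, K, b1, c1, a2, c2, delta_P, b3, a3, m3,
//  n, n1, n2, n3, n4).  Units-native, so the same code serves both
// modes.  Negative excursions are clamped to zero for rate evaluation;
// an absorbed state (N <= 0) has zero derivative.
static double ak_ode_parms[16];

extern "C" {

void ak_ode_init(void (*odeparms)(int*, double*)) {
  int n = 16;
  odeparms(&n, ak_ode_parms);
}

void ak_ode_rhs(int* /*neq*/, double* /*t*/, double* y, double* ydot,
                double* /*yout*/, int* /*ip*/) {
  Params p;
  p.alpha = ak_ode_parms[0]; p.delta_N = ak_ode_parms[1];
  p.K = ak_ode_parms[2]; p.b1 = ak_ode_parms[3];
  p.c1 = ak_ode_parms[4]; p.a2 = ak_ode_parms[5];
  p.c2 = ak_ode_parms[6]; p.delta_P = ak_ode_parms[7];
  p.b3 = ak_ode_parms[8]; p.a3 = ak_ode_parms[9];
  p.m3 = ak_ode_parms[10];
  p.n = ak_ode_parms[11]; p.n1 = ak_ode_parms[12];
  p.n2 = ak_ode_parms[13]; p.n3 = ak_ode_parms[14];
  p.n4 = ak_ode_parms[15];
  p.omega = 1.0; p.conc_mode = false;
  double N = y[0] > 0.0 ? y[0] : 0.0;
  double P = y[1] > 0.0 ? y[1] : 0.0;
  double V = y[2] > 0.0 ? y[2] : 0.0;
  double a[6];
  channel_rates(N, P, V, p, a);
  ydot[0] = a[0] - a[1];
  ydot[1] = a[2] - a[3];
  ydot[2] = a[4] - a[5];
}

}  // extern "C"

// deSolve locates ak_ode_rhs / ak_ode_init by dynamic symbol lookup,
// which the generated registration turns off; turn it back on.
// [[Rcpp::init]]
void ak_enable_dynamic_lookup(DllInfo* dll) {
  R_useDynamicSymbols(dll, TRUE);
}

// Channel rates exposed for cross-checking against the R rate laws.
// [[Rcpp::export(name = ".rates_cpp")]]
NumericVector rates_cpp(List par, double N, double P, double V) {
  Params p = unpack(par);
  double a[6];
  channel_rates(N, P, V, p, a);
  return NumericVector(a, a + 6);
}
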