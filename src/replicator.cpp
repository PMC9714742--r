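// Core engine for compartmentalized host-parasite replicator simulations.
//
// Layout conventions shared with the R side:
//  * population matrices are C x m (compartments x species), column-major
//  * coefficient matrices K are m x m with K[j, i] = rate with which
//    replicase from species j copies template species i; parasite rows are 0
//  * all stochastic entry points take an explicit integer seed; randomness
//    never touches R's global RNG

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <array>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded through splitmix64. Binomial(n, 1/2) draws are
// exact popcounts of random bits, which is what fusion-division needs.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
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

  inline double unif() {  // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }

  inline double range(double lo, double hi) {
    return lo + (hi - lo) * unif();
  }

  inline int unif_int(int n) {  // uniform on {0, ..., n-1}, Lemire rejection
    uint64_t x = next();
    __uint128_t m = (__uint128_t)x * (uint64_t)n;
    uint64_t l = (uint64_t)m;
    if (l < (uint64_t)n) {
      uint64_t t = (-(uint64_t)n) % (uint64_t)n;
      while (l < t) {
        x = next();
        m = (__uint128_t)x * (uint64_t)n;
        l = (uint64_t)m;
      }
    }
    return (int)(m >> 64);
  }

  inline int binom_half(int n) {  // Binomial(n, 1/2)
    int c = 0;
    while (n >= 64) {
      c += __builtin_popcountll(next());
      n -= 64;
    }
    if (n > 0) c += __builtin_popcountll(next() & ((1ULL << n) - 1ULL));
    return c;
  }
};

static inline uint64_t splitmix_once(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Deterministic sub-stream derivation: seeds for (cell, run) work units are
// pure functions of the master seed so execution order never matters.
// [[Rcpp::export]]
double cpp_mix_seed(double master, double a, double b) {
  uint64_t x = (uint64_t)master;
  x = splitmix_once(x ^ (0x9e3779b97f4a7c15ULL * (uint64_t)(a + 1)));
  x = splitmix_once(x ^ (0xbf58476d1ce4e5b9ULL * (uint64_t)(b + 1)));
  // keep within the positive 31-bit range so R can store it as an integer
  return (double)((x >> 33) & 0x7fffffffULL);
}

// ---------------------------------------------------------------------------
// Within-compartment dynamics: coupled logistic cross-replication
//   dx_i/dt = x_i * (sum_j host K[j,i] x_j) * (1 - sum(x)/N)
// integrated with an adaptive Dormand-Prince 5(4) pair.
// ---------------------------------------------------------------------------

#define MAXM 8  // species per compartment is tiny (<= 3 in all study designs)

static inline void rhs(const double* x, double* f, int m, const double* K,
                       const char* host, double N) {
  double s = 0.0;
  for (int i = 0; i < m; ++i) s += x[i];
  const double g = 1.0 - s / N;
  for (int i = 0; i < m; ++i) {
    double r = 0.0;
    for (int j = 0; j < m; ++j)
      if (host[j]) r += K[j + i * m] * x[j];
    f[i] = x[i] * r * g;
  }
}

// returns 0 on success, >0 on numerical failure
static int integrate_dp5(double* x, int m, const double* K, const char* host,
                         double N, double T, double rtol, double atol) {
  double k1[MAXM], k2[MAXM], k3[MAXM], k4[MAXM], k5[MAXM], k6[MAXM], k7[MAXM];
  double xt[MAXM], xn[MAXM];

  rhs(x, k1, m, K, host, N);
  double maxf = 0.0, maxx = 0.0;
  for (int i = 0; i < m; ++i) {
    maxf = std::max(maxf, std::fabs(k1[i]));
    maxx = std::max(maxx, std::fabs(x[i]));
  }
  if (maxf == 0.0) return 0;  // fixed point (empty, host-free, or at capacity)

  double t = 0.0;
  double h = std::min(T, 0.01 * std::max(1.0, maxx) / maxf);
  if (h <= 0.0 || !std::isfinite(h)) h = 1e-6;
  long nsteps = 0;

  while (t < T) {
    if (t + h > T) h = T - t;

    for (int i = 0; i < m; ++i) xt[i] = x[i] + h * (0.2 * k1[i]);
    rhs(xt, k2, m, K, host, N);
    for (int i = 0; i < m; ++i)
      xt[i] = x[i] + h * (3.0 / 40.0 * k1[i] + 9.0 / 40.0 * k2[i]);
    rhs(xt, k3, m, K, host, N);
    for (int i = 0; i < m; ++i)
      xt[i] = x[i] + h * (44.0 / 45.0 * k1[i] - 56.0 / 15.0 * k2[i] +
                          32.0 / 9.0 * k3[i]);
    rhs(xt, k4, m, K, host, N);
    for (int i = 0; i < m; ++i)
      xt[i] = x[i] + h * (19372.0 / 6561.0 * k1[i] - 25360.0 / 2187.0 * k2[i] +
                          64448.0 / 6561.0 * k3[i] - 212.0 / 729.0 * k4[i]);
    rhs(xt, k5, m, K, host, N);
    for (int i = 0; i < m; ++i)
      xt[i] = x[i] + h * (9017.0 / 3168.0 * k1[i] - 355.0 / 33.0 * k2[i] +
                          46732.0 / 5247.0 * k3[i] + 49.0 / 176.0 * k4[i] -
                          5103.0 / 18656.0 * k5[i]);
    rhs(xt, k6, m, K, host, N);
    for (int i = 0; i < m; ++i)
      xn[i] = x[i] + h * (35.0 / 384.0 * k1[i] + 500.0 / 1113.0 * k3[i] +
                          125.0 / 192.0 * k4[i] - 2187.0 / 6784.0 * k5[i] +
                          11.0 / 84.0 * k6[i]);
    rhs(xn, k7, m, K, host, N);

    double errnorm = 0.0;
    bool finite = true;
    for (int i = 0; i < m; ++i) {
      const double e =
          h * (71.0 / 57600.0 * k1[i] - 71.0 / 16695.0 * k3[i] +
               71.0 / 1920.0 * k4[i] - 17253.0 / 339200.0 * k5[i] +
               22.0 / 525.0 * k6[i] - 1.0 / 40.0 * k7[i]);
      const double sc =
          atol + rtol * std::max(std::fabs(x[i]), std::fabs(xn[i]));
      if (!std::isfinite(xn[i]) || !std::isfinite(e)) finite = false;
      const double q = e / sc;
      errnorm += q * q;
    }
    errnorm = std::sqrt(errnorm / m);

    if (!finite) {
      h *= 0.5;
      if (h < 1e-14) return 1;
      continue;
    }

    if (errnorm <= 1.0) {
      t += h;
      maxf = 0.0;
      for (int i = 0; i < m; ++i) {
        x[i] = xn[i] > 0.0 ? xn[i] : 0.0;
        k1[i] = k7[i];
        maxf = std::max(maxf, std::fabs(k1[i]));
      }
      // once the compartment has saturated the solution is flat; stop when
      // the largest possible remaining change is far below the tolerance
      if (maxf * (T - t) < 0.01 * atol) break;
      double fac = errnorm < 1e-10 ? 10.0 : 0.9 * std::pow(errnorm, -0.2);
      h *= std::min(10.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
      if (h < 1e-14) return 1;
    }
    if (++nsteps > 2000000) return 2;
  }
  return 0;
}

// Memo table for the continuous replication map. For a fixed coefficient
// matrix the ODE solution is a deterministic function of the integer initial
// counts, and compartment states repeat heavily across rounds, so caching the
// continuous endpoint (before the stochastic rounding draw) removes most
// integrations without changing any result bit.
typedef std::unordered_map<uint64_t, std::array<double, MAXM> > OdeCache;

static inline bool cache_key(const int* x, int m, uint64_t& key) {
  if (m > 3) return false;
  key = 0;
  for (int i = 0; i < m; ++i) {
    if (x[i] < 0 || x[i] >= (1 << 21)) return false;
    key |= (uint64_t)x[i] << (21 * i);
  }
  return true;
}

// rounding modes: 0 = stochastic (floor + Bernoulli on fraction), 1 = nearest
static inline int discretize_one(double v, int mode, Xoshiro& rng) {
  if (v <= 0.0) return 0;
  if (mode == 1) return (int)std::llround(v);
  double fl = std::floor(v);
  int n = (int)fl;
  double frac = v - fl;
  if (frac > 0.0 && rng.unif() < frac) ++n;
  return n;
}

// [[Rcpp::export]]
NumericVector cpp_integrate(NumericVector x0, NumericMatrix K,
                            LogicalVector is_host, double N, double T,
                            double rtol, double atol) {
  const int m = x0.size();
  if (m > MAXM) stop("at most %d species per compartment are supported", MAXM);
  double x[MAXM];
  char host[MAXM];
  for (int i = 0; i < m; ++i) {
    x[i] = x0[i];
    host[i] = is_host[i] ? 1 : 0;
  }
  int status = integrate_dp5(x, m, K.begin(), host, N, T, rtol, atol);
  if (status != 0)
    stop("ODE integration failed (status %d) for compartment state", status);
  NumericVector out(m);
  for (int i = 0; i < m; ++i) out[i] = x[i];
  out.names() = colnames(K);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_discretize(NumericVector x, int mode, double seed) {
  Xoshiro rng((uint64_t)seed);
  IntegerVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = discretize_one(x[i], mode, rng);
  out.names() = x.names();
  return out;
}

// ---------------------------------------------------------------------------
// Population-level steps
// ---------------------------------------------------------------------------

// replicate every compartment; returns new counts and per-compartment
// replication tallies max(new - old, 0)
static int replicate_all(std::vector<int>& pop, std::vector<int>& repl, int C,
                         int m, const double* K, const char* host, double N,
                         double T, double rtol, double atol, int rounding,
                         Xoshiro& rng, int* bad_comp, OdeCache* cache = 0) {
  double x[MAXM];
  int x0[MAXM];
  const int iN = (int)N;
  const bool N_integer = (std::floor(N) == N);
  for (int c = 0; c < C; ++c) {
    int s = 0;
    bool has_host = false;
    for (int k = 0; k < m; ++k) {
      const int v = pop[c + k * C];
      s += v;
      if (host[k] && v > 0) has_host = true;
    }
    for (int k = 0; k < m; ++k) repl[c + k * C] = 0;
    if (s == 0 || !has_host) continue;
    if (N_integer && s == iN) continue;  // logistic factor exactly zero

    uint64_t key = 0;
    bool keyed = false;
    if (cache) {
      for (int k = 0; k < m; ++k) x0[k] = pop[c + k * C];
      keyed = cache_key(x0, m, key);
      if (keyed) {
        OdeCache::const_iterator it = cache->find(key);
        if (it != cache->end()) {
          for (int k = 0; k < m; ++k) x[k] = it->second[k];
          for (int k = 0; k < m; ++k) {
            const int old = pop[c + k * C];
            const int nv = old == 0 ? 0 : discretize_one(x[k], rounding, rng);
            pop[c + k * C] = nv;
            repl[c + k * C] = nv > old ? nv - old : 0;
          }
          continue;
        }
      }
    }

    for (int k = 0; k < m; ++k) x[k] = (double)pop[c + k * C];
    int status = integrate_dp5(x, m, K, host, N, T, rtol, atol);
    if (status != 0) {
      if (bad_comp) *bad_comp = c + 1;
      return status;
    }
    if (cache && keyed) {
      if (cache->size() > 4000000) cache->clear();  // bound memory
      std::array<double, MAXM> v;
      v.fill(0.0);
      for (int k = 0; k < m; ++k) v[k] = x[k];
      (*cache)[key] = v;
    }
    for (int k = 0; k < m; ++k) {
      const int old = pop[c + k * C];
      const int nv = old == 0 ? 0 : discretize_one(x[k], rounding, rng);
      pop[c + k * C] = nv;
      repl[c + k * C] = nv > old ? nv - old : 0;
    }
  }
  return 0;
}

static void cull_pop(std::vector<int>& pop, int C, int m, int n_keep,
                     Xoshiro& rng, std::vector<int>& idx,
                     std::vector<char>& keep) {
  if (n_keep >= C) return;
  idx.resize(C);
  keep.assign(C, 0);
  for (int i = 0; i < C; ++i) idx[i] = i;
  for (int i = 0; i < n_keep; ++i) {  // partial Fisher-Yates
    int j = i + rng.unif_int(C - i);
    std::swap(idx[i], idx[j]);
    keep[idx[i]] = 1;
  }
  for (int c = 0; c < C; ++c)
    if (!keep[c])
      for (int k = 0; k < m; ++k) pop[c + k * C] = 0;
}

static void fuse_divide(std::vector<int>& pop, int C, int m, int times,
                        Xoshiro& rng) {
  for (int it = 0; it < times; ++it) {
    int a = rng.unif_int(C);
    int b = rng.unif_int(C - 1);
    if (b >= a) ++b;
    for (int k = 0; k < m; ++k) {
      const int na = pop[a + k * C], nb = pop[b + k * C];
      const int n = na + nb;
      if (n == 0) continue;
      const int x = rng.binom_half(n);
      pop[a + k * C] = x;
      pop[b + k * C] = n - x;
    }
  }
}

static std::vector<int> mat_to_vec(const IntegerMatrix& M) {
  return std::vector<int>(M.begin(), M.end());
}

static IntegerMatrix vec_to_mat(const std::vector<int>& v, int C, int m,
                                SEXP dimnames_src) {
  IntegerMatrix out(C, m);
  std::copy(v.begin(), v.end(), out.begin());
  if (dimnames_src != R_NilValue) out.attr("dimnames") = dimnames_src;
  return out;
}

// [[Rcpp::export]]
List cpp_replicate_population(IntegerMatrix pop, NumericMatrix K,
                              LogicalVector is_host, double N, double T,
                              double rtol, double atol, int rounding,
                              double seed) {
  const int C = pop.nrow(), m = pop.ncol();
  if (m > MAXM) stop("at most %d species are supported", MAXM);
  Xoshiro rng((uint64_t)seed);
  char host[MAXM];
  for (int k = 0; k < m; ++k) host[k] = is_host[k] ? 1 : 0;
  std::vector<int> p = mat_to_vec(pop), repl(C * m, 0);
  int bad = 0;
  int status = replicate_all(p, repl, C, m, K.begin(), host, N, T, rtol, atol,
                             rounding, rng, &bad);
  if (status != 0)
    stop("non-finite ODE output in compartment %d (status %d)", bad, status);
  SEXP dn = pop.attr("dimnames");
  return List::create(_["pop"] = vec_to_mat(p, C, m, dn),
                      _["replicated"] = vec_to_mat(repl, C, m, dn));
}

// [[Rcpp::export]]
IntegerMatrix cpp_cull(IntegerMatrix pop, int n_keep, double seed) {
  const int C = pop.nrow(), m = pop.ncol();
  Xoshiro rng((uint64_t)seed);
  std::vector<int> p = mat_to_vec(pop), idx;
  std::vector<char> keep;
  cull_pop(p, C, m, n_keep, rng, idx, keep);
  return vec_to_mat(p, C, m, pop.attr("dimnames"));
}

// [[Rcpp::export]]
IntegerMatrix cpp_fuse_divide(IntegerMatrix pop, int times, double seed) {
  const int C = pop.nrow(), m = pop.ncol();
  if (C < 2) stop("fusion-division requires at least two compartments");
  Xoshiro rng((uint64_t)seed);
  std::vector<int> p = mat_to_vec(pop);
  fuse_divide(p, C, m, times, rng);
  return vec_to_mat(p, C, m, pop.attr("dimnames"));
}

// [[Rcpp::export]]
List cpp_run_simulation(IntegerMatrix init_pop, NumericMatrix K,
                        LogicalVector is_host, double S, int A, int rounds,
                        double N, double T, double rtol, double atol,
                        int rounding, double seed) {
  const int C = init_pop.nrow(), m = init_pop.ncol();
  if (m > MAXM) stop("at most %d species are supported", MAXM);
  Xoshiro rng((uint64_t)seed);
  char host[MAXM];
  for (int k = 0; k < m; ++k) host[k] = is_host[k] ? 1 : 0;
  std::vector<int> pop = mat_to_vec(init_pop), repl(C * m, 0), idx;
  std::vector<char> keep;
  const int n_keep = (int)std::floor((double)C * S);

  IntegerMatrix traj(rounds, m);
  OdeCache cache;  // K is fixed for the whole run
  for (int r = 0; r < rounds; ++r) {
    int bad = 0;
    int status = replicate_all(pop, repl, C, m, K.begin(), host, N, T, rtol,
                               atol, rounding, rng, &bad, &cache);
    if (status != 0)
      stop("non-finite ODE output in compartment %d, round %d", bad, r + 1);
    cull_pop(pop, C, m, n_keep, rng, idx, keep);
    fuse_divide(pop, C, m, A, rng);
    bool any = false;
    for (int k = 0; k < m; ++k) {
      long tot = 0;
      for (int c = 0; c < C; ++c) tot += pop[c + k * C];
      traj(r, k) = (int)tot;
      if (tot > 0) any = true;
    }
    if (!any) {  // extinct: remaining rounds stay at zero
      for (int r2 = r + 1; r2 < rounds; ++r2)
        for (int k = 0; k < m; ++k) traj(r2, k) = 0;
      break;
    }
  }
  colnames(traj) = colnames(K);
  return List::create(_["pop"] = vec_to_mat(pop, C, m, init_pop.attr("dimnames")),
                      _["trajectory"] = traj);
}

// ---------------------------------------------------------------------------
// Mutation step (evolutionary simulation)
// ---------------------------------------------------------------------------

// collect firing compartments for the two candidate classes; scan is
// compartment-major so "who fired first" is well defined
static void collect_firings(const int* prev_repl, const int* role, int C, int m,
                            double rate_hh, double rate_ph, double rate_pp,
                            Xoshiro& rng, std::vector<int>& host_comps,
                            std::vector<int>& par_comps, long& host_first,
                            long& par_first) {
  host_first = par_first = -1;
  long seq = 0;
  for (int c = 0; c < C; ++c) {
    for (int s = 0; s < m; ++s) {
      const int n = prev_repl[c + s * C];
      if (n <= 0) continue;
      if (role[s] == 0) {  // host parent: may spawn a new host or parasite
        double p = std::min(1.0, n * rate_hh);
        if (p > 0.0 && rng.unif() < p) {
          if (host_first < 0) host_first = seq;
          host_comps.push_back(c);
        }
        ++seq;
        p = std::min(1.0, n * rate_ph);
        if (p > 0.0 && rng.unif() < p) {
          if (par_first < 0) par_first = seq;
          par_comps.push_back(c);
        }
        ++seq;
      } else {  // parasite parent: may spawn a new parasite
        const double p = std::min(1.0, n * rate_pp);
        if (p > 0.0 && rng.unif() < p) {
          if (par_first < 0) par_first = seq;
          par_comps.push_back(c);
        }
        ++seq;
      }
    }
  }
}

// draw the complete coefficient set for a new species given the indices of
// the pre-existing species; `set(j, i, k)` stores k for replicase j on
// template i. Hosts draw from [host_lo, host_hi] for host templates and
// [par_lo, par_hi] for parasite templates; parasites are never replicase.
template <typename Setter>
static void draw_new_coeffs(int ni, int new_role,
                            const std::vector<int>& existing, const int* role,
                            double hlo, double hhi, double plo, double phi,
                            Xoshiro& rng, Setter set) {
  if (new_role == 0) {
    set(ni, ni, rng.range(hlo, hhi));  // self-replication
    for (size_t e = 0; e < existing.size(); ++e) {
      const int j = existing[e];
      if (role[j] == 0) set(j, ni, rng.range(hlo, hhi));
    }
    for (size_t e = 0; e < existing.size(); ++e) {
      const int t = existing[e];
      set(ni, t, role[t] == 0 ? rng.range(hlo, hhi) : rng.range(plo, phi));
    }
  } else {
    for (size_t e = 0; e < existing.size(); ++e) {
      const int j = existing[e];
      if (role[j] == 0) set(j, ni, rng.range(plo, phi));
    }
  }
}

// [[Rcpp::export]]
List cpp_mutation_step(IntegerMatrix pop, IntegerVector roles, NumericMatrix K,
                       IntegerMatrix prev_repl, double rate_hh, double rate_ph,
                       double rate_pp, double host_lo, double host_hi,
                       double par_lo, double par_hi, int cap, int seed_all,
                       double seed) {
  const int C = pop.nrow(), m = pop.ncol();
  Xoshiro rng((uint64_t)seed);

  if (m >= cap || m == 0) {
    return List::create(_["pop"] = pop, _["roles"] = roles, _["K"] = K,
                        _["new_roles"] = IntegerVector(0),
                        _["n_seeded"] = IntegerVector(0));
  }

  std::vector<int> host_comps, par_comps;
  long host_first, par_first;
  std::vector<int> role_v(roles.begin(), roles.end());
  collect_firings(prev_repl.begin(), role_v.data(), C, m, rate_hh, rate_ph,
                  rate_pp, rng, host_comps, par_comps, host_first, par_first);

  // creation order follows firing order; stop when the species cap is hit
  std::vector<int> order;  // 0 = new host, 1 = new parasite
  if (host_first >= 0 && par_first >= 0) {
    if (host_first < par_first) {
      order.push_back(0);
      order.push_back(1);
    } else {
      order.push_back(1);
      order.push_back(0);
    }
  } else if (host_first >= 0) {
    order.push_back(0);
  } else if (par_first >= 0) {
    order.push_back(1);
  }

  int n_new = 0;
  int cur = m;
  std::vector<int> created_roles;
  std::vector<std::vector<int>*> created_comps;
  for (size_t q = 0; q < order.size() && cur < cap; ++q) {
    created_roles.push_back(order[q]);
    created_comps.push_back(order[q] == 0 ? &host_comps : &par_comps);
    ++cur;
    ++n_new;
  }

  const int m2 = m + n_new;
  IntegerMatrix pop2(C, m2);
  for (int k = 0; k < m; ++k)
    for (int c = 0; c < C; ++c) pop2(c, k) = pop(c, k);
  NumericMatrix K2(m2, m2);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) K2(j, i) = K(j, i);
  IntegerVector roles2(m2);
  std::vector<int> role2_v(m2);
  for (int k = 0; k < m; ++k) role2_v[k] = roles[k];

  std::vector<int> existing;
  for (int k = 0; k < m; ++k) existing.push_back(k);
  IntegerVector n_seeded(n_new);
  for (int q = 0; q < n_new; ++q) {
    const int ni = m + q;
    role2_v[ni] = created_roles[q];
    draw_new_coeffs(ni, created_roles[q], existing, role2_v.data(), host_lo,
                    host_hi, par_lo, par_hi, rng,
                    [&](int j, int i, double k) { K2(j, i) = k; });
    const std::vector<int>& comps = *created_comps[q];
    if (seed_all) {
      for (size_t t = 0; t < comps.size(); ++t) pop2(comps[t], ni) += 1;
      n_seeded[q] = (int)comps.size();
    } else {  // one founding copy, in one of the firing compartments
      pop2(comps[rng.unif_int((int)comps.size())], ni) += 1;
      n_seeded[q] = 1;
    }
    existing.push_back(ni);
  }
  for (int k = 0; k < m2; ++k) roles2[k] = role2_v[k];

  IntegerVector new_roles(n_new);
  for (int q = 0; q < n_new; ++q) new_roles[q] = created_roles[q];
  return List::create(_["pop"] = pop2, _["roles"] = roles2, _["K"] = K2,
                      _["new_roles"] = new_roles, _["n_seeded"] = n_seeded);
}

// ---------------------------------------------------------------------------
// Full evolutionary run: mutation -> replication -> culling -> fusion-division
// per round, with species bookkeeping in a fixed set of slots (cap <= MAXM).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_evolution(int C, double S, int A, int rounds, double N, double T,
                       double rtol, double atol, int rounding, double rate_hh,
                       double rate_ph, double rate_pp, double host_lo,
                       double host_hi, double par_lo, double par_hi, int cap,
                       double founder_k, int seed_all, double seed) {
  if (cap < 1 || cap > MAXM) stop("species cap must be between 1 and %d", MAXM);
  Xoshiro rng((uint64_t)seed);
  const int M = cap;

  std::vector<int> pop(C * M, 0), repl(C * M, 0), prev_repl(C * M, 0), idx;
  std::vector<char> keep;
  std::vector<char> active(M, 0);
  std::vector<int> slot_sid(M, 0), slot_role(M, 0);
  std::vector<double> K(M * M, 0.0);
  char host_flag[MAXM];

  // species log (global ids, 1-based)
  std::vector<int> sp_id, sp_role, sp_birth;
  // pairwise coefficient log: every draw ever made, by global species id
  std::vector<int> co_rep, co_tmpl;
  std::vector<double> co_k;
  // appearance events
  std::vector<int> ev_round, ev_id, ev_role, ev_seeded;
  // per-round totals of live species
  std::vector<int> log_round, log_id, log_total;

  int next_id = 1;

  // founder: one host filling every compartment to carrying capacity
  active[0] = 1;
  slot_sid[0] = next_id;
  slot_role[0] = 0;
  K[0] = founder_k;
  sp_id.push_back(next_id);
  sp_role.push_back(0);
  sp_birth.push_back(0);
  co_rep.push_back(next_id);
  co_tmpl.push_back(next_id);
  co_k.push_back(founder_k);
  ++next_id;
  const int fill = (int)std::floor(N);
  for (int c = 0; c < C; ++c) pop[c] = fill;

  const int n_keep = (int)std::floor((double)C * S);
  int n_active = 1;
  int extinct_round = NA_INTEGER;
  OdeCache cache;  // invalidated whenever K changes (appearance/extinction)

  for (int r = 1; r <= rounds; ++r) {
    // --- mutation (uses the previous round's replication tallies) ---
    if (r > 1 && n_active >= 1 && n_active < cap) {
      // compact views over active slots, in slot order
      std::vector<int> act;
      for (int s = 0; s < M; ++s)
        if (active[s]) act.push_back(s);
      const int ma = (int)act.size();
      std::vector<int> prc(C * ma), rl(ma);
      for (int k = 0; k < ma; ++k) {
        rl[k] = slot_role[act[k]];
        const int col = act[k] * C;
        for (int c = 0; c < C; ++c) prc[c + k * C] = prev_repl[c + col];
      }
      std::vector<int> host_comps, par_comps;
      long host_first, par_first;
      collect_firings(prc.data(), rl.data(), C, ma, rate_hh, rate_ph, rate_pp,
                      rng, host_comps, par_comps, host_first, par_first);
      std::vector<int> order;
      if (host_first >= 0 && par_first >= 0) {
        if (host_first < par_first) {
          order.push_back(0);
          order.push_back(1);
        } else {
          order.push_back(1);
          order.push_back(0);
        }
      } else if (host_first >= 0) {
        order.push_back(0);
      } else if (par_first >= 0) {
        order.push_back(1);
      }
      for (size_t q = 0; q < order.size() && n_active < cap; ++q) {
        const int new_role = (int)order[q];
        // allocate a free slot
        int ns = -1;
        for (int s = 0; s < M; ++s)
          if (!active[s]) {
            ns = s;
            break;
          }
        std::vector<int> existing;
        for (int s = 0; s < M; ++s)
          if (active[s]) existing.push_back(s);
        active[ns] = 1;
        slot_sid[ns] = next_id;
        slot_role[ns] = new_role;
        for (int s = 0; s < M; ++s) {  // clear any stale entries
          K[ns + s * M] = 0.0;
          K[s + ns * M] = 0.0;
        }
        draw_new_coeffs(ns, new_role, existing, slot_role.data(), host_lo,
                        host_hi, par_lo, par_hi, rng,
                        [&](int j, int i, double k) {
                          K[j + i * M] = k;
                          co_rep.push_back(slot_sid[j]);
                          co_tmpl.push_back(slot_sid[i]);
                          co_k.push_back(k);
                        });
        const std::vector<int>& comps =
            new_role == 0 ? host_comps : par_comps;
        int seeded;
        if (seed_all) {
          for (size_t t = 0; t < comps.size(); ++t)
            pop[comps[t] + ns * C] += 1;
          seeded = (int)comps.size();
        } else {  // one founding copy, in one of the firing compartments
          pop[comps[rng.unif_int((int)comps.size())] + ns * C] += 1;
          seeded = 1;
        }
        for (int c = 0; c < C; ++c) prev_repl[c + ns * C] = 0;
        sp_id.push_back(next_id);
        sp_role.push_back(new_role);
        sp_birth.push_back(r);
        ev_round.push_back(r);
        ev_id.push_back(next_id);
        ev_role.push_back(new_role);
        ev_seeded.push_back(seeded);
        ++next_id;
        ++n_active;
        cache.clear();
      }
    }

    // --- replication (over all slots; inactive slots are all-zero) ---
    for (int s = 0; s < M; ++s) host_flag[s] = (slot_role[s] == 0) ? 1 : 0;
    int bad = 0;
    int status = replicate_all(pop, repl, C, M, K.data(), host_flag, N, T,
                               rtol, atol, rounding, rng, &bad, &cache);
    if (status != 0)
      stop("non-finite ODE output in compartment %d, round %d", bad, r);
    std::swap(prev_repl, repl);

    // --- culling, fusion-division ---
    cull_pop(pop, C, M, n_keep, rng, idx, keep);
    fuse_divide(pop, C, M, A, rng);

    // --- bookkeeping: totals, extinctions ---
    for (int s = 0; s < M; ++s) {
      if (!active[s]) continue;
      long tot = 0;
      const int col = s * C;
      for (int c = 0; c < C; ++c) tot += pop[c + col];
      if (tot == 0) {
        active[s] = 0;
        --n_active;
        for (int t = 0; t < M; ++t) {
          K[s + t * M] = 0.0;
          K[t + s * M] = 0.0;
        }
        for (int c = 0; c < C; ++c) prev_repl[c + col] = 0;
        cache.clear();
      } else {
        log_round.push_back(r);
        log_id.push_back(slot_sid[s]);
        log_total.push_back((int)tot);
      }
    }
    if (n_active == 0) {
      extinct_round = r;
      break;
    }
  }

  return List::create(
      _["totals"] = DataFrame::create(_["round"] = log_round,
                                      _["species_id"] = log_id,
                                      _["total"] = log_total),
      _["species"] = DataFrame::create(_["species_id"] = sp_id,
                                       _["role"] = sp_role,
                                       _["birth_round"] = sp_birth),
      _["coeffs"] = DataFrame::create(_["replicase_id"] = co_rep,
                                      _["template_id"] = co_tmpl,
                                      _["k"] = co_k),
      _["events"] = DataFrame::create(_["round"] = ev_round,
                                      _["species_id"] = ev_id,
                                      _["role"] = ev_role,
                                      _["n_seeded"] = ev_seeded),
      _["extinct_round"] = extinct_round);
}
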