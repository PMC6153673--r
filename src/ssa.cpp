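#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// PCG32 (O'Neill): counter-based-style generator with independent streams.
// One stream per replicate so estimates are reproducible and extensible in
// n_runs without correlating earlier replicates.
struct Pcg32 {
  uint64_t state;
  uint64_t inc;
  Pcg32(uint64_t seed, uint64_t stream) {
    state = 0u;
    inc = (stream << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  // uniform in (0, 1): never returns 0 (safe for log())
  double runif() {
    return (next() + 1.0) * (1.0 / 4294967297.0);
  }
  double rnorm() {
    // Box-Muller, first component only (simplicity over speed)
    double u1 = runif(), u2 = runif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

struct SsaParams {
  double bX, bY, gX, gY, aM, bM, cM, dM;
  bool distinct_pairs; // X(X-1) vs X^2 intra-type counting
};

static inline void propensities(const SsaParams &pr, double X, double Y,
                                double *w) {
  double XX = pr.distinct_pairs ? X * (X - 1.0) : X * X;
  double YY = pr.distinct_pairs ? Y * (Y - 1.0) : Y * Y;
  w[0] = pr.bX * X;        // X -> 2X
  w[1] = pr.bY * Y;        // Y -> 2Y
  w[2] = pr.gX * X;        // X -> 0
  w[3] = pr.gY * Y;        // Y -> 0
  w[4] = XX / pr.aM;       // X+X -> X   (removes one X)
  w[5] = X * Y / pr.bM;    // X+Y -> Y   (removes one X)
  w[6] = X * Y / pr.cM;    // X+Y -> X   (removes one Y)
  w[7] = YY / pr.dM;       // Y+Y -> Y   (removes one Y)
}

static const int dX_of[8] = {+1, 0, -1, 0, -1, -1, 0, 0};
static const int dY_of[8] = {0, +1, 0, -1, 0, 0, -1, -1};

static SsaParams make_params(List spec, bool distinct_pairs) {
  SsaParams pr;
  double M = as<double>(spec["M"]);
  pr.bX = as<double>(spec["beta_X"]);
  pr.bY = as<double>(spec["beta_Y"]);
  pr.gX = as<double>(spec["gamma_X"]);
  pr.gY = as<double>(spec["gamma_Y"]);
  pr.aM = as<double>(spec["a"]) * M;
  pr.bM = as<double>(spec["b"]) * M;
  pr.cM = as<double>(spec["c"]) * M;
  pr.dM = as<double>(spec["d"]) * M;
  pr.distinct_pairs = distinct_pairs;
  return pr;
}

// Single trajectory to absorption (X == 0 or Y == 0) by the direct method.
// outcome: 1 fixation, 0 loss, 2 timeout (max_events or t_max hit).
// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(List spec, double X0, double Y0,
                 double seed, double stream,
                 double max_events, double t_max,
                 bool record, int thin, bool distinct_pairs,
                 double avg_t0 = -1.0, double avg_t1 = -1.0,
                 bool stop_on_absorption = true) {
  SsaParams pr = make_params(spec, distinct_pairs);
  Pcg32 rng((uint64_t)seed, (uint64_t)stream);
  double X = X0, Y = Y0, t = 0.0;
  double w[8];
  double n_events = 0.0;
  // time-average of X over [avg_t0, avg_t1] (exact, waiting-time weighted)
  bool do_avg = avg_t0 >= 0.0 && avg_t1 > avg_t0;
  double avg_acc = 0.0;

  std::vector<double> rec_t, rec_X, rec_Y;
  if (record) {
    rec_t.push_back(t); rec_X.push_back(X); rec_Y.push_back(Y);
  }
  int outcome = 2;
  double t_abs = NA_REAL;
  if (X <= 0.0) { outcome = 0; t_abs = 0.0; }
  else if (Y <= 0.0) { outcome = 1; t_abs = 0.0; }
  if (outcome == 2 || !stop_on_absorption) {
    while (n_events < max_events) {
      propensities(pr, X, Y, w);
      double total = 0.0;
      for (int k = 0; k < 8; ++k) total += w[k];
      if (total <= 0.0) break; // both types extinct: nothing can happen
      double dt = -std::log(rng.runif()) / total;
      double t_new = t + dt;
      if (t_max > 0.0 && t_new > t_max) { t = t_max; break; }
      if (do_avg) {
        double lo = std::max(t, avg_t0), hi = std::min(t_new, avg_t1);
        if (hi > lo) avg_acc += X * (hi - lo);
      }
      t = t_new;
      double u = rng.runif() * total;
      int k = 0;
      double cum = w[0];
      while (u > cum && k < 7) { cum += w[++k]; }
      X += dX_of[k];
      Y += dY_of[k];
      n_events += 1.0;
      if (record && (((long long)n_events) % thin == 0)) {
        rec_t.push_back(t); rec_X.push_back(X); rec_Y.push_back(Y);
      }
      if (outcome == 2) {
        if (X <= 0.0) { outcome = 0; t_abs = t; }
        else if (Y <= 0.0) { outcome = 1; t_abs = t; }
      }
      if (outcome != 2 && stop_on_absorption) break;
      if (do_avg && t >= avg_t1) break;
    }
  }
  if (record &&
      (rec_t.empty() || rec_t.back() != t || rec_X.back() != X)) {
    rec_t.push_back(t); rec_X.push_back(X); rec_Y.push_back(Y);
  }
  List out = List::create(
    _["outcome"] = outcome,
    _["t_abs"] = ISNA(t_abs) ? t : t_abs,
    _["n_events"] = n_events,
    _["X"] = X, _["Y"] = Y,
    _["x_time_avg"] = do_avg ? avg_acc / (avg_t1 - avg_t0) : NA_REAL);
  if (record) {
    out["trajectory"] = DataFrame::create(_["time"] = rec_t,
                                          _["X"] = rec_X, _["Y"] = rec_Y);
  }
  return out;
}

// Batch of replicates: replicate i uses stream i (1-based) of the master
// seed. Returns outcome codes only.
// [[Rcpp::export(name = ".ssa_batch_cpp")]]
IntegerVector ssa_batch_cpp(List spec, double X0, double Y0,
                            double seed, int n_runs,
                            double max_events, double t_max,
                            bool distinct_pairs) {
  SsaParams pr = make_params(spec, distinct_pairs);
  IntegerVector outcomes(n_runs);
  double w[8];
  for (int i = 0; i < n_runs; ++i) {
    Pcg32 rng((uint64_t)seed, (uint64_t)(i + 1));
    double X = X0, Y = Y0, t = 0.0, n_events = 0.0;
    int outcome;
    if (X <= 0.0) outcome = 0;
    else if (Y <= 0.0) outcome = 1;
    else {
      outcome = 2;
      while (n_events < max_events) {
        propensities(pr, X, Y, w);
        double total = w[0] + w[1] + w[2] + w[3] + w[4] + w[5] + w[6] + w[7];
        if (total <= 0.0) break;
        double dt = -std::log(rng.runif()) / total;
        t += dt;
        if (t_max > 0.0 && t > t_max) break;
        double u = rng.runif() * total;
        int k = 0;
        double cum = w[0];
        while (u > cum && k < 7) { cum += w[++k]; }
        X += dX_of[k];
        Y += dY_of[k];
        n_events += 1.0;
        if (X <= 0.0) { outcome = 0; break; }
        if (Y <= 0.0) { outcome = 1; break; }
      }
    }
    outcomes[i] = outcome;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return outcomes;
}

// Euler-Maruyama path of the two-dimensional diffusion approximation.
// States are truncated at 0 and frozen (absorbing) once a coordinate
// underflows 0.
// [[Rcpp::export(name = ".sde_path_cpp")]]
List sde_path_cpp(List spec, double x0, double y0, double dt, double t_end,
                  double seed, double stream, int thin) {
  double a = as<double>(spec["a"]), b = as<double>(spec["b"]),
         c = as<double>(spec["c"]), d = as<double>(spec["d"]),
         bX = as<double>(spec["beta_X"]), bY = as<double>(spec["beta_Y"]),
         gX = as<double>(spec["gamma_X"]), gY = as<double>(spec["gamma_Y"]),
         M = as<double>(spec["M"]);
  Pcg32 rng((uint64_t)seed, (uint64_t)stream);
  long n_steps = (long)std::ceil(t_end / dt);
  double x = x0, y = y0;
  double sqdt = std::sqrt(dt), sqM = std::sqrt(M);
  std::vector<double> rec_t, rec_x, rec_y;
  rec_t.push_back(0.0); rec_x.push_back(x); rec_y.push_back(y);
  for (long i = 1; i <= n_steps; ++i) {
    if (x > 0.0) {
      double mu = x * ((bX - gX) - x / a - y / b);
      double var = x * (bX + gX + x / a + y / b);
      x += mu * dt + std::sqrt(var) / sqM * sqdt * rng.rnorm();
      if (x < 0.0) x = 0.0;
    }
    if (y > 0.0) {
      double mu = y * ((bY - gY) - x / c - y / d);
      double var = y * (bY + gY + x / c + y / d);
      y += mu * dt + std::sqrt(var) / sqM * sqdt * rng.rnorm();
      if (y < 0.0) y = 0.0;
    }
    if (i % thin == 0 || i == n_steps || x == 0.0 || y == 0.0) {
      rec_t.push_back(i * dt); rec_x.push_back(x); rec_y.push_back(y);
    }
    if (x == 0.0 && y == 0.0) break;
    if (x == 0.0 || y == 0.0) break; // absorption of one type decides fixation
  }
  return List::create(
    _["path"] = DataFrame::create(_["time"] = rec_t, _["x"] = rec_x,
                                  _["y"] = rec_y),
    _["x_final"] = x, _["y_final"] = y);
}

// Batch of EM paths, fixation outcome only (1 fix, 0 loss, 2 timeout).
// [[Rcpp::export(name = ".sde_batch_cpp")]]
IntegerVector sde_batch_cpp(List spec, double x0, double y0, double dt,
                            double t_end, double seed, int n_paths) {
  double a = as<double>(spec["a"]), b = as<double>(spec["b"]),
         c = as<double>(spec["c"]), d = as<double>(spec["d"]),
         bX = as<double>(spec["beta_X"]), bY = as<double>(spec["beta_Y"]),
         gX = as<double>(spec["gamma_X"]), gY = as<double>(spec["gamma_Y"]),
         M = as<double>(spec["M"]);
  IntegerVector outcomes(n_paths);
  long n_steps = (long)std::ceil(t_end / dt);
  double sqdt = std::sqrt(dt), sqM = std::sqrt(M);
  for (int p = 0; p < n_paths; ++p) {
    Pcg32 rng((uint64_t)seed, (uint64_t)(p + 1));
    double x = x0, y = y0;
    int outcome = 2;
    if (x <= 0.0) outcome = 0;
    else if (y <= 0.0) outcome = 1;
    else {
      for (long i = 1; i <= n_steps; ++i) {
        double mux = x * ((bX - gX) - x / a - y / b);
        double varx = x * (bX + gX + x / a + y / b);
        double muy = y * ((bY - gY) - x / c - y / d);
        double vary = y * (bY + gY + x / c + y / d);
        x += mux * dt + std::sqrt(varx) / sqM * sqdt * rng.rnorm();
        y += muy * dt + std::sqrt(vary) / sqM * sqdt * rng.rnorm();
        if (x <= 0.0) { outcome = 0; break; }
        if (y <= 0.0) { outcome = 1; break; }
      }
    }
    outcomes[p] = outcome;
    if ((p & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return outcomes;
}
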