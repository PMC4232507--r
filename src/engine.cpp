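#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Benchmark objectives f1..f12 (classic 30-D suite: Sphere, Schwefel 2.22,
// Quadric, Schwefel 2.21, Rosenbrock, Step, noisy Quartic, Schwefel 2.26,
// Rastrigin, Ackley, Griewank, Penalized-1).  f7 consumes one uniform draw
// per call; everything else is deterministic.
// ---------------------------------------------------------------------------

static double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static double penalty_u(double xi, double a, double k, double m) {
  if (xi > a)  return k * std::pow(xi - a, m);
  if (xi < -a) return k * std::pow(-xi - a, m);
  return 0.0;
}

static double bench(int id, const double* x, int D) {
  double s = 0.0, t;
  switch (id) {
  case 1:
    for (int k = 0; k < D; k++) s += x[k] * x[k];
    return s;
  case 2: {
    double a = 0.0, m = 1.0;
    for (int k = 0; k < D; k++) { a += std::fabs(x[k]); m *= std::fabs(x[k]); }
    return a + m;
  }
  case 3: {
    double p = 0.0;
    for (int k = 0; k < D; k++) { p += x[k]; s += p * p; }
    return s;
  }
  case 4: {
    double m = 0.0;
    for (int k = 0; k < D; k++) m = std::max(m, std::fabs(x[k]));
    return m;
  }
  case 5:
    for (int k = 0; k < D - 1; k++) {
      t = x[k + 1] - x[k] * x[k];
      s += 100.0 * t * t + (x[k] - 1.0) * (x[k] - 1.0);
    }
    return s;
  case 6:
    for (int k = 0; k < D; k++) {
      double f = std::floor(x[k] + 0.5);
      s += f * f;
    }
    return s;
  case 7:
    for (int k = 0; k < D; k++) s += (k + 1) * std::pow(x[k], 4.0);
    return s + unif_rand();
  case 8:
    for (int k = 0; k < D; k++)
      s += -x[k] * std::sin(std::sqrt(std::fabs(x[k])));
    return s;
  case 9:
    for (int k = 0; k < D; k++)
      s += x[k] * x[k] - 10.0 * std::cos(2.0 * M_PI * x[k]) + 10.0;
    return s;
  case 10: {
    double q = 0.0;
    for (int k = 0; k < D; k++) {
      s += x[k] * x[k];
      q += std::cos(2.0 * M_PI * x[k]);
    }
    return -20.0 * std::exp(-0.2 * std::sqrt(s / D)) - std::exp(q / D) +
           20.0 + M_E;
  }
  case 11: {
    double pr = 1.0;
    for (int k = 0; k < D; k++) {
      s += x[k] * x[k];
      pr *= std::cos(x[k] / std::sqrt(k + 1.0));
    }
    return s / 4000.0 - pr + 1.0;
  }
  case 12: {
    std::vector<double> y(D);
    for (int k = 0; k < D; k++) y[k] = 1.0 + (x[k] + 1.0) / 4.0;
    double sy = 10.0 * std::pow(std::sin(M_PI * y[0]), 2);
    for (int k = 0; k < D - 1; k++)
      sy += (y[k] - 1.0) * (y[k] - 1.0) *
            (1.0 + 10.0 * std::pow(std::sin(M_PI * y[k + 1]), 2));
    sy += (y[D - 1] - 1.0) * (y[D - 1] - 1.0);
    double pen = 0.0;
    for (int k = 0; k < D; k++) pen += penalty_u(x[k], 10.0, 100.0, 4.0);
    return M_PI / D * sy + pen;
  }
  }
  return NA_REAL;
}

//' @noRd
// [[Rcpp::export(name = ".bench_eval_cpp")]]
double bench_eval_cpp(int id, NumericVector x) {
  return bench(id, x.begin(), x.size());
}

// ---------------------------------------------------------------------------
// Randomization-parameter decay schedules S0..S5 (u = t/T).
// ---------------------------------------------------------------------------

static double alpha_sched(int strat, double t, double T, int N, int D,
                          double alpha0, double alpha_c, double c_decay,
                          double k_power) {
  double u = t / T;
  switch (strat) {
  case 0: return alpha0 * (1.0 - u);
  case 1: return alpha_c * std::exp(-c_decay * u);
  case 2: return alpha_c / (1.0 + c_decay * u);
  case 3: return alpha_c * std::exp(-c_decay * u * (double)N / (double)D);
  case 4: return ::R_pow((double)N, -k_power * u);
  case 5: return ::R_pow((double)N, 1.0 - u) / (double)D;
  }
  return alpha0;
}

//' @noRd
// [[Rcpp::export(name = ".alpha_schedule_cpp")]]
double alpha_schedule_cpp(int strat, double t, double T, int N, int D,
                          double alpha0, double alpha_c, double c_decay,
                          double k_power) {
  return alpha_sched(strat, t, T, N, D, alpha0, alpha_c, c_decay, k_power);
}

// ---------------------------------------------------------------------------
// Swarm engine.  One entry point runs either the standard firefly sweep or
// the adaptive (AdaFa) sweep for T generations.  Objectives:
//   fun_id 1..12  built-in benchmarks (above)
//   fun_id 100    C-alpha placement energy: sum over four previous atoms of
//                 squared (or absolute, energy_abs) deviation between the
//                 candidate-to-atom distance and its target
//   fun_id 0      arbitrary R function (slow path)
// RNG comes from R (RNGScope), so set.seed() in R gives bit-reproducible
// runs; the pure-R reference engine consumes draws in the identical order.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".run_swarm_cpp")]]
List run_swarm_cpp(NumericMatrix init, int fun_id, NumericVector lower,
                   NumericVector upper, List ctrl) {
  const int N = init.nrow(), D = init.ncol();
  const int T = as<int>(ctrl["max_gen"]);
  const bool adafa = as<bool>(ctrl["adaptive"]);
  const double beta0 = as<double>(ctrl["beta0"]);
  const double gamma0 = as<double>(ctrl["gamma"]);
  const double alpha0 = as<double>(ctrl["alpha0"]);
  const int strat = as<int>(ctrl["strategy"]);
  const double alpha_c = as<double>(ctrl["alpha_c"]);
  const double c_decay = as<double>(ctrl["c_decay"]);
  const double k_power = as<double>(ctrl["k_power"]);
  const double delta = as<double>(ctrl["delta"]);
  const double lam = as<double>(ctrl["lambda"]);
  const double rho = as<double>(ctrl["rho"]);
  const double gmin = as<double>(ctrl["g_min"]);
  const double gmax = as<double>(ctrl["g_max"]);
  const double amin = as<double>(ctrl["alpha_min"]);
  const double amax = as<double>(ctrl["alpha_max"]);
  const double branch_p = as<double>(ctrl["branch_prob"]);
  const double p_damp = as<double>(ctrl["damp_power"]);
  const bool scale_range = as<bool>(ctrl["scale_by_range"]);
  const double Lscale = as<double>(ctrl["length_scale"]);
  const bool keep_trace = as<bool>(ctrl["trace"]);
  int run_gens = T;
  if (ctrl.containsElementNamed("run_gens")) run_gens = as<int>(ctrl["run_gens"]);
  bool dbg = ctrl.containsElementNamed("debug_snapshots");
  List dbg_snap;

  // optional aux data for the placement objective
  NumericMatrix prev;    // 4 x 3 previously placed atoms
  NumericVector targets; // 4 target distances
  bool energy_abs = false;
  if (fun_id == 100) {
    prev = as<NumericMatrix>(ctrl["prev_atoms"]);
    targets = as<NumericVector>(ctrl["targets"]);
    energy_abs = as<bool>(ctrl["energy_abs"]);
  }
  Function robj = Rcpp::Environment::base_env()["identity"];
  if (fun_id == 0) robj = as<Function>(ctrl["objective"]);

  NumericMatrix X(clone(init));
  std::vector<double> val(N), rowbuf(D);
  long evals = 0;

  RNGScope scope;

  auto evalrow = [&](int i) {
    for (int d = 0; d < D; d++) rowbuf[d] = X(i, d);
    double v;
    if (fun_id == 100) {
      v = 0.0;
      for (int a = 0; a < 4; a++) {
        double s2 = 0.0;
        for (int d = 0; d < 3; d++) {
          double df = rowbuf[d] - prev(a, d);
          s2 += df * df;
        }
        double dev = std::sqrt(s2) - targets[a];
        v += energy_abs ? std::fabs(dev) : dev * dev;
      }
    } else if (fun_id == 0) {
      v = as<double>(robj(NumericVector(rowbuf.begin(), rowbuf.end())));
    } else {
      v = bench(fun_id, rowbuf.data(), D);
    }
    evals++;
    return std::isfinite(v) ? v : R_PosInf;
  };

  for (int i = 0; i < N; i++) val[i] = evalrow(i);
  int ib = 0;
  for (int i = 1; i < N; i++)
    if (val[i] < val[ib]) ib = i;
  std::vector<double> bestx(D);
  for (int d = 0; d < D; d++) bestx[d] = X(ib, d);
  double bestv = val[ib];

  NumericVector trace(keep_trace ? T : 0);
  std::vector<double> scale(D);
  for (int d = 0; d < D; d++)
    scale[d] = scale_range ? (upper[d] - lower[d]) : 1.0;

  std::vector<double> gam(N, gamma0), K(N, 1.0), spread(D, 0.0);

  for (int t = 1; t <= run_gens; t++) {
    double a_t = alpha_sched(adafa ? strat : 0, t, T, N, D, alpha0, alpha_c,
                             c_decay, k_power);
    double a_eff = adafa ? clampd(a_t, amin, amax) : a_t;
    double damp = ::R_pow(1.0 - (double)t / (double)T, p_damp);

    if (adafa) {
      // distance state: distances to the best-so-far position
      double dmn = R_PosInf, dmx = 0.0;
      std::vector<double> db(N);
      for (int i = 0; i < N; i++) {
        long double s2 = 0.0;
        for (int d = 0; d < D; d++) {
          double df = X(i, d) - bestx[d];
          double sq = df * df;
          s2 += sq;
        }
        db[i] = std::sqrt((double)s2);
        dmn = std::min(dmn, db[i]);
        dmx = std::max(dmx, db[i]);
      }
      for (int i = 0; i < N; i++) {
        double ratio = (dmx > dmn) ? (db[i] - dmn) / (dmx - dmn) : 0.0;
        gam[i] = std::exp(-lam * ratio) / delta;
      }
      // gray state against the best-so-far reference sequence
      double Dmn = R_PosInf, Dmx = 0.0;
      for (int i = 0; i < N; i++)
        for (int d = 0; d < D; d++) {
          double dl = std::fabs(bestx[d] - X(i, d));
          Dmn = std::min(Dmn, dl);
          Dmx = std::max(Dmx, dl);
        }
      const double wk = 1.0 / D;
      for (int i = 0; i < N; i++) {
        long double g = 0.0;
        for (int d = 0; d < D; d++) {
          double cl = 1.0;
          if (Dmx > 0.0) {
            double dl = std::fabs(bestx[d] - X(i, d));
            cl = (Dmn + rho * Dmx) / (dl + rho * Dmx);
          }
          g += wk * cl;
        }
        double Ki = gmax - (gmax - gmin) * (double)g;
        K[i] = Ki < gmin ? gmin : (Ki > gmax ? gmax : Ki);
      }
      // per-dimension population spread
      for (int d = 0; d < D; d++) {
        long double m = 0.0;
        for (int i = 0; i < N; i++) m += X(i, d);
        double mb = (double)(m / N);
        long double vv = 0.0;
        for (int i = 0; i < N; i++) {
          double df = X(i, d) - mb;
          double sq = df * df;
          vv += sq;
        }
        double vd = (double)vv;
        spread[d] = std::sqrt(vd / (N - 1));
      }
    }

    for (int i = 0; i < N; i++) {
      bool any_brighter = false;
      for (int j = 0; j < N; j++) {
        if (val[j] < val[i]) {
          any_brighter = true;
          long double r2 = 0.0;
          for (int d = 0; d < D; d++) {
            double df = X(i, d) - X(j, d);
            double sq = df * df;
            r2 += sq;
          }
          double rn = std::sqrt((double)r2) / Lscale;
          double rn2 = rn * rn;
          double g_i = adafa ? gam[i] : gamma0;
          double beta = beta0 * std::exp(-g_i * rn2);
          if (!adafa) {
            for (int d = 0; d < D; d++) {
              double nv = X(i, d) + beta * (X(j, d) - X(i, d)) +
                          a_t * norm_rand() * scale[d];
              X(i, d) = clampd(nv, lower[d], upper[d]);
            }
          } else {
            bool rule1 = (branch_p >= 1.0) ? true
                       : (branch_p <= 0.0) ? false
                       : (unif_rand() < branch_p);
            if (rule1) {
              for (int d = 0; d < D; d++) {
                double nv = X(i, d) + beta * (X(j, d) - X(i, d)) +
                            K[i] * a_eff * damp * norm_rand();
                X(i, d) = clampd(nv, lower[d], upper[d]);
              }
            } else {
              for (int d = 0; d < D; d++) {
                double nv = X(i, d) + K[i] * a_eff *
                            (damp * norm_rand() + spread[d] * norm_rand());
                X(i, d) = clampd(nv, lower[d], upper[d]);
              }
            }
          }
          val[i] = evalrow(i);
          if (dbg) dbg_snap.push_back(clone(X));
        }
      }
      if (adafa) {
        // one diversification kick per firefly per generation
        for (int d = 0; d < D; d++) {
          double nv = X(i, d) + K[i] * a_eff * spread[d] * norm_rand();
          X(i, d) = clampd(nv, lower[d], upper[d]);
        }
        if (!any_brighter) {
          for (int d = 0; d < D; d++) {
            double nv = X(i, d) + a_eff * damp * norm_rand();
            X(i, d) = clampd(nv, lower[d], upper[d]);
          }
        }
        val[i] = evalrow(i);
      } else if (!any_brighter) {
        for (int d = 0; d < D; d++) {
          double nv = X(i, d) + a_t * norm_rand() * scale[d];
          X(i, d) = clampd(nv, lower[d], upper[d]);
        }
        val[i] = evalrow(i);
      }
      if (dbg) dbg_snap.push_back(clone(X));
    }

    for (int i = 0; i < N; i++) {
      val[i] = evalrow(i);
      if (val[i] < bestv) {
        bestv = val[i];
        for (int d = 0; d < D; d++) bestx[d] = X(i, d);
      }
    }
    if (keep_trace) trace[t - 1] = bestv;
  }

  if (dbg)
    return List::create(_["snapshots"] = dbg_snap, _["positions"] = X);
  return List::create(
      _["best_value"] = bestv,
      _["best_position"] = NumericVector(bestx.begin(), bestx.end()),
      _["trace"] = trace, _["evaluations"] = (double)evals,
      _["positions"] = X,
      _["values"] = NumericVector(val.begin(), val.end()));
}
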