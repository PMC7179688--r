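#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Session codes used throughout: 1 Pre-test, 2 Train1, 3 Test1, 4 Train2,
// 5 Test2.  Train sessions have data-dependent length; tests are fixed.
//
// All randomness goes through R's unif_rand() so set.seed() in R fully
// determines a simulation.  Samples record the pre-step state: sample i is
// the fly at time i*dt, and the laser value is the one applied during the
// step that follows.

namespace {

struct Dyn {
  double dt, walk_speed, lw, lp, alpha, tau_s, beta, hab, L;
  int mode;             // 1 closed-loop, 2 random telegraph, 3 off
  double r_on, r_off;   // telegraph hazards for mode 2
};

struct Fly {
  double pos, S, t;
  int heading;          // +1 or -1
  bool walking;
};

inline void step_dyn(Fly& f, bool laser_on, const Dyn& d) {
  const double u = unif_rand();
  if (f.walking) {
    if (u < 1.0 - std::exp(-d.lp * d.dt)) f.walking = false;
  } else {
    const double lam = d.lw * std::exp(-d.beta * f.S) * std::exp(-d.hab * f.t);
    if (u < 1.0 - std::exp(-lam * d.dt)) {
      f.walking = true;
      f.heading = (unif_rand() < 0.5) ? -1 : 1;
    }
  }
  if (laser_on && f.walking)
    f.S += d.alpha * d.dt;
  else if (d.tau_s > 0.0)
    f.S *= std::exp(-d.dt / d.tau_s);
  if (f.walking) {
    f.pos += d.walk_speed * d.dt * f.heading;
    if (f.pos > d.L) { f.pos = 2.0 * d.L - f.pos; f.heading = -1; }
    if (f.pos < 0.0) { f.pos = -f.pos; f.heading = 1; }
  }
  f.t += d.dt;
}

Dyn make_dyn(const List& cfg) {
  Dyn d;
  d.dt = as<double>(cfg["dt"]);
  d.walk_speed = as<double>(cfg["walk_speed"]);
  d.lw = as<double>(cfg["pause_to_walk_rate"]);
  d.lp = as<double>(cfg["walk_to_pause_rate"]);
  d.alpha = as<double>(cfg["learning_gain"]);
  d.tau_s = as<double>(cfg["suppression_decay"]);
  d.beta = as<double>(cfg["suppression_effect"]);
  d.hab = as<double>(cfg["habituation_rate"]);
  d.L = as<double>(cfg["chamber_length"]);
  d.mode = as<int>(cfg["controller_code"]);
  d.r_on = as<double>(cfg["random_on_rate"]);
  d.r_off = as<double>(cfg["random_off_rate"]);
  return d;
}

Fly init_fly(const Dyn& d) {
  Fly f;
  f.pos = d.L / 2.0;
  f.S = 0.0;
  f.t = 0.0;
  f.heading = (unif_rand() < 0.5) ? -1 : 1;
  f.walking = false;
  return f;
}

} // namespace

// Closed-loop train fly: the virtual operator watches the fly and drives the
// laser during Train sessions.  Returns the full 5-session trace plus the
// per-Train-session episode counts and sample counts per session.
// [[Rcpp::export]]
List sim_train_fly_cpp(List cfg, List proto) {
  Dyn d = make_dyn(cfg);
  const double lat_min = as<double>(cfg["latency_min"]);
  const double lat_max = as<double>(cfg["latency_max"]);
  const double test_dur = as<double>(proto["test_duration"]);
  const int max_ep = as<int>(proto["max_heat_episodes"]);
  const double stat_cut = as<double>(proto["stationary_cutoff"]);
  const double trig = as<double>(proto["trigger_walk_duration"]);
  const double edge = as<double>(proto["edge_zone"]);
  const double max_train = as<double>(proto["max_train_duration"]);

  std::vector<double> pos;
  std::vector<int> las, ses;
  Fly f = init_fly(d);
  IntegerVector ses_len(5), ses_eps(5);

  const int n_test = (int)std::lround(test_dur / d.dt);
  const int n_train_cap = (int)std::lround(max_train / d.dt);

  for (int s = 0; s < 5; ++s) {
    const bool is_train = (s == 1 || s == 3);
    if (!is_train) {
      for (int i = 0; i < n_test; ++i) {
        pos.push_back(f.pos); las.push_back(0); ses.push_back(s + 1);
        step_dyn(f, false, d);
      }
      ses_len[s] = n_test;
      continue;
    }
    // Train session: closed loop (or telegraph / off for null controllers)
    bool laser = false, pend_on = false, pend_off = false;
    double t_on = 0.0, t_off = 0.0;
    double walk_run = 0.0, pause_run = 0.0;
    int episodes = 0, i = 0;
    bool done = false;
    while (!done) {
      pos.push_back(f.pos); las.push_back(laser ? 1 : 0); ses.push_back(s + 1);
      step_dyn(f, laser, d);
      if (f.walking) { walk_run += d.dt; pause_run = 0.0; }
      else           { pause_run += d.dt; walk_run = 0.0; }
      if (d.mode == 1) {
        const bool at_edge = (f.pos <= edge) || (f.pos >= d.L - edge);
        const bool desired = (walk_run > trig) || at_edge;
        if (desired) {
          if (pend_off) pend_off = false;
          if (!laser && !pend_on) {
            pend_on = true;
            t_on = f.t + lat_min + unif_rand() * (lat_max - lat_min);
          }
        } else {
          if (pend_on) pend_on = false;
          if (laser && !pend_off) {
            pend_off = true;
            t_off = f.t + lat_min + unif_rand() * (lat_max - lat_min);
          }
        }
        if (pend_on && f.t >= t_on)   { laser = true;  pend_on = false; }
        if (pend_off && f.t >= t_off) { laser = false; pend_off = false; ++episodes; }
      } else if (d.mode == 2) {
        const double u = unif_rand();
        if (!laser) {
          if (u < 1.0 - std::exp(-d.r_on * d.dt)) laser = true;
        } else if (u < 1.0 - std::exp(-d.r_off * d.dt)) {
          laser = false; ++episodes;
        }
      } // mode 3: laser stays off
      ++i;
      if (episodes >= max_ep || pause_run >= stat_cut || i >= n_train_cap)
        done = true;
    }
    ses_len[s] = i;
    ses_eps[s] = episodes + (laser ? 1 : 0); // count a truncated final episode
  }

  return List::create(
    _["position"] = NumericVector(pos.begin(), pos.end()),
    _["laser"] = IntegerVector(las.begin(), las.end()),
    _["session_code"] = IntegerVector(ses.begin(), ses.end()),
    _["session_len"] = ses_len,
    _["episodes"] = ses_eps);
}

// Yoked or blank fly: dynamics driven by a prescribed laser channel (the
// train partner's mirror, or all-off).  Session structure is inherited from
// the partner's trace.
// [[Rcpp::export]]
NumericVector sim_follower_fly_cpp(List cfg, IntegerVector laser) {
  Dyn d = make_dyn(cfg);
  const int n = laser.size();
  NumericVector pos(n);
  Fly f = init_fly(d);
  for (int i = 0; i < n; ++i) {
    pos[i] = f.pos;
    step_dyn(f, laser[i] == 1, d);
  }
  return pos;
}

// Bootstrap resample medians (with replacement), for the percentile CI of
// the median.  Uses R's RNG; medians of even-sized samples average the two
// central order statistics, matching stats::median.
// [[Rcpp::export]]
NumericVector boot_median_cpp(NumericVector x, int n_resamples) {
  const int n = x.size();
  NumericVector out(n_resamples);
  std::vector<double> buf(n);
  for (int b = 0; b < n_resamples; ++b) {
    for (int i = 0; i < n; ++i)
      buf[i] = x[(int)(unif_rand() * n) % n];
    const int h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (n % 2 == 0) {
      m = (m + *std::max_element(buf.begin(), buf.begin() + h)) / 2.0;
    }
    out[b] = m;
  }
  return out;
}
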