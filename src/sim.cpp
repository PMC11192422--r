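#include <Rcpp.h>
using namespace Rcpp;

// Exponential waiting time at `rate`; rate 0 means the clock never fires.
static inline double rexp_rate(double rate) {
  return rate > 0.0 ? R::exp_rand() / rate : R_PosInf;
}

// Processing-time draw. family: 0 = delta, 1 = erlang(m, m/tau), 2 = exponential(mean tau).
// The Erlang draw is the sum of m independent exponentials with rate m/tau,
// i.e. a Gamma(shape = m, scale = tau/m) variate.
static inline double draw_ptime(int family, double tau, int m) {
  if (family == 0) return tau;
  if (family == 1) return R::rgamma((double)m, tau / (double)m);
  return R::exp_rand() * tau;
}

// Event-driven simulation of the single-substrate receptor cycle
//   E + S <-> ES ~~(processing time)~~> E*S,  E*S -> E*S + P (k_p),  E*S -> E + S (k_unbind_star)
// with full reset of the proofreading progress on every unbinding.
//
// Per bound period the engine schedules the activation deadline (one draw from
// the processing-time model, or the explicit m-step chain) against a memoryless
// unbinding clock and advances to the earlier event; while activated, product
// emissions at rate k_p race the E*S unbinding clock. Ties (measure zero) are
// resolved activation > unbinding > production.
//
// horizon: contact duration per trajectory. Returns first activation time
// (NA if censored), number of binding events, product count, and (optionally)
// the product emission times.
// [[Rcpp::export]]
List cpp_sim_tcr(NumericVector horizon, double k_on, double k_unbind,
                 double k_unbind_star, double k_p, int family, double tau,
                 int m, bool explicit_chain, double max_events,
                 bool keep_times) {
  int n = horizon.size();
  NumericVector act(n, NA_REAL);
  IntegerVector nbind(n), count(n);
  List times(keep_times ? n : 0);
  double kf = explicit_chain ? (double)m / tau : 0.0;

  for (int i = 0; i < n; ++i) {
    const double T = horizon[i];
    double t = 0.0, events = 0.0;
    bool activated_seen = false;
    int nb = 0;
    std::vector<double> pt;

    for (;;) {
      // free receptor: wait for the next binding
      double wb = rexp_rate(k_on);
      if (!(t + wb < T)) break;  // contact ends before the next binding
      t += wb;
      ++nb;
      ++events;

      // bound complex: activation deadline vs unbinding clock
      bool act_now;
      if (explicit_chain) {
        // explicit chain E(0)S -> ... -> E(m-1)S -> E*S, per-step rate m/tau,
        // per-state unbinding at k_unbind (full reset on unbinding)
        act_now = true;
        for (int step = 0; step < m; ++step) {
          double wf = rexp_rate(kf), wu = rexp_rate(k_unbind);
          ++events;
          if (wf <= wu) {
            t += wf;
          } else {
            t += wu;
            act_now = false;
            break;
          }
        }
      } else {
        double d = draw_ptime(family, tau, m);
        double wu = rexp_rate(k_unbind);
        ++events;
        if (d <= wu) {
          act_now = true;
          t += d;
        } else {
          act_now = false;
          t += wu;
        }
      }
      if (t >= T) break;  // event lands beyond the contact window

      if (act_now) {
        if (!activated_seen) {
          activated_seen = true;
          act[i] = t;
        }
        // activated complex: emit products until E*S unbinds (full reset)
        double t_end = t + rexp_rate(k_unbind_star);
        double tp = t + rexp_rate(k_p);
        while (tp <= t_end && tp <= T) {
          pt.push_back(tp);
          ++events;
          tp += rexp_rate(k_p);
        }
        t = t_end;
        if (t >= T) break;
      }

      if (events > max_events)
        stop("event-count overflow (more than %.0f events in one trajectory); "
             "use a smaller contact time T or raise max_events", max_events);
    }

    nbind[i] = nb;
    count[i] = (int)pt.size();
    if (keep_times) times[i] = wrap(pt);
  }

  List out = List::create(_["activation_time"] = act,
                          _["n_binding_events"] = nbind,
                          _["product_count"] = count);
  if (keep_times) out["product_times"] = times;
  return out;
}

// Two-branch replication-fidelity scheme: from free enzyme E, bind the correct
// substrate with probability k1/(k1+k1p); the bound complex either completes
// (processing-time draw) or unbinds first (rate km1 / km1p). Repeat until
// absorption into the correct or incorrect product.
// [[Rcpp::export]]
List cpp_sim_dna(int n, double k1, double k1p, double km1, double km1p,
                 int family, double tau, int m, double max_cycles) {
  IntegerVector winner(n), cycles(n);
  NumericVector ctime(n);
  const double ktot = k1 + k1p;

  for (int i = 0; i < n; ++i) {
    double t = 0.0;
    int nc = 0, win = -1;
    while (win < 0) {
      t += rexp_rate(ktot);
      bool correct = (R::unif_rand() * ktot < k1);
      ++nc;
      double d = draw_ptime(family, tau, m);
      double wu = rexp_rate(correct ? km1 : km1p);
      if (d <= wu) {
        t += d;
        win = correct ? 1 : 0;
      } else {
        t += wu;
      }
      if (nc > max_cycles)
        stop("cycle-count overflow (more than %.0f binding cycles); "
             "check the rates or raise max_cycles", max_cycles);
    }
    winner[i] = win;
    cycles[i] = nc;
    ctime[i] = t;
  }
  return List::create(_["winner"] = winner, _["completion_time"] = ctime,
                      _["n_cycles"] = cycles);
}
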