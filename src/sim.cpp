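#include <Rcpp.h>
using namespace Rcpp;

// One synchronous sweep of the stochastic lattice model, repeated `steps`
// times.  Species codes: 0 = coral, 1 = turf, 2 = macroalgae.
//
// Per step, with rates frozen at the step start:
//   turf node:        T->C at r * c_i,  T->M at gamma * m_i
//   coral node:       C->T at d / nu1,  C->M at a * m_i        (nu1 == 1)
//   macroalgae node:  M->T at g / nu2,  nu2 = max(eps, t_i + m_i)
// where c_i, t_i, m_i are neighbour fractions (or raw counts when
// count_scaling is set).  Each node fires at most one event with
// probability 1 - exp(-Lambda dt) (or min(1, Lambda dt) for the linear
// scheme), the event chosen proportionally to the individual rates.
//
// Random draws come from R's global RNG: first u1 for all nodes in
// row-major order, then u2 for all nodes.  The pure-R reference stepper
// draws in the same order, so both paths are bit-identical under a seed.

// [[Rcpp::export]]
List sim_steps_cpp(IntegerVector state0, IntegerVector indptr,
                   IntegerVector indices, double r, double d, double a,
                   double gamma_, double g, double dt, double eps_div,
                   bool linear_scheme, bool count_scaling, int steps,
                   int record_every, bool stop_on_absorption, double t0) {
  const int n = state0.size();
  std::vector<int> s(state0.begin(), state0.end());
  std::vector<int> snew(n);
  std::vector<double> rate1(n), rate2(n), lambda(n), u1(n), u2(n);

  int nrec = 1 + (record_every > 0 ? steps / record_every : 0);
  IntegerMatrix rec_states(nrec, n);
  NumericVector rec_steps(nrec);
  NumericMatrix cov(steps + 1, 3);
  int irec = 0;

  auto record_covers = [&](int step) {
    int cnt[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i) cnt[s[i]]++;
    for (int k = 0; k < 3; ++k) cov(step, k) = (double)cnt[k] / n;
  };
  auto record_state = [&](int step) {
    for (int i = 0; i < n; ++i) rec_states(irec, i) = s[i];
    rec_steps[irec] = step;
    ++irec;
  };

  record_covers(0);
  record_state(0);

  RNGScope scope;
  int step = 0;
  for (step = 1; step <= steps; ++step) {
    // neighbour composition and per-node rates, frozen at step start
    for (int i = 0; i < n; ++i) {
      int cc = 0, ct = 0, cm = 0;
      for (int k = indptr[i]; k < indptr[i + 1]; ++k) {
        int v = s[indices[k] - 1];
        if (v == 0) ++cc; else if (v == 1) ++ct; else ++cm;
      }
      double deg = (double)(indptr[i + 1] - indptr[i]);
      double fc, ft, fm;
      if (count_scaling || deg == 0.0) {
        fc = cc; ft = ct; fm = cm;
      } else {
        fc = cc / deg; ft = ct / deg; fm = cm / deg;
      }
      double r1 = 0.0, r2 = 0.0;
      switch (s[i]) {
      case 1:  // turf: -> coral, -> macroalgae
        r1 = r * fc; r2 = gamma_ * fm; break;
      case 0:  // coral: -> turf (d / nu1, nu1 == 1), -> macroalgae
        r1 = d; r2 = a * fm; break;
      default: // macroalgae: -> turf at g / nu2
        r1 = g / std::max(eps_div, ft + fm); r2 = 0.0; break;
      }
      rate1[i] = r1; rate2[i] = r2; lambda[i] = r1 + r2;
    }

    for (int i = 0; i < n; ++i) u1[i] = R::runif(0.0, 1.0);
    for (int i = 0; i < n; ++i) u2[i] = R::runif(0.0, 1.0);

    for (int i = 0; i < n; ++i) {
      snew[i] = s[i];
      if (lambda[i] <= 0.0) continue;
      double pfire = linear_scheme ? std::min(1.0, lambda[i] * dt)
                                   : 1.0 - std::exp(-lambda[i] * dt);
      if (u1[i] >= pfire) continue;
      bool first = u2[i] < rate1[i] / lambda[i];
      switch (s[i]) {
      case 1: snew[i] = first ? 0 : 2; break;  // turf -> C or M
      case 0: snew[i] = first ? 1 : 2; break;  // coral -> T or M
      default: snew[i] = 1; break;             // macroalgae -> T
      }
    }
    std::swap(s, snew);

    record_covers(step);
    if (record_every > 0 && step % record_every == 0) record_state(step);

    if (stop_on_absorption) {
      bool has_c = false, has_m = false;
      for (int i = 0; i < n && !(has_c && has_m); ++i) {
        if (s[i] == 0) has_c = true; else if (s[i] == 2) has_m = true;
      }
      if (!has_c || !has_m) break;
    }
  }
  int steps_taken = std::min(step, steps);

  return List::create(
      _["states"] = rec_states(Range(0, irec - 1), _),
      _["rec_steps"] = rec_steps[Range(0, irec - 1)],
      _["covers"] = cov(Range(0, steps_taken), _),
      _["steps_taken"] = steps_taken, _["t0"] = t0, _["dt"] = dt);
}
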