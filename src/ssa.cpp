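#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Gillespie direct-method cores. Both routines use R's RNG (exp_rand /
// unif_rand), so results are reproducible under set.seed() from R.
// Occupancy histograms are holding-time weighted: each state contributes
// the duration it is held (clipped to [burn_in, t*]), not one count per
// event, which would be biased.

// Reversible binding L + R <-> B.
// Free counts are implicit: L = L_max - B, R = R_max - B.
// [[Rcpp::export]]
List ssa_binding_cpp(const int L_max, const int R_max, const int B0,
                     const double kon_over_nu, const double koff,
                     const double t_end, const double burn_in,
                     const bool record, const double max_events) {
  const int B_cap = std::min(L_max, R_max);
  if (B0 < 0 || B0 > B_cap) stop("initial complex count outside [0, B_max]");
  int B = B0;
  double t = 0.0, n_events = 0.0;
  NumericVector occ(B_cap + 1);
  std::vector<double> times;
  std::vector<int> Bs;
  if (record) { times.push_back(0.0); Bs.push_back(B); }

  for (;;) {
    const double a1 = kon_over_nu * (double)(L_max - B) * (double)(R_max - B);
    const double a2 = koff * (double)B;
    const double a0 = a1 + a2;
    if (a0 <= 0.0) {  // absorbing: hold state to the horizon
      if (t_end > t) occ[B] += std::max(0.0, t_end - std::max(t, burn_in));
      t = t_end;
      break;
    }
    const double tau = R::exp_rand() / a0;
    if (t + tau > t_end) {
      occ[B] += std::max(0.0, t_end - std::max(t, burn_in));
      t = t_end;
      break;
    }
    occ[B] += std::max(0.0, (t + tau) - std::max(t, burn_in));
    t += tau;
    if (R::unif_rand() * a0 < a1) ++B; else --B;
    n_events += 1.0;
    if (record) { times.push_back(t); Bs.push_back(B); }
    if (n_events >= max_events)
      stop("SSA event cap (%.0f) exceeded; raise max_events or shorten t_end",
           max_events);
  }

  double wtot = 0.0;
  for (int i = 0; i <= B_cap; ++i) wtot += occ[i];
  NumericVector p(B_cap + 1);
  if (wtot > 0.0) for (int i = 0; i <= B_cap; ++i) p[i] = occ[i] / wtot;

  List out = List::create(
    _["t_final"] = t, _["B_final"] = B, _["n_events"] = n_events,
    _["occupancy"] = p, _["occupancy_time"] = wtot);
  if (record) { out["times"] = wrap(times); out["B"] = wrap(Bs); }
  return out;
}

// Five-reaction minimal signalling model:
//   r1: L + R_I -> B            kon_over_nu * L * R_I
//   r2: B -> L + R_A            koff * B
//   r3: L + R_A -> B            kon_over_nu * L * R_A
//   r4: R_A -> R_I              k_revert * R_A   (defaults to koff)
//   r5: R_A + B -> R_A + B + S  koff * R_A * B
// Terminates at the first of: S > S_stop, next event past t_stop
// (state held at t_stop), or total propensity zero (state reported at
// the time the absorbing state was entered).
// [[Rcpp::export]]
List ssa_signalling_cpp(const int L_max, const int R_max,
                        const double kon_over_nu, const double koff,
                        const double k_revert,
                        const double S_stop, const double t_stop,
                        const double burn_in, const bool record,
                        const double max_events) {
  const int B_cap = std::min(L_max, R_max);
  int RI = R_max, RA = 0, B = 0;
  double S = 0.0, t = 0.0, n_events = 0.0;
  NumericVector occ(B_cap + 1);
  double ra_integral = 0.0, w_total = 0.0;
  std::vector<double> times, Ss;
  std::vector<int> RIs, RAs, Bs;
  if (record) {
    times.push_back(0.0); RIs.push_back(RI); RAs.push_back(RA);
    Bs.push_back(B); Ss.push_back(S);
  }

  for (;;) {
    const double L = (double)(L_max - B);
    const double a1 = kon_over_nu * L * (double)RI;
    const double a2 = koff * (double)B;
    const double a3 = kon_over_nu * L * (double)RA;
    const double a4 = k_revert * (double)RA;
    const double a5 = koff * (double)RA * (double)B;
    const double a0 = a1 + a2 + a3 + a4 + a5;
    if (a0 <= 0.0) break;  // absorbing; t* is the entry time
    const double tau = R::exp_rand() / a0;
    const double t_next = t + tau;
    if (t_next > t_stop) {
      const double w = std::max(0.0, t_stop - std::max(t, burn_in));
      occ[B] += w; ra_integral += w * RA; w_total += w;
      t = t_stop;
      break;
    }
    const double w = std::max(0.0, t_next - std::max(t, burn_in));
    occ[B] += w; ra_integral += w * RA; w_total += w;
    t = t_next;
    const double u = R::unif_rand() * a0;
    if (u < a1)                { --RI; ++B; }
    else if (u < a1 + a2)      { --B; ++RA; }
    else if (u < a1 + a2 + a3) { --RA; ++B; }
    else if (u < a1 + a2 + a3 + a4) { --RA; ++RI; }
    else                       { S += 1.0; }
    n_events += 1.0;
    if (record) {
      times.push_back(t); RIs.push_back(RI); RAs.push_back(RA);
      Bs.push_back(B); Ss.push_back(S);
    }
    if (S > S_stop) break;
    if (n_events >= max_events)
      stop("SSA event cap (%.0f) exceeded; raise max_events or lower t_stop",
           max_events);
  }

  double wtot = 0.0;
  for (int i = 0; i <= B_cap; ++i) wtot += occ[i];
  NumericVector p(B_cap + 1);
  if (wtot > 0.0) for (int i = 0; i <= B_cap; ++i) p[i] = occ[i] / wtot;

  List out = List::create(
    _["t_final"] = t, _["S_final"] = S, _["n_events"] = n_events,
    _["RI_final"] = RI, _["RA_final"] = RA, _["B_final"] = B,
    _["occupancy"] = p, _["occupancy_time"] = wtot,
    _["RA_time_avg"] = (w_total > 0.0 ? ra_integral / w_total : 0.0));
  if (record) {
    out["times"] = wrap(times); out["RI"] = wrap(RIs);
    out["RA"] = wrap(RAs); out["B"] = wrap(Bs); out["S"] = wrap(Ss);
  }
  return out;
}
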