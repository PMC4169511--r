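// Exact stochastic simulation (Gillespie direct method) of a flattened
// transfection network.  Rate kinds: 0 = mass-action first order,
// 1 = attach new-pit channel, 2 = attach join channel, 3 = wash.
// The attach channels share the pit-normalised constant k_A / (n_pits + 1).
// The wash is either an instantaneous removal of L_ex at t_inc
// (wash_mode 0, the large-k_W limit) or an explicit first-order reaction
// that switches on at t_inc (wash_mode 1).  Uses R's RNG so results are
// reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arguments: stoich is the reactions-by-species net-change matrix; kind the
// per-reaction rate kind; ridx the 0-based propensity-carrying reactant;
// lex/pits the 0-based indices of L_ex and the pit species; cargo the
// lipoplexes moved per firing; eclass tags events (1 attach, 2 endocytosis,
// 3 lysis, 4 endosome degradation, 5 unpack, 6 wash, 0 other);
// release_size the mRNA released per unpack firing.

// [[Rcpp::export]]
List ssa_core(IntegerVector x0, IntegerMatrix stoich, IntegerVector kind,
              NumericVector rate, IntegerVector ridx, int lex,
              IntegerVector pits, NumericVector cargo, IntegerVector eclass,
              NumericVector release_size, double t_inc, int wash_mode,
              NumericVector out_times, bool log_events, double budget) {
  const int nr = stoich.nrow(), ns = stoich.ncol(), nt = out_times.size();
  const double t_end = out_times[nt - 1];

  // sparse stoichiometry
  std::vector< std::vector<int> > sp_idx(nr), sp_del(nr);
  for (int j = 0; j < nr; ++j)
    for (int s = 0; s < ns; ++s)
      if (stoich(j, s) != 0) {
        sp_idx[j].push_back(s);
        sp_del[j].push_back(stoich(j, s));
      }

  std::vector<double> x(ns);
  for (int s = 0; s < ns; ++s) x[s] = x0[s];

  NumericMatrix counts(nt, ns);
  std::vector<double> a(nr);
  std::vector<double> rel_t, rel_s, ev_t;
  std::vector<int> ev_r;
  double tal_attach = 0, tal_endo_event = 0, tal_endo_lipo = 0,
         tal_lys_event = 0, tal_lys_lipo = 0, tal_deg_event = 0,
         tal_deg_lipo = 0, tal_unpack = 0, tal_washed = 0;
  double t = 0.0, nev = 0.0;
  int oi = 0;
  bool over_budget = false;

  for (;;) {
    double npits = 0;
    for (int k = 0; k < pits.size(); ++k) npits += x[pits[k]];
    double a0 = 0;
    for (int j = 0; j < nr; ++j) {
      double aj = 0;
      switch (kind[j]) {
      case 0: aj = rate[j] * x[ridx[j]]; break;
      case 1: aj = rate[j] / (npits + 1.0) * x[lex]; break;
      case 2: aj = rate[j] / (npits + 1.0) * x[lex] * x[ridx[j]]; break;
      case 3: aj = (wash_mode == 1 && t >= t_inc) ? rate[j] * x[lex] : 0.0;
        break;
      }
      a[j] = aj; a0 += aj;
    }

    double tbreak = (t < t_inc && t_inc < t_end) ? t_inc : t_end;
    double tnext = (a0 > 0) ? t - std::log(unif_rand()) / a0 : R_PosInf;

    if (tnext >= tbreak) {
      while (oi < nt && out_times[oi] < tbreak - 1e-12) {
        for (int s = 0; s < ns; ++s) counts(oi, s) = x[s];
        ++oi;
      }
      t = tbreak;
      if (tbreak == t_inc && tbreak < t_end) {
        if (wash_mode == 0) { tal_washed += x[lex]; x[lex] = 0; }
        continue;  // propensities change at t_inc in either mode
      }
      break;
    }

    // choose reaction
    double u = unif_rand() * a0, acc = 0;
    int j = nr - 1;
    for (int k = 0; k < nr; ++k) {
      acc += a[k];
      if (u <= acc) { j = k; break; }
    }

    while (oi < nt && out_times[oi] < tnext - 1e-12) {
      for (int s = 0; s < ns; ++s) counts(oi, s) = x[s];
      ++oi;
    }
    t = tnext;
    for (size_t k = 0; k < sp_idx[j].size(); ++k)
      x[sp_idx[j][k]] += sp_del[j][k];

    switch (eclass[j]) {
    case 1: tal_attach += cargo[j]; break;
    case 2: tal_endo_event += 1; tal_endo_lipo += cargo[j]; break;
    case 3: tal_lys_event += 1; tal_lys_lipo += cargo[j]; break;
    case 4: tal_deg_event += 1; tal_deg_lipo += cargo[j]; break;
    case 5: tal_unpack += 1; rel_t.push_back(t);
      rel_s.push_back(release_size[j]); break;
    case 6: tal_washed += cargo[j]; break;
    }
    if (log_events) { ev_t.push_back(t); ev_r.push_back(j + 1); }

    nev += 1;
    if (nev > budget) over_budget = true;
    if (nev > 100.0 * budget)
      stop("SSA event count exceeded 100x the configured budget at t=%g", t);
  }

  while (oi < nt) {
    for (int s = 0; s < ns; ++s) counts(oi, s) = x[s];
    ++oi;
  }

  List out = List::create(
    _["counts"] = counts,
    _["n_events"] = nev,
    _["over_budget"] = over_budget,
    _["release_times"] = wrap(rel_t),
    _["release_sizes"] = wrap(rel_s),
    _["tallies"] = NumericVector::create(
      _["attached"] = tal_attach, _["endocytosis_events"] = tal_endo_event,
      _["endocytosed_lipoplexes"] = tal_endo_lipo,
      _["lysis_events"] = tal_lys_event,
      _["lysed_lipoplexes"] = tal_lys_lipo,
      _["degradation_events"] = tal_deg_event,
      _["degraded_cargo"] = tal_deg_lipo,
      _["unpack_events"] = tal_unpack, _["washed"] = tal_washed));
  if (log_events) {
    out["event_times"] = wrap(ev_t);
    out["event_reaction"] = wrap(ev_r);
  }
  return out;
}
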