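#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven (CTMC) counterpart of the disclosure model.
// Propensities are the flow terms of the mean-field ODE evaluated at the
// integer state; S-class move-ins are resolved as seeded vs clean by one
// uniform draw against k*f at the current state. Uses R's RNG so runs are
// reproducible from set.seed().
//
// Event type codes: 0 infection, 1 move-out, 2 move-in-clean,
// 3 move-in-seeded, 4 treatment, 5 disclosure-expiry.

// [[Rcpp::export]]
List gillespie_core(NumericVector init, double beta, double gamma, double k,
                    double b, double m, double n, double s, double D,
                    double N, NumericVector report_times, bool keep_events) {
  double Sr = init[0], Ir = init[1], Sv = init[2], Iv = init[3],
         Svp = init[4];
  double t = 0.0;
  const int n_rep = report_times.size();
  NumericMatrix report(n_rep, 6);  // t, Sr, Ir, Sv, Iv, Svp
  int rep_i = 0;
  IntegerVector counts(6);
  std::vector<double> ev_t;
  std::vector<int> ev_type;
  std::vector<double> ev_state;
  const double horizon = report_times[n_rep - 1];

  RNGScope scope;
  while (true) {
    // a[]: 0 infection, 1 mSr, 2 bmIr, 3 nSv, 4 (1-s)nSvp, 5 (1-s)nIv,
    //      6 gIr, 7 gIv, 8 Svp/D
    double a[9];
    a[0] = beta * Sr * Ir / N;
    a[1] = m * Sr;
    a[2] = b * m * Ir;
    a[3] = n * Sv;
    a[4] = (1.0 - s) * n * Svp;
    a[5] = (1.0 - s) * n * Iv;
    a[6] = gamma * Ir;
    a[7] = gamma * Iv;
    a[8] = Svp / D;
    double total = 0.0;
    for (int i = 0; i < 9; ++i) total += a[i];

    double t_next = (total > 0.0) ? t + exp_rand() / total : R_PosInf;
    while (rep_i < n_rep && report_times[rep_i] <= t_next) {
      report(rep_i, 0) = report_times[rep_i];
      report(rep_i, 1) = Sr; report(rep_i, 2) = Ir; report(rep_i, 3) = Sv;
      report(rep_i, 4) = Iv; report(rep_i, 5) = Svp;
      ++rep_i;
    }
    if (total <= 0.0 || t_next > horizon || rep_i >= n_rep) { t = t_next; break; }
    t = t_next;

    double u = unif_rand() * total;
    int ev = 0;
    double cum = 0.0;
    for (int i = 0; i < 9; ++i) { cum += a[i]; if (u <= cum) { ev = i; break; } }

    double f_den = Sr + b * Ir;
    double f = (f_den > 0.0) ? b * Ir / f_den : 0.0;
    int type;
    switch (ev) {
      case 0: Sr -= 1; Ir += 1; type = 0; break;             // infection
      case 1: Sr -= 1; Sv += 1; type = 1; break;             // move-out S
      case 2: Ir -= 1; Iv += 1; type = 1; break;             // move-out I
      case 3:                                                // move-in from Sv
        Sv -= 1;
        if (unif_rand() < k * f) { Ir += 1; type = 3; }
        else { Sr += 1; type = 2; }
        break;
      case 4:                                                // move-in from Svp
        Svp -= 1;
        if (unif_rand() < k * f) { Ir += 1; type = 3; }
        else { Sr += 1; type = 2; }
        break;
      case 5: Iv -= 1; Ir += 1; type = 2; break;             // move-in from Iv
      case 6: Ir -= 1; Sr += 1; type = 4; break;             // treatment Ir
      case 7: Iv -= 1; Svp += 1; type = 4; break;            // treatment Iv
      default: Svp -= 1; Sv += 1; type = 5; break;           // expiry
    }
    counts[type] += 1;
    if (keep_events) {
      ev_t.push_back(t);
      ev_type.push_back(type);
      ev_state.push_back(Sr); ev_state.push_back(Ir); ev_state.push_back(Sv);
      ev_state.push_back(Iv); ev_state.push_back(Svp);
    }
  }

  List out = List::create(
      Named("report") = report,
      Named("counts") = counts,
      Named("final") = NumericVector::create(Sr, Ir, Sv, Iv, Svp),
      Named("final_time") = std::min(t, horizon));
  if (keep_events) {
    int ne = ev_t.size();
    NumericMatrix states(ne, 5);
    for (int i = 0; i < ne; ++i)
      for (int j = 0; j < 5; ++j) states(i, j) = ev_state[5 * i + j];
    out["event_times"] = wrap(ev_t);
    out["event_types"] = wrap(ev_type);
    out["event_states"] = states;
  }
  return out;
}
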