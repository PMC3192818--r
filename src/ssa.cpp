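#include <Rcpp.h>
using namespace Rcpp;

// Table-driven Gillespie direct method on an enumerated truncated state
// space. Propensities and destinations are precomputed per state in R;
// jump-kernel reactions carry per-state destination lists with cumulative
// probabilities. Occupancy (time-weighted) is accumulated after
// `burn_in`; the event record is kept while it fits in `record_max`.
//
// A:        n_states x n_rxn propensity table
// dest:     per reaction, either an IntegerVector of 1-based destination
//           indices per state (0 = transition blocked by truncation), or a
//           List(ptr, idx, cum) flattened kernel table (ptr is 0-based,
//           length n_states + 1).
// [[Rcpp::export]]
List ssa_run_cpp(NumericMatrix A, List dest, int init, double t_max,
                 double burn_in, int record_max) {
  const int n_states = A.nrow(), n_rxn = A.ncol();
  NumericVector total(n_states);
  for (int s = 0; s < n_states; ++s) {
    double tot = 0.0;
    for (int j = 0; j < n_rxn; ++j) tot += A(s, j);
    total[s] = tot;
  }
  std::vector<double> occ(n_states, 0.0);
  std::vector<double> rec_t;
  std::vector<int> rec_s;
  bool recording = record_max > 0;
  if (recording) { rec_t.reserve(1024); rec_s.reserve(1024); }

  int cur = init - 1;
  double t = 0.0;
  bool absorbed = false;
  long long n_events = 0;

  while (t < t_max) {
    double tot = total[cur];
    if (tot <= 0.0) {
      // absorbing state: it holds the chain for the rest of the horizon
      absorbed = true;
      double from = t > burn_in ? t : burn_in;
      if (t_max > from) occ[cur] += t_max - from;
      t = t_max;
      break;
    }
    double dt = R::exp_rand() / tot;
    double t_next = t + dt;
    if (t_next > t_max) t_next = t_max;
    // time-weighted occupancy after burn-in
    if (t_next > burn_in) {
      double from = t > burn_in ? t : burn_in;
      occ[cur] += t_next - from;
    }
    if (t + dt >= t_max) { t = t_max; break; }
    t += dt;
    // choose reaction
    double u = unif_rand() * tot;
    int j = 0;
    double acc = A(cur, 0);
    while (acc < u && j < n_rxn - 1) { ++j; acc += A(cur, j); }
    // destination
    SEXP dj = dest[j];
    int nxt = cur;
    if (TYPEOF(dj) == INTSXP) {
      int d = INTEGER(dj)[cur];
      if (d == 0) continue;  // blocked (zero-rate in A; defensive)
      nxt = d - 1;
    } else {
      List kl(dj);
      IntegerVector ptr = kl["ptr"];
      IntegerVector idx = kl["idx"];
      NumericVector cum = kl["cum"];
      int lo = ptr[cur], hi = ptr[cur + 1];
      double v = unif_rand();
      // binary search for first cum >= v within [lo, hi)
      int a = lo, b = hi - 1;
      while (a < b) {
        int mid = (a + b) / 2;
        if (cum[mid] >= v) b = mid; else a = mid + 1;
      }
      nxt = idx[a] - 1;
    }
    cur = nxt;
    ++n_events;
    if (recording) {
      if ((long long)rec_t.size() < record_max) {
        rec_t.push_back(t);
        rec_s.push_back(cur + 1);
      } else {
        recording = false;
        rec_t.clear(); rec_s.clear();
      }
    }
  }

  return List::create(
    _["occupancy"] = NumericVector(occ.begin(), occ.end()),
    _["t_end"] = t,
    _["n_events"] = (double)n_events,
    _["absorbed"] = absorbed,
    _["times"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["state_idx"] = IntegerVector(rec_s.begin(), rec_s.end()),
    _["recorded"] = recording || n_events == 0
  );
}
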