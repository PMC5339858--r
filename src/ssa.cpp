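#include <Rcpp.h>
#include <vector>

// Direct-method Gillespie kernel for a mass-action network.
//
// Propensity of reaction r: rates[r] * product of state over its reactant
// indices (zeroth/first/second order; reactant species are distinct).
// Uses R's RNG so that set.seed() in R makes trajectories reproducible.
// States are carried as doubles but remain integer-valued by construction.
//
// Records the state at t = record_start, record_start + record_interval, ...
// up to t_end (sample-and-hold between reaction events).

// [[Rcpp::export(name = ".ssa_kernel")]]
Rcpp::List ssa_kernel(Rcpp::IntegerMatrix stoich,
                      Rcpp::NumericVector rates,
                      Rcpp::List reactants,
                      Rcpp::NumericVector init,
                      double t_end,
                      double record_start,
                      double record_interval) {
  const int n_sp = stoich.nrow();
  const int n_rx = stoich.ncol();
  if (rates.size() != n_rx || reactants.size() != n_rx)
    Rcpp::stop("rates/reactants length mismatch with stoichiometry");
  if (record_interval <= 0.0 || t_end <= 0.0 || record_start < 0.0)
    Rcpp::stop("invalid time arguments");

  // flatten reactant index lists (0-based)
  std::vector<int> r_off(n_rx + 1, 0);
  std::vector<int> r_idx;
  for (int r = 0; r < n_rx; ++r) {
    Rcpp::IntegerVector v = reactants[r];
    r_off[r + 1] = r_off[r] + v.size();
    for (int k = 0; k < v.size(); ++k) {
      int i = v[k] - 1;
      if (i < 0 || i >= n_sp) Rcpp::stop("reactant index out of range");
      r_idx.push_back(i);
    }
  }

  std::vector<double> x(n_sp);
  for (int i = 0; i < n_sp; ++i) {
    x[i] = init[i];
    if (x[i] < 0 || x[i] != std::floor(x[i]))
      Rcpp::stop("initial state must be non-negative integers");
  }

  const int n_rec = (int)std::floor((t_end - record_start) / record_interval) + 1;
  if (n_rec < 1) Rcpp::stop("no record times before t_end");
  Rcpp::NumericMatrix out(n_rec, n_sp);
  Rcpp::NumericVector times(n_rec);

  Rcpp::RNGScope scope;
  std::vector<double> a(n_rx);
  double t = 0.0;
  int rec = 0;
  const double overflow = 2147483647.0;

  while (rec < n_rec) {
    double a0 = 0.0;
    for (int r = 0; r < n_rx; ++r) {
      double ar = rates[r];
      for (int k = r_off[r]; k < r_off[r + 1]; ++k) ar *= x[r_idx[k]];
      a[r] = ar;
      a0 += ar;
    }

    double t_next;
    if (a0 <= 0.0) {
      t_next = t_end + record_interval;  // frozen: flush remaining records
    } else {
      t_next = t + R::exp_rand() / a0;
    }

    // record all sample times strictly before the next event
    while (rec < n_rec) {
      double t_rec = record_start + rec * record_interval;
      if (t_rec >= t_next) break;
      times[rec] = t_rec;
      for (int i = 0; i < n_sp; ++i) out(rec, i) = x[i];
      ++rec;
    }
    if (rec >= n_rec || t_next > t_end) {
      // flush any remaining records at the frozen/final state
      while (rec < n_rec) {
        double t_rec = record_start + rec * record_interval;
        times[rec] = t_rec;
        for (int i = 0; i < n_sp; ++i) out(rec, i) = x[i];
        ++rec;
      }
      break;
    }

    // select reaction
    double u = R::unif_rand() * a0;
    int sel = n_rx - 1;
    double cum = 0.0;
    for (int r = 0; r < n_rx; ++r) {
      cum += a[r];
      if (u <= cum) { sel = r; break; }
    }
    for (int i = 0; i < n_sp; ++i) {
      x[i] += stoich(i, sel);
      if (x[i] > overflow) Rcpp::stop("copy number overflow in SSA");
      if (x[i] < 0) x[i] = 0;  // cannot occur with valid propensities
    }
    t = t_next;
  }

  return Rcpp::List::create(Rcpp::Named("time") = times,
                            Rcpp::Named("states") = out);
}
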