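#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) over a reaction
// network with mass-action propensities and an optional saturation factor:
//   a_j(x) = c_j * prod_i x_i^{p_ji}            [ / (s_j + x_{v_j}) ]
// The jump process is sampled onto the output grid by carrying the last
// state forward; if the total propensity reaches 0 the remaining grid is
// filled with the absorbing state. Uses R's RNG (two uniforms per event:
// waiting time, then event choice), so set.seed() governs reproducibility
// and the draws match the plain-R reference loop exactly.
//
// The hot loop runs over a flattened event table: each propensity is a
// rate constant times at most two state-variable factors (a squared
// variable contributes the same index twice) and an optional saturation
// divisor. Exponents above 2 are rejected here; the plain-R reference
// loop in simulate_stochastic() has no such limit.
//
// change:    nevents x nvars integer state-change matrix
// rate:      nevents rate constants (parameter products, precomputed in R)
// powers:    nevents x nvars integer exponents (each row summing to <= 2)
// sat_var:   per event, 0-based index of the saturating variable or -1
// sat_const: per event, the saturation constant s_j (ignored if sat_var<0)
// x0:        initial state (nonnegative integers as doubles)
// grid:      strictly increasing output times, grid[0] = tstart
// [[Rcpp::export]]
NumericMatrix ssa_mass_action(IntegerMatrix change, NumericVector rate,
                              IntegerMatrix powers, IntegerVector sat_var,
                              NumericVector sat_const, NumericVector x0,
                              NumericVector grid) {
  const int ne = change.nrow(), nv = change.ncol(), ng = grid.size();
  NumericMatrix out(ng, nv);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(ne), rt(rate.begin(), rate.end());
  std::vector<double> sc(sat_const.begin(), sat_const.end());
  std::vector<double> tgrid(grid.begin(), grid.end());
  // flatten: per event, up to two factor variable indices (-1 = none)
  std::vector<int> f1(ne, -1), f2(ne, -1), sv(ne);
  std::vector<int> chg(ne * nv);
  for (int j = 0; j < ne; ++j) {
    int nf = 0;
    for (int i = 0; i < nv; ++i) {
      chg[j * nv + i] = change(j, i);
      for (int q = 0; q < powers(j, i); ++q) {
        if (nf == 0) f1[j] = i;
        else if (nf == 1) f2[j] = i;
        else stop("compiled SSA supports total exponent <= 2 per event");
        ++nf;
      }
    }
    sv[j] = sat_var[j];
  }
  double t_now = tgrid[0];
  int gi = 0;
  RNGScope scope;
  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < ne; ++j) {
      double aj = rt[j];
      if (f1[j] >= 0) aj *= x[f1[j]];
      if (f2[j] >= 0) aj *= x[f2[j]];
      if (sv[j] >= 0) aj /= sc[j] + x[sv[j]];
      a[j] = aj;
      a0 += aj;
    }
    if (a0 <= 0.0) {  // absorbed
      for (; gi < ng; ++gi)
        for (int i = 0; i < nv; ++i) out(gi, i) = x[i];
      break;
    }
    const double u1 = unif_rand();
    const double u2 = unif_rand();
    const double t_next = t_now - std::log(u1) / a0;
    while (gi < ng && tgrid[gi] <= t_next) {
      for (int i = 0; i < nv; ++i) out(gi, i) = x[i];
      ++gi;
    }
    if (gi >= ng) break;
    const double target = u2 * a0;
    double acc = 0.0;
    int j = ne - 1;
    for (int jj = 0; jj < ne; ++jj) {
      acc += a[jj];
      if (target < acc) { j = jj; break; }  // matches findInterval semantics
    }
    const int *cj = &chg[j * nv];
    for (int i = 0; i < nv; ++i) x[i] += cj[i];
    t_now = t_next;
  }
  return out;
}
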