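#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of a small
// reaction network over a fixed number of cell generations.
//
// Reaction propensity types:
//   0 constant:        a = rate
//   1 unary:           a = rate * n[i]
//   2 binary:          a = rate * n[i] * n[j]   (rate already in count units)
//   3 promoter (Hill): a = Omega * (V0 + Vf * x / (1 + x)),
//                      x = ((n[i]/Omega)/Kf)^h
//
// Generations have fixed duration t_gen. If `division` is true, every
// molecule count is partitioned binomially (p = 1/2) into the followed
// daughter cell at each generation boundary; otherwise boundaries are
// bookkeeping marks only (dilution must then be represented as unary
// reactions).
//
// Uses R's RNG, so results are reproducible under set.seed().

// [[Rcpp::export]]
List ssa_run_cpp(IntegerMatrix nu, IntegerVector rtype, NumericVector rate,
                 IntegerVector ri, IntegerVector rj, NumericMatrix hillpar,
                 double Omega, NumericVector init, double t_gen, int n_gen,
                 bool division, double max_steps) {
  const int n_sp = nu.nrow();
  const int n_rx = nu.ncol();
  std::vector<double> n(init.begin(), init.end());
  std::vector<double> a(n_rx);

  NumericMatrix gen_means(n_gen, n_sp);
  NumericMatrix gen_end(n_gen, n_sp);
  double t = 0.0, steps = 0.0;
  double t_end = t_gen * n_gen;

  int g = 0;
  double t_next = t_gen;
  std::vector<double> acc(n_sp, 0.0);

  auto accumulate = [&](double dt) {
    for (int s = 0; s < n_sp; ++s) acc[s] += n[s] * dt;
  };

  while (g < n_gen) {
    double a0 = 0.0;
    for (int r = 0; r < n_rx; ++r) {
      double ar;
      switch (rtype[r]) {
      case 0: ar = rate[r]; break;
      case 1: ar = rate[r] * n[ri[r]]; break;
      case 2: ar = rate[r] * n[ri[r]] * n[rj[r]]; break;
      default: {
        double x = n[ri[r]] / Omega / hillpar(r, 2);
        double xh = std::pow(x, hillpar(r, 3));
        ar = Omega * (hillpar(r, 0) + hillpar(r, 1) * xh / (1.0 + xh));
      }
      }
      if (ar < 0 || !R_finite(ar))
        stop("invalid propensity in reaction %d (value %g)", r + 1, ar);
      a[r] = ar;
      a0 += ar;
    }

    double dt = (a0 > 0.0) ? R::exp_rand() / a0 : R_PosInf;
    if (t + dt >= t_next || a0 <= 0.0) {
      // advance to the generation boundary without firing
      accumulate(t_next - t);
      t = t_next;
      for (int s = 0; s < n_sp; ++s) {
        gen_means(g, s) = acc[s] / t_gen;
        acc[s] = 0.0;
      }
      if (division)
        for (int s = 0; s < n_sp; ++s)
          n[s] = R::rbinom(n[s], 0.5);
      for (int s = 0; s < n_sp; ++s) gen_end(g, s) = n[s];
      ++g;
      t_next = t_gen * (g + 1);
      continue;
    }

    accumulate(dt);
    t += dt;
    double u = unif_rand() * a0, cum = 0.0;
    int r = n_rx - 1;
    for (int k = 0; k < n_rx; ++k) {
      cum += a[k];
      if (u <= cum) { r = k; break; }
    }
    for (int s = 0; s < n_sp; ++s) {
      n[s] += nu(s, r);
      if (n[s] < 0)
        stop("negative count for species %d after reaction %d", s + 1, r + 1);
    }
    if (++steps > max_steps)
      stop("SSA exceeded max_steps = %g before t = %g", max_steps, t_end);
  }

  return List::create(_["final"] = NumericVector(n.begin(), n.end()),
                      _["gen_means"] = gen_means,
                      _["gen_end"] = gen_end,
                      _["steps"] = steps);
}
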