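#include <Rcpp.h>
using namespace Rcpp;

static inline double sigm(double v, double h) {
  return h / (1.0 + std::exp(-v));
}

// Fixed-step Euler-Maruyama integration of the coupled Wilson-Cowan network.
//
// State update per step (both E and I, additive noise):
//   x_{k+1} = x_k + f(x_k) dt + s sqrt(dt) xi,   xi ~ N(0, 1) i.i.d.
// Noise is drawn from R's RNG (set.seed() in R gives bit-identical runs);
// the draw order is fixed: per step, E noise for regions 1..N, then I noise.
// After each step the state is clipped to [0, 1]; clips are counted.
// A pre-clip excursion beyond |x| > 10 aborts with the offending region/step.
//
// [[Rcpp::export]]
List wc_integrate_cpp(NumericMatrix A, double G,
                      NumericVector tau_e, NumericVector tau_i,
                      NumericVector a_e, NumericVector a_i,
                      NumericVector w_ee, NumericVector w_ei,
                      NumericVector w_ie, NumericVector w_ii,
                      NumericVector B_e, NumericVector B_i,
                      NumericVector h, NumericVector J_const,
                      NumericVector E0, NumericVector I0,
                      double dt, int n_steps, int store_every,
                      double noise_s, bool noise_on_I) {
  const int N = A.nrow();
  const double sq = noise_s * std::sqrt(dt);
  const int n_store = n_steps / store_every;
  NumericMatrix Eout(N, n_store), Iout(N, n_store);
  std::vector<double> E(E0.begin(), E0.end()), I(I0.begin(), I0.end());
  std::vector<double> Je(N), Enew(N), Inew(N);
  long clipped = 0;
  RNGScope scope;
  int stored = 0;
  for (int k = 0; k < n_steps; ++k) {
    // coupling term J_e = G * A %*% E + constant drive
    for (int a = 0; a < N; ++a) {
      double s = 0.0;
      for (int b = 0; b < N; ++b) s += A(a, b) * E[b];
      Je[a] = G * s + J_const[a];
    }
    for (int a = 0; a < N; ++a) {
      double u = a_e[a] * w_ee[a] * E[a] - w_ei[a] * I[a] - B_e[a] + Je[a];
      double v = a_i[a] * w_ie[a] * E[a] - w_ii[a] * I[a] - B_i[a];
      Enew[a] = E[a] + dt * (-E[a] + (1.0 - E[a]) * sigm(u, h[a])) / tau_e[a];
      Inew[a] = I[a] + dt * (-I[a] + (1.0 - I[a]) * sigm(v, h[a])) / tau_i[a];
    }
    if (noise_s > 0.0) {
      for (int a = 0; a < N; ++a) Enew[a] += sq * norm_rand();
      if (noise_on_I) for (int a = 0; a < N; ++a) Inew[a] += sq * norm_rand();
    }
    for (int a = 0; a < N; ++a) {
      if (std::abs(Enew[a]) > 10.0 || std::abs(Inew[a]) > 10.0 ||
          !std::isfinite(Enew[a]) || !std::isfinite(Inew[a])) {
        stop("numerical blow-up in region %d at step %d", a + 1, k + 1);
      }
      if (Enew[a] < 0.0) { Enew[a] = 0.0; ++clipped; }
      else if (Enew[a] > 1.0) { Enew[a] = 1.0; ++clipped; }
      if (Inew[a] < 0.0) { Inew[a] = 0.0; ++clipped; }
      else if (Inew[a] > 1.0) { Inew[a] = 1.0; ++clipped; }
      E[a] = Enew[a];
      I[a] = Inew[a];
    }
    if ((k + 1) % store_every == 0) {
      for (int a = 0; a < N; ++a) {
        Eout(a, stored) = E[a];
        Iout(a, stored) = I[a];
      }
      ++stored;
    }
  }
  return List::create(_["E"] = Eout, _["I"] = Iout,
                      _["n_clipped"] = (double)clipped,
                      _["n_steps"] = n_steps);
}
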