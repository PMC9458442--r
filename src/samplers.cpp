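#include <Rcpp.h>
using namespace Rcpp;

// Tight per-step loops live here; all randomness goes through R's RNG so that
// set.seed() on the R side gives byte-identical trajectories.

static inline double wrap_period(double d, double period) {
  if (period <= 0.0) return d;
  return d - period * std::floor(d / period + 0.5);
}

// [[Rcpp::export]]
IntegerVector cpp_sample_markov_chain(NumericMatrix T, int n_steps, int start) {
  int k = T.nrow();
  // cumulative rows for inverse-cdf sampling
  NumericMatrix cum(k, k);
  for (int i = 0; i < k; ++i) {
    double s = 0.0;
    for (int j = 0; j < k; ++j) { s += T(i, j); cum(i, j) = s; }
    cum(i, k - 1) = 1.0; // guard against rounding
  }
  IntegerVector out(n_steps);
  int state = start;
  out[0] = state;
  for (int t = 1; t < n_steps; ++t) {
    double u = unif_rand();
    int j = 0;
    while (cum(state, j) < u && j < k - 1) ++j;
    state = j;
    out[t] = state;
  }
  return out;
}

// potential ids: 0 harmonic, 1 quartic double well, 2 five-basin 2-D Gaussians
static void potential_grad(int id, const NumericVector& par,
                           const NumericMatrix& centers,
                           const double* x, int dim, double* g) {
  if (id == 0) {                     // V = 0.5 * k * |x|^2
    for (int d = 0; d < dim; ++d) g[d] = par[0] * x[d];
  } else if (id == 1) {              // V = h * ((x/a)^2 - 1)^2, 1-D
    double a = par[1], u = x[0] / a;
    g[0] = par[0] * 4.0 * u * (u * u - 1.0) / a;
  } else {                           // sum of inverted Gaussians + steep wall
    int nb = centers.nrow();
    for (int d = 0; d < dim; ++d) g[d] = 0.0;
    for (int b = 0; b < nb; ++b) {
      double A = centers(b, dim), s2 = centers(b, dim + 1) * centers(b, dim + 1);
      double r2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        double dd = x[d] - centers(b, d);
        r2 += dd * dd;
      }
      double e = A * std::exp(-r2 / (2.0 * s2));
      for (int d = 0; d < dim; ++d) g[d] += e * (x[d] - centers(b, d)) / s2;
    }
    // confining octic wall centred on par[1], half-width par[2], strength par[0]
    for (int d = 0; d < dim; ++d) {
      double u = (x[d] - par[1]) / par[2];
      double u7 = u * u * u * u * u * u * u;
      g[d] += par[0] * 8.0 * u7 / par[2];
    }
  }
}

// [[Rcpp::export]]
List cpp_langevin(int pot_id, NumericVector par, NumericMatrix centers,
                  NumericVector x0, double dt, double kT, double gamma,
                  int n_steps, double box) {
  int dim = x0.size();
  NumericMatrix X(n_steps, dim);
  std::vector<double> x(dim), g(dim);
  for (int d = 0; d < dim; ++d) x[d] = x0[d];
  double mob = dt / gamma;
  double noise = std::sqrt(2.0 * kT * dt / gamma);
  for (int t = 0; t < n_steps; ++t) {
    potential_grad(pot_id, par, centers, x.data(), dim, g.data());
    for (int d = 0; d < dim; ++d) {
      x[d] += -mob * g[d] + noise * norm_rand();
      if (std::fabs(x[d]) > box || !std::isfinite(x[d]))
        stop("trajectory left the bounding box (|x| > %f) at step %d: time step dt is likely unstable", box, t + 1);
      X(t, d) = x[d];
    }
  }
  return List::create(_["x"] = X);
}

// [[Rcpp::export]]
IntegerVector cpp_assign_centers(NumericMatrix X, NumericMatrix C) {
  int n = X.nrow(), k = C.nrow(), d = X.ncol();
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        double diff = X(i, m) - C(j, m);
        s += diff * diff;
        if (s >= best) break;
      }
      if (s < best) { best = s; bj = j; }
    }
    lab[i] = bj;
  }
  return lab;
}

// Monte-Carlo forward-committor oracle: fraction of chains started in each
// state that reach B before A.
// [[Rcpp::export]]
NumericVector cpp_hitting_prob(NumericMatrix T, IntegerVector A, IntegerVector B,
                               int n_rep, int max_steps) {
  int k = T.nrow();
  std::vector<int> role(k, 0); // 0 free, 1 in A, 2 in B
  for (int i = 0; i < A.size(); ++i) role[A[i]] = 1;
  for (int i = 0; i < B.size(); ++i) role[B[i]] = 2;
  NumericMatrix cum(k, k);
  for (int i = 0; i < k; ++i) {
    double s = 0.0;
    for (int j = 0; j < k; ++j) { s += T(i, j); cum(i, j) = s; }
    cum(i, k - 1) = 1.0;
  }
  NumericVector q(k);
  for (int s0 = 0; s0 < k; ++s0) {
    if (role[s0] == 1) { q[s0] = 0.0; continue; }
    if (role[s0] == 2) { q[s0] = 1.0; continue; }
    int hitB = 0;
    for (int r = 0; r < n_rep; ++r) {
      int s = s0;
      for (int t = 0; t < max_steps; ++t) {
        double u = unif_rand();
        int j = 0;
        while (cum(s, j) < u && j < k - 1) ++j;
        s = j;
        if (role[s] == 1) break;
        if (role[s] == 2) { ++hitB; break; }
      }
    }
    q[s0] = (double)hitB / n_rep;
  }
  return q;
}

// 1-D CV potentials for the meta-eABF engine:
// 0 harmonic 0.5*k*x^2, 1 quartic double well h*((x/a)^2-1)^2, 2 flat
static inline double cv_grad(int id, const NumericVector& par, double x) {
  if (id == 0) return par[0] * x;
  if (id == 1) { double a = par[1], u = x / a; return par[0] * 4.0 * u * (u * u - 1.0) / a; }
  return 0.0;
}

// Extended-system ABF + metadynamics on a 1-D collective variable xi = x.
// Accumulates, per xi bin and time block, the biased histogram and the mean
// spring stretch (lambda - xi) needed by the CZAR estimator, and per lambda
// bin the running mean spring force used as the adaptive bias.
// [[Rcpp::export]]
List cpp_meta_eabf(int pot_id, NumericVector par, double x0,
                   double dt, double kT, double gamma_x, double gamma_l,
                   double ku, int n_steps,
                   double gmin, double gmax, int nbins, bool periodic,
                   int abf_nfull, double hill_height, double hill_width,
                   int hill_stride, int n_blocks, int record_stride) {
  double period = periodic ? (gmax - gmin) : -1.0;
  double bw = (gmax - gmin) / nbins;
  double x = x0, lam = x0;
  double mob_x = dt / gamma_x, mob_l = dt / gamma_l;
  double nz_x = std::sqrt(2.0 * kT * dt / gamma_x);
  double nz_l = std::sqrt(2.0 * kT * dt / gamma_l);

  NumericMatrix cnt(n_blocks, nbins), sdisp(n_blocks, nbins);
  NumericVector abf_cnt(nbins), abf_sum(nbins);
  NumericVector W(nbins), dW(nbins); // deposited metadynamics bias on grid
  int n_reflect = 0;
  int block_len = n_steps / n_blocks + 1;
  int n_rec = n_steps / record_stride;
  NumericMatrix rec(n_rec, 2);
  int irec = 0;

  for (int t = 0; t < n_steps; ++t) {
    double d = wrap_period(x - lam, period); // spring stretch xi - lambda
    // physical particle
    double fx = -cv_grad(pot_id, par, x) - ku * d;
    x += mob_x * fx + nz_x * norm_rand();
    if (periodic) {
      x = gmin + wrap_period(x - gmin - 0.5 * period, period) + 0.5 * period;
    } else if (x < gmin) { x = 2.0 * gmin - x; ++n_reflect; }
    else if (x > gmax) { x = 2.0 * gmax - x; ++n_reflect; }

    // bias forces evaluated in lambda's bin
    int bl = (int)((lam - gmin) / bw); if (bl < 0) bl = 0; if (bl >= nbins) bl = nbins - 1;
    double spring_l = ku * d; // systematic force on lambda
    abf_cnt[bl] += 1.0; abf_sum[bl] += spring_l;
    double f_abf = 0.0;
    if (abf_nfull > 0) { // abf_nfull <= 0 disables the adaptive force
      double ramp = abf_cnt[bl] < abf_nfull ? abf_cnt[bl] / abf_nfull : 1.0;
      f_abf = -ramp * abf_sum[bl] / abf_cnt[bl];
    }
    // metadynamics force by linear interpolation of grid gradient
    double gpos = (lam - gmin) / bw - 0.5;
    int g0 = (int)std::floor(gpos);
    double fr = gpos - g0;
    int ga = g0 < 0 ? 0 : (g0 >= nbins ? nbins - 1 : g0);
    int gb = ga + 1 >= nbins ? nbins - 1 : ga + 1;
    double f_meta = -((1.0 - fr) * dW[ga] + fr * dW[gb]);

    double fl = spring_l + f_abf + f_meta;
    lam += mob_l * fl + nz_l * norm_rand();
    if (periodic) {
      lam = gmin + wrap_period(lam - gmin - 0.5 * period, period) + 0.5 * period;
    } else if (lam < gmin) { lam = 2.0 * gmin - lam; ++n_reflect; }
    else if (lam > gmax) { lam = 2.0 * gmax - lam; ++n_reflect; }

    // metadynamics deposition
    if (hill_height > 0.0 && (t + 1) % hill_stride == 0) {
      double s2 = hill_width * hill_width;
      for (int b = 0; b < nbins; ++b) {
        double c = gmin + (b + 0.5) * bw;
        double dd = wrap_period(c - lam, period);
        double e = hill_height * std::exp(-dd * dd / (2.0 * s2));
        W[b] += e;
        dW[b] += -e * dd / s2;
      }
    }

    // CZAR accumulators binned on xi = x
    int bx = (int)((x - gmin) / bw); if (bx < 0) bx = 0; if (bx >= nbins) bx = nbins - 1;
    int blk = t / block_len; if (blk >= n_blocks) blk = n_blocks - 1;
    cnt(blk, bx) += 1.0;
    sdisp(blk, bx) += wrap_period(lam - x, period);

    if ((t + 1) % record_stride == 0 && irec < n_rec) {
      rec(irec, 0) = x; rec(irec, 1) = lam; ++irec;
    }
  }

  return List::create(
    _["counts"] = cnt, _["sum_disp"] = sdisp,
    _["abf_counts"] = abf_cnt, _["abf_force_sum"] = abf_sum,
    _["meta_bias"] = W, _["meta_grad"] = dW,
    _["n_reflections"] = n_reflect, _["traj"] = rec);
}
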