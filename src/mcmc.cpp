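#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared numerical kernels for the Metropolis-within-Gibbs samplers.
// Detection is half-normal: p(d) = p0 * exp(-d^2 / (2 sigma_det^2)).
// Probabilities are clipped to [PCLIP, 1 - PCLIP] inside log-likelihoods so
// that distant receivers (beyond ~7 sigma_det) cannot produce -Inf through
// floating-point underflow.

static const double PCLIP = 1e-12;

static inline double hn_prob(double d2, double p0, double s2det) {
  double p = p0 * std::exp(-d2 / (2.0 * s2det));
  if (p < PCLIP) p = PCLIP;
  if (p > 1.0 - PCLIP) p = 1.0 - PCLIP;
  return p;
}

// Bernoulli encounter log-likelihood of one occasion (row `row` of Y).
static double enc_ll_row(double ux, double uy, const IntegerMatrix &Y, int row,
                         const NumericMatrix &X, double p0, double s2det) {
  const int J = X.nrow();
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    double dx = ux - X(j, 0), dy = uy - X(j, 1);
    double p = hn_prob(dx * dx + dy * dy, p0, s2det);
    ll += Y(row, j) ? std::log(p) : std::log1p(-p);
  }
  return ll;
}

// Encounter log-likelihood of an all-zero occasion at (ux, uy).
static double enc_ll_zero(double ux, double uy, const NumericMatrix &X,
                          double p0, double s2det) {
  const int J = X.nrow();
  double ll = 0.0;
  for (int j = 0; j < J; ++j) {
    double dx = ux - X(j, 0), dy = uy - X(j, 1);
    ll += std::log1p(-hn_prob(dx * dx + dy * dy, p0, s2det));
  }
  return ll;
}

// Brownian-motion transition log-density over elapsed time `delta`:
// independent Normal increments on each axis with variance sigma_u^2 * delta.
static inline double mov_ll(double ax, double ay, double bx, double by,
                            double su2, double delta) {
  double v = su2 * delta;
  double dx = bx - ax, dy = by - ay;
  return -std::log(2.0 * M_PI * v) - (dx * dx + dy * dy) / (2.0 * v);
}

// ---------------------------------------------------------------------------
// Adaptive random-walk scale: multiplicative update toward a target
// acceptance rate, applied only during burn-in.
struct AdaptScale {
  double s;
  int acc, tries;
  AdaptScale(double s0 = 0.1) : s(s0), acc(0), tries(0) {}
  void tally(bool accepted) { tries++; if (accepted) acc++; }
  void maybe_adapt() {
    if (tries >= 50) {
      double rate = (double)acc / tries;
      s *= std::exp(0.8 * (rate - 0.35));
      if (s < 1e-6) s = 1e-6;
      if (s > 1e3) s = 1e3;
      acc = 0; tries = 0;
    }
  }
};

static inline bool mh_accept(double logr) {
  return std::log(R::runif(0.0, 1.0)) < logr;
}

// ---------------------------------------------------------------------------
// Independent per-signal localization: uniform location prior over the
// rectangular state space, joint posterior over (p0, sigma_det) and every
// detected-occasion location, pooled across tags.

static double total_enc_ll(const std::vector<IntegerMatrix> &Ys,
                           const std::vector<NumericMatrix> &Us,
                           const NumericMatrix &X, double p0, double s2det) {
  double ll = 0.0;
  for (size_t i = 0; i < Ys.size(); ++i) {
    const int T = Ys[i].nrow();
    for (int t = 0; t < T; ++t)
      ll += enc_ll_row(Us[i](t, 0), Us[i](t, 1), Ys[i], t, X, p0, s2det);
  }
  return ll;
}

// [[Rcpp::export]]
List mcmc_independent_cpp(List Y_list, NumericMatrix X, NumericVector space,
                          double sigdet_max, List u_init, double p0_init,
                          double sigdet_init, int n_iter, int n_burn, int thin,
                          bool fix_params) {
  const int n_tags = Y_list.size();
  std::vector<IntegerMatrix> Ys(n_tags);
  std::vector<NumericMatrix> Us(n_tags);
  std::vector<std::vector<AdaptScale> > loc_s(n_tags);
  for (int i = 0; i < n_tags; ++i) {
    Ys[i] = as<IntegerMatrix>(Y_list[i]);
    Us[i] = clone(as<NumericMatrix>(u_init[i]));
    loc_s[i].assign(Ys[i].nrow(), AdaptScale(sigdet_init));
  }
  double p0 = p0_init, sigdet = sigdet_init;
  AdaptScale p0_s(0.05), sd_s(0.1 * sigdet_init);
  const double xmin = space[0], xmax = space[1], ymin = space[2], ymax = space[3];

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix params(n_keep, 2);
  List traj(n_tags);
  std::vector<NumericVector> traj_store(n_tags);
  for (int i = 0; i < n_tags; ++i) {
    NumericVector v(n_keep * Ys[i].nrow() * 2);
    v.attr("dim") = IntegerVector::create(n_keep, Ys[i].nrow(), 2);
    traj_store[i] = v;
  }
  int keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    double s2det = sigdet * sigdet;
    for (int i = 0; i < n_tags; ++i) {
      const int T = Ys[i].nrow();
      for (int t = 0; t < T; ++t) {
        double s = loc_s[i][t].s;
        double nx = Us[i](t, 0) + R::rnorm(0.0, s);
        double ny = Us[i](t, 1) + R::rnorm(0.0, s);
        bool acc = false;
        if (nx >= xmin && nx <= xmax && ny >= ymin && ny <= ymax) {
          double logr = enc_ll_row(nx, ny, Ys[i], t, X, p0, s2det) -
                        enc_ll_row(Us[i](t, 0), Us[i](t, 1), Ys[i], t, X, p0, s2det);
          if (mh_accept(logr)) { Us[i](t, 0) = nx; Us[i](t, 1) = ny; acc = true; }
        }
        loc_s[i][t].tally(acc);
        if (it < n_burn) loc_s[i][t].maybe_adapt();
      }
    }
    if (!fix_params) {
      double cur = total_enc_ll(Ys, Us, X, p0, s2det);
      double p0p = p0 + R::rnorm(0.0, p0_s.s);
      bool acc = false;
      if (p0p > 0.0 && p0p < 1.0) {
        double prop = total_enc_ll(Ys, Us, X, p0p, s2det);
        if (mh_accept(prop - cur)) { p0 = p0p; cur = prop; acc = true; }
      }
      p0_s.tally(acc); if (it < n_burn) p0_s.maybe_adapt();
      double sdp = sigdet + R::rnorm(0.0, sd_s.s);
      acc = false;
      if (sdp > 0.0 && sdp < sigdet_max) {
        double prop = total_enc_ll(Ys, Us, X, p0, sdp * sdp);
        if (mh_accept(prop - cur)) { sigdet = sdp; acc = true; }
      }
      sd_s.tally(acc); if (it < n_burn) sd_s.maybe_adapt();
    }
    if (it >= n_burn && (it - n_burn) % thin == 0) {
      params(keep, 0) = p0; params(keep, 1) = sigdet;
      for (int i = 0; i < n_tags; ++i) {
        const int T = Ys[i].nrow();
        for (int t = 0; t < T; ++t) {
          traj_store[i][keep + (size_t)n_keep * t] = Us[i](t, 0);
          traj_store[i][keep + (size_t)n_keep * (T + t)] = Us[i](t, 1);
        }
      }
      keep++;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < n_tags; ++i) traj[i] = traj_store[i];
  return List::create(_["params"] = params, _["traj"] = traj);
}

// ---------------------------------------------------------------------------
// Movement-assisted localization with a fixed signal schedule (covers both
// the detection-only variant, where the schedule is the detected occasions
// and deltas are elapsed times between detections, and the known-interval
// variant, where the full schedule including all-zero occasions is given).

// [[Rcpp::export]]
List mcmc_movement_cpp(List Y_list, List delta_list, NumericMatrix X,
                       double sigdet_max, double sigu_max, List u_init,
                       double p0_init, double sigdet_init, double sigu_init,
                       int n_iter, int n_burn, int thin, bool fix_params) {
  const int n_tags = Y_list.size();
  std::vector<IntegerMatrix> Ys(n_tags);
  std::vector<NumericVector> Ds(n_tags);  // Ds[i][t]: elapsed time t-1 -> t
  std::vector<NumericMatrix> Us(n_tags);
  std::vector<std::vector<AdaptScale> > loc_s(n_tags);
  for (int i = 0; i < n_tags; ++i) {
    Ys[i] = as<IntegerMatrix>(Y_list[i]);
    Ds[i] = as<NumericVector>(delta_list[i]);
    Us[i] = clone(as<NumericMatrix>(u_init[i]));
    loc_s[i].assign(Ys[i].nrow(), AdaptScale(sigdet_init));
  }
  double p0 = p0_init, sigdet = sigdet_init, sigu = sigu_init;
  AdaptScale p0_s(0.05), sd_s(0.1 * sigdet_init), su_s(0.1 * sigu_init);

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix params(n_keep, 3);
  std::vector<NumericVector> traj_store(n_tags);
  for (int i = 0; i < n_tags; ++i) {
    NumericVector v(n_keep * Ys[i].nrow() * 2);
    v.attr("dim") = IntegerVector::create(n_keep, Ys[i].nrow(), 2);
    traj_store[i] = v;
  }
  int keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    double s2det = sigdet * sigdet, su2 = sigu * sigu;
    for (int i = 0; i < n_tags; ++i) {
      const int T = Ys[i].nrow();
      for (int t = 0; t < T; ++t) {
        double s = loc_s[i][t].s;
        double ox = Us[i](t, 0), oy = Us[i](t, 1);
        double nx = ox + R::rnorm(0.0, s), ny = oy + R::rnorm(0.0, s);
        double logr = enc_ll_row(nx, ny, Ys[i], t, X, p0, s2det) -
                      enc_ll_row(ox, oy, Ys[i], t, X, p0, s2det);
        if (t > 0)
          logr += mov_ll(Us[i](t - 1, 0), Us[i](t - 1, 1), nx, ny, su2, Ds[i][t]) -
                  mov_ll(Us[i](t - 1, 0), Us[i](t - 1, 1), ox, oy, su2, Ds[i][t]);
        if (t < T - 1)
          logr += mov_ll(nx, ny, Us[i](t + 1, 0), Us[i](t + 1, 1), su2, Ds[i][t + 1]) -
                  mov_ll(ox, oy, Us[i](t + 1, 0), Us[i](t + 1, 1), su2, Ds[i][t + 1]);
        bool acc = mh_accept(logr);
        if (acc) { Us[i](t, 0) = nx; Us[i](t, 1) = ny; }
        loc_s[i][t].tally(acc);
        if (it < n_burn) loc_s[i][t].maybe_adapt();
      }
    }
    if (!fix_params) {
      // detection parameters against the pooled encounter likelihood
      double cur = total_enc_ll(Ys, Us, X, p0, s2det);
      double p0p = p0 + R::rnorm(0.0, p0_s.s);
      bool acc = false;
      if (p0p > 0.0 && p0p < 1.0) {
        double prop = total_enc_ll(Ys, Us, X, p0p, s2det);
        if (mh_accept(prop - cur)) { p0 = p0p; cur = prop; acc = true; }
      }
      p0_s.tally(acc); if (it < n_burn) p0_s.maybe_adapt();
      double sdp = sigdet + R::rnorm(0.0, sd_s.s);
      acc = false;
      if (sdp > 0.0 && sdp < sigdet_max) {
        double prop = total_enc_ll(Ys, Us, X, p0, sdp * sdp);
        if (mh_accept(prop - cur)) { sigdet = sdp; acc = true; }
      }
      sd_s.tally(acc); if (it < n_burn) sd_s.maybe_adapt();
      // movement scale against the pooled trajectory likelihood
      double sup = sigu + R::rnorm(0.0, su_s.s);
      acc = false;
      if (sup > 0.0 && sup < sigu_max) {
        double mcur = 0.0, mprop = 0.0, sup2 = sup * sup;
        for (int i = 0; i < n_tags; ++i) {
          const int T = Ys[i].nrow();
          for (int t = 1; t < T; ++t) {
            mcur += mov_ll(Us[i](t - 1, 0), Us[i](t - 1, 1), Us[i](t, 0),
                           Us[i](t, 1), su2, Ds[i][t]);
            mprop += mov_ll(Us[i](t - 1, 0), Us[i](t - 1, 1), Us[i](t, 0),
                            Us[i](t, 1), sup2, Ds[i][t]);
          }
        }
        if (mh_accept(mprop - mcur)) { sigu = sup; acc = true; }
      }
      su_s.tally(acc); if (it < n_burn) su_s.maybe_adapt();
    }
    if (it >= n_burn && (it - n_burn) % thin == 0) {
      params(keep, 0) = p0; params(keep, 1) = sigdet; params(keep, 2) = sigu;
      for (int i = 0; i < n_tags; ++i) {
        const int T = Ys[i].nrow();
        for (int t = 0; t < T; ++t) {
          traj_store[i][keep + (size_t)n_keep * t] = Us[i](t, 0);
          traj_store[i][keep + (size_t)n_keep * (T + t)] = Us[i](t, 1);
        }
      }
      keep++;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }
  List traj(n_tags);
  for (int i = 0; i < n_tags; ++i) traj[i] = traj_store[i];
  return List::create(_["params"] = params, _["traj"] = traj);
}

// ---------------------------------------------------------------------------
// Unknown-interval model: the number of signals missed within each
// inter-detection gap is latent.  A gap holding n missed signals is crossed
// by k inter-signal intervals (k = n + k_offset; the default convention is
// k = n + 1).  The schedule sub-model is the normal approximation to a sum
// of k Uniform(a, b) intervals.  The movement bridge through a gap always
// has n + 1 physical segments, each of duration delta_obs / (n + 1), so the
// segment durations sum exactly to the observed gap.  Trans-dimensional
// moves propose n' uniformly on its admissible range together with a
// sub-trajectory drawn from the Brownian bridge between the bounding
// detected locations; because the bridge density is also the proposal
// density, the acceptance ratio reduces to the schedule likelihood and the
// all-zero encounter terms.

static inline double gap_schedule_ll(double delta, int n, double a, double b,
                                     int koff) {
  int k = n + koff;
  if (b - a < 1e-12) return 0.0;  // degenerate (fixed) schedule: point mass
  double mu = k * (a + b) / 2.0, v = k * (b - a) * (b - a) / 12.0;
  return -0.5 * std::log(2.0 * M_PI * v) - (delta - mu) * (delta - mu) / (2.0 * v);
}

// Draw a Brownian bridge with n interior points between (ax,ay) and (bx,by),
// n + 1 segments of duration dseg each, writing into rows 0..n-1 of W.
static void draw_bridge(double ax, double ay, double bx, double by, int n,
                        double dseg, double su2, NumericMatrix &W) {
  double px = ax, py = ay;
  int m = n + 1;  // segments
  for (int i = 1; i <= n; ++i) {
    int rem = m - i + 1;  // segments from previous point to the far endpoint
    double w = 1.0 / rem;
    double sd = std::sqrt(su2 * dseg * (double)(rem - 1) / rem);
    W(i - 1, 0) = px + (bx - px) * w + R::rnorm(0.0, sd);
    W(i - 1, 1) = py + (by - py) * w + R::rnorm(0.0, sd);
    px = W(i - 1, 0); py = W(i - 1, 1);
  }
}

// All-zero encounter log-likelihood of the first n rows of W.
static double enc_ll_zero_traj(const NumericMatrix &W, int n,
                               const NumericMatrix &X, double p0, double s2det) {
  double ll = 0.0;
  for (int i = 0; i < n; ++i) ll += enc_ll_zero(W(i, 0), W(i, 1), X, p0, s2det);
  return ll;
}

// [[Rcpp::export]]
List mcmc_unknown_cpp(List Y_list, List tdet_list, NumericMatrix X, double a,
                      double b, int k_offset, List nmin_list, List nmax_list,
                      double sigdet_max, double sigu_max, List u_init,
                      double p0_init, double sigdet_init, double sigu_init,
                      int n_iter, int n_burn, int thin, bool fix_params,
                      bool save_gap_traj) {
  const int n_tags = Y_list.size();
  std::vector<IntegerMatrix> Ys(n_tags);
  std::vector<NumericVector> Ts(n_tags);
  std::vector<NumericMatrix> Us(n_tags);
  std::vector<IntegerVector> Nmin(n_tags), Nmax(n_tags), CurN(n_tags);
  std::vector<NumericVector> Dobs(n_tags);
  // gap sub-trajectories: one matrix slot per admissible count, the slot for
  // the current n is persistent state, the others are refreshed from the
  // movement bridge every sweep and serve as the trans-dimensional proposal
  std::vector<std::vector<std::vector<NumericMatrix> > > W(n_tags);
  std::vector<std::vector<AdaptScale> > loc_s(n_tags);
  std::vector<std::vector<AdaptScale> > gap_s(n_tags);

  for (int i = 0; i < n_tags; ++i) {
    Ys[i] = as<IntegerMatrix>(Y_list[i]);
    Ts[i] = as<NumericVector>(tdet_list[i]);
    Us[i] = clone(as<NumericMatrix>(u_init[i]));
    Nmin[i] = clone(as<IntegerVector>(nmin_list[i]));
    Nmax[i] = clone(as<IntegerVector>(nmax_list[i]));
    const int D = Ys[i].nrow(), G = D - 1;
    CurN[i] = IntegerVector(G);
    Dobs[i] = NumericVector(G);
    W[i].resize(G);
    loc_s[i].assign(D, AdaptScale(sigdet_init));
    gap_s[i].assign(G, AdaptScale(sigdet_init));
    for (int g = 0; g < G; ++g) {
      Dobs[i][g] = Ts[i][g + 1] - Ts[i][g];
      // initialize n at the schedule-likelihood mode within bounds
      int kstar = (int)std::lround(2.0 * Dobs[i][g] / (a + b));
      int n0 = kstar - k_offset;
      if (n0 < Nmin[i][g]) n0 = Nmin[i][g];
      if (n0 > Nmax[i][g]) n0 = Nmax[i][g];
      CurN[i][g] = n0;
      int nslots = Nmax[i][g] - Nmin[i][g] + 1;
      W[i][g].resize(nslots);
      for (int s = 0; s < nslots; ++s) {
        int n = Nmin[i][g] + s;
        NumericMatrix m(std::max(n, 1), 2);
        // linear interpolation between bounding detected locations
        for (int q = 0; q < n; ++q) {
          double w = (double)(q + 1) / (n + 1);
          m(q, 0) = Us[i](g, 0) + w * (Us[i](g + 1, 0) - Us[i](g, 0));
          m(q, 1) = Us[i](g, 1) + w * (Us[i](g + 1, 1) - Us[i](g, 1));
        }
        W[i][g][s] = m;
      }
    }
  }
  double p0 = p0_init, sigdet = sigdet_init, sigu = sigu_init;
  AdaptScale p0_s(0.05), sd_s(0.1 * sigdet_init), su_s(0.1 * sigu_init);

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix params(n_keep, 3);
  std::vector<NumericVector> traj_store(n_tags);
  std::vector<IntegerMatrix> n_store(n_tags);
  std::vector<NumericVector> gap_store(n_tags);
  for (int i = 0; i < n_tags; ++i) {
    const int D = Ys[i].nrow(), G = D - 1;
    NumericVector v(n_keep * D * 2);
    v.attr("dim") = IntegerVector::create(n_keep, D, 2);
    traj_store[i] = v;
    n_store[i] = IntegerMatrix(n_keep, G);
    if (save_gap_traj) {
      int nmaxall = 0;
      for (int g = 0; g < G; ++g) nmaxall = std::max(nmaxall, (int)Nmax[i][g]);
      NumericVector gv((size_t)n_keep * G * std::max(nmaxall, 1) * 2, NA_REAL);
      gv.attr("dim") = IntegerVector::create(n_keep, G, std::max(nmaxall, 1), 2);
      gap_store[i] = gv;
    }
  }
  int keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    double s2det = sigdet * sigdet, su2 = sigu * sigu;
    for (int i = 0; i < n_tags; ++i) {
      const int D = Ys[i].nrow(), G = D - 1;
      // (1) detected-signal locations, movement terms through adjoining gaps
      for (int d = 0; d < D; ++d) {
        double s = loc_s[i][d].s;
        double ox = Us[i](d, 0), oy = Us[i](d, 1);
        double nx = ox + R::rnorm(0.0, s), ny = oy + R::rnorm(0.0, s);
        double logr = enc_ll_row(nx, ny, Ys[i], d, X, p0, s2det) -
                      enc_ll_row(ox, oy, Ys[i], d, X, p0, s2det);
        if (d > 0) {
          int g = d - 1, n = CurN[i][g];
          double dseg = Dobs[i][g] / (n + 1);
          double lx, ly;
          if (n == 0) { lx = Us[i](d - 1, 0); ly = Us[i](d - 1, 1); }
          else {
            NumericMatrix &m = W[i][g][n - Nmin[i][g]];
            lx = m(n - 1, 0); ly = m(n - 1, 1);
          }
          logr += mov_ll(lx, ly, nx, ny, su2, dseg) -
                  mov_ll(lx, ly, ox, oy, su2, dseg);
        }
        if (d < D - 1) {
          int g = d, n = CurN[i][g];
          double dseg = Dobs[i][g] / (n + 1);
          double rx, ry;
          if (n == 0) { rx = Us[i](d + 1, 0); ry = Us[i](d + 1, 1); }
          else {
            NumericMatrix &m = W[i][g][n - Nmin[i][g]];
            rx = m(0, 0); ry = m(0, 1);
          }
          logr += mov_ll(nx, ny, rx, ry, su2, dseg) -
                  mov_ll(ox, oy, rx, ry, su2, dseg);
        }
        bool acc = mh_accept(logr);
        if (acc) { Us[i](d, 0) = nx; Us[i](d, 1) = ny; }
        loc_s[i][d].tally(acc);
        if (it < n_burn) loc_s[i][d].maybe_adapt();
      }
      // (2) gaps: refresh dormant sub-trajectories, single-site updates on
      // the current one, then the trans-dimensional count move
      for (int g = 0; g < G; ++g) {
        int nmin = Nmin[i][g], nmax = Nmax[i][g], cur = CurN[i][g];
        double ax = Us[i](g, 0), ay = Us[i](g, 1);
        double bx = Us[i](g + 1, 0), by = Us[i](g + 1, 1);
        // refresh every dormant slot from the Brownian bridge
        for (int n = nmin; n <= nmax; ++n) {
          if (n == cur || n == 0) continue;
          draw_bridge(ax, ay, bx, by, n, Dobs[i][g] / (n + 1), su2,
                      W[i][g][n - nmin]);
        }
        // per-location Metropolis update of the current sub-trajectory
        if (cur > 0) {
          NumericMatrix &m = W[i][g][cur - nmin];
          double dseg = Dobs[i][g] / (cur + 1);
          double s = gap_s[i][g].s;
          for (int q = 0; q < cur; ++q) {
            double ox = m(q, 0), oy = m(q, 1);
            double nx = ox + R::rnorm(0.0, s), ny = oy + R::rnorm(0.0, s);
            double px = (q == 0) ? ax : m(q - 1, 0);
            double py = (q == 0) ? ay : m(q - 1, 1);
            double qx = (q == cur - 1) ? bx : m(q + 1, 0);
            double qy = (q == cur - 1) ? by : m(q + 1, 1);
            double logr =
                enc_ll_zero(nx, ny, X, p0, s2det) -
                enc_ll_zero(ox, oy, X, p0, s2det) +
                mov_ll(px, py, nx, ny, su2, dseg) -
                mov_ll(px, py, ox, oy, su2, dseg) +
                mov_ll(nx, ny, qx, qy, su2, dseg) -
                mov_ll(ox, oy, qx, qy, su2, dseg);
            bool acc = mh_accept(logr);
            if (acc) { m(q, 0) = nx; m(q, 1) = ny; }
            gap_s[i][g].tally(acc);
          }
          if (it < n_burn) gap_s[i][g].maybe_adapt();
        }
        // trans-dimensional move on the missed-signal count
        if (nmax > nmin) {
          int np = nmin + (int)std::floor(R::runif(0.0, 1.0) * (nmax - nmin + 1));
          if (np > nmax) np = nmax;
          if (np != cur) {
            NumericMatrix &Wp = W[i][g][np - nmin];
            NumericMatrix &Wc = W[i][g][cur - nmin];
            double logr = gap_schedule_ll(Dobs[i][g], np, a, b, k_offset) -
                          gap_schedule_ll(Dobs[i][g], cur, a, b, k_offset) +
                          enc_ll_zero_traj(Wp, np, X, p0, s2det) -
                          enc_ll_zero_traj(Wc, cur, X, p0, s2det);
            if (mh_accept(logr)) CurN[i][g] = np;
          }
        }
      }
    }
    if (!fix_params) {
      // detection parameters: detected rows plus all-zero terms at the
      // current latent missed-signal locations
      double cur_ll, prop_ll;
      bool acc;
      {
        double p0p = p0 + R::rnorm(0.0, p0_s.s);
        cur_ll = total_enc_ll(Ys, Us, X, p0, s2det);
        for (int i = 0; i < n_tags; ++i)
          for (int g = 0; g < (int)W[i].size(); ++g)
            cur_ll += enc_ll_zero_traj(W[i][g][CurN[i][g] - Nmin[i][g]],
                                       CurN[i][g], X, p0, s2det);
        acc = false;
        if (p0p > 0.0 && p0p < 1.0) {
          prop_ll = total_enc_ll(Ys, Us, X, p0p, s2det);
          for (int i = 0; i < n_tags; ++i)
            for (int g = 0; g < (int)W[i].size(); ++g)
              prop_ll += enc_ll_zero_traj(W[i][g][CurN[i][g] - Nmin[i][g]],
                                          CurN[i][g], X, p0p, s2det);
          if (mh_accept(prop_ll - cur_ll)) { p0 = p0p; cur_ll = prop_ll; acc = true; }
        }
        p0_s.tally(acc); if (it < n_burn) p0_s.maybe_adapt();
        double sdp = sigdet + R::rnorm(0.0, sd_s.s);
        acc = false;
        if (sdp > 0.0 && sdp < sigdet_max) {
          double sp2 = sdp * sdp;
          prop_ll = total_enc_ll(Ys, Us, X, p0, sp2);
          for (int i = 0; i < n_tags; ++i)
            for (int g = 0; g < (int)W[i].size(); ++g)
              prop_ll += enc_ll_zero_traj(W[i][g][CurN[i][g] - Nmin[i][g]],
                                          CurN[i][g], X, p0, sp2);
          if (mh_accept(prop_ll - cur_ll)) { sigdet = sdp; acc = true; }
        }
        sd_s.tally(acc); if (it < n_burn) sd_s.maybe_adapt();
      }
      // movement scale: every physical segment of the current configuration
      {
        double sup = sigu + R::rnorm(0.0, su_s.s);
        acc = false;
        if (sup > 0.0 && sup < sigu_max) {
          double mcur = 0.0, mprop = 0.0, sup2 = sup * sup;
          for (int i = 0; i < n_tags; ++i) {
            const int G = (int)W[i].size();
            for (int g = 0; g < G; ++g) {
              int n = CurN[i][g];
              double dseg = Dobs[i][g] / (n + 1);
              double px = Us[i](g, 0), py = Us[i](g, 1);
              NumericMatrix &m = W[i][g][n - Nmin[i][g]];
              for (int q = 0; q < n; ++q) {
                mcur += mov_ll(px, py, m(q, 0), m(q, 1), su2, dseg);
                mprop += mov_ll(px, py, m(q, 0), m(q, 1), sup2, dseg);
                px = m(q, 0); py = m(q, 1);
              }
              mcur += mov_ll(px, py, Us[i](g + 1, 0), Us[i](g + 1, 1), su2, dseg);
              mprop += mov_ll(px, py, Us[i](g + 1, 0), Us[i](g + 1, 1), sup2, dseg);
            }
          }
          if (mh_accept(mprop - mcur)) { sigu = sup; acc = true; }
        }
        su_s.tally(acc); if (it < n_burn) su_s.maybe_adapt();
      }
    }
    if (it >= n_burn && (it - n_burn) % thin == 0) {
      params(keep, 0) = p0; params(keep, 1) = sigdet; params(keep, 2) = sigu;
      for (int i = 0; i < n_tags; ++i) {
        const int D = Ys[i].nrow(), G = D - 1;
        for (int d = 0; d < D; ++d) {
          traj_store[i][keep + (size_t)n_keep * d] = Us[i](d, 0);
          traj_store[i][keep + (size_t)n_keep * (D + d)] = Us[i](d, 1);
        }
        for (int g = 0; g < G; ++g) n_store[i](keep, g) = CurN[i][g];
        if (save_gap_traj) {
          IntegerVector dm = gap_store[i].attr("dim");
          int nmaxall = dm[2];
          for (int g = 0; g < G; ++g) {
            int n = CurN[i][g];
            NumericMatrix &m = W[i][g][n - Nmin[i][g]];
            for (int q = 0; q < n; ++q) {
              gap_store[i][keep + (size_t)n_keep * (g + (size_t)G * q)] = m(q, 0);
              gap_store[i][keep + (size_t)n_keep *
                                      (g + (size_t)G * (q + (size_t)nmaxall))] =
                  m(q, 1);
            }
          }
        }
      }
      keep++;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  List traj(n_tags), ns(n_tags), gtr(n_tags);
  for (int i = 0; i < n_tags; ++i) {
    traj[i] = traj_store[i];
    ns[i] = n_store[i];
    if (save_gap_traj) gtr[i] = gap_store[i];
  }
  List out = List::create(_["params"] = params, _["traj"] = traj, _["n"] = ns);
  if (save_gap_traj) out["gap_traj"] = gtr;
  return out;
}

// ---------------------------------------------------------------------------
// Product-Gaussian kernel density of a 2-D draw cloud evaluated at points,
// with per-axis bandwidths h1, h2 (standard deviations of the kernel).
// Used for highest-posterior-density coverage assessment.

// [[Rcpp::export]]
NumericVector kde2d_density_at(NumericMatrix draws, NumericMatrix pts,
                               double h1, double h2) {
  const int M = draws.nrow(), P = pts.nrow();
  NumericVector out(P);
  const double norm = 1.0 / (2.0 * M_PI * h1 * h2 * M);
  for (int p = 0; p < P; ++p) {
    double acc = 0.0;
    for (int m = 0; m < M; ++m) {
      double zx = (pts(p, 0) - draws(m, 0)) / h1;
      double zy = (pts(p, 1) - draws(m, 1)) / h2;
      acc += std::exp(-0.5 * (zx * zx + zy * zy));
    }
    out[p] = acc * norm;
  }
  return out;
}
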