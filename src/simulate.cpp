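// Particle-based stochastic simulation of the spatial telegraph model.
//
// The promoter is simulated exactly (event-driven exponential holding
// times); particle transport uses Euler-Maruyama with time step dt.
// Births within a step are Poisson with mean equal to the integral of the
// transcription rate over the exactly known promoter path; each newborn
// starts at the gene site and diffuses for its residual step fraction.
// RNG comes from R's generator so set.seed() controls everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Promoter {
  bool on;
  double t_next;  // time remaining until next switch
  double alpha, beta;
  void init_stationary() {
    double rho = alpha / (alpha + beta);
    on = (unif_rand() < rho);
    t_next = exp_rand() / (on ? beta : alpha);
  }
  // advance by dt, appending (duration, rate-on flag) segments
  void advance(double dt, std::vector<double>& seg_dur,
               std::vector<int>& seg_on) {
    double remain = dt;
    while (t_next <= remain) {
      seg_dur.push_back(t_next);
      seg_on.push_back(on ? 1 : 0);
      remain -= t_next;
      on = !on;
      t_next = exp_rand() / (on ? beta : alpha);
    }
    t_next -= remain;
    if (remain > 0) {
      seg_dur.push_back(remain);
      seg_on.push_back(on ? 1 : 0);
    }
  }
};

// 1D boundary handling. boundary: 0 absorbing, 1 robin, 2 reflecting.
// Returns false if the particle is removed (export). p_abs is the
// partial-reflection absorption probability at the step length dtt.
inline bool boundary_1d(double x_old, double& x, double R, double D,
                        double dtt, int boundary, double kappa) {
  if (boundary == 0) {
    if (x >= R || x <= -R) return false;
    // first-passage bridge correction for an unobserved crossing
    double p_hi = std::exp(-(R - x_old) * (R - x) / (D * dtt));
    if (unif_rand() < p_hi) return false;
    double p_lo = std::exp(-(x_old + R) * (x + R) / (D * dtt));
    if (unif_rand() < p_lo) return false;
    return true;
  }
  // robin / reflecting: mirror reflections, with absorption attempt on
  // each boundary contact for finite kappa
  int guard = 0;
  while ((x > R || x < -R) && guard++ < 64) {
    if (boundary == 1) {
      double p_abs = kappa * std::sqrt(M_PI * dtt / D);
      if (unif_rand() < p_abs) return false;
    }
    if (x > R) x = 2 * R - x; else if (x < -R) x = -2 * R - x;
  }
  return true;
}

}  // namespace

// Simulate one or more 1D cells, each with its own geometry (R_i, z_i)
// but shared kinetics. Returns, per cell, an integer vector of snapshot
// counts and (optionally) a list of snapshot position vectors.
// boundary: 0 absorbing, 1 robin(kappa), 2 reflecting.
// [[Rcpp::export(name = ".sim_cells_1d")]]
List sim_cells_1d(double lam, double lam_off, double alpha, double beta,
                  double gamma_, double D, double kappa, int boundary,
                  NumericVector Rs, NumericVector zs,
                  double dt, double burnin, int n_samples, double spacing,
                  bool keep_positions, int max_particles) {
  int n_cells = Rs.size();
  int burn_steps = (int)std::ceil(burnin / dt);
  int space_steps = std::max(1, (int)std::lround(spacing / dt));
  double sqrt2Ddt = std::sqrt(2.0 * D * dt);
  double p_die = 1.0 - std::exp(-gamma_ * dt);

  List out(n_cells);
  std::vector<double> seg_dur; std::vector<int> seg_on;

  for (int c = 0; c < n_cells; ++c) {
    double R = Rs[c], z = zs[c];
    Promoter prom{false, 0.0, alpha, beta};
    prom.init_stationary();
    std::vector<double> xs;
    xs.reserve(256);
    IntegerVector counts(n_samples);
    List pos_list(keep_positions ? n_samples : 0);
    int sample_idx = 0;
    int total_steps = burn_steps + (n_samples - 1) * space_steps + 1;
    for (int step = 0; step < total_steps; ++step) {
      // move/kill existing particles
      size_t keep = 0;
      for (size_t i = 0; i < xs.size(); ++i) {
        if (unif_rand() < p_die) continue;
        double x_old = xs[i];
        double x = x_old + sqrt2Ddt * norm_rand();
        if (!boundary_1d(x_old, x, R, D, dt, boundary, kappa)) continue;
        xs[keep++] = x;
      }
      xs.resize(keep);
      // promoter path over this step + births
      seg_dur.clear(); seg_on.clear();
      prom.advance(dt, seg_dur, seg_on);
      double integral = 0.0;
      for (size_t s = 0; s < seg_dur.size(); ++s)
        integral += seg_dur[s] * (seg_on[s] ? lam : lam_off);
      if (integral > 0) {
        int n_birth = (int)R::rpois(integral);
        for (int b = 0; b < n_birth; ++b) {
          // birth time uniform w.r.t. rate measure along the segments
          double u = unif_rand() * integral, acc = 0.0, t_birth = 0.0;
          for (size_t s = 0; s < seg_dur.size(); ++s) {
            double w = seg_dur[s] * (seg_on[s] ? lam : lam_off);
            if (u <= acc + w || s + 1 == seg_dur.size()) {
              double rate = seg_on[s] ? lam : lam_off;
              t_birth += (rate > 0) ? (u - acc) / rate : 0.0;
              break;
            }
            acc += w; t_birth += seg_dur[s];
          }
          double resid = dt - t_birth;
          if (resid <= 0) resid = 1e-12;
          if (unif_rand() < 1.0 - std::exp(-gamma_ * resid)) continue;
          double x = z + std::sqrt(2.0 * D * resid) * norm_rand();
          if (!boundary_1d(z, x, R, D, resid, boundary, kappa)) continue;
          xs.push_back(x);
        }
      }
      if ((int)xs.size() > max_particles)
        stop("particle count exceeded safety cap (%d); review parameters",
             max_particles);
      // snapshot?
      if (step >= burn_steps && (step - burn_steps) % space_steps == 0 &&
          sample_idx < n_samples) {
        counts[sample_idx] = (int)xs.size();
        if (keep_positions)
          pos_list[sample_idx] = NumericVector(xs.begin(), xs.end());
        ++sample_idx;
      }
    }
    out[c] = keep_positions
      ? (SEXP)List::create(_["counts"] = counts, _["positions"] = pos_list)
      : (SEXP)List::create(_["counts"] = counts);
  }
  return out;
}

namespace {

inline bool point_in_poly(double x, double y, const NumericMatrix& poly) {
  int n = poly.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = poly(i, 0), yi = poly(i, 1), xj = poly(j, 0), yj = poly(j, 1);
    if (((yi > y) != (yj > y)) &&
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

inline double bilinear(const NumericMatrix& G, double x0, double y0,
                       double hx, double hy, double x, double y) {
  double fx = (x - x0) / hx, fy = (y - y0) / hy;
  int nx = G.nrow(), ny = G.ncol();
  if (fx < 0) fx = 0; if (fx > nx - 1.000001) fx = nx - 1.000001;
  if (fy < 0) fy = 0; if (fy > ny - 1.000001) fy = ny - 1.000001;
  int i = (int)fx, j = (int)fy;
  double tx = fx - i, ty = fy - j;
  return G(i, j) * (1 - tx) * (1 - ty) + G(i + 1, j) * tx * (1 - ty) +
         G(i, j + 1) * (1 - tx) * ty + G(i + 1, j + 1) * tx * ty;
}

}  // namespace

// 2D simulation on a polygonal domain with spatially varying diffusivity
// (Ito convention: the step uses D at the pre-step position). Absorbing
// boundary only: any step ending outside the polygon removes the particle.
// r_quick: radius below which containment is accepted without the ray test.
// [[Rcpp::export(name = ".sim_cell_2d")]]
List sim_cell_2d(double lam, double lam_off, double alpha, double beta,
                 double gamma_, NumericMatrix poly, NumericMatrix Dgrid,
                 double x0, double y0, double hx, double hy,
                 double zx, double zy, double r_quick,
                 double dt, double burnin, int n_samples, double spacing,
                 bool keep_positions, int max_particles) {
  int burn_steps = (int)std::ceil(burnin / dt);
  int space_steps = std::max(1, (int)std::lround(spacing / dt));
  double p_die = 1.0 - std::exp(-gamma_ * dt);

  Promoter prom{false, 0.0, alpha, beta};
  prom.init_stationary();
  std::vector<double> xs, ys;
  IntegerVector counts(n_samples);
  List pos_list(keep_positions ? n_samples : 0);
  std::vector<double> seg_dur; std::vector<int> seg_on;
  int sample_idx = 0;
  int total_steps = burn_steps + (n_samples - 1) * space_steps + 1;

  auto inside = [&](double x, double y) {
    if (x * x + y * y < r_quick * r_quick) return true;
    return point_in_poly(x, y, poly);
  };

  for (int step = 0; step < total_steps; ++step) {
    size_t keep = 0;
    for (size_t i = 0; i < xs.size(); ++i) {
      if (unif_rand() < p_die) continue;
      double Dloc = bilinear(Dgrid, x0, y0, hx, hy, xs[i], ys[i]);
      double s = std::sqrt(2.0 * Dloc * dt);
      double x = xs[i] + s * norm_rand();
      double y = ys[i] + s * norm_rand();
      if (!inside(x, y)) continue;
      xs[keep] = x; ys[keep] = y; ++keep;
    }
    xs.resize(keep); ys.resize(keep);
    seg_dur.clear(); seg_on.clear();
    prom.advance(dt, seg_dur, seg_on);
    double integral = 0.0;
    for (size_t s = 0; s < seg_dur.size(); ++s)
      integral += seg_dur[s] * (seg_on[s] ? lam : lam_off);
    if (integral > 0) {
      int n_birth = (int)R::rpois(integral);
      double Dz = bilinear(Dgrid, x0, y0, hx, hy, zx, zy);
      for (int b = 0; b < n_birth; ++b) {
        double resid = unif_rand() * dt;  // residual fraction of the step
        if (unif_rand() < 1.0 - std::exp(-gamma_ * resid)) continue;
        double s = std::sqrt(2.0 * Dz * resid);
        double x = zx + s * norm_rand();
        double y = zy + s * norm_rand();
        if (!inside(x, y)) continue;
        xs.push_back(x); ys.push_back(y);
      }
    }
    if ((int)xs.size() > max_particles)
      stop("particle count exceeded safety cap (%d); review parameters",
           max_particles);
    if (step >= burn_steps && (step - burn_steps) % space_steps == 0 &&
        sample_idx < n_samples) {
      counts[sample_idx] = (int)xs.size();
      if (keep_positions) {
        NumericMatrix P(xs.size(), 2);
        for (size_t i = 0; i < xs.size(); ++i) { P(i, 0) = xs[i]; P(i, 1) = ys[i]; }
        pos_list[sample_idx] = P;
      }
      ++sample_idx;
    }
  }
  return keep_positions
    ? List::create(_["counts"] = counts, _["positions"] = pos_list)
    : List::create(_["counts"] = counts);
}
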