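#include <Rcpp.h>
using namespace Rcpp;

// Sum-of-isotropic-Gaussians field: value at grid row m is
//   amplitude * sum_n exp(-||grid_m - center_n||^2 / (2 * width2))
// Shared by the lumpy object model, the analytic PRF imaging operator and
// the blob fixture generator.
// [[Rcpp::export]]
NumericVector gaussian_sum_field(NumericMatrix centers, NumericMatrix grid,
                                 double amplitude, double width2) {
  const int M = grid.nrow(), n = centers.nrow();
  NumericVector out(M);
  const double inv2w2 = 1.0 / (2.0 * width2);
  for (int j = 0; j < n; ++j) {
    const double cx = centers(j, 0), cy = centers(j, 1);
    for (int m = 0; m < M; ++m) {
      const double dx = grid(m, 0) - cx, dy = grid(m, 1) - cy;
      out[m] += amplitude * std::exp(-(dx * dx + dy * dy) * inv2w2);
    }
  }
  return out;
}

// Variable-density Poisson-disc dart throwing.  Calibration points are
// pre-accepted and unconstrained; candidates (given in a fixed order) are
// accepted when no previously accepted dart lies closer than
// min(radius_candidate, radius_dart).
// [[Rcpp::export]]
LogicalVector cpp_poisson_disc(NumericMatrix coords, NumericVector radius,
                               LogicalVector calib, IntegerVector order) {
  const int n = coords.nrow();
  LogicalVector accepted(n);
  std::vector<int> darts;
  darts.reserve(n / 4);
  for (int i = 0; i < n; ++i) accepted[i] = calib[i];
  for (int oi = 0; oi < order.size(); ++oi) {
    const int i = order[oi];
    const double xi = coords(i, 0), yi = coords(i, 1), ri = radius[i];
    bool ok = true;
    for (size_t d = 0; d < darts.size(); ++d) {
      const int j = darts[d];
      const double dx = xi - coords(j, 0), dy = yi - coords(j, 1);
      const double rmin = ri < radius[j] ? ri : radius[j];
      if (dx * dx + dy * dy < rmin * rmin) { ok = false; break; }
    }
    if (ok) { accepted[i] = true; darts.push_back(i); }
  }
  return accepted;
}

// Metropolis-Hastings chain over lumpy-background parameters (lump count
// and continuous centers) targeting p(theta | g, H0), with reversible
// center-move / birth / death proposals.  Works on a tensor-product
// measurement grid (xs fast axis, ys slow axis) so each lump's imaged
// field is the outer product of two 1-D Gaussian vectors; the background
// image, residual and signal inner product are updated incrementally
// (only the moved, born or killed lump's field is recomputed).
//
// Inputs are the *imaged* lump amplitude and squared width (object lump
// convolved with the PRF), so the chain works directly in the measurement
// domain.  Uses R's RNG: seed with set.seed() before calling.
//
// Returns the per-iteration log BKE likelihood ratio, acceptance flags,
// lump-count trace and the final centers.

static inline void axis_gauss(const std::vector<double> &ax, double c,
                              double inv2w2, std::vector<double> &buf) {
  for (size_t i = 0; i < ax.size(); ++i) {
    const double d = ax[i] - c;
    buf[i] = std::exp(-d * d * inv2w2);
  }
}

// [[Rcpp::export]]
List cpp_run_lumpy_chain(NumericVector g, NumericVector s, NumericVector xs,
                         NumericVector ys, NumericMatrix centers0,
                         double lambda, double fov, double amp,
                         double width2, double sigma, int n_iter,
                         double p_move, double p_birth, double step_sd) {
  const int Lx = xs.size(), Ly = ys.size(), M = Lx * Ly;
  if (g.size() != M || s.size() != M)
    stop("measurement length does not match the tensor grid");
  const double inv2w2 = 1.0 / (2.0 * width2);
  const double inv_s2 = 1.0 / (sigma * sigma);
  const std::vector<double> ax(xs.begin(), xs.end()),
      ay(ys.begin(), ys.end());

  std::vector<double> cx, cy;
  for (int j = 0; j < centers0.nrow(); ++j) {
    cx.push_back(centers0(j, 0));
    cy.push_back(centers0(j, 1));
  }

  std::vector<double> exo(Lx), eyo(Ly), exn(Lx), eyn(Ly), db(M);
  std::vector<double> b(M, 0.0), r(M), sv(s.begin(), s.end());

  for (int j = 0; j < (int)cx.size(); ++j) {
    axis_gauss(ax, cx[j], inv2w2, exo);
    axis_gauss(ay, cy[j], inv2w2, eyo);
    for (int iy = 0, m = 0; iy < Ly; ++iy)
      for (int ix = 0; ix < Lx; ++ix, ++m)
        b[m] += amp * exo[ix] * eyo[iy];
  }
  double sr = 0.0, ss = 0.0;
  for (int m = 0; m < M; ++m) {
    r[m] = g[m] - b[m];
    sr += sv[m] * r[m];
    ss += sv[m] * sv[m];
  }

  NumericVector log_lbke(n_iter);
  LogicalVector accept(n_iter);
  IntegerVector n_lumps(n_iter);

  for (int t = 0; t < n_iter; ++t) {
    const int n = cx.size();
    const double u = R::unif_rand();
    bool acc = false;
    // delta-field accumulation shared by all move types
    double rd = 0.0, dd = 0.0, sd_ = 0.0;
    bool have_delta = false;
    double log_extra = 0.0;  // prior x proposal log-ratio beyond likelihood
    int move_kind = 0;       // 1 move, 2 birth, 3 death
    int idx = -1;
    double nx = 0.0, ny = 0.0;

    if (u < p_move) {
      if (n == 0) {
        acc = true;  // nothing to move: self-loop
      } else {
        idx = (int)std::floor(R::unif_rand() * n);
        nx = cx[idx] + R::norm_rand() * step_sd;
        ny = cy[idx] + R::norm_rand() * step_sd;
        if (nx >= 0 && nx < fov && ny >= 0 && ny < fov) {
          axis_gauss(ax, cx[idx], inv2w2, exo);
          axis_gauss(ay, cy[idx], inv2w2, eyo);
          axis_gauss(ax, nx, inv2w2, exn);
          axis_gauss(ay, ny, inv2w2, eyn);
          for (int iy = 0, m = 0; iy < Ly; ++iy)
            for (int ix = 0; ix < Lx; ++ix, ++m) {
              const double d = amp * (exn[ix] * eyn[iy] - exo[ix] * eyo[iy]);
              db[m] = d;
              rd += r[m] * d; dd += d * d; sd_ += sv[m] * d;
            }
          have_delta = true;
          move_kind = 1;
        }  // outside the field of view: prior density 0, auto-reject
      }
    } else if (u < p_move + p_birth) {
      nx = R::unif_rand() * fov; ny = R::unif_rand() * fov;
      axis_gauss(ax, nx, inv2w2, exn);
      axis_gauss(ay, ny, inv2w2, eyn);
      for (int iy = 0, m = 0; iy < Ly; ++iy)
        for (int ix = 0; ix < Lx; ++ix, ++m) {
          const double d = amp * exn[ix] * eyn[iy];
          db[m] = d;
          rd += r[m] * d; dd += d * d; sd_ += sv[m] * d;
        }
      have_delta = true;
      move_kind = 2;
      log_extra = std::log(lambda / (n + 1.0));
    } else if (n > 0) {
      idx = (int)std::floor(R::unif_rand() * n);
      axis_gauss(ax, cx[idx], inv2w2, exo);
      axis_gauss(ay, cy[idx], inv2w2, eyo);
      for (int iy = 0, m = 0; iy < Ly; ++iy)
        for (int ix = 0; ix < Lx; ++ix, ++m) {
          const double d = -amp * exo[ix] * eyo[iy];
          db[m] = d;
          rd += r[m] * d; dd += d * d; sd_ += sv[m] * d;
        }
      have_delta = true;
      move_kind = 3;
      log_extra = std::log(n / lambda);
    }
    // death proposed with n == 0: auto-reject

    if (have_delta) {
      const double lr = (2.0 * rd - dd) * 0.5 * inv_s2 + log_extra;
      if (lr >= 0 || R::unif_rand() < std::exp(lr)) {
        for (int m = 0; m < M; ++m) { b[m] += db[m]; r[m] -= db[m]; }
        sr -= sd_;
        if (move_kind == 1) { cx[idx] = nx; cy[idx] = ny; }
        else if (move_kind == 2) { cx.push_back(nx); cy.push_back(ny); }
        else {
          cx[idx] = cx.back(); cy[idx] = cy.back();
          cx.pop_back(); cy.pop_back();
        }
        acc = true;
      }
    }

    log_lbke[t] = (sr - 0.5 * ss) * inv_s2;
    accept[t] = acc;
    n_lumps[t] = cx.size();
  }

  NumericMatrix final_centers(cx.size(), 2);
  for (int j = 0; j < (int)cx.size(); ++j) {
    final_centers(j, 0) = cx[j];
    final_centers(j, 1) = cy[j];
  }
  return List::create(_["log_lbke"] = log_lbke, _["accept"] = accept,
                      _["n_lumps"] = n_lumps,
                      _["final_centers"] = final_centers);
}
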