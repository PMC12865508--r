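#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Even-odd ray casting; vertices need not repeat the first point.
static bool point_in_polygon(double x, double y, const NumericMatrix& poly) {
  int n = poly.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = poly(i, 0), yi = poly(i, 1);
    double xj = poly(j, 0), yj = poly(j, 1);
    if (((yi > y) != (yj > y)) &&
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector points_in_polygon_cpp(NumericVector x, NumericVector y,
                                    NumericMatrix poly) {
  int n = x.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = point_in_polygon(x[i], y[i], poly);
  return out;
}

// Multinomial draw by sequential conditional binomials.  The remainder is
// guaranteed to land on an index with positive weight.
// [[Rcpp::export]]
IntegerVector allocate_counts_cpp(int n, NumericVector w) {
  int m = w.size();
  IntegerVector out(m);
  if (n == 0) return out;
  std::vector<int> pos;
  double wsum = 0.0;
  for (int i = 0; i < m; ++i) {
    if (w[i] < 0) stop("negative allocation weight");
    if (w[i] > 0) { pos.push_back(i); wsum += w[i]; }
  }
  if (pos.empty()) stop("all allocation weights are zero");
  int left = n;
  double wleft = wsum;
  for (size_t k = 0; k + 1 < pos.size() && left > 0; ++k) {
    int i = pos[k];
    double p = w[i] / wleft;
    int draw = (p >= 1.0) ? left : (int) R::rbinom((double) left, p);
    out[i] = draw;
    left -= draw;
    wleft -= w[i];
  }
  if (left > 0) out[pos.back()] += left;
  return out;
}

struct AdaptStep {
  double step;
  int acc = 0, att = 0;
  double lo, hi;
  AdaptStep(double s, double lo_, double hi_) : step(s), lo(lo_), hi(hi_) {}
  void tune() {
    if (att == 0) return;
    double rate = (double) acc / att;
    step *= std::exp(0.4 * (rate - 0.35));
    if (step < lo) step = lo;
    if (step > hi) step = hi;
    acc = 0; att = 0;
  }
};

// Metropolis-within-Gibbs sampler for the rt-SCR model (and standard SCR when
// rtscr = false).  Occasions are collapsed to trap totals; `effort` carries
// the per-trap number of active occasions as the Poisson offset.
// [[Rcpp::export]]
List rtscr_mcmc_cpp(IntegerMatrix y_id, IntegerVector n_noid,
                    NumericVector effort, NumericMatrix trap_xy,
                    int ss_type, NumericVector bounds, NumericMatrix poly,
                    NumericMatrix sites, List priors, List fixed,
                    List init, int n_iter, int n_burnin, int thin,
                    bool adapt, bool retain_latent, bool rtscr,
                    bool mh_allocation) {
  const int M = y_id.nrow(), J = y_id.ncol();
  const int n_sites = sites.nrow();

  const double l0_min = priors["lambda0_min"], l0_max = priors["lambda0_max"];
  const double sg_min = priors["sigma_min"],  sg_max = priors["sigma_max"];
  const double th_a = priors["theta_a"], th_b = priors["theta_b"];
  const double ps_a = priors["psi_a"],   ps_b = priors["psi_b"];

  const bool fix_l0 = fixed["lambda0"], fix_sg = fixed["sigma"];
  const bool fix_th = fixed["theta"],   fix_ps = fixed["psi"];

  double lambda0 = init["lambda0"], sigma = init["sigma"];
  double theta = init["theta"], psi = init["psi"];
  NumericMatrix s_init = init["s"];
  IntegerVector z_init = init["z"];

  std::vector<double> sx(M), sy(M);
  std::vector<int> z(M);
  for (int i = 0; i < M; ++i) {
    sx[i] = s_init(i, 0); sy[i] = s_init(i, 1); z[i] = z_init[i];
  }

  std::vector<int> yid_row(M, 0);
  long yid_tot = 0;
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < J; ++j) { yid_row[i] += y_id(i, j); yid_tot += y_id(i, j); }
  long noid_tot = 0;
  for (int j = 0; j < J; ++j) noid_tot += n_noid[j];

  // identified individuals are members with probability one
  for (int i = 0; i < M; ++i) if (yid_row[i] > 0) z[i] = 1;

  auto inside = [&](double x, double y) -> bool {
    if (ss_type == 0)
      return x >= bounds[0] && x <= bounds[1] && y >= bounds[2] && y <= bounds[3];
    if (ss_type == 1) return point_in_polygon(x, y, poly);
    return true;  // discrete support: proposals are candidate sites
  };

  // c[i,j] = effort_j * exp(-d_ij^2 / (2 sigma^2)); encounter rate = lambda0*c
  std::vector<double> cmat((size_t) M * J), rowc(M);
  std::vector<double> cnew((size_t) M * J), rownew(M), rowscratch(J);
  auto comp_row = [&](int i, double sig, double px, double py,
                      std::vector<double>& target, int stride_i) -> double {
    double rs = 0.0, inv = 1.0 / (2.0 * sig * sig);
    for (int j = 0; j < J; ++j) {
      double dx = px - trap_xy(j, 0), dy = py - trap_xy(j, 1);
      double v = effort[j] * std::exp(-(dx * dx + dy * dy) * inv);
      target[(size_t) stride_i * J + j] = v;
      rs += v;
    }
    return rs;
  };
  for (int i = 0; i < M; ++i) rowc[i] = comp_row(i, sigma, sx[i], sy[i], cmat, i);

  // latent unidentified allocation u and y_full = y_id + u
  std::vector<int> u((size_t) M * J, 0), urow(M, 0);
  auto yfull = [&](int i, int j) { return y_id(i, j) + u[(size_t) i * J + j]; };
  auto yfrow = [&](int i) { return yid_row[i] + urow[i]; };

  std::vector<int> active;  // scratch list of z=1 indices
  auto gibbs_allocate = [&](int j) {
    // zero column j, then draw multinomial(n_noid_j, z_i * c_ij)
    for (int i = 0; i < M; ++i) {
      int& uij = u[(size_t) i * J + j];
      if (uij) { urow[i] -= uij; uij = 0; }
    }
    if (n_noid[j] == 0) return;
    double wsum = 0.0;
    for (int i = 0; i < M; ++i) if (z[i]) wsum += cmat[(size_t) i * J + j];
    if (wsum <= 0.0) {
      // degenerate: no live contributor; force-activate the best-placed one
      int best = 0; double bc = -1.0;
      for (int i = 0; i < M; ++i)
        if (cmat[(size_t) i * J + j] > bc) { bc = cmat[(size_t) i * J + j]; best = i; }
      z[best] = 1;
      wsum = bc;
      if (wsum <= 0.0) {
        // all rates underflowed; split uniformly among members
        u[(size_t) best * J + j] = n_noid[j];
        urow[best] += n_noid[j];
        return;
      }
    }
    int left = n_noid[j];
    double wleft = wsum;
    int last = -1;
    for (int i = 0; i < M; ++i)
      if (z[i] && cmat[(size_t) i * J + j] > 0) last = i;
    for (int i = 0; i <= last && left > 0; ++i) {
      if (!z[i]) continue;
      double w = cmat[(size_t) i * J + j];
      if (w <= 0) continue;
      int draw;
      if (i == last) draw = left;
      else {
        double p = w / wleft;
        draw = (p >= 1.0) ? left : (int) R::rbinom((double) left, p);
      }
      if (draw) { u[(size_t) i * J + j] = draw; urow[i] += draw; }
      left -= draw;
      wleft -= w;
    }
  };

  auto mh_allocate = [&](int j) {
    if (n_noid[j] == 0) return;
    active.clear();
    for (int i = 0; i < M; ++i) if (z[i]) active.push_back(i);
    if (active.empty()) { gibbs_allocate(j); return; }
    for (int rep = 0; rep < n_noid[j]; ++rep) {
      // donor: a uniformly chosen unidentified unit at this trap
      int t = (int) (R::unif_rand() * n_noid[j]);
      if (t >= n_noid[j]) t = n_noid[j] - 1;
      int a = -1, cum = 0;
      for (int i = 0; i < M; ++i) {
        cum += u[(size_t) i * J + j];
        if (t < cum) { a = i; break; }
      }
      if (a < 0) continue;
      int b = active[(int) (R::unif_rand() * active.size()) % active.size()];
      if (a == b) continue;
      double La = lambda0 * cmat[(size_t) a * J + j];
      double Lb = lambda0 * cmat[(size_t) b * J + j];
      int ya = yfull(a, j), yb = yfull(b, j);
      double lr = R::dpois(ya - 1, La, 1) + R::dpois(yb + 1, Lb, 1)
                - R::dpois(ya, La, 1) - R::dpois(yb, Lb, 1)
                + R::dbinom(y_id(a, j), ya - 1, theta, 1)
                + R::dbinom(y_id(b, j), yb + 1, theta, 1)
                - R::dbinom(y_id(a, j), ya, theta, 1)
                - R::dbinom(y_id(b, j), yb, theta, 1)
                // proposal correction: donor unit picked uniformly
                + std::log((double) u[(size_t) b * J + j] + 1.0)
                - std::log((double) u[(size_t) a * J + j]);
      if (std::isfinite(lr) && std::log(R::unif_rand()) < lr) {
        u[(size_t) a * J + j]--; urow[a]--;
        u[(size_t) b * J + j]++; urow[b]++;
      }
    }
  };

  // initial allocation (also under the MH variant, to get a valid state)
  if (rtscr) for (int j = 0; j < J; ++j) gibbs_allocate(j);

  auto Cact = [&]() {
    double v = 0.0;
    for (int i = 0; i < M; ++i) if (z[i]) v += rowc[i];
    return v;
  };
  auto Ytot = [&]() {
    long v = 0;
    for (int i = 0; i < M; ++i) v += yfrow(i);
    return (double) v;
  };

  const double extent = std::max(bounds[1] - bounds[0], bounds[3] - bounds[2]);
  AdaptStep st_l0(0.2, 0.01, 2.0), st_sg(0.2, 0.01, 2.0);
  AdaptStep st_s(sigma > 0 ? sigma : extent / 10.0, extent / 1e4, extent);

  int n_keep = (n_iter > n_burnin) ? (n_iter - n_burnin + thin - 1) / thin : 0;
  NumericMatrix draws(n_keep, 5);
  colnames(draws) = CharacterVector::create("lambda0", "sigma", "theta",
                                            "psi", "N");
  NumericVector s_draws(retain_latent ? (R_xlen_t) n_keep * M * 2 : 0);
  IntegerMatrix z_draws(retain_latent ? n_keep : 0, retain_latent ? M : 0);
  LogicalVector constraint_ok(n_keep);
  int kept = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    if (iter % 4096 == 0) Rcpp::checkUserInterrupt();

    // (1) allocation of unidentified counts
    if (rtscr) {
      for (int j = 0; j < J; ++j) {
        if (n_noid[j] == 0) continue;
        if (mh_allocation) mh_allocate(j); else gibbs_allocate(j);
      }
    }

    // (2) theta | totals  (conjugate Beta; totals are fixed by the data)
    if (rtscr && !fix_th)
      theta = R::rbeta(th_a + yid_tot, th_b + noid_tot);

    // (3) z for individuals with no encounters at all
    for (int i = 0; i < M; ++i) {
      if (yfrow(i) > 0) { z[i] = 1; continue; }
      double p1 = psi * std::exp(-lambda0 * rowc[i]);
      double pr = p1 / (p1 + (1.0 - psi));
      z[i] = (R::unif_rand() < pr) ? 1 : 0;
    }
    int N = 0;
    for (int i = 0; i < M; ++i) N += z[i];

    // (4) psi | z  (conjugate Beta)
    if (!fix_ps) psi = R::rbeta(ps_a + N, ps_b + (M - N));

    double C = Cact(), Y = Ytot();

    // (5) lambda0: random-walk MH on the log scale
    if (!fix_l0) {
      st_l0.att++;
      double lp = std::log(lambda0) + R::norm_rand() * st_l0.step;
      double l0p = std::exp(lp);
      if (l0p >= l0_min && l0p <= l0_max) {
        double lacc = Y * (lp - std::log(lambda0)) - (l0p - lambda0) * C
                    + (lp - std::log(lambda0));  // Jacobian
        if (std::log(R::unif_rand()) < lacc) { lambda0 = l0p; st_l0.acc++; }
      }
    }

    // (6) sigma: random-walk MH on the log scale (full rate recompute)
    if (!fix_sg) {
      st_sg.att++;
      double lsp = std::log(sigma) + R::norm_rand() * st_sg.step;
      double sgp = std::exp(lsp);
      if (sgp >= sg_min && sgp <= sg_max) {
        double Cp = 0.0, lacc = lsp - std::log(sigma);  // Jacobian
        for (int i = 0; i < M; ++i) {
          rownew[i] = comp_row(i, sgp, sx[i], sy[i], cnew, i);
          if (z[i]) Cp += rownew[i];
        }
        for (int i = 0; i < M; ++i) {
          if (!z[i]) continue;
          for (int j = 0; j < J; ++j) {
            int y = yfull(i, j);
            if (y > 0)
              lacc += y * (std::log(cnew[(size_t) i * J + j])
                           - std::log(cmat[(size_t) i * J + j]));
          }
        }
        lacc -= lambda0 * (Cp - C);
        if (std::isfinite(lacc) && std::log(R::unif_rand()) < lacc) {
          sigma = sgp;
          std::swap(cmat, cnew);
          std::swap(rowc, rownew);
          C = Cp;
          st_sg.acc++;
        }
      }
    }

    // (7) activity centers: per-individual random-walk MH (or site jumps)
    for (int i = 0; i < M; ++i) {
      st_s.att++;
      double px, py;
      if (ss_type == 2) {
        int k = (int) (R::unif_rand() * n_sites) % n_sites;
        px = sites(k, 0); py = sites(k, 1);
      } else {
        px = sx[i] + R::norm_rand() * st_s.step;
        py = sy[i] + R::norm_rand() * st_s.step;
        if (!inside(px, py)) continue;
      }
      double rs = comp_row(0, sigma, px, py, rowscratch, 0);
      double lacc = 0.0;
      if (z[i]) {
        for (int j = 0; j < J; ++j) {
          int y = yfull(i, j);
          if (y > 0)
            lacc += y * (std::log(rowscratch[j])
                         - std::log(cmat[(size_t) i * J + j]));
        }
        lacc -= lambda0 * (rs - rowc[i]);
      }
      if (std::isfinite(lacc) && std::log(R::unif_rand()) < lacc) {
        sx[i] = px; sy[i] = py;
        for (int j = 0; j < J; ++j) cmat[(size_t) i * J + j] = rowscratch[j];
        rowc[i] = rs;
        st_s.acc++;
      }
    }

    if (adapt && iter < n_burnin && (iter + 1) % 50 == 0) {
      st_l0.tune(); st_sg.tune(); st_s.tune();
    }

    if (iter >= n_burnin && (iter - n_burnin) % thin == 0) {
      int N2 = 0;
      for (int i = 0; i < M; ++i) N2 += z[i];
      draws(kept, 0) = lambda0;
      draws(kept, 1) = sigma;
      draws(kept, 2) = rtscr ? theta : 1.0;
      draws(kept, 3) = psi;
      draws(kept, 4) = N2;
      bool ok = true;
      for (int j = 0; j < J && ok; ++j) {
        int tot = 0;
        for (int i = 0; i < M; ++i) tot += u[(size_t) i * J + j];
        ok = (tot == (rtscr ? n_noid[j] : 0));
      }
      constraint_ok[kept] = ok;
      if (retain_latent) {
        for (int i = 0; i < M; ++i) {
          s_draws[(R_xlen_t) kept + (R_xlen_t) n_keep * i] = sx[i];
          s_draws[(R_xlen_t) kept + (R_xlen_t) n_keep * (M + i)] = sy[i];
          z_draws(kept, i) = z[i];
        }
      }
      kept++;
    }
  }

  if (retain_latent) s_draws.attr("dim") = IntegerVector::create(n_keep, M, 2);
  return List::create(
    _["draws"] = draws,
    _["s"] = s_draws,
    _["z"] = z_draws,
    _["constraint_ok"] = constraint_ok,
    _["accept"] = NumericVector::create(
        _["lambda0"] = (fix_l0 || st_l0.att == 0)
            ? NA_REAL : (double) st_l0.acc / st_l0.att,
        _["sigma"] = (fix_sg || st_sg.att == 0)
            ? NA_REAL : (double) st_sg.acc / st_sg.att,
        _["s"] = st_s.att == 0 ? NA_REAL : (double) st_s.acc / st_s.att),
    _["final_step"] = NumericVector::create(
        _["lambda0"] = st_l0.step, _["sigma"] = st_sg.step, _["s"] = st_s.step));
}
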