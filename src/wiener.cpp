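#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a Wiener diffusion (diffusion coefficient 1)
// between absorbing boundaries 0 and a, drift v, relative start point w,
// evaluated at decision time t (stimulus time minus t0) for the LOWER boundary.
// Series evaluation follows the small-time / large-time decomposition with the
// standard accuracy-based switching rule; `method` can force a branch
// (0 = auto, 1 = small-time, 2 = large-time).
static double wfpt_lower_core(double t, double v, double a, double w,
                              double eps, int method) {
  if (!(t > 0.0) || !R_finite(t)) return 0.0;
  const double tt = t / (a * a); // time in units of a^2

  // Required number of terms for each expansion at tolerance eps.
  double kl, ks;
  if (M_PI * tt * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * eps));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }

  bool use_small = (method == 1) || (method == 0 && ks < kl);
  double f0; // density of the standardized (v=0, a=1) process at time tt
  if (use_small) {
    int K = (int) std::ceil(ks);
    double sum = 0.0;
    int lo = -((K - 1) / 2), hi = (K + 1) / 2;
    for (int k = lo; k <= hi; k++) {
      double wk = w + 2.0 * k;
      sum += wk * std::exp(-wk * wk / (2.0 * tt));
    }
    f0 = sum / std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {
    // individual sine terms can vanish at rational w, so no early break:
    // the term-count bound alone controls truncation
    int K = (int) std::ceil(method == 2 ? std::max(kl, 10.0) : kl);
    double sum = 0.0;
    for (int k = 1; k <= K; k++) {
      sum += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
        std::sin(k * M_PI * w);
    }
    f0 = sum * M_PI;
  }
  if (f0 < 0.0) f0 = 0.0; // truncation can leave a tiny negative residue
  return f0 * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
}

static bool valid_params(double v, double a, double z, double t0) {
  return R_finite(v) && a > 0.0 && z > 0.0 && z < 1.0 && t0 >= 0.0;
}

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector t, double v, double a, double z,
                               double t0, bool upper, double eps, int method) {
  if (!valid_params(v, a, z, t0)) stop("invalid Wiener parameters");
  const int n = t.size();
  NumericVector out(n);
  // hitting the upper boundary is the mirror problem (-v, 1-z) at the lower one
  double vv = upper ? -v : v;
  double ww = upper ? 1.0 - z : z;
  for (int i = 0; i < n; i++) {
    out[i] = wfpt_lower_core(t[i] - t0, vv, a, ww, eps, method);
  }
  return out;
}

// [[Rcpp::export]]
double choice_prob_upper_cpp(double v, double a, double z) {
  if (!(a > 0.0) || !(z > 0.0 && z < 1.0)) stop("invalid Wiener parameters");
  if (std::fabs(v) < 1e-10) return z;
  // P(hit a before 0 | start z*a) = (1 - e^{-2vaz}) / (1 - e^{-2va})
  return expm1(-2.0 * v * a * z) / expm1(-2.0 * v * a);
}

// [[Rcpp::export]]
double wfpt_loglik_cpp(NumericVector rt, IntegerVector upper,
                       NumericVector v, NumericVector a,
                       NumericVector z, NumericVector t0) {
  const int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; i++) {
    if (!valid_params(v[i], a[i], z[i], t0[i])) return R_NegInf;
    double vv = upper[i] ? -v[i] : v[i];
    double ww = upper[i] ? 1.0 - z[i] : z[i];
    double d = wfpt_lower_core(rt[i] - t0[i], vv, a[i], ww, 1e-10, 0);
    if (!(d > 0.0)) return R_NegInf;
    ll += std::log(d);
  }
  return ll;
}

// [[Rcpp::export]]
List sim_ddm_euler_cpp(int n, double v, double a, double z, double t0,
                       double dt, double t_max) {
  if (!valid_params(v, a, z, t0)) stop("invalid Wiener parameters");
  NumericVector rt(n);
  IntegerVector up(n);
  const double sdt = std::sqrt(dt);
  for (int i = 0; i < n; i++) {
    double x = z * a, t = 0.0;
    while (t < t_max) {
      x += v * dt + sdt * norm_rand();
      t += dt;
      if (x >= a) { up[i] = 1; break; }
      if (x <= 0.0) { up[i] = 0; break; }
    }
    if (t >= t_max) { up[i] = x >= a * 0.5 ? 1 : 0; } // essentially never at sane t_max
    rt[i] = t0 + t;
  }
  return List::create(_["rt"] = rt, _["upper"] = up);
}

// Exact-choice / numerically inverted RT simulator: the boundary is drawn from
// the closed-form hitting probability, the decision time from the inverse of
// the numerically integrated defective density.
// [[Rcpp::export]]
List sim_ddm_hybrid_cpp(int n, double v, double a, double z, double t0,
                        double grid_dt) {
  if (!valid_params(v, a, z, t0)) stop("invalid Wiener parameters");
  const double p_up = (std::fabs(v) < 1e-10) ? z :
    expm1(-2.0 * v * a * z) / expm1(-2.0 * v * a);

  // expand the grid until virtually all mass is covered
  double t_max = 2.0;
  int m = 0;
  std::vector<double> cup, clo, tg;
  for (int tries = 0; tries < 8; tries++) {
    m = (int) std::ceil(t_max / grid_dt);
    tg.assign(m + 1, 0.0);
    cup.assign(m + 1, 0.0);
    clo.assign(m + 1, 0.0);
    double fup_prev = 0.0, flo_prev = 0.0;
    for (int i = 1; i <= m; i++) {
      double t = i * grid_dt;
      tg[i] = t;
      double fup = wfpt_lower_core(t, -v, a, 1.0 - z, 1e-10, 0);
      double flo = wfpt_lower_core(t, v, a, z, 1e-10, 0);
      cup[i] = cup[i - 1] + 0.5 * (fup + fup_prev) * grid_dt;
      clo[i] = clo[i - 1] + 0.5 * (flo + flo_prev) * grid_dt;
      fup_prev = fup; flo_prev = flo;
    }
    if (cup[m] + clo[m] > 1.0 - 1e-6) break;
    t_max *= 2.0;
  }

  NumericVector rt(n);
  IntegerVector up(n);
  for (int i = 0; i < n; i++) {
    bool hit_up = unif_rand() < p_up;
    const std::vector<double> &C = hit_up ? cup : clo;
    double total = C[m];
    double u = unif_rand() * total;
    // binary search for the bracketing grid cell
    int lo = 0, hi = m;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (C[mid] < u) lo = mid; else hi = mid;
    }
    double c0 = C[lo], c1 = C[hi];
    double frac = (c1 > c0) ? (u - c0) / (c1 - c0) : 0.5;
    rt[i] = t0 + tg[lo] + frac * grid_dt;
    up[i] = hit_up ? 1 : 0;
  }
  return List::create(_["rt"] = rt, _["upper"] = up);
}

// First-passage CDF grids for both boundaries, used to invert RT draws for
// many trials sharing one parameter set.
// [[Rcpp::export]]
List wfpt_cdf_grid_cpp(double v, double a, double z, double grid_dt) {
  if (!valid_params(v, a, z, 0.0)) stop("invalid Wiener parameters");
  double p_up = (std::fabs(v) < 1e-10) ? z :
    expm1(-2.0 * v * a * z) / expm1(-2.0 * v * a);
  double t_max = 2.0;
  int m = 0;
  std::vector<double> cup, clo, tg;
  for (int tries = 0; tries < 8; tries++) {
    m = (int) std::ceil(t_max / grid_dt);
    tg.assign(m + 1, 0.0);
    cup.assign(m + 1, 0.0);
    clo.assign(m + 1, 0.0);
    double fup_prev = 0.0, flo_prev = 0.0;
    for (int i = 1; i <= m; i++) {
      double t = i * grid_dt;
      tg[i] = t;
      double fup = wfpt_lower_core(t, -v, a, 1.0 - z, 1e-10, 0);
      double flo = wfpt_lower_core(t, v, a, z, 1e-10, 0);
      cup[i] = cup[i - 1] + 0.5 * (fup + fup_prev) * grid_dt;
      clo[i] = clo[i - 1] + 0.5 * (flo + flo_prev) * grid_dt;
      fup_prev = fup; flo_prev = flo;
    }
    if (cup[m] + clo[m] > 1.0 - 1e-6) break;
    t_max *= 2.0;
  }
  return List::create(_["t"] = NumericVector(tg.begin(), tg.end()),
                      _["cdf_upper"] = NumericVector(cup.begin(), cup.end()),
                      _["cdf_lower"] = NumericVector(clo.begin(), clo.end()),
                      _["p_upper"] = p_up);
}

// splitmix64-style counter hash used to derive independent per-trial RNG
// substreams from (master seed, trial counter); returns a positive 31-bit int.
// [[Rcpp::export]]
IntegerVector substream_seed_cpp(int master, IntegerVector counter) {
  const int n = counter.size();
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    uint64_t x = ((uint64_t)(uint32_t) master << 32) ^ (uint64_t)(uint32_t) counter[i];
    x += 0x9E3779B97f4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    x = x ^ (x >> 31);
    out[i] = (int) (x % 2147483646ULL) + 1;
  }
  return out;
}

// Log posterior of the hierarchical Wiener model, vectorized over parameter
// vectors (rows of `theta`). Layout of one parameter vector:
//   beta_v (pv) | beta_z (pz) | beta_a (pa) | beta_t (pt) |
//   u_v (S) | u_z (S) | u_a (S) | u_t (S) | lsd (4)
// Cell values come from cell design matrices (sum-to-zero coded); subject
// deviations u are centered (u ~ N(0, exp(lsd)) on the link scale), which
// mixes well here because each participant contributes many trials.
// Links: v identity, z logit, a log, t0 log.
// [[Rcpp::export]]
NumericVector wiener_logpost_cpp(NumericMatrix theta, List data) {
  NumericVector rt = data["rt"];
  IntegerVector upper = data["upper"];
  IntegerVector subj = data["subj"];       // 0-based
  IntegerVector cell_vz = data["cell_vz"]; // 0-based
  IntegerVector cell_at = data["cell_at"]; // 0-based
  NumericMatrix Xvz = data["Xvz"];         // n_cells_vz x pv
  NumericMatrix Xat = data["Xat"];         // n_cells_at x pa
  NumericMatrix min_rt = data["min_rt"];   // subject x at-cell minimum RT
  NumericVector pr_mean = data["prior_mean"];
  NumericVector pr_sd = data["prior_sd"];  // for the beta blocks, length pv+pz+pa+pt
  double sd_hyp = as<double>(data["sd_hyper"]); // scale of half-normal on RI SDs

  const int n = rt.size();
  const int S = min_rt.nrow();
  const int Cvz = Xvz.nrow(), pv = Xvz.ncol();
  const int Cat = Xat.nrow(), pa = Xat.ncol();
  const int nb = 2 * pv + 2 * pa;
  const int K = theta.nrow();
  NumericVector out(K);

  std::vector<double> lv(Cvz), lz(Cvz), la(Cat), lt(Cat);
  std::vector<double> v_sc(S * Cvz), z_sc(S * Cvz), a_sc(S * Cat), t_sc(S * Cat);

  for (int k = 0; k < K; k++) {
    // matrices are column-major; copy the chain's row once
    std::vector<double> par(theta.ncol());
    for (int j = 0; j < theta.ncol(); j++) par[j] = theta(k, j);
    const double *th = par.data();

    const double *bv = th, *bz = th + pv, *ba = th + 2 * pv, *bt = th + 2 * pv + pa;
    const double *ev = th + nb, *ez = ev + S, *ea = ez + S, *et = ea + S;
    const double *lsd = th + nb + 4 * S;

    double lp = 0.0;
    bool bad = false;

    // priors on fixed effects
    for (int j = 0; j < nb; j++) {
      double d = (par[j] - pr_mean[j]) / pr_sd[j];
      lp += -0.5 * d * d - std::log(pr_sd[j]);
    }
    // half-normal SD priors (with the log-scale Jacobian for lsd = log sd),
    // then centered subject deviations u ~ N(0, sd)
    double sdlink[4];
    for (int j = 0; j < 4; j++) {
      double ls = lsd[j];
      if (ls > 5.0 || ls < -12.0) { bad = true; break; }
      double sdv = std::exp(ls);
      sdlink[j] = sdv;
      double d = sdv / sd_hyp;
      lp += -0.5 * d * d + ls; // half-normal density kernel + Jacobian
    }
    if (bad) { out[k] = R_NegInf; continue; }
    for (int j = 0; j < 4; j++) {
      for (int s = 0; s < S; s++) {
        double d = par[nb + j * S + s] / sdlink[j];
        lp += -0.5 * d * d - std::log(sdlink[j]);
      }
    }

    // cell linear predictors
    for (int c = 0; c < Cvz; c++) {
      double s1 = 0.0, s2 = 0.0;
      for (int j = 0; j < pv; j++) {
        s1 += Xvz(c, j) * bv[j];
        s2 += Xvz(c, j) * bz[j];
      }
      lv[c] = s1; lz[c] = s2;
    }
    for (int c = 0; c < Cat; c++) {
      double s1 = 0.0, s2 = 0.0;
      for (int j = 0; j < pa; j++) {
        s1 += Xat(c, j) * ba[j];
        s2 += Xat(c, j) * bt[j];
      }
      la[c] = s1; lt[c] = s2;
    }

    // subject-by-cell parameter values
    for (int s = 0; s < S && !bad; s++) {
      double uv = ev[s], uz = ez[s];
      double ua = ea[s], ut = et[s];
      for (int c = 0; c < Cvz; c++) {
        v_sc[s * Cvz + c] = lv[c] + uv;
        z_sc[s * Cvz + c] = 1.0 / (1.0 + std::exp(-(lz[c] + uz)));
      }
      for (int c = 0; c < Cat; c++) {
        double av = std::exp(la[c] + ua);
        double tv = std::exp(lt[c] + ut);
        if (!R_finite(av) || av > 50.0) { bad = true; break; }
        // feasibility: t0 may approach the fastest response this subject
        // produced under this cell's non-decision regime, but not reach it
        // (the first-passage density vanishes smoothly there, so no extra
        // safety margin is required)
        if (tv >= min_rt(s, c)) { bad = true; break; }
        a_sc[s * Cat + c] = av;
        t_sc[s * Cat + c] = tv;
      }
    }
    if (bad) { out[k] = R_NegInf; continue; }

    // likelihood
    for (int i = 0; i < n; i++) {
      int s = subj[i];
      double vi = v_sc[s * Cvz + cell_vz[i]];
      double zi = z_sc[s * Cvz + cell_vz[i]];
      double ai = a_sc[s * Cat + cell_at[i]];
      double ti = t_sc[s * Cat + cell_at[i]];
      double vv = upper[i] ? -vi : vi;
      double ww = upper[i] ? 1.0 - zi : zi;
      double d = wfpt_lower_core(rt[i] - ti, vv, ai, ww, 1e-8, 0);
      if (!(d > 0.0)) { bad = true; break; }
      lp += std::log(d);
    }
    out[k] = bad ? R_NegInf : lp;
  }
  return out;
}
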