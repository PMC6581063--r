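// Compiled core of the population-likelihood evaluation: per-subject
// penalised objective, analytic eta-gradient, damped-Newton posterior-mode
// search and the Laplace / FOCE-I -2 log marginal likelihood.  Mirrors the
// R implementation used by map_estimate(); the two are cross-checked in the
// test suite.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

struct SubjectData {
  int nt, nd;
  const double *y, *rate, *m1, *m2, *active;
};

struct HParts {
  double h;
  double g[2];
  std::vector<double> f, g2, f1, f2;
};

// concentration, df/deta and the penalised data objective at (e1, e2)
void h_parts(const SubjectData &s, double clb, double w, double e1,
             double e2, double siga2, double sigp2, HParts &out) {
  const double cl = clb * std::exp(e1);
  const double v = w * std::exp(e2);
  const double k = cl / v;
  const double twopi = 2.0 * M_PI;
  out.f.assign(s.nt, 0.0);
  out.g2.assign(s.nt, 0.0);
  out.f1.assign(s.nt, 0.0);
  out.f2.assign(s.nt, 0.0);
  out.h = 0.0;
  out.g[0] = out.g[1] = 0.0;
  for (int j = 0; j < s.nt; ++j) {
    double f = 0.0, dfdk = 0.0;
    for (int d = 0; d < s.nd; ++d) {
      const double act = s.active[j + d * s.nt];
      if (act == 0.0) continue;
      const double m1 = s.m1[j + d * s.nt];
      const double m2 = s.m2[j + d * s.nt];
      const double e1m = std::exp(-k * m1);
      const double e2m = std::exp(-k * m2);
      f += s.rate[d] * (1.0 - e1m) * e2m;
      dfdk += s.rate[d] * (m1 * e1m - m2 * (1.0 - e1m)) * e2m;
    }
    f /= cl;
    dfdk /= cl;
    const double fj1 = -f + k * dfdk;  // df/d eta_cl
    const double fj2 = -k * dfdk;      // df/d eta_v
    const double r = s.y[j] - f;
    double g2 = siga2 + sigp2 * f * f;
    if (g2 < 1e-12) g2 = 1e-12;
    out.f[j] = f;
    out.g2[j] = g2;
    out.f1[j] = fj1;
    out.f2[j] = fj2;
    out.h += 0.5 * (r * r / g2 + std::log(twopi * g2));
    const double common = -r / g2 + sigp2 * f * (1.0 / g2 - r * r / (g2 * g2));
    out.g[0] += common * fj1;
    out.g[1] += common * fj2;
  }
}

inline double penalised_h(const SubjectData &s, double clb, double w,
                          const double *eta, const double *om2,
                          const bool *free_eta, double prior_const,
                          double siga2, double sigp2, HParts &scratch) {
  h_parts(s, clb, w, eta[0], eta[1], siga2, sigp2, scratch);
  double h = scratch.h + prior_const;
  for (int m = 0; m < 2; ++m)
    if (free_eta[m]) h += 0.5 * eta[m] * eta[m] / om2[m];
  return h;
}

// Gauss-Newton Hessian of the penalised objective
void gn_hessian(const HParts &sp, const double *om2, const bool *free_eta,
                double H[2][2]) {
  H[0][0] = H[0][1] = H[1][0] = H[1][1] = 0.0;
  for (size_t j = 0; j < sp.f1.size(); ++j) {
    const double w = 1.0 / sp.g2[j];
    H[0][0] += w * sp.f1[j] * sp.f1[j];
    H[0][1] += w * sp.f1[j] * sp.f2[j];
    H[1][1] += w * sp.f2[j] * sp.f2[j];
  }
  H[1][0] = H[0][1];
  for (int m = 0; m < 2; ++m) {
    const double o = om2[m] > 1e-12 ? om2[m] : 1e-12;
    H[m][m] += 1.0 / o;
    (void)free_eta;
  }
}

// exact Hessian by central differences of the analytic gradient
void fd_hessian(const SubjectData &s, double clb, double w,
                const double *eta, const double *om2, const bool *free_eta,
                double siga2, double sigp2, double H[2][2],
                HParts &scratch) {
  const double dd = 1e-5;
  double G[2][2];
  for (int m = 0; m < 2; ++m) {
    double ep[2] = {eta[0], eta[1]};
    double em[2] = {eta[0], eta[1]};
    ep[m] += dd;
    em[m] -= dd;
    double gp[2], gm[2];
    h_parts(s, clb, w, ep[0], ep[1], siga2, sigp2, scratch);
    for (int q = 0; q < 2; ++q)
      gp[q] = scratch.g[q] + (free_eta[q] ? ep[q] / om2[q] : 0.0);
    h_parts(s, clb, w, em[0], em[1], siga2, sigp2, scratch);
    for (int q = 0; q < 2; ++q)
      gm[q] = scratch.g[q] + (free_eta[q] ? em[q] / om2[q] : 0.0);
    for (int q = 0; q < 2; ++q) G[m][q] = (gp[q] - gm[q]) / (2.0 * dd);
  }
  H[0][0] = G[0][0];
  H[1][1] = G[1][1];
  H[0][1] = H[1][0] = 0.5 * (G[0][1] + G[1][0]);
  // ridge to positive definiteness
  const double tr = 0.5 * (H[0][0] + H[1][1]);
  const double det0 = H[0][0] * H[1][1] - H[0][1] * H[0][1];
  const double disc = std::sqrt(std::max(tr * tr - det0, 0.0));
  const double lmin = tr - disc;
  if (lmin < 1e-8) {
    H[0][0] += 1e-8 - lmin;
    H[1][1] += 1e-8 - lmin;
  }
}

struct InnerResult {
  double eta[2];
  double h;
  bool converged;
  HParts sp;
};

void inner_map(const SubjectData &s, double clb, double w,
               const double *om2, double siga2, double sigp2,
               const double *eta0, InnerResult &res) {
  const bool free_eta[2] = {om2[0] > 0.0, om2[1] > 0.0};
  double prior_const = 0.0;
  for (int m = 0; m < 2; ++m)
    if (free_eta[m]) prior_const += 0.5 * std::log(2.0 * M_PI * om2[m]);
  double eta[2] = {free_eta[0] ? eta0[0] : 0.0,
                   free_eta[1] ? eta0[1] : 0.0};
  HParts scratch;
  double h = penalised_h(s, clb, w, eta, om2, free_eta, prior_const, siga2,
                         sigp2, res.sp);
  bool converged = !(free_eta[0] || free_eta[1]);
  const double tol = 1e-7;
  for (int it = 0; it < 60 && (free_eta[0] || free_eta[1]); ++it) {
    double grad[2];
    double gmax = 0.0;
    for (int m = 0; m < 2; ++m) {
      grad[m] = res.sp.g[m] + (free_eta[m] ? eta[m] / om2[m] : 0.0);
      if (free_eta[m] && std::fabs(grad[m]) > gmax)
        gmax = std::fabs(grad[m]);
    }
    if (gmax < tol) {
      converged = true;
      break;
    }
    double H[2][2];
    if (it < 8)
      gn_hessian(res.sp, om2, free_eta, H);
    else
      fd_hessian(s, clb, w, eta, om2, free_eta, siga2, sigp2, H, scratch);
    // Newton step restricted to the free etas (2x2 or 1x1 solve)
    double delta[2] = {0.0, 0.0};
    if (free_eta[0] && free_eta[1]) {
      const double det = H[0][0] * H[1][1] - H[0][1] * H[1][0];
      if (std::fabs(det) < 1e-300) break;
      delta[0] = (-grad[0] * H[1][1] + grad[1] * H[0][1]) / det;
      delta[1] = (-grad[1] * H[0][0] + grad[0] * H[1][0]) / det;
    } else {
      const int m = free_eta[0] ? 0 : 1;
      if (H[m][m] <= 0.0) break;
      delta[m] = -grad[m] / H[m][m];
    }
    double step = 1.0;
    double eta_new[2], h_new = 0.0;
    bool ok = false;
    while (step >= 1e-6) {
      eta_new[0] = eta[0] + step * delta[0];
      eta_new[1] = eta[1] + step * delta[1];
      h_new = penalised_h(s, clb, w, eta_new, om2, free_eta, prior_const,
                          siga2, sigp2, scratch);
      if (R_finite(h_new) && h_new <= h + 1e-12) {
        ok = true;
        break;
      }
      step /= 2.0;
    }
    if (!ok) {
      converged = gmax < 1e-3;
      break;
    }
    eta[0] = eta_new[0];
    eta[1] = eta_new[1];
    std::swap(res.sp.f, scratch.f);
    std::swap(res.sp.g2, scratch.g2);
    std::swap(res.sp.f1, scratch.f1);
    std::swap(res.sp.f2, scratch.f2);
    res.sp.h = scratch.h;
    res.sp.g[0] = scratch.g[0];
    res.sp.g[1] = scratch.g[1];
    h = h_new;
    const double dmax = std::max(std::fabs(step * delta[0]),
                                 std::fabs(step * delta[1]));
    if (step == 1.0 && dmax < 1e-9) {
      converged = true;
      break;
    }
  }
  res.eta[0] = eta[0];
  res.eta[1] = eta[1];
  res.h = h;
  res.converged = converged;
}

}  // namespace

// [[Rcpp::export]]
List pop_nll_cpp(List subjects, NumericVector clb, NumericVector w,
                 double om2_cl, double om2_v, double sig_a2, double sig_p2,
                 NumericMatrix eta_init, int laplace_exact) {
  const int n = subjects.size();
  double total = 0.0;
  NumericMatrix etas(n, 2);
  const double om2[2] = {om2_cl, om2_v};
  const bool free_eta[2] = {om2[0] > 0.0, om2[1] > 0.0};
  const int p = (free_eta[0] ? 1 : 0) + (free_eta[1] ? 1 : 0);
  InnerResult res;
  HParts scratch;
  for (int i = 0; i < n; ++i) {
    List sl = subjects[i];
    NumericVector y = sl["y"];
    if (y.size() == 0) continue;
    NumericVector rate = sl["rate"];
    NumericMatrix m1 = sl["m1"], m2 = sl["m2"], active = sl["active"];
    SubjectData s;
    s.nt = y.size();
    s.nd = rate.size();
    s.y = y.begin();
    s.rate = rate.begin();
    s.m1 = m1.begin();
    s.m2 = m2.begin();
    s.active = active.begin();
    const double eta0[2] = {eta_init(i, 0), eta_init(i, 1)};
    inner_map(s, clb[i], w[i], om2, sig_a2, sig_p2, eta0, res);
    etas(i, 0) = res.eta[0];
    etas(i, 1) = res.eta[1];
    double nll;
    if (p == 0) {
      nll = 2.0 * res.h;
    } else {
      double H[2][2];
      if (laplace_exact)
        fd_hessian(s, clb[i], w[i], res.eta, om2, free_eta, sig_a2, sig_p2,
                   H, scratch);
      else
        gn_hessian(res.sp, om2, free_eta, H);
      double detH;
      if (free_eta[0] && free_eta[1])
        detH = H[0][0] * H[1][1] - H[0][1] * H[1][0];
      else
        detH = free_eta[0] ? H[0][0] : H[1][1];
      if (!R_finite(detH) || detH <= 0.0) {
        gn_hessian(res.sp, om2, free_eta, H);
        detH = free_eta[0] && free_eta[1]
                   ? H[0][0] * H[1][1] - H[0][1] * H[1][0]
                   : (free_eta[0] ? H[0][0] : H[1][1]);
      }
      nll = 2.0 * res.h - p * std::log(2.0 * M_PI) + std::log(detH);
    }
    total += nll;
  }
  return List::create(Named("nll") = total, Named("etas") = etas);
}
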