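#include <Rcpp.h>
using namespace Rcpp;

// First-passage density of a single linear ballistic accumulator:
// start ~ U(0, A), drift ~ N(v, s), threshold b, decision time t > 0.
// A == 0 uses the analytic ballistic limit (crossing time b / drift).
static inline double acc_fpt_pdf(double t, double b, double A,
                                 double v, double s) {
  if (!(t > 0.0)) return 0.0;
  if (A <= 0.0) {
    double z = (b / t - v) / s;
    return b / (t * t * s) * R::dnorm(z, 0.0, 1.0, 0);
  }
  double ts = t * s;
  double z1 = (b - A - t * v) / ts;
  double z2 = (b - t * v) / ts;
  double d = (-v * R::pnorm(z1, 0.0, 1.0, 1, 0) + s * R::dnorm(z1, 0.0, 1.0, 0)
              + v * R::pnorm(z2, 0.0, 1.0, 1, 0) - s * R::dnorm(z2, 0.0, 1.0, 0)) / A;
  return d > 0.0 ? d : 0.0;
}

// Matching first-passage CDF; limit t -> Inf is Phi(v/s), the probability
// that the sampled drift is positive (only those trials ever cross).
static inline double acc_fpt_cdf(double t, double b, double A,
                                 double v, double s) {
  if (!(t > 0.0)) return 0.0;
  if (A <= 0.0) {
    return R::pnorm((v - b / t) / s, 0.0, 1.0, 1, 0);
  }
  double ts = t * s;
  double z1 = (b - A - t * v) / ts;
  double z2 = (b - t * v) / ts;
  double F = 1.0 + (b - A - t * v) / A * R::pnorm(z1, 0.0, 1.0, 1, 0)
                 - (b - t * v) / A * R::pnorm(z2, 0.0, 1.0, 1, 0)
                 + ts / A * (R::dnorm(z1, 0.0, 1.0, 0) - R::dnorm(z2, 0.0, 1.0, 0));
  if (F < 0.0) F = 0.0;
  if (F > 1.0) F = 1.0;
  return F;
}

// Defective density of one race at decision time tau, renormalized by the
// race's finish probability Z: f_winner(tau) * (1 - F_loser(tau)) / Z.
static inline double race_dens(double tau, double b, double A,
                               double v_w, double v_l, double s,
                               double Z) {
  if (!(tau > 0.0)) return 0.0;
  double f = acc_fpt_pdf(tau, b, A, v_w, s);
  if (f <= 0.0) return 0.0;
  double Fl = acc_fpt_cdf(tau, b, A, v_l, s);
  double d = f * (1.0 - Fl) / Z;
  return d > 0.0 ? d : 0.0;
}

//' Batch log-likelihood of the constrained speed-accuracy LBA model
//'
//' Hot path used by the DE-MCMC sampler: one log-likelihood per row of
//' \code{theta}. Column order is (t0, b_acc, v_t_acc, v_d_acc, v_t_spd,
//' v_d_spd, s_acc, p). The speed setting uses threshold
//' \code{b_ratio * b_acc} and drift SD fixed at 1; accuracy-emphasis trials
//' are a p-mixture of the speed and accuracy settings. Trials with
//' \code{is_acc == 1} are accuracy-emphasis; \code{resp == 0} means the
//' target accumulator won. Densities below \code{dens_floor} are floored
//' before taking logs.
//'
//' @keywords internal
// [[Rcpp::export]]
NumericVector sat_loglik_cpp(NumericMatrix theta,
                             IntegerVector is_acc,
                             IntegerVector resp,
                             NumericVector rt,
                             double A,
                             double b_ratio,
                             double dens_floor) {
  const int m = theta.nrow();
  const int n = rt.size();
  NumericVector out(m);
  const double log_floor = std::log(dens_floor);

  for (int r = 0; r < m; ++r) {
    const double t0    = theta(r, 0);
    const double b_acc = theta(r, 1);
    const double vt_a  = theta(r, 2);
    const double vd_a  = theta(r, 3);
    const double vt_s  = theta(r, 4);
    const double vd_s  = theta(r, 5);
    const double s_a   = theta(r, 6);
    const double p     = theta(r, 7);
    const double b_spd = b_ratio * b_acc;
    const double s_s   = 1.0;

    bool ok = R_finite(t0) && t0 >= 0.0 && b_acc > 0.0 && s_a > 0.0 &&
              p >= 0.0 && p <= 1.0 && A >= 0.0 && A < b_acc && A < b_spd &&
              R_finite(vt_a) && R_finite(vd_a) && R_finite(vt_s) && R_finite(vd_s);
    if (!ok) {
      out[r] = R_NegInf;
      continue;
    }

    // finish probabilities (independent of b and A: crossing needs drift > 0)
    double Z_s = 1.0 - R::pnorm(-vt_s / s_s, 0.0, 1.0, 1, 0) *
                       R::pnorm(-vd_s / s_s, 0.0, 1.0, 1, 0);
    double Z_a = 1.0 - R::pnorm(-vt_a / s_a, 0.0, 1.0, 1, 0) *
                       R::pnorm(-vd_a / s_a, 0.0, 1.0, 1, 0);
    if (!(Z_s > 0.0) || !(Z_a > 0.0)) {
      out[r] = R_NegInf;
      continue;
    }

    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double tau = rt[i] - t0;
      const bool target_won = (resp[i] == 0);
      double dens_spd = target_won
        ? race_dens(tau, b_spd, A, vt_s, vd_s, s_s, Z_s)
        : race_dens(tau, b_spd, A, vd_s, vt_s, s_s, Z_s);
      double dens;
      if (is_acc[i] == 1) {
        double dens_acc = target_won
          ? race_dens(tau, b_acc, A, vt_a, vd_a, s_a, Z_a)
          : race_dens(tau, b_acc, A, vd_a, vt_a, s_a, Z_a);
        dens = (1.0 - p) * dens_acc + p * dens_spd;
      } else {
        dens = dens_spd;
      }
      ll += (dens > dens_floor) ? std::log(dens) : log_floor;
    }
    out[r] = ll;
  }
  return out;
}
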