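// Monthly agent-update kernel.
//
// One pass over the living working-age agents, updating beta-cell function,
// cumulative dysglycemia exposure, the pregnancy glycemic-index tracker and
// BMI in place, and collecting the discrete-event work for the step:
// screening tests falling due, deliveries at week 40, postpartum intervals
// ending, and conceptions (thinned by pre-drawn uniforms against the
// age-band hazard). The arithmetic mirrors the R reference implementations
// (insulin_sensitivity, glycemic_index, step_metabolism, bmi_step,
// treatment_effect, conception_hazard); the R functions remain the
// documented source of the model equations and the test suite checks that
// kernel trajectories agree with them.

#include <Rcpp.h>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// piecewise-linear age-drift spline, constant beyond the knots
static inline double interp_drift(double age, const NumericVector& xs,
                                  const NumericVector& ys) {
  const int n = xs.size();
  if (age <= xs[0]) return ys[0];
  if (age >= xs[n - 1]) return ys[n - 1];
  int i = 1;
  while (xs[i] < age) ++i;
  double w = (age - xs[i - 1]) / (xs[i] - xs[i - 1]);
  return ys[i - 1] + w * (ys[i] - ys[i - 1]);
}

// [[Rcpp::export(name = ".step_scan_cpp")]]
List step_scan_cpp(IntegerVector li, NumericVector age, NumericVector bmi,
                   NumericVector B, NumericVector E, NumericVector s_base,
                   IntegerVector preg, NumericVector preg_t0,
                   NumericVector diag_w, NumericVector gsum,
                   NumericVector gn, NumericVector dmult, NumericVector z,
                   NumericVector smult, NumericVector dbmi,
                   NumericVector sw_early, NumericVector sw_univ,
                   NumericVector pp_end, NumericVector u_conc,
                   NumericVector p_band, double fert_min, double fert_max,
                   double dt_weeks, double t, double dt, List ph,
                   bool mech) {
  const double k_bmi = ph["k_bmi"], bmi_ref = ph["bmi_ref"],
    s_min = ph["s_min"], rho = ph["rho_preg"], g_max = ph["g_max"],
    g_thr = ph["g_thr"], k_decay = ph["k_decay"], r_regen = ph["r_regen"],
    e_rev = ph["e_rev"], secular = ph["bmi_secular"],
    noise_sd = ph["bmi_noise_sd"], m_full = ph["m_full"],
    ramp_weeks = ph["ramp_weeks"];
  const NumericVector drift_age = ph["drift_age"];
  const NumericVector drift_rate = ph["drift_rate"];
  const bool has_smult = smult.size() > 0;
  const bool has_dbmi = dbmi.size() > 0;
  const double sqdt = std::sqrt(dt);
  const int m = li.size();
  std::vector<int> due_e, due_u, due_d, pp_done, conc;
  int ec = 0;
  const int n_u = u_conc.size();
  for (int j = 0; j < m; ++j) {
    const int i = li[j] - 1;
    const bool pregnant = preg[i] == 1;
    double week = -1.0, pm = 1.0;
    if (pregnant) {
      week = (t - preg_t0[i]) * 52.0;
      pm = 1.0 - rho * std::min(40.0, week) / 40.0;
    }
    double sb = s_base[i];
    if (has_smult) sb *= smult[i];
    double S = clampd(sb * std::exp(-k_bmi * std::max(0.0, bmi[i] - bmi_ref)) * pm,
                      s_min, 1.0);
    double G = std::min(1.0 / (S * std::max(B[i], 1e-12)), g_max);
    if (pregnant && !ISNAN(diag_w[i])) {
      double wks = std::max(0.0, week - diag_w[i]);
      G *= 1.0 - (1.0 - m_full) * std::min(1.0, wks / ramp_weeks);
    }
    if (mech) {
      const double y = std::max(0.0, G - g_thr);
      const double regen = (E[i] < e_rev) ? r_regen * (1.0 - B[i]) : 0.0;
      E[i] += y * dt;
      B[i] = clampd(B[i] + (regen - k_decay * y * B[i]) * dt, 0.0, 1.0);
    }
    if (pregnant) {
      gsum[i] += G;
      gn[i] += 1.0;
      const double w_new = week + dt_weeks;
      if (!ISNAN(sw_early[i]) && week < sw_early[i] && sw_early[i] <= w_new)
        due_e.push_back(i + 1);
      if (!ISNAN(sw_univ[i]) && week < sw_univ[i] && sw_univ[i] <= w_new)
        due_u.push_back(i + 1);
      if (w_new >= 40.0) due_d.push_back(i + 1);
    } else if (preg[i] == 2) {
      if (!ISNAN(pp_end[i]) && pp_end[i] <= t + dt) pp_done.push_back(i + 1);
    } else if (age[i] >= fert_min && age[i] < fert_max && ec < n_u) {
      const int b = (int)(age[i] - fert_min);
      if (u_conc[ec++] < p_band[b]) conc.push_back(i + 1);
    }
    double drift = interp_drift(age[i], drift_age, drift_rate) * dmult[i];
    double nb = bmi[i] + (drift + secular) * dt + z[j] * noise_sd * sqdt;
    if (has_dbmi) nb += dbmi[i];
    bmi[i] = std::max(12.0, nb);
  }
  return List::create(_["due_early"] = wrap(due_e),
                      _["due_univ"] = wrap(due_u),
                      _["due_deliver"] = wrap(due_d),
                      _["pp_done"] = wrap(pp_done),
                      _["conc"] = wrap(conc));
}
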