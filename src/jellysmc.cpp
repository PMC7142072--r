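#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Carbon-budget kernel shared by the trajectory simulator and the SMC match
// loop. All rates are daily; temperatures may hold one or two entries
// (surface and deep water for the nycthemeral migration), in which case each
// rate is evaluated at both and averaged with equal weight.

namespace {

struct Pars {
  double p_max, b_p, k_p, R_o, b_r, t10p, t10r,
         alpha, beta, a_re, b_re, W_e, c_re, spn,
         a_max, k_a, c_e, maturity_bd;
  int resp_basis;   // 0 = wet mass (g), 1 = carbon mass (g)
  int repro_basis;  // 0 = bell diameter (cm), 1 = carbon mass (mg), 2 = carbon mass (g)
};

inline double bd_from_cm_(double cm) {
  return std::pow(cm * 1000.0 / 0.26, 1.0 / 3.017);
}
inline double wm_from_bd_(double bd) {
  return 0.075 * std::pow(bd, 2.993);
}

// out: P I A RO2 RC Ex Re Eg dG
void fluxes(double cm, const double* temps, int ntemp, double F,
            const Pars& p, double* out) {
  double bd = bd_from_cm_(cm);
  double wm = wm_from_bd_(bd);
  double P = 0.0, I = 0.0, A = 0.0, RO2 = 0.0;
  double mr = (p.resp_basis == 0) ? wm : cm;
  for (int k = 0; k < ntemp; ++k) {
    double T = temps[k];
    double Pk = p.p_max * std::pow(cm, p.b_p) * std::pow(p.t10p, T) / (F + p.k_p);
    double Ik = Pk * F;
    double Ak = Ik * (1.0 - p.a_max * F / (F + p.k_a));
    double Rk = p.R_o * std::pow(mr, p.b_r) * std::pow(p.t10r, T);
    P += Pk; I += Ik; A += Ak; RO2 += Rk;
  }
  P /= ntemp; I /= ntemp; A /= ntemp; RO2 /= ntemp;
  double RC = RO2 * p.beta * p.alpha;
  double Ex = RC * p.c_e;
  double Re = 0.0;
  if (bd >= p.maturity_bd) {
    double size = (p.repro_basis == 0) ? bd
                : (p.repro_basis == 1) ? cm * 1000.0 : cm;
    Re = p.a_re * std::pow(size, p.b_re) * p.W_e * p.c_re * p.spn;
  }
  double Eg = I - A;
  double dG = A - (RC + Ex + Re);
  out[0] = P;  out[1] = I;  out[2] = A;  out[3] = RO2; out[4] = RC;
  out[5] = Ex; out[6] = Re; out[7] = Eg; out[8] = dG;
}

Pars pars_from_list(const List& pl) {
  Pars p;
  p.p_max = pl["p_max"]; p.b_p = pl["b_p"]; p.k_p = pl["k_p"];
  p.R_o = pl["R_o"]; p.b_r = pl["b_r"];
  p.t10p = pl["t_10p"]; p.t10r = pl["t_10r"];
  p.alpha = pl["alpha"]; p.beta = pl["beta"];
  p.a_re = pl["a_re"]; p.b_re = pl["b_re"]; p.W_e = pl["W_e"];
  p.c_re = pl["c_re"]; p.spn = pl["spn"];
  p.a_max = pl["a_max"]; p.k_a = pl["k_a"]; p.c_e = pl["c_e"];
  p.maturity_bd = pl["maturity_bd"];
  p.resp_basis = pl["resp_basis"];
  p.repro_basis = pl["repro_basis"];
  return p;
}

// Forward-Euler integration along a step grid. Returns the number of rows
// with a valid state (n_valid < n means the organism exhausted its carbon).
// traj must be n x 13: t cm bd wm P I A RO2 RC Ex Re Eg dG.
int integrate(double cm0, const NumericVector& t, const NumericVector& Ts,
              const NumericVector& Td, const NumericVector& F,
              const Pars& p, double* traj, int n) {
  double cm = cm0;
  double fx[9];
  double temps[2];
  for (int i = 0; i < n; ++i) {
    int ntemp = 1;
    temps[0] = Ts[i];
    if (!NumericVector::is_na(Td[i])) { temps[1] = Td[i]; ntemp = 2; }
    fluxes(cm, temps, ntemp, F[i], p, fx);
    double bd = bd_from_cm_(cm);
    double* row = traj + (size_t)i * 13;
    row[0] = t[i]; row[1] = cm; row[2] = bd; row[3] = wm_from_bd_(bd);
    for (int k = 0; k < 9; ++k) row[4 + k] = fx[k];
    if (i + 1 < n) {
      double dt = t[i + 1] - t[i];
      double cm_next = cm + fx[8] * dt;
      if (cm_next <= 0.0) return i + 1;  // exhausted before reaching t[i+1]
      cm = cm_next;
    }
  }
  return n;
}

// Linear interpolation of a trajectory variable at time x; times beyond the
// last valid state are reported as 0 (no organism left).
double interp_var(double x, const double* tt, const double* vv, int n_valid) {
  if (n_valid <= 0) return 0.0;
  if (x <= tt[0]) return vv[0];
  if (x > tt[n_valid - 1]) return 0.0;
  // find the bracketing interval
  int lo = 0, hi = n_valid - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (tt[mid] < x) lo = mid; else hi = mid;
  }
  double w = (x - tt[lo]) / (tt[hi] - tt[lo]);
  return vv[lo] + w * (vv[hi] - vv[lo]);
}

} // namespace

// [[Rcpp::export]]
List sim_core_cpp(double initial_cm, NumericVector t, NumericVector Ts,
                  NumericVector Td, NumericVector F, List params) {
  int n = t.size();
  Pars p = pars_from_list(params);
  NumericMatrix traj(n, 13);
  std::vector<double> buf((size_t)n * 13, NA_REAL);
  int n_valid = integrate(initial_cm, t, Ts, Td, F, p, buf.data(), n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 13; ++j)
      traj(i, j) = (i < n_valid) ? buf[(size_t)i * 13 + j] : NA_REAL;
  // keep the time column for truncated rows so the record stays addressable
  for (int i = n_valid; i < n; ++i) traj(i, 0) = t[i];
  return List::create(_["traj"] = traj, _["n_valid"] = n_valid,
                      _["status"] = (n_valid == n) ? "ok" : "exhausted");
}

// Per-candidate Monte Carlo match estimation with one-sided SPRT pruning.
// draws: n_sims x 8 (k_p a_max k_a c_re spn c_e F_lab p_max), pre-generated
// in R so that serial and parallel runs consume identical streams.
// scenarios: list of lists with fields t, Ts, Td, F, use_flab, initial_cm,
// tun_t, tun_lo, tun_up, var (0 = bell diameter, 1 = carbon mass).
// [[Rcpp::export]]
List match_candidate_cpp(NumericMatrix draws, List fixed, List scenarios,
                         double gamma, double epsilon, double delta,
                         bool use_sprt) {
  int n_sims = draws.nrow();
  int n_scen = scenarios.size();
  Pars base = pars_from_list(fixed);

  // unpack scenarios once
  std::vector<NumericVector> s_t(n_scen), s_Ts(n_scen), s_Td(n_scen),
      s_F(n_scen), s_tt(n_scen), s_lo(n_scen), s_up(n_scen);
  std::vector<int> s_var(n_scen), s_n(n_scen), s_npts(n_scen);
  std::vector<bool> s_flab(n_scen);
  std::vector<double> s_cm0(n_scen);
  for (int s = 0; s < n_scen; ++s) {
    List sc = scenarios[s];
    s_t[s] = sc["t"]; s_Ts[s] = sc["Ts"]; s_Td[s] = sc["Td"]; s_F[s] = sc["F"];
    s_flab[s] = as<bool>(sc["use_flab"]);
    s_cm0[s] = as<double>(sc["initial_cm"]);
    s_tt[s] = sc["tun_t"]; s_lo[s] = sc["tun_lo"]; s_up[s] = sc["tun_up"];
    s_var[s] = as<int>(sc["var"]);
    s_n[s] = s_t[s].size();
    s_npts[s] = s_tt[s].size();
  }

  // Wald boundary for H1: p <= gamma - epsilon against H0: p >= gamma + epsilon
  double p1 = gamma + epsilon, p0 = gamma - epsilon;
  double la = std::log(p0 / p1);               // per pass (negative)
  double lb = std::log((1.0 - p0) / (1.0 - p1)); // per fail (positive)
  double bound = std::log((1.0 - delta) / delta);

  std::vector<double> out_sum(n_scen, 0.0), dist_sum(n_scen, 0.0);
  int k_pass = 0, n_used = 0, decided = 0;
  std::vector<double> times, vals;

  for (int i = 0; i < n_sims; ++i) {
    Pars p = base;
    p.k_p = draws(i, 0); p.a_max = draws(i, 1); p.k_a = draws(i, 2);
    p.c_re = draws(i, 3); p.spn = draws(i, 4); p.c_e = draws(i, 5);
    p.p_max = draws(i, 7);
    double F_lab = draws(i, 6);
    bool pass = true;
    for (int s = 0; s < n_scen; ++s) {
      int n = s_n[s];
      times.assign(n, 0.0); vals.assign(n, 0.0);
      // inline integration tracking only the compared variable
      double cm = s_cm0[s];
      double fx[9], temps[2];
      int n_valid = n;
      for (int j = 0; j < n; ++j) {
        int ntemp = 1;
        temps[0] = s_Ts[s][j];
        if (!NumericVector::is_na(s_Td[s][j])) { temps[1] = s_Td[s][j]; ntemp = 2; }
        double Fj = s_flab[s] ? F_lab : s_F[s][j];
        fluxes(cm, temps, ntemp, Fj, p, fx);
        times[j] = s_t[s][j];
        vals[j] = (s_var[s] == 0) ? bd_from_cm_(cm) : cm;
        if (j + 1 < n) {
          double dt = s_t[s][j + 1] - s_t[s][j];
          double cm_next = cm + fx[8] * dt;
          if (cm_next <= 0.0) { n_valid = j + 1; break; }
          cm = cm_next;
        }
      }
      // tunnel check
      int n_out = 0; double d = 0.0;
      for (int q = 0; q < s_npts[s]; ++q) {
        double v = interp_var(s_tt[s][q], times.data(), vals.data(), n_valid);
        double lo = s_lo[s][q], up = s_up[s][q];
        double exc = 0.0;
        if (v < lo) exc = lo - v; else if (v > up) exc = v - up;
        if (exc > 0.0) {
          ++n_out;
          double half = 0.5 * (up - lo);
          d += (half > 0.0) ? exc / half : exc;
        }
      }
      out_sum[s] += n_out;
      dist_sum[s] += (s_npts[s] > 0) ? d / s_npts[s] : 0.0;
      if (n_out > 0) pass = false;
    }
    if (pass) ++k_pass;
    n_used = i + 1;
    if (use_sprt && n_used < n_sims) {
      double llr = k_pass * la + (n_used - k_pass) * lb;
      if (llr >= bound) { decided = 1; break; }
    }
  }

  NumericVector score(n_scen), dist(n_scen);
  for (int s = 0; s < n_scen; ++s) {
    score[s] = out_sum[s] / n_used;
    dist[s] = dist_sum[s] / n_used;
  }
  return List::create(
      _["theta_hat"] = (double)k_pass / n_used,
      _["n_used"] = n_used, _["k_pass"] = k_pass,
      _["decided_by"] = decided ? "sprt_reject" : "monte_carlo",
      _["score"] = score, _["dist"] = dist);
}
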