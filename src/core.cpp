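#include <Rcpp.h>
using namespace Rcpp;

// Single forward pass through one session for any model in the nested family.
//
// State coding (integers, R side must agree):
//   first-stage: 0 = P1, 1 = P2 (passive), 2 = A1, 3 = A2 (active)
//   second-stage: 0 = S1, 1 = S2
//   actions: 0 = left (A_L), 1 = right (A_R); terminal values are fixed at 0.
//
// Each non-error trial is one episode of two TD steps:
//   step 1: first_state --(action or pseudoaction)--> second_state, r = 0
//   step 2: second_state --(pseudoaction)--> terminal, r = reward
// Eligibility traces never cross trial boundaries.
//
// mode: 0 = likelihood (choices and outcomes taken from the session)
//       1 = simulate   (choices sampled from pi, outcomes from the task rows)
//       2 = yoked      (choices sampled; passive-trial outcomes replayed;
//                       active-trial outcomes sampled; error trials replayed)
//
// Transition rows are supplied per trial so the caller owns block structure:
//   p_s1_a / p_s1_b: P(S1 | first_state, action L / R); for passive trials
//   p_s1_a is the single row and p_s1_b is ignored.
//   p_rw_s1 / p_rw_s2: P(reward | S1), P(reward | S2).

static inline double num_or(const List& par, const char* nm, double dflt) {
  if (par.containsElementNamed(nm)) return as<double>(par[nm]);
  return dflt;
}

// [[Rcpp::export(name = ".core_pass")]]
List core_pass(IntegerVector trial_type, IntegerVector first,
               IntegerVector action_in, IntegerVector second_in,
               IntegerVector reward_in, IntegerVector error_in,
               NumericVector p_s1_a, NumericVector p_s1_b,
               NumericVector p_rw_s1, NumericVector p_rw_s2,
               List par, List flags, int mode, bool record = true) {
  const int n = trial_type.size();

  const double alpha      = num_or(par, "alpha", 0.0);
  const double lambda     = num_or(par, "lambda", 0.0);
  const double w_q        = num_or(par, "w_q", 1.0);
  const double alpha_star = num_or(par, "alpha_star", 0.0);
  const double w_star     = num_or(par, "w_star", 0.0);
  const double tau        = num_or(par, "tau", 1.0);
  const double beta_r     = num_or(par, "beta_r", 0.0);
  const double beta_0     = num_or(par, "beta_0", 0.0);
  const double lambda_b   = num_or(par, "lambda_beta", 0.0);
  const double p_a1       = num_or(par, "p_a1", 0.5);

  const bool critic  = as<bool>(flags["critic"]);
  const bool actor   = as<bool>(flags["actor"]);
  const bool qlearn  = as<bool>(flags["qlearn"]);
  const bool pure_q  = as<bool>(flags["pure_q"]);
  const bool mb      = as<bool>(flags["mb"]);
  const bool is_null = as<bool>(flags["is_null"]);

  // Latent state, all zero-initialized; V indexed P1,P2,A1,A2,S1,S2.
  double V[6] = {0, 0, 0, 0, 0, 0};
  double pref[2][2] = {{0, 0}, {0, 0}};  // actor preferences, active states
  double Qv[2][2] = {{0, 0}, {0, 0}};    // model-free action values
  double bias[2][2] = {{0, 0}, {0, 0}};  // perseveration biases
  // Model-based transition estimates, uniform prior 1/2 over two successors;
  // each row stored as P(S1 | .) or P(reward | .), complement implied.
  double tP[2] = {0.5, 0.5};
  double tA[2][2] = {{0.5, 0.5}, {0.5, 0.5}};
  double tS[2] = {0.5, 0.5};
  double qstar[2][2] = {{0.5, 0.5}, {0.5, 0.5}};  // planner values, active

  const int NC = 23;
  NumericMatrix trace(record ? n : 1, NC);
  std::fill(trace.begin(), trace.end(), NA_REAL);
  if (record) {
    CharacterVector tr_names = CharacterVector::create(
        "V_first", "V_second", "p_L", "p_R", "Q_L", "Q_R", "W_L", "W_R",
        "Wstar_L", "Wstar_R", "Qstar_L", "Qstar_R", "bias_L", "bias_R",
        "pi_L", "pi_chosen", "dV1", "dV2", "dQ1", "dQ2", "dStar1", "dStar2",
        "Q_chosen");
    colnames(trace) = tr_names;
  }

  IntegerVector action_out(n), second_out(n), reward_out(n);
  NumericVector ll(n, NA_REAL);
  double loglik = 0.0;
  int n_choices = 0;

  RNGScope rng;  // honors set.seed() on the R side

  for (int t = 0; t < n; t++) {
    const int tt = trial_type[t];
    const int s0 = first[t];

    if (error_in[t] != 0) {
      // Aborted trial: no choice likelihood, no latent updates.
      action_out[t] = NA_INTEGER;
      second_out[t] = NA_INTEGER;
      reward_out[t] = NA_INTEGER;
      continue;
    }

    int a = -1, s1 = -1, r = 0;
    const int ai = (tt == 1) ? s0 - 2 : -1;

    if (tt == 1) {
      // Policy at the active state, computed before any update this trial.
      const double WL = w_q * Qv[ai][0] + (1.0 - w_q) * pref[ai][0];
      const double WR = w_q * Qv[ai][1] + (1.0 - w_q) * pref[ai][1];
      const double WsL = w_star * qstar[ai][0] + (1.0 - w_star) * WL;
      const double WsR = w_star * qstar[ai][1] + (1.0 - w_star) * WR;
      double piL;
      if (is_null) {
        piL = p_a1;
      } else {
        const double zL = (WsL + bias[ai][0]) / tau;
        const double zR = (WsR + bias[ai][1] + beta_r) / tau;
        const double m = std::max(zL, zR);
        const double eL = std::exp(zL - m), eR = std::exp(zR - m);
        piL = eL / (eL + eR);
      }

      if (mode == 0) a = action_in[t];
      else a = (unif_rand() < piL) ? 0 : 1;

      const double pi_ch = (a == 0) ? piL : 1.0 - piL;
      ll[t] = std::log(pi_ch);
      loglik += ll[t];
      n_choices++;

      if (record) {
        trace(t, 2) = pref[ai][0]; trace(t, 3) = pref[ai][1];
        trace(t, 4) = Qv[ai][0];   trace(t, 5) = Qv[ai][1];
        trace(t, 6) = WL;          trace(t, 7) = WR;
        trace(t, 8) = WsL;         trace(t, 9) = WsR;
        trace(t, 10) = qstar[ai][0]; trace(t, 11) = qstar[ai][1];
        trace(t, 12) = bias[ai][0];  trace(t, 13) = bias[ai][1];
        trace(t, 14) = piL;          trace(t, 15) = pi_ch;
        trace(t, 22) = Qv[ai][a];
      }
    }

    // Outcome of the trial.
    if (mode == 0 || (mode == 2 && tt == 0)) {
      s1 = second_in[t];
      r = reward_in[t];
    } else {
      const double ps1 = (tt == 1) ? ((a == 0) ? p_s1_a[t] : p_s1_b[t])
                                   : p_s1_a[t];
      s1 = (unif_rand() < ps1) ? 0 : 1;
      const double prw = (s1 == 0) ? p_rw_s1[t] : p_rw_s2[t];
      r = (unif_rand() < prw) ? 1 : 0;
    }
    action_out[t] = (tt == 1) ? a : NA_INTEGER;
    second_out[t] = s1;
    reward_out[t] = r;

    if (record) {
      trace(t, 0) = V[s0];
      trace(t, 1) = V[4 + s1];
    }

    // ---- step 1: first_state -> second_state, r = 0 ----
    double dV1 = NA_REAL, dQ1 = NA_REAL, dS1 = NA_REAL;
    if (critic) dV1 = V[4 + s1] - V[s0];
    if (qlearn && tt == 1 && !pure_q)
      dQ1 = V[4 + s1] - Qv[ai][a];  // pseudoaction: max_a' Q(s', a') = V(s')
    if (mb) {
      const double trow = (tt == 1) ? tA[ai][a] : tP[s0];
      dS1 = (s1 == 0) ? (1.0 - trow) : trow;  // 1 - T(s, a, s_observed)
    }
    if (critic) {
      V[s0] += alpha * dV1;
      if (tt == 1 && actor) pref[ai][a] += alpha * dV1;
    }
    if (qlearn && tt == 1 && !pure_q) Qv[ai][a] += alpha * dQ1;
    if (mb) {
      if (tt == 1) tA[ai][a] += (s1 == 0) ? alpha_star * (1.0 - tA[ai][a])
                                          : -alpha_star * tA[ai][a];
      else tP[s0] += (s1 == 0) ? alpha_star * (1.0 - tP[s0])
                               : -alpha_star * tP[s0];
    }

    // ---- step 2: second_state -> terminal, r = reward ----
    double dV2 = NA_REAL, dQ2 = NA_REAL, dS2 = NA_REAL;
    if (critic) dV2 = (double)r - V[4 + s1];
    if (qlearn && tt == 1)
      dQ2 = pure_q ? ((double)r - Qv[ai][a]) : ((double)r - V[4 + s1]);
    if (mb) dS2 = (r == 1) ? (1.0 - tS[s1]) : tS[s1];
    if (critic) {
      V[4 + s1] += alpha * dV2;
      V[s0] += alpha * lambda * dV2;
      if (tt == 1 && actor) pref[ai][a] += alpha * lambda * dV2;
    }
    if (qlearn && tt == 1) {
      if (pure_q) Qv[ai][a] += alpha * dQ2;  // single bridged update
      else Qv[ai][a] += alpha * lambda * dQ2;
    }
    if (mb) {
      tS[s1] += (r == 1) ? alpha_star * (1.0 - tS[s1])
                         : -alpha_star * tS[s1];
      // Replan all action values by backward induction over the episode DAG.
      const double qs1 = tS[0], qs2 = tS[1];
      for (int s = 0; s < 2; s++)
        for (int b = 0; b < 2; b++)
          qstar[s][b] = tA[s][b] * qs1 + (1.0 - tA[s][b]) * qs2;
    }

    if (record) {
      trace(t, 16) = dV1; trace(t, 17) = dV2;
      trace(t, 18) = dQ1; trace(t, 19) = dQ2;
      trace(t, 20) = dS1; trace(t, 21) = dS2;
    }

    // Perseveration: geometric decay per completed visit to this state.
    if (tt == 1) {
      for (int b = 0; b < 2; b++)
        bias[ai][b] = lambda_b * bias[ai][b] + ((b == a) ? beta_0 : 0.0);
    }
  }

  return List::create(
      _["loglik"] = loglik, _["ll"] = ll, _["n_choices"] = n_choices,
      _["action"] = action_out, _["second_state"] = second_out,
      _["reward"] = reward_out, _["trace"] = trace);
}
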