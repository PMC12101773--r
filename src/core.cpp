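#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Model codes shared with R/models.R:
//   1 momentum, 2 prospective, 3 retrospective, 4 td_persistence,
//   5 hybrid, 6 rw_ck
//
// Packed parameter layout (see pack_params() in R/models.R):
//   0 alpha, 1 gamma, 2 cost, 3 beta_g, 4 beta_a, 5 alpha_ck,
//   6 w, 7 reward, 8 beta, 9 beta_ck, 10 horizon

static const double LIK_FLOOR = 1e-12;

// Discounted rollout value of a goal with `togo` tokens still needed,
// belief M of gaining one token per round, finite horizon.
// f_h(0) = reward; f_0(r>0) = 0; f_h(r) = g*(M*f_{h-1}(r-1) + (1-M)*f_{h-1}(r)).
static double prosp_q(double M, double gamma, int togo, int horizon,
                      double reward) {
  if (togo <= 0) return reward;
  if (horizon <= 0) return 0.0;
  std::vector<double> f(togo + 1, 0.0), g(togo + 1, 0.0);
  f[0] = reward;
  for (int h = 1; h <= horizon; ++h) {
    g[0] = reward;
    for (int r = 1; r <= togo; ++r)
      g[r] = gamma * (M * f[r - 1] + (1.0 - M) * f[r]);
    f.swap(g);
  }
  return f[togo];
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// softmax over two values at temperature beta
static inline void softmax2(double beta, double q1, double q2, double* p) {
  double a = beta * q1, b = beta * q2, m = a > b ? a : b;
  double e1 = std::exp(a - m), e2 = std::exp(b - m);
  p[0] = e1 / (e1 + e2);
  p[1] = e2 / (e1 + e2);
}

static inline void softmax3(const double* x, double* p) {
  double m = x[0];
  if (x[1] > m) m = x[1];
  if (x[2] > m) m = x[2];
  double s = 0.0;
  for (int i = 0; i < 3; ++i) { p[i] = std::exp(x[i] - m); s += p[i]; }
  for (int i = 0; i < 3; ++i) p[i] /= s;
}

struct AgentState {
  double M[3];    // token-outcome beliefs
  double v[3];    // momentum speed
  double b[3];    // momentum bias
  double rwq[3];  // Rescorla-Wagner values
  double ck[3];   // choice kernels
  int s[3];       // slot counts
};

static void init_state(AgentState& st) {
  for (int g = 0; g < 3; ++g) {
    st.M[g] = 1.0 / 3.0;
    st.v[g] = 0.5;
    st.b[g] = 0.1;
    st.rwq[g] = 0.0;
    st.ck[g] = 0.0;
    st.s[g] = 0;
  }
}

// cache of per-suit rollout values: valid while (M, s) are unchanged,
// which holds for every suit except the one acted on last round
struct RolloutCache {
  double M[3];
  int s[3];
  double q[3];
  bool valid[3];
  RolloutCache() { valid[0] = valid[1] = valid[2] = false; }
};

static inline double cached_prosp(RolloutCache& cache, int g, double M,
                                  double gamma, int s, int T, int horizon,
                                  double reward) {
  if (cache.valid[g] && cache.M[g] == M && cache.s[g] == s)
    return cache.q[g];
  double q = prosp_q(M, gamma, T - s, horizon, reward);
  cache.M[g] = M;
  cache.s[g] = s;
  cache.q[g] = q;
  cache.valid[g] = true;
  return q;
}

static void model_values(int model, const double* par, const AgentState& st,
                         const int* T, double* Q, RolloutCache& cache) {
  double gamma = par[1], w = par[6], reward = par[7];
  int horizon = (int)par[10];
  for (int g = 0; g < 3; ++g) {
    switch (model) {
      case 1: {  // momentum: Q = v*m + b
        double m = (double)st.s[g] / (double)T[g];
        Q[g] = st.v[g] * m + st.b[g];
        break;
      }
      case 2:
        Q[g] = cached_prosp(cache, g, st.M[g], gamma, st.s[g], T[g],
                            horizon, reward);
        break;
      case 3:
        Q[g] = std::pow(gamma, (double)(T[g] - st.s[g])) * reward;
        break;
      case 4:
        Q[g] = st.M[g];
        break;
      case 5: {
        double qp = cached_prosp(cache, g, st.M[g], gamma, st.s[g], T[g],
                                 horizon, reward);
        double qr = std::pow(gamma, (double)(T[g] - st.s[g])) * reward;
        Q[g] = w * qp + (1.0 - w) * qr;
        break;
      }
      case 6:
        Q[g] = st.rwq[g];
        break;
      default:
        stop("unknown model code");
    }
  }
}

// advantage of goal g over the best alternative
static inline double advantage_of(const double* Q, int g) {
  double best = -1e300;
  for (int j = 0; j < 3; ++j)
    if (j != g && Q[j] > best) best = Q[j];
  return Q[g] - best;
}

// Stay/switch row of the goal transition matrix for previous goal G:
// row[G] = p_stay, row[alt] = (1 - p_stay) * softmax_{beta}(Q_alt1, Q_alt2)
static void stay_switch_row(const double* Q, const double* ck, int G,
                            double cost, double beta, double* row) {
  double A = advantage_of(Q, G);
  double pstay = logistic(cost + ck[G] + beta * A);
  int alt[2], na = 0;
  for (int j = 0; j < 3; ++j)
    if (j != G) alt[na++] = j;
  double ps[2];
  softmax2(beta, Q[alt[0]], Q[alt[1]], ps);
  row[G] = pstay;
  row[alt[0]] = (1.0 - pstay) * ps[0];
  row[alt[1]] = (1.0 - pstay) * ps[1];
}

// value update from the observed (chosen suit, token) pair
static void value_update(int model, const double* par, AgentState& st,
                         int a, int token, const int* T) {
  double alpha = par[0], gamma = par[1];
  switch (model) {
    case 2: case 4: case 5:
      st.M[a] += alpha * ((double)token - st.M[a]);
      break;
    case 1: {
      double m0 = (double)st.s[a] / (double)T[a];
      double m1 = (double)(st.s[a] + token) / (double)T[a];
      double delta = gamma * (st.v[a] * m1 + st.b[a]) -
                     (st.v[a] * m0 + st.b[a]);
      st.v[a] += alpha * delta * m0;
      st.b[a] += alpha * delta;
      break;
    }
    case 6:
      st.rwq[a] += alpha * ((double)token - st.rwq[a]);
      break;
    default:  // retrospective learns nothing
      break;
  }
}

static void advance_slots(AgentState& st, int a, int token, const int* T,
                          int* completed) {
  *completed = 0;
  if (token) {
    st.s[a] += 1;
    if (st.s[a] >= T[a]) {
      st.s[a] = 0;
      *completed = 1;
    }
  }
}

static int sample_index(const double* p, int n) {
  double u = R::runif(0.0, 1.0), c = 0.0;
  for (int i = 0; i < n; ++i) {
    c += p[i];
    if (u <= c) return i;
  }
  return n - 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate(NumericMatrix probs, IntegerVector targets,
                           int probe_every, int model, NumericVector par) {
  int n = probs.nrow();
  int T[3] = {targets[0], targets[1], targets[2]};
  const double* pp = par.begin();
  double cost = pp[2], beta_g = pp[3], beta_a = pp[4], alpha_ck = pp[5];
  double beta = pp[8], beta_ck = pp[9];

  AgentState st;
  init_state(st);
  RolloutCache cache;
  int goal = -1;

  // columns: card1..card3, chosen, token, s1b..s3b, s1a..s3a, completed,
  //          goal, probe
  NumericMatrix out(n, 14);
  double Q[3], row[3], ps[2];

  for (int t = 0; t < n; ++t) {
    // one of the suit's two cards offered, uniformly
    for (int g = 0; g < 3; ++g)
      out(t, g) = (R::runif(0.0, 1.0) < 0.5) ? 1 : 2;

    model_values(model, pp, st, T, Q, cache);

    int action;
    if (model == 6) {
      // flat softmax over beta*Q + beta_ck*ck; goal == action
      double x[3], pr[3];
      for (int g = 0; g < 3; ++g) x[g] = beta * st.rwq[g] + beta_ck * st.ck[g];
      softmax3(x, pr);
      action = sample_index(pr, 3);
      goal = action;
      for (int g = 0; g < 3; ++g)
        st.ck[g] += alpha_ck * ((g == action ? 1.0 : 0.0) - st.ck[g]);
    } else {
      // hierarchical: goal stay/switch, then action stay/explore
      if (goal < 0) {
        double x[3], pr[3];
        for (int g = 0; g < 3; ++g) x[g] = beta_g * Q[g];
        softmax3(x, pr);
        goal = sample_index(pr, 3);
      } else {
        stay_switch_row(Q, st.ck, goal, cost, beta_g, row);
        goal = sample_index(row, 3);
      }
      // kernel update with the realized goal, then act with updated kernel
      for (int g = 0; g < 3; ++g)
        st.ck[g] += alpha_ck * ((g == goal ? 1.0 : 0.0) - st.ck[g]);
      double A = advantage_of(Q, goal);
      double pstay = logistic(cost + st.ck[goal] + beta_a * A);
      if (R::runif(0.0, 1.0) <= pstay) {
        action = goal;
      } else {
        int alt[2], na = 0;
        for (int j = 0; j < 3; ++j)
          if (j != goal) alt[na++] = j;
        softmax2(beta_a, Q[alt[0]], Q[alt[1]], ps);
        action = (R::runif(0.0, 1.0) <= ps[0]) ? alt[0] : alt[1];
      }
    }

    int token = (R::runif(0.0, 1.0) < probs(t, action)) ? 1 : 0;

    out(t, 3) = action + 1;
    out(t, 4) = token;
    for (int g = 0; g < 3; ++g) out(t, 5 + g) = st.s[g];

    // learn from the outcome before slots advance (momentum needs m_before)
    value_update(model, pp, st, action, token, T);
    int completed;
    advance_slots(st, action, token, T, &completed);

    for (int g = 0; g < 3; ++g) out(t, 8 + g) = st.s[g];
    out(t, 11) = completed;
    out(t, 12) = goal + 1;
    out(t, 13) = ((t + 1) % probe_every == 0) ? 1 : 0;
  }
  return out;
}

// Latent-goal likelihood forward pass.
// actions: 1..3 per round; tokens: 0/1; probes: 0 absent, -1 undecided,
// 1..3 reported suit. Returns per-round action and goal negative
// log-likelihood contributions (goal term nonzero only on probe rounds).
// [[Rcpp::export]]
List cpp_nll(IntegerVector actions, IntegerVector tokens,
             IntegerVector probes, IntegerVector targets, int model,
             NumericVector par, bool bayes_filter = false) {
  int n = actions.size();
  int T[3] = {targets[0], targets[1], targets[2]};
  const double* pp = par.begin();
  double cost = pp[2], beta_g = pp[3], beta_a = pp[4], alpha_ck = pp[5];
  double beta = pp[8], beta_ck = pp[9];

  AgentState st;
  init_state(st);
  RolloutCache cache;
  double bel[3] = {0.0, 0.0, 0.0};
  bool started = false;

  NumericVector nll_a(n), nll_g(n);
  double Q[3], row[3], newbel[3], ps[2];

  for (int t = 0; t < n; ++t) {
    int a = actions[t] - 1;
    int token = tokens[t];
    if (a < 0 || a > 2) stop("actions must be in 1..3");

    model_values(model, pp, st, T, Q, cache);

    if (model == 6) {
      double x[3], pr[3];
      for (int g = 0; g < 3; ++g) x[g] = beta * st.rwq[g] + beta_ck * st.ck[g];
      softmax3(x, pr);
      double pa = pr[a];
      nll_a[t] = -std::log(pa > LIK_FLOOR ? pa : LIK_FLOOR);
      for (int g = 0; g < 3; ++g)
        st.ck[g] += alpha_ck * ((g == a ? 1.0 : 0.0) - st.ck[g]);
    } else {
      // propagate the latent-goal belief through the stay/switch chain
      if (!started) {
        double x[3];
        for (int g = 0; g < 3; ++g) x[g] = beta_g * Q[g];
        softmax3(x, newbel);
        started = true;
      } else {
        for (int g = 0; g < 3; ++g) newbel[g] = 0.0;
        for (int G = 0; G < 3; ++G) {
          if (bel[G] <= 0.0) continue;
          stay_switch_row(Q, st.ck, G, cost, beta_g, row);
          for (int g = 0; g < 3; ++g) newbel[g] += bel[G] * row[g];
        }
        double s = newbel[0] + newbel[1] + newbel[2];
        for (int g = 0; g < 3; ++g) newbel[g] /= s;
      }

      // probe round: score the propagated belief, then collapse
      if (probes[t] > 0) {
        int pg = probes[t] - 1;
        double p = newbel[pg];
        nll_g[t] = -std::log(p > LIK_FLOOR ? p : LIK_FLOOR);
        for (int g = 0; g < 3; ++g) newbel[g] = (g == pg) ? 1.0 : 0.0;
      }

      // expected kernel update (hard indicator once the belief is collapsed)
      for (int g = 0; g < 3; ++g)
        st.ck[g] += alpha_ck * (newbel[g] - st.ck[g]);

      // marginal probability of the observed card choice
      double pa = 0.0, pa_g[3];
      for (int G = 0; G < 3; ++G) {
        double A = advantage_of(Q, G);
        double pstay = logistic(cost + st.ck[G] + beta_a * A);
        double pcond;
        if (a == G) {
          pcond = pstay;
        } else {
          int alt[2], na = 0;
          for (int j = 0; j < 3; ++j)
            if (j != G) alt[na++] = j;
          softmax2(beta_a, Q[alt[0]], Q[alt[1]], ps);
          pcond = (1.0 - pstay) * (a == alt[0] ? ps[0] : ps[1]);
        }
        pa_g[G] = pcond;
        pa += newbel[G] * pcond;
      }
      nll_a[t] = -std::log(pa > LIK_FLOOR ? pa : LIK_FLOOR);

      if (bayes_filter) {
        double s = 0.0;
        for (int g = 0; g < 3; ++g) {
          newbel[g] *= pa_g[g];
          s += newbel[g];
        }
        if (s > 0)
          for (int g = 0; g < 3; ++g) newbel[g] /= s;
      }
      for (int g = 0; g < 3; ++g) bel[g] = newbel[g];
    }

    if (ISNAN(nll_a[t]) || ISNAN(nll_g[t]))
      stop("NaN likelihood term at round %d", t + 1);

    value_update(model, pp, st, a, token, T);
    int completed;
    advance_slots(st, a, token, T, &completed);
  }
  return List::create(_["nll_action"] = nll_a, _["nll_goal"] = nll_g);
}

// [[Rcpp::export]]
double cpp_prospective_value(double M, double gamma, int s, int T,
                             int horizon, double reward) {
  if (s > T) stop("s must not exceed the target");
  return prosp_q(M, gamma, T - s, horizon, reward);
}
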