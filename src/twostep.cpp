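#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Wiener first-passage-time density
//
// Density of hitting the *lower* boundary of a Wiener process with drift v,
// boundary separation a, relative start w = z/a, diffusion sigma = 1, at
// decision time t (non-decision time already subtracted).  Series follow the
// classic small-time / large-time expansions with automatic switching; the
// truncation error target is `err` on the normalised-time density.
// ---------------------------------------------------------------------------

static const double LOG_FLOOR = -690.7755278982137; // log(1e-300)

// density in normalised time tt = t / a^2, zero drift, unit boundary
static double ftt01w(double tt, double w, double err) {
  double kl, ks;
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * err));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  double p = 0.0;
  if (ks < kl) { // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; k++) {
      double q = w + 2.0 * k;
      p += q * std::exp(-q * q / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {       // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p;
}

// log density at the chosen boundary; upper obtained by (v, w) -> (-v, 1 - w)
static double wiener_lpdf_one(double t, bool upper, double v, double a,
                              double w, double err) {
  if (!(t > 0.0) || !(a > 0.0)) return LOG_FLOOR;
  double vv = upper ? -v : v;
  double ww = upper ? 1.0 - w : w;
  double p = ftt01w(t / (a * a), ww, err);
  if (!(p > 1e-300)) return LOG_FLOOR;
  double lp = std::log(p) - 2.0 * std::log(a) - vv * a * ww - vv * vv * t / 2.0;
  return (lp < LOG_FLOOR) ? LOG_FLOOR : lp;
}

// [[Rcpp::export]]
NumericVector wiener_lpdf_cpp(NumericVector rt, LogicalVector upper,
                              NumericVector drift, NumericVector boundary,
                              NumericVector ndt, double tol) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double v = drift[drift.size() == 1 ? 0 : i];
    double a = boundary[boundary.size() == 1 ? 0 : i];
    double t0 = ndt[ndt.size() == 1 ? 0 : i];
    out[i] = wiener_lpdf_one(rt[i] - t0, upper[i], v, a, 0.5, tol);
  }
  return out;
}

// Euler-Maruyama first-passage sampler (unbiased start z = a/2, sigma = 1).
// Returns decision times; rt = decision time + ndt; paths not absorbed by
// tmax are flagged missed.  Uses R's RNG so results are seed-reproducible.
// [[Rcpp::export]]
DataFrame wiener_fpt_sim_cpp(int n, double drift, double boundary, double ndt,
                             double dt, double tmax) {
  NumericVector rt(n);
  LogicalVector up(n), missed(n);
  double sdt = std::sqrt(dt);
  int max_steps = (int)std::ceil((tmax - ndt) / dt);
  for (int i = 0; i < n; i++) {
    double x = boundary / 2.0;
    int step = 0;
    bool hit = false, hit_up = false;
    while (step < max_steps) {
      x += drift * dt + sdt * norm_rand();
      step++;
      if (x >= boundary) { hit = true; hit_up = true; break; }
      if (x <= 0.0)      { hit = true; hit_up = false; break; }
    }
    rt[i] = hit ? step * dt + ndt : NA_REAL;
    up[i] = hit ? hit_up : NA_LOGICAL;
    missed[i] = !hit;
  }
  return DataFrame::create(_["choice_upper"] = up, _["rt"] = rt,
                           _["missed"] = missed);
}

// ---------------------------------------------------------------------------
// Hybrid learner + session likelihood
//
// Parameter vector layout (14, one participant):
//  0 beta_mb_self  1 beta_mf_self  2 diff_mb (Other-Self)  3 diff_mf
//  4 alpha_self    5 alpha_other   6 pi_self   7 pi_other
//  8 rho_self      9 rho_other    10 bound_self 11 bound_other
// 12 ndt_self     13 ndt_other
// Condition code: 0 = self, 1 = other.
// Action 0 maps to the upper boundary (stable stimulus coding).
// ---------------------------------------------------------------------------

struct Cond {
  double bmb, bmf, alpha, pi, rho, bound, ndt;
};

static void expand_par(const double *p, Cond cond[2]) {
  cond[0].bmb = p[0];        cond[1].bmb = p[0] + p[2];
  cond[0].bmf = p[1];        cond[1].bmf = p[1] + p[3];
  cond[0].alpha = p[4];      cond[1].alpha = p[5];
  cond[0].pi = p[6];         cond[1].pi = p[7];
  cond[0].rho = p[8];        cond[1].rho = p[9];
  cond[0].bound = p[10];     cond[1].bound = p[11];
  cond[0].ndt = p[12];       cond[1].ndt = p[13];
}

struct Learner {
  double q1[2][2]; // first-stage model-free values [state][action]
  double q2[2];    // second-stage values (one action per planet)
  void reset() {
    q1[0][0] = q1[0][1] = q1[1][0] = q1[1][1] = 4.5;
    q2[0] = q2[1] = 4.5;
  }
};

// net drift v(action 0) - v(action 1) for current state s1
static double net_drift(const Learner &L, const Cond &c, const int dest[2][2],
                        int s1, int prev_state, int prev_action, int prev_key,
                        int key_a0) {
  double v[2];
  for (int a = 0; a < 2; a++) {
    double qmb = L.q2[dest[s1][a]];
    double ch = (prev_action >= 0 && prev_state == s1 && a == prev_action) ? 1.0 : 0.0;
    int key_a = (a == 0) ? key_a0 : 1 - key_a0;
    double resp = (prev_key >= 0 && key_a == prev_key) ? 1.0 : 0.0;
    v[a] = c.bmb * qmb + c.bmf * L.q1[s1][a] + c.pi * ch + c.rho * resp;
  }
  return v[0] - v[1];
}

static void mf_step(Learner &L, const Cond &c, int s1, int a1, int s2,
                    double r, double lambda) {
  double d1 = L.q2[s2] - L.q1[s1][a1];
  double d2 = r - L.q2[s2];
  L.q1[s1][a1] += c.alpha * d1 + c.alpha * lambda * d2;
  L.q2[s2] += c.alpha * d2;
}

// Summed log-likelihood of a session for each row of `par` (k x 14 matrix).
// data: integer vectors block, cond, s1, a1, key, s2, valid, learn (all
// 0-based, -1 for absent), numeric rt (s) and reward, integer matrix dest.
// [[Rcpp::export]]
NumericVector session_loglik_cpp(NumericMatrix par, List data, double tol,
                                 bool reset_per_block, double lambda) {
  IntegerVector block = data["block"], condv = data["cond"], s1v = data["s1"],
                a1v = data["a1"], keyv = data["key"], s2v = data["s2"],
                validv = data["valid"], learnv = data["learn"];
  NumericVector rtv = data["rt"], rewv = data["reward"];
  IntegerMatrix destm = data["dest"];
  int dest[2][2] = {{destm(0, 0), destm(0, 1)}, {destm(1, 0), destm(1, 1)}};
  int n = block.size(), K = par.nrow();
  NumericVector out(K);

  for (int k = 0; k < K; k++) {
    double p[14];
    for (int j = 0; j < 14; j++) p[j] = par(k, j);
    Cond cond[2];
    expand_par(p, cond);
    Learner L;
    L.reset();
    int prev_state = -1, prev_action = -1, prev_key = -1, cur_block = -1;
    double ll = 0.0;
    for (int t = 0; t < n; t++) {
      if (block[t] != cur_block) {
        cur_block = block[t];
        if (reset_per_block) L.reset();
        prev_state = prev_action = prev_key = -1;
      }
      int a1 = a1v[t];
      if (a1 < 0) { // no first-stage response
        prev_state = prev_action = prev_key = -1;
        continue;
      }
      const Cond &c = cond[condv[t]];
      int s1 = s1v[t];
      int key_a0 = (a1 == 0) ? keyv[t] : 1 - keyv[t];
      double v = net_drift(L, c, dest, s1, prev_state, prev_action, prev_key,
                           key_a0);
      if (validv[t]) {
        ll += wiener_lpdf_one(rtv[t] - c.ndt, a1 == 0, v, c.bound, 0.5, tol);
      }
      if (learnv[t]) mf_step(L, c, s1, a1, s2v[t], rewv[t], lambda);
      prev_state = s1;
      prev_action = a1;
      prev_key = keyv[t];
    }
    out[k] = ll;
  }
  return out;
}

// Forward-simulate one session from a 14-parameter vector on a scaffold.
// scaffold: integer vectors block, cond, s1, action_left; numeric pay0, pay1.
// [[Rcpp::export]]
List simulate_session_cpp(NumericVector par, List scaffold, double dt,
                          double rt_limit, double fast_cutoff,
                          double keypress_p, double miss_rate, double lambda,
                          bool reset_per_block, IntegerMatrix destm) {
  IntegerVector block = scaffold["block"], condv = scaffold["cond"],
                s1v = scaffold["s1"], aleft = scaffold["action_left"];
  NumericVector pay0 = scaffold["pay0"], pay1 = scaffold["pay1"];
  int dest[2][2] = {{destm(0, 0), destm(0, 1)}, {destm(1, 0), destm(1, 1)}};
  int n = block.size();
  double p[14];
  for (int j = 0; j < 14; j++) p[j] = par[j];
  Cond cond[2];
  expand_par(p, cond);
  Learner L;
  L.reset();
  int prev_state = -1, prev_action = -1, prev_key = -1, cur_block = -1;

  IntegerVector a1(n), key(n), s2(n);
  NumericVector rt(n), reward(n), vnet(n);
  LogicalVector keypress(n), valid(n);
  double sdt = std::sqrt(dt);

  for (int t = 0; t < n; t++) {
    if (block[t] != cur_block) {
      cur_block = block[t];
      if (reset_per_block) L.reset();
      prev_state = prev_action = prev_key = -1;
    }
    const Cond &c = cond[condv[t]];
    int s1 = s1v[t];
    // key identity of action 0 on this trial (0 = left, 1 = right)
    int key_a0 = (aleft[t] == 0) ? 0 : 1;
    double v = net_drift(L, c, dest, s1, prev_state, prev_action, prev_key,
                         key_a0);
    vnet[t] = v;

    bool lapse = (miss_rate > 0.0) && (unif_rand() < miss_rate);
    bool hit = false, hit_up = false;
    int step = 0;
    if (!lapse) {
      int max_steps = (int)std::ceil((rt_limit - c.ndt) / dt);
      double x = c.bound / 2.0;
      while (step < max_steps) {
        x += v * dt + sdt * norm_rand();
        step++;
        if (x >= c.bound) { hit = true; hit_up = true; break; }
        if (x <= 0.0)     { hit = true; hit_up = false; break; }
      }
    }
    if (!hit) { // missed trial: no response, zero outcome
      a1[t] = NA_INTEGER; key[t] = NA_INTEGER; s2[t] = NA_INTEGER;
      rt[t] = NA_REAL; reward[t] = 0.0;
      keypress[t] = false; valid[t] = false;
      prev_state = prev_action = prev_key = -1;
      continue;
    }
    int act = hit_up ? 0 : 1;
    double rts = step * dt + c.ndt;
    int s2t = dest[s1][act];
    bool kp = unif_rand() < keypress_p;
    double r = kp ? (s2t == 0 ? pay0[t] : pay1[t]) : 0.0;
    a1[t] = act;
    key[t] = (act == 0) ? key_a0 : 1 - key_a0;
    s2[t] = s2t;
    rt[t] = rts;
    reward[t] = r;
    keypress[t] = kp;
    valid[t] = rts >= fast_cutoff;
    if (kp) mf_step(L, c, s1, act, s2t, r, lambda);
    prev_state = s1;
    prev_action = act;
    prev_key = key[t];
  }
  return List::create(_["a1"] = a1, _["key"] = key, _["rt"] = rt,
                      _["s2"] = s2, _["keypress"] = keypress,
                      _["reward"] = reward, _["valid"] = valid,
                      _["vnet"] = vnet);
}
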