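// Core kernels: Gill-Johansen empirical sampling over Nelson-Aalen
// increments, the nested bootstrap loop, and the product integral.
// All randomness goes through R's RNG (unif_rand), so set.seed() in R
// governs every draw.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

// Per-state sampling plan: grid positions where the state has positive
// all-cause increment, the times at those positions, cumulative
// log-survival logS[k] = sum_{j<=k} log(1 - dA_l.(u_j)) (-inf once an
// increment hits 1), and per-position destination tables.
struct StatePlan {
  std::vector<int> gidx;        // global grid index per position
  std::vector<double> t;        // grid time per position
  std::vector<double> logS;     // cumulative log-survival
  std::vector<int> doff;        // destination offsets, size npos+1
  std::vector<int> dstate;      // destination state (0-based)
  std::vector<double> dcum;     // cumulative destination probabilities
};

struct Plan {
  int K;
  std::vector<double> grid;     // global sorted event times
  std::vector<bool> absorbing;
  std::vector<StatePlan> st;    // length K (empty for absorbing states)
};

Plan build_plan(const List& plan) {
  Plan p;
  p.K = as<int>(plan["K"]);
  p.grid = as<std::vector<double>>(plan["grid"]);
  LogicalVector ab = plan["absorbing"];
  p.absorbing.assign(ab.begin(), ab.end());
  List st = plan["states"];
  p.st.resize(p.K);
  for (int l = 0; l < p.K; ++l) {
    if (Rf_isNull(st[l])) continue;
    List sl = st[l];
    p.st[l].gidx  = as<std::vector<int>>(sl["gidx"]);
    p.st[l].t     = as<std::vector<double>>(sl["t"]);
    p.st[l].logS  = as<std::vector<double>>(sl["logS"]);
    p.st[l].doff  = as<std::vector<int>>(sl["doff"]);
    p.st[l].dstate= as<std::vector<int>>(sl["dstate"]);
    p.st[l].dcum  = as<std::vector<double>>(sl["dcum"]);
  }
  return p;
}

// One sojourn draw out of state l entered at time t_cur.
// Returns position k in the state plan of the event, or -1 for the
// residual atom (mass beyond the largest observed time).
inline int draw_event_pos(const StatePlan& sp, double t_cur) {
  const size_t n = sp.t.size();
  if (n == 0) return -1;
  // first position with time strictly greater than t_cur
  size_t k0 = std::upper_bound(sp.t.begin(), sp.t.end(), t_cur) - sp.t.begin();
  if (k0 >= n) return -1;
  double base = (k0 == 0) ? 0.0 : sp.logS[k0 - 1];
  double u = unif_rand();
  double target = std::log(u) + base;  // event at first k with logS[k] <= target
  if (sp.logS[n - 1] > target) return -1;
  size_t lo = k0, hi = n - 1;
  while (lo < hi) {
    size_t mid = (lo + hi) / 2;
    if (sp.logS[mid] <= target) hi = mid; else lo = mid + 1;
  }
  return static_cast<int>(lo);
}

inline int draw_destination(const StatePlan& sp, int k) {
  double u = unif_rand();
  int a = sp.doff[k], b = sp.doff[k + 1];
  for (int i = a; i < b; ++i) {
    if (u <= sp.dcum[i]) return sp.dstate[i];
  }
  return sp.dstate[b - 1];
}

} // namespace

// Simulate n multistate trajectories from an increment-table plan.
// init: 0-based initial state per subject; cens: censoring time per
// subject (R_PosInf = none).  Returns long-format records.
// [[Rcpp::export]]
List cpp_sim_empirical(List plan_in, IntegerVector init, NumericVector cens) {
  Plan plan = build_plan(plan_in);
  const int n = init.size();
  const double tmax = plan.grid.empty() ? 0.0 : plan.grid.back();
  std::vector<int> rid, rfrom, rto, rstatus;
  std::vector<double> rentry, rexit;
  rid.reserve(3 * n);

  for (int i = 0; i < n; ++i) {
    int s = init[i];
    double t_cur = 0.0;
    double C = cens[i];
    while (!plan.absorbing[s]) {
      int k = draw_event_pos(plan.st[s], t_cur);
      if (k < 0) {  // residual mass: censor at the largest observed time
        double tc = std::min(tmax, C);
        if (tc > t_cur) {
          rid.push_back(i + 1); rfrom.push_back(s); rto.push_back(NA_INTEGER);
          rentry.push_back(t_cur); rexit.push_back(tc); rstatus.push_back(0);
        }
        break;
      }
      double t_ev = plan.st[s].t[k];
      if (t_ev > C) {  // superimposed censoring strikes first
        if (C > t_cur) {
          rid.push_back(i + 1); rfrom.push_back(s); rto.push_back(NA_INTEGER);
          rentry.push_back(t_cur); rexit.push_back(C); rstatus.push_back(0);
        }
        break;
      }
      int m = draw_destination(plan.st[s], k);
      rid.push_back(i + 1); rfrom.push_back(s); rto.push_back(m);
      rentry.push_back(t_cur); rexit.push_back(t_ev); rstatus.push_back(1);
      t_cur = t_ev;
      s = m;
    }
  }
  return List::create(
    _["id"] = wrap(rid), _["from"] = wrap(rfrom), _["to"] = wrap(rto),
    _["entry"] = wrap(rentry), _["exit"] = wrap(rexit),
    _["status"] = wrap(rstatus));
}

namespace {

// Multiply running row-major K x K matrix P by (I + dA) where dA has the
// given off-diagonal entries and zero row sums.
inline void multiply_factor(std::vector<double>& P, int K,
                            const std::vector<int>& from,
                            const std::vector<int>& to,
                            const std::vector<double>& inc,
                            std::vector<double>& scratch) {
  std::fill(scratch.begin(), scratch.end(), 0.0);
  // F = I + dA
  for (int r = 0; r < K; ++r) scratch[r * K + r] = 1.0;
  for (size_t e = 0; e < from.size(); ++e) {
    scratch[from[e] * K + to[e]] += inc[e];
    scratch[from[e] * K + from[e]] -= inc[e];
  }
  std::vector<double> out(K * K, 0.0);
  for (int r = 0; r < K; ++r)
    for (int c2 = 0; c2 < K; ++c2) {
      double acc = 0.0;
      for (int q = 0; q < K; ++q) acc += P[r * K + q] * scratch[q * K + c2];
      out[r * K + c2] = acc;
    }
  P.swap(out);
}

} // namespace

// Product integral prod_{s < u <= t}(I + dA(u)) over sorted table rows.
// Rows must be sorted by time; eval_times sorted ascending.
// Returns K*K*T vector, column-major over (row, col, time) with row-major
// unrolled manually: element (r, c, ti) at r + c*K + ti*K*K (R array order).
// [[Rcpp::export]]
NumericVector cpp_prod_integral(NumericVector time, IntegerVector from,
                                IntegerVector to, NumericVector inc,
                                double s, NumericVector eval_times, int K) {
  const int R = time.size(), T = eval_times.size();
  NumericVector out(K * K * T);
  std::vector<double> P(K * K, 0.0), scratch(K * K);
  for (int r = 0; r < K; ++r) P[r * K + r] = 1.0;
  int i = 0;
  // skip factors with u <= s
  while (i < R && time[i] <= s) ++i;
  std::vector<int> f, t2; std::vector<double> d;
  for (int ti = 0; ti < T; ++ti) {
    double tt = eval_times[ti];
    while (i < R && time[i] <= tt) {
      double u = time[i];
      f.clear(); t2.clear(); d.clear();
      std::vector<double> rowsum(K, 0.0);
      while (i < R && time[i] == u) {
        f.push_back(from[i]); t2.push_back(to[i]); d.push_back(inc[i]);
        rowsum[from[i]] += inc[i];
        ++i;
      }
      for (int r = 0; r < K; ++r)
        if (rowsum[r] > 1.0 + 1e-12)
          stop("all-cause increment exceeds 1 at time %f", u);
      multiply_factor(P, K, f, t2, d, scratch);
    }
    for (int r = 0; r < K; ++r)
      for (int c2 = 0; c2 < K; ++c2)
        out[r + c2 * K + ti * K * K] = P[r * K + c2];
  }
  return out;
}

// Nested empirical bootstrap: B replicates of n subjects simulated from the
// plan, each re-estimated (Nelson-Aalen on the replicate, product integral,
// occupation with the replicate's own empirical initial proportions).
// cens_kind: 0 none, 1 uniform(a,b), 2 administrative(tau), 3 discrete
// atoms (cens_t, cens_p with residual mass = never censored).
// Returns occ: B x K x T array, trans: B x K x K x T array, both R-ordered.
// [[Rcpp::export]]
List cpp_empirical_boot(List plan_in, int n, int B, NumericVector init_probs,
                        int cens_kind, NumericVector cens_par,
                        NumericVector cens_t, NumericVector cens_p,
                        NumericVector eval_times) {
  Plan plan = build_plan(plan_in);
  const int K = plan.K, T = eval_times.size();
  const int J = plan.grid.size();
  const double tmax = J ? plan.grid.back() : 0.0;
  NumericVector occ(B * K * T), trans(B * K * K * T);

  std::vector<double> icum(K, 0.0);
  double acc = 0.0;
  for (int l = 0; l < K; ++l) { acc += init_probs[l]; icum[l] = acc; }

  std::vector<double> ccum;
  if (cens_kind == 3) {
    ccum.resize(cens_p.size());
    double a2 = 0.0;
    for (int i = 0; i < cens_p.size(); ++i) { a2 += cens_p[i]; ccum[i] = a2; }
  }

  // per-replicate tallies on the source grid
  std::vector<int> Nlm(static_cast<size_t>(J) * K * K);
  std::vector<int> diff(static_cast<size_t>(J + 1) * K);
  std::vector<int> icount(K);
  std::vector<double> P(K * K), scratch(K * K);
  std::vector<int> f, t2; std::vector<double> d;

  for (int b = 0; b < B; ++b) {
    std::fill(Nlm.begin(), Nlm.end(), 0);
    std::fill(diff.begin(), diff.end(), 0);
    std::fill(icount.begin(), icount.end(), 0);

    for (int i = 0; i < n; ++i) {
      double u0 = unif_rand();
      int s = 0;
      while (s < K - 1 && u0 > icum[s]) ++s;
      icount[s]++;
      double C = R_PosInf;
      if (cens_kind == 1) C = cens_par[0] + unif_rand() * (cens_par[1] - cens_par[0]);
      else if (cens_kind == 2) C = cens_par[0];
      else if (cens_kind == 3) {
        double uc = unif_rand();
        size_t ci = std::lower_bound(ccum.begin(), ccum.end(), uc) - ccum.begin();
        C = (ci < ccum.size()) ? cens_t[ci] : R_PosInf;
      }
      double t_cur = 0.0;
      int j_cur = -1;  // grid index of current arrival (-1: time origin)
      while (!plan.absorbing[s]) {
        int k = draw_event_pos(plan.st[s], t_cur);
        double t_end; int j_end;
        bool event = false; int m = -1, jg = -1;
        if (k < 0) {
          t_end = std::min(tmax, C);
        } else {
          double t_ev = plan.st[s].t[k];
          if (t_ev > C) { t_end = C; }
          else { event = true; jg = plan.st[s].gidx[k]; t_end = t_ev; }
        }
        if (!event && t_end <= t_cur) break;
        // risk interval: at risk at grid u iff t_cur < u <= t_end
        int j_start = j_cur + 1;
        if (event) j_end = jg;
        else j_end = static_cast<int>(std::upper_bound(plan.grid.begin(),
                        plan.grid.end(), t_end) - plan.grid.begin()) - 1;
        if (j_end >= j_start) {
          diff[static_cast<size_t>(s) * (J + 1) + j_start]++;
          diff[static_cast<size_t>(s) * (J + 1) + j_end + 1]--;
        }
        if (!event) break;
        m = draw_destination(plan.st[s], k);
        Nlm[(static_cast<size_t>(jg) * K + s) * K + m]++;
        t_cur = t_end; j_cur = jg; s = m;
      }
    }

    // replicate Nelson-Aalen -> product integral -> occupation
    std::fill(P.begin(), P.end(), 0.0);
    for (int r = 0; r < K; ++r) P[r * K + r] = 1.0;
    std::vector<double> Y(K, 0.0);
    std::vector<double> run(K, 0.0);
    int ti = 0;
    for (int j = 0; j <= J; ++j) {
      double tj = (j < J) ? plan.grid[j] : R_PosInf;
      while (ti < T && eval_times[ti] < tj) {
        for (int r = 0; r < K; ++r) {
          double o = 0.0;
          for (int l = 0; l < K; ++l) o += icount[l] * P[l * K + r];
          occ[b + r * B + ti * B * K] = o / n;
          for (int c2 = 0; c2 < K; ++c2)
            trans[b + r * B + c2 * B * K + ti * B * K * K] = P[r * K + c2];
        }
        ++ti;
      }
      if (j == J) break;
      for (int l = 0; l < K; ++l)
        run[l] += diff[static_cast<size_t>(l) * (J + 1) + j];
      f.clear(); t2.clear(); d.clear();
      for (int l = 0; l < K; ++l)
        for (int m = 0; m < K; ++m) {
          int cnt = Nlm[(static_cast<size_t>(j) * K + l) * K + m];
          if (cnt > 0) {
            f.push_back(l); t2.push_back(m);
            d.push_back(cnt / run[l]);
          }
        }
      if (!f.empty()) multiply_factor(P, K, f, t2, d, scratch);
    }
  }
  occ.attr("dim") = IntegerVector::create(B, K, T);
  trans.attr("dim") = IntegerVector::create(B, K, K, T);
  return List::create(_["occ"] = occ, _["trans"] = trans);
}
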