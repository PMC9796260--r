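#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double logistic_s(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Falling-factorial products of the two exclusive Step-2 outcomes.
// pA: all learner draws green, all item draws red; pB: the reverse.
// Any non-positive factor marks the branch impossible (probability 0).
static inline void branch_products(const int* rstar, int rstar_j,
                                   const int* nl, int ni,
                                   const int* w, int M, int W,
                                   double& pA, double& pB) {
  pA = 1.0; pB = 1.0;
  for (int m = 0; m < M; m++) {
    int wm = w[m];
    if (!wm) continue;
    for (int v = 0; v < wm; v++) {
      double a = (double)rstar[m] - v;            if (a < 0) a = 0;
      double b = (double)nl[m] + wm - rstar[m] - v; if (b < 0) b = 0;
      pA *= a; pB *= b;
    }
  }
  for (int v = 0; v < W; v++) {
    double a = (double)ni + W - rstar_j - v; if (a < 0) a = 0;
    double b = (double)rstar_j - v;          if (b < 0) b = 0;
    pA *= a; pB *= b;
  }
}

// [[Rcpp::export]]
double cpp_green_prob(IntegerVector r_star, int r_star_j,
                      IntegerVector n_learner, int n_item, IntegerVector w) {
  int M = w.size(), W = 0;
  for (int m = 0; m < M; m++) W += w[m];
  double pA, pB;
  branch_products(r_star.begin(), r_star_j, n_learner.begin(), n_item,
                  w.begin(), M, W, pA, pB);
  if (pA == 0 && pB == 0) stop("degenerate configuration: both Step-2 outcomes impossible");
  return pA / (pA + pB);
}

// Batch evaluation over rows of configuration matrices; NA_real_ where both
// branches are impossible.
// [[Rcpp::export]]
NumericVector cpp_green_prob_batch(IntegerMatrix r_star, IntegerVector r_star_j,
                                   IntegerMatrix n_learner, IntegerVector n_item,
                                   IntegerMatrix w) {
  int K = r_star.nrow(), M = r_star.ncol();
  NumericVector out(K);
  std::vector<int> rs(M), nl(M), wv(M);
  for (int k = 0; k < K; k++) {
    int W = 0;
    for (int m = 0; m < M; m++) {
      rs[m] = r_star(k, m); nl[m] = n_learner(k, m); wv[m] = w(k, m); W += wv[m];
    }
    double pA, pB;
    branch_products(rs.data(), r_star_j[k], nl.data(), n_item[k],
                    wv.data(), M, W, pA, pB);
    out[k] = (pA == 0 && pB == 0) ? NA_REAL : pA / (pA + pB);
  }
  return out;
}

// Long run of the two-step update on a single fixed learner-item pair with
// stable true parameters; returns visit counts of the item urning after
// each update (the learner urnings are determined by conservation).
// [[Rcpp::export]]
IntegerVector cpp_run_pair(IntegerVector n_learner, int n_item, IntegerVector w,
                           NumericVector theta, double delta,
                           IntegerVector r0, int r0_j, int n_updates,
                           int thin = 1) {
  int M = w.size(), W = 0;
  for (int m = 0; m < M; m++) W += w[m];
  std::vector<int> r(r0.begin(), r0.end());
  int rj = r0_j;
  double s = -delta;
  for (int m = 0; m < M; m++) s += w[m] * theta[m];
  double p_true = logistic_s(s);
  IntegerVector counts(n_item + 1);
  std::vector<int> rstar(M);
  for (int it = 0; it < n_updates; it++) {
    int X = (unif_rand() < p_true) ? 1 : 0;
    for (int m = 0; m < M; m++) rstar[m] = r[m] + w[m] * X;
    int rstar_j = rj + W * (1 - X);
    double pA, pB;
    branch_products(rstar.data(), rstar_j, n_learner.begin(), n_item,
                    w.begin(), M, W, pA, pB);
    if (unif_rand() < pA / (pA + pB)) {
      for (int m = 0; m < M; m++) r[m] = rstar[m] - w[m];
      rj = rstar_j;
    } else {
      for (int m = 0; m < M; m++) r[m] = rstar[m];
      rj = rstar_j - W;
    }
    if ((it + 1) % thin == 0) counts[rj]++;
  }
  return counts;
}

// Long run of the legacy sample-then-replace update (M = 1, w = 1) on a
// fixed pair; returns visit counts of the learner urning.
// [[Rcpp::export]]
IntegerVector cpp_legacy_pair(int n_i, int n_j, double theta, double delta,
                              int r0_i, int r0_j, int n_updates, int thin = 1) {
  int ri = r0_i, rj = r0_j;
  double p_true = logistic_s(theta - delta);
  IntegerVector counts(n_i + 1);
  for (int it = 0; it < n_updates; it++) {
    int X = (unif_rand() < p_true) ? 1 : 0;
    double num_ig = (double)ri * (n_j - rj);
    double num_ir = (double)(n_i - ri) * rj;
    int yi = (unif_rand() < num_ig / (num_ig + num_ir)) ? 1 : 0;
    int yj = 1 - yi;
    int rip = ri - yi + X;
    int rjp = rj - yj + (1 - X);
    double den = (double)rip * (n_j - rjp) + (double)(n_i - rip) * rjp;
    double acc = (den == 0) ? 1.0 : (num_ig + num_ir) / den;
    if (acc >= 1.0 || unif_rand() < acc) { ri = rip; rj = rjp; }
    if ((it + 1) % thin == 0) counts[ri]++;
  }
  return counts;
}

struct QueueState {
  // key = dim * max_w + (|delta| - 1); one up and one down list per key
  std::vector<std::vector<int>> up, down;
  int max_w;
};

// partner codes recorded in the event log
enum { PAIR_DIRECT = -9, PAIR_DROPPED = -2, PAIR_CANCELLED = -1, PAIR_QUEUED = -3 };

// One session (timepoint): every learner answers n_random randomly selected
// items followed by n_adaptive adaptively selected items, without repeating
// an item within the session. Urning matrices are modified in place.
// [[Rcpp::export]]
List cpp_session(IntegerMatrix lr, IntegerMatrix ln,
                 IntegerMatrix w_sys, IntegerMatrix w_true,
                 IntegerVector item_r, IntegerVector item_n,
                 IntegerVector ref_dim,  // 0-based dimension or -1
                 NumericMatrix theta, NumericVector delta,
                 int n_random, int n_adaptive,
                 bool correct_adaptivity, bool anchor,
                 List queue_up, List queue_down, int max_w,
                 bool record_events, int t_index) {
  int N = lr.nrow(), M = lr.ncol(), J = item_r.size();
  int G = n_random + n_adaptive;

  IntegerVector W_sys(J), W_true_tot(J);
  for (int j = 0; j < J; j++) {
    int a = 0, b = 0;
    for (int m = 0; m < M; m++) { a += w_sys(j, m); b += w_true(j, m); }
    W_sys[j] = a; W_true_tot[j] = b;
  }

  QueueState qs;
  qs.max_w = max_w;
  int nkeys = M * max_w;
  qs.up.resize(nkeys); qs.down.resize(nkeys);
  for (int k = 0; k < nkeys; k++) {
    IntegerVector u = queue_up[k], d = queue_down[k];
    qs.up[k].resize(u.size()); qs.down[k].resize(d.size());
    for (int z = 0; z < u.size(); z++) qs.up[k][z] = u[z] - 1;   // R ids are 1-based
    for (int z = 0; z < d.size(); z++) qs.down[k][z] = d[z] - 1;
  }

  // cached smoothed item difficulty estimates on the Eq.-5 scale:
  // R_j/n_j estimates logistic(delta_j / W_j), so delta-hat = W * logit
  std::vector<double> delta_hat(J);
  for (int j = 0; j < J; j++)
    delta_hat[j] = W_sys[j] *
      (std::log(item_r[j] + 1.0) - std::log(item_n[j] + 1.0 - item_r[j]));

  int n_events = record_events ? N * G : 0;
  IntegerVector ev_t(n_events), ev_learner(n_events), ev_item(n_events),
      ev_mode(n_events), ev_x(n_events), ev_green(n_events), ev_acc(n_events),
      ev_rstar_j(n_events), ev_partner(n_events);
  IntegerMatrix ev_rstar(record_events ? n_events : 1, M);
  int ev = 0;

  // shuffled learner order
  std::vector<int> order(N);
  for (int i = 0; i < N; i++) order[i] = i;
  for (int i = N - 1; i > 0; i--) {
    int k = (int)(unif_rand() * (i + 1));
    if (k > i) k = i;
    std::swap(order[i], order[k]);
  }

  std::vector<char> used(J);
  std::vector<double> theta_hat(M), selw(J);
  std::vector<int> rstar(M), rnew(M);

  for (int oi = 0; oi < N; oi++) {
    int i = order[oi];
    std::fill(used.begin(), used.end(), 0);
    for (int k = 0; k < G; k++) {
      bool adaptive = (k >= n_random);
      int j = -1;
      double s_cur = 0.0, Z = 0.0;
      if (!adaptive) {
        int n_avail = 0;
        for (int jj = 0; jj < J; jj++) if (!used[jj]) n_avail++;
        int pick = (int)(unif_rand() * n_avail);
        if (pick >= n_avail) pick = n_avail - 1;
        for (int jj = 0; jj < J; jj++) {
          if (used[jj]) continue;
          if (pick-- == 0) { j = jj; break; }
        }
      } else {
        for (int m = 0; m < M; m++)
          theta_hat[m] = std::log(lr(i, m) + 1.0) - std::log(ln(i, m) + 1.0 - lr(i, m));
        for (int jj = 0; jj < J; jj++) {
          if (used[jj]) { selw[jj] = 0.0; continue; }
          double s = -delta_hat[jj];
          for (int m = 0; m < M; m++)
            if (w_sys(jj, m)) s += w_sys(jj, m) * theta_hat[m];
          double p = logistic_s(s);
          selw[jj] = p * (1.0 - p);
          Z += selw[jj];
        }
        double u = unif_rand() * Z, acc = 0.0;
        for (int jj = 0; jj < J; jj++) {
          if (used[jj]) continue;
          acc += selw[jj];
          if (u <= acc) { j = jj; break; }
        }
        if (j < 0) { for (int jj = J - 1; jj >= 0; jj--) if (!used[jj]) { j = jj; break; } }
        s_cur = selw[j] / Z;
      }

      // true response
      double s = -delta[j];
      for (int m = 0; m < M; m++)
        if (w_true(j, m)) s += w_true(j, m) * theta(i, m);
      int X = (unif_rand() < logistic_s(s)) ? 1 : 0;

      // Step 1 + Step 2 with the system weights
      int Wj = W_sys[j];
      std::vector<int> wv(M), nlv(M);
      for (int m = 0; m < M; m++) { wv[m] = w_sys(j, m); nlv[m] = ln(i, m); }
      for (int m = 0; m < M; m++) rstar[m] = lr(i, m) + wv[m] * X;
      int rstar_j = item_r[j] + Wj * (1 - X);
      double pA, pB;
      branch_products(rstar.data(), rstar_j, nlv.data(), item_n[j],
                      wv.data(), M, Wj, pA, pB);
      bool green = (unif_rand() < pA / (pA + pB));
      int rnew_j;
      if (green) {
        for (int m = 0; m < M; m++) rnew[m] = rstar[m] - wv[m];
        rnew_j = rstar_j;
      } else {
        for (int m = 0; m < M; m++) rnew[m] = rstar[m];
        rnew_j = rstar_j - Wj;
      }

      bool changed = (rnew_j != item_r[j]);
      if (!changed) for (int m = 0; m < M; m++) if (rnew[m] != lr(i, m)) { changed = true; break; }

      bool accepted = true;
      if (adaptive && correct_adaptivity && changed) {
        // selection probability of j at the proposed urnings, same candidate set
        for (int m = 0; m < M; m++)
          theta_hat[m] = std::log(rnew[m] + 1.0) - std::log(ln(i, m) + 1.0 - rnew[m]);
        double dh_j = Wj * (std::log(rnew_j + 1.0) - std::log(item_n[j] + 1.0 - rnew_j));
        double Zp = 0.0, vj = 0.0;
        for (int jj = 0; jj < J; jj++) {
          if (used[jj]) continue;
          double sp = (jj == j) ? -dh_j : -delta_hat[jj];
          for (int m = 0; m < M; m++)
            if (w_sys(jj, m)) sp += w_sys(jj, m) * theta_hat[m];
          double p = logistic_s(sp);
          double v = p * (1.0 - p);
          Zp += v;
          if (jj == j) vj = v;
        }
        double s_prop = vj / Zp;
        if (s_prop < s_cur && unif_rand() >= s_prop / s_cur) accepted = false;
      }

      int partner = PAIR_DIRECT;
      int dj = rnew_j - item_r[j];
      if (accepted && changed) {
        for (int m = 0; m < M; m++) lr(i, m) = rnew[m];
        if (dj != 0) {
          if (anchor && ref_dim[j] >= 0) {
            // learner applied immediately; the reference item's update waits
            // for an opposite-direction request of equal magnitude (possibly
            // its own pending one, giving a net-zero self-pairing)
            int mag = dj > 0 ? dj : -dj;
            int key = ref_dim[j] * max_w + (mag - 1);
            std::vector<int>& same = dj > 0 ? qs.up[key] : qs.down[key];
            std::vector<int>& opp  = dj > 0 ? qs.down[key] : qs.up[key];
            // a queued request may have gone stale (the partner's urning
            // moved since): pop uniformly among entries still applicable
            std::vector<int> valid;
            for (size_t z = 0; z < opp.size(); z++) {
              int nv = item_r[opp[z]] - dj;
              if (nv >= 0 && nv <= item_n[opp[z]]) valid.push_back((int)z);
            }
            if (!valid.empty()) {
              int pick = valid[(int)(unif_rand() * valid.size()) % valid.size()];
              partner = opp[pick];
              opp.erase(opp.begin() + pick);
              item_r[j] += dj;
              item_r[partner] -= dj;
              delta_hat[j] = W_sys[j] *
                (std::log(item_r[j] + 1.0) - std::log(item_n[j] + 1.0 - item_r[j]));
              delta_hat[partner] = W_sys[partner] *
                (std::log(item_r[partner] + 1.0) -
                 std::log(item_n[partner] + 1.0 - item_r[partner]));
            } else {
              same.push_back(j);
              partner = PAIR_QUEUED;
            }
          } else {
            item_r[j] += dj;
            delta_hat[j] = W_sys[j] *
              (std::log(item_r[j] + 1.0) - std::log(item_n[j] + 1.0 - item_r[j]));
          }
        }
      }

      if (record_events) {
        ev_t[ev] = t_index; ev_learner[ev] = i + 1; ev_item[ev] = j + 1;
        ev_mode[ev] = adaptive ? 1 : 0; ev_x[ev] = X;
        ev_green[ev] = green ? 1 : 0; ev_acc[ev] = accepted ? 1 : 0;
        ev_rstar_j[ev] = rstar_j;
        for (int m = 0; m < M; m++) ev_rstar(ev, m) = rstar[m];
        // log codes: >0 paired partner id, 0 queued, -1 cancelled,
        // -2 dropped, -9 applied directly (non-reference or no anchoring)
        ev_partner[ev] = (partner >= 0) ? partner + 1 :
                         (partner == PAIR_QUEUED ? 0 : partner);
        ev++;
      }
      used[j] = 1;
    }
  }

  List qup(nkeys), qdown(nkeys);
  for (int k = 0; k < nkeys; k++) {
    IntegerVector u(qs.up[k].size()), d(qs.down[k].size());
    for (size_t z = 0; z < qs.up[k].size(); z++) u[z] = qs.up[k][z] + 1;
    for (size_t z = 0; z < qs.down[k].size(); z++) d[z] = qs.down[k][z] + 1;
    qup[k] = u; qdown[k] = d;
  }
  List out = List::create(_["queue_up"] = qup, _["queue_down"] = qdown);
  if (record_events) {
    out["events"] = List::create(
      _["t"] = ev_t, _["learner"] = ev_learner, _["item"] = ev_item,
      _["mode"] = ev_mode, _["x"] = ev_x, _["learner_green"] = ev_green,
      _["accepted"] = ev_acc, _["r_star_j"] = ev_rstar_j,
      _["r_star"] = ev_rstar, _["partner"] = ev_partner);
  }
  return out;
}
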