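#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Moran Bd/Db dynamics of a two-type population on a static undirected graph.
// Invaders carry relative fitness r (residents 1); r = infinity is a separate
// code path: Bd births are uniform over invaders, Db deaths uniform over
// residents (invaders never die). Every elementary update event counts as one
// time step, including events that change nothing.

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

namespace {

struct GraphState {
  const int *offsets;
  const int *neighbors;
  int n;
  std::vector<int> labels;            // 0 resident, 1 invader
  std::vector<int> members[2];        // node ids per class
  std::vector<int> pos;               // index of node within its class list

  GraphState(const IntegerVector &off, const IntegerVector &nbr)
      : offsets(off.begin()), neighbors(nbr.begin()),
        n(off.size() - 1), labels(n, 0), pos(n) {
    members[0].reserve(n);
    members[1].reserve(n);
  }

  void reset_all_resident() {
    std::fill(labels.begin(), labels.end(), 0);
    members[0].clear();
    members[1].clear();
    for (int v = 0; v < n; ++v) {
      members[0].push_back(v);
      pos[v] = v;
    }
  }

  void set_labels(const IntegerVector &lab) {
    members[0].clear();
    members[1].clear();
    for (int v = 0; v < n; ++v) {
      labels[v] = lab[v] ? 1 : 0;
      pos[v] = members[labels[v]].size();
      members[labels[v]].push_back(v);
    }
  }

  int invaders() const { return (int)members[1].size(); }

  void flip(int v) { // move v to the other class
    int a = labels[v];
    std::vector<int> &from = members[a];
    int last = from.back();
    from[pos[v]] = last;
    pos[last] = pos[v];
    from.pop_back();
    labels[v] = 1 - a;
    pos[v] = members[1 - a].size();
    members[1 - a].push_back(v);
  }

  int uniform_member(int cls) const {
    return members[cls][runif_int((int)members[cls].size())];
  }

  int uniform_neighbor(int v) const {
    int deg = offsets[v + 1] - offsets[v];
    return neighbors[offsets[v] + runif_int(deg)];
  }

  // one elementary update; rule 0 = Bd, 1 = Db
  void step(int rule, double r, bool r_inf) {
    int m = invaders(), nres = n - m;
    if (rule == 0) { // Birth-death
      int b;
      if (r_inf) {
        if (m == 0) return; // absorbing
        b = uniform_member(1);
      } else {
        if (m == 0) b = uniform_member(0);
        else if (nres == 0) b = uniform_member(1);
        else {
          double w_inv = (double)m * r;
          int cls = (unif_rand() * (w_inv + nres) < w_inv) ? 1 : 0;
          b = uniform_member(cls);
        }
      }
      int t = uniform_neighbor(b);
      if (labels[t] != labels[b]) flip(t);
    } else { // Death-birth
      int d;
      if (r_inf) {
        if (nres == 0) return; // invaders never die
        d = uniform_member(0);
      } else {
        if (m == 0) d = uniform_member(0);
        else if (nres == 0) d = uniform_member(1);
        else {
          double w_inv = (double)m / r;
          int cls = (unif_rand() * (w_inv + nres) < w_inv) ? 1 : 0;
          d = uniform_member(cls);
        }
      }
      int t = uniform_neighbor(d);
      if (labels[t] != labels[d]) flip(d);
    }
  }

  void seed_dose(int dose) { // dose distinct uniform nodes become invaders
    reset_all_resident();
    std::vector<int> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = 0; i < dose; ++i) {
      int j = i + runif_int(n - i);
      std::swap(perm[i], perm[j]);
      flip(perm[i]);
    }
  }

  // returns steps taken; outcome via invaders() afterwards
  double run(int rule, double r, bool r_inf, int threshold, double max_steps) {
    double steps = 0.0;
    while (invaders() > 0 && invaders() < threshold) {
      if (steps >= max_steps)
        stop("trial exceeded max_steps (%.0f) without absorbing", max_steps);
      step(rule, r, r_inf);
      steps += 1.0;
    }
    return steps;
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_one_step(IntegerVector offsets, IntegerVector neighbors,
                           IntegerVector labels, int rule, double r,
                           bool r_inf) {
  GraphState st(offsets, neighbors);
  st.set_labels(labels);
  st.step(rule, r, r_inf);
  return IntegerVector(st.labels.begin(), st.labels.end());
}

// [[Rcpp::export]]
NumericVector cpp_run_trial(IntegerVector offsets, IntegerVector neighbors,
                            int rule, double r, bool r_inf, int dose,
                            int threshold, double max_steps) {
  GraphState st(offsets, neighbors);
  st.seed_dose(dose);
  double steps = st.run(rule, r, r_inf, threshold, max_steps);
  return NumericVector::create((double)(st.invaders() >= threshold), steps);
}

// Rejection-sampled conditioned ensemble on a fixed graph: extinct trials are
// discarded until n_samples threshold-reaching times are collected.
// [[Rcpp::export]]
List cpp_run_ensemble(IntegerVector offsets, IntegerVector neighbors, int rule,
                      double r, bool r_inf, int dose, int threshold,
                      int n_samples, double max_attempts, double max_steps) {
  GraphState st(offsets, neighbors);
  NumericVector times(n_samples);
  double attempts = 0.0, rejected = 0.0;
  int got = 0;
  while (got < n_samples) {
    if (attempts >= max_attempts)
      stop("exceeded %.0f attempts with only %d of %d fixations: "
           "fixation probability is implausibly low for this spec",
           max_attempts, got, n_samples);
    attempts += 1.0;
    st.seed_dose(dose);
    double steps = st.run(rule, r, r_inf, threshold, max_steps);
    if (st.invaders() >= threshold) times[got++] = steps;
    else rejected += 1.0;
    if (((long long)attempts & 0x3FF) == 0) checkUserInterrupt();
  }
  return List::create(_["times"] = times, _["n_rejected"] = rejected,
                      _["attempts"] = attempts);
}

// ---------------------------------------------------------------------------
// Complete graph, tracked by counts only. Exact in distribution for the
// per-step dynamics (node identity is irrelevant on the complete graph) and
// the only path supporting a non-static population, where new resident nodes
// are adjacent to all preexisting nodes so the graph stays complete.
// pop_mode: 0 static, 1 grow, 2 shrink, 3 random walk (+-1 resident, 1/2
// each). The population event is applied first within a time step, then one
// Moran update; the tick counts as a single step. Takeover for variable
// populations means invaders equal to the current population size.

namespace {

struct CompleteTrial {
  double steps;
  int m;    // invaders at absorption
  int popn; // population at absorption
};

CompleteTrial run_complete(int N, int rule, double r, bool r_inf, int dose,
                           int threshold, int pop_mode, double pop_p,
                           double max_steps) {
  int popn = N, m = dose;
  double steps = 0.0;
  bool variable = pop_mode != 0;
  while (true) {
    int thr = variable ? popn : threshold;
    if (m <= 0 || m >= thr) break;
    if (steps >= max_steps)
      stop("trial exceeded max_steps (%.0f) without absorbing", max_steps);
    // population event
    if (pop_mode == 1) {
      if (unif_rand() < pop_p) popn += 1;
    } else if (pop_mode == 2) {
      if (unif_rand() < pop_p && popn > m) popn -= 1;
    } else if (pop_mode == 3) {
      if (unif_rand() < 0.5) popn += 1;
      else if (popn > m) popn -= 1;
    }
    if (variable && m >= popn) { steps += 1.0; break; }
    // one Moran update on the complete graph of popn nodes
    int nres = popn - m;
    if (rule == 0) { // Bd
      bool inv_births;
      if (r_inf) inv_births = true;
      else {
        double w_inv = (double)m * r;
        inv_births = unif_rand() * (w_inv + nres) < w_inv;
      }
      if (inv_births) {
        if (unif_rand() * (popn - 1) < nres) m += 1;
      } else {
        if (unif_rand() * (popn - 1) < m) m -= 1;
      }
    } else { // Db
      bool inv_dies;
      if (r_inf) inv_dies = false;
      else {
        double w_inv = (double)m / r;
        inv_dies = unif_rand() * (w_inv + nres) < w_inv;
      }
      if (inv_dies) {
        if (unif_rand() * (popn - 1) < nres) m -= 1;
      } else {
        if (unif_rand() * (popn - 1) < m) m += 1;
      }
    }
    steps += 1.0;
  }
  return CompleteTrial{steps, m, popn};
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_complete_trial(int N, int rule, double r, bool r_inf,
                                 int dose, int threshold, int pop_mode,
                                 double pop_p, double max_steps) {
  CompleteTrial t =
      run_complete(N, rule, r, r_inf, dose, threshold, pop_mode, pop_p, max_steps);
  int thr = (pop_mode != 0) ? t.popn : threshold;
  return NumericVector::create((double)(t.m >= thr), t.steps, (double)t.popn);
}

// [[Rcpp::export]]
List cpp_complete_ensemble(int N, int rule, double r, bool r_inf, int dose,
                           int threshold, int n_samples, double max_attempts,
                           int pop_mode, double pop_p, double max_steps) {
  NumericVector times(n_samples);
  double attempts = 0.0, rejected = 0.0;
  int got = 0;
  while (got < n_samples) {
    if (attempts >= max_attempts)
      stop("exceeded %.0f attempts with only %d of %d takeovers: "
           "fixation probability is implausibly low for this spec",
           max_attempts, got, n_samples);
    attempts += 1.0;
    CompleteTrial t =
        run_complete(N, rule, r, r_inf, dose, threshold, pop_mode, pop_p, max_steps);
    int thr = (pop_mode != 0) ? t.popn : threshold;
    if (t.m >= thr) times[got++] = t.steps;
    else rejected += 1.0;
    if (((long long)attempts & 0x3FF) == 0) checkUserInterrupt();
  }
  return List::create(_["times"] = times, _["n_rejected"] = rejected,
                      _["attempts"] = attempts);
}
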