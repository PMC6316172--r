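// Conflict-driven clause-learning (CDCL) SAT solver used as the decision
// engine for bounded-model-checking queries over abstract Boolean networks.
// MiniSat-style: two-watched-literal propagation, first-UIP clause learning,
// VSIDS-like activity with phase saving, Luby restarts. Deterministic: no
// randomised branching, so identical inputs yield identical answers.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

inline int var_of(int lit) { return lit >> 1; }
inline bool sign_of(int lit) { return lit & 1; }          // 1 = negated
inline int neg(int lit) { return lit ^ 1; }
inline int mklit(int v, bool neg_) { return (v << 1) | (neg_ ? 1 : 0); }

struct Solver {
  int nvars;
  std::vector<std::vector<int>> clauses;       // problem + learnt
  std::vector<std::vector<int>> watches;       // literal -> clause ids
  std::vector<int8_t> assigns;                 // var: -1 undef, 0 false, 1 true
  std::vector<int8_t> polarity;                // saved phase (1 = true)
  std::vector<int> level_, reason_;
  std::vector<int> trail, trail_lim;
  std::vector<double> activity;
  std::vector<char> seen;
  std::vector<int> heap, heap_pos;             // max-heap on activity
  size_t qhead = 0;
  double var_inc = 1.0;
  long long conflicts = 0;
  bool ok = true;

  explicit Solver(int n) : nvars(n) {
    watches.assign(2 * n, {});
    assigns.assign(n, -1);
    polarity.assign(n, 0);
    level_.assign(n, 0);
    reason_.assign(n, -1);
    activity.assign(n, 0.0);
    seen.assign(n, 0);
    heap_pos.assign(n, -1);
    for (int v = 0; v < n; ++v) heap_insert(v);
  }

  // ---- activity heap -------------------------------------------------
  bool heap_lt(int a, int b) const { return activity[a] > activity[b]; }
  void heap_up(int i) {
    int v = heap[i];
    while (i > 0) {
      int p = (i - 1) >> 1;
      if (!heap_lt(v, heap[p])) break;
      heap[i] = heap[p]; heap_pos[heap[i]] = i; i = p;
    }
    heap[i] = v; heap_pos[v] = i;
  }
  void heap_down(int i) {
    int v = heap[i];
    size_t n = heap.size();
    for (;;) {
      size_t l = 2 * i + 1, r = l + 1, best = l;
      if (l >= n) break;
      if (r < n && heap_lt(heap[r], heap[l])) best = r;
      if (!heap_lt(heap[best], v)) break;
      heap[i] = heap[best]; heap_pos[heap[i]] = i; i = (int)best;
    }
    heap[i] = v; heap_pos[v] = i;
  }
  void heap_insert(int v) {
    if (heap_pos[v] >= 0) return;
    heap.push_back(v);
    heap_pos[v] = (int)heap.size() - 1;
    heap_up((int)heap.size() - 1);
  }
  int heap_pop() {
    int v = heap[0];
    heap_pos[v] = -1;
    heap[0] = heap.back(); heap.pop_back();
    if (!heap.empty()) { heap_pos[heap[0]] = 0; heap_down(0); }
    return v;
  }

  void bump(int v) {
    activity[v] += var_inc;
    if (activity[v] > 1e100) {
      for (int i = 0; i < nvars; ++i) activity[i] *= 1e-100;
      var_inc *= 1e-100;
    }
    if (heap_pos[v] >= 0) heap_up(heap_pos[v]);
  }

  // ---- assignment ----------------------------------------------------
  int lit_value(int l) const {              // -1 undef, 0 false, 1 true
    int8_t a = assigns[var_of(l)];
    if (a < 0) return -1;
    return sign_of(l) ? 1 - a : a;
  }
  int decision_level() const { return (int)trail_lim.size(); }

  bool enqueue(int l, int reason) {
    int v = var_of(l);
    int val = lit_value(l);
    if (val == 0) return false;       // conflicting assignment
    if (val == 1) return true;        // already true
    assigns[v] = sign_of(l) ? 0 : 1;
    level_[v] = decision_level();
    reason_[v] = reason;
    trail.push_back(l);
    return true;
  }

  void cancel_until(int lvl) {
    if (decision_level() <= lvl) return;
    int bound = trail_lim[lvl];
    for (int i = (int)trail.size() - 1; i >= bound; --i) {
      int v = var_of(trail[i]);
      polarity[v] = assigns[v];
      assigns[v] = -1;
      reason_[v] = -1;
      heap_insert(v);
    }
    trail.resize(bound);
    trail_lim.resize(lvl);
    qhead = trail.size();
  }

  // ---- clauses -------------------------------------------------------
  // returns false on immediate top-level conflict
  bool add_clause(std::vector<int> lits) {
    std::sort(lits.begin(), lits.end());
    lits.erase(std::unique(lits.begin(), lits.end()), lits.end());
    for (size_t i = 0; i + 1 < lits.size(); ++i) {
      if (lits[i] == neg(lits[i + 1])) return true;  // tautology
    }
    std::vector<int> kept;
    for (int l : lits) {
      int val = lit_value(l);
      if (val == 1 && level_[var_of(l)] == 0) return true;  // satisfied
      if (val == 0 && level_[var_of(l)] == 0) continue;     // falsified
      kept.push_back(l);
    }
    if (kept.empty()) return false;
    if (kept.size() == 1) return enqueue(kept[0], -1);
    int id = (int)clauses.size();
    clauses.push_back(kept);
    watches[kept[0]].push_back(id);
    watches[kept[1]].push_back(id);
    return true;
  }

  int attach_learnt(const std::vector<int>& lits) {
    int id = (int)clauses.size();
    clauses.push_back(lits);
    watches[lits[0]].push_back(id);
    watches[lits[1]].push_back(id);
    return id;
  }

  // ---- propagation ---------------------------------------------------
  int propagate() {  // returns conflicting clause id or -1
    while (qhead < trail.size()) {
      int p = trail[qhead++];
      int fl = neg(p);                  // literal made false
      std::vector<int>& ws = watches[fl];
      size_t i = 0, j = 0;
      while (i < ws.size()) {
        int cid = ws[i++];
        std::vector<int>& c = clauses[cid];
        if (c[0] == fl) std::swap(c[0], c[1]);
        if (lit_value(c[0]) == 1) { ws[j++] = cid; continue; }
        bool moved = false;
        for (size_t k = 2; k < c.size(); ++k) {
          if (lit_value(c[k]) != 0) {
            std::swap(c[1], c[k]);
            watches[c[1]].push_back(cid);
            moved = true;
            break;
          }
        }
        if (moved) continue;
        ws[j++] = cid;                   // keep watching fl
        if (lit_value(c[0]) == 0) {      // conflict
          while (i < ws.size()) ws[j++] = ws[i++];
          ws.resize(j);
          qhead = trail.size();
          return cid;
        }
        if (!enqueue(c[0], cid)) Rcpp::stop("internal: enqueue failed");
      }
      ws.resize(j);
    }
    return -1;
  }

  // ---- conflict analysis (first UIP) ---------------------------------
  void analyze(int confl, std::vector<int>& learnt, int& bt_level) {
    learnt.clear();
    learnt.push_back(0);  // slot for asserting literal
    int pathC = 0;
    int p = -1;
    size_t index = trail.size();
    do {
      const std::vector<int>& c = clauses[confl];
      for (size_t j = (p == -1 ? 0 : 1); j < c.size(); ++j) {
        int q = c[j];
        int v = var_of(q);
        if (!seen[v] && level_[v] > 0) {
          seen[v] = 1;
          bump(v);
          if (level_[v] >= decision_level()) ++pathC;
          else learnt.push_back(q);
        }
      }
      while (!seen[var_of(trail[--index])]) {}
      p = trail[index];
      confl = reason_[var_of(p)];
      seen[var_of(p)] = 0;
      --pathC;
    } while (pathC > 0);
    learnt[0] = neg(p);

    if (learnt.size() == 1) {
      bt_level = 0;
    } else {
      size_t maxi = 1;
      for (size_t i = 2; i < learnt.size(); ++i) {
        if (level_[var_of(learnt[i])] > level_[var_of(learnt[maxi])]) maxi = i;
      }
      std::swap(learnt[1], learnt[maxi]);
      bt_level = level_[var_of(learnt[1])];
    }
    for (size_t i = 1; i < learnt.size(); ++i) seen[var_of(learnt[i])] = 0;
  }

  int pick_branch() {
    while (!heap.empty()) {
      int v = heap_pop();
      if (assigns[v] < 0) return v;
    }
    return -1;
  }

  // ---- main search ---------------------------------------------------
  // status: 1 sat, 0 unsat, -1 conflict budget exceeded
  int solve(double max_conflicts) {
    if (!ok) return 0;
    std::vector<int> learnt;
    long long restart_count = 0;
    long long conflicts_at_restart = 0;
    auto luby = [](long long i) {
      // Luby sequence (1,1,2,1,1,2,4,...)
      long long k = 1;
      while ((1LL << k) - 1 < i + 1) ++k;
      while ((1LL << (k - 1)) - 1 != i) {
        i = i - ((1LL << (k - 1)) - 1);
        k = 1;
        while ((1LL << k) - 1 < i + 1) ++k;
      }
      return 1LL << (k - 1);
    };
    long long budget = luby(restart_count) * 128;
    for (;;) {
      int confl = propagate();
      if (confl != -1) {
        ++conflicts;
        if (decision_level() == 0) return 0;
        int bt;
        analyze(confl, learnt, bt);
        cancel_until(bt);
        if (learnt.size() == 1) {
          if (!enqueue(learnt[0], -1)) return 0;
        } else {
          int id = attach_learnt(learnt);
          if (!enqueue(learnt[0], id)) Rcpp::stop("internal: learnt enqueue");
        }
        var_inc *= (1.0 / 0.95);
        if (conflicts - conflicts_at_restart >= budget) {
          ++restart_count;
          conflicts_at_restart = conflicts;
          budget = luby(restart_count) * 128;
          cancel_until(0);
        }
      } else {
        if (conflicts >= (long long)max_conflicts) return -1;
        int next = pick_branch();
        if (next == -1) return 1;
        trail_lim.push_back((int)trail.size());
        if (!enqueue(mklit(next, polarity[next] == 0), -1)) {
          Rcpp::stop("internal: decision enqueue");
        }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cdcl_solve_cpp(int nvars, IntegerVector lits, IntegerVector clause_len,
                    double max_conflicts) {
  Solver s(nvars);
  size_t pos = 0;
  bool ok = true;
  for (int ci = 0; ci < clause_len.size() && ok; ++ci) {
    int len = clause_len[ci];
    std::vector<int> cl;
    cl.reserve(len);
    for (int k = 0; k < len; ++k) {
      int dl = lits[pos + k];  // DIMACS: +v / -v, 1-based
      int v = std::abs(dl) - 1;
      if (v < 0 || v >= nvars) Rcpp::stop("literal out of range");
      cl.push_back(mklit(v, dl < 0));
    }
    pos += len;
    ok = s.add_clause(std::move(cl));
  }
  int status;
  if (!ok) {
    status = 0;
  } else {
    status = s.solve(max_conflicts);
  }
  LogicalVector model(nvars, NA_LOGICAL);
  if (status == 1) {
    for (int v = 0; v < nvars; ++v) {
      model[v] = s.assigns[v] == 1;  // unassigned vars default false
    }
  }
  return List::create(_["status"] = status,
                      _["model"] = model,
                      _["conflicts"] = (double)s.conflicts,
                      _["n_learnt"] = (double)(s.clauses.size()));
}
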