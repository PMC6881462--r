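// Simulated-annealing modularity maximisation.
//
// State is a membership vector over module labels 0..n-1 (empty labels act
// as "fresh" modules). Per-module within-edge counts and degree sums are
// maintained incrementally; merges and splits rescan the (small) edge list.
// All randomness comes from R's RNG so set.seed() in R fixes the run.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
List anneal_cpp(int n, IntegerMatrix edges, double t0, double cooling,
                int steps_per_t, double t_min) {
  int m = edges.nrow();
  std::vector<std::vector<int>> adj(n);
  std::vector<double> deg(n, 0.0);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    adj[a].push_back(b);
    adj[b].push_back(a);
    deg[a] += 1.0; deg[b] += 1.0;
  }
  double dm = (double)m;

  std::vector<int> memb(n), best_memb(n);
  std::vector<double> within(n, 0.0), dsum(n, 0.0);
  std::vector<int> msize(n, 0);
  for (int v = 0; v < n; ++v) {   // start from singletons
    memb[v] = v; dsum[v] = deg[v]; msize[v] = 1;
  }
  double q = 0.0;
  for (int s = 0; s < n; ++s)
    q += within[s] / dm - (dsum[s] / (2.0 * dm)) * (dsum[s] / (2.0 * dm));
  double best_q = q;
  best_memb = memb;

  std::vector<double> trace_t, trace_q;
  std::vector<int> snodes, tnodes;   // split scratch

  for (double T = t0; T >= t_min; T *= cooling) {
    for (int step = 0; step < steps_per_t; ++step) {
      double r = unif_rand();
      double dq = 0.0;
      bool accepted = false;
      if (r < 0.85) {
        // single-node move (target may be an empty label = fresh module)
        int v = runif_int(n);
        int s = memb[v];
        int t = runif_int(n);
        if (t == s) continue;
        if (msize[s] == 1 && msize[t] == 0) continue;  // relabel only
        double evs = 0.0, evt = 0.0;
        for (int w : adj[v]) {
          if (memb[w] == s) evs += 1.0;
          else if (memb[w] == t) evt += 1.0;
        }
        dq = (evt - evs) / dm
           - deg[v] * (dsum[t] - dsum[s] + deg[v]) / (2.0 * dm * dm);
        if (dq > 0 || unif_rand() < std::exp(dq / T)) {
          memb[v] = t;
          within[s] -= evs; within[t] += evt;
          dsum[s] -= deg[v]; dsum[t] += deg[v];
          msize[s] -= 1; msize[t] += 1;
          accepted = true;
        }
      } else if (r < 0.925) {
        // merge two distinct non-empty modules
        int s = memb[runif_int(n)];
        int t = memb[runif_int(n)];
        if (s == t) continue;
        double est = 0.0;
        for (int e = 0; e < m; ++e) {
          int ma = memb[edges(e, 0)], mb = memb[edges(e, 1)];
          if ((ma == s && mb == t) || (ma == t && mb == s)) est += 1.0;
        }
        dq = est / dm - dsum[s] * dsum[t] / (2.0 * dm * dm);
        if (dq > 0 || unif_rand() < std::exp(dq / T)) {
          for (int v = 0; v < n; ++v) if (memb[v] == s) memb[v] = t;
          within[t] += within[s] + est;
          dsum[t] += dsum[s];
          msize[t] += msize[s];
          within[s] = 0.0; dsum[s] = 0.0; msize[s] = 0;
          accepted = true;
        }
      } else {
        // random bipartition split of a module with >= 2 nodes
        int s = memb[runif_int(n)];
        if (msize[s] < 2) continue;
        int t = -1;
        for (int l = 0; l < n; ++l) if (msize[l] == 0) { t = l; break; }
        if (t < 0) continue;
        snodes.clear(); tnodes.clear();
        double dt_new = 0.0;
        std::vector<char> tot(n, 0);
        for (int v = 0; v < n; ++v) if (memb[v] == s) {
          if (unif_rand() < 0.5) { tnodes.push_back(v); tot[v] = 1; dt_new += deg[v]; }
          else snodes.push_back(v);
        }
        if (tnodes.empty() || snodes.empty()) continue;
        double ess = 0.0, ett = 0.0;
        for (int e = 0; e < m; ++e) {
          int a = edges(e, 0), b = edges(e, 1);
          if (memb[a] != s || memb[b] != s) continue;
          if (tot[a] && tot[b]) ett += 1.0;
          else if (!tot[a] && !tot[b]) ess += 1.0;
        }
        double ds_old = dsum[s], ds_new = ds_old - dt_new;
        dq = (ess + ett - within[s]) / dm
           - (ds_new * ds_new + dt_new * dt_new - ds_old * ds_old)
             / (4.0 * dm * dm);
        if (dq > 0 || unif_rand() < std::exp(dq / T)) {
          for (int v : tnodes) memb[v] = t;
          within[s] = ess; within[t] = ett;
          dsum[s] = ds_new; dsum[t] = dt_new;
          msize[s] = (int)snodes.size(); msize[t] = (int)tnodes.size();
          accepted = true;
        }
      }
      if (accepted) {
        q += dq;
        trace_t.push_back(T);
        trace_q.push_back(q);
        if (q > best_q + 1e-12) { best_q = q; best_memb = memb; }
      }
    }
  }
  // recompute Q of the best partition exactly (discards accumulated
  // floating-point drift from the incremental updates)
  {
    std::vector<double> w2(n, 0.0), d2(n, 0.0);
    for (int e = 0; e < m; ++e)
      if (best_memb[edges(e, 0)] == best_memb[edges(e, 1)])
        w2[best_memb[edges(e, 0)]] += 1.0;
    for (int v = 0; v < n; ++v) d2[best_memb[v]] += deg[v];
    best_q = 0.0;
    for (int s = 0; s < n; ++s)
      best_q += w2[s] / dm - (d2[s] / (2.0 * dm)) * (d2[s] / (2.0 * dm));
  }
  return List::create(_["membership"] = IntegerVector(best_memb.begin(),
                                                      best_memb.end()),
                      _["q"] = best_q,
                      _["trace_t"] = NumericVector(trace_t.begin(), trace_t.end()),
                      _["trace_q"] = NumericVector(trace_q.begin(), trace_q.end()));
}
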