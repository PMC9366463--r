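#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Jukes-Cantor pruning likelihood and coordinate-wise optimizers.
//
// Conventions shared by every entry point:
//  * `edge` is the 2-column (parent, child) matrix of a phylo object in
//    postorder, 1-based node ids, tips 1..ntip, node count 2*ntip-1 for
//    rooted binary trees (the root of an unrooted ape tree may have 3
//    children; the code only assumes parents appear after all their
//    children's edges).
//  * `tip` is an ntip x npat integer matrix of states 1..4; 0 means
//    missing/ambiguous (partial likelihood 1 in every state).
//  * `w` holds site-pattern weights.
//  * branch lengths `en` are expected substitutions per site.

struct TreeData {
  IntegerMatrix edge;
  IntegerMatrix tip;
  NumericVector w;
  int ntip, nnode, npat, root;
  std::vector<double> part; // partials, nnode*4*npat
  std::vector<int> touched;

  TreeData(IntegerMatrix edge_, IntegerMatrix tip_, NumericVector w_)
    : edge(edge_), tip(tip_), w(w_) {
    ntip = tip.nrow();
    npat = tip.ncol();
    int mx = 0;
    for (int e = 0; e < edge.nrow(); ++e) {
      if (edge(e, 0) > mx) mx = edge(e, 0);
      if (edge(e, 1) > mx) mx = edge(e, 1);
    }
    nnode = mx;
    root = edge(edge.nrow() - 1, 0); // postorder: last edge's parent
    part.assign((size_t)nnode * 4 * npat, 0.0);
    touched.assign(nnode + 1, 0);
  }

  double loglik(const std::vector<double>& en) {
    const int ne = edge.nrow();
    // internal nodes occupy ids ntip+1..nnode
    for (int i = ntip; i < nnode; ++i) touched[i + 1] = 0;
    for (int e = 0; e < ne; ++e) {
      int p = edge(e, 0), c = edge(e, 1);
      double n = en[e];
      if (n < 0) n = 0;
      double ps = 0.25 + 0.75 * std::exp(-4.0 / 3.0 * n);
      double pd = (1.0 - ps) / 3.0;
      double d = ps - pd;
      double* pp = &part[(size_t)(p - 1) * 4 * npat];
      if (!touched[p]) {
        for (int j = 0; j < 4 * npat; ++j) pp[j] = 1.0;
        touched[p] = 1;
      }
      if (c <= ntip) {
        for (int j = 0; j < npat; ++j) {
          int s = tip(c - 1, j);
          if (s == 0) continue; // P %*% 1 = 1: multiply by one
          double* q = pp + (size_t)4 * j;
          for (int k = 0; k < 4; ++k) q[k] *= (k == s - 1) ? ps : pd;
        }
      } else {
        const double* cp = &part[(size_t)(c - 1) * 4 * npat];
        for (int j = 0; j < npat; ++j) {
          const double* L = cp + (size_t)4 * j;
          double cs = L[0] + L[1] + L[2] + L[3];
          double* q = pp + (size_t)4 * j;
          for (int k = 0; k < 4; ++k) q[k] *= d * L[k] + pd * cs;
        }
      }
    }
    const double* rp = &part[(size_t)(root - 1) * 4 * npat];
    double ll = 0.0;
    for (int j = 0; j < npat; ++j) {
      const double* L = rp + (size_t)4 * j;
      double site = 0.25 * (L[0] + L[1] + L[2] + L[3]);
      ll += w[j] * std::log(site);
    }
    return ll;
  }

  // --- incremental evaluation -------------------------------------------
  // Partials of a node depend only on its subtree, so when one node's
  // height moves it suffices to rebuild the partials on the path from that
  // node to the root. These helpers keep `part` consistent with the caller-
  // maintained `en` vector.

  // child edge indices per node, filled on demand
  std::vector<std::vector<int> > child_edges;
  std::vector<int> parent_of;

  void build_maps() {
    child_edges.assign(nnode + 1, std::vector<int>());
    parent_of.assign(nnode + 1, 0);
    for (int e = 0; e < edge.nrow(); ++e) {
      child_edges[edge(e, 0)].push_back(e);
      parent_of[edge(e, 1)] = edge(e, 0);
    }
  }

  void recompute_node(int u, const std::vector<double>& en) {
    double* pp = &part[(size_t)(u - 1) * 4 * npat];
    for (int j = 0; j < 4 * npat; ++j) pp[j] = 1.0;
    for (size_t k = 0; k < child_edges[u].size(); ++k) {
      int e = child_edges[u][k];
      int c = edge(e, 1);
      double n = en[e] < 0 ? 0 : en[e];
      double ps = 0.25 + 0.75 * std::exp(-4.0 / 3.0 * n);
      double pd = (1.0 - ps) / 3.0;
      double d = ps - pd;
      if (c <= ntip) {
        for (int j = 0; j < npat; ++j) {
          int s = tip(c - 1, j);
          if (s == 0) continue;
          double* q = pp + (size_t)4 * j;
          for (int kk = 0; kk < 4; ++kk) q[kk] *= (kk == s - 1) ? ps : pd;
        }
      } else {
        const double* cp = &part[(size_t)(c - 1) * 4 * npat];
        for (int j = 0; j < npat; ++j) {
          const double* L = cp + (size_t)4 * j;
          double cs = L[0] + L[1] + L[2] + L[3];
          double* q = pp + (size_t)4 * j;
          for (int kk = 0; kk < 4; ++kk) q[kk] *= d * L[kk] + pd * cs;
        }
      }
    }
  }

  double root_loglik() const {
    const double* rp = &part[(size_t)(root - 1) * 4 * npat];
    double ll = 0.0;
    for (int j = 0; j < npat; ++j) {
      const double* L = rp + (size_t)4 * j;
      ll += w[j] * std::log(0.25 * (L[0] + L[1] + L[2] + L[3]));
    }
    return ll;
  }

  // rebuild partials from `from` up to the root and return the loglik
  double loglik_path(int from, const std::vector<double>& en) {
    int u = from;
    while (true) {
      recompute_node(u, en);
      if (u == root) break;
      u = parent_of[u];
    }
    return root_loglik();
  }
};

// Brent's method for 1-D minimisation on [a, b] (no derivatives).
template <typename F>
static double brent_min(F f, double a, double b, double tol, double* fmin) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), wv = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double m = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-12;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0, q = 0, r = 0;
    bool useGolden = true;
    if (std::fabs(e) > tol1) {
      r = (x - wv) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - wv) * r;
      q = 2.0 * (q - r);
      if (q > 0) p = -p;
      q = std::fabs(q);
      double etmp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etmp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (m > x) ? tol1 : -tol1;
        useGolden = false;
      }
    }
    if (useGolden) {
      e = (x < m) ? b - x : a - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = wv; fv = fw; wv = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || wv == x) { v = wv; fv = fw; wv = u; fw = fu; }
      else if (fu <= fv || v == x || v == wv) { v = u; fv = fu; }
    }
  }
  *fmin = fx;
  return x;
}

// [[Rcpp::export]]
double cpp_jc_loglik(IntegerMatrix edge, NumericVector en, IntegerMatrix tip,
                     NumericVector w) {
  TreeData td(edge, tip, w);
  std::vector<double> env(en.begin(), en.end());
  return td.loglik(env);
}

// Strict-clock ML over internal node ages (root fixed), optionally over the
// single clock rate inside [rate_lo, rate_hi].
//
// The search runs on substitution-scale node heights h = rate * age: branch
// lengths are then plain height differences, so the strong rate/age ridge of
// the naive parameterisation disappears. A free rate is simply a free root
// height inside [rate_lo, rate_hi] * root_age; rate = h_root / root_age on
// exit.
// [[Rcpp::export]]
List cpp_fit_clock(IntegerMatrix edge, NumericVector ages0, int root,
                   IntegerMatrix tip, NumericVector w, double rate,
                   bool opt_rate, double rate_lo, double rate_hi, double tol,
                   int max_sweeps) {
  TreeData td(edge, tip, w);
  const int ne = edge.nrow();
  const double root_age = ages0[root - 1];
  std::vector<double> h(td.nnode);
  for (int i = 0; i < td.nnode; ++i) h[i] = rate * ages0[i];
  std::vector<int> parent(td.nnode + 1, 0);
  for (int e = 0; e < ne; ++e) parent[edge(e, 1)] = edge(e, 0);
  std::vector<std::vector<int> > kids(td.nnode + 1);
  for (int e = 0; e < ne; ++e) kids[edge(e, 0)].push_back(edge(e, 1));

  // free internal nodes (everything internal except the root)
  std::vector<int> freeN;
  for (int v = td.ntip + 1; v <= td.nnode; ++v)
    if (v != root) freeN.push_back(v);
  // sweep from old to young so parents settle first
  std::sort(freeN.begin(), freeN.end(), [&](int a, int b) {
    return h[a - 1] > h[b - 1];
  });

  std::vector<double> en(ne);
  auto refresh_en = [&]() {
    for (int e = 0; e < ne; ++e)
      en[e] = h[edge(e, 0) - 1] - h[edge(e, 1) - 1];
  };
  refresh_en();
  td.build_maps();
  // edges incident to each node, so a single-node move touches only them
  std::vector<std::vector<int> > inc(td.nnode + 1);
  for (int e = 0; e < ne; ++e) {
    inc[edge(e, 0)].push_back(e);
    inc[edge(e, 1)].push_back(e);
  }
  auto set_height = [&](int v, double x) {
    h[v - 1] = x;
    for (size_t k = 0; k < inc[v].size(); ++k) {
      int e = inc[v][k];
      en[e] = h[edge(e, 0) - 1] - h[edge(e, 1) - 1];
    }
  };

  double best = td.loglik(en); // full pass fills the partial cache
  int sweeps = 0;
  for (; sweeps < max_sweeps; ++sweeps) {
    double prev = best;
    double margin = 1e-9 * h[root - 1];
    for (size_t i = 0; i < freeN.size(); ++i) {
      int v = freeN[i];
      double lo = 0.0;
      for (size_t k = 0; k < kids[v].size(); ++k)
        lo = std::max(lo, h[kids[v][k] - 1]);
      double hi = h[parent[v] - 1];
      if (hi - lo <= 4.0 * margin) continue;
      double fbest;
      auto g = [&](double x) {
        set_height(v, x);
        return -td.loglik_path(v, en);
      };
      double x = brent_min(g, lo + margin, hi - margin, 1e-7, &fbest);
      best = -g(x); // leave cache consistent with the accepted height
    }
    if (opt_rate) {
      double lo = rate_lo * root_age;
      for (size_t k = 0; k < kids[root].size(); ++k)
        lo = std::max(lo, h[kids[root][k] - 1] + margin);
      double hi = rate_hi * root_age;
      if (hi > lo) {
        double fbest;
        auto g = [&](double x) {
          set_height(root, x);
          return -td.loglik_path(root, en);
        };
        double x = brent_min(g, lo, hi, 1e-7, &fbest);
        best = -g(x);
      }
    }
    if (best - prev < tol && sweeps > 0) { ++sweeps; break; }
  }
  double out_rate = h[root - 1] / root_age;
  NumericVector ages(td.nnode);
  for (int i = 0; i < td.nnode; ++i) ages[i] = h[i] / out_rate;
  return List::create(_["ages"] = ages, _["rate"] = out_rate,
                      _["loglik"] = best, _["sweeps"] = sweeps);
}

// ML branch lengths (expected substitutions/site) on a fixed topology.
// [[Rcpp::export]]
List cpp_fit_edges(IntegerMatrix edge, NumericVector en0, IntegerMatrix tip,
                   NumericVector w, double n_max, double tol,
                   int max_sweeps) {
  TreeData td(edge, tip, w);
  const int ne = edge.nrow();
  std::vector<double> en(en0.begin(), en0.end());
  double best = td.loglik(en);
  int sweeps = 0;
  for (; sweeps < max_sweeps; ++sweeps) {
    double prev = best;
    for (int e = 0; e < ne; ++e) {
      double fbest;
      auto f = [&](double x) { en[e] = x; return -td.loglik(en); };
      double x = brent_min(f, 0.0, n_max, 1e-7, &fbest);
      en[e] = x;
      best = -fbest;
    }
    if (best - prev < tol && sweeps > 0) { ++sweeps; break; }
  }
  return List::create(_["en"] = NumericVector(en.begin(), en.end()),
                      _["loglik"] = best, _["sweeps"] = sweeps);
}

// MAP per-branch rates with node ages fixed: maximises JC log-likelihood
// (branch n = r * t) plus independent lognormal log-densities on the rates.
// mu/sigma parameterise the underlying normal.
// [[Rcpp::export]]
List cpp_fit_rates(IntegerMatrix edge, NumericVector tdur, NumericVector r0,
                   IntegerMatrix tip, NumericVector w, double mu,
                   double sigma, double r_lo, double r_hi, double tol,
                   int max_sweeps) {
  TreeData td(edge, tip, w);
  const int ne = edge.nrow();
  std::vector<double> r(r0.begin(), r0.end());
  std::vector<double> en(ne);
  auto obj = [&]() {
    double lp = 0.0;
    for (int e = 0; e < ne; ++e) {
      en[e] = r[e] * tdur[e];
      double lr = std::log(r[e]);
      double z = (lr - mu) / sigma;
      lp += -lr - std::log(sigma) - 0.5 * std::log(2.0 * M_PI) - 0.5 * z * z;
    }
    return td.loglik(en) + lp;
  };
  double best = obj();
  int sweeps = 0;
  for (; sweeps < max_sweeps; ++sweeps) {
    double prev = best;
    for (int e = 0; e < ne; ++e) {
      double fbest;
      auto f = [&](double u) { r[e] = std::exp(u); return -obj(); };
      double u = brent_min(f, std::log(r_lo), std::log(r_hi), 1e-7, &fbest);
      r[e] = std::exp(u);
      best = -fbest;
    }
    if (best - prev < tol && sweeps > 0) { ++sweeps; break; }
  }
  return List::create(_["rates"] = NumericVector(r.begin(), r.end()),
                      _["objective"] = best, _["sweeps"] = sweeps);
}
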