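// Batch Monte Carlo kernels for tabular toy models.
//
// These reproduce, generation for generation and uniform for uniform, the
// RNG-consumption order of the reference R decoding loops
// (speculative_generate / baseline_generate): draft draws in position
// order, acceptance uniforms in position order, then the residual draw,
// then the bonus draw. Long-double accumulation mirrors R's sum()/cumsum()
// so warped probabilities agree bitwise with warp_logits(). A property
// test asserts token-identity against the R path under shared seeds; the
// kernels exist solely to make 10^5-generation goodness-of-fit runs cheap.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Warper {
  double temperature;
  int top_k;      // 0 = off
  double top_p;   // 0 = off
  bool greedy;
  std::vector<int> idx;

  void warp(std::vector<double>& z) {
    const int V = (int)z.size();
    if (greedy) {
      int am = 0;
      for (int i = 1; i < V; ++i) if (z[i] > z[am]) am = i;
      std::fill(z.begin(), z.end(), 0.0);
      z[am] = 1.0;
      return;
    }
    double mx = z[0] / temperature;
    for (int i = 0; i < V; ++i) {
      z[i] = z[i] / temperature;
      if (z[i] > mx) mx = z[i];
    }
    long double s = 0.0L;
    for (int i = 0; i < V; ++i) {
      z[i] = std::exp(z[i] - mx);
      s += z[i];
    }
    for (int i = 0; i < V; ++i) z[i] = z[i] / (double)s;
    if (top_k > 0 && top_k < V) {
      stable_desc(z);
      for (int r = top_k; r < V; ++r) z[idx[r]] = 0.0;
    }
    if (top_p > 0.0 && top_p < 1.0) {
      stable_desc(z);
      long double cum = 0.0L, total = 0.0L;
      for (int r = 0; r < V; ++r) total += z[idx[r]];
      double thr = std::min(top_p, (double)total);
      int cut = V - 1;
      for (int r = 0; r < V; ++r) {
        cum += z[idx[r]];
        if ((double)cum >= thr) { cut = r; break; }
      }
      for (int r = cut + 1; r < V; ++r) z[idx[r]] = 0.0;
    }
    long double s2 = 0.0L;
    for (int i = 0; i < V; ++i) s2 += z[i];
    for (int i = 0; i < V; ++i) z[i] = z[i] / (double)s2;
  }

  void stable_desc(const std::vector<double>& p) {
    const int V = (int)p.size();
    idx.resize(V);
    for (int i = 0; i < V; ++i) idx[i] = i;
    std::stable_sort(idx.begin(), idx.end(),
                     [&p](int a, int b) { return p[a] > p[b]; });
  }
};

// one uniform per draw; semantics identical to sample_categorical()
int sample_cat(const std::vector<double>& p) {
  const int V = (int)p.size();
  double u = unif_rand();
  long double cum = 0.0L;
  int id = V;  // falls through if u lands past the accumulated mass
  for (int i = 0; i < V; ++i) {
    cum += p[i];
    if (u < (double)cum) { id = i; break; }
  }
  if (id >= V || p[id] <= 0.0) {
    int pick = -1;
    for (int i = (id >= V ? V - 1 : id); i < V; ++i)
      if (p[i] > 0.0) { pick = i; break; }
    if (pick < 0)
      for (int i = V - 1; i >= 0; --i) if (p[i] > 0.0) { pick = i; break; }
    id = pick;
  }
  return id;  // 0-based
}

struct TabModel {
  std::vector<NumericMatrix> log_tables;  // context length 0..order
  int order;
  int vocab;

  TabModel(List lt, int ord, int V) : order(ord), vocab(V) {
    for (int j = 0; j <= ord; ++j)
      log_tables.push_back(as<NumericMatrix>(lt[j]));
  }

  // log-probability row conditioning the token after ids[0..pos-1]
  void row(const std::vector<int>& ids, int pos, std::vector<double>& out) {
    int j = std::min(pos, order);
    int r = 0;
    for (int t = pos - j; t < pos; ++t) r = r * vocab + ids[t];
    const NumericMatrix& tab = log_tables[j];
    for (int c = 0; c < vocab; ++c) out[c] = tab(r, c);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_tabular_speculative_batch(List t_logtab, int t_order,
                                   List d_logtab, int d_order, int vocab,
                                   IntegerVector prompt, int n_reps,
                                   int horizon, int L, double temperature,
                                   int top_k, double top_p, bool greedy,
                                   bool bonus, bool always_accept) {
  TabModel tgt(t_logtab, t_order, vocab), drf(d_logtab, d_order, vocab);
  Warper w{temperature, top_k, top_p, greedy, {}};
  IntegerMatrix suff(n_reps, horizon);
  IntegerVector n_prop(n_reps), n_acc_out(n_reps);
  std::vector<double> z(vocab), res(vocab);
  std::vector<std::vector<double>> pd(L, std::vector<double>(vocab));
  std::vector<std::vector<double>> pt(L + 1, std::vector<double>(vocab));
  const int P0 = prompt.size();
  std::vector<int> ids;
  RNGScope scope;

  for (int rep = 0; rep < n_reps; ++rep) {
    ids.assign(prompt.begin(), prompt.end());
    for (int i = 0; i < P0; ++i) ids[i] -= 1;  // to 0-based
    int n_gen = 0, tot_prop = 0, tot_acc = 0;
    while (n_gen < horizon) {
      int Lr = std::min(L, horizon - n_gen);
      int P = (int)ids.size();
      // propose: draft samples Lr tokens from its warped distributions
      for (int j = 0; j < Lr; ++j) {
        drf.row(ids, (int)ids.size(), z);
        w.warp(z);
        pd[j] = z;
        ids.push_back(sample_cat(z));
      }
      // verify: warped target distributions for each span position + post
      for (int i = 0; i <= Lr; ++i) {
        tgt.row(ids, P + i, z);
        w.warp(z);
        pt[i] = z;
      }
      // accept/reject scan
      int n_acc = Lr;
      int repl = -1;
      if (!always_accept) {
        for (int i = 0; i < Lr; ++i) {
          int x = ids[P + i];
          double a = pt[i][x] / pd[i][x];
          if (unif_rand() >= a) {
            long double m = 0.0L;
            for (int c = 0; c < vocab; ++c) {
              res[c] = pt[i][c] - pd[i][c];
              if (res[c] < 0.0) res[c] = 0.0;
              m += res[c];
            }
            if ((double)m < 1e-12) res = pt[i];
            else for (int c = 0; c < vocab; ++c) res[c] /= (double)m;
            n_acc = i;
            repl = sample_cat(res);
            break;
          }
        }
      }
      tot_prop += Lr;
      tot_acc += n_acc;
      if (repl < 0) {  // full acceptance
        n_gen += Lr;
        if (bonus && n_gen < horizon) {
          ids.push_back(sample_cat(pt[Lr]));
          n_gen += 1;
        }
      } else {
        ids.resize(P + n_acc);
        ids.push_back(repl);
        n_gen += n_acc + 1;
      }
    }
    for (int t = 0; t < horizon; ++t) suff(rep, t) = ids[P0 + t] + 1;
    n_prop[rep] = tot_prop;
    n_acc_out[rep] = tot_acc;
  }
  return List::create(_["suffixes"] = suff, _["n_proposed"] = n_prop,
                      _["n_accepted"] = n_acc_out);
}

// [[Rcpp::export]]
IntegerMatrix cpp_tabular_baseline_batch(List t_logtab, int t_order,
                                         int vocab, IntegerVector prompt,
                                         int n_reps, int horizon,
                                         double temperature, int top_k,
                                         double top_p, bool greedy) {
  TabModel tgt(t_logtab, t_order, vocab);
  Warper w{temperature, top_k, top_p, greedy, {}};
  IntegerMatrix suff(n_reps, horizon);
  std::vector<double> z(vocab);
  const int P0 = prompt.size();
  std::vector<int> ids;
  RNGScope scope;

  for (int rep = 0; rep < n_reps; ++rep) {
    ids.assign(prompt.begin(), prompt.end());
    for (int i = 0; i < P0; ++i) ids[i] -= 1;
    for (int t = 0; t < horizon; ++t) {
      tgt.row(ids, (int)ids.size(), z);
      w.warp(z);
      ids.push_back(sample_cat(z));
    }
    for (int t = 0; t < horizon; ++t) suff(rep, t) = ids[P0 + t] + 1;
  }
  return suff;
}
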