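#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Flow centrality by BFS predecessor-DAG accumulation (Brandes-style),
// restricted to ordered source-target pairs (s in src, t in tgt).
//
// For one BFS rooted at s, processing nodes in reverse BFS order:
//   delta(v) = sum_{w : v in pred(w)} sigma(v)/sigma(w) * ([w in T, w != s] + delta(w))
// gives delta(v) = sum_{t in T} sigma_st(v)/sigma_st with v strictly interior.
// A parallel accumulation over absolute counts,
//   cont(v) = sum_{w : v in pred(w)} ([w in T, w != s] + cont(w)),
// counts geodesic suffixes from v to any target, so sigma(v)*cont(v) is the
// number of s->T geodesics with v interior (the node's path support).
//
// adj: 0-based adjacency list; src, tgt: 0-based node indices.
// Returns fc normalized by |src|*|tgt| and the raw support counts.
// [[Rcpp::export(name = ".fcBrandes")]]
List fcBrandes(List adj, IntegerVector src, IntegerVector tgt) {
    const int n = adj.size();
    std::vector< std::vector<int> > A(n);
    for (int i = 0; i < n; ++i) A[i] = as< std::vector<int> >(adj[i]);

    std::vector<char> isT(n, 0);
    for (int i = 0; i < tgt.size(); ++i) isT[tgt[i]] = 1;

    NumericVector fc(n), support(n);
    std::vector<int> dist(n), order, queue(n);
    std::vector<double> sigma(n), delta(n), cont(n);
    std::vector< std::vector<int> > pred(n);
    order.reserve(n);

    for (int si = 0; si < src.size(); ++si) {
        const int s = src[si];
        std::fill(dist.begin(), dist.end(), -1);
        std::fill(sigma.begin(), sigma.end(), 0.0);
        std::fill(delta.begin(), delta.end(), 0.0);
        std::fill(cont.begin(), cont.end(), 0.0);
        for (int i = 0; i < n; ++i) pred[i].clear();
        order.clear();

        int qh = 0, qt = 0;
        dist[s] = 0; sigma[s] = 1.0; queue[qt++] = s;
        while (qh < qt) {
            const int v = queue[qh++];
            order.push_back(v);
            for (size_t j = 0; j < A[v].size(); ++j) {
                const int w = A[v][j];
                if (dist[w] < 0) { dist[w] = dist[v] + 1; queue[qt++] = w; }
                if (dist[w] == dist[v] + 1) {
                    sigma[w] += sigma[v];
                    pred[w].push_back(v);
                }
            }
        }
        for (int i = (int)order.size() - 1; i >= 0; --i) {
            const int w = order[i];
            const double inj = (isT[w] && w != s) ? 1.0 : 0.0;
            const double dcoef = inj + delta[w];
            const double ccoef = inj + cont[w];
            for (size_t j = 0; j < pred[w].size(); ++j) {
                const int v = pred[w][j];
                delta[v] += (sigma[v] / sigma[w]) * dcoef;
                cont[v]  += ccoef;
            }
            if (w != s) {
                fc[w] += delta[w];
                support[w] += sigma[w] * cont[w];
            }
        }
    }
    const double norm = (double)src.size() * (double)tgt.size();
    for (int i = 0; i < n; ++i) fc[i] /= norm;
    return List::create(_["fc"] = fc, _["support"] = support);
}
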