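#include <Rcpp.h>
#include <vector>
#include <queue>
#include <stack>

using namespace Rcpp;

// Unweighted all-pairs shortest-path lengths by repeated BFS.
// Returns hop counts; unreachable pairs are R_PosInf.
// [[Rcpp::export(name = ".bfs_distances_cpp")]]
NumericMatrix bfs_distances_cpp(const IntegerMatrix& adj) {
    const int n = adj.nrow();
    std::vector< std::vector<int> > nbr(n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            if (adj(i, j) != 0 && i != j) nbr[i].push_back(j);

    NumericMatrix d(n, n);
    std::fill(d.begin(), d.end(), R_PosInf);
    std::vector<int> dist(n);
    for (int s = 0; s < n; ++s) {
        std::fill(dist.begin(), dist.end(), -1);
        dist[s] = 0;
        std::queue<int> q;
        q.push(s);
        while (!q.empty()) {
            int v = q.front(); q.pop();
            for (size_t k = 0; k < nbr[v].size(); ++k) {
                int w = nbr[v][k];
                if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
            }
        }
        for (int t = 0; t < n; ++t)
            if (dist[t] >= 0) d(s, t) = dist[t];
    }
    return d;
}

// Brandes betweenness centrality for an unweighted, undirected graph.
// Fractional shortest-path credit; each unordered (s,t) pair counted once;
// endpoints excluded.
// [[Rcpp::export(name = ".brandes_betweenness_cpp")]]
NumericVector brandes_betweenness_cpp(const IntegerMatrix& adj) {
    const int n = adj.nrow();
    std::vector< std::vector<int> > nbr(n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            if (adj(i, j) != 0 && i != j) nbr[i].push_back(j);

    NumericVector bc(n);
    std::vector<double> sigma(n), delta(n);
    std::vector<int> dist(n);
    std::vector< std::vector<int> > pred(n);

    for (int s = 0; s < n; ++s) {
        std::stack<int> order;
        for (int i = 0; i < n; ++i) { pred[i].clear(); sigma[i] = 0.0; dist[i] = -1; }
        sigma[s] = 1.0; dist[s] = 0;
        std::queue<int> q;
        q.push(s);
        while (!q.empty()) {
            int v = q.front(); q.pop();
            order.push(v);
            for (size_t k = 0; k < nbr[v].size(); ++k) {
                int w = nbr[v][k];
                if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
                if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
            }
        }
        std::fill(delta.begin(), delta.end(), 0.0);
        while (!order.empty()) {
            int w = order.top(); order.pop();
            for (size_t k = 0; k < pred[w].size(); ++k) {
                int v = pred[w][k];
                delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
            }
            if (w != s) bc[w] += delta[w];
        }
    }
    // Undirected: every unordered pair was visited from both endpoints.
    for (int i = 0; i < n; ++i) bc[i] /= 2.0;
    return bc;
}
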