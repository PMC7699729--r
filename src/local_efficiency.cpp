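#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Weighted local efficiency per node.
//
// For node i with neighbour set G_i (n_i = |G_i|), E(G_i) is the mean of
// 1/d(j,k) over ordered pairs j != k in G_i, with shortest paths confined to
// the subgraph induced by G_i.  Link lengths are 1 / (w / w_max), w_max taken
// over the full matrix, so every length is >= 1 and E lies in [0, 1].
// Disconnected pairs contribute 0; nodes with fewer than 2 neighbours get 0.
// With `inverse_lengths = false`, raw weights are used as lengths instead
// (the literal minimize-the-sum-of-weights reading).

// [[Rcpp::export(name = ".localEfficiencyCpp")]]
NumericVector local_efficiency_cpp(NumericMatrix W, bool inverse_lengths) {
    const int N = W.nrow();
    const double INF = std::numeric_limits<double>::infinity();
    double wmax = 0.0;
    for (int i = 0; i < N; ++i)
        for (int j = 0; j < N; ++j)
            if (W(i, j) > wmax) wmax = W(i, j);

    NumericVector eff(N);
    if (wmax == 0.0) return eff;   // empty graph: all efficiencies 0

    std::vector<int> nb;
    for (int i = 0; i < N; ++i) {
        nb.clear();
        for (int j = 0; j < N; ++j)
            if (j != i && W(i, j) > 0.0) nb.push_back(j);
        const int n = (int)nb.size();
        if (n < 2) { eff[i] = 0.0; continue; }

        // distance matrix of the induced subgraph
        std::vector<double> D((size_t)n * n, INF);
        for (int a = 0; a < n; ++a) {
            D[(size_t)a * n + a] = 0.0;
            for (int b = 0; b < n; ++b) {
                if (a == b) continue;
                double w = W(nb[a], nb[b]);
                if (w > 0.0)
                    D[(size_t)a * n + b] = inverse_lengths ? wmax / w : w;
            }
        }
        // Floyd-Warshall
        for (int k = 0; k < n; ++k)
            for (int a = 0; a < n; ++a) {
                double dak = D[(size_t)a * n + k];
                if (dak == INF) continue;
                for (int b = 0; b < n; ++b) {
                    double alt = dak + D[(size_t)k * n + b];
                    if (alt < D[(size_t)a * n + b]) D[(size_t)a * n + b] = alt;
                }
            }
        double s = 0.0;
        for (int a = 0; a < n; ++a)
            for (int b = 0; b < n; ++b) {
                if (a == b) continue;
                double d = D[(size_t)a * n + b];
                if (d < INF) s += 1.0 / d;
            }
        eff[i] = s / ((double)n * (n - 1));
    }
    return eff;
}
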