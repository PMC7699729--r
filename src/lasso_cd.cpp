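#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Cyclic coordinate descent for the Lasso on pre-standardized predictors.
//
// Minimizes (1/(2M)) * ||z - X b||^2 + lambda * ||b||_1, where every active
// column of X has mean 0 and x_j' x_j / M = 1 and z has mean 0.  Columns
// flagged inactive (constant in the training data) are pinned at 0.  Solves
// the whole descending lambda path with warm starts and an active-set
// strategy: full sweeps bring violators into the active set, inner sweeps
// iterate it until the largest coefficient update falls below `tol`.
// Coefficient-update stalling implies the KKT conditions hold to the same
// order; the largest KKT violation at each solution is returned alongside
// the path so callers can verify.

static inline double soft(double x, double t) {
    if (x > t) return x - t;
    if (x < -t) return x + t;
    return 0.0;
}

// One sweep over `cols`; returns the largest absolute coefficient change.
static double cd_cycle(const NumericMatrix& X, std::vector<double>& r,
                       std::vector<double>& b, const std::vector<int>& cols,
                       double lambda, int M) {
    double maxdel = 0.0;
    for (size_t c = 0; c < cols.size(); ++c) {
        int j = cols[c];
        const double* xj = &X(0, j);
        double rho = 0.0;
        for (int i = 0; i < M; ++i) rho += xj[i] * r[i];
        rho = rho / M + b[j];          // partial residual correlation
        double bnew = soft(rho, lambda);
        double del = bnew - b[j];
        if (del != 0.0) {
            for (int i = 0; i < M; ++i) r[i] -= del * xj[i];
            b[j] = bnew;
            double a = std::fabs(del);
            if (a > maxdel) maxdel = a;
        }
    }
    return maxdel;
}

static double kkt_violation(const NumericMatrix& X, const std::vector<double>& r,
                            const std::vector<double>& b,
                            const std::vector<int>& cols, double lambda, int M) {
    double worst = 0.0;
    for (size_t c = 0; c < cols.size(); ++c) {
        int j = cols[c];
        const double* xj = &X(0, j);
        double g = 0.0;
        for (int i = 0; i < M; ++i) g += xj[i] * r[i];
        g /= M;
        double v = (b[j] == 0.0) ? std::max(0.0, std::fabs(g) - lambda)
                                 : std::fabs(std::fabs(g) - lambda);
        if (v > worst) worst = v;
    }
    return worst;
}

// [[Rcpp::export(name = ".lassoPathCpp")]]
List lasso_path_cpp(NumericMatrix X, NumericVector z, NumericVector lambdas,
                    LogicalVector active, double tol, int max_iter) {
    const int M = X.nrow(), P = X.ncol(), L = lambdas.size();
    std::vector<int> cols;
    cols.reserve(P);
    for (int j = 0; j < P; ++j) if (active[j]) cols.push_back(j);

    std::vector<double> b(P, 0.0), r(z.begin(), z.end());
    NumericMatrix beta(P, L);
    NumericVector kkt(L);

    for (int l = 0; l < L; ++l) {
        double lambda = lambdas[l];
        int it = 0;
        while (it < max_iter) {
            // full sweep over all columns (admits new nonzeros)
            double d = cd_cycle(X, r, b, cols, lambda, M);
            ++it;
            if (d < tol) break;
            // sweeps restricted to the current nonzero set
            std::vector<int> act;
            act.reserve(cols.size());
            for (size_t c = 0; c < cols.size(); ++c)
                if (b[cols[c]] != 0.0) act.push_back(cols[c]);
            while (it < max_iter) {
                double da = cd_cycle(X, r, b, act, lambda, M);
                ++it;
                if (da < tol) break;
            }
        }
        for (int j = 0; j < P; ++j) beta(j, l) = b[j];
        kkt[l] = kkt_violation(X, r, b, cols, lambda, M);
    }
    return List::create(Named("beta") = beta, Named("kkt") = kkt);
}
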