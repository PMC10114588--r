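#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Average-tie ranks of every column. The iterative Spearman classifier
// re-ranks tens of thousands of reference cells per elimination round, so
// this is the package's single hottest operation.
// [[Rcpp::export(name = ".colRanksCpp")]]
NumericMatrix colRanksCpp(const NumericMatrix& x) {
    const int g = x.nrow(), n = x.ncol();
    NumericMatrix out(g, n);
    std::vector<int> idx(g);
    for (int j = 0; j < n; ++j) {
        const double* col = &x(0, j);
        for (int i = 0; i < g; ++i) idx[i] = i;
        std::sort(idx.begin(), idx.end(),
                  [&](int a, int b) { return col[a] < col[b]; });
        int i = 0;
        while (i < g) {
            int k = i;
            while (k + 1 < g && col[idx[k + 1]] == col[idx[i]]) ++k;
            const double avg = 0.5 * (i + k) + 1.0;   // mean of ranks i+1..k+1
            for (int t = i; t <= k; ++t) out(idx[t], j) = avg;
            i = k + 1;
        }
    }
    return out;
}

// Row medians of selected columns (0-based handled in R wrapper; idx is
// 1-based here). Used for the per-type discriminative gene scores.
// [[Rcpp::export(name = ".rowMediansCpp")]]
NumericVector rowMediansCpp(const NumericMatrix& x, const IntegerVector& idx) {
    const int g = x.nrow(), m = idx.size();
    NumericVector out(g);
    std::vector<double> buf(m);
    for (int i = 0; i < g; ++i) {
        for (int k = 0; k < m; ++k) buf[k] = x(i, idx[k] - 1);
        const int h = m / 2;
        std::nth_element(buf.begin(), buf.begin() + h, buf.end());
        double med = buf[h];
        if (m % 2 == 0) {
            const double lo = *std::max_element(buf.begin(), buf.begin() + h);
            med = 0.5 * (med + lo);
        }
        out[i] = med;
    }
    return out;
}

// Linear-interpolation (type 7) quantile of every column.
// [[Rcpp::export(name = ".colQuantileCpp")]]
NumericVector colQuantileCpp(const NumericMatrix& x, const double p) {
    const int g = x.nrow(), n = x.ncol();
    NumericVector out(n);
    std::vector<double> buf(g);
    for (int j = 0; j < n; ++j) {
        for (int i = 0; i < g; ++i) buf[i] = x(i, j);
        const double h = (g - 1) * p;
        const int lo = static_cast<int>(std::floor(h));
        std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
        const double vlo = buf[lo];
        if (lo + 1 >= g) { out[j] = vlo; continue; }
        const double vhi = *std::min_element(buf.begin() + lo + 1, buf.end());
        out[j] = vlo + (h - lo) * (vhi - vlo);
    }
    return out;
}

// Column-standardize (mean 0, unit L2 after centering) for correlation via
// crossprod; zero-variance columns become all-zero.
// [[Rcpp::export(name = ".colStandardizeCpp")]]
NumericMatrix colStandardizeCpp(const NumericMatrix& x) {
    const int g = x.nrow(), n = x.ncol();
    NumericMatrix out(g, n);
    for (int j = 0; j < n; ++j) {
        const double* col = &x(0, j);
        double mean = 0.0;
        for (int i = 0; i < g; ++i) mean += col[i];
        mean /= g;
        double ss = 0.0;
        for (int i = 0; i < g; ++i) {
            const double d = col[i] - mean;
            out(i, j) = d;
            ss += d * d;
        }
        const double sc = ss < 1e-24 ? 0.0 : 1.0 / std::sqrt(ss);
        for (int i = 0; i < g; ++i) out(i, j) *= sc;
    }
    return out;
}
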