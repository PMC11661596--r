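#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Direct-form II transposed IIR filter, zero initial conditions.
// Coefficients are normalised by a[0] internally.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
    int nb = b.size(), na = a.size(), n = x.size();
    int nf = std::max(na, nb);
    if (nf < 1 || a[0] == 0.0) stop("invalid filter coefficients");
    std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
    for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
    for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
    NumericVector y(n);
    if (nf == 1) {
        for (int i = 0; i < n; ++i) y[i] = bb[0] * x[i];
        return y;
    }
    std::vector<double> z(nf - 1, 0.0);
    for (int i = 0; i < n; ++i) {
        double xi = x[i];
        double yi = bb[0] * xi + z[0];
        for (int j = 1; j < nf - 1; ++j)
            z[j - 1] = bb[j] * xi + z[j] - aa[j] * yi;
        z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
        y[i] = yi;
    }
    return y;
}

// 8-connected component labelling of a logical mask. Returns an integer
// matrix with 0 = background and components numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> stack;
    int cur = 0;
    const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            if (!mask(r, c) || lab(r, c) != 0) continue;
            ++cur;
            stack.clear();
            stack.push_back(r + c * nr);
            lab(r, c) = cur;
            while (!stack.empty()) {
                int idx = stack.back();
                stack.pop_back();
                int rr = idx % nr, cc = idx / nr;
                for (int k = 0; k < 8; ++k) {
                    int r2 = rr + dr[k], c2 = cc + dc[k];
                    if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
                    if (mask(r2, c2) && lab(r2, c2) == 0) {
                        lab(r2, c2) = cur;
                        stack.push_back(r2 + c2 * nr);
                    }
                }
            }
        }
    }
    return lab;
}
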