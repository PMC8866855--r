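#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Grayscale erosion with a non-flat structuring element given as offset lists
// (dy, dx) and heights h. Out-of-bounds offsets are skipped, so a constant
// image erodes to constant - max(h) everywhere (the SE centre must be in the
// offset list for that to hold; callers guarantee it).
// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(const NumericMatrix& img,
                             const IntegerVector& dy,
                             const IntegerVector& dx,
                             const NumericVector& h) {
    const int nr = img.nrow(), nc = img.ncol(), k = dy.size();
    NumericMatrix out(nr, nc);
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            double m = R_PosInf;
            for (int t = 0; t < k; ++t) {
                const int ii = i + dy[t], jj = j + dx[t];
                if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
                const double v = img(ii, jj) - h[t];
                if (v < m) m = v;
            }
            out(i, j) = m;
        }
    }
    return out;
}

// Grayscale dilation adjoint to cpp_gray_erode (reflected SE applied here so
// erode-then-dilate with the same offset lists is a true opening).
// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& img,
                              const IntegerVector& dy,
                              const IntegerVector& dx,
                              const NumericVector& h) {
    const int nr = img.nrow(), nc = img.ncol(), k = dy.size();
    NumericMatrix out(nr, nc);
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            double m = R_NegInf;
            for (int t = 0; t < k; ++t) {
                const int ii = i - dy[t], jj = j - dx[t];
                if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
                const double v = img(ii, jj) + h[t];
                if (v > m) m = v;
            }
            out(i, j) = m;
        }
    }
    return out;
}

// Connected-component labeling under 4- or 8-connectivity. Labels are assigned
// in column-major scan order, so the result is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity) {
    const int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    static const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
    static const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
    const int nn = (connectivity == 8) ? 8 : 4;
    int next = 0;
    std::vector<int> stack;
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
            if (!mask(i, j) || lab(i, j) != 0) continue;
            ++next;
            lab(i, j) = next;
            stack.clear();
            stack.push_back(i + j * nr);
            while (!stack.empty()) {
                const int p = stack.back();
                stack.pop_back();
                const int pi = p % nr, pj = p / nr;
                for (int t = 0; t < nn; ++t) {
                    const int ii = pi + dy8[t], jj = pj + dx8[t];
                    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
                    if (mask(ii, jj) && lab(ii, jj) == 0) {
                        lab(ii, jj) = next;
                        stack.push_back(ii + jj * nr);
                    }
                }
            }
        }
    }
    return lab;
}
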