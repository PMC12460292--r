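#include <Rcpp.h>
#include "kdtree.h"

using namespace Rcpp;

// k nearest neighbours in `ref` for every row of `query`.
// Returns 1-based index matrix and distance matrix, nearest first.
// [[Rcpp::export(name = ".knn_search_cpp")]]
List knn_search_cpp(NumericMatrix ref, NumericMatrix query, int k) {
    const int n = ref.nrow(), m = query.nrow();
    if (k < 1) stop("k must be >= 1");
    if (k > n) stop("k exceeds number of reference points");
    KDTree3 tree(REAL(ref), n);
    IntegerMatrix idx(m, k);
    NumericMatrix dist(m, k);
    std::vector<KDTree3::Hit> hits;
    double q[3];
    for (int i = 0; i < m; ++i) {
        q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
        tree.knn(q, k, hits);
        for (int j = 0; j < k; ++j) {
            idx(i, j) = hits[j].idx + 1;
            dist(i, j) = std::sqrt(hits[j].d2);
        }
    }
    return List::create(_["idx"] = idx, _["dist"] = dist);
}
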