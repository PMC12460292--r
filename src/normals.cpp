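// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "kdtree.h"

using namespace Rcpp;

// Per-point unit normals for a 3-D point cloud, sign arbitrary.
//
// method 0 (quadratic): for each point, take the point plus its k nearest
// neighbours, build a PCA frame of that neighbourhood (least-variance axis is
// the local z), least-squares fit z = a x^2 + b y^2 + c xy + d x + e y + f in
// local coordinates centred at the query point, and evaluate the surface
// normal (-d, -e, 1) at the origin. Degenerate fits fall back to the
// covariance (PCA) normal and are flagged.
//
// method 1 (covariance): the PCA least-variance axis of the neighbourhood.
// [[Rcpp::export(name = ".estimate_normals_cpp")]]
List estimate_normals_cpp(NumericMatrix pts, int k, int method) {
    const int n = pts.nrow();
    if (n < k + 1) stop("cloud must have at least k + 1 points");
    KDTree3 tree(REAL(pts), n);

    arma::mat P(REAL(pts), n, 3, false, true);
    NumericMatrix normals(n, 3);
    LogicalVector fallback(n);
    NumericVector resid(n);

    std::vector<KDTree3::Hit> hits;
    const int m = k + 1;  // neighbourhood includes the query point itself

    arma::mat Q(m, 3), A(m, 6);
    arma::vec zv(m), coef;

    for (int i = 0; i < n; ++i) {
        double q[3] = {P(i, 0), P(i, 1), P(i, 2)};
        tree.knn(q, m, hits);
        for (int j = 0; j < m; ++j) {
            int pj = hits[j].idx;
            Q(j, 0) = P(pj, 0); Q(j, 1) = P(pj, 1); Q(j, 2) = P(pj, 2);
        }
        arma::rowvec ctr = arma::mean(Q, 0);
        arma::mat C = Q.each_row() - ctr;
        arma::mat cov = C.t() * C;
        arma::vec eval;
        arma::mat evec;
        bool ok = arma::eig_sym(eval, evec, cov);
        if (!ok) {
            normals(i, 0) = 0; normals(i, 1) = 0; normals(i, 2) = 1;
            fallback[i] = true;
            continue;
        }
        // eig_sym returns ascending eigenvalues: col 0 = local z (least variance)
        arma::vec e3 = evec.col(0), e1 = evec.col(2);
        arma::vec e2 = arma::cross(e3, e1);  // (e1, e2, e3) right-handed

        arma::vec nvec;
        bool used_fallback = (method == 1);
        double rms = 0.0;
        if (method == 0) {
            // local coordinates centred at the query point
            for (int j = 0; j < m; ++j) {
                arma::rowvec u = Q.row(j) - P.row(i);
                double x = arma::dot(u, e1), y = arma::dot(u, e2), z = arma::dot(u, e3);
                A(j, 0) = x * x; A(j, 1) = y * y; A(j, 2) = x * y;
                A(j, 3) = x;     A(j, 4) = y;     A(j, 5) = 1.0;
                zv(j) = z;
            }
            bool solved = arma::solve(coef, A, zv, arma::solve_opts::no_approx);
            if (solved && coef.is_finite()) {
                nvec = -coef(3) * e1 - coef(4) * e2 + e3;
                arma::vec r = A * coef - zv;
                rms = std::sqrt(arma::dot(r, r) / m);
            } else {
                used_fallback = true;
            }
        }
        if (used_fallback || method == 1) {
            nvec = e3;
            fallback[i] = (method == 0);
        }
        double len = arma::norm(nvec);
        if (!(len > 0) || !nvec.is_finite()) { nvec = e3; len = 1.0; fallback[i] = true; }
        nvec /= len;
        normals(i, 0) = nvec(0); normals(i, 1) = nvec(1); normals(i, 2) = nvec(2);
        resid[i] = rms;
    }
    return List::create(_["normals"] = normals, _["fallback"] = fallback,
                        _["residual_rms"] = resid);
}
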