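#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Marching tetrahedra over a regular grid scalar field. The isosurface is the
// zero level set of `field`; negative values are inside the solid. Each grid
// cube is split into six tetrahedra around the (0,0,0)-(1,1,1) diagonal, a
// decomposition whose face diagonals match between adjacent cubes, so the
// extracted surface is closed wherever the zero set does not touch the grid
// boundary. Isosurface vertices on shared tetrahedron edges are welded via an
// edge-keyed map, and triangles are wound so face normals point toward
// positive field values (outside).

static const int TETS[6][4] = {
    {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
    {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

static const int CUBE_OFF[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

struct MeshAcc {
    std::vector<double> vx, vy, vz;
    std::vector<int> f0, f1, f2;
    std::unordered_map<std::uint64_t, int> edge_vertex;
};

// [[Rcpp::export(name = ".marching_tetra_cpp")]]
List marching_tetra_cpp(NumericVector field, IntegerVector dims,
                        NumericVector origin, double h) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double* G = REAL(field);
    auto nid = [&](int ix, int iy, int iz) -> std::int64_t {
        return ix + static_cast<std::int64_t>(nx) * (iy + static_cast<std::int64_t>(ny) * iz);
    };
    auto coord = [&](std::int64_t id, double* p) {
        std::int64_t ix = id % nx, rem = id / nx;
        std::int64_t iy = rem % ny, iz = rem / ny;
        p[0] = origin[0] + h * ix;
        p[1] = origin[1] + h * iy;
        p[2] = origin[2] + h * iz;
    };

    MeshAcc acc;
    acc.edge_vertex.reserve(1 << 16);

    // interpolated vertex on grid edge (a, b); welded by sorted key
    auto edge_point = [&](std::int64_t a, std::int64_t b) -> int {
        if (a > b) std::swap(a, b);
        std::uint64_t key = (static_cast<std::uint64_t>(a) << 32) |
                            static_cast<std::uint64_t>(b & 0xffffffff);
        auto it = acc.edge_vertex.find(key);
        if (it != acc.edge_vertex.end()) return it->second;
        double ga = G[a], gb = G[b];
        double t = ga / (ga - gb);
        double pa[3], pb[3];
        coord(a, pa);
        coord(b, pb);
        acc.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
        acc.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
        acc.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
        int id = static_cast<int>(acc.vx.size()) - 1;
        acc.edge_vertex.emplace(key, id);
        return id;
    };

    auto vpos = [&](int v, double* p) {
        p[0] = acc.vx[v]; p[1] = acc.vy[v]; p[2] = acc.vz[v];
    };

    // append triangle (v0, v1, v2), winding so the normal has positive dot
    // with `dir` (inside -> outside direction of the parent tetrahedron)
    auto add_tri = [&](int v0, int v1, int v2, const double* dir) {
        double p0[3], p1[3], p2[3];
        vpos(v0, p0); vpos(v1, p1); vpos(v2, p2);
        double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
        double w[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
        double nrm[3] = {u[1] * w[2] - u[2] * w[1],
                         u[2] * w[0] - u[0] * w[2],
                         u[0] * w[1] - u[1] * w[0]};
        double d = nrm[0] * dir[0] + nrm[1] * dir[1] + nrm[2] * dir[2];
        if (d < 0) std::swap(v1, v2);
        acc.f0.push_back(v0); acc.f1.push_back(v1); acc.f2.push_back(v2);
    };

    std::int64_t corner[8];
    for (int iz = 0; iz < nz - 1; ++iz) {
        for (int iy = 0; iy < ny - 1; ++iy) {
            for (int ix = 0; ix < nx - 1; ++ix) {
                bool any_neg = false, any_pos = false;
                for (int c = 0; c < 8; ++c) {
                    corner[c] = nid(ix + CUBE_OFF[c][0], iy + CUBE_OFF[c][1],
                                    iz + CUBE_OFF[c][2]);
                    (G[corner[c]] < 0 ? any_neg : any_pos) = true;
                }
                if (!any_neg || !any_pos) continue;
                for (int t = 0; t < 6; ++t) {
                    std::int64_t tv[4];
                    bool neg[4];
                    int nneg = 0;
                    for (int c = 0; c < 4; ++c) {
                        tv[c] = corner[TETS[t][c]];
                        neg[c] = G[tv[c]] < 0;
                        if (neg[c]) ++nneg;
                    }
                    if (nneg == 0 || nneg == 4) continue;
                    // inside -> outside direction from corner centroids
                    double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0}, pc[3];
                    for (int c = 0; c < 4; ++c) {
                        coord(tv[c], pc);
                        double* tgt = neg[c] ? ci : co;
                        tgt[0] += pc[0]; tgt[1] += pc[1]; tgt[2] += pc[2];
                    }
                    double dir[3] = {co[0] / (4 - nneg) - ci[0] / nneg,
                                     co[1] / (4 - nneg) - ci[1] / nneg,
                                     co[2] / (4 - nneg) - ci[2] / nneg};
                    if (nneg == 1 || nneg == 3) {
                        int lone = -1;
                        bool lone_neg = (nneg == 1);
                        for (int c = 0; c < 4; ++c)
                            if (neg[c] == lone_neg) lone = c;
                        int e[3], j = 0;
                        for (int c = 0; c < 4; ++c)
                            if (c != lone) e[j++] = edge_point(tv[lone], tv[c]);
                        add_tri(e[0], e[1], e[2], dir);
                    } else {
                        // 2 vs 2: quad with corners on the four mixed edges
                        int a0 = -1, a1 = -1, b0 = -1, b1 = -1;
                        for (int c = 0; c < 4; ++c) {
                            if (neg[c]) { if (a0 < 0) a0 = c; else a1 = c; }
                            else        { if (b0 < 0) b0 = c; else b1 = c; }
                        }
                        int q00 = edge_point(tv[a0], tv[b0]);
                        int q01 = edge_point(tv[a0], tv[b1]);
                        int q10 = edge_point(tv[a1], tv[b0]);
                        int q11 = edge_point(tv[a1], tv[b1]);
                        // quad ring q00-q01-q11-q10 split along q00-q11
                        add_tri(q00, q01, q11, dir);
                        add_tri(q00, q11, q10, dir);
                    }
                }
            }
        }
    }

    const int nv = static_cast<int>(acc.vx.size());
    const int nf = static_cast<int>(acc.f0.size());
    NumericMatrix V(nv, 3);
    IntegerMatrix F(nf, 3);
    for (int i = 0; i < nv; ++i) {
        V(i, 0) = acc.vx[i]; V(i, 1) = acc.vy[i]; V(i, 2) = acc.vz[i];
    }
    for (int i = 0; i < nf; ++i) {
        F(i, 0) = acc.f0[i] + 1; F(i, 1) = acc.f1[i] + 1; F(i, 2) = acc.f2[i] + 1;
    }
    return List::create(_["vertices"] = V, _["faces"] = F);
}
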