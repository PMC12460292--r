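#include <Rcpp.h>
#include <cstdint>

using namespace Rcpp;

static inline std::int64_t node_id(int ix, int iy, int iz, int nx, int ny) {
    return ix + static_cast<std::int64_t>(nx) * (iy + static_cast<std::int64_t>(ny) * iz);
}

// Trilinear splat of a per-point vector field (the oriented normals) onto a
// regular grid. Returns three numeric vectors of length nx*ny*nz, column-major.
// [[Rcpp::export(name = ".splat_vectors_cpp")]]
List splat_vectors_cpp(NumericMatrix pts, NumericMatrix vec,
                       NumericVector origin, double h, IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const std::int64_t nn = static_cast<std::int64_t>(nx) * ny * nz;
    NumericVector vx(nn), vy(nn), vz(nn);
    const int n = pts.nrow();
    for (int i = 0; i < n; ++i) {
        double gx = (pts(i, 0) - origin[0]) / h;
        double gy = (pts(i, 1) - origin[1]) / h;
        double gz = (pts(i, 2) - origin[2]) / h;
        int ix = static_cast<int>(std::floor(gx));
        int iy = static_cast<int>(std::floor(gy));
        int iz = static_cast<int>(std::floor(gz));
        if (ix < 0 || iy < 0 || iz < 0 || ix >= nx - 1 || iy >= ny - 1 || iz >= nz - 1)
            stop("point outside splat grid");
        double fx = gx - ix, fy = gy - iy, fz = gz - iz;
        for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                    double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                    std::int64_t id = node_id(ix + dx, iy + dy, iz + dz, nx, ny);
                    vx[id] += w * vec(i, 0);
                    vy[id] += w * vec(i, 1);
                    vz[id] += w * vec(i, 2);
                }
    }
    return List::create(_["vx"] = vx, _["vy"] = vy, _["vz"] = vz);
}

// Trilinear interpolation of a scalar grid field at arbitrary points.
// [[Rcpp::export(name = ".trilinear_interp_cpp")]]
NumericVector trilinear_interp_cpp(NumericVector field, IntegerVector dims,
                                   NumericVector origin, double h,
                                   NumericMatrix pts) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int n = pts.nrow();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        double gx = (pts(i, 0) - origin[0]) / h;
        double gy = (pts(i, 1) - origin[1]) / h;
        double gz = (pts(i, 2) - origin[2]) / h;
        int ix = static_cast<int>(std::floor(gx));
        int iy = static_cast<int>(std::floor(gy));
        int iz = static_cast<int>(std::floor(gz));
        if (ix < 0) { ix = 0; gx = 0; }
        if (iy < 0) { iy = 0; gy = 0; }
        if (iz < 0) { iz = 0; gz = 0; }
        if (ix > nx - 2) { ix = nx - 2; gx = nx - 1; }
        if (iy > ny - 2) { iy = ny - 2; gy = ny - 1; }
        if (iz > nz - 2) { iz = nz - 2; gz = nz - 1; }
        double fx = gx - ix, fy = gy - iy, fz = gz - iz;
        double acc = 0.0;
        for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                    double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                    acc += w * field[node_id(ix + dx, iy + dy, iz + dz, nx, ny)];
                }
        out[i] = acc;
    }
    return out;
}
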