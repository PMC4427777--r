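#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Linear index for a voxel in an nx * ny * nz grid (column-major, 0-based).
static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// Binary erosion: a voxel survives iff every structuring-element translate
// stays inside the grid and lands on foreground (outside == background).
// [[Rcpp::export]]
LogicalVector morph_erode(const LogicalVector& mask, const IntegerVector& dim,
                          const IntegerMatrix& off) {
    const int nx = dim[0], ny = dim[1], nz = dim[2], K = off.nrow();
    LogicalVector out(mask.size());
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                const R_xlen_t i = idx3(x, y, z, nx, ny);
                if (!mask[i]) { out[i] = FALSE; continue; }
                bool keep = true;
                for (int k = 0; k < K; ++k) {
                    const int xx = x + off(k, 0), yy = y + off(k, 1), zz = z + off(k, 2);
                    if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz ||
                        !mask[idx3(xx, yy, zz, nx, ny)]) { keep = false; break; }
                }
                out[i] = keep;
            }
    return out;
}

// Binary dilation: a voxel is set iff any structuring-element translate hits
// input foreground (the element is symmetric, so v+o and v-o are equivalent).
// [[Rcpp::export]]
LogicalVector morph_dilate(const LogicalVector& mask, const IntegerVector& dim,
                           const IntegerMatrix& off) {
    const int nx = dim[0], ny = dim[1], nz = dim[2], K = off.nrow();
    LogicalVector out(mask.size());
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                const R_xlen_t i = idx3(x, y, z, nx, ny);
                bool hit = false;
                for (int k = 0; k < K; ++k) {
                    const int xx = x + off(k, 0), yy = y + off(k, 1), zz = z + off(k, 2);
                    if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz &&
                        mask[idx3(xx, yy, zz, nx, ny)]) { hit = true; break; }
                }
                out[i] = hit;
            }
    return out;
}

// Connected-component labelling by breadth-first flood fill. Components are
// numbered in order of discovery while scanning in raster order; relabelling
// by size is done on the R side. `off` holds the neighbour offsets for the
// requested connectivity (6, 18 or 26), excluding the origin.
// [[Rcpp::export]]
IntegerVector morph_label(const LogicalVector& mask, const IntegerVector& dim,
                          const IntegerMatrix& off) {
    const int nx = dim[0], ny = dim[1], nz = dim[2], K = off.nrow();
    IntegerVector lab(mask.size(), 0);
    int next = 0;
    std::queue<R_xlen_t> q;
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                const R_xlen_t i0 = idx3(x, y, z, nx, ny);
                if (!mask[i0] || lab[i0] != 0) continue;
                ++next;
                lab[i0] = next;
                q.push(i0);
                while (!q.empty()) {
                    const R_xlen_t i = q.front(); q.pop();
                    const int cz = (int)(i / ((R_xlen_t)nx * ny));
                    const int rem = (int)(i - (R_xlen_t)cz * nx * ny);
                    const int cy = rem / nx, cx = rem % nx;
                    for (int k = 0; k < K; ++k) {
                        const int xx = cx + off(k, 0), yy = cy + off(k, 1), zz = cz + off(k, 2);
                        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                            continue;
                        const R_xlen_t j = idx3(xx, yy, zz, nx, ny);
                        if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
                    }
                }
            }
    return lab;
}

// Trilinear interpolation of `vol` at 0-based voxel coordinates `pts` (n x 3).
// Points outside the grid evaluate to `outside`.
// [[Rcpp::export]]
NumericVector sample_trilinear(const NumericVector& vol, const IntegerVector& dim,
                               const NumericMatrix& pts, double outside) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = pts.nrow();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
        if (px < 0 || py < 0 || pz < 0 || px > nx - 1 || py > ny - 1 || pz > nz - 1) {
            out[i] = outside; continue;
        }
        int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
        if (x0 == nx - 1) --x0;
        if (y0 == ny - 1) --y0;
        if (z0 == nz - 1) --z0;
        if (nx == 1) x0 = 0;
        if (ny == 1) y0 = 0;
        if (nz == 1) z0 = 0;
        const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
                  z1 = std::min(z0 + 1, nz - 1);
        const double fx = px - x0, fy = py - y0, fz = pz - z0;
        const double c000 = vol[idx3(x0, y0, z0, nx, ny)], c100 = vol[idx3(x1, y0, z0, nx, ny)],
                     c010 = vol[idx3(x0, y1, z0, nx, ny)], c110 = vol[idx3(x1, y1, z0, nx, ny)],
                     c001 = vol[idx3(x0, y0, z1, nx, ny)], c101 = vol[idx3(x1, y0, z1, nx, ny)],
                     c011 = vol[idx3(x0, y1, z1, nx, ny)], c111 = vol[idx3(x1, y1, z1, nx, ny)];
        const double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx,
                     c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
        const double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
        out[i] = c0 * (1 - fz) + c1 * fz;
    }
    return out;
}

// Nearest-neighbour sampling at 0-based voxel coordinates; outside -> `outside`.
// [[Rcpp::export]]
NumericVector sample_nearest(const NumericVector& vol, const IntegerVector& dim,
                             const NumericMatrix& pts, double outside) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = pts.nrow();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const int x = (int)std::lround(pts(i, 0));
        const int y = (int)std::lround(pts(i, 1));
        const int z = (int)std::lround(pts(i, 2));
        out[i] = (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
                     ? outside
                     : vol[idx3(x, y, z, nx, ny)];
    }
    return out;
}
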