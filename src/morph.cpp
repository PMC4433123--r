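#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static inline void neighbour_offsets(int connectivity, std::vector<std::array<int,3>> &off) {
    off.clear();
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (connectivity == 6 && manh != 1) continue;
                off.push_back({dx, dy, dz});
            }
}

// Connected-component labelling of a 3-D binary volume (6 or 26
// connectivity). Components numbered 1..K in order of first (lexicographic)
// foreground voxel; background is 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, int connectivity) {
    IntegerVector dims = mask.attr("dim");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    IntegerVector lab(mask.length());
    lab.attr("dim") = dims;
    std::vector<std::array<int,3>> off;
    neighbour_offsets(connectivity, off);

    int next = 0;
    std::vector<R_xlen_t> stack;
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
                if (!mask[idx] || lab[idx]) continue;
                ++next;
                stack.clear();
                stack.push_back(idx);
                lab[idx] = next;
                while (!stack.empty()) {
                    const R_xlen_t cur = stack.back(); stack.pop_back();
                    const int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((R_xlen_t)nx * ny);
                    for (auto &d : off) {
                        const int ii = ci + d[0], jj = cj + d[1], kk = ck + d[2];
                        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
                        const R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
                        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
                    }
                }
            }
    return lab;
}

// Background voxels 6-connected to the volume border. Used for hole
// filling: holes are background voxels NOT reachable from the border.
// [[Rcpp::export]]
LogicalVector border_background_cpp(LogicalVector mask) {
    IntegerVector dims = mask.attr("dim");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    LogicalVector reach(mask.length());
    reach.attr("dim") = dims;
    std::vector<std::array<int,3>> off;
    neighbour_offsets(6, off);
    std::vector<R_xlen_t> stack;

    auto push_if = [&](int i, int j, int k) {
        const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[idx] && !reach[idx]) { reach[idx] = true; stack.push_back(idx); }
    };
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i)
                if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1)
                    push_if(i, j, k);

    while (!stack.empty()) {
        const R_xlen_t cur = stack.back(); stack.pop_back();
        const int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((R_xlen_t)nx * ny);
        for (auto &d : off) {
            const int ii = ci + d[0], jj = cj + d[1], kk = ck + d[2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            push_if(ii, jj, kk);
        }
    }
    return reach;
}
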