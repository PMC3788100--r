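#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 3D connected-component labelling of a logical mask under 6-, 18- or
// 26-connectivity. Returns an integer array of the same dimensions with
// 0 for background and 1..n_components for foreground, labelled in
// first-encounter (column-major scan) order.
// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims,
                                  int connectivity) {
    if (dims.size() != 3)
        stop("dims must have length 3");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n)
        stop("mask length does not match dims");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");

    // Neighbour offsets by Chebyshev shell: 6 = faces, 18 = faces+edges,
    // 26 = full cube.
    std::vector<int> dx, dy, dz;
    for (int cz = -1; cz <= 1; ++cz)
        for (int cy = -1; cy <= 1; ++cy)
            for (int cx = -1; cx <= 1; ++cx) {
                int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
                if (manh == 0) continue;
                if (connectivity == 6 && manh > 1) continue;
                if (connectivity == 18 && manh > 2) continue;
                dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
            }
    const size_t nnb = dx.size();

    IntegerVector labels(n, 0);
    labels.attr("dim") = dims;
    std::vector<R_xlen_t> stack;
    int current = 0;

    for (R_xlen_t start = 0; start < n; ++start) {
        if (!mask[start] || labels[start] != 0) continue;
        ++current;
        labels[start] = current;
        stack.clear();
        stack.push_back(start);
        while (!stack.empty()) {
            R_xlen_t v = stack.back();
            stack.pop_back();
            int x = (int)(v % nx);
            int y = (int)((v / nx) % ny);
            int z = (int)(v / ((R_xlen_t)nx * ny));
            for (size_t t = 0; t < nnb; ++t) {
                int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz)
                    continue;
                R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                if (mask[w] && labels[w] == 0) {
                    labels[w] = current;
                    stack.push_back(w);
                }
            }
        }
    }
    return labels;
}
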