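#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 3D connected-component labeling by breadth-first search. Components are
// labeled 1,2,... in order of their smallest linear index (x fastest, then y,
// then z), which makes the labeling deterministic and order-independent.

// [[Rcpp::export(name = ".label3dCpp")]]
IntegerVector label3dCpp(LogicalVector mask, IntegerVector dims,
                         int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");

    // neighbour offsets
    std::vector<std::array<int, 3>> offs;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                offs.push_back({dx, dy, dz});
            }

    IntegerVector labels(n, 0);
    std::vector<R_xlen_t> queue;
    int next = 0;

    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || labels[i] != 0) continue;
        ++next;
        labels[i] = next;
        queue.clear();
        queue.push_back(i);
        while (!queue.empty()) {
            R_xlen_t c = queue.back();
            queue.pop_back();
            int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / ((R_xlen_t)nx * ny));
            for (const auto &o : offs) {
                int ax = x + o[0], ay = y + o[1], az = z + o[2];
                if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
                    continue;
                R_xlen_t cc = ax + (R_xlen_t)nx * (ay + (R_xlen_t)ny * az);
                if (mask[cc] && labels[cc] == 0) {
                    labels[cc] = next;
                    queue.push_back(cc);
                }
            }
        }
    }
    labels.attr("n_objects") = next;
    return labels;
}
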