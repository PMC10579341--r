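#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Incremental engine for the modified Eden growth model: Eden surface growth
// plus rare Gaussian jumps of exposed cells, driven by an exact Gillespie loop.
//
// Uniform choices over the boundary-site set and the jumpable (N2) cell set are
// made in ascending encoded-site order (code = x + L*y + L*L*z, 0-based), via
// Fenwick-tree order statistics. The pure-R reference engine makes the same
// choices over sorted site vectors, so both engines consume R's RNG stream in
// an identical order and produce bit-identical event logs for a given seed.

namespace {

// Fenwick (binary indexed) tree over site codes supporting prefix sums and
// select-by-cumulative-weight in O(log n).
struct Fenwick {
    std::vector<int> tree;
    int n = 0;
    int top = 0; // largest power of two <= n

    void init(int n_) {
        n = n_;
        tree.assign((size_t)n + 1, 0);
        top = 1;
        while ((top << 1) <= n) top <<= 1;
    }
    void add(int i, int v) {
        for (++i; i <= n; i += i & -i) tree[(size_t)i] += v;
    }
    // smallest index idx with prefix_sum(0..idx) > k; k in [0, total)
    int select(int k) const {
        int idx = 0;
        for (int pw = top; pw; pw >>= 1) {
            int nxt = idx + pw;
            if (nxt <= n && tree[(size_t)nxt] <= k) {
                idx = nxt;
                k -= tree[(size_t)nxt];
            }
        }
        return idx; // 0-based site code
    }
};

struct Engine {
    int L;
    long long N;
    double k, ks, sigma;
    int n2MinEmpty;
    bool multiplicity; // boundary-site weighting by adjacency multiplicity
    int margin;

    std::vector<uint8_t> occ;     // occupancy
    std::vector<uint8_t> occNbr;  // # occupied face-neighbours
    std::vector<uint8_t> cls;     // 0 none, 1 N1, 2 N2, 3 enclosed cell
    std::vector<uint8_t> bw;      // current boundary weight of each site

    Fenwick bfen, n2fen;
    long long n1Count = 0, n2Count = 0, wTotal = 0, nCells = 0;

    // historical bounding box of every site ever occupied (monotone; the
    // truncation guard is deliberately conservative after jumps away)
    int lo[3], hi[3];

    inline int code(int x, int y, int z) const { return x + L * (y + L * z); }
    inline void coords(int c, int *xyz) const {
        xyz[0] = c % L; xyz[1] = (c / L) % L; xyz[2] = c / (L * L);
    }
    inline int walls(int x, int y, int z) const {
        return (x == 0) + (x == L - 1) + (y == 0) + (y == L - 1) +
               (z == 0) + (z == L - 1);
    }

    void init(int L_, double k_, double ks_, double sigma_, int n2MinEmpty_,
              bool multiplicity_, int margin_) {
        L = L_; N = (long long)L * L * L;
        k = k_; ks = ks_; sigma = sigma_;
        n2MinEmpty = n2MinEmpty_; multiplicity = multiplicity_; margin = margin_;
        occ.assign(N, 0); occNbr.assign(N, 0);
        cls.assign(N, 0); bw.assign(N, 0);
        bfen.init((int)N); n2fen.init((int)N);
        lo[0] = lo[1] = lo[2] = L; hi[0] = hi[1] = hi[2] = -1;
    }

    void setCellClass(int c, int x, int y, int z) {
        int e = 6 - walls(x, y, z) - occNbr[(size_t)c];
        uint8_t nc = (e == 0) ? 3 : (e >= n2MinEmpty ? 2 : 1);
        uint8_t oc = cls[(size_t)c];
        if (oc == nc) return;
        if (oc == 1) n1Count--;
        if (oc == 2) { n2Count--; n2fen.add(c, -1); }
        if (nc == 1) n1Count++;
        if (nc == 2) { n2Count++; n2fen.add(c, 1); }
        cls[(size_t)c] = nc;
    }

    void clearCellClass(int c) {
        uint8_t oc = cls[(size_t)c];
        if (oc == 1) n1Count--;
        if (oc == 2) { n2Count--; n2fen.add(c, -1); }
        cls[(size_t)c] = 0;
    }

    void updateBoundaryWeight(int c) {
        int tw = occ[(size_t)c] ? 0
                 : (multiplicity ? occNbr[(size_t)c] : (occNbr[(size_t)c] > 0));
        int d = tw - bw[(size_t)c];
        if (d != 0) {
            bfen.add(c, d);
            wTotal += d;
            bw[(size_t)c] = (uint8_t)tw;
        }
    }

    template <typename F> void forEachNeighbor(int x, int y, int z, F f) {
        if (x > 0) f(code(x - 1, y, z), x - 1, y, z);
        if (x < L - 1) f(code(x + 1, y, z), x + 1, y, z);
        if (y > 0) f(code(x, y - 1, z), x, y - 1, z);
        if (y < L - 1) f(code(x, y + 1, z), x, y + 1, z);
        if (z > 0) f(code(x, y, z - 1), x, y, z - 1);
        if (z < L - 1) f(code(x, y, z + 1), x, y, z + 1);
    }

    void addCell(int c) {
        int xyz[3]; coords(c, xyz);
        occ[(size_t)c] = 1;
        updateBoundaryWeight(c);
        forEachNeighbor(xyz[0], xyz[1], xyz[2], [&](int nc, int nx, int ny, int nz) {
            occNbr[(size_t)nc]++;
            if (occ[(size_t)nc]) setCellClass(nc, nx, ny, nz);
            else updateBoundaryWeight(nc);
        });
        setCellClass(c, xyz[0], xyz[1], xyz[2]);
        nCells++;
        for (int d = 0; d < 3; ++d) {
            if (xyz[d] < lo[d]) lo[d] = xyz[d];
            if (xyz[d] > hi[d]) hi[d] = xyz[d];
        }
    }

    void removeCell(int c) {
        int xyz[3]; coords(c, xyz);
        occ[(size_t)c] = 0;
        clearCellClass(c);
        forEachNeighbor(xyz[0], xyz[1], xyz[2], [&](int nc, int nx, int ny, int nz) {
            occNbr[(size_t)nc]--;
            if (occ[(size_t)nc]) setCellClass(nc, nx, ny, nz);
            else updateBoundaryWeight(nc);
        });
        updateBoundaryWeight(c);
        nCells--;
    }

    bool marginBreached() const {
        for (int d = 0; d < 3; ++d)
            if (lo[d] < margin || hi[d] > L - 1 - margin) return true;
        return false;
    }
};

inline double unifPositive() {
    double r;
    do { r = unif_rand(); } while (r <= 0.0);
    return r;
}

} // namespace

// [[Rcpp::export(name = ".edenRunCpp")]]
List edenRunCpp(int L, double k, double ks, double sigma, double maxEvents,
                int n2MinEmpty, bool multiplicity, int boundaryMargin,
                int redrawCap) {
    Engine eng;
    eng.init(L, k, ks, sigma, n2MinEmpty, multiplicity, boundaryMargin);

    RNGScope scope;

    int c0 = eng.code(L / 2, L / 2, L / 2);
    eng.addCell(c0);

    R_xlen_t cap = (R_xlen_t)maxEvents;
    std::vector<double> tVec, tauVec, Tvec;
    std::vector<int> typeVec, fromVec, toVec, popVec;
    tVec.reserve(cap); tauVec.reserve(cap); Tvec.reserve(cap);
    typeVec.reserve(cap); fromVec.reserve(cap); toVec.reserve(cap);
    popVec.reserve(cap);

    double t = 0.0;
    std::string status = "completed";
    long long nAborted = 0;

    for (R_xlen_t ev = 0; ev < cap; ++ev) {
        double T = (double)eng.n1Count * k + (double)eng.n2Count * (k + ks);
        if (T <= 0.0) { status = "jammed"; break; }

        double r = unifPositive();
        double tau = -std::log(r) / T;
        t += tau;

        double a = unif_rand();
        bool growth = (a <= (double)(eng.n1Count + eng.n2Count) * k / T);

        int type, from = NA_INTEGER, to = NA_INTEGER;
        if (growth) {
            double u = unif_rand();
            long long kk = (long long)(u * (double)eng.wTotal);
            if (kk >= eng.wTotal) kk = eng.wTotal - 1;
            int site = eng.bfen.select((int)kk);
            eng.addCell(site);
            type = 0; to = site;
        } else {
            double u = unif_rand();
            long long kk = (long long)(u * (double)eng.n2Count);
            if (kk >= eng.n2Count) kk = eng.n2Count - 1;
            int cell = eng.n2fen.select((int)kk);
            int xyz[3]; eng.coords(cell, xyz);
            int target = -1;
            for (int it = 0; it < redrawCap; ++it) {
                int tx = xyz[0] + (int)std::nearbyint(norm_rand() * sigma);
                int ty = xyz[1] + (int)std::nearbyint(norm_rand() * sigma);
                int tz = xyz[2] + (int)std::nearbyint(norm_rand() * sigma);
                if (tx < 0 || tx >= L || ty < 0 || ty >= L || tz < 0 || tz >= L)
                    continue; // outside the closed walls: counts as occupied
                int tc = eng.code(tx, ty, tz);
                if (eng.occ[(size_t)tc]) continue; // includes the origin itself
                target = tc;
                break;
            }
            from = cell;
            if (target >= 0) {
                eng.removeCell(cell);
                eng.addCell(target);
                type = 1; to = target;
            } else {
                type = 2; // aborted jump: state unchanged, clock advanced
                nAborted++;
            }
        }

        tVec.push_back(t); tauVec.push_back(tau); Tvec.push_back(T);
        typeVec.push_back(type); fromVec.push_back(from); toVec.push_back(to);
        popVec.push_back((int)eng.nCells);

        if (eng.marginBreached()) { status = "truncated"; break; }
    }

    // occupied sites, ascending code order
    IntegerMatrix sites((int)eng.nCells, 3);
    {
        int row = 0;
        for (long long c = 0; c < eng.N; ++c) {
            if (eng.occ[(size_t)c]) {
                int xyz[3]; eng.coords((int)c, xyz);
                sites(row, 0) = xyz[0]; sites(row, 1) = xyz[1]; sites(row, 2) = xyz[2];
                row++;
            }
        }
    }

    return List::create(
        _["sites"] = sites,
        _["t"] = t,
        _["n_cells"] = (double)eng.nCells,
        _["status"] = status,
        _["n_aborted"] = (double)nAborted,
        _["ev_t"] = wrap(tVec),
        _["ev_tau"] = wrap(tauVec),
        _["ev_T"] = wrap(Tvec),
        _["ev_type"] = wrap(typeVec),
        _["ev_from"] = wrap(fromVec),
        _["ev_to"] = wrap(toVec),
        _["ev_pop"] = wrap(popVec));
}
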