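#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// 3D convex hull by the quickhull algorithm, written from first principles.
// Exposes (a) the hull volume of an arbitrary point set and (b) the voxel
// count of the convex image of a voxel object -- the voxels whose centres lie
// inside the hull of the object's voxel centres -- which is the denominator
// of the solidity/convexity metric.

namespace {

struct Vec3 {
    double x, y, z;
};
inline Vec3 sub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
    return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
    int a, b, c;
    Vec3 n;       // outward normal (not normalized)
    double off;   // plane offset: dot(n, p) == off on the plane
    bool alive = true;
    std::vector<int> outside;
};

inline double faceDist(const Face &f, const Vec3 &p) { return dot(f.n, p) - f.off; }

Face makeFace(int a, int b, int c, const std::vector<Vec3> &P, const Vec3 &interior) {
    Face f;
    f.a = a; f.b = b; f.c = c;
    f.n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
    f.off = dot(f.n, P[a]);
    if (dot(f.n, interior) - f.off > 0) { // flip so the interior is below
        std::swap(f.b, f.c);
        f.n = {-f.n.x, -f.n.y, -f.n.z};
        f.off = -f.off;
    }
    return f;
}

// builds the hull face list; returns false on degenerate input
bool buildHull(const std::vector<Vec3> &P, std::vector<Face> &faces,
               Vec3 &interiorOut, double &epsOut);

double quickhullVolume(const std::vector<Vec3> &P) {
    std::vector<Face> faces;
    Vec3 interior;
    double eps;
    if (!buildHull(P, faces, interior, eps)) return 0.0;
    double vol = 0.0;
    for (const auto &f : faces) {
        if (!f.alive) continue;
        Vec3 a = sub(P[f.a], interior), b = sub(P[f.b], interior),
             c = sub(P[f.c], interior);
        vol += std::fabs(dot(a, cross(b, c))) / 6.0;
    }
    return vol;
}

bool buildHull(const std::vector<Vec3> &P, std::vector<Face> &faces,
               Vec3 &interiorOut, double &epsOut) {
    const int n = (int)P.size();
    if (n < 4) return false;

    // bounding-box scale for tolerances
    Vec3 mn = P[0], mx = P[0];
    for (const auto &p : P) {
        mn.x = std::min(mn.x, p.x); mx.x = std::max(mx.x, p.x);
        mn.y = std::min(mn.y, p.y); mx.y = std::max(mx.y, p.y);
        mn.z = std::min(mn.z, p.z); mx.z = std::max(mx.z, p.z);
    }
    double scale = norm(sub(mx, mn));
    if (scale <= 0) return false;
    double eps = 1e-9 * scale;

    // initial simplex: two extreme points, farthest from the line, farthest
    // from the plane
    int i0 = 0, i1 = 0;
    for (int i = 1; i < n; ++i) {
        if (P[i].x < P[i0].x) i0 = i;
        if (P[i].x > P[i1].x) i1 = i;
    }
    if (i0 == i1) { // all x equal; fall back to y
        for (int i = 1; i < n; ++i) {
            if (P[i].y < P[i0].y) i0 = i;
            if (P[i].y > P[i1].y) i1 = i;
        }
    }
    if (norm(sub(P[i1], P[i0])) <= eps) return false;

    int i2 = -1;
    double best = eps;
    Vec3 d01 = sub(P[i1], P[i0]);
    for (int i = 0; i < n; ++i) {
        double dist = norm(cross(d01, sub(P[i], P[i0]))) / norm(d01);
        if (dist > best) { best = dist; i2 = i; }
    }
    if (i2 < 0) return false; // collinear

    int i3 = -1;
    best = eps;
    Vec3 nrm = cross(d01, sub(P[i2], P[i0]));
    double nn = norm(nrm);
    for (int i = 0; i < n; ++i) {
        double dist = std::fabs(dot(nrm, sub(P[i], P[i0]))) / nn;
        if (dist > best) { best = dist; i3 = i; }
    }
    if (i3 < 0) return false; // coplanar

    interiorOut = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                     (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                     (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};
    const Vec3 interior = interiorOut;

    faces.clear();
    faces.push_back(makeFace(i0, i1, i2, P, interior));
    faces.push_back(makeFace(i0, i1, i3, P, interior));
    faces.push_back(makeFace(i0, i2, i3, P, interior));
    faces.push_back(makeFace(i1, i2, i3, P, interior));

    // assign every point to the first face it lies strictly above
    for (int i = 0; i < n; ++i) {
        for (auto &f : faces) {
            if (faceDist(f, P[i]) > eps) { f.outside.push_back(i); break; }
        }
    }

    // expand
    for (;;) {
        int fi = -1;
        for (int i = 0; i < (int)faces.size(); ++i)
            if (faces[i].alive && !faces[i].outside.empty()) { fi = i; break; }
        if (fi < 0) break;

        // farthest outside point of this face
        int pi = -1;
        double d = -1.0;
        for (int idx : faces[fi].outside) {
            double dd = faceDist(faces[fi], P[idx]);
            if (dd > d) { d = dd; pi = idx; }
        }
        const Vec3 &p = P[pi];

        // all faces visible from p
        std::vector<int> visible;
        for (int i = 0; i < (int)faces.size(); ++i)
            if (faces[i].alive && faceDist(faces[i], p) > eps) visible.push_back(i);

        // horizon: undirected edges belonging to exactly one visible face
        std::unordered_map<int64_t, std::pair<int, int>> edgeCount;
        auto addEdge = [&](int a, int b) {
            int64_t key = ((int64_t)std::min(a, b) << 32) | (uint32_t)std::max(a, b);
            auto it = edgeCount.find(key);
            if (it == edgeCount.end()) edgeCount[key] = {1, a == std::min(a, b) ? 0 : 1};
            else it->second.first++;
        };
        for (int vi : visible) {
            addEdge(faces[vi].a, faces[vi].b);
            addEdge(faces[vi].b, faces[vi].c);
            addEdge(faces[vi].c, faces[vi].a);
        }

        // orphaned outside points
        std::vector<int> orphans;
        for (int vi : visible) {
            for (int idx : faces[vi].outside)
                if (idx != pi) orphans.push_back(idx);
            faces[vi].outside.clear();
            faces[vi].alive = false;
        }

        std::vector<int> fresh;
        for (const auto &kv : edgeCount) {
            if (kv.second.first != 1) continue;
            int a = (int)(kv.first >> 32);
            int b = (int)(kv.first & 0xffffffff);
            Face f = makeFace(a, b, pi, P, interior);
            faces.push_back(f);
            fresh.push_back((int)faces.size() - 1);
        }
        for (int idx : orphans) {
            for (int nf : fresh) {
                if (faceDist(faces[nf], P[idx]) > eps) {
                    faces[nf].outside.push_back(idx);
                    break;
                }
            }
        }
    }

    epsOut = eps;
    return true;
}

} // namespace

// [[Rcpp::export(name = ".hullVolumeCpp")]]
double hullVolumeCpp(NumericMatrix pts) {
    std::vector<Vec3> P(pts.nrow());
    for (int i = 0; i < pts.nrow(); ++i) P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    return quickhullVolume(P);
}

// Convex-image voxel count of an object given by 0-based integer voxel
// coordinates: the number of lattice points inside the convex hull of the
// object's voxel centres (working in index space; solidity is invariant
// under the anisotropic voxel scaling). Candidate hull points are pruned to
// per-(y,z)-column x extremes, and counting walks each column of the hull's
// bounding box, intersecting it with the face half-spaces.
// [[Rcpp::export(name = ".convexImageCountCpp")]]
List convexImageCountCpp(IntegerMatrix vox) {
    const int n = vox.nrow();
    if (n == 0) return List::create(_["n_hull"] = 0.0, _["degenerate"] = true);

    std::unordered_map<int64_t, std::pair<int, int>> cols;
    cols.reserve((size_t)n);
    int ylo = vox(0, 1), yhi = ylo, zlo = vox(0, 2), zhi = zlo;
    for (int i = 0; i < n; ++i) {
        int cy = vox(i, 1), cz = vox(i, 2);
        ylo = std::min(ylo, cy); yhi = std::max(yhi, cy);
        zlo = std::min(zlo, cz); zhi = std::max(zhi, cz);
        int64_t key = ((int64_t)cy << 32) | (uint32_t)cz;
        auto it = cols.find(key);
        if (it == cols.end()) cols[key] = {vox(i, 0), vox(i, 0)};
        else {
            it->second.first = std::min(it->second.first, vox(i, 0));
            it->second.second = std::max(it->second.second, vox(i, 0));
        }
    }
    std::vector<Vec3> P;
    P.reserve(cols.size() * 2);
    for (const auto &kv : cols) {
        double py = (double)(int)(kv.first >> 32);
        double pz = (double)(int)(kv.first & 0xffffffff);
        P.push_back({(double)kv.second.first, py, pz});
        if (kv.second.second != kv.second.first)
            P.push_back({(double)kv.second.second, py, pz});
    }

    std::vector<Face> faces;
    Vec3 interior;
    double eps;
    if (!buildHull(P, faces, interior, eps))
        return List::create(_["n_hull"] = (double)n, _["degenerate"] = true);

    // unit-normal planes for a geometric tolerance
    struct Plane { double nx, ny, nz, off; };
    std::vector<Plane> planes;
    for (const auto &f : faces) {
        if (!f.alive) continue;
        double ln = norm(f.n);
        if (ln <= 0) continue;
        planes.push_back({f.n.x / ln, f.n.y / ln, f.n.z / ln, f.off / ln});
    }
    const double tol = 1e-7;

    double count = 0.0;
    for (int z = zlo; z <= zhi; ++z) {
        for (int y = ylo; y <= yhi; ++y) {
            double xl = -1e300, xh = 1e300;
            bool feasible = true;
            for (const auto &pl : planes) {
                double c = pl.off + tol - pl.ny * y - pl.nz * z;
                if (pl.nx > tol) xh = std::min(xh, c / pl.nx);
                else if (pl.nx < -tol) xl = std::max(xl, c / pl.nx);
                else if (c < 0) { feasible = false; break; }
            }
            if (!feasible || xh < xl) continue;
            double lo = std::ceil(xl - 1e-9), hi = std::floor(xh + 1e-9);
            if (hi >= lo) count += hi - lo + 1.0;
        }
    }
    return List::create(_["n_hull"] = count, _["degenerate"] = false);
}
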