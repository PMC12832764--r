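#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8-neighbourhood offsets and chamfer step lengths
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const double SQ2 = 1.4142135623730951;
static const double STEP[8] = {SQ2, 1.0, SQ2, 1.0, 1.0, SQ2, 1.0, SQ2};

// [[Rcpp::export]]
LogicalMatrix cpp_flood_fill(LogicalMatrix blocked, int seed_row, int seed_col) {
    const int h = blocked.nrow(), w = blocked.ncol();
    if (seed_row < 0 || seed_row >= h || seed_col < 0 || seed_col >= w)
        stop("seed outside grid");
    if (blocked(seed_row, seed_col))
        stop("seed lies on a blocked pixel");
    LogicalMatrix out(h, w);
    std::vector<std::pair<int,int>> stack;
    stack.emplace_back(seed_row, seed_col);
    out(seed_row, seed_col) = true;
    while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (int k = 0; k < 8; ++k) {
            int nr = r + DR[k], nc = c + DC[k];
            if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
            if (out(nr, nc) || blocked(nr, nc)) continue;
            out(nr, nc) = true;
            stack.emplace_back(nr, nc);
        }
    }
    return out;
}

struct Cand {
    double v;        // intensity at the candidate pixel (flood high first)
    int r, c;        // candidate pixel
    double gd;       // geodesic (chamfer) distance accumulated from the seed
    int label;
    long long seq;   // push order, final determinism tie-break
};

// flood highest intensity first; ties by (row, col) of the candidate, then
// by push order — fully deterministic
struct CandLess {
    bool operator()(const Cand& a, const Cand& b) const {
        if (a.v != b.v) return a.v < b.v;       // max-heap on intensity
        if (a.r != b.r) return a.r > b.r;       // then min on row (y)
        if (a.c != b.c) return a.c > b.c;       // then min on col (x)
        return a.seq > b.seq;
    }
};

// Marker-seeded watershed on an intensity landscape: pixels are claimed in
// order of decreasing intensity (equivalently, flooding the negated map from
// its minima), restricted to `mask`, with growth clipped to a chamfer
// geodesic distance `max_geodesic` from the seeding markers.
// [[Rcpp::export]]
List cpp_watershed(NumericMatrix intensity, IntegerMatrix markers,
                   LogicalMatrix mask, double max_geodesic) {
    const int h = intensity.nrow(), w = intensity.ncol();
    if (markers.nrow() != h || markers.ncol() != w ||
        mask.nrow() != h || mask.ncol() != w)
        stop("shape mismatch between intensity, markers and mask");
    IntegerMatrix labels(h, w);
    NumericMatrix geod(h, w);
    std::fill(geod.begin(), geod.end(), NA_REAL);
    std::priority_queue<Cand, std::vector<Cand>, CandLess> pq;
    long long seq = 0;
    for (int c = 0; c < w; ++c)
        for (int r = 0; r < h; ++r)
            if (markers(r, c) > 0) {
                labels(r, c) = markers(r, c);
                geod(r, c) = 0.0;
            }
    for (int c = 0; c < w; ++c)
        for (int r = 0; r < h; ++r) {
            if (labels(r, c) == 0) continue;
            for (int k = 0; k < 8; ++k) {
                int nr = r + DR[k], nc = c + DC[k];
                if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
                if (labels(nr, nc) != 0 || !mask(nr, nc)) continue;
                double gd = geod(r, c) + STEP[k];
                if (gd > max_geodesic) continue;
                pq.push({intensity(nr, nc), nr, nc, gd, labels(r, c), seq++});
            }
        }
    while (!pq.empty()) {
        Cand top = pq.top();
        pq.pop();
        if (labels(top.r, top.c) != 0) continue;
        labels(top.r, top.c) = top.label;
        geod(top.r, top.c) = top.gd;
        for (int k = 0; k < 8; ++k) {
            int nr = top.r + DR[k], nc = top.c + DC[k];
            if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
            if (labels(nr, nc) != 0 || !mask(nr, nc)) continue;
            double gd = top.gd + STEP[k];
            if (gd > max_geodesic) continue;
            pq.push({intensity(nr, nc), nr, nc, gd, top.label, seq++});
        }
    }
    return List::create(_["labels"] = labels, _["geodesic"] = geod);
}
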