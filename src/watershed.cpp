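#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Neighbor offsets: first 4 are the 4-connected set, all 8 the 8-connected set.
static const int DR[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
static const int DC[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };

// Label connected components of equal value within a mask.
// values: integer matrix (e.g. quantized gray levels; pass all-1s for binary
// labeling); mask: which pixels participate. Components are maximal connected
// sets of in-mask pixels sharing one value. Labels are assigned 1..K in
// raster-scan order of each component's first pixel, so output is deterministic.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(IntegerMatrix values, LogicalMatrix mask,
                           int connectivity) {
  int nr = values.nrow(), nc = values.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("values and mask must have identical dimensions");
  int nnb = (connectivity == 8) ? 8 : 4;
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      int v = values(r, c);
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int qr = pr + DR[k], qc = pc + DC[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (!mask(qr, qc) || lab(qr, qc) != 0 || values(qr, qc) != v) continue;
          lab(qr, qc) = next;
          stack.push_back(qr + qc * nr);
        }
      }
    }
  }
  return lab;
}

struct QEntry {
  double prio;    // gradient height at the pixel being flooded
  long long ord;  // FIFO tie-break: insertion order
  int pixel;      // column-major linear index
  int label;      // label of the basin trying to claim it
};
struct QCompare {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // min-heap on height
    return a.ord > b.ord;                          // then FIFO
  }
};

// Marker-controlled watershed: flood the gradient surface from labeled
// markers. Pixels are claimed in order of ascending gradient (ties FIFO),
// each taking the label of the basin that reached it first. With
// keep_lines = TRUE a pixel reachable from two distinct basins at claim time
// is labeled 0 (watershed ridge) and does not propagate.
// [[Rcpp::export(name = ".watershed_flood_cpp")]]
IntegerMatrix watershed_flood_cpp(NumericMatrix gradient, IntegerMatrix markers,
                                  int connectivity, bool keep_lines) {
  int nr = gradient.nrow(), nc = gradient.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("gradient and markers must have identical dimensions");
  int nnb = (connectivity == 8) ? 8 : 4;
  IntegerMatrix lab(nr, nc);
  std::vector<char> queued(static_cast<size_t>(nr) * nc, 0);
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  long long ord = 0;

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      lab(r, c) = markers(r, c);

  // Seed the queue with unlabeled neighbors of every marker pixel.
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) <= 0) continue;
      for (int k = 0; k < nnb; ++k) {
        int qr = r + DR[k], qc = c + DC[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int qi = qr + qc * nr;
        if (lab(qr, qc) == 0 && !queued[qi]) {
          queued[qi] = 1;
          pq.push(QEntry{ gradient(qr, qc), ord++, qi, lab(r, c) });
        }
      }
    }
  }

  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int pr = e.pixel % nr, pc = e.pixel / nr;
    if (lab(pr, pc) != 0) continue;  // already claimed (or ridge)
    if (keep_lines) {
      // Ridge test: adjacent to >= 2 distinct positive basin labels?
      int seen = 0; bool ridge = false;
      for (int k = 0; k < nnb; ++k) {
        int qr = pr + DR[k], qc = pc + DC[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int l = lab(qr, qc);
        if (l > 0) {
          if (seen == 0) seen = l;
          else if (l != seen) { ridge = true; break; }
        }
      }
      if (ridge) { lab(pr, pc) = -1; continue; }
    }
    lab(pr, pc) = e.label;
    for (int k = 0; k < nnb; ++k) {
      int qr = pr + DR[k], qc = pc + DC[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      int qi = qr + qc * nr;
      if (lab(qr, qc) == 0 && !queued[qi]) {
        queued[qi] = 1;
        pq.push(QEntry{ gradient(qr, qc), ord++, qi, e.label });
      }
    }
  }

  if (keep_lines) {
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        if (lab(r, c) == -1) lab(r, c) = 0;
  }
  return lab;
}
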