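#include <Rcpp.h>
using namespace Rcpp;

// Fast perimeter kernels: same marching rules as contours.cpp but
// counting edges only (no vertex storage), for large cluster ensembles.

static inline int site(const IntegerMatrix &b, int r, int c) {
    if (r < 0 || c < 0 || r >= b.nrow() || c >= b.ncol()) return 0;
    return b(r, c);
}

static inline bool edge_valid(const IntegerMatrix &b, int i, int j, int d) {
    switch (d) {
    case 1: return site(b, i, j) == 1     && site(b, i, j - 1) == 0;
    case 3: return site(b, i - 1, j - 1) == 1 && site(b, i - 1, j) == 0;
    case 0: return site(b, i - 1, j) == 1 && site(b, i, j) == 0;
    default: return site(b, i, j - 1) == 1 && site(b, i - 1, j - 1) == 0;
    }
}

static inline void advance(int d, int &i, int &j) {
    switch (d) {
    case 0: ++j; break;
    case 1: ++i; break;
    case 2: --j; break;
    default: --i; break;
    }
}

static inline int next_dir(const IntegerMatrix &b, int i, int j, int d,
                           int connectivity) {
    int A, B;
    switch (d) {
    case 1: B = site(b, i, j);         A = site(b, i, j - 1);     break;
    case 0: B = site(b, i - 1, j);     A = site(b, i, j);         break;
    case 3: B = site(b, i - 1, j - 1); A = site(b, i - 1, j);     break;
    default: B = site(b, i, j - 1);    A = site(b, i - 1, j - 1); break;
    }
    if (B == 1 && A == 0) return d;
    if (B == 1 && A == 1) return (d + 1) % 4;
    if (B == 0 && A == 0) return (d + 3) % 4;
    bool left;
    if (connectivity == 8) left = true;
    else if (connectivity == 4) left = false;
    else left = (d == 0 || d == 2);
    return left ? (d + 1) % 4 : (d + 3) % 4;
}

static inline R_xlen_t edge_key(int i, int j, int d, int nc) {
    return (((R_xlen_t)i * (nc + 2)) + j) * 4 + d;
}

// outer-perimeter edge count per cluster label (0 where a label has no
// traced outer boundary, which cannot happen for non-empty labels)
// [[Rcpp::export(name = ".cluster_perims_cpp")]]
IntegerVector cluster_perims_cpp(IntegerMatrix b, IntegerMatrix labels,
                                 int n_labels, int connectivity) {
    const int nr = b.nrow(), nc = b.ncol();
    std::vector<bool> visited((R_xlen_t)(nr + 2) * (nc + 2) * 4, false);
    IntegerVector out(n_labels);
    for (int i0 = 0; i0 <= nr; ++i0) {
        for (int j0 = 0; j0 <= nc; ++j0) {
            for (int d0 = 0; d0 < 4; ++d0) {
                if (!edge_valid(b, i0, j0, d0)) continue;
                if (visited[edge_key(i0, j0, d0, nc)]) continue;
                int lab;
                switch (d0) {
                case 1: lab = labels(i0, j0); break;
                case 3: lab = labels(i0 - 1, j0 - 1); break;
                case 0: lab = labels(i0 - 1, j0); break;
                default: lab = labels(i0, j0 - 1); break;
                }
                int i = i0, j = j0, d = d0, n = 0;
                double area2 = 0.0;
                do {
                    visited[edge_key(i, j, d, nc)] = true;
                    int ip = i, jp = j;
                    advance(d, i, j);
                    area2 += (jp - 0.5) * (i - 0.5) - (j - 0.5) * (ip - 0.5);
                    ++n;
                    d = next_dir(b, i, j, d, connectivity);
                } while (!(i == i0 && j == j0 && d == d0));
                if (area2 < 0 && lab >= 1 && lab <= n_labels)
                    out[lab - 1] = n;
            }
        }
    }
    return out;
}

// outer edge count of a single connected 0/1 mask (assumed non-empty),
// starting from its bottom-most, then left-most site
static int outer_edges(const IntegerMatrix &m, int connectivity) {
    const int nr = m.nrow(), nc = m.ncol();
    int si = -1, sj = -1;
    for (int i = 0; i < nr && si < 0; ++i)
        for (int j = 0; j < nc; ++j)
            if (m(i, j) == 1) { si = i; sj = j; break; }
    if (si < 0) return 0;
    // leftward edge under the bottom-most site keeps it on the right
    int i0 = si, j0 = sj + 1, d0 = 2;
    int i = i0, j = j0, d = d0, n = 0;
    do {
        advance(d, i, j);
        ++n;
        d = next_dir(m, i, j, d, connectivity);
    } while (!(i == i0 && j == j0 && d == d0));
    return n;
}

// accessible outer-perimeter edge counts for a set of labels: the
// cluster mask is morphologically closed (plus-shaped dilation then
// erosion), which seals fjord gates of one lattice unit without
// thickening the boundary, and the outer contour of the closed set is
// walked with the cluster's own saddle rule
// [[Rcpp::export(name = ".accessible_perims_cpp")]]
IntegerVector accessible_perims_cpp(IntegerMatrix labels,
                                    IntegerVector which_labels,
                                    int connectivity) {
    const int nr = labels.nrow(), nc = labels.ncol();
    const int nl = which_labels.size();
    std::map<int, int> pos;
    for (int k = 0; k < nl; ++k) pos[which_labels[k]] = k;
    std::vector<std::vector<int> > rows(nl), cols(nl);
    for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
            int l = labels(i, j);
            if (l == 0) continue;
            std::map<int, int>::iterator it = pos.find(l);
            if (it == pos.end()) continue;
            rows[it->second].push_back(i);
            cols[it->second].push_back(j);
        }
    IntegerVector out(nl);
    for (int k = 0; k < nl; ++k) {
        const std::vector<int> &ri = rows[k], &ci = cols[k];
        if (ri.empty()) { out[k] = NA_INTEGER; continue; }
        int r0 = ri[0], r1 = ri[0], c0 = ci[0], c1 = ci[0];
        for (size_t t = 1; t < ri.size(); ++t) {
            if (ri[t] < r0) r0 = ri[t];
            if (ri[t] > r1) r1 = ri[t];
            if (ci[t] < c0) c0 = ci[t];
            if (ci[t] > c1) c1 = ci[t];
        }
        IntegerMatrix m(r1 - r0 + 5, c1 - c0 + 5);
        for (size_t t = 0; t < ri.size(); ++t)
            m(ri[t] - r0 + 2, ci[t] - c0 + 2) = 2; // mark original sites
        const int nrm = m.nrow(), ncm = m.ncol();
        // plus-shaped dilation (added sites marked 3; originals are 2)
        for (int j = 0; j < ncm; ++j)
            for (int i = 0; i < nrm; ++i) {
                if (m(i, j) == 2) continue;
                if ((i > 0 && m(i - 1, j) == 2) ||
                    (i + 1 < nrm && m(i + 1, j) == 2) ||
                    (j > 0 && m(i, j - 1) == 2) ||
                    (j + 1 < ncm && m(i, j + 1) == 2))
                    m(i, j) = 3;
            }
        // plus-shaped erosion of the dilated set: an added site survives
        // only if its whole plus neighbourhood lies in the dilated set
        // (original sites always do, closing being extensive); eroded
        // sites are marked 4 so they still count as dilated for their
        // neighbours' checks
        for (int j = 0; j < ncm; ++j)
            for (int i = 0; i < nrm; ++i) {
                if (m(i, j) != 3) continue;
                bool keep = i > 0 && m(i - 1, j) >= 2 &&
                            i + 1 < nrm && m(i + 1, j) >= 2 &&
                            j > 0 && m(i, j - 1) >= 2 &&
                            j + 1 < ncm && m(i, j + 1) >= 2;
                if (!keep) m(i, j) = 4;
            }
        for (int t = 0; t < nrm * ncm; ++t)
            m[t] = (m[t] == 2 || m[t] == 3) ? 1 : 0;
        out[k] = outer_edges(m, connectivity);
    }
    return out;
}
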