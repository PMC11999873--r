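#include <Rcpp.h>
using namespace Rcpp;

// Orientation-preserving marching squares on a binary site field.
//
// Sites live at integer positions (x = col, y = row, 0-based); contour
// vertices live on the dual lattice at half-integer positions
// (x = j - 1/2, y = i - 1/2).  Every directed contour edge keeps a
// 1-site on its right and a 0-site (or the outside) on its left, which
// is the tracing convention for zero-vorticity isolines: positive
// vorticity always on the right of travel.  y increases with row index.
//
// Saddle cells (diagonal pairs of 1s) are resolved according to the
// declared site connectivity:
//   4 : 1-phase 4-connected  -> diagonals never connect (always turn right)
//   6 : triangular embedding -> only the (+1,+1)/(-1,-1) diagonal connects
//   8 : 1-phase 8-connected  -> diagonals always connect (turn left)
//
// Directions: 0 = +x, 1 = +y, 2 = -x, 3 = -y.

static inline int site(const IntegerMatrix &b, int r, int c) {
    if (r < 0 || c < 0 || r >= b.nrow() || c >= b.ncol()) return 0;
    return b(r, c);
}

// validity of directed edge starting at vertex (i, j) with direction d
static inline bool edge_valid(const IntegerMatrix &b, int i, int j, int d) {
    switch (d) {
    case 1: return site(b, i, j) == 1     && site(b, i, j - 1) == 0;     // U
    case 3: return site(b, i - 1, j - 1) == 1 && site(b, i - 1, j) == 0; // D
    case 0: return site(b, i - 1, j) == 1 && site(b, i, j) == 0;         // R
    default: return site(b, i, j - 1) == 1 && site(b, i - 1, j - 1) == 0; // L
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

// next direction leaving vertex (i, j), having arrived travelling d
static inline int next_dir(const IntegerMatrix &b, int i, int j, int d,
                           int connectivity) {
    int A, B; // ahead-left, ahead-right (relative to d)
    switch (d) {
    case 1: B = site(b, i, j);         A = site(b, i, j - 1);     break; // U
    case 0: B = site(b, i - 1, j);     A = site(b, i, j);         break; // R
    case 3: B = site(b, i - 1, j - 1); A = site(b, i - 1, j);     break; // D
    default: B = site(b, i, j - 1);    A = site(b, i - 1, j - 1); break; // L
    }
    if (B == 1 && A == 0) return d;            // straight
    if (B == 1 && A == 1) return (d + 1) % 4;  // turn left
    if (B == 0 && A == 0) return (d + 3) % 4;  // turn right
    // saddle: 1s on behind-right and ahead-left
    bool left;
    if (connectivity == 8) left = true;
    else if (connectivity == 4) left = false;
    else left = (d == 0 || d == 2); // 6: (+1,+1) diagonal connects
    return left ? (d + 1) % 4 : (d + 3) % 4;
}

static inline R_xlen_t edge_key(int i, int j, int d, int nc) {
    return (((R_xlen_t)i * (nc + 2)) + j) * 4 + d;
}

// Trace every closed contour of the binary field.  Returns, per trace,
// the dual-lattice vertices (index units), the label of the 1-phase
// cluster on its right, the shoelace signed area and the edge count.
// [[Rcpp::export(name = ".trace_contours")]]
List trace_contours_cpp(IntegerMatrix b, IntegerMatrix labels,
                        int connectivity) {
    const int nr = b.nrow(), nc = b.ncol();
    std::vector<bool> visited((R_xlen_t)(nr + 2) * (nc + 2) * 4, false);
    List out;

    for (int i0 = 0; i0 <= nr; ++i0) {
        for (int j0 = 0; j0 <= nc; ++j0) {
            for (int d0 = 0; d0 < 4; ++d0) {
                if (!edge_valid(b, i0, j0, d0)) continue;
                if (visited[edge_key(i0, j0, d0, nc)]) continue;

                std::vector<double> xs, ys;
                int i = i0, j = j0, d = d0;
                int lab = 0;
                // label of the 1-site on the right of the first edge
                switch (d0) {
                case 1: lab = labels(i0, j0); break;
                case 3: lab = labels(i0 - 1, j0 - 1); break;
                case 0: lab = labels(i0 - 1, j0); break;
                default: lab = labels(i0, j0 - 1); break;
                }
                double area2 = 0.0;
                int nedges = 0;
                do {
                    visited[edge_key(i, j, d, nc)] = true;
                    double x = j - 0.5, y = i - 0.5;
                    xs.push_back(x);
                    ys.push_back(y);
                    int ip = i, jp = j;
                    advance(d, i, j);
                    // shoelace increment x_k*y_{k+1} - x_{k+1}*y_k
                    area2 += (jp - 0.5) * (i - 0.5) - (j - 0.5) * (ip - 0.5);
                    ++nedges;
                    d = next_dir(b, i, j, d, connectivity);
                } while (!(i == i0 && j == j0 && d == d0));
                xs.push_back(j0 - 0.5); // close the polyline
                ys.push_back(i0 - 0.5);

                out.push_back(List::create(
                    _["x"] = NumericVector(xs.begin(), xs.end()),
                    _["y"] = NumericVector(ys.begin(), ys.end()),
                    _["label"] = lab,
                    _["area"] = 0.5 * area2,
                    _["n_edges"] = nedges));
            }
        }
    }
    return out;
}

// Chordal explorer walk.  `b` must already be conditioned below the
// axis (rows < axis_row filled with the chordal boundary colouring).
// Starts travelling up from vertex (axis_row, origin_col) and stops on
// reaching the domain boundary, dropping below the axis, or closing.
// [[Rcpp::export(name = ".chordal_walk")]]
List chordal_walk_cpp(IntegerMatrix b, int axis_row, int origin_col,
                      int connectivity) {
    const int nr = b.nrow(), nc = b.ncol();
    int i = axis_row, j = origin_col, d = 1;
    if (!edge_valid(b, i, j, d))
        stop("no upward contour edge at the requested origin");
    std::vector<double> xs, ys;
    std::vector<bool> visited((R_xlen_t)(nr + 2) * (nc + 2) * 4, false);
    bool closed = false;
    const char *stopped = "boundary";
    for (;;) {
        if (visited[edge_key(i, j, d, nc)]) { closed = true; stopped = "closed"; break; }
        visited[edge_key(i, j, d, nc)] = true;
        xs.push_back(j - 0.5);
        ys.push_back(i - 0.5);
        advance(d, i, j);
        if (i == 0 || i == nr || j == 0 || j == nc) {
            xs.push_back(j - 0.5);
            ys.push_back(i - 0.5);
            break;
        }
        if (i < axis_row) { // descended into the conditioned region
            xs.push_back(j - 0.5);
            ys.push_back(i - 0.5);
            stopped = "axis";
            break;
        }
        d = next_dir(b, i, j, d, connectivity);
    }
    return List::create(_["x"] = NumericVector(xs.begin(), xs.end()),
                        _["y"] = NumericVector(ys.begin(), ys.end()),
                        _["closed"] = closed,
                        _["stopped"] = std::string(stopped));
}
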