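#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labelling with union-find.
//
// Connectivity:
//   4 : von Neumann neighbours
//   6 : triangular lattice embedded on the square grid, extra neighbours
//       along the (+1,+1) / (-1,-1) diagonal
//   8 : Moore neighbours
//
// Final labels are renumbered in raster-scan first-contact order (rows
// scanned bottom to top, columns left to right), so the labelling is
// deterministic and independent of union-find internals.

static int uf_find(std::vector<int> &parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".cc_label")]]
List cc_label(IntegerMatrix b, int connectivity) {
    const int nr = b.nrow(), nc = b.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> parent;
    parent.push_back(0); // dummy for label 0

    // offsets to already-scanned neighbours (scan: i = row outer, j inner)
    std::vector<std::pair<int, int> > off;
    off.push_back(std::make_pair(0, -1));  // (i, j-1)
    off.push_back(std::make_pair(-1, 0));  // (i-1, j)
    if (connectivity == 6) {
        off.push_back(std::make_pair(-1, -1));
    } else if (connectivity == 8) {
        off.push_back(std::make_pair(-1, -1));
        off.push_back(std::make_pair(-1, 1));
    }

    int next = 0;
    for (int i = 0; i < nr; ++i) {
        for (int j = 0; j < nc; ++j) {
            if (b(i, j) == 0) continue;
            int assigned = 0;
            for (size_t k = 0; k < off.size(); ++k) {
                int ii = i + off[k].first, jj = j + off[k].second;
                if (ii < 0 || jj < 0 || jj >= nc) continue;
                int nb = lab(ii, jj);
                if (nb == 0) continue;
                if (assigned == 0) {
                    assigned = uf_find(parent, nb);
                } else {
                    uf_union(parent, assigned, nb);
                    assigned = uf_find(parent, assigned);
                }
            }
            if (assigned == 0) {
                ++next;
                parent.push_back(next);
                assigned = next;
            }
            lab(i, j) = assigned;
        }
    }

    // second pass: resolve + renumber in first-contact order, accumulate
    // per-cluster site counts and coordinate moments (lattice index units)
    std::vector<int> newlab(next + 1, 0);
    int nfinal = 0;
    std::vector<int> sizes;
    std::vector<double> sx, sy, sxx, syy;
    for (int i = 0; i < nr; ++i) {
        for (int j = 0; j < nc; ++j) {
            int l = lab(i, j);
            if (l == 0) continue;
            int r = uf_find(parent, l);
            if (newlab[r] == 0) {
                newlab[r] = ++nfinal;
                sizes.push_back(0);
                sx.push_back(0.0); sy.push_back(0.0);
                sxx.push_back(0.0); syy.push_back(0.0);
            }
            int f = newlab[r];
            lab(i, j) = f;
            sizes[f - 1] += 1;
            double x = (double)j, y = (double)i;
            sx[f - 1] += x;  sy[f - 1] += y;
            sxx[f - 1] += x * x; syy[f - 1] += y * y;
        }
    }

    NumericVector rg(nfinal);
    for (int k = 0; k < nfinal; ++k) {
        double n = (double)sizes[k];
        double vx = sxx[k] / n - (sx[k] / n) * (sx[k] / n);
        double vy = syy[k] / n - (sy[k] / n) * (sy[k] / n);
        double v = vx + vy;
        rg[k] = v > 0 ? std::sqrt(v) : 0.0;
    }

    return List::create(_["labels"] = lab,
                        _["n_clusters"] = nfinal,
                        _["sizes"] = IntegerVector(sizes.begin(), sizes.end()),
                        _["r_g"] = rg);
}
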