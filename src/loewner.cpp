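#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

typedef std::complex<double> cplx;

// principal complex square root by the direct real formula (much faster
// than std::sqrt on std::complex, which guards against over/underflow
// irrelevant at these magnitudes)
static inline cplx csqrt_fast(double qr, double qi) {
    double r = std::hypot(qr, qi);
    double re = std::sqrt(0.5 * (r + qr));
    double im = std::sqrt(0.5 * (r - qr));
    return cplx(re, qi >= 0.0 ? im : -im);
}

// Vertical slit map g(z) = delta + sqrt((z - delta)^2 + 4*Delta).
// Branch: sqrt taken so that Re(g - delta) has the sign of Re(z - delta)
// and Im(g) >= 0 on the closed upper half-plane minus the slit; the slit
// from delta to delta + 2i*sqrt(Delta) is projected onto the real axis.
static inline cplx slit_fwd(cplx z, double delta, double Delta) {
    double wr = z.real() - delta, wi = z.imag();
    cplx s = csqrt_fast(wr * wr - wi * wi + 4.0 * Delta, 2.0 * wr * wi);
    if (wr < 0.0) s = -s;
    if (s.imag() < 0.0) s = cplx(s.real(), 0.0); // round-off guard
    return s + delta;
}

// Inverse slit map h(w) = delta + sqrt((w - delta)^2 - 4*Delta),
// mapping the upper half-plane onto the half-plane minus the slit.
static inline cplx slit_inv(cplx w, double delta, double Delta) {
    double vr = w.real() - delta, vi = w.imag();
    cplx s = csqrt_fast(vr * vr - vi * vi - 4.0 * Delta, 2.0 * vr * vi);
    if (vr < 0.0) s = -s;
    if (vr == 0.0 && s.imag() < 0.0) s = -s;
    if (s.imag() < 0.0) s = cplx(s.real(), 0.0);
    return s + delta;
}

// [[Rcpp::export(name = ".slit_map_cpp")]]
ComplexVector slit_map_cpp(ComplexVector z, double delta, double Delta) {
    R_xlen_t n = z.size();
    ComplexVector out(n);
    double tip = 2.0 * std::sqrt(Delta);
    for (R_xlen_t k = 0; k < n; ++k) {
        cplx zz(z[k].r, z[k].i);
        if (zz.imag() < 0)
            stop("slit_map: point below the real axis");
        if (zz.real() == delta && zz.imag() < tip && zz.imag() > 0)
            stop("slit_map: point lies strictly inside the slit");
        cplx g = slit_fwd(zz, delta, Delta);
        out[k].r = g.real();
        out[k].i = g.imag();
    }
    return out;
}

// Loewner zipper: successive vertical slit maps unzip a chordal trace
// into its driving function.  Points whose (mapped) height is below
// y_floor advance the driving value but not the Loewner time.
// The loop is organised point by point: each trace point is pushed
// through the slit maps accumulated so far and then, if it gained
// height, contributes its own slit.  The driving is causal in the
// point index, so with a capacity cap `t_stop` the cost is quadratic
// in the number of processed points only, independent of the trace
// length behind the cap.
// [[Rcpp::export(name = ".zipper_cpp")]]
List zipper_cpp(ComplexVector pts, double y_floor, double im_tol,
                double t_stop) {
    R_xlen_t n = pts.size();
    std::vector<double> deltas, Deltas, times, values;
    deltas.reserve(1024); Deltas.reserve(1024);
    times.reserve(1024); values.reserve(1024);
    double t = 0.0;
    for (R_xlen_t k = 0; k < n; ++k) {
        if (t_stop > 0 && t > t_stop) break;
        cplx w(pts[k].r, pts[k].i);
        for (size_t j = 0; j < deltas.size(); ++j)
            w = slit_fwd(w, deltas[j], Deltas[j]);
        double x = w.real(), y = w.imag();
        if (y < -im_tol)
            stop("zipper: point %d mapped below the real axis (Im = %g)",
                 (int)(k + 1), y);
        if (y <= y_floor) continue; // axis touch: no capacity gained
        double Delta = y * y / 4.0;
        t += Delta;
        deltas.push_back(x);
        Deltas.push_back(Delta);
        times.push_back(t);
        values.push_back(x);
    }
    return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                        _["values"] = NumericVector(values.begin(), values.end()));
}

// Forward discrete Loewner evolution: reconstruct the trace tip at each
// partition time from a stepwise driving function (delta_k constant on
// step k of capacity increment Delta_k).  Exact inverse of the zipper.
// [[Rcpp::export(name = ".forward_trace_cpp")]]
ComplexVector forward_trace_cpp(NumericVector delta, NumericVector Delta) {
    R_xlen_t n = delta.size();
    if (Delta.size() != n) stop("delta and Delta must have equal length");
    ComplexVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        cplx w(delta[k], 2.0 * std::sqrt(Delta[k])); // slit tip at step k
        for (R_xlen_t j = k; j-- > 0;)
            w = slit_inv(w, delta[j], Delta[j]);
        if (w.imag() < 0.0) w = cplx(w.real(), 0.0);
        out[k].r = w.real();
        out[k].i = w.imag();
    }
    return out;
}

// Unwrapped total angle swept by (trace - z0) and the principal argument
// of the last point, for the left-passage winding criterion; vectorised
// over probe points.
// [[Rcpp::export(name = ".swept_angle_cpp")]]
NumericMatrix swept_angle_cpp(ComplexVector pts, ComplexVector probes) {
    R_xlen_t n = pts.size(), m = probes.size();
    NumericMatrix out(m, 2);
    for (R_xlen_t p = 0; p < m; ++p) {
        cplx z0(probes[p].r, probes[p].i);
        double total = 0.0;
        cplx prev = cplx(pts[0].r, pts[0].i) - z0;
        for (R_xlen_t k = 1; k < n; ++k) {
            cplx cur = cplx(pts[k].r, pts[k].i) - z0;
            total += std::arg(cur / prev);
            prev = cur;
        }
        out(p, 0) = total;
        out(p, 1) = std::arg(prev);
    }
    return out;
}
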