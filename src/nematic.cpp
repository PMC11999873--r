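#include <Rcpp.h>
using namespace Rcpp;

// Hybrid solver for 2D active nematic hydrodynamics:
//   momentum: incompressible Stokes limit approximated by a D2Q9
//             lattice-kinetic (BGK) step, forced by the divergence of
//             the elastic + active stress (Guo forcing),
//   order parameter: explicit central finite differences for the
//             Beris-Edwards transport of the traceless symmetric
//             Q-tensor (components q1 = Q_xx, q2 = Q_xy), with the
//             purely elastic free energy F = K (d_k Q_ij)^2, so the
//             molecular field is H = 2K lap(Q).
// Periodic boundaries; lattice spacing and LB time step are unity.
// The Q update is sub-stepped when the explicit diffusion number
// 2*Gamma*K approaches its stability limit.

static const int CX[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
static const int CY[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
static const double W[9] = {4.0 / 9.0,
                            1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0,
                            1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0};

struct Work {
    int nr, nc, N;
    std::vector<int> up, dn, rt, lt; // periodic neighbour row/col tables
    std::vector<double> q1, q2, f, fpost;
    std::vector<double> Pxx, Pxy, Pyx, Pyy, Fx, Fy, ux, uy, rho, nq1, nq2;
    inline int at(int i, int j) const { return i + nr * j; }
};

// elastic + active deviatoric stress at every node (fills Pxx..Pyy)
static void compute_stress(Work &w, double K, double lambda, double zeta) {
    const int nr = w.nr, nc = w.nc;
    for (int j = 0; j < nc; ++j) {
        const int jr = w.rt[j], jl = w.lt[j];
        for (int i = 0; i < nr; ++i) {
            const int iu = w.up[i], id = w.dn[i];
            const int k = w.at(i, j);
            const double a = w.q1[k], b = w.q2[k];
            const double gx1 = 0.5 * (w.q1[w.at(i, jr)] - w.q1[w.at(i, jl)]);
            const double gy1 = 0.5 * (w.q1[w.at(iu, j)] - w.q1[w.at(id, j)]);
            const double gx2 = 0.5 * (w.q2[w.at(i, jr)] - w.q2[w.at(i, jl)]);
            const double gy2 = 0.5 * (w.q2[w.at(iu, j)] - w.q2[w.at(id, j)]);
            const double l1 = w.q1[w.at(i, jr)] + w.q1[w.at(i, jl)] +
                              w.q1[w.at(iu, j)] + w.q1[w.at(id, j)] - 4.0 * a;
            const double l2 = w.q2[w.at(i, jr)] + w.q2[w.at(i, jl)] +
                              w.q2[w.at(iu, j)] + w.q2[w.at(id, j)] - 4.0 * b;
            const double ha = 2.0 * K * l1, hb = 2.0 * K * l2;
            const double qh = a * ha + b * hb;   // Q : H
            const double asym = a * hb - b * ha; // (QH - HQ)_xy / 2
            const double er_xx = -4.0 * K * (gx1 * gx1 + gx2 * gx2);
            const double er_xy = -4.0 * K * (gx1 * gy1 + gx2 * gy2);
            const double er_yy = -4.0 * K * (gy1 * gy1 + gy2 * gy2);
            const double lam_xx = lambda * (4.0 * qh * a - ha);
            const double lam_xy = lambda * (4.0 * qh * b - hb);
            w.Pxx[k] = -zeta * a + er_xx + lam_xx;
            w.Pyy[k] = zeta * a + er_yy - lam_xx;
            w.Pxy[k] = -zeta * b + er_xy + lam_xy + 2.0 * asym;
            w.Pyx[k] = -zeta * b + er_xy + lam_xy - 2.0 * asym;
        }
    }
}

// body force = divergence of the stress, capped in magnitude
static void compute_force(Work &w, double fcap) {
    const int nr = w.nr, nc = w.nc;
    for (int j = 0; j < nc; ++j) {
        const int jr = w.rt[j], jl = w.lt[j];
        for (int i = 0; i < nr; ++i) {
            const int iu = w.up[i], id = w.dn[i];
            const int k = w.at(i, j);
            double fx = 0.5 * (w.Pxx[w.at(i, jr)] - w.Pxx[w.at(i, jl)]) +
                        0.5 * (w.Pxy[w.at(iu, j)] - w.Pxy[w.at(id, j)]);
            double fy = 0.5 * (w.Pyx[w.at(i, jr)] - w.Pyx[w.at(i, jl)]) +
                        0.5 * (w.Pyy[w.at(iu, j)] - w.Pyy[w.at(id, j)]);
            const double fn = std::sqrt(fx * fx + fy * fy);
            if (fn > fcap) { fx *= fcap / fn; fy *= fcap / fn; }
            w.Fx[k] = fx; w.Fy[k] = fy;
        }
    }
    // binomial smoothing of the force: removes the grid-Nyquist
    // components of the stress divergence, which otherwise couple back
    // through the strain rate into the Q update and destabilise the
    // explicit backflow loop; physical scales (>= the active length)
    // are untouched
    for (int pass = 0; pass < 2; ++pass) {
        std::vector<double> &src = pass == 0 ? w.Fx : w.Fy;
        std::vector<double> &tmp = pass == 0 ? w.nq1 : w.nq2;
        for (int j = 0; j < nc; ++j) {
            const int jr = w.rt[j], jl = w.lt[j];
            for (int i = 0; i < nr; ++i) {
                const int iu = w.up[i], id = w.dn[i];
                tmp[w.at(i, j)] = 0.25 * src[w.at(i, j)] +
                    0.125 * (src[w.at(i, jr)] + src[w.at(i, jl)] +
                             src[w.at(iu, j)] + src[w.at(id, j)]) +
                    0.0625 * (src[w.at(iu, jr)] + src[w.at(iu, jl)] +
                              src[w.at(id, jr)] + src[w.at(id, jl)]);
            }
        }
        src.swap(tmp);
    }
    // the divergence of a periodic stress field has zero mean; restore
    // that exactly after capping so no net momentum is pumped in
    double sx = 0.0, sy = 0.0;
    for (int k = 0; k < w.N; ++k) { sx += w.Fx[k]; sy += w.Fy[k]; }
    sx /= w.N; sy /= w.N;
    for (int k = 0; k < w.N; ++k) { w.Fx[k] -= sx; w.Fy[k] -= sy; }
}

// [[Rcpp::export(name = ".nematic_steps_cpp")]]
List nematic_steps_cpp(NumericMatrix q1m, NumericMatrix q2m, NumericMatrix fm,
                       double Gamma, double K, double mu, double lambda,
                       double zeta, double fcap, int n_steps) {
    const int nr = q1m.nrow(), nc = q1m.ncol();
    const int N = nr * nc;
    if (fm.nrow() != N || fm.ncol() != 9)
        stop("population matrix must be (nr*nc) x 9");
    const double tau = 3.0 * mu + 0.5;
    const double omega = 1.0 / tau, guo = 1.0 - 0.5 / tau;
    int n_sub = (int)std::ceil(2.0 * Gamma * K / 0.12);
    if (n_sub < 1) n_sub = 1;
    const double dt_sub = 1.0 / n_sub;

    Work w;
    w.nr = nr; w.nc = nc; w.N = N;
    w.up.resize(nr); w.dn.resize(nr); w.rt.resize(nc); w.lt.resize(nc);
    for (int i = 0; i < nr; ++i) {
        w.up[i] = (i + 1) % nr;
        w.dn[i] = (i + nr - 1) % nr;
    }
    for (int j = 0; j < nc; ++j) {
        w.rt[j] = (j + 1) % nc;
        w.lt[j] = (j + nc - 1) % nc;
    }
    w.q1.assign(q1m.begin(), q1m.end());
    w.q2.assign(q2m.begin(), q2m.end());
    w.f.resize((size_t)N * 9); w.fpost.resize((size_t)N * 9);
    for (int q = 0; q < 9; ++q)
        for (int k = 0; k < N; ++k) w.f[(size_t)q * N + k] = fm(k, q);
    w.Pxx.resize(N); w.Pxy.resize(N); w.Pyx.resize(N); w.Pyy.resize(N);
    w.Fx.resize(N); w.Fy.resize(N); w.ux.resize(N); w.uy.resize(N);
    w.rho.resize(N); w.nq1.resize(N); w.nq2.resize(N);

    for (int step = 0; step < n_steps; ++step) {
        compute_stress(w, K, lambda, zeta);
        compute_force(w, fcap);

        // --- macroscopic fields, BGK collision with Guo forcing ---------
        double maxq = 0.0;
        for (int k = 0; k < N; ++k) {
            double r = 0.0, mx = 0.0, my = 0.0;
            for (int q = 0; q < 9; ++q) {
                const double fq = w.f[(size_t)q * N + k];
                r += fq; mx += fq * CX[q]; my += fq * CY[q];
            }
            const double uxk = (mx + 0.5 * w.Fx[k]) / r;
            const double uyk = (my + 0.5 * w.Fy[k]) / r;
            w.rho[k] = r; w.ux[k] = uxk; w.uy[k] = uyk;
            const double u2 = uxk * uxk + uyk * uyk;
            const double uf = uxk * w.Fx[k] + uyk * w.Fy[k];
            for (int q = 0; q < 9; ++q) {
                const double cu = CX[q] * uxk + CY[q] * uyk;
                const double feq = W[q] * r *
                    (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * u2);
                const double cf = CX[q] * w.Fx[k] + CY[q] * w.Fy[k];
                const double phi = W[q] * (3.0 * (cf - uf) + 9.0 * cu * cf);
                w.fpost[(size_t)q * N + k] =
                    w.f[(size_t)q * N + k] * (1.0 - omega) + omega * feq +
                    guo * phi;
            }
        }
        // --- streaming (periodic) ---------------------------------------
        for (int q = 0; q < 9; ++q) {
            const double *src = &w.fpost[(size_t)q * N];
            double *dst = &w.f[(size_t)q * N];
            for (int j = 0; j < nc; ++j) {
                const int jj = CX[q] == 1 ? w.rt[j]
                             : (CX[q] == -1 ? w.lt[j] : j);
                for (int i = 0; i < nr; ++i) {
                    const int ii = CY[q] == 1 ? w.up[i]
                                 : (CY[q] == -1 ? w.dn[i] : i);
                    dst[w.at(ii, jj)] = src[w.at(i, j)];
                }
            }
        }
        // --- Q-tensor transport (sub-stepped explicit Euler) ------------
        for (int sub = 0; sub < n_sub; ++sub) {
            for (int j = 0; j < nc; ++j) {
                const int jr = w.rt[j], jl = w.lt[j];
                for (int i = 0; i < nr; ++i) {
                    const int iu = w.up[i], id = w.dn[i];
                    const int k = w.at(i, j);
                    const double a = w.q1[k], b = w.q2[k];
                    // velocity gradients (frozen during substeps)
                    const double dxux = 0.5 * (w.ux[w.at(i, jr)] - w.ux[w.at(i, jl)]);
                    const double dyux = 0.5 * (w.ux[w.at(iu, j)] - w.ux[w.at(id, j)]);
                    const double dxuy = 0.5 * (w.uy[w.at(i, jr)] - w.uy[w.at(i, jl)]);
                    const double dyuy = 0.5 * (w.uy[w.at(iu, j)] - w.uy[w.at(id, j)]);
                    const double exx = dxux, eyy = dyuy;
                    const double exy = 0.5 * (dxuy + dyux);
                    const double om = 0.5 * (dxuy - dyux); // Omega_xy
                    const double m11 = a + 0.5, m12 = b, m22 = 0.5 - a;
                    const double L11 = lambda * exx, L12 = lambda * exy + om;
                    const double L21 = lambda * exy - om, L22 = lambda * eyy;
                    // (lambda E + Omega) M + M (lambda E - Omega)
                    const double S11 = L11 * m11 + L12 * m12 + m11 * L11 + m12 * L12;
                    const double S12 = L11 * m12 + L12 * m22 + m11 * L21 + m12 * L22;
                    const double S21 = L21 * m11 + L22 * m12 + m12 * L11 + m22 * L12;
                    const double S22 = L21 * m12 + L22 * m22 + m12 * L21 + m22 * L22;
                    const double qdu = a * dxux + b * dxuy + b * dyux - a * dyuy;
                    const double s1 = 0.5 * (S11 - S22) - 2.0 * lambda * qdu * a;
                    const double s2 = 0.5 * (S12 + S21) - 2.0 * lambda * qdu * b;
                    const double l1 = w.q1[w.at(i, jr)] + w.q1[w.at(i, jl)] +
                                      w.q1[w.at(iu, j)] + w.q1[w.at(id, j)] - 4.0 * a;
                    const double l2 = w.q2[w.at(i, jr)] + w.q2[w.at(i, jl)] +
                                      w.q2[w.at(iu, j)] + w.q2[w.at(id, j)] - 4.0 * b;
                    // first-order upwind advection of Q (the standard
                    // stabilisation of hybrid LB / finite-difference
                    // nematohydrodynamics at cell Peclet > 1)
                    const double uxk = w.ux[k], uyk = w.uy[k];
                    const double adv1 =
                        (uxk > 0 ? uxk * (a - w.q1[w.at(i, jl)])
                                 : uxk * (w.q1[w.at(i, jr)] - a)) +
                        (uyk > 0 ? uyk * (a - w.q1[w.at(id, j)])
                                 : uyk * (w.q1[w.at(iu, j)] - a));
                    const double adv2 =
                        (uxk > 0 ? uxk * (b - w.q2[w.at(i, jl)])
                                 : uxk * (w.q2[w.at(i, jr)] - b)) +
                        (uyk > 0 ? uyk * (b - w.q2[w.at(id, j)])
                                 : uyk * (w.q2[w.at(iu, j)] - b));
                    w.nq1[k] = a + dt_sub * (-adv1 + s1 + Gamma * 2.0 * K * l1);
                    w.nq2[k] = b + dt_sub * (-adv2 + s2 + Gamma * 2.0 * K * l2);
                }
            }
            std::swap(w.q1, w.nq1);
            std::swap(w.q2, w.nq2);
        }
        for (int k = 0; k < N; ++k) {
            const double aq = std::fabs(w.q1[k]) + std::fabs(w.q2[k]);
            if (aq > maxq) maxq = aq;
        }
        if (!std::isfinite(maxq) || maxq > 20.0)
            stop("nematic solver unstable at step %d (max |Q| = %g)",
                 step + 1, maxq);
    }

    // macroscopic fields of the final state (with its own force)
    compute_stress(w, K, lambda, zeta);
    compute_force(w, fcap);
    NumericMatrix q1o(nr, nc), q2o(nr, nc), fo(N, 9);
    NumericMatrix uxo(nr, nc), uyo(nr, nc), rhoo(nr, nc);
    for (int k = 0; k < N; ++k) {
        q1o[k] = w.q1[k]; q2o[k] = w.q2[k];
        double r = 0.0, mx = 0.0, my = 0.0;
        for (int q = 0; q < 9; ++q) {
            const double fq = w.f[(size_t)q * N + k];
            fo(k, q) = fq;
            r += fq; mx += fq * CX[q]; my += fq * CY[q];
        }
        rhoo[k] = r;
        uxo[k] = (mx + 0.5 * w.Fx[k]) / r;
        uyo[k] = (my + 0.5 * w.Fy[k]) / r;
    }
    return List::create(_["q1"] = q1o, _["q2"] = q2o, _["f"] = fo,
                        _["ux"] = uxo, _["uy"] = uyo, _["rho"] = rhoo);
}
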