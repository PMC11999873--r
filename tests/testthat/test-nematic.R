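# active nematic hydrodynamics solver

test_that("uniform Q with no activity is a fixed point", {
    p <- active_nematic_params(lattice = c(32L, 32L), zeta = 0, seed = 1)
    s0 <- init_nematic(p, mode = "uniform", uniform_q = c(0.3, -0.1))
    s1 <- step_active_nematic(s0, p, 5)
    expect_equal(s1$q1, s0$q1, tolerance = 1e-12)
    expect_equal(s1$q2, s0$q2, tolerance = 1e-12)
    expect_equal(max(abs(s1$ux)), 0, tolerance = 1e-12)
})

test_that("free energy descends under passive relaxation", {
    p <- active_nematic_params(lattice = c(48L, 48L), zeta = 0, seed = 7)
    s <- init_nematic(p, amplitude = 0.05)
    fe <- nematic_free_energy(s, p)
    for (k in 1:12) {
        s <- step_active_nematic(s, p, 25)
        fe2 <- nematic_free_energy(s, p)
        expect_lte(fe2, fe * (1 + 1e-10))
        fe <- fe2
    }
    expect_lt(fe, 0.2 * nematic_free_energy(init_nematic(p, amplitude = 0.05), p))
})

test_that("mass is conserved to near machine precision", {
    p <- active_nematic_params(lattice = c(32L, 32L), seed = 2,
                               zeta = 0.002)
    s <- init_nematic(p, amplitude = 0.02)
    m0 <- sum(s$f)
    s <- step_active_nematic(s, p, 500)
    expect_equal(sum(s$f), m0, tolerance = 1e-12)
})

test_that("Q stays traceless-symmetric by construction and bounded", {
    p <- active_nematic_params(lattice = c(48L, 48L), seed = 3)
    s <- step_active_nematic(init_nematic(p), p, 2000)
    # only two components are stored: the invariant is that they remain
    # finite and the order parameter saturates near |Q| ~ 1/2
    expect_true(all(is.finite(s$q1)) && all(is.finite(s$q2)))
    expect_lt(max(abs(s$q1), abs(s$q2)), 1)
})

test_that("mirror symmetry: a reflected state evolves to the reflection", {
    p <- active_nematic_params(lattice = c(32L, 32L), seed = 11)
    s <- init_nematic(p, amplitude = 0.03)
    mirror_state <- function(st) {
        flip <- function(m) m[, ncol(m):1]
        f2 <- st$f
        dim(f2) <- c(nrow(st$q1), ncol(st$q1), 9L)
        f2 <- f2[, ncol(st$q1):1, , drop = FALSE]
        # reflect x: population directions with c_x = +1 swap with c_x = -1
        perm <- c(1L, 4L, 3L, 2L, 5L, 7L, 6L, 9L, 8L)
        f2 <- f2[, , perm]
        dim(f2) <- c(nrow(st$q1) * ncol(st$q1), 9L)
        structure(list(q1 = flip(st$q1), q2 = -flip(st$q2), f = f2,
                       ux = -flip(st$ux), uy = flip(st$uy),
                       rho = flip(st$rho), step = st$step),
                  class = "nematic_state")
    }
    a <- step_active_nematic(s, p, 50)
    b <- step_active_nematic(mirror_state(s), p, 50)
    bm <- mirror_state(b)
    expect_equal(bm$q1, a$q1, tolerance = 1e-10)
    expect_equal(bm$q2, a$q2, tolerance = 1e-10)
    expect_equal(bm$ux, a$ux, tolerance = 1e-10)
})

test_that("seeded runs are bit-reproducible", {
    p <- active_nematic_params(lattice = c(32L, 32L), seed = 5)
    a <- run_active_nematic(p, n_snapshots = 2, warmup = 50,
                            snapshot_interval = 25)
    b <- run_active_nematic(p, n_snapshots = 2, warmup = 50,
                            snapshot_interval = 25)
    expect_identical(a$snapshots[[2]]$u_x, b$snapshots[[2]]$u_x)
    expect_identical(a$times, b$times)
})

test_that("developed flow is nearly incompressible", {
    # gentle activity: the kinetic solver approximates Stokes flow with
    # lattice-unit divergence well below the flow amplitude
    p <- active_nematic_params(lattice = c(64L, 64L), seed = 9,
                               zeta = 0.0015, K = 0.0375)
    s <- step_active_nematic(init_nematic(p), p, 12000)
    f <- nematic_velocity_field(s)
    expect_gt(max(sqrt(s$ux^2 + s$uy^2)), 1e-4)  # flow actually developed
    expect_lt(max_divergence(f), 1e-3)
})

test_that("instability is reported with the offending step", {
    p <- suppressWarnings(active_nematic_params(lattice = c(32L, 32L),
                                                seed = 1, zeta = 5, K = 5))
    s <- init_nematic(p, amplitude = 0.1)
    expect_error(step_active_nematic(s, p, 500), "unstable at step")
})
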