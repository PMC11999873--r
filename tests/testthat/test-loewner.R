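# slit maps, the zipper, and driving-function statistics

test_that("slit map fixes its tip, expands at infinity, handles i-axis", {
    expect_equal(slit_map(1 + 1i, delta = 1, Delta = 0.25), 1 + 0i,
                 tolerance = 1e-14)
    # g(z) ~ z + 2 Delta / (z - delta) far from the slit
    for (z in c(40 + 2i, -25 + 7i, 60i)) {
        expect_equal(slit_map(z, 0.5, 1), z + 2 / (z - 0.5),
                     tolerance = 1e-3)
    }
    # purely imaginary input above the slit stays imaginary:
    # sqrt((3i)^2 + 4) = i sqrt(5)
    expect_equal(slit_map(3i, 0, 1), sqrt(5) * 1i, tolerance = 1e-14)
    expect_error(slit_map(0.5i, 0, 1), "slit")
    expect_error(slit_map(1 - 1i, 0, 1), "below")
    expect_error(slit_map(1i, 0, -1), "Delta")
})

test_that("upper half-plane maps into the upper half-plane", {
    set.seed(6)
    z <- complex(real = rnorm(500, sd = 3), imaginary = abs(rnorm(500, sd = 2)))
    g <- slit_map(z, delta = 0.7, Delta = 0.9)
    expect_true(all(Im(g) >= 0))
})

test_that("a vertical segment has identically zero driving", {
    tr <- chordal_trace(complex(real = 0, imaginary = seq(0, 2, 0.01)))
    df <- compute_driving_function(tr)
    expect_true(all(df$values == 0))
    expect_true(all(diff(df$times) > 0))
    expect_equal(df$times[1], 0)
})

test_that("zipper inverts the forward evolution to machine precision", {
    tr <- sample_sle_trace(6, n_steps = 400, dt = 5e-4, seed = 21)
    df <- compute_driving_function(tr)
    expect_equal(df$values[-1], tr$driving$values, tolerance = 1e-10)
    expect_equal(df$times[-1], tr$driving$times, tolerance = 1e-10)
})

test_that("zipper round trip converges under refinement of the driving", {
    # fixed continuous driving U(t) = sin(8 t) sampled at three
    # resolutions.  On its own partition the zipper inverts the forward
    # map exactly; re-extracting from an arclength-resampled copy of the
    # trace (which destroys the partition) must converge as it refines.
    errs <- vapply(c(100, 400, 1600), function(n) {
        t <- seq(0, 0.5, length.out = n + 1)[-1]
        delta <- sin(8 * t)
        z <- sleflow:::.forward_trace_cpp(delta, rep(0.5 / n, n))
        tr <- chordal_trace(c(0 + 0i, z))
        df <- compute_driving_function(tr)
        expect_equal(df$values[-1], delta, tolerance = 1e-9)
        expect_equal(df$times[-1], t, tolerance = 1e-9)
        rs <- chordal_trace(resample_trace(tr))
        dr <- compute_driving_function(rs)
        mid <- seq(0.1, 0.9 * dr$capacity, length.out = 50)
        max(abs(approx(dr$times, dr$values, mid, method = "constant",
                       f = 1, rule = 2)$y - sin(8 * mid)))
    }, numeric(1))
    expect_true(all(diff(errs) < 0))
    expect_lt(errs[3], 0.05)
})

test_that("spatial rescaling scales Loewner time by s^2, kappa unchanged", {
    tr <- sample_sle_trace(6, n_steps = 300, dt = 5e-4, seed = 33)
    df1 <- compute_driving_function(tr)
    s <- 2.5
    tr2 <- chordal_trace(s * tr$points)
    df2 <- compute_driving_function(tr2)
    expect_equal(df2$capacity, s^2 * df1$capacity, tolerance = 1e-9)
    expect_equal(df2$values, s * df1$values, tolerance = 1e-9)

    dfs1 <- lapply(sle_trace_ensemble(80, 6, n_steps = 300, dt = 5e-4,
                                      seed = 3), compute_driving_function)
    dfs2 <- lapply(dfs1, function(d)
        structure(list(times = s^2 * d$times, values = s * d$values,
                       capacity = s^2 * d$capacity),
                  class = "driving_function"))
    f1 <- fit_kappa_driving(dfs1)
    f2 <- fit_kappa_driving(dfs2)
    # tiny differences arise from tie-breaking of the interpolation grid
    expect_equal(f1$kappa, f2$kappa, tolerance = 1e-3)
})

test_that("Brownian driving ensembles recover their diffusivity", {
    set.seed(13)
    mk <- function(kap) {
        n <- 400; dt <- 1e-3
        structure(list(times = c(0, (1:n) * dt),
                       values = c(0, sqrt(kap) * cumsum(rnorm(n, sd = sqrt(dt)))),
                       capacity = n * dt),
                  class = "driving_function")
    }
    for (kap in c(2, 6)) {
        fit <- fit_kappa_driving(replicate(600, mk(kap), simplify = FALSE))
        expect_equal(fit$kappa, kap, tolerance = 0.15 * kap)
        # rescaled collapse onto a unit normal at both diagnostic times
        expect_lt(max(fit$diagnostics$ks_distance), 0.06)
    }
})

test_that("increment autocorrelation separates white from AR(1) driving", {
    set.seed(14)
    n <- 64
    mk_from_incr <- function(du) {
        structure(list(times = 0:length(du), values = c(0, cumsum(du)),
                       capacity = length(du)),
                  class = "driving_function")
    }
    white <- replicate(400, mk_from_incr(rnorm(n)), simplify = FALSE)
    cw <- driving_autocorrelation(white, taus = 0:4, n_grid = n,
                                  t_max_quantile = 0)
    expect_equal(cw$C[1], 1)
    expect_lt(max(abs(cw$C[-1])), 0.05)

    ar <- replicate(400, {
        e <- rnorm(n + 20)
        du <- stats::filter(e, 0.5, method = "recursive")[-(1:20)]
        mk_from_incr(as.numeric(du))
    }, simplify = FALSE)
    ca <- driving_autocorrelation(ar, taus = 0:3, n_grid = n,
                                  t_max_quantile = 0)
    expect_equal(ca$C[2], 0.5, tolerance = 0.08)

    dup <- replicate(100, {
        du <- rnorm(n); du[seq(2, n, 2)] <- du[seq(1, n, 2)]
        mk_from_incr(du)
    }, simplify = FALSE)
    cd <- driving_autocorrelation(dup, taus = 1, t = 1, n_grid = n,
                                  t_max_quantile = 0)
    expect_equal(cd$C[1], 1, tolerance = 1e-9)
})

test_that("forward SLE traces are reproducible and degenerate at kappa 0", {
    a <- sample_sle_trace(6, n_steps = 150, seed = 5)
    b <- sample_sle_trace(6, n_steps = 150, seed = 5)
    expect_identical(a$points, b$points)
    v <- sample_sle_trace(0, n_steps = 150)
    expect_true(all(Re(v$points) == 0))
    expect_true(all(diff(Im(v$points)) > 0))
    expect_error(sample_sle_trace(9, 200), "kappa")
})
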