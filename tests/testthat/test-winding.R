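# winding angles and the variance-slope estimator

test_that("winding angles of simple polylines", {
    straight <- complex(real = 0:10, imaginary = 0)
    expect_true(all(winding_angles(straight) == 0))

    # three edges of a regular hexagon: turns of pi/3 each
    ang <- c(0, pi / 3, 2 * pi / 3)
    hexarc <- cumsum(c(0, exp(1i * ang)))
    th <- winding_angles(hexarc)
    expect_equal(th, c(0, pi / 3, 2 * pi / 3))

    expect_error(winding_angles(c(0, 0, 1i)), "degenerate")
    expect_error(winding_angles(c(0, 1i)), "3 vertices")
})

test_that("closed simple traces wind by exactly 2 pi", {
    sq <- new_contour_trace(cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)),
                            closed = TRUE, kind = "complete", label = 1L,
                            area = 1, n_edges = 4L, spacing = 1)
    expect_equal(sum(diff(winding_angles(sq))), 2 * pi)

    # irregular convex polygon, traversed clockwise
    th <- sort(runif(9, 0, 2 * pi), decreasing = TRUE)
    poly <- cbind(cos(th), sin(th))
    tr <- new_contour_trace(rbind(poly, poly[1, ]), closed = TRUE,
                            kind = "complete", label = 1L, area = -1,
                            n_edges = 9L, spacing = 1)
    expect_equal(abs(sum(diff(winding_angles(tr)))), 2 * pi)

    # marching-squares traces close with total winding +/- 2 pi
    b <- random_binary(16, 16, seed = 2)
    for (trc in trace_contours(b, 4)[1:5])
        expect_equal(abs(sum(diff(winding_angles(trc)))), 2 * pi,
                     tolerance = 1e-12)
})

test_that("kappa/alpha conversion is a round trip on (0, 8)", {
    for (k in c(0.5, 2, 8 / 3, 4, 6, 7.5))
        expect_equal(kappa_from_alpha(alpha_from_kappa(k)), k,
                     tolerance = 1e-12)
    expect_error(kappa_from_alpha(2.5), "alpha")
})

test_that("constructed log-variance series recover the planted slope", {
    # theta series built as Brownian motion in log-arclength so that
    # Var(theta(s)) = 0.9 log(s) exactly
    set.seed(99)
    L <- 2048
    lg <- log(seq_len(L))
    thetas <- replicate(3000, {
        incr <- rnorm(L - 1, sd = sqrt(0.9 * diff(lg)))
        c(0, cumsum(incr))
    }, simplify = FALSE)
    fit <- winding_variance_fit(thetas, s_grid = round(exp(seq(log(16),
        log(500), length.out = 10))))
    expect_equal(fit$slope_alpha, 0.9, tolerance = 0.05)
})

test_that("ensembles that are too small or too short are rejected", {
    expect_error(winding_variance_fit(list(1:5), min_traces = 50), "at least")
    short <- replicate(60, complex(real = 0:20, imaginary = (0:20)^1.1),
                       simplify = FALSE)
    expect_error(winding_variance_fit(short), "too short")
})
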