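# gyration radii, fractal-dimension fits, duality

test_that("gyration radius matches hand-computed cases", {
    expect_equal(gyration_radius(cbind(2, 3)), 0)
    expect_equal(gyration_radius(rbind(c(0, 0), c(4, 0))), 2)  # d/2
    expect_equal(gyration_radius(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))),
                 sqrt(2) / 2)
    expect_error(gyration_radius(matrix(numeric(), 0, 2)), "empty")
})

test_that("gyration radius is rigid-motion invariant and scales linearly", {
    set.seed(4)
    pts <- matrix(rnorm(40), 20, 2)
    r0 <- gyration_radius(pts)
    th <- 0.83
    rot <- pts %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    expect_equal(gyration_radius(rot), r0, tolerance = 1e-12)
    expect_equal(gyration_radius(sweep(pts, 2, c(5, -11), "+")), r0,
                 tolerance = 1e-12)
    expect_equal(gyration_radius(3.7 * pts), 3.7 * r0, tolerance = 1e-12)
})

test_that("planted power laws are recovered to numerical precision", {
    rg <- exp(seq(log(1), log(1000), length.out = 200))
    geom <- data.frame(r_g = rg, l_complete = 3 * rg^1.5,
                       l_accessible = 2 * rg^1.2)
    fit <- fit_fractal_dimension(geom, "complete",
                                 fit_range = c(min(rg), max(rg)))
    expect_equal(fit$exponent, 1.5, tolerance = 1e-10)
    expect_lt(fit$stderr, 1e-10)
    fit2 <- fit_fractal_dimension(geom, "accessible",
                                  fit_range = c(min(rg), max(rg)))
    expect_equal(fit2$exponent, 1.2, tolerance = 1e-10)
})

test_that("shared axis normalisation does not change the exponent", {
    set.seed(8)
    rg <- exp(runif(400, 0, log(500)))
    l <- 2.2 * rg^1.75 * exp(rnorm(400, sd = 0.05))
    g1 <- data.frame(r_g = rg, l_complete = l)
    g2 <- data.frame(r_g = rg / max(rg), l_complete = l / max(rg))
    f1 <- fit_fractal_dimension(g1, "complete")
    f2 <- fit_fractal_dimension(g2, "complete",
                                fit_range = f1$fit_range / max(rg))
    expect_equal(f1$exponent, f2$exponent, tolerance = 1e-9)
})

test_that("insufficient dynamic range raises a fit error", {
    geom <- data.frame(r_g = runif(50, 10, 11), l_complete = runif(50, 5, 6))
    expect_error(fit_fractal_dimension(geom, "complete"),
                 "range|bins|clusters")
})

test_that("duality product algebra and error propagation", {
    expect_equal(duality_product(7 / 4, 4 / 3), 1)
    expect_equal(duality_product(2, 5 / 4), 1)
    expect_error(duality_product(0.9, 4 / 3), "exceed 1")
    f1 <- structure(list(exponent = 1.75, stderr = 0.01), class = "scaling_fit")
    f2 <- structure(list(exponent = 4 / 3, stderr = 0.02), class = "scaling_fit")
    d <- duality_product(f1, f2)
    expect_equal(as.numeric(d), 1)
    expect_equal(attr(d, "stderr"),
                 sqrt((4 * (4 / 3 - 1) * 0.01)^2 + (4 * 0.75 * 0.02)^2))
})
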