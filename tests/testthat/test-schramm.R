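# Schramm's formula and left-passage inference

test_that("Schramm formula symmetry and midpoint values are exact", {
    for (k in c(1, 2, 8 / 3, 4, 6, 7.5)) {
        expect_equal(schramm_probability(pi / 2, k), 0.5, tolerance = 1e-12)
        for (phi in c(pi / 7, pi / 3, 0.45 * pi))
            expect_equal(schramm_probability(phi, k) +
                         schramm_probability(pi - phi, k), 1,
                         tolerance = 1e-12)
    }
})

test_that("Schramm formula matches the closed-form Student-t oracle", {
    # the hypergeometric term has the closed form of a t CDF with
    # nu = 8/kappa - 1 degrees of freedom (independent evaluation route)
    t_oracle <- function(phi, k) {
        nu <- 8 / k - 1
        pt(cos(phi) / sin(phi) * sqrt(nu), df = nu)
    }
    for (k in c(2, 3, 6, 7.9)) for (phi in pi * c(0.1, 0.25, 0.5, 0.8))
        expect_equal(schramm_probability(phi, k), t_oracle(phi, k),
                     tolerance = 1e-10)
})

test_that("P is strictly decreasing in the angle", {
    phi <- seq(0.05, pi - 0.05, length.out = 40)
    for (k in c(2, 6))
        expect_true(all(diff(schramm_probability(phi, k)) < 0))
})

test_that("domain bounds are enforced", {
    expect_error(schramm_probability(0, 6), "phi")
    expect_error(schramm_probability(pi, 6), "phi")
    expect_error(schramm_probability(pi / 2, 0), "kappa")
    expect_error(schramm_probability(pi / 2, 8), "kappa")
})

test_that("a straight vertical trace is left of right-half points only", {
    tr <- chordal_trace(complex(real = 0, imaginary = seq(0, 10, 0.1)))
    g <- empirical_left_passage(list(tr),
                                points = c(complex(modulus = 1, argument = pi / 4),
                                           complex(modulus = 1, argument = 3 * pi / 4)))
    expect_equal(g$counts_left, c(1L, 0L))
})

test_that("kappa recovery is exact when P follows Schramm's formula", {
    phi <- pi * (1:9) / 10
    for (k0 in c(3, 6)) {
        grid <- data.frame(phi = rep(phi, 3),
                           p_left = rep(schramm_probability(phi, k0), 3),
                           n_eligible = 500)
        est <- estimate_kappa_lpp(grid)
        expect_equal(est$kappa, k0, tolerance = 2e-3)
        expect_lt(est$diagnostics$Q_min, 1e-6)
    }
})

test_that("degenerate passage grids are rejected", {
    grid <- data.frame(phi = pi * (1:9) / 10,
                       p_left = rep(c(0, 1), length.out = 9),
                       n_eligible = 100)
    expect_error(estimate_kappa_lpp(grid), "degenerate")
})
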