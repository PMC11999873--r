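# velocity-field IO and five-point-stencil vorticity

test_that("table dialect reads a regular grid, in any row order", {
    df <- expand.grid(x = c(0, 10, 20), y = c(0, 10, 20))
    df$u <- 1; df$v <- 0
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(df, path, row.names = FALSE)
    f <- read_velocity_field(path)
    expect_equal(dim(f), c(3L, 3L))
    expect_equal(f$spacing, 10)
    expect_true(all(f$u_x == 1) && all(f$u_y == 0))

    # shuffled rows, whitespace separation, comments -> identical field
    path2 <- withr::local_tempfile(fileext = ".txt")
    set.seed(1)
    sh <- df[sample(nrow(df)), ]
    writeLines(c("# PIV export", "x y u v",
                 apply(sh, 1, paste, collapse = " ")), path2)
    f2 <- read_velocity_field(path2)
    expect_equal(f2$u_x, f$u_x)
    expect_equal(f2$u_y, f$u_y)
    expect_equal(f2$spacing, f$spacing)
})

test_that("table dialect rejects irregular and incomplete grids", {
    df <- expand.grid(x = c(0, 10, 25), y = c(0, 10, 20))
    df$u <- 1; df$v <- 0
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(df, path, row.names = FALSE)
    expect_error(read_velocity_field(path), "irregular")

    df2 <- expand.grid(x = c(0, 10, 20), y = c(0, 10, 20))
    df2$u <- 1; df2$v <- 0
    df2 <- df2[-5, ]
    path2 <- withr::local_tempfile(fileext = ".csv")
    write.csv(df2, path2, row.names = FALSE)
    expect_error(read_velocity_field(path2), "missing")
    f <- read_velocity_field(path2, allow_missing = TRUE)
    expect_equal(sum(!f$mask), 1L)
})

test_that("grid container round-trips to machine precision", {
    set.seed(42)
    f <- velocity_field(matrix(rnorm(48), 6, 8), matrix(rnorm(48), 6, 8),
                        spacing = pi / 7, origin = c(-3.2, 11.17))
    path <- withr::local_tempfile(fileext = ".dat")
    write_velocity_field(f, path)
    g <- read_velocity_field(path)
    expect_identical(g$u_x, f$u_x)
    expect_identical(g$u_y, f$u_y)
    expect_identical(g$spacing, f$spacing)
    expect_identical(g$origin, f$origin)
})

test_that("five-point stencil vorticity is exact on canonical fields", {
    w <- compute_vorticity(rigid_rotation_field(Omega = 0.5))
    expect_equal(range(w$omega, na.rm = TRUE), c(1, 1))

    w0 <- compute_vorticity(uniform_field())
    expect_equal(max(abs(w0$omega), na.rm = TRUE), 0)

    # degree-4 polynomial: stencil exact at interior nodes
    p <- polynomial_field(n = 12, h = 0.5)
    w4 <- compute_vorticity(p$field, boundary = "crop")
    inner <- 3:10
    expect_equal(w4$omega[inner, inner], p$omega_exact[inner, inner],
                 tolerance = 1e-10)
})

test_that("crop excludes the two-node frame; periodic wraps", {
    f <- rigid_rotation_field(n = 9)
    w <- compute_vorticity(f, "crop")
    expect_true(all(is.na(w$omega[1:2, ])))
    expect_true(all(is.na(w$omega[, 8:9])))
    expect_equal(w$valid$rows, c(3L, 7L))

    # periodic stencil on a periodic field is exact everywhere
    n <- 16; xy <- 0:(n - 1)
    g <- coord_grids(n)
    fp <- velocity_field(sin(2 * pi * g$y / n), sin(2 * pi * g$x / n))
    wp <- compute_vorticity(fp, "periodic")
    exact <- (2 * pi / n) * (cos(2 * pi * g$x / n) - cos(2 * pi * g$y / n))
    # fourth-order stencil on a smooth periodic field: small uniform error
    expect_lt(max(abs(wp$omega - exact)), 2e-3)
    expect_false(anyNA(wp$omega))
})

test_that("vorticity is linear and blind to uniform translation", {
    set.seed(7)
    n <- 11
    u1 <- matrix(rnorm(n^2), n); v1 <- matrix(rnorm(n^2), n)
    u2 <- matrix(rnorm(n^2), n); v2 <- matrix(rnorm(n^2), n)
    wa <- compute_vorticity(velocity_field(u1, v1))$omega
    wb <- compute_vorticity(velocity_field(u2, v2))$omega
    wab <- compute_vorticity(velocity_field(u1 + 2 * u2, v1 + 2 * v2))$omega
    expect_equal(wab, wa + 2 * wb, tolerance = 1e-12)

    wt <- compute_vorticity(velocity_field(u1 + 5, v1 - 4))$omega
    expect_equal(wt, wa, tolerance = 1e-12)
})

test_that("gradient fields of degree <= 5 potentials have zero vorticity", {
    # u = grad(phi), phi = x^2 y^3 (degree 5): u_x = 2 x y^3, u_y = 3 x^2 y^2
    g <- coord_grids(12, 0.4)
    f <- velocity_field(2 * g$x * g$y^3, 3 * g$x^2 * g$y^2, spacing = 0.4)
    w <- compute_vorticity(f)
    expect_lt(max(abs(w$omega), na.rm = TRUE), 1e-9)
})

test_that("binarization follows the strict positive-sign rule", {
    m <- matrix(c(2, -1, 0, 1e-300), 2, 2)
    b <- binarize_vorticity(m)
    expect_identical(b$sign, matrix(c(1L, 0L, 0L, 1L), 2, 2))

    expect_identical(binarize_vorticity(matrix(0, 3, 3))$sign,
                     matrix(0L, 3, 3))
    cb <- matrix(rep_len(c(1, -1), 25), 5, 5)
    expect_identical(binarize_vorticity(cb)$sign,
                     matrix(rep_len(c(1L, 0L), 25), 5, 5))
})

test_that("binarized vorticity is invariant under positive velocity scaling", {
    set.seed(11)
    n <- 12
    f <- velocity_field(matrix(rnorm(n^2), n), matrix(rnorm(n^2), n))
    f3 <- velocity_field(3.7 * f$u_x, 3.7 * f$u_y)
    b1 <- binarize_vorticity(compute_vorticity(f))
    b2 <- binarize_vorticity(compute_vorticity(f3))
    expect_identical(b1$sign, b2$sign)
})

test_that("too-small grids and interior NaNs are rejected", {
    expect_error(compute_vorticity(uniform_field(n = 4)), "5 nodes")
    n <- 9
    u <- matrix(1, n, n); u[5, 5] <- NaN
    f <- structure(list(u_x = u, u_y = matrix(0, n, n), spacing = 1,
                        origin = c(0, 0), mask = NULL),
                   class = "velocity_field")
    expect_error(compute_vorticity(f), "non-finite")
})
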