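# small synthetic field builders shared across tests

# x varies along columns, y along rows (matrix rows index y, matching
# the field orientation used throughout the package)
coord_grids <- function(n, h = 1) {
    xy <- h * (0:(n - 1))
    list(x = matrix(rep(xy, each = n), n, n),
         y = matrix(rep(xy, times = n), n, n))
}

# rigid rotation u = (-Omega y, Omega x): omega = 2 Omega everywhere
rigid_rotation_field <- function(n = 11, Omega = 0.5, h = 1) {
    g <- coord_grids(n, h)
    velocity_field(-Omega * g$y, Omega * g$x, spacing = h)
}

uniform_field <- function(n = 9, ux = 3, uy = -2, h = 1) {
    velocity_field(matrix(ux, n, n), matrix(uy, n, n), spacing = h)
}

# polynomial field u_x = y^4, u_y = x^3: omega = 3 x^2 - 4 y^3 (exact for
# the degree-4 five-point stencil)
polynomial_field <- function(n = 12, h = 0.5) {
    g <- coord_grids(n, h)
    list(field = velocity_field(g$y^4, g$x^3, spacing = h),
         omega_exact = 3 * g$x^2 - 4 * g$y^3)
}

random_binary <- function(nr, nc, p = 0.5, seed = 1) {
    set.seed(seed)
    binary_field(matrix(as.integer(runif(nr * nc) < p), nr, nc))
}

# brute-force flood-fill labelling oracle (BFS), independent of the
# union-find implementation under test
flood_fill_labels <- function(sign, connectivity) {
    nr <- nrow(sign); nc <- ncol(sign)
    offs <- switch(as.character(connectivity),
        "4" = rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)),
        "6" = rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(-1, -1)),
        "8" = rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                    c(1, 1), c(-1, -1), c(1, -1), c(-1, 1)))
    lab <- matrix(0L, nr, nc)
    cur <- 0L
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
        if (sign[i, j] == 0L || lab[i, j] != 0L) next
        cur <- cur + 1L
        queue <- list(c(i, j)); lab[i, j] <- cur
        while (length(queue)) {
            p0 <- queue[[1L]]; queue <- queue[-1L]
            for (k in seq_len(nrow(offs))) {
                ii <- p0[1] + offs[k, 1]; jj <- p0[2] + offs[k, 2]
                if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                    sign[ii, jj] == 1L && lab[ii, jj] == 0L) {
                    lab[ii, jj] <- cur
                    queue[[length(queue) + 1L]] <- c(ii, jj)
                }
            }
        }
    }
    lab
}

# check the right-hand rule of a traced contour on the lattice: for every
# edge the site half a step to the right is 1, to the left is 0
check_right_hand_rule <- function(trace, binary) {
    v <- trace$vertices
    h <- binary$spacing; o <- binary$origin
    n <- nrow(v) - 1L
    ok <- TRUE
    site <- function(ix, iy) {
        if (ix < 1 || iy < 1 || iy > nrow(binary$sign) ||
            ix > ncol(binary$sign)) return(0L)
        binary$sign[iy, ix]
    }
    for (k in seq_len(n)) {
        mid <- (v[k, ] + v[k + 1L, ]) / 2
        d <- (v[k + 1L, ] - v[k, ]) / h
        right <- mid + h / 2 * c(d[2], -d[1])
        left <- mid - h / 2 * c(d[2], -d[1])
        ir <- round((right - o) / h) + 1L
        il <- round((left - o) / h) + 1L
        if (site(ir[1], ir[2]) != 1L || site(il[1], il[2]) != 0L) {
            ok <- FALSE
            break
        }
    }
    ok
}
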