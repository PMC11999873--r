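# internal helpers

# run `expr` under a fixed RNG seed without clobbering the caller's stream
with_seed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# circular / NA-padded matrix shift: entry (i,j) of the result is
# m(i + di, j + dj), rows = y, cols = x
shift_mat <- function(m, di, dj, periodic = TRUE) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- seq_len(nr) + di
    cj <- seq_len(nc) + dj
    if (periodic) {
        ri <- (ri - 1L) %% nr + 1L
        cj <- (cj - 1L) %% nc + 1L
        m[ri, cj, drop = FALSE]
    } else {
        out <- matrix(NA_real_, nr, nc)
        ok_i <- ri >= 1L & ri <= nr
        ok_j <- cj >= 1L & cj <= nc
        out[ok_i, ok_j] <- m[ri[ok_i], cj[ok_j]]
        out
    }
}

# fourth-order five-point first derivative along x (cols) or y (rows)
stencil5 <- function(m, h, along = c("x", "y"), periodic = FALSE) {
    along <- match.arg(along)
    sh <- function(k) {
        if (along == "x") shift_mat(m, 0L, k, periodic)
        else shift_mat(m, k, 0L, periodic)
    }
    (sh(-2L) - 8 * sh(-1L) + 8 * sh(1L) - sh(2L)) / (12 * h)
}

# second-order central derivative (used by diagnostics on periodic fields)
central1 <- function(m, h, along = c("x", "y"), periodic = TRUE) {
    along <- match.arg(along)
    sh <- function(k) {
        if (along == "x") shift_mat(m, 0L, k, periodic)
        else shift_mat(m, k, 0L, periodic)
    }
    (sh(1L) - sh(-1L)) / (2 * h)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(a) {
    w <- a %% (2 * pi)
    w[w > pi] <- w[w > pi] - 2 * pi
    w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
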