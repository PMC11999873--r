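#' Vertical slit map
#'
#' The elementary solution of the chordal Loewner equation with constant
#' driving: `g(z) = delta + sqrt((z - delta)^2 + 4 Delta)` projects the
#' vertical slit from `delta` to `delta + 2 i sqrt(Delta)` onto the real
#' axis, mapping the upper half-plane minus the slit onto the upper
#' half-plane.  The square-root branch is chosen so that
#' `Re(g - delta)` keeps the sign of `Re(z - delta)` and the image stays
#' in the closed upper half-plane.
#'
#' @param z complex vector in the closed upper half-plane (points
#'   strictly inside the slit are rejected).
#' @param delta slit base position on the real axis.
#' @param Delta capacity increment (> 0); the slit has height
#'   `2 sqrt(Delta)`.
#' @return Complex vector of mapped points.
#' @examples
#' slit_map(1 + 1i, delta = 1, Delta = 0.25)  # slit tip -> its base: 1 + 0i
#' @export
slit_map <- function(z, delta, Delta) {
    if (!is.finite(Delta) || Delta <= 0) stopf("Delta must be positive")
    if (!is.finite(delta)) stopf("delta must be finite")
    .slit_map_cpp(as.complex(z), delta, Delta)
}

#' Extract the Loewner driving function of a chordal trace ("zipper")
#'
#' Unzips a chordal trace by successive vertical slit maps: at step `k`
#' the first unmapped point `w = x + i y` fixes the driving value
#' `U = x` and the capacity increment `Delta = y^2 / 4`; all remaining
#' points are then pushed forward through the slit map.  The result is
#' the discretised driving function `U_t` sampled at the Loewner times
#' `t_k`, the stochastic process whose variance grows as
#' `Var(U_t) = kappa t` for SLE(kappa).
#'
#' Points that touch the real axis (height below `y_floor`) move the
#' driving value without adding capacity and are skipped, keeping the
#' Loewner times strictly increasing.
#'
#' @param trace a `chordal_trace` (or complex vector starting at 0 in
#'   the closed upper half-plane).
#' @param subsample keep every `subsample`-th point before unzipping
#'   (the zipper is O(n^2); lattice traces are conventionally thinned).
#' @param y_floor heights below this are treated as axis touches;
#'   default `1e-9` times the trace extent.
#' @param im_tol tolerance for mapped points dipping below the axis
#'   before a numerical-instability error is raised.
#' @param t_stop stop unzipping once the Loewner time exceeds this value
#'   (the driving at earlier times does not depend on later trace
#'   points, so capping the capacity saves the quadratic tail cost);
#'   `Inf` processes the whole trace.
#' @return Object of class `driving_function`: `times` (strictly
#'   increasing, starting at 0), `values` (`U_{t_k}`, starting at 0)
#'   and `capacity` (final Loewner time).
#' @export
compute_driving_function <- function(trace, subsample = 1, y_floor = NULL,
                                     im_tol = NULL, t_stop = Inf) {
    z <- trace_points(trace)
    if (length(z) >= 1L && Mod(z[1L]) != 0)
        stopf("chordal trace must start at the origin")
    if (subsample > 1) {
        idx <- unique(c(seq(1L, length(z), by = as.integer(subsample)),
                        length(z)))
        z <- z[idx]
    }
    if (length(z) < 10L) stopf("trace too short for driving-function extraction")
    ext <- max(Mod(z))
    if (is.null(y_floor)) y_floor <- 1e-9 * ext
    if (is.null(im_tol)) im_tol <- 1e-6 * ext
    neg <- Im(z) < 0
    if (any(Im(z)[neg] < -im_tol))
        stopf("trace has points below the real axis")
    z[neg] <- complex(real = Re(z)[neg], imaginary = 0)
    res <- .zipper_cpp(z, y_floor, im_tol,
                       if (is.finite(t_stop)) t_stop else -1)
    structure(list(times = c(0, res$times), values = c(0, res$values),
                   capacity = res$times[length(res$times)]),
              class = "driving_function")
}

#' @export
print.driving_function <- function(x, ...) {
    cat(sprintf("<driving_function> %d steps, capacity %.4g, U in [%.4g, %.4g]\n",
                length(x$times) - 1L, x$capacity, min(x$values), max(x$values)))
    invisible(x)
}

#' @export
plot.driving_function <- function(x, normalized = FALSE, ...) {
    t <- if (normalized) x$times / x$capacity else x$times
    plot(t, x$values, type = "s",
         xlab = if (normalized) "t / T" else "Loewner time t",
         ylab = expression(U[t]), ...)
    invisible(x)
}

# piecewise-constant interpolation of a driving function on a time grid
# (U is constant on (t_{k-1}, t_k] at value_k, matching the zipper)
interp_driving <- function(df, t_grid) {
    approx(df$times, df$values, xout = t_grid, method = "constant",
           f = 1, rule = 2, ties = "ordered")$y
}

#' Estimate kappa from the variance growth of driving functions
#'
#' Interpolates an ensemble of driving functions onto a common time
#' grid (piecewise-constant, matching the zipper discretisation), fits
#' the ensemble variance linearly through the origin,
#' `Var(U_t) = kappa t`, and reports the slope as the diffusivity (the
#' standard error is bootstrapped over traces, since the variance
#' estimates at different times share paths).  The
#' fit is performed in trace time units; for the distributional
#' collapse diagnostic each trace is then rescaled to its own final
#' capacity and the rescaled values `U_t / sqrt(kappa t)` at normalised
#' times `t = 0.25` and `t = 0.75` are compared against a unit normal
#' (Kolmogorov-Smirnov distance).
#'
#' @param dfs list of `driving_function` objects.
#' @param t_grid optional common time grid; default `n_grid` points up
#'   to the `t_max_quantile` quantile of the final capacities (traces
#'   not reaching the grid end are dropped).
#' @param t_max_quantile,n_grid construction of the default grid.
#' @param collapse_times normalised times of the collapse diagnostic.
#' @param min_traces minimum ensemble size.
#' @return Object of class `kappa_estimate` with
#'   `method = "driving_variance"`; diagnostics hold the variance
#'   curve, the rescaled samples and their KS distances.
#' @export
fit_kappa_driving <- function(dfs, t_grid = NULL, t_max_quantile = 0.25,
                              n_grid = 50, collapse_times = c(0.25, 0.75),
                              min_traces = 50) {
    caps <- vapply(dfs, `[[`, numeric(1), "capacity")
    if (is.null(t_grid)) {
        t_max <- unname(quantile(caps, t_max_quantile))
        # the default grid must leave at least min_traces traces that
        # reach its end, so cap it at the min_traces-th largest capacity
        if (length(caps) >= min_traces)
            t_max <- min(t_max, sort(caps, decreasing = TRUE)[min_traces])
        t_grid <- seq(t_max / n_grid, t_max, length.out = n_grid)
    }
    keep <- caps >= t_grid[length(t_grid)]
    if (sum(keep) < min_traces)
        stopf("only %d driving functions reach the end of the time grid (need %d)",
              sum(keep), min_traces)
    used <- dfs[keep]
    U <- vapply(used, interp_driving, numeric(length(t_grid)),
                t_grid = t_grid)       # n_grid x n_traces
    v <- apply(U, 1L, var)
    # through-origin least squares of the ensemble variance curve; the
    # standard error comes from a bootstrap over traces because the
    # variance estimates at different times share the same paths
    slope_of <- function(vv) sum(vv * t_grid) / sum(t_grid^2)
    kappa <- slope_of(v)
    nb <- 100L
    bs <- with_seed(1402L, vapply(seq_len(nb), function(b) {
        idx <- sample.int(ncol(U), ncol(U), replace = TRUE)
        slope_of(apply(U[, idx, drop = FALSE], 1L, var))
    }, numeric(1)))  # fixed resampling stream: se is reproducible
    se <- sd(bs)
    collapse <- list(); ks <- c()
    for (tc in collapse_times) {
        u <- vapply(used, function(d)
            interp_driving(d, tc * d$capacity) / sqrt(kappa * tc * d$capacity),
            numeric(1))
        collapse[[sprintf("%g", tc)]] <- u
        ks[sprintf("%g", tc)] <-
            unname(suppressWarnings(ks.test(u, "pnorm"))$statistic)
    }
    new_kappa_estimate(kappa, se, "driving_variance",
                       diagnostics = list(t_grid = t_grid, variance = v,
                                          n_traces = sum(keep),
                                          collapse = collapse,
                                          ks_distance = ks))
}

#' Autocorrelation of driving-function increments
#'
#' Pearson correlation across the ensemble between increments
#' `dU_t` and `dU_{t + tau}` on a common uniform time grid,
#' \deqn{C(t; \tau) = \mathrm{Cov}(\delta U_{t+\tau}, \delta U_t) /
#'   \sqrt{\mathrm{Var}(\delta U_{t+\tau})\,\mathrm{Var}(\delta U_t)}.}
#' For a Markovian (Brownian) driving process `C(t; tau > 0) = 0`;
#' `C(t; 0) = 1` by construction.  With `t = NULL` the correlation is
#' averaged over all grid times at each lag (increment stationarity),
#' which is the low-noise summary used for Markovianity checks.
#'
#' @param dfs list of `driving_function` objects.
#' @param taus lags, in grid steps.
#' @param t time (in grid steps) of the first increment, or `NULL` to
#'   average over all available times.
#' @param t_max_quantile,n_grid common-grid construction as in
#'   [fit_kappa_driving()].
#' @return data.frame with columns `tau` (grid steps) and `C`.
#' @export
driving_autocorrelation <- function(dfs, taus = 0:8, t = NULL,
                                    t_max_quantile = 0.25, n_grid = 64) {
    caps <- vapply(dfs, `[[`, numeric(1), "capacity")
    t_max <- unname(quantile(caps, t_max_quantile))
    t_grid <- seq(0, t_max, length.out = n_grid + 1L)
    used <- dfs[caps >= t_max]
    if (length(used) < 10L) stopf("too few driving functions")
    U <- vapply(used, interp_driving, numeric(length(t_grid)),
                t_grid = t_grid)
    dU <- diff(U)                      # n_grid x n_traces
    nsteps <- nrow(dU)
    corr_at <- function(i, j) {
        a <- dU[i, ]; b <- dU[j, ]
        if (sd(a) == 0 || sd(b) == 0) stopf("zero-variance increments")
        stats::cor(a, b)
    }
    C <- vapply(taus, function(tau) {
        if (!is.null(t)) {
            i <- as.integer(t)
            if (i < 1L || i + tau > nsteps) return(NA_real_)
            corr_at(i, i + tau)
        } else {
            ii <- seq_len(nsteps - tau)
            mean(vapply(ii, function(i) corr_at(i, i + tau), numeric(1)))
        }
    }, numeric(1))
    data.frame(tau = taus, C = C)
}
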