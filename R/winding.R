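#' Cumulative winding angle along a trace
#'
#' The winding angle `theta_j` is the cumulative sum of the signed local
#' turning angles `alpha_i` between consecutive segments, each wrapped
#' to `(-pi, pi]`.  For closed traces the turn closing the loop is
#' included, so the total winding of a simple closed trace is exactly
#' `+/- 2 pi` (Gauss turning theorem; sign set by the traversal
#' direction).
#'
#' @param trace a `contour_trace`, `chordal_trace`, complex vector or
#'   two-column matrix (at least 3 distinct vertices).
#' @return Numeric vector starting at 0: `theta_j` after each turn.
#' @export
winding_angles <- function(trace) {
    z <- trace_points(trace)
    closed <- inherits(trace, "contour_trace") && isTRUE(trace$closed)
    if (closed && z[1L] == z[length(z)]) z <- z[-length(z)]
    dz <- diff(z)
    if (closed) dz <- c(dz, z[1L] - z[length(z)])
    if (any(Mod(dz) == 0)) stopf("degenerate segment: repeated identical vertices")
    if (length(dz) < 2L) stopf("trace needs at least 3 vertices")
    ang <- Arg(dz)
    # for closed traces the turn from the closing segment back onto the
    # first segment completes the loop (total winding +/- 2 pi)
    alpha <- wrap_angle(diff(if (closed) c(ang, ang[1L]) else ang))
    c(0, cumsum(alpha))
}

#' Diffusivity from the winding-angle variance slope
#'
#' Inverts `alpha = 2 kappa / (8 + kappa)`.
#' @param alpha slope of `Var(theta)` against `log s`, in (0, 2).
#' @return `kappa = 8 alpha / (2 - alpha)`.
#' @export
kappa_from_alpha <- function(alpha) {
    if (any(alpha <= 0 | alpha >= 2)) stopf("alpha must lie in (0, 2)")
    8 * alpha / (2 - alpha)
}

#' @rdname kappa_from_alpha
#' @param kappa diffusivity in (0, 8).
#' @export
alpha_from_kappa <- function(kappa) {
    2 * kappa / (8 + kappa)
}

# pooled winding angles within windows of s steps, each measured
# relative to the window's average angle; deterministic evenly-spaced
# window starts.  The log-slope of the pooled variance is the
# conformal-curve coefficient 2 kappa / (8 + kappa): measuring within a
# segment halves the end-to-end increment coefficient (both increment
# ends fluctuate) and recovers the convention in which the winding is
# taken relative to the contour's average direction.
window_windings <- function(theta, s, n_windows) {
    L <- length(theta)
    if (L <= s + 1L) return(numeric())
    starts <- unique(round(seq(1L, L - s, length.out = min(n_windows, L - s))))
    unlist(lapply(starts, function(r) {
        seg <- theta[r:(r + s)]
        seg - mean(seg)
    }), use.names = FALSE)
}

#' Fit the logarithmic growth of the winding-angle variance
#'
#' For conformally invariant curve ensembles the variance of the
#' winding angle at distance `s` along the curve grows as
#' `Var(theta) = a + (2 kappa / (8 + kappa)) log(s)`.  The winding is
#' measured within evenly spaced segments of `s` steps, relative to
#' each segment's average angle (which is what makes the coefficient
#' the conformal one: end-to-end increments over interior windows pick
#' up the fluctuation of both ends and double the slope).  The pooled
#' variance is evaluated on a logarithmic grid of arclengths, fitted
#' linearly in `log s`, and the slope inverted for `kappa`.
#' Gaussianity of the winding distribution is assessed at fixed window
#' lengths (64 and 512 steps by default) by standardised moments
#' (flagged Gaussian when `|skewness| < 0.2` and `|excess kurtosis| <
#' 0.3`).
#'
#' @param traces list of traces (any representation accepted by
#'   [winding_angles()]), or a list of precomputed winding-angle series
#'   (plain numeric vectors, in which case `Var(theta(s))` is measured
#'   directly across the series with no segment pooling).
#' @param s_grid arclengths (vertex steps) at which to evaluate the
#'   variance; default a logarithmic grid in `[s_min, L/4]` where `L`
#'   is the shortest trace.
#' @param s_min smallest arclength of the default grid.
#' @param n_windows windows sampled per trace per arclength.
#' @param gaussian_s window lengths for the Gaussianity diagnostic.
#' @param min_traces minimum ensemble size.
#' @return Object of class `winding_fit`: `slope_alpha`, `intercept_a`,
#'   `stderr`, `kappa_from_alpha`, the variance table, and a
#'   `gaussian` diagnostic frame.
#' @export
winding_variance_fit <- function(traces, s_grid = NULL, s_min = 16,
                                 n_windows = 16, gaussian_s = c(64, 512),
                                 min_traces = 50) {
    if (length(traces) < min_traces)
        stopf("need at least %d traces (got %d)", min_traces, length(traces))
    raw_series <- is.numeric(traces[[1L]]) && !is.matrix(traces[[1L]]) &&
        !is.complex(traces[[1L]])
    thetas <- if (raw_series) traces else lapply(traces, winding_angles)
    L <- min(lengths(thetas)) - 1L
    if (is.null(s_grid)) {
        s_max <- max(s_min + 1, L %/% 4L)
        s_grid <- unique(round(exp(seq(log(s_min), log(s_max),
                                       length.out = 14))))
    }
    s_grid <- s_grid[s_grid >= 2 & s_grid <= L]
    if (length(s_grid) < 4L)
        stopf("traces too short for the requested arclength grid")
    samples_at <- function(s) {
        if (raw_series) {
            v <- vapply(thetas, function(th)
                if (length(th) > s) th[s + 1L] - th[1L] else NA_real_,
                numeric(1))
            v[is.finite(v)]
        } else {
            unlist(lapply(thetas, window_windings, s = s,
                          n_windows = n_windows), use.names = FALSE)
        }
    }
    vars <- vapply(s_grid, function(s) var(samples_at(s)), numeric(1))
    fit <- lm(vars ~ log(s_grid))
    sm <- summary(fit)$coefficients
    alpha <- unname(coef(fit)[2])
    gauss <- NULL
    for (s in gaussian_s) {
        if (s > L) next
        w <- samples_at(s)
        if (length(w) < 100L) next
        zc <- (w - mean(w)) / sd(w)
        sk <- mean(zc^3)
        ku <- mean(zc^4) - 3
        ks <- suppressWarnings(ks.test(zc, "pnorm"))$statistic
        gauss <- rbind(gauss, data.frame(
            s = s, n = length(w), skewness = sk, excess_kurtosis = ku,
            ks_distance = unname(ks),
            gaussian = abs(sk) < 0.2 && abs(ku) < 0.3))
    }
    structure(list(slope_alpha = alpha,
                   intercept_a = unname(coef(fit)[1]),
                   stderr = unname(sm[2, 2]),
                   kappa_from_alpha =
                       if (alpha > 0 && alpha < 2) kappa_from_alpha(alpha)
                       else NA_real_,
                   arclengths = s_grid, variances = unname(vars),
                   gaussian = gauss, n_traces = length(thetas)),
              class = "winding_fit")
}

#' @export
print.winding_fit <- function(x, ...) {
    cat(sprintf("<winding_fit> Var(theta) = %.4f + %.4f log s  (se %.4f)\n",
                x$intercept_a, x$slope_alpha, x$stderr))
    cat(sprintf("  kappa from alpha: %.3f; %d traces, s in [%d, %d]\n",
                x$kappa_from_alpha, x$n_traces, min(x$arclengths),
                max(x$arclengths)))
    if (!is.null(x$gaussian)) {
        for (i in seq_len(nrow(x$gaussian)))
            cat(sprintf("  s = %4d: skew %+.3f, ex.kurt %+.3f (%s)\n",
                        x$gaussian$s[i], x$gaussian$skewness[i],
                        x$gaussian$excess_kurtosis[i],
                        if (x$gaussian$gaussian[i]) "Gaussian" else "non-Gaussian"))
    }
    invisible(x)
}

#' @export
coef.winding_fit <- function(object, ...) {
    c(alpha = object$slope_alpha, a = object$intercept_a,
      kappa = object$kappa_from_alpha)
}

#' @export
plot.winding_fit <- function(x, ...) {
    plot(x$arclengths, x$variances, log = "x", pch = 19,
         xlab = "s (vertex steps)", ylab = "Var(theta)", ...)
    curve(x$intercept_a + x$slope_alpha * log(s), xname = "s",
          add = TRUE, col = "red3")
    legend("topleft", bty = "n",
           legend = sprintf("slope %.3f (kappa %.2f)", x$slope_alpha,
                            x$kappa_from_alpha))
    invisible(x)
}
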