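#' Sample a forward SLE(kappa) trace from Brownian driving
#'
#' Discrete forward Loewner evolution: the driving function
#' `U_t = sqrt(kappa) B_t` is sampled as a Brownian path on a uniform
#' partition of step `dt`, held constant on each step, and the trace tip
#' is reconstructed by composing inverse vertical slit maps in reverse
#' order.  This generator is the exact inverse of
#' [compute_driving_function()] on the same partition, which makes the
#' forward/zipper round trip a machine-precision identity test.
#'
#' `kappa = 0` produces the degenerate straight vertical trace.
#'
#' @param kappa diffusivity in `[0, 8)`.
#' @param n_steps number of partition steps (>= 100).
#' @param dt Loewner-time step; final capacity is `n_steps * dt`.
#' @param seed optional RNG seed.
#' @return A `chordal_trace` with `n_steps + 1` points starting at 0.
#' @examples
#' tr <- sample_sle_trace(2, n_steps = 200, seed = 1)
#' tr
#' @export
sample_sle_trace <- function(kappa, n_steps = 1000, dt = 1e-4, seed = NULL) {
    if (!is.finite(kappa) || kappa < 0 || kappa >= 8)
        stopf("kappa must lie in [0, 8)")
    if (n_steps < 100) stopf("n_steps must be at least 100")
    delta <- if (kappa == 0) rep(0, n_steps) else
        with_seed(seed, sqrt(kappa) * cumsum(rnorm(n_steps, sd = sqrt(dt))))
    z <- .forward_trace_cpp(delta, rep(dt, n_steps))
    structure(list(points = c(complex(real = 0, imaginary = 0), z),
                   spacing = NA_real_, axis_offset = 0, origin = c(0, 0),
                   mirrored = FALSE, stopped = "forward_sle",
                   driving = list(times = dt * seq_len(n_steps),
                                  values = delta)),
              class = "chordal_trace")
}

#' Ensemble of forward SLE traces
#'
#' @param n number of traces.
#' @param kappa diffusivity in `[0, 8)`.
#' @param n_steps,dt passed to [sample_sle_trace()].
#' @param seed master seed; traces use independent substreams.
#' @return List of `chordal_trace` objects.
#' @export
sle_trace_ensemble <- function(n, kappa, n_steps = 1000, dt = 1e-4,
                               seed = NULL) {
    seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
    lapply(seq_len(n), function(i)
        sample_sle_trace(kappa, n_steps, dt, seed = seeds[i]))
}
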