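#' Compute the vorticity field with a five-point stencil
#'
#' Evaluates `omega = dx u_y - dy u_x` at every grid node, each partial
#' derivative by the fourth-order five-point central stencil
#' `(f[-2] - 8 f[-1] + 8 f[+1] - f[+2]) / (12 h)`, which is exact for
#' polynomials up to degree 4.  With `boundary = "crop"` the outer
#' two-node frame (where the stencil is undefined) is excluded from the
#' valid region, mirroring the treatment of experimental fields whose
#' image edges are discarded; with `boundary = "periodic"` the stencil
#' wraps, as appropriate for simulation snapshots.
#'
#' @param field a [velocity_field()].
#' @param boundary `"crop"` (default) or `"periodic"`.
#' @return An object of class `vorticity_field` with elements `omega`
#'   (full-size matrix, `NA` outside the valid region), `spacing`,
#'   `origin`, `valid` (list of row/col index ranges) and `boundary`.
#' @examples
#' n <- 9; xy <- (0:(n - 1))
#' u <- -0.5 * matrix(rep(xy, n), n, n, byrow = FALSE)  # u_x = -Omega y
#' v <-  0.5 * matrix(rep(xy, n), n, n, byrow = TRUE)   # u_y =  Omega x
#' w <- compute_vorticity(velocity_field(u, v))
#' range(w$omega, na.rm = TRUE)  # rigid rotation: omega = 2 Omega = 1
#' @export
compute_vorticity <- function(field, boundary = c("crop", "periodic")) {
    stopifnot(inherits(field, "velocity_field"))
    boundary <- match.arg(boundary)
    nr <- nrow(field$u_x); nc <- ncol(field$u_x)
    if (nr < 5L || nc < 5L)
        stopf("grid too small for the five-point stencil (need >= 5 nodes per axis)")
    periodic <- boundary == "periodic"
    h <- field$spacing
    omega <- stencil5(field$u_y, h, "x", periodic) -
             stencil5(field$u_x, h, "y", periodic)
    if (periodic) {
        valid <- list(rows = c(1L, nr), cols = c(1L, nc))
    } else {
        valid <- list(rows = c(3L, nr - 2L), cols = c(3L, nc - 2L))
        keep <- matrix(FALSE, nr, nc)
        keep[valid$rows[1]:valid$rows[2], valid$cols[1]:valid$cols[2]] <- TRUE
        omega[!keep] <- NA_real_
    }
    vr <- omega[valid$rows[1]:valid$rows[2], valid$cols[1]:valid$cols[2]]
    if (!all(is.finite(vr)))
        stopf("non-finite vorticity inside the valid region (NA/NaN in input?)")
    structure(list(omega = omega, spacing = h, origin = field$origin,
                   valid = valid, boundary = boundary),
              class = "vorticity_field")
}

#' @export
print.vorticity_field <- function(x, ...) {
    cat(sprintf("<vorticity_field> %d x %d, spacing %g, boundary %s\n",
                nrow(x$omega), ncol(x$omega), x$spacing, x$boundary))
    cat(sprintf("  omega in [%.4g, %.4g] on the valid region\n",
                min(x$omega, na.rm = TRUE), max(x$omega, na.rm = TRUE)))
    invisible(x)
}

#' Binarize a vorticity field by sign
#'
#' Applies the strict ternary rule `1 if omega > 0 else 0` on the valid
#' region of the vorticity field; exact zeros join the non-positive
#' phase.  For cropped fields the result is restricted to the valid
#' region (its origin is shifted accordingly).
#'
#' @param vort a `vorticity_field` from [compute_vorticity()], or a bare
#'   numeric matrix (spacing 1, origin 0).
#' @return An object of class `binary_vorticity` with integer matrix
#'   `sign` (entries 0/1), `spacing` and `origin`.
#' @export
binarize_vorticity <- function(vort) {
    if (is.matrix(vort))
        vort <- structure(list(omega = vort, spacing = 1, origin = c(0, 0),
                               valid = list(rows = c(1L, nrow(vort)),
                                            cols = c(1L, ncol(vort))),
                               boundary = "periodic"),
                          class = "vorticity_field")
    stopifnot(inherits(vort, "vorticity_field"))
    rows <- vort$valid$rows; cols <- vort$valid$cols
    om <- vort$omega[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    if (!all(is.finite(om))) stopf("non-finite vorticity in valid region")
    sgn <- matrix(as.integer(om > 0), nrow(om), ncol(om))
    origin <- vort$origin + vort$spacing * c(cols[1] - 1L, rows[1] - 1L)
    binary_field(sgn, spacing = vort$spacing, origin = origin)
}

#' Construct a binary vorticity-sign field
#'
#' Low-level constructor used by [binarize_vorticity()] and the
#' synthetic generators.
#'
#' @param sign integer/logical matrix of 0s and 1s (1 = positive phase).
#' @param spacing grid step.
#' @param origin physical coordinate of node `[1, 1]`.
#' @return Object of class `binary_vorticity`.
#' @export
binary_field <- function(sign, spacing = 1, origin = c(0, 0)) {
    sign <- as.matrix(sign)
    st <- matrix(as.integer(sign), nrow(sign), ncol(sign))
    if (anyNA(st) || !all(st %in% c(0L, 1L)))
        stopf("binary field entries must be 0 or 1")
    structure(list(sign = st, spacing = as.numeric(spacing),
                   origin = as.numeric(origin)),
              class = "binary_vorticity")
}

#' @export
print.binary_vorticity <- function(x, ...) {
    cat(sprintf("<binary_vorticity> %d x %d, spacing %g, %.1f%% positive\n",
                nrow(x$sign), ncol(x$sign), x$spacing, 100 * mean(x$sign)))
    invisible(x)
}

#' Write a vorticity field in the dense grid container
#'
#' Reuses the [write_velocity_field()] container with `u_y` zeroed; the
#' vorticity occupies the first block.
#' @param vort a `vorticity_field`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vorticity_field <- function(vort, path) {
    stopifnot(inherits(vort, "vorticity_field"))
    om <- vort$omega
    mask <- is.finite(om)
    om[!mask] <- 0
    f <- velocity_field(om, matrix(0, nrow(om), ncol(om)),
                        spacing = vort$spacing, origin = vort$origin,
                        mask = if (all(mask)) NULL else mask)
    write_velocity_field(f, path)
}
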