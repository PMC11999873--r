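#' Radius of gyration of a set of lattice points
#'
#' Root-mean-square distance of the sites from their centroid,
#' `R_g^2 = (1/N) sum_n |r_n - rbar|^2`, algebraically equal to the
#' pair form `(1/(2 N^2)) sum_{n,m} |r_n - r_m|^2`.
#'
#' @param sites two-column matrix (or data.frame) of point coordinates.
#' @return Non-negative number; 0 for a single site.
#' @examples
#' gyration_radius(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))  # sqrt(1/2)
#' @export
gyration_radius <- function(sites) {
    sites <- as.matrix(sites)
    if (!nrow(sites)) stopf("empty site set")
    if (ncol(sites) != 2L) stopf("sites must have two columns")
    v <- mean(sites[, 1]^2) - mean(sites[, 1])^2 +
         mean(sites[, 2]^2) - mean(sites[, 2])^2
    sqrt(max(v, 0))
}

#' Per-cluster geometry table
#'
#' For every labelled cluster of the positive phase: site count,
#' gyration radius, complete outer-perimeter length and (optionally)
#' accessible external-perimeter length.  Perimeters are vertex-step
#' counts times the grid step `h`.
#'
#' @param binary a `binary_vorticity` field (or 0/1 matrix).
#' @param connectivity 4, 6 or 8.
#' @param min_size drop clusters with fewer sites.
#' @param accessible compute accessible perimeters as well.
#' @param accessible_min_edges only compute the (more expensive)
#'   accessible perimeter for clusters whose complete perimeter has at
#'   least this many edges; others get `NA`.
#' @return data.frame with columns `label`, `size`, `r_g`,
#'   `l_complete`, `l_accessible`.
#' @export
cluster_geometry <- function(binary, connectivity = 4, min_size = 2,
                             accessible = TRUE, accessible_min_edges = 32) {
    binary <- as_binary(binary)
    lab <- label_clusters(binary, connectivity)
    if (lab$n_clusters == 0L)
        return(data.frame(label = integer(), size = integer(),
                          r_g = numeric(), l_complete = numeric(),
                          l_accessible = numeric()))
    # edge-count kernels: no per-contour objects are materialised
    h <- binary$spacing
    edges <- .cluster_perims_cpp(binary$sign, lab$labels, lab$n_clusters,
                                 as.integer(connectivity))
    df <- data.frame(label = seq_len(lab$n_clusters), size = lab$sizes,
                     r_g = lab$r_g, l_complete = edges * h,
                     l_accessible = NA_real_)
    df <- df[df$size >= min_size, , drop = FALSE]
    if (accessible) {
        sel <- which(df$l_complete / h >= accessible_min_edges)
        if (length(sel)) {
            acc <- .accessible_perims_cpp(lab$labels, df$label[sel],
                                          as.integer(connectivity))
            df$l_accessible[sel] <- acc * h
        }
    }
    rownames(df) <- NULL
    df
}

#' Fit a perimeter/gyration-radius fractal dimension
#'
#' Least-squares fit of `log l` against `log R_g` over an ensemble of
#' clusters, expecting `l ~ R_g^D`.  The cloud of clusters is reduced to
#' logarithmically binned medians (12 bins per decade by default)
#' before fitting.
#'
#' The default fit window excludes the lattice regime below and the
#' finite-size regime above.  For complete perimeters it is
#' `[10 h, R_max / 4]`, where `h` is the grid step and `R_max` the
#' largest gyration radius in the ensemble: hull scaling carries strong
#' corrections over the first decade of lattice units, and the largest
#' clusters are cut by the system size.  For accessible perimeters the
#' window is `[32 h, R_max / 2]`: the closing that seals the fjords
#' adds its own morphological scale, so the external-perimeter scaling
#' sets in later (effective exponents below 4/3 persist to radii of a
#' few tens of lattice units), while accessible perimeters are only
#' measured for large clusters in the first place.  Axes may be
#' normalised by the gyration radius of the largest cluster
#' (`normalization`); a shared rescaling leaves the exponent unchanged.
#'
#' @param geometries data.frame from [cluster_geometry()] (or any frame
#'   with columns `r_g` plus `l_complete` / `l_accessible`), or a list
#'   of such frames (rows are pooled).
#' @param kind `"complete"` or `"accessible"`.
#' @param fit_range optional `c(R_min, R_max)` overriding the default
#'   window.
#' @param spacing grid step `h` used by the default window (the
#'   geometry tables are in physical units).
#' @param bins_per_decade bins per decade of `R_g` for the median
#'   reduction.
#' @param min_points minimum number of populated bins required.
#' @return Object of class `scaling_fit` with `exponent`, `intercept`,
#'   `stderr`, `fit_range`, `n_points`, `normalization`, `kind` and the
#'   binned table.
#' @export
fit_fractal_dimension <- function(geometries, kind = c("complete", "accessible"),
                                  fit_range = NULL, spacing = 1,
                                  bins_per_decade = 12, min_points = 10) {
    kind <- match.arg(kind)
    if (is.data.frame(geometries)) geometries <- list(geometries)
    df <- do.call(rbind, geometries)
    col <- paste0("l_", kind)
    if (!all(c("r_g", col) %in% names(df)))
        stopf("geometries must have columns r_g and %s", col)
    x <- df$r_g; y <- df[[col]]
    ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
    x <- x[ok]; y <- y[ok]
    if (length(x) < min_points) stopf("too few clusters for a scaling fit")
    rg_max <- if ("r_g" %in% names(df)) max(df$r_g[is.finite(df$r_g)]) else max(x)
    if (is.null(fit_range)) {
        fit_range <- if (kind == "complete") c(10 * spacing, rg_max / 4)
                     else c(32 * spacing, rg_max / 2)
    }
    if (fit_range[2] <= fit_range[1])
        stopf("empty fit range [%g, %g]", fit_range[1], fit_range[2])
    sel <- x >= fit_range[1] & x <= fit_range[2]
    if (sum(sel) < min_points)
        stopf("insufficient dynamic range: only %d clusters inside [%g, %g]",
              sum(sel), fit_range[1], fit_range[2])
    lx <- log10(x[sel]); ly <- log10(y[sel])
    breaks <- seq(min(lx) - 1e-9, max(lx) + 1e-9,
                  length.out = max(2L, ceiling(diff(range(lx)) * bins_per_decade) + 1L))
    bin <- cut(lx, breaks, include.lowest = TRUE)
    bx <- tapply(lx, bin, median); by <- tapply(ly, bin, median)
    nb <- tapply(lx, bin, length)
    ok <- !is.na(bx)
    bx <- bx[ok]; by <- by[ok]; nb <- nb[ok]
    if (length(bx) < min_points)
        stopf("insufficient dynamic range: only %d populated bins", length(bx))
    fit <- lm(by ~ bx)
    s <- summary(fit)$coefficients
    structure(list(exponent = unname(coef(fit)[2]),
                   intercept = unname(coef(fit)[1]),
                   stderr = unname(s[2, 2]),
                   fit_range = fit_range,
                   n_points = length(bx),
                   n_clusters = sum(sel),
                   normalization = rg_max,
                   kind = kind,
                   binned = data.frame(log10_rg = unname(bx),
                                       log10_l = unname(by),
                                       n = as.integer(nb))),
              class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
    cat(sprintf("<scaling_fit> %s perimeter: D = %.4f +/- %.4f\n",
                x$kind, x$exponent, x$stderr))
    cat(sprintf("  %d binned points from %d clusters, R_g in [%.3g, %.3g], R_g,max = %.4g\n",
                x$n_points, x$n_clusters, x$fit_range[1], x$fit_range[2],
                x$normalization))
    invisible(x)
}

#' @export
summary.scaling_fit <- function(object, ...) {
    cat(sprintf("Perimeter scaling fit (%s)\n", object$kind))
    cat(sprintf("  exponent  %.5f (se %.5f)\n", object$exponent, object$stderr))
    cat(sprintf("  intercept %.5f\n", object$intercept))
    cat(sprintf("  window    [%.4g, %.4g], %d bins, %d clusters\n",
                object$fit_range[1], object$fit_range[2], object$n_points,
                object$n_clusters))
    invisible(object)
}

#' @export
coef.scaling_fit <- function(object, ...) {
    c(exponent = object$exponent, intercept = object$intercept)
}

#' @export
plot.scaling_fit <- function(x, ...) {
    b <- x$binned
    plot(b$log10_rg, b$log10_l, pch = 19,
         xlab = "log10 R_g", ylab = sprintf("log10 l (%s)", x$kind), ...)
    abline(x$intercept, x$exponent, col = "red3")
    legend("topleft", bty = "n",
           legend = sprintf("slope %.3f +/- %.3f", x$exponent, x$stderr))
    invisible(x)
}

#' Duality product of complete and accessible perimeter dimensions
#'
#' For conformally invariant curves the complete perimeter dimension `D`
#' and the accessible external-perimeter dimension `D*` are conjectured
#' to satisfy `4 (D - 1)(D* - 1) = 1`.
#'
#' @param D,D_star exponents (> 1) or `scaling_fit` objects; standard
#'   errors are propagated when fits are supplied.
#' @return The product, with attribute `"stderr"` when available.
#' @examples
#' duality_product(7 / 4, 4 / 3)  # exactly 1
#' @export
duality_product <- function(D, D_star) {
    se_d <- se_s <- NA_real_
    if (inherits(D, "scaling_fit")) { se_d <- D$stderr; D <- D$exponent }
    if (inherits(D_star, "scaling_fit")) { se_s <- D_star$stderr; D_star <- D_star$exponent }
    if (D <= 1 || D_star <= 1) stopf("exponents must both exceed 1")
    val <- 4 * (D - 1) * (D_star - 1)
    if (is.finite(se_d) && is.finite(se_s)) {
        se <- sqrt((4 * (D_star - 1) * se_d)^2 + (4 * (D - 1) * se_s)^2)
        attr(val, "stderr") <- se
    }
    val
}
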