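#' Label connected clusters of the positive-vorticity phase
#'
#' Two-pass connected-component labelling with union-find.  Labels are
#' assigned in raster-scan first-contact order, so the labelling is
#' deterministic.  Connectivity 6 is the square-grid embedding of the
#' triangular lattice (extra neighbours along the `(+1,+1)` diagonal),
#' the natural choice for the critical-percolation reference fields.
#'
#' @param binary a `binary_vorticity` field (or 0/1 matrix).
#' @param connectivity 4, 6 or 8.
#' @return Object of class `cluster_labeling`: `labels` (integer
#'   matrix, 0 = background), `n_clusters`, `sizes`, `r_g` (per-cluster
#'   gyration radius, physical units), `connectivity`, `spacing`,
#'   `origin`.
#' @export
label_clusters <- function(binary, connectivity = 4) {
    binary <- as_binary(binary)
    connectivity <- as.integer(connectivity)
    if (!connectivity %in% c(4L, 6L, 8L))
        stopf("connectivity must be 4, 6 or 8")
    res <- .cc_label(binary$sign, connectivity)
    structure(list(labels = res$labels, n_clusters = res$n_clusters,
                   sizes = res$sizes, r_g = res$r_g * binary$spacing,
                   connectivity = connectivity, spacing = binary$spacing,
                   origin = binary$origin),
              class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
    cat(sprintf("<cluster_labeling> %d clusters (connectivity %d), largest %d sites\n",
                x$n_clusters, x$connectivity,
                if (x$n_clusters) max(x$sizes) else 0L))
    invisible(x)
}

as_binary <- function(binary) {
    if (inherits(binary, "binary_vorticity")) binary
    else binary_field(binary)
}

#' Trace oriented zero-vorticity contours
#'
#' Orientation-preserving marching squares: every closed trace walks the
#' cluster boundary keeping sites of positive vorticity on its right.
#' One trace is produced per boundary component (outer boundary and each
#' hole separately).  Vertices lie on dual-lattice points between sites;
#' with the y-up convention outer boundaries come out clockwise
#' (negative shoelace area) and hole boundaries counter-clockwise.
#'
#' @param binary a `binary_vorticity` field (or 0/1 matrix).
#' @param connectivity saddle-resolution rule, matching
#'   [label_clusters()]: 4, 6 or 8.
#' @param min_length drop traces with fewer edges than this.
#' @param labeling optional precomputed [label_clusters()] result (must
#'   use the same connectivity).
#' @return List of `contour_trace` objects; each has `vertices` (n x 2
#'   matrix, physical coordinates, first row repeated last), `closed`,
#'   `kind = "complete"`, `label`, `area` (signed, physical units),
#'   `n_edges` and `spacing`.
#' @export
trace_contours <- function(binary, connectivity = 4, min_length = 0,
                           labeling = NULL) {
    binary <- as_binary(binary)
    connectivity <- as.integer(connectivity)
    if (is.null(labeling)) labeling <- label_clusters(binary, connectivity)
    if (labeling$connectivity != connectivity)
        stopf("labeling connectivity (%d) does not match connectivity (%d)",
              labeling$connectivity, connectivity)
    raw <- .trace_contours(binary$sign, labeling$labels, connectivity)
    h <- binary$spacing; o <- binary$origin
    out <- lapply(raw, function(tr) {
        if (tr$n_edges < min_length) return(NULL)
        new_contour_trace(
            vertices = cbind(x = o[1] + h * tr$x, y = o[2] + h * tr$y),
            closed = TRUE, kind = "complete", label = tr$label,
            area = tr$area * h^2, n_edges = tr$n_edges, spacing = h)
    })
    out[!vapply(out, is.null, logical(1))]
}

new_contour_trace <- function(vertices, closed, kind, label, area, n_edges,
                              spacing) {
    structure(list(vertices = vertices, closed = closed, kind = kind,
                   label = label, area = area, n_edges = n_edges,
                   spacing = spacing),
              class = "contour_trace")
}

#' @export
print.contour_trace <- function(x, ...) {
    cat(sprintf("<contour_trace> %s, %d edges, %s, label %d, area %.4g\n",
                x$kind, x$n_edges, if (x$closed) "closed" else "open",
                x$label, x$area))
    invisible(x)
}

#' @export
plot.contour_trace <- function(x, add = FALSE, ...) {
    if (!add)
        plot(x$vertices, type = "l", asp = 1, xlab = "x", ylab = "y", ...)
    else lines(x$vertices, ...)
    invisible(x)
}

#' Accessible external perimeter of a cluster
#'
#' The accessible (external) perimeter is obtained by morphologically
#' closing the cluster mask with the plus-shaped (von Neumann)
#' structuring element -- one dilation followed by one erosion -- which
#' seals fjords whose entrance gate is one lattice unit wide while
#' leaving the outer boundary unthickened, and re-tracing the outer
#' contour of the closed set with the oriented marching-squares tracer
#' under the labelling's own saddle rule.  (A plain dilation, the other
#' common recipe, thickens every boundary feature by the probe size
#' and noticeably depresses the fitted perimeter exponent at
#' accessible finite sizes.)
#'
#' @param labeling a [label_clusters()] result.
#' @param label cluster label to process.
#' @return A `contour_trace` with `kind = "accessible"` in absolute
#'   physical coordinates.
#' @export
accessible_perimeter <- function(labeling, label) {
    stopifnot(inherits(labeling, "cluster_labeling"))
    label <- as.integer(label)
    if (label < 1L || label > labeling$n_clusters)
        stopf("no cluster with label %d", label)
    idx <- which(labeling$labels == label, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    # bounding box padded by 2 so the closed set never touches the edge
    m <- matrix(0L, r1 - r0 + 5L, c1 - c0 + 5L)
    m[cbind(idx[, 1] - r0 + 3L, idx[, 2] - c0 + 3L)] <- 1L
    d <- close_plus(m)
    lab <- .cc_label(d, labeling$connectivity)
    raw <- .trace_contours(d, lab$labels, labeling$connectivity)
    areas <- vapply(raw, `[[`, numeric(1), "area")
    tr <- raw[[which.min(areas)]]  # outer boundary: most negative area
    h <- labeling$spacing
    ox <- labeling$origin[1] + h * (c0 - 3L)  # offset of padded box col 0
    oy <- labeling$origin[2] + h * (r0 - 3L)
    new_contour_trace(
        vertices = cbind(x = ox + h * tr$x, y = oy + h * tr$y),
        closed = TRUE, kind = "accessible", label = label,
        area = tr$area * h^2, n_edges = tr$n_edges, spacing = h)
}

# binary morphological closing with the plus-shaped (von Neumann)
# structuring element: dilate, then erode.  Seals fjord gates of one
# lattice unit without thickening the boundary; extensive (the result
# contains the input, so original sites are never removed).
close_plus <- function(m) {
    sh <- function(x, di, dj) {
        s <- shift_mat(x, di, dj, periodic = FALSE)
        s[is.na(s)] <- 0L
        s
    }
    d <- pmax(m, sh(m, 1, 0), sh(m, -1, 0), sh(m, 0, 1), sh(m, 0, -1))
    e <- d * sh(d, 1, 0) * sh(d, -1, 0) * sh(d, 0, 1) * sh(d, 0, -1)
    matrix(as.integer(pmax(m, e)), nrow(m), ncol(m))
}

#' Extract chordal explorer traces from a binary vorticity field
#'
#' Implements the explorer construction for candidate chordal SLE
#' traces: a horizontal real axis is drawn across the binary field, and
#' from every intersection of a zero-vorticity contour with that axis an
#' explorer walks the contour keeping positive vorticity on its right.
#' When the walk returns to the axis it travels along the axis,
#' preserving its orientation, until it can re-enter the upper
#' half-plane; it terminates at the domain boundary.  Internally this is
#' realised by conditioning the field below the axis with the chordal
#' boundary colouring (positive phase right of the origin, negative
#' left), under which the plain oriented marching walk reproduces the
#' axis-sliding rule exactly.  Intersections where the contour leaves
#' downward are mirrored left-right so every walk enters the upper
#' half-plane.
#'
#' @param binary a `binary_vorticity` field (or 0/1 matrix).
#' @param axis_row row index of the first site row above the real axis
#'   (the axis runs between rows `axis_row - 1` and `axis_row`); default
#'   is the middle row.  Must be at least 3 rows from the field edge.
#' @param connectivity saddle rule: 4, 6 or 8.
#' @param min_length drop walks with fewer than this many vertices.
#' @return List of `chordal_trace` objects: complex `points` starting at
#'   0 with non-negative imaginary part, plus `axis_offset` (physical y
#'   of the axis), `origin` (physical x, y of the walk origin),
#'   `mirrored`, `stopped` and `spacing`.
#' @export
extract_chordal_traces <- function(binary, axis_row = NULL, connectivity = 4,
                                   min_length = 16) {
    binary <- as_binary(binary)
    b <- binary$sign
    nr <- nrow(b); nc <- ncol(b)
    if (is.null(axis_row)) axis_row <- nr %/% 2L + 1L
    axis_row <- as.integer(axis_row)
    if (axis_row < 3L || axis_row > nr - 2L)
        stopf("axis_row must be at least 2 rows from the field edge")
    row <- b[axis_row, ]
    up_cols <- which(row[-1L] == 1L & row[-nc] == 0L) + 1L   # 0 -> 1
    dn_cols <- which(row[-1L] == 0L & row[-nc] == 1L) + 1L   # 1 -> 0
    traces <- list()
    for (j in up_cols) {
        w <- chordal_walk_at(b, axis_row, j, connectivity, mirrored = FALSE)
        traces[[length(traces) + 1L]] <- w
    }
    for (j in dn_cols) {
        # walks entering downward are reflected into the upper half-plane.
        # On the square lattice (connectivity 4/8) the field is mirrored
        # left-right; the triangular embedding (connectivity 6) is not
        # mirror symmetric, so there the colours are swapped instead
        # (which preserves the adjacency and, at p = 1/2, the ensemble)
        # and the resulting trace is reflected afterwards.
        if (connectivity == 6) {
            bs <- 1L - b
            w <- chordal_walk_at(bs, axis_row, j, connectivity,
                                 mirrored = TRUE)
        } else {
            bm <- b[, nc:1, drop = FALSE]
            jm <- nc - j + 2L  # the 0->1 step in mirrored column indexing
            w <- chordal_walk_at(bm, axis_row, jm, connectivity,
                                 mirrored = TRUE)
        }
        traces[[length(traces) + 1L]] <- w
    }
    traces <- lapply(traces, finish_chordal, binary = binary,
                     axis_row = axis_row,
                     lattice = if (connectivity == 6) "triangular" else "square")
    traces[vapply(traces, function(t) length(t$points) >= min_length,
                  logical(1))]
}

# run the conditioned walk on (possibly mirrored) field b starting at the
# 0->1 intersection left-closed at column j (1-based)
chordal_walk_at <- function(b, axis_row, j, connectivity, mirrored) {
    nr <- nrow(b); nc <- ncol(b)
    bc <- b
    if (axis_row > 1L) {
        below <- seq_len(axis_row - 1L)
        bc[below, ] <- 0L
        if (j <= nc) bc[below, j:nc] <- 1L
    }
    w <- .chordal_walk(bc, axis_row - 1L, j - 1L, as.integer(connectivity))
    list(x = w$x, y = w$y, closed = w$closed, stopped = w$stopped,
         mirrored = mirrored, j = j)
}

finish_chordal <- function(w, binary, axis_row, lattice = "square") {
    # Square-lattice walks at 1->0 intersections were run on the
    # left-right mirrored field; their coordinates are kept in the
    # mirrored (walk) frame so that every trace in the ensemble has the
    # positive phase on its right -- the reflection foreseen by the
    # explorer construction.  Triangular-lattice walks are un-sheared
    # into the true lattice geometry (site (r, c) sits at
    # x = c - r/2, y = r sqrt(3)/2, which makes the (+1,+1) diagonal a
    # unit edge); colour-swapped walks are then reflected, which is a
    # symmetry of the true triangular geometry.
    h <- binary$spacing
    nc <- ncol(binary$sign)
    x <- w$x; y <- w$y
    dx <- x - x[1L]; dy <- y - y[1L]
    if (lattice == "triangular") {
        zr <- dx - dy / 2
        zi <- dy * sqrt(3) / 2
        if (w$mirrored) zr <- -zr
    } else {
        zr <- dx; zi <- dy
    }
    z <- complex(real = zr * h, imaginary = zi * h)
    x0 <- if (w$mirrored && lattice != "triangular") (nc - 1) - x[1L]
          else x[1L]
    ox <- binary$origin[1] + h * x0
    oy <- binary$origin[2] + h * y[1L]
    structure(list(points = z, spacing = h,
                   axis_offset = oy, origin = c(ox, oy),
                   mirrored = w$mirrored, stopped = w$stopped),
              class = "chordal_trace")
}

#' Map a trace from the square-grid embedding to true triangular
#' geometry
#'
#' Traces computed on the square-grid embedding of the triangular
#' lattice (connectivity 6) live in sheared coordinates; this maps
#' their vertices to the true lattice geometry, where site `(r, c)`
#' sits at `x = c - r/2`, `y = r sqrt(3)/2`.  Exponents of
#' perimeter/gyration-radius scaling are affine invariant, but angular
#' statistics (winding, left passage, driving functions) require the
#' true geometry.  Chordal traces produced by the percolation
#' generators are already un-sheared.
#'
#' @param trace a `contour_trace` (index-coordinate vertices assumed at
#'   unit spacing) or two-column vertex matrix.
#' @return The trace with vertices replaced by true-geometry
#'   coordinates.
#' @export
unshear_triangular <- function(trace) {
    v <- if (inherits(trace, "contour_trace")) trace$vertices else trace
    out <- cbind(x = v[, 1] - v[, 2] / 2, y = v[, 2] * sqrt(3) / 2)
    if (inherits(trace, "contour_trace")) {
        trace$vertices <- out
        trace
    } else out
}

#' Construct a chordal trace
#'
#' @param points complex vector; first point must be 0 and no point may
#'   have negative imaginary part.
#' @param spacing lattice step of the source grid (`NA` if not lattice
#'   based).
#' @param axis_offset physical position of the real axis.
#' @return Object of class `chordal_trace`.
#' @export
chordal_trace <- function(points, spacing = NA_real_, axis_offset = 0) {
    points <- as.complex(points)
    if (!length(points)) stopf("empty trace")
    if (Mod(points[1L]) != 0) stopf("chordal trace must start at the origin")
    if (any(Im(points) < 0)) stopf("chordal trace has points below the real axis")
    structure(list(points = points, spacing = spacing,
                   axis_offset = axis_offset, origin = c(0, axis_offset),
                   mirrored = FALSE, stopped = "constructed"),
              class = "chordal_trace")
}

#' @export
print.chordal_trace <- function(x, ...) {
    cat(sprintf("<chordal_trace> %d points, extent %.4g, stopped: %s\n",
                length(x$points), max(Mod(x$points)), x$stopped))
    invisible(x)
}

#' @export
plot.chordal_trace <- function(x, ...) {
    plot(Re(x$points), Im(x$points), type = "l", asp = 1,
         xlab = "Re z", ylab = "Im z", ...)
    abline(h = 0, col = "grey60", lty = 2)
    invisible(x)
}

#' Resample a polyline trace at uniform arclength steps
#'
#' Linear interpolation along the cumulative arclength, used to put
#' traces with heterogeneous segment lengths (e.g. forward SLE samples)
#' on a uniform footing before winding-angle statistics.
#'
#' @param trace a `chordal_trace`, `contour_trace`, complex vector or
#'   two-column matrix.
#' @param step arclength step; default the median segment length.
#' @return Complex vector of resampled points.
#' @export
resample_trace <- function(trace, step = NULL) {
    z <- trace_points(trace)
    seg <- Mod(diff(z))
    keep <- seg > 0
    z <- c(z[1L], z[-1L][keep])
    seg <- seg[keep]
    if (length(z) < 3L) stopf("trace too short to resample")
    if (is.null(step)) step <- median(seg)
    s <- c(0, cumsum(seg))
    out_s <- seq(0, s[length(s)], by = step)
    complex(real = approx(s, Re(z), out_s)$y,
            imaginary = approx(s, Im(z), out_s)$y)
}

# extract points of any supported trace representation as complex vector
trace_points <- function(trace) {
    if (inherits(trace, "chordal_trace")) trace$points
    else if (inherits(trace, "contour_trace"))
        complex(real = trace$vertices[, 1], imaginary = trace$vertices[, 2])
    else if (is.complex(trace)) trace
    else if (is.matrix(trace) && ncol(trace) == 2)
        complex(real = trace[, 1], imaginary = trace[, 2])
    else stopf("unsupported trace representation")
}

#' Export traces as delimited text plus a JSON manifest
#'
#' Writes `<prefix>.tsv` with columns `trace, vertex, x, y` and
#' `<prefix>.json` describing each trace (kind, closed, label, length).
#'
#' @param traces list of `contour_trace` / `chordal_trace` objects.
#' @param prefix output path prefix.
#' @return The TSV path, invisibly.
#' @export
write_traces <- function(traces, prefix) {
    rows <- lapply(seq_along(traces), function(i) {
        z <- trace_points(traces[[i]])
        data.frame(trace = i, vertex = seq_along(z), x = Re(z), y = Im(z))
    })
    df <- do.call(rbind, rows)
    tsv <- paste0(prefix, ".tsv")
    write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
    meta <- lapply(seq_along(traces), function(i) {
        tr <- traces[[i]]
        list(trace = i,
             kind = if (inherits(tr, "chordal_trace")) "chordal" else tr$kind,
             closed = isTRUE(tr$closed),
             label = if (is.null(tr$label)) NA else tr$label,
             n_points = length(trace_points(tr)))
    })
    jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(tsv)
}

#' Read traces written by [write_traces()]
#' @param prefix path prefix used when writing.
#' @return List of `chordal_trace` (kind chordal) or `contour_trace`
#'   objects.
#' @export
read_traces <- function(prefix) {
    df <- read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t")
    meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
    lapply(seq_len(nrow(meta)), function(i) {
        sub <- df[df$trace == meta$trace[i], ]
        if (identical(meta$kind[i], "chordal"))
            chordal_trace(complex(real = sub$x, imaginary = sub$y))
        else
            new_contour_trace(cbind(x = sub$x, y = sub$y),
                              closed = meta$closed[i], kind = meta$kind[i],
                              label = if (is.na(meta$label[i])) 0L else meta$label[i],
                              area = NA_real_, n_edges = nrow(sub) - 1L,
                              spacing = NA_real_)
    })
}
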