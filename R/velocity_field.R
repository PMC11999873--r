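#' Construct a gridded 2D velocity field
#'
#' A velocity field holds the two velocity components on a regular grid.
#' Row index corresponds to increasing physical `y`, column index to
#' increasing `x`, so the vorticity `omega = dx u_y - dy u_x` follows the
#' right-handed convention.
#'
#' @param u_x,u_y numeric matrices of equal dimension with the x- and
#'   y-components of the velocity (rows = y, columns = x).
#' @param spacing positive grid step `h` (same units as coordinates).
#' @param origin length-2 numeric, physical coordinate of grid node
#'   `[1, 1]`.
#' @param mask optional logical matrix flagging valid nodes (`TRUE` =
#'   valid).  Invalid nodes may hold `NA`.
#' @return An object of class `velocity_field`.
#' @examples
#' f <- velocity_field(matrix(1, 8, 8), matrix(0, 8, 8), spacing = 10)
#' f
#' @export
velocity_field <- function(u_x, u_y, spacing = 1, origin = c(0, 0),
                           mask = NULL) {
    u_x <- as.matrix(u_x); u_y <- as.matrix(u_y)
    if (!identical(dim(u_x), dim(u_y)))
        stopf("u_x and u_y must have identical dimensions")
    if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
        spacing <= 0)
        stopf("spacing must be a single positive number")
    if (length(origin) != 2L || !all(is.finite(origin)))
        stopf("origin must be two finite numbers")
    if (!is.null(mask)) {
        mask <- as.matrix(mask)
        if (!identical(dim(mask), dim(u_x)))
            stopf("mask dimensions must match the velocity grids")
        mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
    }
    check <- if (is.null(mask)) rbind(u_x, u_y) else rbind(u_x[mask], u_y[mask])
    if (!all(is.finite(check)))
        stopf("velocity components contain non-finite values at unmasked nodes")
    structure(list(u_x = u_x, u_y = u_y, spacing = as.numeric(spacing),
                   origin = as.numeric(origin), mask = mask),
              class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
    cat(sprintf("<velocity_field> %d x %d nodes, spacing %g, origin (%g, %g)\n",
                nrow(x$u_x), ncol(x$u_x), x$spacing, x$origin[1], x$origin[2]))
    cat(sprintf("  |u| in [%.4g, %.4g]%s\n",
                min(sqrt(x$u_x^2 + x$u_y^2), na.rm = TRUE),
                max(sqrt(x$u_x^2 + x$u_y^2), na.rm = TRUE),
                if (is.null(x$mask)) "" else
                    sprintf(", %d masked nodes", sum(!x$mask))))
    invisible(x)
}

#' @export
dim.velocity_field <- function(x) dim(x$u_x)

#' Physical node coordinates of a gridded field
#' @param field a `velocity_field`, `vorticity_field` or `binary_vorticity`.
#' @return list with numeric vectors `x` and `y`.
#' @export
grid_coordinates <- function(field) {
    m <- field[[1L]]
    list(x = field$origin[1] + field$spacing * (seq_len(ncol(m)) - 1L),
         y = field$origin[2] + field$spacing * (seq_len(nrow(m)) - 1L))
}

#' Read a velocity field from disk
#'
#' Two dialects are supported.  `"table"` is the PIV-export style: a
#' delimited text file with columns `x, y, u, v` covering a complete
#' regular grid, comma- or whitespace-separated (auto-detected), with
#' optional `#` comment lines and an optional header row.  `"grid"` is
#' the package's own dense text container written by
#' [write_velocity_field()].
#'
#' @param path file to read.
#' @param dialect `"auto"` (default), `"table"` or `"grid"`.
#' @param allow_missing for the table dialect: if `TRUE`, absent grid
#'   nodes become masked instead of raising an error.
#' @return A [velocity_field()].
#' @export
read_velocity_field <- function(path, dialect = c("auto", "table", "grid"),
                                allow_missing = FALSE) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stopf("file not found: %s", path)
    first <- readLines(path, n = 1L)
    if (dialect == "auto")
        dialect <- if (grepl("^# sleflow grid", first)) "grid" else "table"
    if (dialect == "grid") read_grid_file(path) else
        read_table_field(path, allow_missing)
}

read_table_field <- function(path, allow_missing) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (!length(lines)) stopf("no data rows in %s", path)
    sep <- if (grepl(",", lines[[1L]])) "," else ""
    tokens <- strsplit(trimws(lines[[1L]]), if (sep == ",") "," else "\\s+")[[1L]]
    header <- any(is.na(suppressWarnings(as.numeric(tokens))))
    df <- read.table(text = lines, sep = sep, header = header,
                     strip.white = TRUE)
    if (ncol(df) < 4L) stopf("table dialect needs columns x, y, u, v")
    if (header) {
        names(df) <- tolower(names(df))
        need <- c("x", "y", "u", "v")
        if (!all(need %in% names(df)))
            stopf("table header must name columns x, y, u, v")
        df <- df[need]
    } else names(df) <- c("x", "y", "u", "v")

    xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
    step_of <- function(v, lab) {
        if (length(v) < 2L) stopf("need at least 2 distinct %s coordinates", lab)
        d <- diff(v)
        if (max(abs(d - d[1])) > 1e-6 * abs(d[1]))
            stopf("irregular grid: non-constant %s step", lab)
        d[1]
    }
    hx <- step_of(xs, "x"); hy <- step_of(ys, "y")
    if (abs(hx - hy) > 1e-6 * abs(hx))
        stopf("irregular grid: x step %g differs from y step %g", hx, hy)
    nr <- length(ys); nc <- length(xs)
    ci <- match(df$x, xs); ri <- match(df$y, ys)
    idx <- (ci - 1L) * nr + ri
    if (anyDuplicated(idx)) stopf("duplicate grid nodes in %s", path)
    u <- matrix(NA_real_, nr, nc); v <- matrix(NA_real_, nr, nc)
    u[idx] <- df$u; v[idx] <- df$v
    miss <- is.na(u)
    if (any(miss) && !allow_missing)
        stopf("grid has %d missing nodes (set allow_missing = TRUE to mask them)",
              sum(miss))
    velocity_field(u, v, spacing = hx, origin = c(xs[1], ys[1]),
                   mask = if (any(miss)) !miss else NULL)
}

#' Write a velocity field in the dense grid container
#'
#' Plain-text container: a tag line, a header line
#' `nrow ncol spacing origin_x origin_y has_mask`, then the `u_x` rows,
#' the `u_y` rows and optionally the mask rows, all at full double
#' precision so a read/write cycle is exact.
#'
#' @param field a [velocity_field()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(field, path) {
    stopifnot(inherits(field, "velocity_field"))
    con <- file(path, "w"); on.exit(close(con))
    nr <- nrow(field$u_x); nc <- ncol(field$u_x)
    writeLines("# sleflow grid v1", con)
    writeLines(sprintf("%d %d %.17g %.17g %.17g %d", nr, nc, field$spacing,
                       field$origin[1], field$origin[2],
                       as.integer(!is.null(field$mask))), con)
    wm <- function(m) writeLines(apply(m, 1L, function(r)
        paste(sprintf("%.17g", r), collapse = " ")), con)
    ux <- field$u_x; uy <- field$u_y
    ux[is.na(ux)] <- 0; uy[is.na(uy)] <- 0
    wm(ux); wm(uy)
    if (!is.null(field$mask)) wm(field$mask * 1)
    invisible(path)
}

read_grid_file <- function(path) {
    lines <- readLines(path)
    if (!grepl("^# sleflow grid", lines[[1L]]))
        stopf("%s is not a sleflow grid file", path)
    hdr <- as.numeric(strsplit(trimws(lines[[2L]]), "\\s+")[[1L]])
    nr <- as.integer(hdr[1]); nc <- as.integer(hdr[2])
    parse_block <- function(at) {
        t(vapply(lines[at], function(l)
            as.numeric(strsplit(trimws(l), "\\s+")[[1L]]),
            numeric(nc), USE.NAMES = FALSE))
    }
    u <- parse_block(2L + seq_len(nr))
    v <- parse_block(2L + nr + seq_len(nr))
    mask <- NULL
    if (hdr[6] == 1) {
        mask <- parse_block(2L + 2L * nr + seq_len(nr)) > 0.5
        u[!mask] <- NA; v[!mask] <- NA
    }
    velocity_field(u, v, spacing = hdr[3], origin = hdr[4:5], mask = mask)
}

#' @export
plot.velocity_field <- function(x, thin = max(1L, floor(nrow(x$u_x) / 24)),
                                ...) {
    co <- grid_coordinates(x)
    spd <- sqrt(x$u_x^2 + x$u_y^2)
    image(co$x, co$y, t(spd), asp = 1, xlab = "x", ylab = "y",
          col = hcl.colors(64, "viridis"), ...)
    ii <- seq(1L, nrow(spd), by = thin); jj <- seq(1L, ncol(spd), by = thin)
    sc <- 0.8 * thin * x$spacing / max(spd, na.rm = TRUE)
    graphics::arrows(rep(co$x[jj], each = length(ii)),
                     rep(co$y[ii], times = length(jj)),
                     rep(co$x[jj], each = length(ii)) + sc * x$u_x[ii, jj],
                     rep(co$y[ii], times = length(jj)) + sc * x$u_y[ii, jj],
                     length = 0.03, col = "white")
    invisible(x)
}
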