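#' Run the full conformal-invariance analysis pipeline
#'
#' Composes the analysis stages in order -- fields, vorticity, oriented
#' contours, perimeter scaling, winding angles, left-passage and
#' driving-function inference -- and assembles a report in the layout
#' of the study summary table (scale invariance / conformal invariance
#' / SLE).  Inputs come either from the synthetic generators or from
#' velocity-field files.
#'
#' The configuration is a nested list (or path to a YAML file) with
#' blocks:
#' \describe{
#'   \item{input}{`type` one of `"percolation"`, `"sle"`,
#'     `"simulation"`, `"files"`; plus type-specific settings:
#'     `n_fields`, `width`, `height` (percolation); `n_traces`,
#'     `kappa`, `n_steps`, `dt` (sle); `params` (simulation,
#'     passed to [active_nematic_params()]), `n_snapshots`; `paths`
#'     (files).}
#'   \item{analysis}{`connectivity` (default 6 for percolation, 4
#'     otherwise), `min_trace_length`, `winding_min_edges`,
#'     `accessible_min_edges`, `fit_range` (gyration-radius window of
#'     the perimeter fits; the kind-specific defaults need lattices of
#'     several hundred sites), `axis_row`, `subsample`.}
#'   \item{seed}{master seed for every stochastic stage.}
#' }
#'
#' @param config nested list or YAML file path.
#' @param out_dir optional run directory; stage outputs, `report.json`
#'   and `run.log` are written there.
#' @param quiet suppress progress messages.
#' @return Object of class `flow_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    seed <- config$seed %||% 1L
    input <- config$input %||% list(type = "percolation")
    an <- config$analysis %||% list()
    type <- input$type %||% "percolation"
    conn <- an$connectivity %||% (if (type == "percolation") 6L else 4L)
    min_tr <- an$min_trace_length %||% 16L
    wind_min <- an$winding_min_edges %||% 512L
    acc_min <- an$accessible_min_edges %||% 24L
    fit_rng <- an$fit_range %||% NULL
    subsample <- an$subsample %||% 4L

    t0 <- Sys.time()
    logfile <- NULL
    if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        for (d in c("fields", "contours", "stats"))
            dir.create(file.path(out_dir, d), showWarnings = FALSE)
        logfile <- file.path(out_dir, "run.log")
        cat(sprintf("pipeline start (input: %s, seed: %d)\n", type, seed),
            file = logfile)
    }
    say <- function(fmt, ...) {
        msg <- sprintf(fmt, ...)
        if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
        if (!quiet) message(msg)
    }

    # --- stage 1: binary fields and chordal traces ----------------------
    fields <- list(); traces <- NULL
    if (type == "percolation") {
        nf <- input$n_fields %||% 20L
        w <- input$width %||% 256L
        h <- input$height %||% 256L
        seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            nf + 1L))
        fields <- lapply(seq_len(nf), function(i)
            percolation_field(w, h, seed = seeds[i]))
        nt <- input$n_traces %||% 100L
        traces <- percolation_interface_ensemble(
            nt, width = input$trace_width %||% w,
            height = input$trace_height %||% h, seed = seeds[nf + 1L])
        say("generated %d percolation fields (%d x %d) and %d interfaces",
            nf, w, h, length(traces))
    } else if (type == "sle") {
        nt <- input$n_traces %||% 200L
        traces <- sle_trace_ensemble(nt, kappa = input$kappa %||% 6,
                                     n_steps = input$n_steps %||% 1500L,
                                     dt = input$dt %||% 1e-4, seed = seed)
        say("generated %d forward SLE traces (kappa = %g)", nt,
            input$kappa %||% 6)
    } else if (type == "simulation") {
        pars <- do.call(active_nematic_params,
                        c(input$params %||% list(), list(seed = seed)))
        sim <- run_active_nematic(pars,
                                  n_snapshots = input$n_snapshots %||% 20L)
        say("simulated %d snapshots on a %d x %d lattice", length(sim$snapshots),
            pars$lattice[1], pars$lattice[2])
        fields <- lapply(sim$snapshots, function(f)
            binarize_vorticity(compute_vorticity(f, boundary = "periodic")))
        traces <- unlist(lapply(fields, extract_chordal_traces,
                                connectivity = conn, min_length = min_tr,
                                axis_row = an$axis_row %||% NULL),
                         recursive = FALSE)
    } else if (type == "files") {
        vf <- lapply(input$paths, read_velocity_field)
        fields <- lapply(vf, function(f)
            binarize_vorticity(compute_vorticity(f, boundary =
                input$boundary %||% "crop")))
        traces <- unlist(lapply(fields, extract_chordal_traces,
                                connectivity = conn, min_length = min_tr,
                                axis_row = an$axis_row %||% NULL),
                         recursive = FALSE)
        say("read %d velocity fields", length(vf))
    } else stopf("unknown input type '%s'", type)

    # --- stage 2: cluster geometry and perimeter scaling ---------------
    scale_block <- NULL; geoms <- NULL; winding <- NULL
    if (length(fields)) {
        geoms <- lapply(fields, cluster_geometry, connectivity = conn,
                        accessible_min_edges = acc_min)
        fitD <- try(fit_fractal_dimension(geoms, "complete",
                                          fit_range = fit_rng), silent = TRUE)
        fitA <- try(fit_fractal_dimension(geoms, "accessible",
                                          fit_range = fit_rng), silent = TRUE)
        if (inherits(fitD, "try-error") || inherits(fitA, "try-error")) {
            say("perimeter scaling fit failed: %s",
                paste(c(if (inherits(fitD, "try-error")) fitD,
                        if (inherits(fitA, "try-error")) fitA),
                      collapse = "; "))
            scale_block <- NULL
        } else {
            dual <- duality_product(fitD, fitA)
            scale_block <- list(complete = fitD, accessible = fitA,
                                duality = dual)
            say("fractal dimensions: D = %.3f, D* = %.3f, duality %.3f",
                fitD$exponent, fitA$exponent, as.numeric(dual))
        }
        # winding statistics on long closed contours
        long_tr <- list()
        for (f in fields) {
            trs <- trace_contours(f, conn, min_length = wind_min)
            long_tr <- c(long_tr, trs)
        }
        if (length(long_tr) >= 50L) {
            winding <- winding_variance_fit(long_tr)
            say("winding slope alpha = %.3f (kappa %.2f) from %d contours",
                winding$slope_alpha, winding$kappa_from_alpha,
                length(long_tr))
        } else say("only %d long contours; winding fit skipped",
                   length(long_tr))
    }
    if (is.null(winding) && length(traces) >= 50L) {
        rs <- lapply(traces, function(t) resample_trace(t))
        rs <- rs[vapply(rs, length, integer(1)) >= 256L]
        if (length(rs) >= 50L) {
            winding <- winding_variance_fit(rs)
            say("winding slope alpha = %.3f from %d chordal traces",
                winding$slope_alpha, length(rs))
        }
    }

    # --- stage 3: SLE inference ----------------------------------------
    lpp <- NULL; driving <- NULL; acf_df <- NULL
    if (length(traces) >= 20L) {
        grid <- empirical_left_passage(traces)
        lpp <- try(estimate_kappa_lpp(grid), silent = TRUE)
        if (inherits(lpp, "try-error")) { say("LPP fit failed"); lpp <- NULL }
        else say("left-passage kappa = %.3f +/- %.3f", lpp$kappa, lpp$stderr)
        dfs <- lapply(traces, function(t)
            try(compute_driving_function(t, subsample = subsample),
                silent = TRUE))
        dfs <- dfs[!vapply(dfs, inherits, logical(1), "try-error")]
        if (length(dfs) >= 50L) {
            driving <- fit_kappa_driving(dfs)
            acf_df <- driving_autocorrelation(dfs, taus = 0:5)
            say("driving kappa = %.3f +/- %.3f", driving$kappa,
                driving$stderr)
        } else say("only %d driving functions; driving fit skipped",
                   length(dfs))
    }

    report <- structure(list(
        scale = scale_block,
        winding = winding,
        lpp = lpp,
        driving = driving,
        autocorrelation = acf_df,
        provenance = list(seed = seed, input = input,
                          n_fields = length(fields),
                          n_traces = length(traces),
                          connectivity = conn,
                          timestamp = format(t0, "%Y-%m-%d %H:%M:%S"))),
        class = "flow_report")

    if (!is.null(out_dir)) {
        jsonlite::write_json(report_values(report),
                             file.path(out_dir, "report.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
        if (!is.null(geoms))
            write.table(do.call(rbind, geoms),
                        file.path(out_dir, "stats", "cluster_geometry.tsv"),
                        sep = "\t", row.names = FALSE, quote = FALSE)
        if (length(traces))
            write_traces(traces[seq_len(min(20L, length(traces)))],
                         file.path(out_dir, "contours", "chordal_traces"))
        say("report written to %s", out_dir)
    }
    report
}

# plain-number view of a report (used for JSON export and comparison)
report_values <- function(report) {
    num <- function(x) if (is.null(x)) NULL else as.numeric(x)
    out <- list()
    if (!is.null(report$scale)) {
        out$fractal_dimension <- report$scale$complete$exponent
        out$fractal_dimension_se <- report$scale$complete$stderr
        out$accessible_dimension <- report$scale$accessible$exponent
        out$accessible_dimension_se <- report$scale$accessible$stderr
        out$duality_product <- num(report$scale$duality)
    }
    if (!is.null(report$winding)) {
        out$winding_alpha <- report$winding$slope_alpha
        out$winding_alpha_se <- report$winding$stderr
    }
    if (!is.null(report$lpp)) {
        out$kappa_lpp <- report$lpp$kappa
        out$kappa_lpp_se <- report$lpp$stderr
    }
    if (!is.null(report$driving)) {
        out$kappa_driving <- report$driving$kappa
        out$kappa_driving_se <- report$driving$stderr
    }
    out$seed <- report$provenance$seed
    out
}

#' @export
print.flow_report <- function(x, ...) {
    cat("<flow_report>\n")
    v <- report_values(x)
    fmt <- function(nm, lab) {
        if (!is.null(v[[nm]]))
            cat(sprintf("  %-28s %.4f %s\n", lab, v[[nm]],
                        if (!is.null(v[[paste0(nm, "_se")]]))
                            sprintf("+/- %.4f", v[[paste0(nm, "_se")]])
                        else ""))
    }
    cat(" Scale invariance\n")
    fmt("fractal_dimension", "fractal dimension D")
    fmt("accessible_dimension", "accessible dimension D*")
    if (!is.null(v$duality_product))
        cat(sprintf("  %-28s %.4f\n", "duality 4(D-1)(D*-1)",
                    v$duality_product))
    cat(" Conformal invariance\n")
    fmt("winding_alpha", "winding angle alpha")
    cat(" SLE\n")
    fmt("kappa_lpp", "left-passage kappa")
    fmt("kappa_driving", "driving-function kappa")
    invisible(x)
}

#' Reference values of the percolation universality class
#'
#' Exact theoretical values for interfaces in the percolation (SLE(6))
#' class, with the comparison tolerances used by [compare_report()].
#'
#' @return data.frame with columns `metric`, `value`, `tol`.
#' @export
percolation_reference <- function() {
    data.frame(
        metric = c("fractal_dimension", "accessible_dimension",
                   "winding_alpha", "kappa_lpp", "kappa_driving",
                   "duality_product"),
        value = c(7 / 4, 4 / 3, 6 / 7, 6, 6, 1),
        tol = c(0.05, 0.05, 0.04, 0.25, 0.3, 0.15))
}

#' Compare a pipeline report against reference values
#'
#' @param report a `flow_report`.
#' @param reference data.frame with columns `metric`, `value`, `tol`
#'   (default [percolation_reference()]).
#' @return data.frame with the estimate, reference, deviation, z-score
#'   (deviation over the estimate's standard error where available) and
#'   a pass flag per metric; metrics absent from the report raise an
#'   error.
#' @export
compare_report <- function(report, reference = percolation_reference()) {
    v <- report_values(report)
    rows <- lapply(seq_len(nrow(reference)), function(i) {
        m <- reference$metric[i]
        if (is.null(v[[m]]))
            stopf("report is missing metric '%s'", m)
        est <- v[[m]]
        se <- v[[paste0(m, "_se")]] %||% NA_real_
        dev <- est - reference$value[i]
        data.frame(metric = m, estimate = est, reference = reference$value[i],
                   deviation = dev, stderr = se,
                   z = if (is.finite(se) && se > 0) dev / se else NA_real_,
                   pass = abs(dev) <= reference$tol[i])
    })
    do.call(rbind, rows)
}
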