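# cluster labelling and oriented contour tracing

test_that("labelling matches simple counting examples", {
    lab <- label_clusters(matrix(1L, 5, 5), 4)
    expect_equal(lab$n_clusters, 1L)
    expect_equal(lab$sizes, 25L)

    m <- matrix(0L, 5, 7)
    m[2:4, 2:3] <- 1L
    m[2:4, 5:6] <- 1L
    expect_equal(label_clusters(m, 4)$n_clusters, 2L)
})

test_that("labelling agrees with a flood-fill oracle up to relabeling", {
    for (conn in c(4, 6, 8)) {
        b <- random_binary(64, 64, seed = conn)
        lab <- label_clusters(b, conn)
        oracle <- flood_fill_labels(b$sign, conn)
        expect_equal(lab$n_clusters, max(oracle))
        expect_equal(sum(lab$sizes), sum(b$sign))
        # same partition: cross-tabulation is a permutation matrix
        tab <- table(lab$labels[lab$labels > 0], oracle[oracle > 0])
        expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    }
})

test_that("per-cluster gyration radii match the direct definition", {
    b <- random_binary(32, 32, seed = 5)
    lab <- label_clusters(b, 6)
    for (l in sample.int(lab$n_clusters, min(8, lab$n_clusters))) {
        idx <- which(lab$labels == l, arr.ind = TRUE)
        expect_equal(lab$r_g[l],
                     gyration_radius(cbind(idx[, 2], idx[, 1])),
                     tolerance = 1e-12)
    }
})

test_that("single sites and blocks trace to the expected perimeters", {
    m <- matrix(0L, 6, 6); m[3, 4] <- 1L
    tr <- trace_contours(m)
    expect_length(tr, 1L)
    expect_equal(tr[[1]]$n_edges, 4L)
    expect_true(tr[[1]]$closed)
    expect_equal(tr[[1]]$vertices[1, ], tr[[1]]$vertices[5, ])

    m2 <- matrix(0L, 6, 6); m2[3:4, 3:4] <- 1L
    expect_equal(trace_contours(m2)[[1]]$n_edges, 8L)
})

test_that("signed areas of all traces add up to the occupied area", {
    for (seed in 1:3) {
        b <- random_binary(32, 32, seed = seed)
        tr <- trace_contours(b, connectivity = 4)
        total <- sum(vapply(tr, `[[`, numeric(1), "area"))
        # outer boundaries are clockwise (negative), holes positive:
        # the net enclosed area equals the number of occupied sites
        expect_equal(-total, sum(b$sign))
    }
})

test_that("every traced edge keeps the positive phase on its right", {
    for (conn in c(4, 6, 8)) {
        b <- random_binary(12, 12, seed = 10 + conn)
        for (tr in trace_contours(b, conn))
            expect_true(check_right_hand_rule(tr, b))
    }
})

test_that("outer trace count equals cluster count", {
    for (conn in c(4, 6, 8)) {
        b <- random_binary(48, 48, p = 0.45, seed = conn)
        lab <- label_clusters(b, conn)
        tr <- trace_contours(b, conn, labeling = lab)
        outer <- Filter(function(t) t$area < 0, tr)
        expect_length(outer, lab$n_clusters)
        # one outer trace per label
        expect_setequal(vapply(outer, `[[`, integer(1), "label"),
                        seq_len(lab$n_clusters))
    }
})

test_that("mirroring the field mirrors the traces (square lattice)", {
    b <- random_binary(16, 16, seed = 3)
    bm <- binary_field(b$sign[, ncol(b$sign):1])
    tr <- trace_contours(b, 4)
    trm <- trace_contours(bm, 4)
    key <- function(t) {
        v <- t$vertices[-nrow(t$vertices), , drop = FALSE]  # drop closure
        paste(sort(sprintf("%.1f", v[, 2] * 100 + v[, 1])), collapse = ",")
    }
    mirror_key <- function(t) {
        v <- t$vertices[-nrow(t$vertices), , drop = FALSE]
        v[, 1] <- (ncol(b$sign) - 1) - v[, 1]
        paste(sort(sprintf("%.1f", v[, 2] * 100 + v[, 1])), collapse = ",")
    }
    expect_setequal(vapply(trm, key, character(1)),
                    vapply(tr, mirror_key, character(1)))
})

test_that("accessible perimeter seals fjords and handles convex blocks", {
    # convex block: morphological closing is the identity, so the
    # accessible perimeter equals the complete one
    m <- matrix(0L, 9, 9); m[4:6, 4:6] <- 1L
    lab <- label_clusters(m, 4)
    acc <- accessible_perimeter(lab, 1L)
    expect_equal(acc$n_edges, 12L)

    # U-shape with a one-lattice-unit fjord: closing seals it, and the
    # accessible perimeter drops below the complete one
    u <- matrix(0L, 12, 12)
    u[3:8, 4] <- 1L; u[3:8, 6] <- 1L; u[3, 5] <- 1L
    labu <- label_clusters(u, 4)
    comp <- Filter(function(t) t$area < 0, trace_contours(u, 4))[[1]]
    accu <- accessible_perimeter(labu, 1L)
    expect_lt(accu$n_edges, comp$n_edges)

    expect_error(accessible_perimeter(labu, 99L), "label")
})

test_that("cluster geometry table is consistent with its pieces", {
    b <- random_binary(48, 48, seed = 21)
    df <- cluster_geometry(b, connectivity = 6, min_size = 2,
                           accessible_min_edges = 12)
    lab <- label_clusters(b, 6)
    expect_true(all(df$size >= 2))
    expect_equal(df$size, lab$sizes[df$label])
    expect_true(all(df$l_complete >= 4))
    has_acc <- is.finite(df$l_accessible)
    expect_true(any(has_acc))
    for (k in which(has_acc)[1:min(3, sum(has_acc))])
        expect_equal(df$l_accessible[k],
                     accessible_perimeter(lab, df$label[k])$n_edges)
})
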