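plain <- cluster_params(normalization = "none", prune_fraction = 0)

test_that("merge_profiles averages by coverage and lays out flanks", {
    p1 <- signal_profile(c(1, 2, 3), id = "a")
    a <- align_pair(p1, p1, plain)
    m <- merge_profiles(p1, p1, a)$profile
    expect_equal(m$values, p1$values, ignore_attr = TRUE)
    expect_equal(m$weight, 2L)
    expect_equal(m$coverage, c(2L, 2L, 2L))

    # weighted mean: coverage 1 x value 0 with coverage 3 x value 2 -> 1.5
    c1 <- signal_profile(0, id = "c1")
    c3 <- signal_profile(2, id = "c3", weight = 3L, coverage = 3L)
    a <- align_pair(c1, c3, cluster_params(normalization = "none",
                                           min_overlap_fraction = 1))
    m <- merge_profiles(c1, c3, a)$profile
    expect_equal(as.numeric(m$values), 1.5)
    expect_equal(m$coverage, 4L)
    expect_equal(m$weight, 4L)
})

test_that("merge at an offset keeps n_total and flank coverages", {
    set.seed(20)
    v <- runif(10)
    p1 <- signal_profile(v, id = "a")
    p2 <- signal_profile(c(runif(2), v[1:8]), id = "b")  # delayed by 2
    a <- align_pair(p1, p2, cluster_params(normalization = "none",
                                           allow_mirror = FALSE))
    expect_equal(a$r, 2L)
    m <- merge_profiles(p1, p2, a)
    expect_equal(profile_length(m$profile), a$n_total)
    expect_equal(a$n_total, 10L + 10L - a$n_overlap)
    # flanking bins carry a single child's coverage
    expect_equal(m$profile$coverage, c(rep(1L, 2), rep(2L, 8), rep(1L, 2)))
    # overlapping bins are exact (children agree there)
    expect_equal(as.numeric(m$profile$values)[3:10], v[1:8])
})

test_that("mirrored merges re-project the mirrored child", {
    asym <- c(0, 1, 5, 2, 0, 0)
    p1 <- signal_profile(asym, id = "a")
    p2 <- signal_profile(rev(asym), id = "b")
    a <- align_pair(p1, p2, plain)
    expect_true(a$mirrored)
    m <- merge_profiles(p1, p2, a)$profile
    expect_equal(as.numeric(m$values), asym)
    expect_equal(m$coverage, rep(2L, 6))
})

test_that("prune_profile trims only edge runs, with a degenerate fallback", {
    p <- signal_profile(matrix(1:6, 1), id = "p", weight = 4L,
                        coverage = c(1L, 2L, 4L, 4L, 2L, 1L))
    expect_equal(prune_profile(p, 0)$profile, p)
    out <- prune_profile(p, 0.5)
    expect_equal(out$trimmed_left, 1L)
    expect_equal(out$trimmed_right, 1L)
    expect_equal(out$profile$coverage, c(2L, 4L, 4L, 2L))

    # interior low-coverage bins are never removed
    p2 <- signal_profile(matrix(1:5, 1), id = "p2", weight = 4L,
                         coverage = c(4L, 1L, 1L, 1L, 4L))
    out <- prune_profile(p2, 0.5)
    expect_equal(profile_length(out$profile), 5L)

    # everything below threshold: keep the max-coverage run
    p3 <- signal_profile(matrix(1:2, 1), id = "p3", weight = 4L,
                         coverage = c(1L, 1L))
    out <- prune_profile(p3, 0.5)
    expect_equal(profile_length(out$profile), 2L)
    p4 <- signal_profile(matrix(1:4, 1), id = "p4", weight = 8L,
                         coverage = c(1L, 2L, 2L, 1L))
    out <- prune_profile(p4, 0.9)
    expect_equal(out$profile$coverage, c(2L, 2L))
    expect_equal(out$trimmed_left, 1L)
})

test_that("clustering two identical profiles gives a height-0 root", {
    p1 <- signal_profile(c(1, 2, 3), id = "a")
    p2 <- signal_profile(c(1, 2, 3), id = "b")
    root <- cluster_profiles(list(p1, p2), plain)
    expect_equal(root$height, 0)
    expect_setequal(node_leaves(root), c("a", "b"))
    expect_equal(root$placements$offset, c(0L, 0L))
    expect_false(any(root$placements$mirrored))
    # single input: the leaf is the root
    solo <- cluster_profiles(list(p1), plain)
    expect_equal(solo$node_id, "a")
    expect_null(solo$children)
})

test_that("well-separated pairs merge first and give the expected topology", {
    set.seed(21)
    i <- seq_len(40)
    # two groups distinguished by their track COMBINATION (a lone peak with
    # the same shape would be mergeable across groups by a mere shift)
    mkA <- function(s, id) signal_profile(
        rbind(10 * exp(-(i - 12 - s)^2 / 8) + rnorm(40, sd = 0.3),
              6 * exp(-(i - 30 - s)^2 / 18) + rnorm(40, sd = 0.3)),
        id = id)
    mkB <- function(s, id) signal_profile(
        rbind(rnorm(40, sd = 0.3),
              8 * exp(-(i - 20 - s)^2 / 8) + rnorm(40, sd = 0.3)),
        id = id)
    profs <- list(mkA(0, "A1"), mkB(1, "B1"), mkA(1, "A2"), mkB(-1, "B2"))
    root <- cluster_profiles(profs, plain)
    log <- attr(root, "merge_log")
    first_two <- list(sort(c(log$child1[1], log$child2[1])),
                      sort(c(log$child1[2], log$child2[2])))
    expect_setequal(lapply(first_two, paste, collapse = ","),
                    c("A1,A2", "B1,B2"))
    part <- cut_tree(root, k = 2)
    expect_setequal(lapply(part, sort), list(c("A1", "A2"), c("B1", "B2")))

    # independent pool-loop re-implementation reproduces the merge order;
    # pool members are identified by their sorted leaf sets
    oracle_merge_order <- function(mats, params) {
        pool <- mats
        order_log <- character()
        while (length(pool) > 1) {
            best <- NULL
            for (i in seq_len(length(pool) - 1)) {
                for (j in (i + 1):length(pool)) {
                    o <- oracle_align(pool[[i]]$m, pool[[j]]$m,
                                      params$min_overlap_fraction,
                                      params$allow_mirror)
                    if (is.null(best) || o$score < best$score)
                        best <- c(o, list(i = i, j = j))
                }
            }
            ni <- pool[[best$i]]; nj <- pool[[best$j]]
            order_log <- c(order_log,
                           paste(sort(c(paste(sort(ni$leaves), collapse = "+"),
                                        paste(sort(nj$leaves), collapse = "+"))),
                                 collapse = " , "))
            mj <- if (best$mirrored) nj$m[, ncol(nj$m):1, drop = FALSE] else nj$m
            o1 <- max(0, best$r); o2 <- max(0, -best$r)
            TT <- nrow(ni$m)
            L <- max(o1 + ncol(ni$m), o2 + ncol(mj))
            num <- matrix(0, TT, L); cnt <- matrix(0, TT, L)
            i1 <- o1 + seq_len(ncol(ni$m)); i2 <- o2 + seq_len(ncol(mj))
            num[, i1] <- num[, i1] + ni$m * ni$w
            cnt[, i1] <- cnt[, i1] + ni$w
            num[, i2] <- num[, i2] + mj * nj$w
            cnt[, i2] <- cnt[, i2] + nj$w
            merged <- list(leaves = c(ni$leaves, nj$leaves), m = num / cnt,
                           w = ni$w + nj$w)
            pool <- c(pool[-c(best$i, best$j)], list(merged))
        }
        order_log
    }
    mats <- lapply(profs, function(p) list(leaves = p$id, m = p$values, w = 1))
    leafset <- function(id) {
        for (n in tree_nodes(root))
            if (n$node_id == id)
                return(paste(sort(node_leaves(n)), collapse = "+"))
        id
    }
    pkg_order <- vapply(seq_len(nrow(log)), function(k)
        paste(sort(c(leafset(log$child1[k]), leafset(log$child2[k]))),
              collapse = " , "), character(1))
    expect_equal(oracle_merge_order(mats, plain), pkg_order)
})

test_that("representatives equal the leaf re-projection oracle (no pruning)", {
    set.seed(22)
    spec <- planted_spec(n_clusters = 2, members_per_cluster = 5,
                         n_tracks = 2, profile_len = 40, max_shift = 5,
                         noise_sd = 0.5, seed = 22)
    sim <- generate_planted_dataset(spec)
    root <- cluster_profiles(sim$profiles, plain)
    leaves <- setNames(normalize_tracks(sim$profiles, "none"),
                       vapply(sim$profiles, function(p) p$id, character(1)))
    for (n in tree_nodes(root, internal_only = TRUE)) {
        o <- oracle_reproject(n, leaves)
        expect_equal(n$representative$values, o$values, ignore_attr = TRUE,
                     tolerance = 1e-10)
        expect_equal(n$representative$coverage, as.integer(o$coverage))
    }
})

test_that("leaf sets are conserved and cuts partition them", {
    set.seed(23)
    profs <- lapply(1:7, function(i) random_profile(15, 1, paste0("p", i)))
    root <- cluster_profiles(profs, plain)
    ids <- paste0("p", 1:7)
    expect_setequal(node_leaves(root), ids)
    for (k in c(1, 3, 7)) {
        part <- cut_tree(root, k = k)
        expect_equal(length(part), k)
        expect_setequal(unlist(part), ids)   # exhaustive + disjoint
        expect_equal(sum(lengths(part)), 7L)
    }
    expect_true(all(lengths(cut_tree(root, k = 7)) == 1L))  # singletons
    expect_error(cut_tree(root, k = 8), "between 1 and")
    expect_error(cut_tree(root, k = 2, max_height = 1), "exactly one")
    # cutting at height >= root height gives one block
    part <- cut_tree(root, max_height = max(vapply(
        tree_nodes(root, TRUE), function(n) n$height, numeric(1))))
    expect_equal(length(part), 1L)
    # height 0 gives blocks that are all score-0 subtrees or singletons
    part0 <- cut_tree(root, max_height = 0)
    expect_setequal(unlist(part0), ids)
})

test_that("clustering is deterministic and independent of worker count", {
    set.seed(24)
    profs <- lapply(1:9, function(i) random_profile(20, 2, paste0("p", i)))
    r1 <- cluster_profiles(profs, plain, workers = 1L)
    r2 <- cluster_profiles(profs, plain, workers = 1L)
    expect_identical(to_newick(r1), to_newick(r2))
    r4 <- cluster_profiles(profs, plain, workers = 4L)
    expect_identical(to_newick(r1), to_newick(r4))
    expect_identical(r1$placements, r4$placements)
})

test_that("to_newick writes valid trees that ape can parse back", {
    p1 <- signal_profile(c(1, 2, 3), id = "p1")
    expect_equal(to_newick(cluster_profiles(list(p1), plain)), "p1;")

    p2 <- signal_profile(c(1, 2, 3), id = "p2")
    root2 <- cluster_profiles(list(p1, p2), plain)
    root2$height <- 0.5   # force the documented branch-length example
    expect_equal(to_newick(root2), "(p1:0.5,p2:0.5);")

    skip_if_not_installed("ape")
    set.seed(25)
    profs <- lapply(1:6, function(i) random_profile(12, 1, paste0("leaf", i)))
    root <- cluster_profiles(profs, plain)
    tree <- ape::read.tree(text = to_newick(root))
    expect_setequal(tree$tip.label, paste0("leaf", 1:6))
    expect_equal(tree$Nnode, 5L)
    # topology round-trip: ape's clades match ours
    ape_clades <- lapply(ape::prop.part(tree), function(ix)
        sort(tree$tip.label[ix]))
    our_clades <- lapply(canonical_clades(root), `[[`, "leaves")
    expect_true(all(vapply(our_clades, function(cl)
        any(vapply(ape_clades, identical, logical(1), y = cl)),
        logical(1))))
})

test_that("empty input errors; duplicate ids error", {
    expect_error(cluster_profiles(list(), plain), "empty")
    p <- signal_profile(1:3, id = "x")
    expect_error(cluster_profiles(list(p, p), plain), "unique")
})
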