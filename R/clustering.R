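#' Merge two aligned profiles into their coverage-weighted average
#'
#' Realizes the centroid step: the representative of a cluster is the average
#' of its aligned members. `p2` is mirrored first if the alignment says so,
#' the two matrices are laid out at relative shift `a$r` over
#' `n_total = L1 + L2 - n_overlap` bins, and each merged bin is the
#' coverage-weighted mean of the children present there
#' (`(c1*v1 + c2*v2)/(c1+c2)` per track). Non-overlapping flanks are copied
#' from whichever child is present. The new coverage is the sum of the child
#' coverages where present, the new weight is `w1 + w2` — so iterated merging
#' reproduces the true centroid (the coverage-weighted mean of all leaves).
#'
#' @param p1,p2 `signal_profile`s with identical track sets.
#' @param a a `profile_alignment` produced by [align_pair()] for this pair.
#' @param new_id identifier of the merged profile.
#' @return a list with `profile` (the merged `signal_profile`), `offset1` and
#'   `offset2` (bin offsets of `p1` and of the possibly mirrored `p2` inside
#'   the merged frame).
#' @export
merge_profiles <- function(p1, p2, a, new_id = paste0(p1$id, "+", p2$id)) {
    stopifnot(inherits(p1, "signal_profile"), inherits(p2, "signal_profile"),
              inherits(a, "profile_alignment"))
    check_track_compat(p1, p2)
    if (isTRUE(a$mirrored))
        p2 <- mirror_profile(p2)
    L1 <- profile_length(p1)
    L2 <- profile_length(p2)
    r <- a$r
    n_ov <- min(L1, L2 - r) - max(0L, -r)
    if (n_ov < 1L)
        stop("inconsistent alignment: shift yields no overlap")
    off1 <- max(0L, r)           # p1 start in the merged frame
    off2 <- max(0L, -r)          # p2 start in the merged frame
    Lm <- max(off1 + L1, off2 + L2)
    TT <- nrow(p1$values)
    num <- matrix(0, TT, Lm)
    cov <- integer(Lm)
    i1 <- off1 + seq_len(L1)
    num[, i1] <- num[, i1, drop = FALSE] +
        sweep(p1$values, 2L, p1$coverage, `*`)
    cov[i1] <- cov[i1] + p1$coverage
    i2 <- off2 + seq_len(L2)
    num[, i2] <- num[, i2, drop = FALSE] +
        sweep(p2$values, 2L, p2$coverage, `*`)
    cov[i2] <- cov[i2] + p2$coverage
    vals <- sweep(num, 2L, cov, `/`)
    prof <- signal_profile(vals, id = new_id, bin_size = p1$bin_size,
                           weight = p1$weight + p2$weight, coverage = cov,
                           track_names = p1$track_names)
    list(profile = prof, offset1 = off1, offset2 = off2)
}

#' Trim sparsely aligned alignment edges
#'
#' Removes the maximal runs at the left and right edges (only — interior
#' low-coverage bins are never touched) where per-bin coverage is below
#' `prune_fraction * weight`. Pruning enforces pattern significance by
#' recurrence: the heavily aligned core is kept, the loosely aligned flanks
#' introduced by merging at offsets are dropped. If every bin falls below the
#' threshold, the leftmost run of maximum-coverage bins (including its
#' contiguous equals) is kept instead of emptying the profile.
#'
#' @param p a `signal_profile`.
#' @param prune_fraction fraction of `weight` in \[0, 1\]; 0 is a no-op.
#' @return list with `profile`, `trimmed_left`, `trimmed_right`.
#' @export
prune_profile <- function(p, prune_fraction) {
    stopifnot(inherits(p, "signal_profile"))
    if (!is.numeric(prune_fraction) || prune_fraction < 0 || prune_fraction > 1)
        stop("`prune_fraction` must be in [0, 1]")
    L <- profile_length(p)
    keep <- p$coverage >= prune_fraction * p$weight
    if (!any(keep)) {
        mx <- max(p$coverage)
        first <- which(p$coverage == mx)[1L]
        last <- first
        while (last < L && p$coverage[last + 1L] == mx) last <- last + 1L
        keep <- rep.int(FALSE, L)
        keep[first:last] <- TRUE
    }
    lo <- which(keep)[1L]
    hi <- max(which(keep))
    if (lo == 1L && hi == L)
        return(list(profile = p, trimmed_left = 0L, trimmed_right = 0L))
    p$values <- p$values[, lo:hi, drop = FALSE]
    p$coverage <- p$coverage[lo:hi]
    list(profile = p, trimmed_left = lo - 1L, trimmed_right = L - hi)
}

new_leaf_node <- function(p) {
    structure(list(node_id = p$id, children = NULL, representative = p,
                   merge = NULL, height = 0,
                   placements = data.frame(
                       leaf_id = p$id, offset = 0L, mirrored = FALSE,
                       length = profile_length(p),
                       stringsAsFactors = FALSE)),
              class = "cluster_node")
}

# Compose the two children's leaf placements into the merged (and pruned)
# frame. Mirroring a node of length L2 sends a leaf at [o, o + l) to
# [L2 - o - l, L2 - o) with its orientation flipped.
merge_nodes <- function(n1, n2, a, node_id, prune_fraction) {
    m <- merge_profiles(n1$representative, n2$representative, a,
                        new_id = node_id)
    pl1 <- n1$placements
    pl1$offset <- pl1$offset + m$offset1
    pl2 <- n2$placements
    if (isTRUE(a$mirrored)) {
        L2 <- profile_length(n2$representative)
        pl2$offset <- L2 - pl2$offset - pl2$length
        pl2$mirrored <- !pl2$mirrored
    }
    pl2$offset <- pl2$offset + m$offset2
    prof <- m$profile
    trimmed <- list(profile = prof, trimmed_left = 0L, trimmed_right = 0L)
    if (prune_fraction > 0)
        trimmed <- prune_profile(prof, prune_fraction)
    pl <- rbind(pl1, pl2)
    pl$offset <- pl$offset - trimmed$trimmed_left
    structure(list(node_id = node_id, children = list(n1, n2),
                   representative = trimmed$profile, merge = a,
                   height = a$score, placements = pl),
              class = "cluster_node")
}

#' @export
print.cluster_node <- function(x, ...) {
    cat(sprintf("<cluster_node '%s'> %d leaf(s), height=%.6g, representative %d bin(s)\n",
                x$node_id, nrow(x$placements), x$height,
                profile_length(x$representative)))
    invisible(x)
}

#' Leaf identifiers under a node
#' @param node a `cluster_node`.
#' @return character vector of leaf ids.
#' @export
node_leaves <- function(node) node$placements$leaf_id

#' Pool-based centroid clustering of aligned profiles
#'
#' Agglomerative clustering interleaved with alignment (unweighted pair-group
#' centroid clustering): starting from the pool of all input profiles, the
#' pair with the lowest alignment score is merged into its coverage-weighted
#' average representative (pruned at the edges), the pair is replaced by the
#' merged profile, and the new profile is aligned against everything left in
#' the pool. The sequence of merges defines the dendrogram; merge scores are
#' the node heights (inversions are possible, as is inherent to centroid
#' linkage). Cached scores between untouched pool members are reused, so a
#' full run performs `choose(N,2) + choose(N-1,2)` pairwise alignments.
#'
#' Ties in the pair selection are broken by the smaller pair of pool
#' insertion indices, making the whole procedure deterministic for a fixed
#' input order.
#'
#' @param profiles list of `signal_profile`s (>= 1) with identical track sets.
#' @param params a [cluster_params()] object; normalization is applied to the
#'   dataset first.
#' @param workers number of workers used to compute the initial all-pairs
#'   scores (via forked processes when > 1). Results are identical for any
#'   worker count; only speed changes.
#' @return the root `cluster_node`. Its `placements` give every leaf's
#'   cumulative bin offset and orientation in the root frame. Attributes:
#'   `n_align_calls` (number of [align_pair()] invocations) and `merge_log`
#'   (data.frame of the merge sequence). In the pathological case that no
#'   remaining pool pair can be aligned, a list of roots (class
#'   `cluster_forest`) is returned instead.
#' @export
cluster_profiles <- function(profiles, params = cluster_params(), workers = 1L) {
    if (length(profiles) == 0L)
        stop("empty input: need at least one profile")
    ids <- vapply(profiles, function(p) p$id, character(1L))
    if (anyDuplicated(ids))
        stop("profile ids must be unique")
    profiles <- normalize_tracks(profiles, params$normalization)
    n_calls <- 0L
    pool <- lapply(profiles, new_leaf_node)
    ins <- seq_along(pool)            # insertion-order ids, tie-break key
    next_ins <- length(pool) + 1L
    if (length(pool) == 1L) {
        root <- pool[[1L]]
        attr(root, "n_align_calls") <- 0L
        attr(root, "merge_log") <- empty_merge_log()
        return(root)
    }

    cache <- new.env(parent = emptyenv())
    pair_key <- function(i, j) paste0(min(i, j), "_", max(i, j))
    do_align <- function(ni, nj) {
        tryCatch(align_pair(ni$representative, nj$representative, params),
                 error = function(e) NULL)
    }

    # initial all-pairs scores, chunked over workers
    pairs <- utils::combn(seq_along(pool), 2L)
    npairs <- ncol(pairs)
    chunk_of <- rep(seq_len(max(1L, workers)), length.out = npairs)
    chunks <- split(seq_len(npairs), chunk_of)
    fun <- function(idx) lapply(idx, function(k)
        do_align(pool[[pairs[1L, k]]], pool[[pairs[2L, k]]]))
    chunk_res <- if (workers > 1L && .Platform$OS.type == "unix")
        parallel::mclapply(chunks, fun, mc.cores = workers)
    else
        lapply(chunks, fun)
    res <- vector("list", npairs)
    for (ci in seq_along(chunks))
        res[chunks[[ci]]] <- chunk_res[[ci]]
    for (k in seq_len(npairs))
        assign(pair_key(ins[pairs[1L, k]], ins[pairs[2L, k]]), res[[k]],
               envir = cache)
    n_calls <- n_calls + npairs

    log <- list()
    repeat {
        if (length(pool) == 1L)
            break
        best <- NULL
        bi <- bj <- 0L
        for (i in seq_len(length(pool) - 1L)) {
            for (j in (i + 1L):length(pool)) {
                al <- get0(pair_key(ins[i], ins[j]), envir = cache)
                if (is.null(al))
                    next
                take <- is.null(best) || al$score < best$score
                if (take) {
                    best <- al
                    bi <- i
                    bj <- j
                }
            }
        }
        if (is.null(best)) {
            # no alignable pair left: return remaining pool as a forest
            forest <- pool
            for (r in seq_along(forest)) {
                attr(forest[[r]], "n_align_calls") <- NULL
            }
            attr(forest, "n_align_calls") <- n_calls
            attr(forest, "merge_log") <- merge_log_df(log)
            class(forest) <- "cluster_forest"
            return(forest)
        }
        node_id <- paste0("node_", next_ins)
        newn <- merge_nodes(pool[[bi]], pool[[bj]], best, node_id,
                            params$prune_fraction)
        log[[length(log) + 1L]] <- data.frame(
            node_id = node_id, child1 = pool[[bi]]$node_id,
            child2 = pool[[bj]]$node_id, score = best$score, r = best$r,
            mirrored = best$mirrored, stringsAsFactors = FALSE)
        drop_ins <- ins[c(bi, bj)]
        pool <- pool[-c(bi, bj)]
        ins <- ins[-c(bi, bj)]
        for (key in ls(cache)) {
            ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1L]])
            if (any(ij %in% drop_ins))
                rm(list = key, envir = cache)
        }
        # keep cached alignments oriented as (smaller insertion id, larger):
        # selection iterates the pool in insertion order, so merge_nodes()
        # receives (n1, n2) in exactly that orientation
        for (i in seq_along(pool)) {
            al <- do_align(pool[[i]], newn)
            n_calls <- n_calls + 1L
            assign(pair_key(next_ins, ins[i]), al, envir = cache)
        }
        pool <- c(pool, list(newn))
        ins <- c(ins, next_ins)
        next_ins <- next_ins + 1L
    }
    root <- pool[[1L]]
    attr(root, "n_align_calls") <- n_calls
    attr(root, "merge_log") <- merge_log_df(log)
    root
}

empty_merge_log <- function() {
    data.frame(node_id = character(), child1 = character(),
               child2 = character(), score = numeric(), r = integer(),
               mirrored = logical(), stringsAsFactors = FALSE)
}

merge_log_df <- function(log) {
    if (length(log) == 0L) empty_merge_log() else do.call(rbind, log)
}

#' All nodes of a dendrogram
#' @param node root `cluster_node`.
#' @param internal_only drop leaves from the result.
#' @return list of `cluster_node`s (preorder).
#' @export
tree_nodes <- function(node, internal_only = FALSE) {
    out <- list()
    walk <- function(n) {
        if (!internal_only || !is.null(n$children))
            out[[length(out) + 1L]] <<- n
        if (!is.null(n$children)) {
            walk(n$children[[1L]])
            walk(n$children[[2L]])
        }
    }
    walk(node)
    out
}

#' Cut a dendrogram into clusters
#'
#' Cutting by `k` undoes the `k - 1` highest-score merges: starting from the
#' root, the current subtree of maximum merge height is split repeatedly
#' (ties: the earlier-created node first), which handles the height
#' inversions that centroid linkage permits. Cutting by `max_height` returns
#' the maximal subtrees whose merge height is `<= max_height` (leaves have
#' height 0).
#'
#' @param root a `cluster_node`.
#' @param k number of clusters (>= 1, <= number of leaves).
#' @param max_height height threshold (>= 0); exactly one of `k` and
#'   `max_height` must be given.
#' @return list of character vectors of leaf ids; an exhaustive, disjoint
#'   partition of the root's leaves.
#' @export
cut_tree <- function(root, k = NULL, max_height = NULL) {
    stopifnot(inherits(root, "cluster_node"))
    if (is.null(k) == is.null(max_height))
        stop("give exactly one of `k` and `max_height`")
    if (!is.null(k)) {
        k <- as.integer(k)
        n_leaves <- nrow(root$placements)
        if (k < 1L || k > n_leaves)
            stop("`k` must be between 1 and the number of leaves (", n_leaves, ")")
        roots <- list(root)
        while (length(roots) < k) {
            hts <- vapply(roots, function(n)
                if (is.null(n$children)) -Inf else n$height, numeric(1L))
            pick <- which.max(hts)   # ties: first (creation order preserved)
            n <- roots[[pick]]
            roots <- c(roots[-pick], n$children)
        }
        return(lapply(roots, node_leaves))
    }
    if (max_height < 0)
        stop("`max_height` must be >= 0")
    out <- list()
    walk <- function(n) {
        if (is.null(n$children) || n$height <= max_height) {
            out[[length(out) + 1L]] <<- node_leaves(n)
        } else {
            walk(n$children[[1L]])
            walk(n$children[[2L]])
        }
    }
    walk(root)
    out
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are `parent height - child height`, floored at 0 (heights
#' may invert under centroid linkage); leaves sit at height 0. The string is
#' terminated by `";"`.
#'
#' @param root a `cluster_node`.
#' @return single Newick string.
#' @export
to_newick <- function(root) {
    stopifnot(inherits(root, "cluster_node"))
    fmt <- function(x) sprintf("%.15g", x)
    rec <- function(n, parent_height) {
        bl <- max(0, parent_height - n$height)
        if (is.null(n$children))
            return(paste0(quote_newick(n$node_id), ":", fmt(bl)))
        paste0("(", rec(n$children[[1L]], n$height), ",",
               rec(n$children[[2L]], n$height), "):", fmt(bl))
    }
    if (is.null(root$children))
        return(paste0(quote_newick(root$node_id), ";"))
    paste0("(", rec(root$children[[1L]], root$height), ",",
           rec(root$children[[2L]], root$height), ");")
}

quote_newick <- function(id) {
    if (grepl("[ \t(),:;\\[\\]']", id))
        paste0("'", gsub("'", "''", id, fixed = TRUE), "'")
    else id
}
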