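# Independent oracles, written against plain matrices without sharing code
# with the package internals.

# Exhaustive re-enumeration of all (shift, orientation) candidates.
# Convention: bin i of m1 is compared with bin i + r of m2.
oracle_align <- function(m1, m2, min_frac = 0.5, allow_mirror = TRUE) {
    L1 <- ncol(m1)
    L2 <- ncol(m2)
    TT <- nrow(m1)
    min_ov <- max(1, ceiling(min_frac * min(L1, L2)))
    better <- function(a, b) {
        if (a$score != b$score) return(a$score < b$score)
        if (abs(a$r) != abs(b$r)) return(abs(a$r) < abs(b$r))
        if (a$mirrored != b$mirrored) return(!a$mirrored)
        a$r < b$r
    }
    best <- NULL
    for (mir in c(FALSE, if (allow_mirror) TRUE)) {
        mm <- if (mir) m2[, L2:1, drop = FALSE] else m2
        for (r in (-(L1 - 1)):(L2 - 1)) {
            i <- seq_len(L1)
            ok <- (i + r) >= 1 & (i + r) <= L2
            n <- sum(ok)
            if (n < min_ov) next
            sc <- sum((m1[, i[ok], drop = FALSE] -
                       mm[, i[ok] + r, drop = FALSE])^2) / (n * TT)
            cand <- list(score = sc, r = r, mirrored = mir, n_overlap = n)
            if (is.null(best) || better(cand, best)) best <- cand
        }
    }
    best
}

# Re-projection oracle: rebuild a node's representative from its leaf
# placements alone (coverage-weighted average of the placed leaves).
oracle_reproject <- function(node, leaf_profiles) {
    pl <- node$placements
    L <- profclust::profile_length(node$representative)
    TT <- nrow(node$representative$values)
    num <- matrix(0, TT, L)
    cnt <- matrix(0, TT, L)
    for (k in seq_len(nrow(pl))) {
        p <- leaf_profiles[[pl$leaf_id[k]]]
        v <- p$values
        if (pl$mirrored[k])
            v <- v[, ncol(v):1, drop = FALSE]
        idx <- pl$offset[k] + seq_len(ncol(v))
        inside <- idx >= 1 & idx <= L
        num[, idx[inside]] <- num[, idx[inside], drop = FALSE] +
            v[, inside, drop = FALSE]
        cnt[, idx[inside]] <- cnt[, idx[inside], drop = FALSE] + 1
    }
    list(values = num / pmax(cnt, 1), coverage = cnt[1, ])
}

# Per-base brute-force binned means for profile extraction: expand a track
# to one value per base (NA where missing), then average per bin.
oracle_bin_means <- function(track_df, rs, re, bin_size) {
    L <- (re - rs) %/% bin_size
    per_base <- rep(NA_real_, L * bin_size)
    if (!is.null(track_df)) {
        for (k in seq_len(nrow(track_df))) {
            lo <- max(track_df$start[k], rs)
            hi <- min(track_df$end[k], rs + L * bin_size)
            if (hi > lo)
                per_base[(lo - rs + 1):(hi - rs)] <- track_df$value[k]
        }
    }
    vapply(seq_len(L), function(b) {
        v <- per_base[((b - 1) * bin_size + 1):(b * bin_size)]
        mean(v, na.rm = TRUE)   # NaN when the whole bin is missing
    }, numeric(1))
}

# Canonical tree form: the multiset of clades (sorted leaf-id sets) with
# their merge heights, insensitive to child order and input permutation.
canonical_clades <- function(root) {
    out <- lapply(profclust::tree_nodes(root, internal_only = TRUE),
                  function(n) list(leaves = sort(profclust::node_leaves(n)),
                                   height = n$height))
    keys <- vapply(out, function(x) paste(x$leaves, collapse = "|"),
                   character(1))
    out[order(keys)]
}

random_profile <- function(L, TT = 1, id = "p") {
    profclust::signal_profile(matrix(runif(TT * L, -1, 1), nrow = TT),
                              id = id)
}
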