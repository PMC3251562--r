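#' Parameters of the alignment-and-clustering procedure
#'
#' @param min_overlap_fraction minimum alignment overlap, as a fraction of
#'   the SHORTER profile, in (0, 1]. Default 0.5: at least half of the
#'   shorter profile must lie inside the overlap.
#' @param allow_mirror compare profiles in both the forward and the mirrored
#'   orientation (default `TRUE`); mirroring is what makes asymmetric
#'   patterns detectable regardless of genomic strand.
#' @param normalization dataset-wide track normalization applied before
#'   clustering; see [normalize_tracks()]. Default `"per_track_max"` so that
#'   no single high-signal track dominates the distance.
#' @param prune_fraction after each merge, alignment edges whose per-bin
#'   coverage falls below `prune_fraction * weight` are trimmed (edges only,
#'   never interior bins). In \[0, 1\], default 0.25; 0 disables pruning.
#' @param similarity similarity measure; only `"ssd"` (normalized sum of
#'   squared distances) is implemented. The enum is kept for extension.
#'
#' @return a list of class `cluster_params`.
#' @export
cluster_params <- function(min_overlap_fraction = 0.5, allow_mirror = TRUE,
                           normalization = c("per_track_max", "none",
                                             "per_track_zscore"),
                           prune_fraction = 0.25,
                           similarity = "ssd") {
    normalization <- match.arg(normalization)
    similarity <- match.arg(similarity, "ssd")
    if (!is.numeric(min_overlap_fraction) || length(min_overlap_fraction) != 1L ||
        is.na(min_overlap_fraction) ||
        min_overlap_fraction <= 0 || min_overlap_fraction > 1)
        stop("`min_overlap_fraction` must be in (0, 1]")
    if (!is.numeric(prune_fraction) || length(prune_fraction) != 1L ||
        is.na(prune_fraction) || prune_fraction < 0 || prune_fraction > 1)
        stop("`prune_fraction` must be in [0, 1]")
    structure(list(min_overlap_fraction = min_overlap_fraction,
                   allow_mirror = isTRUE(allow_mirror),
                   normalization = normalization,
                   prune_fraction = prune_fraction,
                   similarity = similarity),
              class = "cluster_params")
}

check_track_compat <- function(p1, p2) {
    if (!identical(p1$track_names, p2$track_names))
        stop("profiles have different track sets: ",
             paste(p1$track_names, collapse = ","), " vs ",
             paste(p2$track_names, collapse = ","))
}

#' Score one shift of a profile pair
#'
#' The dissimilarity of two profiles at a fixed rigid shift `r` is the sum of
#' squared differences over all overlapping bin pairs and all tracks, divided
#' by `n_overlap * T`. The per-bin, per-track normalization makes candidates
#' with different overlap lengths comparable; without it shorter overlaps
#' would trivially win by contributing fewer terms.
#'
#' The shift convention: bin `i` of `p1` is compared with bin `i + r` of
#' `p2`, so positive `r` moves `p2` to the left relative to `p1` and negative
#' `r` moves it to the right.
#'
#' @param p1,p2 `signal_profile`s with identical track sets.
#' @param r shift in bins (integer).
#' @return list with `score` (>= 0, lower = more similar) and `n_overlap`.
#' @export
pair_score <- function(p1, p2, r) {
    stopifnot(inherits(p1, "signal_profile"), inherits(p2, "signal_profile"))
    check_track_compat(p1, p2)
    r <- as.integer(r)
    pair_score_cpp(p1$values, p2$values, r)
}

#' Exhaustively align two profiles
#'
#' Evaluates [pair_score()] for every shift whose overlap satisfies the
#' minimum-overlap constraint (`ceiling(min_overlap_fraction * min(L1, L2))`
#' bins), in the forward orientation and, if `allow_mirror`, the mirrored
#' orientation of `p2`, and returns the best candidate. Ties are broken
#' deterministically: lowest score, then smaller `|r|`, then non-mirrored,
#' then smaller signed `r`.
#'
#' @param p1,p2 `signal_profile`s with identical track sets.
#' @param params a [cluster_params()] object.
#' @return an object of class `profile_alignment`: a list with `id1`, `id2`,
#'   `r` (shift in bins; see [pair_score()] for the sign convention),
#'   `mirrored`, `score`, `n_overlap` and `n_total = L1 + L2 - n_overlap`.
#' @export
align_pair <- function(p1, p2, params = cluster_params()) {
    stopifnot(inherits(p1, "signal_profile"), inherits(p2, "signal_profile"))
    check_track_compat(p1, p2)
    L1 <- profile_length(p1)
    L2 <- profile_length(p2)
    min_ov <- max(1L, as.integer(ceiling(params$min_overlap_fraction * min(L1, L2))))
    res <- best_alignment_cpp(p1$values, p2$values, min_ov, params$allow_mirror)
    if (!isTRUE(res$ok))
        stop("no shift satisfies the minimum-overlap constraint for '",
             p1$id, "' vs '", p2$id, "'")
    structure(list(id1 = p1$id, id2 = p2$id,
                   r = as.integer(res$r), mirrored = res$mirrored,
                   score = res$score, n_overlap = as.integer(res$n_overlap),
                   n_total = L1 + L2 - as.integer(res$n_overlap)),
              class = "profile_alignment")
}

#' @export
print.profile_alignment <- function(x, ...) {
    cat(sprintf("<alignment '%s' vs '%s'> r=%d mirrored=%s score=%.6g overlap=%d/%d\n",
                x$id1, x$id2, x$r, x$mirrored, x$score, x$n_overlap, x$n_total))
    invisible(x)
}
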