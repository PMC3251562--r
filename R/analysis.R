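#' Correlation of profile orientation with an annotation orientation
#'
#' Given, per leaf, the orientation of the profile in the cluster alignment
#' (`+1`/`-1`, from the root or subtree placements) and an annotation
#' orientation (for instance the strand of an asymmetric binding motif),
#' computes the Pearson correlation of the two sign sequences — identical to
#' the phi coefficient of the underlying 2x2 contingency table. Because a
#' cluster's frame is only defined up to a global mirror, the magnitude
#' `|corr|`, maximized over a global flip of the profile column, is reported
#' together with the flip that was chosen; the signed raw value is kept.
#'
#' @param table data.frame with columns `leaf_id` (unique),
#'   `profile_orientation` and `annotation_orientation` (both strictly
#'   `+1`/`-1`).
#' @return list of class `orientation_correlation`: `defined` (FALSE when a
#'   column is constant — the correlation is then undefined, not 0),
#'   `estimate` (`|corr|`), `flipped` (whether the reported estimate
#'   corresponds to flipping the profile column), `raw` (signed correlation
#'   as given), and `n`.
#' @export
orientation_correlation <- function(table) {
    need <- c("leaf_id", "profile_orientation", "annotation_orientation")
    if (!all(need %in% names(table)))
        stop("table must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(table$leaf_id))
        stop("leaf_ids must be unique")
    po <- table$profile_orientation
    ao <- table$annotation_orientation
    if (!all(po %in% c(-1, 1)) || !all(ao %in% c(-1, 1)))
        stop("orientations must be strictly +1 or -1")
    if (nrow(table) < 2L)
        stop("need at least 2 rows")
    out <- list(defined = TRUE, estimate = NA_real_, flipped = NA,
                raw = NA_real_, n = nrow(table))
    if (length(unique(po)) == 1L || length(unique(ao)) == 1L) {
        out$defined <- FALSE
        class(out) <- "orientation_correlation"
        return(out)
    }
    raw <- cor(po, ao)
    out$raw <- raw
    out$estimate <- abs(raw)
    out$flipped <- raw < 0
    class(out) <- "orientation_correlation"
    out
}

#' @export
print.orientation_correlation <- function(x, ...) {
    if (!x$defined)
        cat("<orientation_correlation> undefined (constant column), n =",
            x$n, "\n")
    else
        cat(sprintf("<orientation_correlation> |corr| = %.4f (raw %.4f, flip=%s), n = %d\n",
                    x$estimate, x$raw, x$flipped, x$n))
    invisible(x)
}

#' Average (meta-)profile of a set of profiles
#'
#' Without placements this is the plain positional average over profiles of
#' equal length — the unaligned baseline. With placements (as carried by a
#' `cluster_node`), every profile is first mirrored and offset per its
#' placement and the average is coverage-weighted, i.e. the same
#' re-projection machinery that defines a cluster representative. Alignment
#' concentrates the signal: the placed average of a coherent cluster has a
#' sharper, higher peak than the positional average.
#'
#' @param profiles list of `signal_profile`s with identical track sets.
#' @param placements optional data.frame with columns `leaf_id`, `offset`,
#'   `mirrored` covering all profiles.
#' @return a `signal_profile` whose weight is the number of inputs.
#' @export
meta_profile <- function(profiles, placements = NULL) {
    if (length(profiles) == 0L)
        stop("empty input")
    tn <- profiles[[1L]]$track_names
    for (p in profiles)
        check_track_compat(profiles[[1L]], p)
    if (is.null(placements)) {
        L <- unique(vapply(profiles, profile_length, integer(1L)))
        if (length(L) != 1L)
            stop("positional averaging needs equal-length profiles; give placements")
        placements <- data.frame(
            leaf_id = vapply(profiles, function(p) p$id, character(1L)),
            offset = 0L, mirrored = FALSE, stringsAsFactors = FALSE)
    }
    ids <- vapply(profiles, function(p) p$id, character(1L))
    if (!all(ids %in% placements$leaf_id))
        stop("placements must cover all profiles")
    pl <- placements[match(ids, placements$leaf_id), , drop = FALSE]
    lens <- vapply(profiles, profile_length, integer(1L))
    lo <- min(pl$offset)
    hi <- max(pl$offset + lens)
    Lm <- hi - lo
    TT <- length(tn)
    num <- matrix(0, TT, Lm)
    cov <- integer(Lm)
    for (k in seq_along(profiles)) {
        p <- profiles[[k]]
        if (pl$mirrored[k])
            p <- mirror_profile(p)
        idx <- (pl$offset[k] - lo) + seq_len(lens[k])
        num[, idx] <- num[, idx, drop = FALSE] +
            sweep(p$values, 2L, p$coverage, `*`)
        cov[idx] <- cov[idx] + p$coverage
    }
    vals <- sweep(num, 2L, pmax(cov, 1L), `/`)
    signal_profile(vals, id = "meta_profile",
                   bin_size = profiles[[1L]]$bin_size,
                   weight = length(profiles),
                   coverage = pmax(cov, 1L), track_names = tn)
}
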