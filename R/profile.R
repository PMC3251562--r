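#' Multi-track signal profile
#'
#' A `signal_profile` is the unit that gets aligned, merged and clustered: a
#' `T x L` matrix of real-valued signal (one row per track, one column per
#' bin), together with the bin width in bp, the number of leaf profiles the
#' matrix represents (`weight`) and, per bin, how many of those leaves
#' contribute signal there (`coverage`). A freshly extracted profile has
#' `weight = 1` and coverage 1 everywhere; merged cluster representatives
#' accumulate weight and carry coverage < weight near sparsely aligned edges.
#'
#' @param values numeric matrix (tracks x bins) or a numeric vector for a
#'   single-track profile.
#' @param id profile identifier.
#' @param bin_size bin width in bp (integer >= 1).
#' @param weight number of leaf profiles represented (integer >= 1).
#' @param coverage integer vector, per-bin count of contributing leaves;
#'   defaults to `weight` at every bin (valid for leaves; merged profiles
#'   must supply it).
#' @param track_names optional character vector of track labels; defaults to
#'   the rownames of `values` or `track1..trackT`.
#'
#' @return an object of class `signal_profile`.
#' @export
signal_profile <- function(values, id = "profile", bin_size = 1L, weight = 1L,
                           coverage = NULL, track_names = NULL) {
    if (is.vector(values) && is.numeric(values))
        values <- matrix(values, nrow = 1L)
    if (!is.matrix(values) || !is.numeric(values))
        stop("`values` must be a numeric matrix or vector")
    if (ncol(values) < 1L)
        stop("a profile needs at least one bin")
    if (anyNA(values))
        stop("profile values must be dense; handle missing data at extraction time")
    bin_size <- as.integer(bin_size)
    if (is.na(bin_size) || bin_size < 1L)
        stop("`bin_size` must be an integer >= 1")
    weight <- as.integer(weight)
    if (is.na(weight) || weight < 1L)
        stop("`weight` must be an integer >= 1")
    if (is.null(coverage))
        coverage <- rep.int(weight, ncol(values))
    coverage <- as.integer(coverage)
    if (length(coverage) != ncol(values))
        stop("`coverage` must have one entry per bin")
    if (any(coverage < 1L) || any(coverage > weight))
        stop("coverage must satisfy 1 <= coverage <= weight at every bin")
    if (is.null(track_names))
        track_names <- if (!is.null(rownames(values))) rownames(values)
                       else paste0("track", seq_len(nrow(values)))
    if (length(track_names) != nrow(values))
        stop("`track_names` must have one entry per track")
    rownames(values) <- track_names
    structure(
        list(id = as.character(id), values = values, bin_size = bin_size,
             weight = weight, coverage = coverage,
             track_names = as.character(track_names)),
        class = "signal_profile")
}

#' @export
print.signal_profile <- function(x, ...) {
    cat(sprintf("<signal_profile '%s'> %d track(s) x %d bin(s), bin_size=%d bp, weight=%d\n",
                x$id, nrow(x$values), ncol(x$values), x$bin_size, x$weight))
    cat("  tracks:", paste(x$track_names, collapse = ", "), "\n")
    invisible(x)
}

#' Number of bins of a profile
#' @param p a `signal_profile`.
#' @return integer bin count.
#' @export
profile_length <- function(p) ncol(p$values)

#' Mirror a profile
#'
#' Reverses the bin order of every track (and of the coverage vector) so the
#' profile reads right-to-left. All tracks are flipped jointly: a profile is
#' mirrored as a unit. Mirroring is an involution.
#'
#' @param p a `signal_profile`.
#' @return the mirrored `signal_profile`.
#' @export
mirror_profile <- function(p) {
    stopifnot(inherits(p, "signal_profile"))
    L <- ncol(p$values)
    p$values <- p$values[, L:1, drop = FALSE]
    p$coverage <- rev(p$coverage)
    p
}

#' Normalize signal tracks across a profile set
#'
#' Strong tracks (high antibody affinity, deep sequencing) otherwise dominate
#' a sum-of-squared-distances comparison, so the clustering would sort
#' profiles by intensity rather than by pattern. Normalization is dataset
#' wide: the scaling constants for track `t` are computed from the values of
#' track `t` pooled over all profiles, and the same constants are applied to
#' every profile.
#'
#' @param profiles list of `signal_profile` objects sharing the same track
#'   names (same order).
#' @param method `"none"` (identity), `"per_track_max"` (divide each track by
#'   its dataset-wide maximum absolute value; a zero maximum is left alone) or
#'   `"per_track_zscore"` (subtract the dataset-wide mean and divide by the
#'   dataset-wide standard deviation, sample `n - 1` denominator; a zero
#'   standard deviation skips the division).
#'
#' @return the list of profiles with rescaled values.
#' @export
normalize_tracks <- function(profiles,
                             method = c("per_track_max", "none", "per_track_zscore")) {
    method <- match.arg(method)
    stopifnot(length(profiles) >= 1L)
    lapply(profiles, function(p) stopifnot(inherits(p, "signal_profile")))
    tn <- profiles[[1L]]$track_names
    for (p in profiles)
        if (!identical(p$track_names, tn))
            stop("profiles have mismatched track sets; cannot normalize")
    if (method == "none")
        return(profiles)
    TT <- length(tn)
    pooled <- lapply(seq_len(TT), function(t)
        unlist(lapply(profiles, function(p) p$values[t, ]), use.names = FALSE))
    if (method == "per_track_max") {
        mx <- vapply(pooled, function(v) max(abs(v)), numeric(1L))
        scale_fun <- function(v, t) if (mx[t] > 0) v / mx[t] else v
    } else {
        mu <- vapply(pooled, mean, numeric(1L))
        sg <- vapply(pooled, sd, numeric(1L))
        scale_fun <- function(v, t) {
            v <- v - mu[t]
            if (!is.na(sg[t]) && sg[t] > 0) v / sg[t] else v
        }
    }
    lapply(profiles, function(p) {
        for (t in seq_len(TT))
            p$values[t, ] <- scale_fun(p$values[t, ], t)
        p
    })
}
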