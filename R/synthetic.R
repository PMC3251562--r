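#' Specification of a planted-cluster profile dataset
#'
#' Describes a synthetic world with known ground truth: `n_clusters` groups
#' of profiles, each group defined by a characteristic combination of
#' Gaussian-shaped peaks across tracks. Each member's peak centers are
#' shifted by a uniform integer offset (the pattern moves inside a fixed
#' window, mimicking imprecise peak calling around enrichment summits), the
#' whole pattern is mirrored with probability `mirror_probability`, and
#' i.i.d. Gaussian noise is added per bin.
#'
#' The defaults state the validation world used throughout the package: 3
#' clusters of 20 members, 4 tracks, 100 bins, shifts up to +/-10 bins,
#' mirroring with probability 0.5, and noise at 10% of the peak amplitude.
#'
#' @param n_clusters number of planted clusters.
#' @param members_per_cluster profiles per cluster.
#' @param n_tracks number of tracks.
#' @param profile_len profile length in bins.
#' @param peak_spec list (one element per cluster) of lists (one per track)
#'   of data.frames with columns `center`, `width`, `amplitude` (bins /
#'   bins / signal units; centers 1-based). `NULL` uses a built-in set of
#'   distinct asymmetric peak combinations (requires `n_tracks >= 2`).
#' @param max_shift maximum |shift| in bins (< `profile_len/2`).
#' @param mirror_probability probability a member is mirrored.
#' @param noise_sd standard deviation of the additive per-bin noise.
#' @param seed integer seed; generation is fully reproducible (Mersenne
#'   Twister with inversion normals, fixed explicitly).
#' @return list of class `planted_spec`.
#' @export
planted_spec <- function(n_clusters = 3L, members_per_cluster = 20L,
                         n_tracks = 4L, profile_len = 100L, peak_spec = NULL,
                         max_shift = 10L, mirror_probability = 0.5,
                         noise_sd = 1, seed = 1L) {
    n_clusters <- as.integer(n_clusters)
    members_per_cluster <- as.integer(members_per_cluster)
    n_tracks <- as.integer(n_tracks)
    profile_len <- as.integer(profile_len)
    max_shift <- as.integer(max_shift)
    stopifnot(n_clusters >= 1L, members_per_cluster >= 1L, n_tracks >= 1L,
              profile_len >= 2L, max_shift >= 0L,
              mirror_probability >= 0, mirror_probability <= 1, noise_sd >= 0)
    if (max_shift >= profile_len / 2)
        stop("`max_shift` must be < profile_len/2")
    if (is.null(peak_spec))
        peak_spec <- default_peak_spec(n_clusters, n_tracks, profile_len)
    for (cl in peak_spec) for (pk in cl) {
        if (nrow(pk) > 0L) {
            stopifnot(all(pk$amplitude >= 0), all(pk$width >= 1))
        }
    }
    structure(list(n_clusters = n_clusters,
                   members_per_cluster = members_per_cluster,
                   n_tracks = n_tracks, profile_len = profile_len,
                   peak_spec = peak_spec, max_shift = max_shift,
                   mirror_probability = mirror_probability,
                   noise_sd = noise_sd, seed = as.integer(seed)),
              class = "planted_spec")
}

# Distinct asymmetric track/position combinations, cycling if n_clusters or
# n_tracks exceeds the hand-written templates. Amplitude 10 throughout, so
# the default noise_sd of 1 is 10% of peak height.
default_peak_spec <- function(n_clusters, n_tracks, profile_len) {
    if (n_tracks < 2L)
        stop("the built-in peak spec needs n_tracks >= 2; supply `peak_spec`")
    peak <- function(center, width = 5, amplitude = 10)
        data.frame(center = center, width = width, amplitude = amplitude)
    none <- data.frame(center = numeric(), width = numeric(),
                       amplitude = numeric())
    at <- function(f) max(2L, min(profile_len - 1L, round(f * profile_len)))
    templates <- list(
        list(t1 = peak(at(0.30)), t2 = peak(at(0.60))),
        list(t2 = peak(at(0.40)), t3 = peak(at(0.70))),
        list(t1 = peak(at(0.70)), t4 = peak(at(0.35), width = 8)),
        list(t3 = peak(at(0.25)), t4 = peak(at(0.65))),
        list(t1 = peak(at(0.50)), t3 = peak(at(0.80)))
    )
    lapply(seq_len(n_clusters), function(c) {
        tmpl <- templates[[(c - 1L) %% length(templates) + 1L]]
        lapply(seq_len(n_tracks), function(t) {
            key <- paste0("t", (t - 1L) %% 4L + 1L)
            if (!is.null(tmpl[[key]])) tmpl[[key]] else none
        })
    })
}

with_fixed_rng <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                              normal.kind = "Inversion",
                              sample.kind = "Rejection"))
    force(code)
}

#' Build one synthetic profile from Gaussian peaks
#'
#' Track `t` is the sum of its Gaussian bumps,
#' `amplitude * exp(-(i - center)^2 / (2 width^2))` over bins `i = 1..L`,
#' plus `N(0, noise_sd^2)` noise per bin. Draws from the current RNG stream.
#'
#' @param peaks list (one per track) of data.frames with columns `center`,
#'   `width`, `amplitude`.
#' @param length profile length in bins.
#' @param noise_sd noise standard deviation.
#' @param id profile identifier.
#' @param track_names optional track labels.
#' @return a `signal_profile` with weight 1.
#' @export
make_profile <- function(peaks, length, noise_sd = 0, id = "profile",
                         track_names = NULL) {
    L <- as.integer(length)
    stopifnot(L >= 1L)
    TT <- base::length(peaks)
    vals <- matrix(0, nrow = TT, ncol = L)
    i <- seq_len(L)
    for (t in seq_len(TT)) {
        pk <- peaks[[t]]
        if (!is.null(pk) && nrow(pk) > 0L) {
            for (k in seq_len(nrow(pk)))
                vals[t, ] <- vals[t, ] + pk$amplitude[k] *
                    exp(-(i - pk$center[k])^2 / (2 * pk$width[k]^2))
        }
        if (noise_sd > 0)
            vals[t, ] <- vals[t, ] + rnorm(L, sd = noise_sd)
    }
    signal_profile(vals, id = id, track_names = track_names)
}

#' Generate a planted-cluster dataset with ground truth
#'
#' For each member: a uniform integer shift in `[-max_shift, max_shift]` is
#' added to all of the cluster's peak centers, the noiseless pattern is then
#' mirrored with probability `mirror_probability`, and Gaussian noise is
#' added per bin. Reproducible from `spec$seed`.
#'
#' @param spec a [planted_spec()].
#' @return list with `profiles` (list of `signal_profile`s, ids
#'   `c<cluster>_m<member>`) and `truth` (data.frame `leaf_id`, `cluster`,
#'   `shift`, `mirrored`).
#' @export
generate_planted_dataset <- function(spec) {
    stopifnot(inherits(spec, "planted_spec"))
    track_names <- paste0("track", seq_len(spec$n_tracks))
    with_fixed_rng(spec$seed, {
        profiles <- list()
        truth <- list()
        for (c in seq_len(spec$n_clusters)) {
            base_peaks <- spec$peak_spec[[c]]
            for (m in seq_len(spec$members_per_cluster)) {
                id <- sprintf("c%d_m%d", c, m)
                shift <- if (spec$max_shift > 0)
                    sample.int(2L * spec$max_shift + 1L, 1L) -
                        spec$max_shift - 1L
                else 0L
                mirrored <- runif(1L) < spec$mirror_probability
                peaks <- lapply(base_peaks, function(pk) {
                    if (nrow(pk) > 0L) pk$center <- pk$center + shift
                    pk
                })
                p <- make_profile(peaks, spec$profile_len, noise_sd = 0,
                                  id = id, track_names = track_names)
                if (mirrored)
                    p <- mirror_profile(p)
                if (spec$noise_sd > 0)
                    p$values <- p$values +
                        matrix(rnorm(base::length(p$values),
                                     sd = spec$noise_sd),
                               nrow = nrow(p$values))
                profiles[[base::length(profiles) + 1L]] <- p
                truth[[base::length(truth) + 1L]] <- data.frame(
                    leaf_id = id, cluster = c, shift = shift,
                    mirrored = mirrored, stringsAsFactors = FALSE)
            }
        }
        list(profiles = profiles, truth = do.call(rbind, truth))
    })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same leaf set,
#' computed from the contingency table. 1 for identical partitions, about 0
#' for independent ones, and can be negative.
#'
#' @param partition_a,partition_b either a list of character vectors (leaf id
#'   sets) or a named membership vector.
#' @return a number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(partition_a, partition_b) {
    memb <- function(p) {
        if (is.list(p)) {
            ids <- unlist(p, use.names = FALSE)
            if (anyDuplicated(ids))
                stop("partition blocks are not disjoint")
            setNames(rep(seq_along(p), lengths(p)), ids)
        } else if (!is.null(names(p))) {
            setNames(as.integer(factor(p)), names(p))
        } else {
            stop("partitions must be lists of id sets or named vectors")
        }
    }
    a <- memb(partition_a)
    b <- memb(partition_b)
    if (!setequal(names(a), names(b)))
        stop("partitions cover different leaf sets")
    b <- b[names(a)]
    tab <- table(a, b)
    n <- sum(tab)
    sum_ij <- sum(choose(tab, 2))
    sum_a <- sum(choose(rowSums(tab), 2))
    sum_b <- sum(choose(colSums(tab), 2))
    expected <- sum_a * sum_b / choose(n, 2)
    max_index <- (sum_a + sum_b) / 2
    if (max_index == expected)   # both partitions trivial
        return(1)
    (sum_ij - expected) / (max_index - expected)
}
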