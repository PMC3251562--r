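read_input_lines <- function(x) {
    if (is.character(x) && length(x) == 1L && !grepl("[\n\t]", x) && file.exists(x))
        return(readLines(x, warn = FALSE))
    if (inherits(x, "connection"))
        return(readLines(x, warn = FALSE))
    as.character(x)
}

is_header_line <- function(line) {
    grepl("^\\s*$", line) | grepl("^#", line) |
        grepl("^(track|browser)\\b", line)
}

#' Parse a BED file of genomic regions
#'
#' Accepts 3- to 6-column BED. Coordinates are BED-standard 0-based
#' half-open. Column 4 (name) and column 6 (strand) are captured when
#' present; `track`/`browser` headers, comments and blank lines are skipped.
#'
#' @param x file path, connection, or character vector of lines.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `strand`
#'   (strand is `+`, `-` or `*` for unknown), in file order.
#' @export
parse_bed <- function(x) {
    lines <- read_input_lines(x)
    keep <- !is_header_line(lines)
    out <- vector("list", sum(keep))
    k <- 0L
    for (ln in which(keep)) {
        f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1L]]
        if (length(f) < 3L)
            stop("BED parse error at line ", ln, ": fewer than 3 fields")
        start <- suppressWarnings(as.integer(f[2L]))
        end <- suppressWarnings(as.integer(f[3L]))
        if (is.na(start) || is.na(end))
            stop("BED parse error at line ", ln, ": non-integer coordinate")
        if (start < 0L)
            stop("BED parse error at line ", ln, ": negative start")
        if (start >= end)
            stop("BED parse error at line ", ln, ": start >= end")
        nm <- if (length(f) >= 4L) f[4L] else NA_character_
        strand <- if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "*"
        k <- k + 1L
        out[[k]] <- data.frame(chrom = f[1L], start = start, end = end,
                               name = nm, strand = strand,
                               stringsAsFactors = FALSE)
    }
    regions <- do.call(rbind, out)
    if (is.null(regions))
        regions <- data.frame(chrom = character(), start = integer(),
                              end = integer(), name = character(),
                              strand = character(), stringsAsFactors = FALSE)
    miss <- is.na(regions$name)
    if (any(miss))
        regions$name[miss] <- paste0("region_", which(miss))
    regions
}

new_signal_track <- function(name, data) {
    structure(list(name = name, data = data), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
    n <- sum(vapply(x$data, nrow, integer(1L)))
    cat(sprintf("<signal_track '%s'> %d interval(s) on %d chromosome(s)\n",
                x$name, n, length(x$data)))
    invisible(x)
}

finalize_track_intervals <- function(name, chrom, start, end, value) {
    df <- data.frame(start = start, end = end, value = value)
    sp <- split(df, chrom)
    data <- lapply(names(sp), function(ch) {
        d <- sp[[ch]]
        d <- d[order(d$start, d$end), , drop = FALSE]
        if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
            stop("overlapping intervals on ", ch, " in track '", name, "'")
        rownames(d) <- NULL
        d
    })
    names(data) <- names(sp)
    new_signal_track(name, data)
}

#' Parse a bedGraph signal track
#'
#' Lines are `chrom start end value` with 0-based half-open coordinates.
#' Positions not covered by any interval are missing (not zero); the
#' distinction drives interpolation at profile extraction. Overlapping
#' intervals are an error; adjacent intervals are retained unmerged.
#'
#' @param x file path, connection, or character vector of lines.
#' @param name track label.
#' @return a `signal_track`.
#' @export
parse_bedgraph <- function(x, name = "track") {
    lines <- read_input_lines(x)
    keep <- which(!is_header_line(lines))
    chrom <- character(length(keep))
    start <- integer(length(keep))
    end <- integer(length(keep))
    value <- numeric(length(keep))
    for (k in seq_along(keep)) {
        ln <- keep[k]
        f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1L]]
        if (length(f) < 4L)
            stop("bedGraph parse error at line ", ln, ": fewer than 4 fields")
        s <- suppressWarnings(as.integer(f[2L]))
        e <- suppressWarnings(as.integer(f[3L]))
        v <- suppressWarnings(as.numeric(f[4L]))
        if (is.na(s) || is.na(e) || s < 0L || s >= e)
            stop("bedGraph parse error at line ", ln, ": bad interval")
        if (is.na(v))
            stop("bedGraph parse error at line ", ln, ": non-numeric value")
        chrom[k] <- f[1L]; start[k] <- s; end[k] <- e; value[k] <- v
    }
    finalize_track_intervals(name, chrom, start, end, value)
}

#' Parse a wiggle (fixedStep/variableStep) signal track
#'
#' Follows the UCSC wiggle conventions: positions in the file are 1-based and
#' are converted to 0-based half-open intervals internally. `span` defaults
#' to 1 for `variableStep` and to `step` (contiguous coverage) for
#' `fixedStep`.
#'
#' @param x file path, connection, or character vector of lines.
#' @param name track label.
#' @return a `signal_track`.
#' @export
parse_wiggle <- function(x, name = "track") {
    lines <- read_input_lines(x)
    chrom <- character(); start <- integer(); end <- integer(); value <- numeric()
    mode <- NULL; cur_chrom <- NULL; cur_pos <- NA_integer_
    step <- NA_integer_; span <- NA_integer_; last_start <- -1L
    get_attr <- function(f, key) {
        hit <- grep(paste0("^", key, "="), f, value = TRUE)
        if (length(hit) == 0L) return(NA_character_)
        sub(paste0("^", key, "="), "", hit[1L])
    }
    for (ln in seq_along(lines)) {
        line <- trimws(lines[ln])
        if (is_header_line(line))
            next
        f <- strsplit(line, "[ \t]+")[[1L]]
        if (f[1L] == "fixedStep" || f[1L] == "variableStep") {
            mode <- f[1L]
            cur_chrom <- get_attr(f, "chrom")
            if (is.na(cur_chrom))
                stop("wiggle parse error at line ", ln, ": missing chrom=")
            if (mode == "fixedStep") {
                st <- suppressWarnings(as.integer(get_attr(f, "start")))
                step <- suppressWarnings(as.integer(get_attr(f, "step")))
                if (is.na(st) || is.na(step))
                    stop("wiggle parse error at line ", ln,
                         ": fixedStep needs start= and step=")
                sp <- suppressWarnings(as.integer(get_attr(f, "span")))
                span <- if (is.na(sp)) step else sp
                cur_pos <- st
            } else {
                sp <- suppressWarnings(as.integer(get_attr(f, "span")))
                span <- if (is.na(sp)) 1L else sp
            }
            last_start <- -1L
            next
        }
        if (is.null(mode))
            stop("wiggle parse error at line ", ln,
                 ": data line before any step declaration")
        if (mode == "fixedStep") {
            v <- suppressWarnings(as.numeric(f[1L]))
            if (is.na(v))
                stop("wiggle parse error at line ", ln, ": non-numeric value")
            s0 <- cur_pos - 1L          # 1-based -> 0-based
            chrom <- c(chrom, cur_chrom)
            start <- c(start, s0)
            end <- c(end, s0 + span)
            value <- c(value, v)
            cur_pos <- cur_pos + step
        } else {
            if (length(f) < 2L)
                stop("wiggle parse error at line ", ln,
                     ": variableStep needs position and value")
            pos <- suppressWarnings(as.integer(f[1L]))
            v <- suppressWarnings(as.numeric(f[2L]))
            if (is.na(pos) || is.na(v))
                stop("wiggle parse error at line ", ln, ": non-numeric field")
            s0 <- pos - 1L
            if (s0 <= last_start)
                stop("wiggle parse error at line ", ln,
                     ": non-monotone position within block")
            last_start <- s0
            chrom <- c(chrom, cur_chrom)
            start <- c(start, s0)
            end <- c(end, s0 + span)
            value <- c(value, v)
        }
    }
    finalize_track_intervals(name, chrom, start, end, value)
}

#' Serialize a signal track as bedGraph text
#'
#' Values are written with enough digits (`%.17g`) that
#' `parse_bedgraph(write_bedgraph(x))` reproduces the track exactly.
#'
#' @param track a `signal_track`.
#' @return character vector of bedGraph lines.
#' @export
write_bedgraph <- function(track) {
    stopifnot(inherits(track, "signal_track"))
    unlist(lapply(names(track$data), function(ch) {
        d <- track$data[[ch]]
        sprintf("%s\t%d\t%d\t%.17g", ch, d$start, d$end, d$value)
    }), use.names = FALSE)
}

#' Extract a binned multi-track profile from signal tracks
#'
#' The window is divided into `L = floor((end - start)/bin_size)` bins. Each
#' bin takes the interval-weighted mean of the signal defined within it; bins
#' with no defined signal are filled by linear interpolation between the
#' nearest flanking defined bins of the same track, and leading/trailing gaps
#' are filled by the nearest defined value (constant extrapolation — linear
#' interpolation needs two anchors). A track with no defined signal anywhere
#' in the window (including a chromosome absent from the track) yields an
#' all-zero row. Missing-value handling ends here: profiles are dense.
#'
#' @param tracks list of `signal_track`s.
#' @param region one row of a [parse_bed()] data.frame, or any list with
#'   `chrom`, `start`, `end` (0-based half-open) and optionally `name`.
#' @param bin_size bin width in bp; must not exceed the region length.
#' @return a `signal_profile` with one row per track, `weight = 1` and
#'   coverage 1 at every bin.
#' @export
extract_profile <- function(tracks, region, bin_size) {
    bin_size <- as.integer(bin_size)
    if (is.na(bin_size) || bin_size < 1L)
        stop("`bin_size` must be an integer >= 1")
    rs <- as.integer(region$start)
    re <- as.integer(region$end)
    if (re - rs < bin_size)
        stop("bin_size (", bin_size, ") exceeds region length (", re - rs, ")")
    L <- (re - rs) %/% bin_size
    vals <- matrix(0, nrow = length(tracks), ncol = L)
    for (t in seq_along(tracks)) {
        tr <- tracks[[t]]
        stopifnot(inherits(tr, "signal_track"))
        d <- tr$data[[as.character(region$chrom)]]
        binned <- rep(NA_real_, L)
        if (!is.null(d) && nrow(d) > 0L) {
            sums <- numeric(L)
            lens <- numeric(L)
            # clip intervals to the binned part of the window
            win_end <- rs + L * bin_size
            sel <- d$end > rs & d$start < win_end
            d <- d[sel, , drop = FALSE]
            for (k in seq_len(nrow(d))) {
                s <- max(d$start[k], rs) - rs
                e <- min(d$end[k], win_end) - rs
                b0 <- s %/% bin_size          # first bin touched, 0-based
                b1 <- (e - 1L) %/% bin_size   # last bin touched
                for (b in b0:b1) {
                    lo <- max(s, b * bin_size)
                    hi <- min(e, (b + 1L) * bin_size)
                    sums[b + 1L] <- sums[b + 1L] + d$value[k] * (hi - lo)
                    lens[b + 1L] <- lens[b + 1L] + (hi - lo)
                }
            }
            def <- lens > 0
            binned[def] <- sums[def] / lens[def]
        }
        def <- which(!is.na(binned))
        if (length(def) == 0L) {
            vals[t, ] <- 0
        } else if (length(def) == L) {
            vals[t, ] <- binned
        } else if (length(def) == 1L) {
            vals[t, ] <- binned[def]
        } else {
            # rule = 2: constant extrapolation beyond the outermost anchors
            vals[t, ] <- approx(def, binned[def], xout = seq_len(L),
                                rule = 2)$y
        }
    }
    nm <- if (!is.null(region$name) && !is.na(region$name)) region$name
          else sprintf("%s:%d-%d", region$chrom, rs, re)
    signal_profile(vals, id = nm, bin_size = bin_size,
                   track_names = vapply(tracks, function(x) x$name, character(1L)))
}

#' Extract profiles for every region of a BED data.frame
#'
#' @param tracks list of `signal_track`s.
#' @param regions data.frame as returned by [parse_bed()].
#' @param bin_size bin width in bp.
#' @return list of `signal_profile`s, one per region, in region order.
#' @export
extract_profiles <- function(tracks, regions, bin_size) {
    lapply(seq_len(nrow(regions)), function(i)
        extract_profile(tracks, regions[i, ], bin_size))
}

#' Export a cluster node as plain text
#'
#' Produces the two standard exports for a cluster: the average (pruned)
#' profile pattern as TSV (one row per bin, one column per track, plus the
#' per-bin coverage), and the member list as BED, with each leaf's
#' orientation in the cluster frame in the strand column and its bin offset
#' in the score column.
#'
#' @param node a `cluster_node`.
#' @param regions optional data.frame from [parse_bed()] keyed by the `name`
#'   column; leaves without a matching region are written on chromosome `.`
#'   with coordinates 0..1.
#' @return list with `profile_tsv` and `members_bed`, each a character vector
#'   of lines.
#' @export
write_cluster_exports <- function(node, regions = NULL) {
    stopifnot(inherits(node, "cluster_node"))
    p <- node$representative
    header <- paste(c("bin", p$track_names, "coverage"), collapse = "\t")
    rows <- vapply(seq_len(profile_length(p)), function(i)
        paste(c(i, sprintf("%.10g", p$values[, i]), p$coverage[i]),
              collapse = "\t"), character(1L))
    profile_tsv <- c(header, rows)
    pl <- node$placements
    bed <- vapply(seq_len(nrow(pl)), function(i) {
        id <- pl$leaf_id[i]
        strand <- if (pl$mirrored[i]) "-" else "+"
        if (!is.null(regions) && id %in% regions$name) {
            rg <- regions[match(id, regions$name), ]
            sprintf("%s\t%d\t%d\t%s\t%d\t%s", rg$chrom, rg$start, rg$end,
                    id, pl$offset[i], strand)
        } else {
            sprintf(".\t0\t1\t%s\t%d\t%s", id, pl$offset[i], strand)
        }
    }, character(1L))
    list(profile_tsv = profile_tsv, members_bed = bed)
}

#' Write a list of profiles in the long TSV layout
#'
#' The layout (also accepted by the CLI as pre-binned input) is a
#' tab-separated table with header `profile_id  track  bin  value`; bins are
#' 1-based consecutive integers per profile and track.
#'
#' @param profiles list of `signal_profile`s.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("profile_id\ttrack\tbin\tvalue", con)
    for (p in profiles) {
        for (t in seq_along(p$track_names)) {
            writeLines(sprintf("%s\t%s\t%d\t%.17g", p$id, p$track_names[t],
                               seq_len(profile_length(p)), p$values[t, ]), con)
        }
    }
    invisible(path)
}

#' Read profiles from the long TSV layout
#'
#' @param path file written by [write_profiles_tsv()] (or any table with
#'   columns `profile_id`, `track`, `bin`, `value`).
#' @param bin_size bin width in bp recorded on the profiles (default 1).
#' @return list of `signal_profile`s in first-appearance order.
#' @export
read_profiles_tsv <- function(path, bin_size = 1L) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("profile_id", "track", "bin", "value")
    if (!all(need %in% names(df)))
        stop("profiles TSV must have columns: ", paste(need, collapse = ", "))
    ids <- unique(df$profile_id)
    lapply(ids, function(id) {
        d <- df[df$profile_id == id, , drop = FALSE]
        tracks <- unique(d$track)
        L <- max(d$bin)
        vals <- matrix(NA_real_, nrow = length(tracks), ncol = L,
                       dimnames = list(tracks, NULL))
        for (t in tracks) {
            dt <- d[d$track == t, , drop = FALSE]
            vals[t, dt$bin] <- dt$value
        }
        if (anyNA(vals))
            stop("profile '", id, "' has missing bins in the TSV")
        signal_profile(vals, id = id, bin_size = bin_size,
                       track_names = tracks)
    })
}
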