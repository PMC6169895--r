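# Strand-aware TSS-centred profiles and length-scaled CGI profiles.
# Fragment input is converted to per-bp coverage first: midpoint coverage
# for nucleosome-centric signals, full-fragment coverage for accessibility.

# Per-bp coverage of a window [start, end) from a fragment set.
window_coverage <- function(fragments, chrom, start, end,
                            coverage = c("midpoint", "fragment")) {
  coverage <- match.arg(coverage)
  L <- end - start
  v <- numeric(L)
  r <- fragments$records
  r <- r[r$chrom == chrom, , drop = FALSE]
  if (nrow(r) == 0) return(v)
  if (coverage == "midpoint") {
    m <- r$midpoint[r$midpoint >= start & r$midpoint < end]
    if (length(m) > 0) v <- tabulate(m - start + 1L, nbins = L)
  } else {
    keep <- r$end > start & r$start < end
    r <- r[keep, , drop = FALSE]
    if (nrow(r) > 0) {
      # difference-array accumulation of clipped fragment bodies
      d <- numeric(L + 1L)
      s <- pmax(r$start, start) - start + 1L
      e <- pmin(r$end, end) - start
      for (i in seq_along(s)) {
        d[s[i]] <- d[s[i]] + 1
        d[e[i] + 1L] <- d[e[i] + 1L] - 1
      }
      v <- cumsum(d)[seq_len(L)]
    }
  }
  as.numeric(v)
}

# Extract the window [start, end) from a bp_track, zero-padding outside the
# track's region. Returns list(values, n_padded).
track_window <- function(track, chrom, start, end) {
  L <- end - start
  v <- numeric(L)
  padded <- FALSE
  if (chrom == track$chrom) {
    lo <- max(start, track$start); hi <- min(end, track$end)
    if (hi > lo) {
      v[(lo - start + 1L):(hi - start)] <-
        track$values[(lo - track$start + 1L):(hi - track$start)]
    }
    padded <- lo > start || hi < end
  } else {
    padded <- TRUE
  }
  list(values = v, padded = padded)
}

new_meta_profile <- function(axis, mean_signal, n_regions, signal_name,
                             axis_name = "offset") {
  structure(data.frame(axis, mean_signal = mean_signal,
                       stringsAsFactors = FALSE) |>
              stats::setNames(c(axis_name, "mean_signal")),
            n_regions = n_regions, signal_name = signal_name,
            class = c("meta_profile", "data.frame"))
}

#' TSS-centred metaplot
#'
#' Extracts the signal over `[tss - half_window, tss + half_window)` for
#' every promoter, reverses minus-strand windows so that downstream always
#' points right, and averages across promoters (regions with zero coverage
#' contribute zeros). Windows extending past the available region are
#' zero-padded and counted.
#'
#' @param x A [fragment_set()] or a [bp_track()] covering the promoters'
#'   chromosome.
#' @param promoters data.frame with `chrom`, `tss`, `strand` (e.g. a TSS
#'   table or promoter table with a `tss` column).
#' @param half_window Half-width of the profile in bp (default 2000).
#' @param bin_size Averaging bin width in bp (default 1).
#' @param coverage For fragment input: `"midpoint"` (nucleosome signals) or
#'   `"fragment"` (accessibility; full-fragment coverage).
#' @param signal_name Label stored on the profile.
#' @return A `meta_profile` data.frame with columns `offset` (bin centre
#'   relative to the TSS) and `mean_signal`; attributes `n_regions`,
#'   `signal_name`.
#' @export
tss_metaplot <- function(x, promoters, half_window = 2000, bin_size = 1,
                         coverage = c("midpoint", "fragment"),
                         signal_name = "signal") {
  coverage <- match.arg(coverage)
  stopifnot(half_window >= 1, bin_size >= 1)
  hw <- as.integer(half_window)
  n <- nrow(promoters)
  stopifnot(n > 0)
  acc <- numeric(2L * hw)
  n_padded <- 0L
  for (i in seq_len(n)) {
    s <- promoters$tss[i] - hw
    e <- promoters$tss[i] + hw
    if (inherits(x, "fragment_set")) {
      v <- window_coverage(x, promoters$chrom[i], max(0L, s), e, coverage)
      if (s < 0) { v <- c(numeric(-s), v); n_padded <- n_padded + 1L }
    } else if (inherits(x, "bp_track")) {
      tw <- track_window(x, promoters$chrom[i], s, e)
      v <- tw$values
      if (tw$padded) n_padded <- n_padded + 1L
    } else {
      stop("x must be a fragment_set or bp_track")
    }
    if (identical(promoters$strand[i], "-")) v <- rev(v)
    acc <- acc + v
  }
  if (n_padded > 0) {
    message(sprintf("tss_metaplot: %d window(s) zero-padded at region edges",
                    n_padded))
  }
  mean_sig <- acc / n
  offsets <- seq.int(-hw, hw - 1L)
  if (bin_size > 1) {
    g <- (seq_along(mean_sig) - 1L) %/% as.integer(bin_size)
    mean_sig <- as.numeric(tapply(mean_sig, g, mean))
    offsets <- as.numeric(tapply(offsets, g, mean))
  }
  new_meta_profile(offsets, mean_sig, n, signal_name)
}

# Resample a per-bp signal to `nbins` values: mean pooling when the signal
# is at least nbins long, linear interpolation otherwise.
resample_signal <- function(v, nbins) {
  L <- length(v)
  if (L == nbins) return(as.numeric(v))
  if (L > nbins) {
    g <- ceiling(seq_len(L) * nbins / L)
    return(as.numeric(tapply(v, g, mean)))
  }
  approx(seq_len(L), v, n = nbins)$y
}

#' Length-scaled CGI metaplot
#'
#' Each CGI body is resampled to `body_bins` bins (mean pooling; linear
#' interpolation for CGIs shorter than `body_bins`); flanks of
#' `flank_fraction` times the CGI length on each side are resampled to
#' `flank_bins` bins each. Profiles are averaged across CGIs, so CGIs of
#' different lengths contribute on a common axis.
#'
#' @param x A [fragment_set()] or [bp_track()].
#' @param cgi_intervals Interval data.frame of CGIs.
#' @param flank_fraction Flank length as a fraction of the CGI length
#'   (default 0.2).
#' @param body_bins,flank_bins Bin counts (defaults 100 and 20).
#' @param coverage Coverage mode for fragment input (see [tss_metaplot()]).
#' @param signal_name Label stored on the profile.
#' @return A `meta_profile` data.frame with columns `bin` (1-based index
#'   across left flank, body, right flank), `region` (`"flank5"`,
#'   `"body"`, `"flank3"`) and `mean_signal`.
#' @export
scaled_cgi_metaplot <- function(x, cgi_intervals, flank_fraction = 0.2,
                                body_bins = 100L, flank_bins = 20L,
                                coverage = c("midpoint", "fragment"),
                                signal_name = "signal") {
  coverage <- match.arg(coverage)
  check_interval_df(cgi_intervals, "cgi_intervals")
  n <- nrow(cgi_intervals)
  stopifnot(n > 0, flank_fraction >= 0, body_bins >= 1, flank_bins >= 0)
  total_bins <- body_bins + 2L * flank_bins
  acc <- numeric(total_bins)
  for (i in seq_len(n)) {
    len <- cgi_intervals$end[i] - cgi_intervals$start[i]
    f <- as.integer(round(flank_fraction * len))
    s <- cgi_intervals$start[i] - f
    e <- cgi_intervals$end[i] + f
    if (inherits(x, "fragment_set")) {
      v <- window_coverage(x, cgi_intervals$chrom[i], max(0L, s), e,
                           coverage)
      if (s < 0) v <- c(numeric(-s), v)
    } else if (inherits(x, "bp_track")) {
      v <- track_window(x, cgi_intervals$chrom[i], s, e)$values
    } else {
      stop("x must be a fragment_set or bp_track")
    }
    left <- if (f > 0) v[seq_len(f)] else numeric(0)
    body <- v[(f + 1L):(f + len)]
    right <- if (f > 0) v[(f + len + 1L):(f + len + f)] else numeric(0)
    prof <- c(if (flank_bins > 0) resample_signal(left, flank_bins),
              resample_signal(body, body_bins),
              if (flank_bins > 0) resample_signal(right, flank_bins))
    acc <- acc + prof
  }
  region <- c(rep("flank5", flank_bins), rep("body", body_bins),
              rep("flank3", flank_bins))
  out <- new_meta_profile(seq_len(total_bins), acc / n, n, signal_name,
                          axis_name = "bin")
  out$region <- region
  out
}

#' Local maxima of a metaplot profile and their spacings
#'
#' Applies the same maxima rule as [call_nucleosomes()] (strict local
#' maxima, leftmost bp of plateaus, greedy descending-value acceptance with
#' a minimum separation) to the mean profile, returning the average
#' nucleosome positions and the distances between consecutive positions --
#' the profile-level nucleosome repeat readout.
#'
#' @param profile A `meta_profile` (from [tss_metaplot()] or
#'   [scaled_cgi_metaplot()]).
#' @param min_separation_bins Minimum separation between accepted maxima,
#'   in axis units (default 1).
#' @param min_score Minimum profile value for a candidate (default
#'   `-Inf`, i.e. no filter).
#' @return List with `positions` (axis values of accepted maxima, sorted)
#'   and `distances` (consecutive differences).
#' @export
profile_maxima <- function(profile, min_separation_bins = 1,
                           min_score = -Inf) {
  v <- profile$mean_signal
  stopifnot(all(is.finite(v)))
  axis <- profile[[1]]
  idx <- local_maxima(v)
  idx <- idx[v[idx] >= min_score]
  if (length(idx) == 0) {
    return(list(positions = numeric(0), distances = numeric(0)))
  }
  ord <- order(-v[idx], axis[idx])
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) == 0 ||
        min(abs(axis[idx[accepted]] - axis[idx[i]])) >= min_separation_bins) {
      accepted <- c(accepted, i)
    }
  }
  pos <- sort(axis[idx[accepted]])
  list(positions = pos, distances = diff(pos))
}

#' Write a metaplot profile as TSV
#'
#' @param profile A `meta_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  df$n_regions <- attr(profile, "n_regions")
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
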