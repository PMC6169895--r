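# Kernel-density surrogate for the nucleosome-occupancy stage: mono-fragment
# midpoints are smoothed with a truncated Gaussian kernel; occupancy is the
# mono share of the all-fragment density; dyads are local maxima of the
# occupancy signal.

#' Per-bp track constructor
#'
#' A `bp_track` stores a per-bp numeric signal over a 0-based half-open
#' region; `values[i]` belongs to genomic position `start + i - 1`.
#'
#' @param chrom Chromosome name.
#' @param start,end Region bounds (0-based half-open).
#' @param values Numeric vector of length `end - start`.
#' @param bandwidth_sd Kernel standard deviation used to build the track
#'   (bp), when applicable.
#' @return A `bp_track` object.
#' @export
bp_track <- function(chrom, start, end, values, bandwidth_sd = NA_real_) {
  stopifnot(end > start, length(values) == end - start)
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), values = as.numeric(values),
                 bandwidth_sd = bandwidth_sd),
            class = "bp_track")
}

#' @export
print.bp_track <- function(x, ...) {
  cat(sprintf("<bp_track %s:%d-%d (%d bp), range [%.4g, %.4g]>\n",
              x$chrom, x$start, x$end, x$end - x$start,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Kernel density of fragment midpoints (dyad density)
#'
#' Each fragment contributes a unit-mass Gaussian kernel centred at its
#' midpoint (sd = `bandwidth_sd`, truncated at +/- 3 sd and renormalised to
#' mass exactly 1), evaluated at every bp of the region. Fragments whose
#' midpoints lie within 3 sd outside the region still contribute their
#' overlapping kernel tail. For mononucleosomal fragments the midpoint
#' estimates the nucleosome dyad, so this density is a dyad-centre density.
#'
#' @param fragments A [fragment_set()] (typically the `mono` class from
#'   [split_by_size()]; pass the full set to build the all-fragment
#'   denominator for [occupancy_track()]).
#' @param region One-row data.frame/list with `chrom`, `start`, `end`.
#' @param bandwidth_sd Kernel sd in bp (default 20).
#' @return A [bp_track()] whose values integrate (per bp) to the number of
#'   contributing interior fragments.
#' @export
dyad_density <- function(fragments, region, bandwidth_sd = 20) {
  stopifnot(inherits(fragments, "fragment_set"), bandwidth_sd > 0)
  start <- as.integer(region$start); end <- as.integer(region$end)
  stopifnot(end > start)
  L <- end - start
  W <- as.integer(ceiling(3 * bandwidth_sd))
  kern <- dnorm(seq.int(-W, W), mean = 0, sd = bandwidth_sd)
  kern <- kern / sum(kern)

  r <- fragments$records
  sel <- r$chrom == region$chrom &
    r$midpoint >= start - W & r$midpoint < end + W
  mids <- r$midpoint[sel]
  if (length(mids) == 0) {
    return(bp_track(region$chrom, start, end, numeric(L), bandwidth_sd))
  }
  # counts over the padded region, then centred moving-window convolution
  counts <- tabulate(mids - (start - W) + 1L, nbins = L + 2L * W)
  sm <- stats::filter(c(numeric(W), counts, numeric(W)), kern, sides = 2)
  vals <- as.numeric(sm[(2L * W + 1L):(2L * W + L)])
  bp_track(region$chrom, start, end, vals, bandwidth_sd)
}

#' Nucleosome occupancy track
#'
#' Occupancy at each bp is the mononucleosomal share of the total fragment
#' density: `mono / (all + epsilon)`, clipped to `[0, 1]`. Positions with
#' no fragment density score 0. Both tracks must cover the same region and
#' use the same bandwidth.
#'
#' @param mono_density [dyad_density()] of mononucleosomal fragments.
#' @param all_density [dyad_density()] of all fragments (every size).
#' @param epsilon Pseudo-density stabilising empty positions (default 1e-3,
#'   in per-bp density units).
#' @return A [bp_track()] with values in `[0, 1]`.
#' @export
occupancy_track <- function(mono_density, all_density, epsilon = 1e-3) {
  stopifnot(inherits(mono_density, "bp_track"),
            inherits(all_density, "bp_track"))
  if (mono_density$chrom != all_density$chrom ||
      mono_density$start != all_density$start ||
      mono_density$end != all_density$end) {
    stop("occupancy_track: mono and all density regions differ")
  }
  if (!isTRUE(all.equal(mono_density$bandwidth_sd,
                        all_density$bandwidth_sd))) {
    stop("occupancy_track: mono and all density bandwidths differ")
  }
  occ <- mono_density$values / (all_density$values + epsilon)
  occ <- pmin(1, pmax(0, occ))
  bp_track(mono_density$chrom, mono_density$start, mono_density$end, occ,
           mono_density$bandwidth_sd)
}

# Strict local maxima of a numeric vector, treating a plateau higher than
# both neighbours as a single maximum at its leftmost index. Boundary runs
# are not maxima. Returns integer indices.
local_maxima <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  is_max <- c(FALSE, r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                r$values[2:(k - 1)] > r$values[3:k], FALSE)
  starts[is_max]
}

#' Call nucleosome dyad positions from a signal track
#'
#' Candidate dyads are strict local maxima of the track with value at least
#' `min_score` (plateaus take their leftmost bp). Candidates are accepted
#' greedily in descending value order (ties broken by leftmost position)
#' subject to every accepted pair being at least `min_separation` bp apart,
#' so two overlapping nucleosomes are never called.
#'
#' @param track A [bp_track()] (typically an [occupancy_track()]).
#' @param min_separation Minimum distance between accepted dyads (bp,
#'   default 120).
#' @param min_score Minimum track value for a candidate (default 0.1).
#' @return data.frame: `chrom`, `dyad`, `occ_score`; zero rows when no
#'   maximum qualifies.
#' @export
call_nucleosomes <- function(track, min_separation = 120, min_score = 0.1) {
  stopifnot(inherits(track, "bp_track"), all(is.finite(track$values)))
  idx <- local_maxima(track$values)
  idx <- idx[track$values[idx] >= min_score]
  empty <- data.frame(chrom = character(), dyad = integer(),
                      occ_score = numeric())
  if (length(idx) == 0) return(empty)
  pos <- track$start + idx - 1L
  val <- track$values[idx]
  ord <- order(-val, pos)
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) == 0 ||
        min(abs(pos[accepted] - pos[i])) >= min_separation) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- accepted[order(pos[accepted])]
  data.frame(chrom = track$chrom, dyad = pos[accepted],
             occ_score = val[accepted], stringsAsFactors = FALSE)
}

#' Positional fuzziness of a called nucleosome
#'
#' Population standard deviation of mononucleosomal-fragment midpoints
#' falling within `dyad +/- half_window`. Low values indicate a
#' well-positioned nucleosome. With fewer than two midpoints the score is
#' missing.
#'
#' @param dyad Dyad position (bp).
#' @param mono_fragments [fragment_set()] of mononucleosomal fragments on
#'   the dyad's chromosome.
#' @param half_window Window half-width (default 73 bp, the nucleosome
#'   half-footprint).
#' @param chrom Chromosome of the dyad; defaults to the only chromosome in
#'   `mono_fragments`.
#' @return Fuzziness in bp, or `NA_real_`.
#' @export
fuzziness <- function(dyad, mono_fragments, half_window = 73,
                      chrom = NULL) {
  stopifnot(inherits(mono_fragments, "fragment_set"))
  r <- mono_fragments$records
  if (!is.null(chrom)) r <- r[r$chrom == chrom, , drop = FALSE]
  m <- r$midpoint[r$midpoint >= dyad - half_window &
                    r$midpoint <= dyad + half_window]
  if (length(m) < 2) return(NA_real_)
  sqrt(mean((m - mean(m))^2))
}

#' Annotate nucleosome calls with fuzziness and supporting-fragment counts
#'
#' @param calls Output of [call_nucleosomes()].
#' @param mono_fragments [fragment_set()] of mononucleosomal fragments.
#' @param half_window Window half-width for fuzziness (default 73 bp).
#' @return `calls` with added columns `fuzziness` and `n_fragments`.
#' @export
annotate_calls <- function(calls, mono_fragments, half_window = 73) {
  stopifnot(inherits(mono_fragments, "fragment_set"))
  if (nrow(calls) == 0) {
    calls$fuzziness <- numeric(0)
    calls$n_fragments <- integer(0)
    return(calls)
  }
  r <- mono_fragments$records
  calls$fuzziness <- NA_real_
  calls$n_fragments <- 0L
  for (i in seq_len(nrow(calls))) {
    m <- r$midpoint[r$chrom == calls$chrom[i] &
                      r$midpoint >= calls$dyad[i] - half_window &
                      r$midpoint <= calls$dyad[i] + half_window]
    calls$n_fragments[i] <- length(m)
    if (length(m) >= 2) calls$fuzziness[i] <- sqrt(mean((m - mean(m))^2))
  }
  calls
}

#' Summed occupancy per kilobase over an interval
#'
#' Sum of per-bp occupancy values across the interval divided by the
#' interval length in kb -- the coverage-style per-promoter occupancy
#' statistic.
#'
#' @param occ_track An [occupancy_track()] (any [bp_track()] works).
#' @param interval One-row data.frame/list with `chrom`, `start`, `end`;
#'   must lie within the track region.
#' @return Occupancy per kb (numeric).
#' @export
occupancy_per_kb <- function(occ_track, interval) {
  stopifnot(inherits(occ_track, "bp_track"))
  len <- interval$end - interval$start
  if (len <= 0) stop("zero-length interval")
  if (interval$chrom != occ_track$chrom ||
      interval$start < occ_track$start || interval$end > occ_track$end) {
    stop("interval outside track region")
  }
  i0 <- interval$start - occ_track$start + 1L
  sum(occ_track$values[i0:(i0 + len - 1L)]) / (len / 1000)
}

#' Write a per-bp track as bedGraph
#'
#' Runs of equal value are merged into one line; zero-valued runs are kept
#' so the file round-trips losslessly over its region.
#'
#' @param track A [bp_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "bp_track"))
  r <- rle(track$values)
  ends <- track$start + cumsum(r$lengths)
  starts <- c(track$start, head(ends, -1L))
  data.table::fwrite(data.frame(chrom = track$chrom, start = starts,
                                end = ends, value = signif(r$values, 10)),
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()] into a per-bp track
#'
#' @param path Path to the bedGraph file.
#' @return A [bp_track()] spanning the file's covered range (gaps filled
#'   with 0).
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (length(unique(dt[[1]])) != 1) {
    stop("read_bedgraph supports single-chromosome tracks")
  }
  start <- min(dt[[2]]); end <- max(dt[[3]])
  vals <- numeric(end - start)
  for (i in seq_len(nrow(dt))) {
    vals[(dt[i, 2] - start + 1L):(dt[i, 3] - start)] <- dt[i, 4]
  }
  bp_track(dt[1, 1], start, end, vals)
}

#' Write nucleosome calls as BED6+2
#'
#' Columns: chrom, dyad, dyad + 1, call id, occupancy score, strand (`.`),
#' fuzziness, supporting mono-fragment count.
#'
#' @param calls Output of [annotate_calls()].
#' @param path Output path.
#' @export
write_nucleosome_calls <- function(calls, path) {
  df <- data.frame(chrom = calls$chrom, start = calls$dyad,
                   end = calls$dyad + 1L,
                   name = sprintf("nuc_%d", seq_len(nrow(calls))),
                   score = signif(calls$occ_score, 6), strand = ".",
                   fuzziness = signif(calls$fuzziness %||% NA_real_, 6),
                   n_fragments = calls$n_fragments %||% NA_integer_)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
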