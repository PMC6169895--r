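#' Construct a fragment set
#'
#' A fragment set holds sequenced-fragment coordinates (0-based half-open)
#' together with the post-filtering library size used for RPKM
#' normalisation. Fragment size is `end - start`; the midpoint is
#' `floor((start + end) / 2)` so that positions stay integral.
#'
#' @param records data.frame with columns `chrom`, `start`, `end` (extra
#'   columns are kept).
#' @param sample_id Character label for the library.
#' @return An object of class `fragment_set` with elements `records`,
#'   `library_size`, `sample_id`.
#' @export
fragment_set <- function(records, sample_id = "sample") {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    records <- data.frame(chrom = character(), start = integer(),
                          end = integer(), size = integer(),
                          midpoint = integer())
  } else {
    check_interval_df(records, "fragment records")
    records$size <- as.integer(records$end - records$start)
    records$midpoint <- as.integer((records$start + records$end) %/% 2L)
  }
  structure(list(records = records,
                 library_size = nrow(records),
                 sample_id = sample_id),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set '%s': %d fragments", x$sample_id,
              x$library_size))
  if (x$library_size > 0) {
    cat(sprintf(", sizes %d-%d bp", min(x$records$size), max(x$records$size)))
  }
  cat(">\n")
  invisible(x)
}

#' Read fragments from a BED-like file
#'
#' Parses tab-separated `chrom`, `start`, `end` (additional columns are
#' ignored; gzip input is supported). Malformed lines -- non-numeric
#' coordinates, `end <= start`, or negative `start` -- are skipped; their
#' count is reported in a message and stored in the `n_malformed` attribute.
#'
#' @param path Path to the fragment file.
#' @param sample_id Library label; defaults to the file name.
#' @return A [fragment_set()].
#' @export
read_fragments <- function(path, sample_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gz$", path)) {
    # base-R gzip path; fread's own gz support needs an extra package
    lines <- readLines(gzfile(path))
    dt <- if (length(lines) == 0) data.frame() else
      data.table::fread(text = lines, header = FALSE, sep = "\t",
                        fill = TRUE, colClasses = list(character = 1),
                        data.table = FALSE)
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                            colClasses = list(character = 1),
                            data.table = FALSE)
  }
  if (nrow(dt) == 0) {
    fs <- fragment_set(data.frame(chrom = character(), start = integer(),
                                  end = integer()), sample_id)
    attr(fs, "n_malformed") <- 0L
    return(fs)
  }
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  ok <- !is.na(start) & !is.na(end) & start >= 0 & end > start
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(sprintf("read_fragments: skipped %d malformed line(s) in %s",
                    n_bad, path))
  }
  fs <- fragment_set(data.frame(chrom = as.character(dt[[1]])[ok],
                                start = start[ok], end = end[ok],
                                stringsAsFactors = FALSE),
                     sample_id)
  attr(fs, "n_malformed") <- n_bad
  fs
}

#' Write a fragment set as BED3
#'
#' @param fragments A [fragment_set()].
#' @param path Output path (`.gz` suffix triggers compression).
#' @export
write_fragments <- function(fragments, path) {
  stopifnot(inherits(fragments, "fragment_set"))
  data.table::fwrite(fragments$records[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE, quote = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Remove coordinate-duplicate fragments
#'
#' Collapses PCR duplicates by keeping at most one record per
#' `(chrom, start, end)` triple (the first in file order).
#'
#' @param fragments A [fragment_set()].
#' @return A deduplicated [fragment_set()].
#' @export
deduplicate <- function(fragments) {
  stopifnot(inherits(fragments, "fragment_set"))
  r <- fragments$records
  keep <- !duplicated(r[, c("chrom", "start", "end")])
  fragment_set(r[keep, , drop = FALSE], fragments$sample_id)
}

#' Remove fragments whose midpoint lies in a blacklist region
#'
#' @param fragments A [fragment_set()].
#' @param blacklist Interval data.frame of artefact regions (BED
#'   convention); `NULL` or empty leaves the set unchanged.
#' @return Filtered [fragment_set()].
#' @export
filter_blacklist <- function(fragments, blacklist) {
  stopifnot(inherits(fragments, "fragment_set"))
  if (is.null(blacklist) || nrow(blacklist) == 0 ||
      nrow(fragments$records) == 0) {
    return(fragment_set(fragments$records, fragments$sample_id))
  }
  check_interval_df(blacklist, "blacklist")
  r <- fragments$records
  mid_gr <- GenomicRanges::GRanges(r$chrom,
                                   IRanges::IRanges(r$midpoint + 1L,
                                                    r$midpoint + 1L))
  inside <- GenomicRanges::countOverlaps(mid_gr, as_granges0(blacklist)) > 0
  fragment_set(r[!inside, , drop = FALSE], fragments$sample_id)
}

#' Randomly downsample a fragment set
#'
#' Uniform sampling without replacement to `min(n, library_size)` records;
#' the same seed always yields the same subset. Used to equalise replicate
#' depths before merging.
#'
#' @param fragments A [fragment_set()].
#' @param n Target number of fragments (`n >= 0`).
#' @param seed Integer seed.
#' @return Downsampled [fragment_set()] (records keep their input order).
#' @export
downsample <- function(fragments, n, seed) {
  stopifnot(inherits(fragments, "fragment_set"), n >= 0)
  total <- nrow(fragments$records)
  k <- min(as.integer(n), total)
  idx <- if (k == total) seq_len(total) else
    with_seed(seed, sort(sample.int(total, k)))
  fragment_set(fragments$records[idx, , drop = FALSE], fragments$sample_id)
}

#' Fragment size-class configuration
#'
#' Bounds for splitting fragments into nucleosome-free (short) and
#' mononucleosomal (long) pools. Defaults follow the tagmentation
#' periodicity convention: fragments shorter than 120 bp are
#' sub-nucleosomal ("nucleosome-free"), 150-250 bp fragments span one
#' nucleosome; the 120-149 bp and >250 bp bands are assigned to neither
#' class but stay in the parent set for whole-set metrics such as the
#' median fragment size.
#'
#' @param nfr_max Exclusive upper bound of the nucleosome-free class (bp).
#' @param mono_min,mono_max Inclusive bounds of the mononucleosomal class.
#' @return A `size_class_config` list.
#' @export
size_class_config <- function(nfr_max = 120L, mono_min = 150L,
                              mono_max = 250L) {
  if (!(nfr_max <= mono_min)) stop("nfr_max must be <= mono_min")
  if (!(mono_min < mono_max)) stop("mono_min must be < mono_max")
  structure(list(nfr_max = as.integer(nfr_max),
                 mono_min = as.integer(mono_min),
                 mono_max = as.integer(mono_max)),
            class = "size_class_config")
}

#' Split fragments into nucleosome-free and mononucleosomal classes
#'
#' @param fragments A [fragment_set()].
#' @param config A [size_class_config()].
#' @return List with elements `nfr` and `mono`, each a [fragment_set()].
#' @export
split_by_size <- function(fragments, config = size_class_config()) {
  stopifnot(inherits(fragments, "fragment_set"),
            inherits(config, "size_class_config"))
  r <- fragments$records
  nfr <- r[r$size < config$nfr_max, , drop = FALSE]
  mono <- r[r$size >= config$mono_min & r$size <= config$mono_max, ,
            drop = FALSE]
  list(nfr = fragment_set(nfr, paste0(fragments$sample_id, ".nfr")),
       mono = fragment_set(mono, paste0(fragments$sample_id, ".mono")))
}
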