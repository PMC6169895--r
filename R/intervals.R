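#' Read a BED3/BED6 interval file
#'
#' Intervals are kept in the BED convention used throughout nucleoscape:
#' 0-based, half-open `[start, end)`. Columns beyond the sixth are ignored.
#'
#' @param path Path to a tab-separated BED file (may be gzip-compressed).
#' @return A data.frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          data.table = FALSE)
  if (nrow(dt) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  out <- data.frame(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(dt) >= 4) out$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) out$score <- dt[[5]]
  if (ncol(dt) >= 6) out$strand <- as.character(dt[[6]])
  check_interval_df(out, path)
  out
}

#' Write intervals as BED
#'
#' @param df Interval data.frame (`chrom`, `start`, `end`, optionally
#'   `name`, `score`, `strand`).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  check_interval_df(df)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  # BED requires a contiguous column prefix; fill gaps with placeholders
  if ("strand" %in% cols && !("score" %in% cols)) df$score <- 0L
  if (any(c("score", "strand") %in% cols) && !("name" %in% cols)) {
    df$name <- "."
  }
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  data.table::fwrite(df[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' Expects tab-separated columns `gene_id`, `chrom`, `tss`, `strand` (header
#' optional but recommended). TSS positions are 0-based.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, data.table = FALSE)
  if (!all(c("gene_id", "chrom", "tss", "strand") %in% names(dt))) {
    names(dt)[1:4] <- c("gene_id", "chrom", "tss", "strand")
  }
  out <- dt[, c("gene_id", "chrom", "tss", "strand")]
  out$gene_id <- as.character(out$gene_id)
  out$chrom <- as.character(out$chrom)
  out$tss <- as.integer(out$tss)
  out$strand <- as.character(out$strand)
  if (anyDuplicated(out$gene_id)) stop("duplicate gene_id in TSS table")
  out
}

#' Build promoter windows around TSSs
#'
#' Each window is `[tss - flank, tss + flank)`, clipped at zero (and at the
#' chromosome end when `chrom_lengths` is supplied). Windows are
#' strand-symmetric; the strand is carried through for later orientation of
#' metaplots.
#'
#' @param tss_table data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param flank Half-width in bp (default 500, giving the TSS +/- 500 bp
#'   promoter definition).
#' @param chrom_lengths Optional named integer vector of chromosome lengths
#'   used to validate chromosome names and clip windows.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
make_tss_windows <- function(tss_table, flank = 500L, chrom_lengths = NULL) {
  stopifnot(is.data.frame(tss_table))
  if (!is.numeric(flank) || length(flank) != 1L || flank <= 0) {
    stop("`flank` must be a single positive number")
  }
  flank <- as.integer(flank)
  bad <- tss_table$tss < 0 | is.na(tss_table$tss)
  if (!is.null(chrom_lengths)) {
    bad <- bad | !(tss_table$chrom %in% names(chrom_lengths))
  }
  if (any(bad)) {
    stop("invalid TSS records (negative position or unknown chromosome): ",
         paste(tss_table$gene_id[bad], collapse = ", "))
  }
  start <- pmax(0L, tss_table$tss - flank)
  end <- tss_table$tss + flank
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, as.integer(chrom_lengths[tss_table$chrom]))
  }
  data.frame(gene_id = tss_table$gene_id,
             chrom = tss_table$chrom,
             start = start,
             end = end,
             strand = tss_table$strand,
             tss = tss_table$tss,
             stringsAsFactors = FALSE)
}

#' Intersection length of two intervals
#'
#' Returns the number of shared base pairs between two 0-based half-open
#' intervals, or 0 when the chromosomes differ. Vectorised over both
#' arguments.
#'
#' @param a,b Interval data.frames (columns `chrom`, `start`, `end`).
#' @return Integer vector of intersection lengths.
#' @export
interval_overlap <- function(a, b) {
  check_interval_df(a, "a"); check_interval_df(b, "b")
  len <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  len[a$chrom != b$chrom] <- 0L
  as.integer(len)
}

#' Classify CGI promoters by Polycomb subunit peak overlap
#'
#' A promoter window is labelled `PcG` when it overlaps at least one peak
#' from each of two repressive-complex subunit ChIP peak sets (canonically a
#' PRC1 subunit such as RNF2 and a PRC2 subunit such as SUZ12) and overlaps
#' a CpG island; `nonPcG` when it overlaps a CGI but fails the dual-peak
#' condition; `excluded` when it overlaps no CGI. Overlap means at least one
#' shared base pair. A window overlapping several CGIs is assigned the CGI
#' with the largest intersection (ties broken by leftmost CGI start).
#'
#' @param tss_windows Output of [make_tss_windows()].
#' @param rnf2_peaks,suz12_peaks Peak interval data.frames (BED convention).
#' @param cgi_intervals CpG-island interval data.frame.
#' @param require_cgi When `FALSE`, the CGI restriction is disabled: windows
#'   are labelled `PcG`/`nonPcG` by the peak rule alone and the CGI columns
#'   record an overlap where one exists. Used by [cgi_fraction()] to report
#'   CGI co-occurrence before the restriction is applied.
#' @return A promoter table: `gene_id`, `chrom`, `window_start`,
#'   `window_end`, `strand`, `tss`, `cgi_chrom`, `cgi_start`, `cgi_end`,
#'   `label`.
#' @export
classify_promoters <- function(tss_windows, rnf2_peaks, suz12_peaks,
                               cgi_intervals, require_cgi = TRUE) {
  check_interval_df(tss_windows, "tss_windows")
  n <- nrow(tss_windows)
  win_gr <- as_granges0(tss_windows)

  overlaps_any <- function(peaks) {
    if (is.null(peaks) || nrow(peaks) == 0) return(rep(FALSE, n))
    check_interval_df(peaks, "peaks")
    GenomicRanges::countOverlaps(win_gr, as_granges0(peaks)) > 0
  }
  has_rnf2 <- overlaps_any(rnf2_peaks)
  has_suz12 <- overlaps_any(suz12_peaks)

  cgi_chrom <- rep(NA_character_, n)
  cgi_start <- rep(NA_integer_, n)
  cgi_end <- rep(NA_integer_, n)
  if (is.null(cgi_intervals) || nrow(cgi_intervals) == 0) {
    warning("empty CGI interval set: every promoter will be excluded")
  } else {
    check_interval_df(cgi_intervals, "cgi_intervals")
    hits <- GenomicRanges::findOverlaps(win_gr, as_granges0(cgi_intervals))
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- interval_overlap(
        tss_windows[qi, c("chrom", "start", "end")],
        cgi_intervals[si, c("chrom", "start", "end")])
      # largest intersection wins; ties -> leftmost CGI start
      ord <- order(qi, -ov, cgi_intervals$start[si])
      keep <- ord[!duplicated(qi[ord])]
      cgi_chrom[qi[keep]] <- cgi_intervals$chrom[si[keep]]
      cgi_start[qi[keep]] <- cgi_intervals$start[si[keep]]
      cgi_end[qi[keep]] <- cgi_intervals$end[si[keep]]
    }
  }
  has_cgi <- !is.na(cgi_start)

  label <- ifelse(has_rnf2 & has_suz12, "PcG", "nonPcG")
  if (require_cgi) label[!has_cgi] <- "excluded"

  data.frame(gene_id = tss_windows$gene_id,
             chrom = tss_windows$chrom,
             window_start = tss_windows$start,
             window_end = tss_windows$end,
             strand = tss_windows$strand,
             tss = tss_windows$tss %||% NA_integer_,
             cgi_chrom = cgi_chrom,
             cgi_start = cgi_start,
             cgi_end = cgi_end,
             label = label,
             stringsAsFactors = FALSE)
}

#' Percentage of promoters of a label that co-occur with a CGI
#'
#' Intended to be run on a classification produced with
#' `classify_promoters(..., require_cgi = FALSE)`, so that the reported
#' percentage measures CGI co-occurrence before the CGI restriction.
#'
#' @param promoter_table Output of [classify_promoters()].
#' @param label Label to summarise (`"PcG"` or `"nonPcG"`).
#' @return Percentage in `[0, 100]`, or `NA` when no promoter carries the
#'   label.
#' @export
cgi_fraction <- function(promoter_table, label) {
  rows <- promoter_table[promoter_table$label == label, , drop = FALSE]
  if (nrow(rows) == 0) return(NA_real_)
  100 * mean(!is.na(rows$cgi_start))
}

#' Nearest-neighbour distance for each point
#'
#' For each position, the distance to the closest other position in the
#' same set (the rule used for inter-dyad distances between called
#' nucleosome dyad centres). Distances are returned in the input order.
#'
#' @param points Numeric vector of bp positions on one chromosome.
#' @return Numeric vector of the same length; `numeric(0)` when fewer than
#'   two points are supplied.
#' @export
nearest_neighbor_distances <- function(points) {
  n <- length(points)
  if (n < 2) return(numeric(0))
  ord <- order(points)
  p <- points[ord]
  gaps <- diff(p)
  d <- pmin(c(Inf, gaps), c(gaps, Inf))
  out <- numeric(n)
  out[ord] <- d
  out
}

#' Write a promoter table as TSV
#'
#' @param promoter_table Output of [classify_promoters()].
#' @param path Output path.
#' @export
write_promoter_table <- function(promoter_table, path) {
  data.table::fwrite(promoter_table, path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a promoter table written by [write_promoter_table()]
#'
#' @param path Path to the TSV file.
#' @return Promoter table data.frame.
#' @export
read_promoter_table <- function(path) {
  data.table::fread(path, data.table = FALSE, na.strings = "NA")
}
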