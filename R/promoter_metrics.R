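# Fragments are assigned to an interval when their midpoint falls inside it
# (half-open), so each fragment counts toward at most one of a set of
# disjoint intervals.

assigned_sizes <- function(fragments, interval) {
  r <- fragments$records
  sel <- r$chrom == interval$chrom &
    r$midpoint >= interval$start & r$midpoint < interval$end
  r$size[sel]
}

#' Median fragment size within an interval
#'
#' The median size of fragments whose midpoint falls inside the interval.
#' Higher medians indicate a larger share of nucleosome-sized fragments,
#' lower medians a shift toward nucleosome-free DNA. With an even number of
#' fragments the mean of the two central order statistics is returned; with
#' no assigned fragments the result is `NA` (never silently 0).
#'
#' @param fragments A [fragment_set()].
#' @param interval One-row data.frame (or list) with `chrom`, `start`, `end`.
#' @return Median size in bp, or `NA_real_`.
#' @export
median_fragment_size <- function(fragments, interval) {
  stopifnot(inherits(fragments, "fragment_set"))
  sizes <- assigned_sizes(fragments, interval)
  if (length(sizes) == 0) return(NA_real_)
  as.numeric(median(sizes))
}

#' Fragments per kilobase per million (RPKM) within an interval
#'
#' `count / ((interval length in kb) * (library_size / 1e6))`, counting one
#' unit per fragment whose midpoint falls in the interval.
#'
#' @param fragments A [fragment_set()].
#' @param interval One-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param library_size Total post-filter fragment count of the library;
#'   defaults to the fragment set's own size.
#' @return RPKM (numeric, `>= 0`).
#' @export
rpkm <- function(fragments, interval, library_size = fragments$library_size) {
  stopifnot(inherits(fragments, "fragment_set"), library_size > 0)
  len <- interval$end - interval$start
  if (len <= 0) stop("zero-length interval")
  n <- length(assigned_sizes(fragments, interval))
  n / ((len / 1000) * (library_size / 1e6))
}

#' Per-promoter accessibility and fragment-size metrics
#'
#' Computes, for every promoter with a CGI (or for the promoter window when
#' `on = "window"`), the number of assigned fragments, their median size,
#' and the RPKM.
#'
#' @param fragments A [fragment_set()].
#' @param promoter_table Output of [classify_promoters()].
#' @param on Interval to quantify over: the matched CGI (default, the unit
#'   used for promoter-based statistics) or the TSS window.
#' @param library_size Library size for RPKM (defaults to the set's own).
#' @return data.frame: `promoter_id`, `label`, `n_fragments`,
#'   `median_fragment_size`, `rpkm`. Promoters without the requested
#'   interval get `NA` metrics.
#' @export
promoter_metrics <- function(fragments, promoter_table,
                             on = c("cgi", "window"),
                             library_size = fragments$library_size) {
  stopifnot(inherits(fragments, "fragment_set"), library_size > 0)
  on <- match.arg(on)
  if (on == "cgi") {
    iv <- data.frame(chrom = promoter_table$cgi_chrom,
                     start = promoter_table$cgi_start,
                     end = promoter_table$cgi_end,
                     stringsAsFactors = FALSE)
  } else {
    iv <- data.frame(chrom = promoter_table$chrom,
                     start = promoter_table$window_start,
                     end = promoter_table$window_end,
                     stringsAsFactors = FALSE)
  }
  n <- nrow(promoter_table)
  out <- data.frame(promoter_id = promoter_table$gene_id,
                    label = promoter_table$label,
                    n_fragments = rep(NA_integer_, n),
                    median_fragment_size = rep(NA_real_, n),
                    rpkm = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  usable <- which(!is.na(iv$start) & !is.na(iv$end) & iv$end > iv$start)
  if (length(usable) == 0 || nrow(fragments$records) == 0) {
    out$n_fragments[usable] <- 0L
    out$rpkm[usable] <- 0
    return(out)
  }
  r <- fragments$records
  mid_gr <- GenomicRanges::GRanges(r$chrom,
                                   IRanges::IRanges(r$midpoint + 1L,
                                                    r$midpoint + 1L))
  iv_gr <- as_granges0(iv[usable, , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(mid_gr, iv_gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  counts <- tabulate(si, nbins = length(usable))
  med <- rep(NA_real_, length(usable))
  if (length(qi) > 0) {
    med_by <- tapply(r$size[qi], si, function(s) as.numeric(median(s)))
    med[as.integer(names(med_by))] <- unname(med_by)
  }
  len_kb <- (iv$end[usable] - iv$start[usable]) / 1000
  out$n_fragments[usable] <- counts
  out$median_fragment_size[usable] <- med
  out$rpkm[usable] <- counts / (len_kb * (library_size / 1e6))
  out
}

#' Per-promoter change in a metric between two conditions
#'
#' Computes `cond2 - cond1` per promoter for a chosen metric column.
#' Promoters present in only one condition are dropped with a warning;
#' a value missing in either condition yields a missing delta.
#'
#' @param metrics_cond1,metrics_cond2 Outputs of [promoter_metrics()] (or
#'   any table keyed by `promoter_id`).
#' @param metric Column to difference (default `"median_fragment_size"`).
#' @return data.frame: `promoter_id`, `metric`, `cond1`, `cond2`, `delta`.
#' @export
delta_metric <- function(metrics_cond1, metrics_cond2,
                         metric = "median_fragment_size") {
  stopifnot(metric %in% names(metrics_cond1), metric %in% names(metrics_cond2))
  m <- merge(metrics_cond1[, c("promoter_id", metric)],
             metrics_cond2[, c("promoter_id", metric)],
             by = "promoter_id", suffixes = c("_1", "_2"))
  n_unmatched <- nrow(metrics_cond1) + nrow(metrics_cond2) - 2 * nrow(m)
  if (n_unmatched > 0) {
    warning(sprintf("delta_metric: %d unmatched promoter id(s) dropped",
                    n_unmatched))
  }
  data.frame(promoter_id = m$promoter_id,
             metric = metric,
             cond1 = m[[paste0(metric, "_1")]],
             cond2 = m[[paste0(metric, "_2")]],
             delta = m[[paste0(metric, "_2")]] - m[[paste0(metric, "_1")]],
             stringsAsFactors = FALSE)
}
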