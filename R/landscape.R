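# Per-promoter aggregation of nucleosome calls into spacing / fuzziness
# statistics, and condition deltas over the full landscape table.

#' Median inter-dyad distance within a CGI
#'
#' Dyads are restricted to those inside the CGI interval; each dyad's
#' distance to its nearest neighbouring dyad (within the same CGI only) is
#' computed and the median taken. With fewer than two dyads the statistic
#' is missing rather than imputed. `mode = "consecutive"` instead uses the
#' distances between consecutive sorted dyads.
#'
#' @param calls Nucleosome call data.frame (needs `chrom`, `dyad`).
#' @param cgi_interval One-row data.frame/list with `chrom`, `start`, `end`.
#' @param mode `"nearest"` (default) or `"consecutive"`.
#' @return Median distance in bp, or `NA_real_`.
#' @export
inter_dyad_median <- function(calls, cgi_interval,
                              mode = c("nearest", "consecutive")) {
  mode <- match.arg(mode)
  d <- calls$dyad[calls$chrom == cgi_interval$chrom &
                    calls$dyad >= cgi_interval$start &
                    calls$dyad < cgi_interval$end]
  if (length(d) < 2) return(NA_real_)
  dist <- if (mode == "nearest") nearest_neighbor_distances(d)
          else diff(sort(d))
  as.numeric(median(dist))
}

#' Assemble the per-promoter nucleosome landscape table
#'
#' Joins the accessibility metrics, occupancy-per-kb values and per-CGI
#' call summaries into one row per PcG / nonPcG promoter. Missing
#' components propagate as missing fields.
#'
#' @param metrics Output of [promoter_metrics()] (keyed by `promoter_id`).
#' @param occ_per_kb Named numeric vector or data.frame
#'   (`promoter_id`, `occupancy_per_kb`).
#' @param calls Named list of per-promoter annotated nucleosome call
#'   data.frames (names are promoter ids).
#' @param promoter_table Output of [classify_promoters()].
#' @param mode Spacing mode passed to [inter_dyad_median()].
#' @return data.frame: `promoter_id`, `label`, `n_fragments`,
#'   `median_fragment_size`, `rpkm`, `occupancy_per_kb`, `n_calls`,
#'   `median_inter_dyad`, `median_fuzziness`.
#' @export
build_landscape_table <- function(metrics, occ_per_kb, calls,
                                  promoter_table,
                                  mode = c("nearest", "consecutive")) {
  mode <- match.arg(mode)
  if (anyDuplicated(promoter_table$gene_id)) {
    stop("duplicate promoter ids in promoter_table")
  }
  keep <- promoter_table$label %in% c("PcG", "nonPcG")
  pt <- promoter_table[keep, , drop = FALSE]
  if (is.data.frame(occ_per_kb)) {
    occ_map <- stats::setNames(occ_per_kb$occupancy_per_kb,
                               occ_per_kb$promoter_id)
  } else {
    occ_map <- occ_per_kb
  }
  met_idx <- match(pt$gene_id, metrics$promoter_id)
  n <- nrow(pt)
  out <- data.frame(promoter_id = pt$gene_id,
                    label = pt$label,
                    n_fragments = metrics$n_fragments[met_idx],
                    median_fragment_size =
                      metrics$median_fragment_size[met_idx],
                    rpkm = metrics$rpkm[met_idx],
                    occupancy_per_kb =
                      as.numeric(occ_map[pt$gene_id]),
                    n_calls = rep(0L, n),
                    median_inter_dyad = rep(NA_real_, n),
                    median_fuzziness = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cl <- calls[[pt$gene_id[i]]]
    if (is.null(cl) || nrow(cl) == 0) next
    cgi <- list(chrom = pt$cgi_chrom[i], start = pt$cgi_start[i],
                end = pt$cgi_end[i])
    inside <- cl[cl$chrom == cgi$chrom & cl$dyad >= cgi$start &
                   cl$dyad < cgi$end, , drop = FALSE]
    out$n_calls[i] <- nrow(inside)
    out$median_inter_dyad[i] <- inter_dyad_median(inside, cgi, mode = mode)
    if ("fuzziness" %in% names(inside) &&
        any(!is.na(inside$fuzziness))) {
      out$median_fuzziness[i] <-
        as.numeric(median(inside$fuzziness, na.rm = TRUE))
    }
  }
  out
}

#' Per-promoter condition deltas of the nucleosome landscape
#'
#' All deltas are `cond2 - cond1`. Occupancy is compared as a log2 fold
#' change with a fixed pseudocount: `log2((occ2 + c) / (occ1 + c))`.
#' Promoters present in only one table are reported in a warning and
#' excluded.
#'
#' @param table_cond1,table_cond2 Outputs of [build_landscape_table()].
#' @param pseudocount Pseudocount `c` in occupancy-per-kb units (default 1).
#' @return data.frame: `promoter_id`, `label`,
#'   `delta_median_fragment_size`, `log2fc_occupancy`, `delta_inter_dyad`,
#'   `delta_fuzziness`, `log2fc_rpkm`.
#' @export
condition_delta <- function(table_cond1, table_cond2, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  m <- merge(table_cond1, table_cond2, by = c("promoter_id", "label"),
             suffixes = c("_1", "_2"))
  n_unmatched <- nrow(table_cond1) + nrow(table_cond2) - 2 * nrow(m)
  if (n_unmatched > 0) {
    warning(sprintf("condition_delta: %d unmatched promoter id(s) dropped",
                    n_unmatched))
  }
  data.frame(
    promoter_id = m$promoter_id,
    label = m$label,
    delta_median_fragment_size =
      m$median_fragment_size_2 - m$median_fragment_size_1,
    log2fc_occupancy = log2((m$occupancy_per_kb_2 + pseudocount) /
                              (m$occupancy_per_kb_1 + pseudocount)),
    delta_inter_dyad = m$median_inter_dyad_2 - m$median_inter_dyad_1,
    delta_fuzziness = m$median_fuzziness_2 - m$median_fuzziness_1,
    log2fc_rpkm = log2((m$rpkm_2 + pseudocount) / (m$rpkm_1 + pseudocount)),
    stringsAsFactors = FALSE)
}

#' Full fragment-to-landscape computation for every promoter
#'
#' Convenience driver joining the whole per-condition pipeline: per
#' promoter, mono/all kernel densities over the CGI (padded to absorb
#' kernel edge effects), occupancy track, dyad calls with fuzziness, and
#' the per-CGI summary statistics, merged with [promoter_metrics()].
#'
#' @param fragments A [fragment_set()] for one condition.
#' @param promoter_table Output of [classify_promoters()].
#' @param config Size-class configuration from [size_class_config()].
#' @param bandwidth_sd Kernel sd (bp) for [dyad_density()].
#' @param epsilon Pseudo-density for [occupancy_track()].
#' @param min_separation,min_score Dyad-calling parameters
#'   ([call_nucleosomes()]).
#' @param half_window Fuzziness window half-width (bp).
#' @param pad Extra bp analysed on each side of the CGI so that dyads near
#'   the CGI edge are supported by a full kernel neighbourhood (default
#'   200).
#' @param mode Spacing mode passed to [inter_dyad_median()].
#' @return A landscape table as from [build_landscape_table()].
#' @export
landscape_from_fragments <- function(fragments, promoter_table,
                                     config = size_class_config(),
                                     bandwidth_sd = 20, epsilon = 1e-3,
                                     min_separation = 120, min_score = 0.1,
                                     half_window = 73, pad = 200,
                                     mode = c("nearest", "consecutive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fragments, "fragment_set"))
  split <- split_by_size(fragments, config)
  metrics <- promoter_metrics(fragments, promoter_table, on = "cgi")
  keep <- promoter_table$label %in% c("PcG", "nonPcG")
  pt <- promoter_table[keep, , drop = FALSE]
  occ_vec <- stats::setNames(rep(NA_real_, nrow(pt)), pt$gene_id)
  calls_list <- vector("list", nrow(pt))
  names(calls_list) <- pt$gene_id
  for (i in seq_len(nrow(pt))) {
    if (is.na(pt$cgi_start[i])) next
    region <- list(chrom = pt$cgi_chrom[i],
                   start = max(0L, pt$cgi_start[i] - as.integer(pad)),
                   end = pt$cgi_end[i] + as.integer(pad))
    mono_d <- dyad_density(split$mono, region, bandwidth_sd)
    all_d <- dyad_density(fragments, region, bandwidth_sd)
    occ <- occupancy_track(mono_d, all_d, epsilon)
    cgi <- list(chrom = pt$cgi_chrom[i], start = pt$cgi_start[i],
                end = pt$cgi_end[i])
    occ_vec[i] <- occupancy_per_kb(occ, cgi)
    calls <- call_nucleosomes(occ, min_separation, min_score)
    calls_list[[i]] <- annotate_calls(calls, split$mono, half_window)
  }
  build_landscape_table(metrics, occ_vec, calls_list, promoter_table,
                        mode = mode)
}

#' Write a landscape or delta table as TSV
#'
#' @param table Landscape or delta data.frame.
#' @param path Output path.
#' @export
write_landscape <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
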