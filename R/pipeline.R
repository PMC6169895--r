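# End-to-end orchestration: simulate (or load) two conditions, classify
# promoters, compute metrics, landscapes, deltas and group tests, and write
# every table plus a JSON run manifest.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its documented default. Unknown keys
#' supplied to [run_pipeline()] are rejected.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,                 # global seed for all randomness
    n_per_class = 50L,         # simulated promoters per class
    spacing_bp = 5000L,        # distance between simulated TSSs
    flank = 500L,              # promoter window half-width (bp)
    nfr_max = 120L,            # nucleosome-free size class upper bound
    mono_min = 150L,           # mononucleosomal class bounds (bp)
    mono_max = 250L,
    bandwidth_sd = 20,         # dyad-density kernel sd (bp)
    epsilon = 1e-3,            # occupancy pseudo-density
    min_separation = 120,      # minimum dyad separation (bp)
    min_score = 0.1,           # minimum occupancy for a dyad call
    half_window = 73,          # fuzziness window half-width (bp)
    pseudocount = 1,           # occupancy-per-kb pseudocount for log2fc
    fdr_threshold = 0.05,      # significance thresholds
    fc_threshold = 1.5,
    metaplot_half_window = 2000L,
    knockout_occupancy_factor = 0.5,  # condition-2 perturbation (class A)
    knockout_delta_nrl = 20
  )
}

#' Validate a pipeline configuration
#'
#' Fills unset keys with defaults, rejects unknown keys, and checks
#' cross-key invariants (size-class ordering, positive windows,
#' probability bounds).
#'
#' @param config Named list of overrides (possibly partial).
#' @return The completed, validated configuration list.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (!(cfg$nfr_max <= cfg$mono_min)) {
    stop("invalid size classes: nfr_max (", cfg$nfr_max,
         ") must be <= mono_min (", cfg$mono_min, ")")
  }
  if (!(cfg$mono_min < cfg$mono_max)) {
    stop("invalid size classes: mono_min must be < mono_max")
  }
  stopifnot(cfg$flank > 0, cfg$bandwidth_sd > 0, cfg$epsilon > 0,
            cfg$min_separation > 0, cfg$half_window > 0,
            cfg$fdr_threshold > 0, cfg$fc_threshold > 0,
            cfg$knockout_occupancy_factor >= 0,
            cfg$n_per_class >= 1)
  cfg
}

#' Run the full two-condition pipeline on simulated data
#'
#' Stages, in order: simulate condition 1 (baseline classes) and condition
#' 2 (class A perturbed by [simulate_knockout()], class B untouched) on the
#' same promoter layout; classify promoters from the emitted peak/CGI
#' sets; per-condition fragment processing (deduplication, blacklist
#' filter, size split); per-promoter metrics and nucleosome landscapes;
#' condition deltas; class-level rank-sum tests. All tables are written as
#' TSV into `outdir` together with a JSON manifest of parameters and
#' per-stage record counts. Deterministic given the configuration.
#'
#' @param config Partial configuration (see [default_config()]).
#' @param outdir Output directory.
#' @return Invisibly, a list with the in-memory results (`promoters`,
#'   `landscape_cond1`, `landscape_cond2`, `deltas`, `class_tests`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("nucleoscape_")) {
  cfg <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  params_a <- params_pcg_like()
  params_b <- params_active_like()
  params_a2 <- simulate_knockout(params_a, cfg$knockout_occupancy_factor,
                                 cfg$knockout_delta_nrl)
  sim1 <- simulate_experiment(params_a, params_b, cfg$n_per_class,
                              cfg$spacing_bp, seed = cfg$seed)
  sim2 <- simulate_experiment(params_a2, params_b, cfg$n_per_class,
                              cfg$spacing_bp,
                              seed = derive_seed(cfg$seed, 10007L))
  counts$fragments_cond1 <- sim1$fragments$library_size
  counts$fragments_cond2 <- sim2$fragments$library_size

  windows <- make_tss_windows(sim1$tss_table, flank = cfg$flank)
  promoters <- classify_promoters(windows, sim1$rnf2_peaks,
                                  sim1$suz12_peaks, sim1$cgi_intervals)
  counts$promoters <- nrow(promoters)
  counts$pcg <- sum(promoters$label == "PcG")
  counts$nonpcg <- sum(promoters$label == "nonPcG")
  write_promoter_table(promoters, file.path(outdir, "promoters.tsv"))

  scc <- size_class_config(cfg$nfr_max, cfg$mono_min, cfg$mono_max)
  process <- function(fs) {
    filter_blacklist(deduplicate(fs), sim1$blacklist)
  }
  land <- list()
  for (cond in 1:2) {
    fs <- process(if (cond == 1) sim1$fragments else sim2$fragments)
    land[[cond]] <- landscape_from_fragments(
      fs, promoters, config = scc, bandwidth_sd = cfg$bandwidth_sd,
      epsilon = cfg$epsilon, min_separation = cfg$min_separation,
      min_score = cfg$min_score, half_window = cfg$half_window)
    write_landscape(land[[cond]],
                    file.path(outdir, sprintf("landscape_cond%d.tsv", cond)))
  }

  deltas <- condition_delta(land[[1]], land[[2]],
                            pseudocount = cfg$pseudocount)
  write_landscape(deltas, file.path(outdir, "landscape_delta.tsv"))
  counts$delta_rows <- nrow(deltas)

  metrics_for_test <- c("median_fragment_size", "rpkm", "occupancy_per_kb",
                        "median_inter_dyad", "median_fuzziness")
  class_tests <- do.call(rbind, lapply(metrics_for_test, function(m) {
    compare_classes(land[[1]], m)
  }))
  class_tests$q_value <- bh_fdr(class_tests$p_value)
  write_landscape(class_tests, file.path(outdir, "class_tests.tsv"))

  manifest <- list(package = "nucleoscape",
                   version = as.character(packageVersion("nucleoscape")),
                   parameters = cfg, record_counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(promoters = promoters, landscape_cond1 = land[[1]],
                 landscape_cond2 = land[[2]], deltas = deltas,
                 class_tests = class_tests, manifest = manifest,
                 outdir = outdir))
}
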