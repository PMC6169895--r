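# Seeded synthetic-fragment generator. Each promoter carries a phased
# nucleosome array around a nucleosome-free region (NFR) at the TSS;
# mononucleosomal fragments are emitted around true dyads with positional
# jitter, nucleosome-free fragments from the NFR and linkers. Ground truth
# (dyads, class parameters) is recorded for parameter-recovery tests.

NUC_HALF_FOOTPRINT <- 73L  # bp from dyad to nucleosome edge
MONO_SIZE_RANGE <- c(150L, 250L)
NFR_SIZE_RANGE <- c(20L, 119L)

#' Promoter-class simulation parameters
#'
#' Describes one promoter class of the generator: a symmetric nucleosome
#' array of `nucs_per_side` nucleosomes on each side of an NFR centred at
#' the TSS, with dyads `nrl` bp apart.
#'
#' @param nrl Nucleosome repeat length: centre-to-centre dyad distance
#'   (bp, `>= 147`).
#' @param occupancy Probability in `[0, 1]` that a candidate draw at an
#'   array position yields a mononucleosomal fragment.
#' @param fuzziness_sd Per-fragment dyad jitter sd (bp).
#' @param nfr_width Width of the nucleosome-free region centred at the TSS
#'   (bp).
#' @param nfr_rate Expected number of nucleosome-free fragments per
#'   promoter.
#' @param mono_size_mean,mono_size_sd Mononucleosomal fragment size
#'   distribution (bp; truncated to 150-250).
#' @param nfr_size_mean,nfr_size_sd Nucleosome-free fragment size
#'   distribution (bp; truncated to 20-119).
#' @param nucs_per_side Nucleosomes per side of the NFR.
#' @param depth Expected candidate mono draws per nucleosome position
#'   (Poisson mean); kept draws per position are thinned by `occupancy`.
#' @return A `promoter_class_params` list.
#' @export
promoter_class_params <- function(nrl = 175, occupancy = 0.9,
                                  fuzziness_sd = 25, nfr_width = 60,
                                  nfr_rate = 10, mono_size_mean = 180,
                                  mono_size_sd = 20, nfr_size_mean = 60,
                                  nfr_size_sd = 25, nucs_per_side = 5,
                                  depth = 20) {
  if (nrl < 147) stop("nrl must be >= 147 (nucleosome footprint)")
  if (occupancy < 0 || occupancy > 1) stop("occupancy must lie in [0, 1]")
  if (fuzziness_sd < 0 || mono_size_sd < 0 || nfr_size_sd < 0) {
    stop("standard deviations must be >= 0")
  }
  if (nfr_width < 0 || nfr_rate < 0 || depth < 0) {
    stop("nfr_width, nfr_rate and depth must be >= 0")
  }
  if (nucs_per_side < 1) stop("nucs_per_side must be >= 1")
  structure(list(nrl = nrl, occupancy = occupancy,
                 fuzziness_sd = fuzziness_sd, nfr_width = nfr_width,
                 nfr_rate = nfr_rate, mono_size_mean = mono_size_mean,
                 mono_size_sd = mono_size_sd, nfr_size_mean = nfr_size_mean,
                 nfr_size_sd = nfr_size_sd,
                 nucs_per_side = as.integer(nucs_per_side), depth = depth),
            class = "promoter_class_params")
}

#' Default Polycomb-like promoter class
#'
#' Closely spaced, highly occupied, fuzzier nucleosomes over a narrow NFR
#' with few nucleosome-free fragments -- the repressed-promoter phenotype.
#' @return A [promoter_class_params()].
#' @export
params_pcg_like <- function() {
  promoter_class_params(nrl = 175, occupancy = 0.9, fuzziness_sd = 25,
                        nfr_width = 60, nfr_rate = 10)
}

#' Default active-like promoter class
#'
#' Wider spacing, lower occupancy, well-positioned nucleosomes flanking a
#' broad NFR rich in short nucleosome-free fragments.
#' @return A [promoter_class_params()].
#' @export
params_active_like <- function() {
  promoter_class_params(nrl = 195, occupancy = 0.6, fuzziness_sd = 12,
                        nfr_width = 300, nfr_rate = 60)
}

# True dyad positions of the array, left to right.
true_dyad_positions <- function(params, tss) {
  off <- params$nfr_width / 2 + NUC_HALF_FOOTPRINT +
    (seq_len(params$nucs_per_side) - 1) * params$nrl
  round(c(tss - rev(off), tss + off))
}

# Normal draw truncated to [lo, hi] by rejection (deterministic per RNG
# state); returns integers.
rtrunc_norm_int <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(integer(0))
  if (sd == 0) return(rep(as.integer(round(min(max(mean, lo), hi))), n))
  out <- integer(0)
  while (length(out) < n) {
    x <- as.integer(round(rnorm(n - length(out), mean, sd)))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out
}

# Accessible (non-nucleosomal) segments of the array: NFR plus internal
# linkers. Matrix with columns start, end (0-based half-open).
accessible_segments <- function(params, tss) {
  dy <- true_dyad_positions(params, tss)
  segs <- rbind(c(tss - params$nfr_width / 2, tss + params$nfr_width / 2))
  n <- length(dy)
  left <- dy[seq_len(n - 1)] + NUC_HALF_FOOTPRINT + 1
  right <- dy[seq.int(2, n)] - NUC_HALF_FOOTPRINT
  linkers <- cbind(left, right)[right > left, , drop = FALSE]
  segs <- rbind(segs, linkers)
  segs[segs[, 2] > segs[, 1], , drop = FALSE]
}

#' Simulate fragments for one promoter
#'
#' True dyads sit at `tss +/- (nfr_width/2 + 73 + k * nrl)` for
#' `k = 0 .. nucs_per_side - 1`. Each dyad receives `Poisson(depth)`
#' candidate draws, each kept with probability `occupancy`; a kept draw
#' emits a mononucleosomal fragment whose midpoint is the dyad plus
#' `Normal(0, fuzziness_sd)` jitter (rounded) and whose size is
#' `Normal(mono_size_mean, mono_size_sd)` truncated to 150-250 bp.
#' `Poisson(nfr_rate)` nucleosome-free fragments get midpoints uniform over
#' the NFR and internal linkers, sizes truncated to 20-119 bp. Identical
#' seed and parameters give identical fragments.
#'
#' @param params A [promoter_class_params()].
#' @param tss TSS position (bp).
#' @param strand `"+"` or `"-"` (annotation only; the array is symmetric).
#' @param seed Integer seed for this locus.
#' @param chrom Chromosome name.
#' @param gene_id Promoter identifier.
#' @return A `simulated_locus` list: `gene_id`, `chrom`, `tss`, `strand`,
#'   `cgi` (interval covering the array), `true_dyads`, `fragments`
#'   (data.frame with `chrom`, `start`, `end`, `size`, `midpoint`, `type`,
#'   `origin_dyad`), `params`, `seed`.
#' @export
simulate_promoter <- function(params, tss, strand = "+", seed = 1L,
                              chrom = "chrS", gene_id = "gene") {
  stopifnot(inherits(params, "promoter_class_params"))
  dyads <- true_dyad_positions(params, tss)
  span <- params$nfr_width / 2 + 2 * NUC_HALF_FOOTPRINT +
    (params$nucs_per_side - 1) * params$nrl
  cgi <- data.frame(chrom = chrom,
                    start = as.integer(floor(tss - span)),
                    end = as.integer(ceiling(tss + span)),
                    stringsAsFactors = FALSE)
  frag <- with_seed(seed, {
    mono_mid <- integer(0); mono_dyad <- integer(0)
    for (d in dyads) {
      n_cand <- rpois(1, params$depth)
      kept <- sum(runif(n_cand) < params$occupancy)
      if (kept > 0) {
        jitter <- if (params$fuzziness_sd > 0)
          as.integer(round(rnorm(kept, 0, params$fuzziness_sd)))
        else rep(0L, kept)
        mono_mid <- c(mono_mid, d + jitter)
        mono_dyad <- c(mono_dyad, rep(as.integer(d), kept))
      }
    }
    mono_size <- rtrunc_norm_int(length(mono_mid), params$mono_size_mean,
                                 params$mono_size_sd, MONO_SIZE_RANGE[1],
                                 MONO_SIZE_RANGE[2])
    n_nfr <- rpois(1, params$nfr_rate)
    nfr_mid <- integer(0)
    if (n_nfr > 0) {
      segs <- accessible_segments(params, tss)
      lens <- segs[, 2] - segs[, 1]
      seg_i <- sample.int(nrow(segs), n_nfr, replace = TRUE,
                          prob = lens / sum(lens))
      nfr_mid <- as.integer(floor(segs[seg_i, 1] +
                                    runif(n_nfr) * lens[seg_i]))
    }
    nfr_size <- rtrunc_norm_int(length(nfr_mid), params$nfr_size_mean,
                                params$nfr_size_sd, NFR_SIZE_RANGE[1],
                                NFR_SIZE_RANGE[2])
    mid <- c(mono_mid, nfr_mid)
    size <- c(mono_size, nfr_size)
    start <- as.integer(mid - size %/% 2L)
    data.frame(chrom = chrom, start = start, end = start + size,
               size = as.integer(size), midpoint = as.integer(mid),
               type = rep(c("mono", "nfr"),
                          c(length(mono_mid), length(nfr_mid))),
               origin_dyad = c(mono_dyad, rep(NA_integer_,
                                              length(nfr_mid))),
               stringsAsFactors = FALSE)
  })
  structure(list(gene_id = gene_id, chrom = chrom, tss = as.integer(tss),
                 strand = strand, cgi = cgi,
                 true_dyads = as.integer(dyads), fragments = frag,
                 params = params, seed = as.integer(seed)),
            class = "simulated_locus")
}

#' Simulate a two-class promoter experiment
#'
#' Places `n_per_class` promoters of each class alternately along one
#' synthetic chromosome, `spacing_bp` apart. Class-A promoters are emitted
#' as intervals in both synthetic ChIP peak sets ("RNF2"-like and
#' "SUZ12"-like) as well as in the CGI set; class-B promoters appear only
#' in the CGI set, so [classify_promoters()] reconstructs the class labels
#' exactly (A -> PcG, B -> nonPcG).
#'
#' @param params_classA,params_classB [promoter_class_params()] for the two
#'   classes (defaults: [params_pcg_like()], [params_active_like()]).
#' @param n_per_class Promoters per class (default 50).
#' @param spacing_bp Distance between consecutive TSSs (default 5000; must
#'   exceed both array spans so promoters never overlap).
#' @param chrom_length Chromosome length (default accommodates all
#'   promoters plus one spacing of margin).
#' @param seed Global seed; per-locus seeds are derived deterministically
#'   from it, so the whole experiment is reproducible.
#' @param chrom Chromosome name.
#' @return List: `fragments` (a [fragment_set()]), `tss_table`,
#'   `cgi_intervals`, `rnf2_peaks`, `suz12_peaks`, `blacklist` (empty),
#'   `truth` (per-promoter class and parameters, with true dyads as a
#'   comma-separated list), `loci` (the `simulated_locus` objects).
#' @export
simulate_experiment <- function(params_classA = params_pcg_like(),
                                params_classB = params_active_like(),
                                n_per_class = 50, spacing_bp = 5000,
                                chrom_length = NULL, seed = 1L,
                                chrom = "chrS") {
  stopifnot(inherits(params_classA, "promoter_class_params"),
            inherits(params_classB, "promoter_class_params"),
            n_per_class >= 1)
  span_a <- params_classA$nfr_width / 2 + 2 * NUC_HALF_FOOTPRINT +
    (params_classA$nucs_per_side - 1) * params_classA$nrl
  span_b <- params_classB$nfr_width / 2 + 2 * NUC_HALF_FOOTPRINT +
    (params_classB$nucs_per_side - 1) * params_classB$nrl
  if (spacing_bp <= 2 * max(span_a, span_b)) {
    stop("spacing_bp too small: promoter arrays would overlap")
  }
  n_total <- 2L * as.integer(n_per_class)
  chrom_length <- chrom_length %||% ((n_total + 1L) * spacing_bp)
  tss <- spacing_bp * seq_len(n_total)
  if (max(tss) + max(span_a, span_b) > chrom_length) {
    stop("promoters exceed chrom_length")
  }
  class <- rep(c("A", "B"), n_per_class)
  # period-4 strand pattern so each class has promoters on both strands
  strand <- rep(c("+", "+", "-", "-"), length.out = n_total)
  loci <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    p <- if (class[i] == "A") params_classA else params_classB
    loci[[i]] <- simulate_promoter(p, tss[i], strand[i],
                                   seed = derive_seed(seed, i),
                                   chrom = chrom,
                                   gene_id = sprintf("gene_%03d", i))
  }
  frag <- do.call(rbind, lapply(loci, `[[`, "fragments"))
  cgi <- do.call(rbind, lapply(loci, `[[`, "cgi"))
  cgi$name <- vapply(loci, `[[`, "", "gene_id")
  peaks <- cgi[class == "A", , drop = FALSE]
  truth <- do.call(rbind, lapply(seq_len(n_total), function(i) {
    p <- loci[[i]]$params
    data.frame(promoter_id = loci[[i]]$gene_id, class = class[i],
               nrl = p$nrl, occupancy = p$occupancy,
               fuzziness_sd = p$fuzziness_sd, nfr_width = p$nfr_width,
               nfr_rate = p$nfr_rate,
               true_dyads = paste(loci[[i]]$true_dyads, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  list(fragments = fragment_set(frag, sample_id = sprintf("sim_seed%d",
                                                          seed)),
       tss_table = data.frame(gene_id = vapply(loci, `[[`, "", "gene_id"),
                              chrom = chrom, tss = tss, strand = strand,
                              stringsAsFactors = FALSE),
       cgi_intervals = cgi,
       rnf2_peaks = peaks,
       suz12_peaks = peaks,
       blacklist = data.frame(chrom = character(), start = integer(),
                              end = integer()),
       truth = truth,
       loci = loci,
       chrom_length = chrom_length,
       seed = as.integer(seed))
}

#' Derive perturbed ("knockout") class parameters
#'
#' Emulates loss of a repressive complex at the bound class only: the
#' occupancy probability is multiplied by `delta_occupancy_factor` and the
#' repeat length increased by `delta_nrl_bp`; all other parameters are
#' untouched. Apply to class A and re-simulate with class B unchanged to
#' obtain the second condition.
#'
#' @param params_classA [promoter_class_params()] of the bound class.
#' @param delta_occupancy_factor Multiplier on `occupancy` (default 0.5).
#' @param delta_nrl_bp Added repeat length in bp (default 20).
#' @return A [promoter_class_params()] for the perturbed condition.
#' @export
simulate_knockout <- function(params_classA, delta_occupancy_factor = 0.5,
                              delta_nrl_bp = 20) {
  stopifnot(inherits(params_classA, "promoter_class_params"))
  occ <- params_classA$occupancy * delta_occupancy_factor
  if (occ < 0 || occ > 1) stop("resulting occupancy outside [0, 1]")
  promoter_class_params(
    nrl = params_classA$nrl + delta_nrl_bp, occupancy = occ,
    fuzziness_sd = params_classA$fuzziness_sd,
    nfr_width = params_classA$nfr_width, nfr_rate = params_classA$nfr_rate,
    mono_size_mean = params_classA$mono_size_mean,
    mono_size_sd = params_classA$mono_size_sd,
    nfr_size_mean = params_classA$nfr_size_mean,
    nfr_size_sd = params_classA$nfr_size_sd,
    nucs_per_side = params_classA$nucs_per_side, depth = params_classA$depth)
}

#' Write a simulated experiment to disk
#'
#' Emits the generator's standard file set: fragments BED, TSS TSV,
#' CGI/peak/blacklist BEDs, the ground-truth TSV, and a flat key-value
#' config recording the seed.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fragments = file.path(dir, "fragments.bed"),
             tss = file.path(dir, "tss.tsv"),
             cgi = file.path(dir, "cgi.bed"),
             rnf2 = file.path(dir, "rnf2_peaks.bed"),
             suz12 = file.path(dir, "suz12_peaks.bed"),
             blacklist = file.path(dir, "blacklist.bed"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "sim_config.txt"))
  write_fragments(sim$fragments, paths[["fragments"]])
  data.table::fwrite(sim$tss_table, paths[["tss"]], sep = "\t",
                     quote = FALSE)
  write_bed(sim$cgi_intervals, paths[["cgi"]])
  write_bed(sim$rnf2_peaks, paths[["rnf2"]])
  write_bed(sim$suz12_peaks, paths[["suz12"]])
  write_bed(sim$blacklist, paths[["blacklist"]])
  data.table::fwrite(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE)
  writeLines(c(sprintf("seed: %d", sim$seed),
               sprintf("chrom_length: %d", sim$chrom_length)),
             paths[["config"]])
  invisible(paths)
}
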