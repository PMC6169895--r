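region1 <- function(s, e) list(chrom = "chr1", start = s, end = e)

test_that("dyad density peaks at the fragment midpoint with the renormalised kernel height", {
  fs <- toy_fragments(1000, 180)  # midpoint 1090
  tr <- dyad_density(fs, region1(900, 1300), bandwidth_sd = 20)
  pos <- tr$start + which.max(tr$values) - 1L
  expect_equal(pos, 1090)
  # quadrature oracle: truncated-at-3sd kernel renormalised to unit mass
  kern_height <- dnorm(0, 0, 20) / sum(dnorm(-60:60, 0, 20))
  expect_equal(max(tr$values), kern_height, tolerance = 1e-12)
  expect_equal(dnorm(0, 0, 20), 0.0199, tolerance = 5e-3)
  # symmetry about the midpoint
  i0 <- which.max(tr$values)
  expect_equal(tr$values[i0 - 30], tr$values[i0 + 30], tolerance = 1e-12)
})

test_that("dyad density is linear in fragments and conserves unit mass per interior fragment", {
  fs1 <- toy_fragments(1000, 180)
  fs2 <- toy_fragments(c(1000, 1000), c(180, 180))
  r <- region1(900, 1300)
  t1 <- dyad_density(fs1, r)
  t2 <- dyad_density(fs2, r)
  expect_equal(t2$values, 2 * t1$values, tolerance = 1e-12)

  set.seed(5)
  mids <- sample(500:1500, 40, replace = TRUE)
  fsn <- toy_fragments(mids - 90, rep(180, 40))
  tn <- dyad_density(fsn, region1(400, 1700), bandwidth_sd = 20)
  # every midpoint is >= 3 sd from the region edges -> exact mass
  expect_equal(sum(tn$values), 40, tolerance = 40 * 1e-6)
  expect_true(all(tn$values >= 0))

  empty <- fragment_set(data.frame(chrom = character(), start = integer(),
                                   end = integer()))
  expect_true(all(dyad_density(empty, r)$values == 0))
})

test_that("occupancy is the mono share of total density, bounded in [0,1]", {
  mono <- toy_fragments(rep(1000, 10), rep(180, 10))
  all_f <- toy_fragments(c(rep(1000, 10), rep(1600, 10)),
                         c(rep(180, 10), rep(60, 10)))
  r <- region1(800, 1900)
  occ <- occupancy_track(dyad_density(mono, r), dyad_density(all_f, r))
  expect_true(all(occ$values >= 0 & occ$values <= 1))
  # where all local fragments are mononucleosomal and density >> epsilon
  at <- function(p) occ$values[p - occ$start + 1L]
  expect_gt(at(1090), 0.99)
  # zero-density bp
  expect_equal(at(1900 - 1), 0, tolerance = 1e-4)
  # equal mono and non-mono density -> 0.5 (mirror-image fragment stacks)
  half <- occupancy_track(dyad_density(mono, r),
                          dyad_density(toy_fragments(
                            c(rep(1000, 10), rep(910, 10)),
                            c(rep(180, 10), rep(360, 10))), r))
  expect_equal(half$values[1090 - 800 + 1], 0.5, tolerance = 0.01)

  r2 <- region1(0, 100)
  expect_error(occupancy_track(dyad_density(mono, r), dyad_density(mono, r2)),
               "regions differ")

  # property: random fragment mixes stay bounded
  set.seed(11)
  for (i in 1:5) {
    starts <- sample(0:3000, 80, replace = TRUE)
    sizes <- sample(c(60, 100, 180, 220), 80, replace = TRUE)
    fs <- toy_fragments(starts, sizes)
    sp <- split_by_size(fs)
    o <- occupancy_track(dyad_density(sp$mono, region1(0, 3400)),
                         dyad_density(fs, region1(0, 3400)))
    expect_true(all(o$values >= 0 & o$values <= 1))
  }
})

test_that("nucleosome calling finds modes, enforces separation, breaks ties leftmost", {
  # single symmetric bump
  v <- dnorm(seq(0, 400), 200, 30)
  tr <- bp_track("chr1", 0, 401, v)
  calls <- call_nucleosomes(tr, min_separation = 120, min_score = 0)
  expect_equal(calls$dyad, 200)

  # two equal bumps 200 bp apart with min_separation 120 -> both kept
  v2 <- dnorm(seq(0, 600), 150, 30) + dnorm(seq(0, 600), 350, 30)
  calls2 <- call_nucleosomes(bp_track("chr1", 0, 601, v2), 120, 0)
  expect_equal(calls2$dyad, c(150, 350))

  # two bumps 50 bp apart -> only one kept; equal heights -> leftmost
  v3 <- dnorm(seq(0, 400), 180, 20) + dnorm(seq(0, 400), 230, 20)
  calls3 <- call_nucleosomes(bp_track("chr1", 0, 401, v3), 120, 0)
  expect_equal(nrow(calls3), 1L)
  v4 <- pmax(dnorm(seq(0, 400), 180, 20), dnorm(seq(0, 400), 230, 20))
  calls4 <- call_nucleosomes(bp_track("chr1", 0, 401, v4), 120, 0)
  expect_equal(calls4$dyad, 180)

  # plateau -> leftmost bp
  v5 <- c(0, 1, 2, 2, 2, 1, 0)
  calls5 <- call_nucleosomes(bp_track("chr1", 100, 107, v5), 1, 0)
  expect_equal(calls5$dyad, 102)

  # min_score filters candidates
  expect_equal(nrow(call_nucleosomes(tr, 120, min_score = 1)), 0L)
})

test_that("noise-free phased arrays are recovered dyad-for-dyad within 2 bp", {
  p <- promoter_class_params(occupancy = 1, fuzziness_sd = 0,
                             nfr_rate = 0, depth = 50)
  for (seed in c(2, 21)) {
    loc <- simulate_promoter(p, tss = 5000, seed = seed)
    fs <- fragment_set(loc$fragments)
    sp <- split_by_size(fs)
    r <- region1(loc$cgi$start - 200, loc$cgi$end + 200)
    r$chrom <- loc$chrom
    occ <- occupancy_track(dyad_density(sp$mono, r), dyad_density(fs, r))
    calls <- call_nucleosomes(occ)
    found <- vapply(loc$true_dyads, function(d)
      any(abs(calls$dyad - d) <= 2), logical(1))
    expect_true(all(found))
  }
})

test_that("fuzziness is the population sd of nearby mono midpoints", {
  # all midpoints at the dyad
  fs0 <- toy_fragments(rep(1000 - 90, 5), rep(180, 5))
  expect_equal(fuzziness(1000, fs0), 0)
  # midpoints at dyad +/- 10 -> exactly 10
  fs1 <- toy_fragments(c(900, 920), c(180, 180))  # midpoints 990, 1010
  expect_equal(fuzziness(1000, fs1), 10)
  # < 2 midpoints in window -> missing
  expect_true(is.na(fuzziness(5000, fs1)))

  # simulation + direct-formula oracle: jitter sd 20 recovered
  set.seed(8)
  mids <- round(rnorm(50, 1000, 20))
  mids <- mids[abs(mids - 1000) <= 73]
  fsj <- toy_fragments(mids - 90, rep(180, length(mids)))
  f <- fuzziness(1000, fsj)
  expect_equal(f, sqrt(mean((mids - mean(mids))^2)))
  expect_lt(abs(f - 20), 3 * 20 / sqrt(2 * length(mids)) + 2)
})

test_that("occupancy per kb matches direct summation and validates intervals", {
  tr <- bp_track("chr1", 1000, 2000, rep(0.8, 1000))
  expect_equal(occupancy_per_kb(tr, region1(1000, 2000)), 800)
  tr0 <- bp_track("chr1", 1000, 2000, rep(0, 1000))
  expect_equal(occupancy_per_kb(tr0, region1(1000, 2000)), 0)
  # step-function toy track vs hand-summed coverage
  step <- bp_track("chr1", 0, 300, rep(c(0.2, 1, 0.5), each = 100))
  expect_equal(occupancy_per_kb(step, region1(50, 250)),
               (50 * 0.2 + 100 * 1 + 50 * 0.5) / 0.2)
  expect_error(occupancy_per_kb(step, region1(100, 100)), "zero-length")
  expect_error(occupancy_per_kb(step, region1(200, 400)), "outside")
})

test_that("fuzziness estimates increase with the generator's jitter sd", {
  jitters <- c(2, 8, 15, 25, 40)
  med_by_jitter <- sapply(c(1, 2, 3), function(seed) {
    sapply(jitters, function(j) {
      p <- promoter_class_params(fuzziness_sd = j, nfr_rate = 0,
                                 depth = 30)
      loc <- simulate_promoter(p, tss = 5000, seed = seed)
      fs <- fragment_set(loc$fragments)
      sp <- split_by_size(fs)
      r <- list(chrom = loc$chrom, start = loc$cgi$start - 200,
                end = loc$cgi$end + 200)
      occ <- occupancy_track(dyad_density(sp$mono, r), dyad_density(fs, r))
      calls <- annotate_calls(call_nucleosomes(occ), sp$mono)
      median(calls$fuzziness, na.rm = TRUE)
    })
  })
  for (k in 1:3) {
    expect_gt(cor(jitters, med_by_jitter[, k], method = "spearman"), 0.9)
  }
})

test_that("bedGraph and call writers round-trip / emit well-formed files", {
  dir <- withr::local_tempdir()
  tr <- bp_track("chr1", 100, 400, rep(c(0, 0.25, 1), each = 100))
  p <- file.path(dir, "occ.bedgraph")
  write_bedgraph(tr, p)
  lines <- readLines(p)
  expect_length(lines, 3)  # runs merged
  back <- read_bedgraph(p)
  expect_equal(back$values, tr$values)
  expect_equal(back$start, tr$start)

  calls <- data.frame(chrom = "chr1", dyad = c(150L, 350L),
                      occ_score = c(0.9, 0.8))
  calls <- annotate_calls(calls, toy_fragments(c(60, 70), c(180, 180)))
  pc <- file.path(dir, "calls.bed")
  write_nucleosome_calls(calls, pc)
  got <- read.delim(pc, header = FALSE)
  expect_equal(got$V2, c(150, 350))
  expect_equal(got$V3, got$V2 + 1)
})
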