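test_that("TSS windows are flank-symmetric, clipped at zero, strand-preserving", {
  tss <- data.frame(gene_id = c("g1", "g2", "g3"),
                    chrom = "chr1",
                    tss = c(10000L, 300L, 10000L),
                    strand = c("+", "+", "-"))
  w <- make_tss_windows(tss, flank = 500)
  expect_equal(w$start, c(9500L, 0L, 9500L))
  expect_equal(w$end, c(10500L, 800L, 10500L))
  expect_equal(w$strand, c("+", "+", "-"))

  bad <- data.frame(gene_id = "gneg", chrom = "chr1", tss = -5L,
                    strand = "+")
  expect_error(make_tss_windows(bad), "gneg")
  expect_error(
    make_tss_windows(data.frame(gene_id = "gx", chrom = "chrZ",
                                tss = 100L, strand = "+"),
                     chrom_lengths = c(chr1 = 1e6)),
    "gx")
})

test_that("interval_overlap follows half-open arithmetic and symmetry", {
  iv <- function(chrom, s, e) data.frame(chrom = chrom, start = s, end = e)
  expect_equal(interval_overlap(iv("chr1", 0, 100), iv("chr1", 50, 150)), 50L)
  expect_equal(interval_overlap(iv("chr1", 0, 100), iv("chr1", 100, 200)), 0L)
  expect_equal(interval_overlap(iv("chr1", 0, 100), iv("chr2", 0, 100)), 0L)
  # symmetry and bound by the shorter interval, on random cases
  set.seed(7)
  for (i in 1:50) {
    a <- iv("chr1", s <- sample(0:500, 1), s + sample(1:200, 1))
    b <- iv("chr1", s2 <- sample(0:500, 1), s2 + sample(1:200, 1))
    ov <- interval_overlap(a, b)
    expect_identical(ov, interval_overlap(b, a))
    expect_lte(ov, min(a$end - a$start, b$end - b$start))
  }
})

test_that("promoter classification applies the dual-peak and CGI rules", {
  win <- data.frame(gene_id = c("both", "rnf2_only", "no_cgi", "none"),
                    chrom = "chr1",
                    start = c(1000L, 3000L, 5000L, 7000L),
                    end = c(2000L, 4000L, 6000L, 8000L),
                    strand = "+", tss = c(1500L, 3500L, 5500L, 7500L))
  rnf2 <- data.frame(chrom = "chr1", start = c(1100L, 3100L, 5100L),
                     end = c(1200L, 3200L, 5200L))
  suz12 <- data.frame(chrom = "chr1", start = c(1300L, 5300L),
                      end = c(1400L, 5400L))
  cgi <- data.frame(chrom = "chr1", start = c(900L, 2900L, 6900L),
                    end = c(1600L, 3600L, 7600L))
  pt <- classify_promoters(win, rnf2, suz12, cgi)
  expect_equal(pt$label,
               c("PcG", "nonPcG", "excluded", "nonPcG"))
  # PcG/nonPcG rows carry the overlapping CGI
  expect_equal(pt$cgi_start[pt$gene_id == "both"], 900L)
  expect_true(is.na(pt$cgi_start[pt$gene_id == "no_cgi"]))
})

test_that("classification is an exhaustive partition, order-invariant, and warns on empty CGIs", {
  sim <- small_sim()
  win <- make_tss_windows(sim$tss_table)
  pt <- classify_promoters(win, sim$rnf2_peaks, sim$suz12_peaks,
                           sim$cgi_intervals)
  expect_equal(sum(pt$label %in% c("PcG", "nonPcG", "excluded")), nrow(win))
  expect_equal(nrow(pt), nrow(sim$tss_table))

  # permuting every input interval list leaves labels unchanged
  shuf <- function(df) df[sample(nrow(df)), , drop = FALSE]
  set.seed(1)
  pt2 <- classify_promoters(win, shuf(sim$rnf2_peaks),
                            shuf(sim$suz12_peaks),
                            shuf(sim$cgi_intervals))
  expect_identical(pt$label, pt2$label)
  expect_identical(pt$cgi_start, pt2$cgi_start)

  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  expect_warning(pt3 <- classify_promoters(win, sim$rnf2_peaks,
                                           sim$suz12_peaks, empty),
                 "empty CGI")
  expect_true(all(pt3$label == "excluded"))
})

test_that("multi-CGI windows pick the largest intersection, leftmost on ties", {
  win <- data.frame(gene_id = "g", chrom = "chr1", start = 1000L,
                    end = 2000L, strand = "+", tss = 1500L)
  cgi <- data.frame(chrom = "chr1",
                    start = c(900L, 1400L),  # overlaps 200 vs 600
                    end = c(1200L, 2500L))
  pt <- classify_promoters(win, NULL, NULL, cgi)
  expect_equal(pt$cgi_start, 1400L)
  # exact tie in intersection length -> leftmost CGI start
  cgi_tie <- data.frame(chrom = "chr1", start = c(1600L, 1100L),
                        end = c(1900L, 1400L))  # both intersect 300
  pt_tie <- classify_promoters(win, NULL, NULL, cgi_tie)
  expect_equal(pt_tie$cgi_start, 1100L)
})

test_that("cgi_fraction reports CGI co-occurrence before the restriction", {
  win <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                    start = c(0L, 1000L, 2000L, 3000L),
                    end = c(500L, 1500L, 2500L, 3500L),
                    strand = "+", tss = c(250L, 1250L, 2250L, 3250L))
  peaks <- win[, c("chrom", "start", "end")]  # every window dual-bound
  cgi <- data.frame(chrom = "chr1", start = c(100L, 1100L, 2100L),
                    end = c(200L, 1200L, 2200L))
  pt <- classify_promoters(win, peaks, peaks, cgi, require_cgi = FALSE)
  expect_true(all(pt$label == "PcG"))
  # brute-force all-pairs overlap oracle: 3 of 4 windows hit a CGI
  expect_equal(mean(brute_any_overlap(win, cgi)), 0.75)
  expect_equal(cgi_fraction(pt, "PcG"), 75)
  expect_true(is.na(cgi_fraction(pt, "nonPcG")))

  expect_warning(
    pt0 <- classify_promoters(win, peaks, peaks,
                              data.frame(chrom = character(),
                                         start = integer(),
                                         end = integer()),
                              require_cgi = FALSE))
  expect_equal(cgi_fraction(pt0, "PcG"), 0)
})

test_that("nearest-neighbour distances match the all-pairs oracle", {
  expect_equal(nearest_neighbor_distances(c(100, 280, 470)),
               c(180, 180, 190))
  expect_equal(nearest_neighbor_distances(c(500, 740)), c(240, 240))
  expect_length(nearest_neighbor_distances(c(5)), 0)

  set.seed(101)
  for (rep in 1:10) {
    pts <- sample.int(1e6, sample(c(3, 10, 100, 1000), 1))
    expect_equal(nearest_neighbor_distances(pts), brute_nn_distances(pts))
  }
  # unsorted input: distances returned in input order
  pts <- c(470, 100, 280)
  expect_equal(nearest_neighbor_distances(pts), c(190, 180, 180))
})

test_that("BED and promoter-table round-trips preserve coordinates", {
  dir <- withr::local_tempdir()
  iv <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 500L),
                   end = c(100L, 900L), name = c("a", "b"),
                   score = c(1L, 2L), strand = c("+", "-"))
  p <- file.path(dir, "x.bed")
  write_bed(iv, p)
  expect_equal(read_bed(p), iv)

  sim <- small_sim()
  pt <- classified_promoters(sim)
  p2 <- file.path(dir, "prom.tsv")
  write_promoter_table(pt, p2)
  back <- read_promoter_table(p2)
  expect_equal(back$label, pt$label)
  expect_equal(back$cgi_start, pt$cgi_start)
})
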