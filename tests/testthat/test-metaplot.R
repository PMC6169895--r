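test_that("TSS metaplots are flat for constant signal and linear in the signal", {
  tr <- bp_track("chr1", 0, 10000, rep(3, 10000))
  prom <- data.frame(chrom = "chr1", tss = c(3000L, 6000L),
                     strand = c("+", "-"))
  p <- tss_metaplot(tr, prom, half_window = 500)
  expect_true(all(p$mean_signal == 3))
  expect_equal(p$offset, seq(-500, 499))

  tr2 <- bp_track("chr1", 0, 10000, rep(3, 10000) + 2)
  p2 <- tss_metaplot(tr2, prom, half_window = 500)
  expect_equal(p2$mean_signal, p$mean_signal + 2)
})

test_that("TSS metaplots orient minus-strand promoters and centre offsets", {
  v <- numeric(10000)
  v[3001] <- 1  # unit signal at bp 3000 (a plus-strand TSS)
  v[6101] <- 1  # unit signal at bp 6100 = minus-strand TSS + 100
  tr <- bp_track("chr1", 0, 10000, v)
  plus <- tss_metaplot(tr, data.frame(chrom = "chr1", tss = 3000L,
                                      strand = "+"), half_window = 500)
  expect_equal(plus$offset[which.max(plus$mean_signal)], 0)
  minus <- tss_metaplot(tr, data.frame(chrom = "chr1", tss = 6000L,
                                       strand = "-"), half_window = 500)
  expect_equal(minus$offset[which.max(minus$mean_signal)], -101)

  # flipping commutes with averaging: the minus-strand profile of a
  # promoter is exactly the reversed plus-strand profile
  p_plus <- tss_metaplot(tr, data.frame(chrom = "chr1", tss = 6000L,
                                        strand = "+"), half_window = 150)
  p_minus <- tss_metaplot(tr, data.frame(chrom = "chr1", tss = 6000L,
                                         strand = "-"), half_window = 150)
  expect_equal(p_minus$mean_signal, rev(p_plus$mean_signal))
})

test_that("fragment metaplots use midpoint or full-fragment coverage as requested", {
  fs <- toy_fragments(c(950), c(100))  # spans [950,1050), midpoint 1000
  prom <- data.frame(chrom = "chr1", tss = 1000L, strand = "+")
  pm <- tss_metaplot(fs, prom, half_window = 200, coverage = "midpoint")
  expect_equal(sum(pm$mean_signal), 1)
  expect_equal(pm$offset[which.max(pm$mean_signal)], 0)
  pf <- tss_metaplot(fs, prom, half_window = 200, coverage = "fragment")
  expect_equal(sum(pf$mean_signal), 100)
  expect_true(all(pf$mean_signal[pf$offset %in% -50:49] == 1))
  # window past the chromosome start is zero-padded with a note
  expect_message(tss_metaplot(fs, data.frame(chrom = "chr1", tss = 100L,
                                             strand = "+"),
                              half_window = 200),
                 "zero-padded")
})

test_that("scaled CGI metaplots are invariant to CGI length for constant signal", {
  tr <- bp_track("chr1", 0, 20000, rep(1, 20000))
  cgi <- data.frame(chrom = "chr1", start = c(2000L, 9000L),
                    end = c(2600L, 11000L))  # 600 bp and 2000 bp
  p <- scaled_cgi_metaplot(tr, cgi)
  expect_true(all(abs(p$mean_signal - 1) < 1e-9))
  expect_equal(nrow(p), 140)
  expect_equal(as.vector(table(p$region)[c("flank5", "body", "flank3")]),
               c(20L, 100L, 20L))

  # signal confined to bodies leaves flank bins at zero
  v <- numeric(20000)
  v[(2000:2599) + 1] <- 1
  v[(9000:10999) + 1] <- 1
  p2 <- scaled_cgi_metaplot(bp_track("chr1", 0, 20000, v), cgi)
  expect_true(all(p2$mean_signal[p2$region != "body"] < 1e-9))
  expect_true(all(p2$mean_signal[p2$region == "body"] > 0.99))

  # CGI shorter than body_bins -> interpolated, still constant
  tiny <- data.frame(chrom = "chr1", start = 500L, end = 550L)
  p3 <- scaled_cgi_metaplot(tr, tiny, body_bins = 100)
  expect_true(all(abs(p3$mean_signal[p3$region == "body"] - 1) < 1e-9))
})

test_that("profile maxima recover phased-array spacing from the generator", {
  # mean occupancy metaplot over many noise-free arrays, NRL 185
  # nfr_width = nrl - 146 makes the central inter-dyad gap equal the NRL,
  # giving one unbroken phased array across the TSS
  p <- promoter_class_params(nrl = 185, occupancy = 1, fuzziness_sd = 0,
                             nfr_rate = 0, depth = 30, nfr_width = 39)
  loc <- simulate_promoter(p, tss = 6000, seed = 3)
  fs <- fragment_set(loc$fragments)
  sp <- split_by_size(fs)
  r <- list(chrom = "chrS", start = 4000, end = 8000)
  occ <- occupancy_track(dyad_density(sp$mono, r), dyad_density(fs, r))
  prof <- tss_metaplot(occ, data.frame(chrom = "chrS", tss = 6000L,
                                       strand = "+"), half_window = 1500)
  mx <- profile_maxima(prof, min_separation_bins = 120, min_score = 0.2)
  expect_true(all(abs(mx$distances - 185) <= 5))
  expect_gte(length(mx$positions), 6)

  # monotone profile -> no internal maxima
  mono <- structure(data.frame(offset = 1:100, mean_signal = 1:100),
                    class = c("meta_profile", "data.frame"))
  expect_length(profile_maxima(mono)$positions, 0)

  # two equal bumps 200 bins apart
  v <- numeric(500); v[c(101, 301)] <- 1
  two <- structure(data.frame(offset = seq_len(500), mean_signal = v),
                   class = c("meta_profile", "data.frame"))
  expect_equal(profile_maxima(two, 50)$distances, 200)
})
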