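# Independent oracles used across the suite. These deliberately use naive
# O(n^2) / enumeration formulations, not the package's implementations.

# Nearest-neighbour distances by all-pairs scan.
brute_nn_distances <- function(points) {
  n <- length(points)
  vapply(seq_len(n), function(i) min(abs(points[-i] - points[i])),
         numeric(1))
}

# Intersection length of every (window, interval) pair, by plain arithmetic.
brute_any_overlap <- function(win, ivs) {
  vapply(seq_len(nrow(win)), function(i) {
    any(vapply(seq_len(nrow(ivs)), function(j) {
      win$chrom[i] == ivs$chrom[j] &&
        min(win$end[i], ivs$end[j]) - max(win$start[i], ivs$start[j]) > 0
    }, logical(1)))
  }, logical(1))
}

# Two-sided rank-sum p-value by full enumeration of label assignments.
perm_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  rk <- rank(pooled)
  n <- length(pooled)
  w_obs <- sum(rk[seq_along(a)])
  sums <- apply(utils::combn(n, length(a)), 2, function(ix) sum(rk[ix]))
  tol <- 1e-9
  min(1, 2 * min(mean(sums <= w_obs + tol), mean(sums >= w_obs - tol)))
}

# Hand-applied BH step-up: q_(i) = min_{j >= i} p_(j) * m / j.
hand_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

# Small deterministic fragment set builder.
toy_fragments <- function(starts, sizes, chrom = "chr1",
                          sample_id = "toy") {
  fragment_set(data.frame(chrom = chrom, start = starts,
                          end = starts + sizes), sample_id)
}

# Shared small simulated experiment (cached per test run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_experiment(n_per_class = 10, seed = 42)
    }
    cache
  }
})

classified_promoters <- function(sim, flank = 500) {
  win <- make_tss_windows(sim$tss_table, flank = flank)
  classify_promoters(win, sim$rnf2_peaks, sim$suz12_peaks,
                     sim$cgi_intervals)
}
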