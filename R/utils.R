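#' @importFrom stats median rnorm rpois runif dnorm pnorm sd approx p.adjust
#' @importFrom utils head tail packageVersion
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-locus child seed, kept inside 32-bit integer range.
derive_seed <- function(global_seed, index) {
  as.integer((as.numeric(global_seed) * 1000003 + as.numeric(index) * 7919) %%
               2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Convert a 0-based half-open interval data.frame (chrom, start, end) into
# GRanges (1-based closed) for overlap machinery.
as_granges0 <- function(df, start_col = "start", end_col = "end") {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df[[start_col]] + 1L, end = df[[end_col]])
  )
}

check_interval_df <- function(df, what = "interval table") {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    stop(sprintf("%s must be a data.frame with columns chrom, start, end", what))
  }
  if (nrow(df) > 0 && any(df$end <= df$start)) {
    stop(sprintf("%s contains intervals with end <= start", what))
  }
  invisible(df)
}
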