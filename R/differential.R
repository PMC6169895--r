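# Rank-based group comparisons with the FDR / fold-change significance
# thresholds used for promoter-level contrasts.

#' Two-sided rank-sum (Mann-Whitney) test
#'
#' The statistic is the sum of midranks of group `a` in the pooled sample.
#' For `n_a + n_b <= 12` the two-sided p-value is computed by exact
#' enumeration of all label arrangements (ties handled naturally through
#' midranks): `p = min(1, 2 * min(P(W <= w), P(W >= w)))`. For larger
#' samples a normal approximation with continuity correction and the
#' standard tie correction of the rank variance is used.
#'
#' @param values_a,values_b Numeric vectors (both non-empty; `NA`s removed).
#' @return List with `statistic` (rank sum of group a), `p_value`,
#'   `n_a`, `n_b`, `method`.
#' @export
rank_sum_test <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0 || n_b == 0) stop("both groups must be non-empty")
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks for ties
  w <- sum(rk[seq_len(n_a)])
  n <- n_a + n_b
  if (n <= 12) {
    combos <- utils::combn(n, n_a)
    sums <- colSums(matrix(rk[combos], nrow = n_a))
    tol <- 1e-9
    p <- min(1, 2 * min(mean(sums <= w + tol), mean(sums >= w - tol)))
    method <- "exact enumeration"
  } else {
    mu <- n_a * (n + 1) / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, n_a = n_a, n_b = n_b, method = method)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min over j >= i of (p_(j) * m / j)`, mapped back to the input
#' order (`NA`s are preserved; `m` counts non-missing p-values).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values of the same length.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Apply FDR / fold-change significance thresholds
#'
#' A change is significant when `q < fdr_threshold` and the linear fold
#' change exceeds `fc_threshold` in either direction
#' (`2^|log2fc| > fc_threshold`). The direction is `up` or `down` (sign of
#' `log2fc`) for significant calls and `none` otherwise.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param q Numeric vector of q-values.
#' @param fdr_threshold FDR cut-off (default 0.05).
#' @param fc_threshold Linear fold-change cut-off (default 1.5; use 2 for
#'   expression-style calls).
#' @param promoter_id Optional id vector carried through.
#' @return data.frame: `promoter_id`, `log2fc`, `q_value`, `significant`,
#'   `direction`.
#' @export
call_significant <- function(log2fc, q, fdr_threshold = 0.05,
                             fc_threshold = 1.5, promoter_id = NULL) {
  stopifnot(fdr_threshold > 0, fc_threshold > 0,
            length(log2fc) == length(q))
  sig <- !is.na(q) & !is.na(log2fc) & q < fdr_threshold &
    2^abs(log2fc) > fc_threshold
  direction <- rep("none", length(log2fc))
  direction[sig & log2fc > 0] <- "up"
  direction[sig & log2fc < 0] <- "down"
  data.frame(promoter_id = promoter_id %||%
               sprintf("p%d", seq_along(log2fc)),
             log2fc = log2fc, q_value = q, significant = sig,
             direction = direction, stringsAsFactors = FALSE)
}

#' Percentage of labelled promoters changing in a direction
#'
#' @param calls Output of [call_significant()].
#' @param promoter_table Output of [classify_promoters()].
#' @param label Promoter class to summarise (`"PcG"` or `"nonPcG"`).
#' @param direction `"up"` or `"down"`.
#' @return Percentage of `label` promoters whose call has the given
#'   direction, or `NA` when no promoter carries the label.
#' @export
fraction_changed <- function(calls, promoter_table, label,
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  ids <- promoter_table$gene_id[promoter_table$label == label]
  if (length(ids) == 0) return(NA_real_)
  dir_map <- stats::setNames(calls$direction, calls$promoter_id)
  100 * sum(dir_map[ids] == direction, na.rm = TRUE) / length(ids)
}

#' Rank-sum comparison of a landscape metric between promoter classes
#'
#' @param landscape A landscape or metrics table with a `label` column.
#' @param metric Column to compare.
#' @param labels Two labels to contrast (default PcG vs nonPcG).
#' @return One-row data.frame: `metric`, group sizes, medians, `statistic`,
#'   `p_value`, and `direction` (sign of the median difference, group 1
#'   relative to group 2).
#' @export
compare_classes <- function(landscape, metric,
                            labels = c("PcG", "nonPcG")) {
  stopifnot(metric %in% names(landscape), length(labels) == 2)
  va <- landscape[[metric]][landscape$label == labels[1]]
  vb <- landscape[[metric]][landscape$label == labels[2]]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  res <- rank_sum_test(va, vb)
  med_diff <- median(va) - median(vb)
  data.frame(metric = metric, group1 = labels[1], group2 = labels[2],
             n1 = res$n_a, n2 = res$n_b,
             median1 = median(va), median2 = median(vb),
             statistic = res$statistic, p_value = res$p_value,
             direction = if (med_diff > 0) "higher" else if (med_diff < 0)
               "lower" else "equal",
             stringsAsFactors = FALSE)
}
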