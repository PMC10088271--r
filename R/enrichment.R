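# Inferential summaries: Tukey upper-fence outlier detection for per-element
# PQS counts within a clade, and an exact binomial test of PQS strand
# asymmetry.

#' Tukey upper outliers of per-element PQS counts
#'
#' Quartiles are computed by linear interpolation on the order statistics
#' (the "type 7" convention: quantile q sits at position (n-1)q, linear
#' between neighbours). Elements with a count strictly above
#' `q3 + k * IQR` are flagged; a percentile rank (percent of values <= each
#' value) is reported so the flagging can be audited under other conventions.
#'
#' @param values Numeric vector of per-element counts (length >= 4).
#' @param k Fence multiplier (default 1.5).
#' @param ids Optional element ids parallel to `values`.
#' @return A list of class `"outlier_report"`: `q1`, `q3`, `iqr`,
#'   `upper_fence`, `flagged` (ids or indices), `percentile_rank`.
#' @export
tukey_upper_outliers <- function(values, k = 1.5, ids = NULL) {
  if (length(values) < 4L) {
    stop("insufficient data: need at least 4 values for quartile fences")
  }
  if (is.null(ids)) ids <- as.character(seq_along(values))
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fence <- q[2] + k * iqr
  flagged <- ids[values > fence]
  pr <- vapply(values, function(v) 100 * mean(values <= v), numeric(1))
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr, upper_fence = fence,
                 flagged = flagged,
                 percentile_rank = stats::setNames(pr, ids)),
            class = "outlier_report")
}

#' Exact binomial test of PQS strand asymmetry
#'
#' The asymmetry index is `|n_sense - n_antisense| / (n_sense + n_antisense)`
#' (1 when all PQS sit on one strand). The p-value is the exact two-sided
#' binomial probability under p = 0.5: the sum of the probabilities of all
#' outcomes no more likely than the observed count.
#'
#' @param n_sense,n_antisense Non-negative counts, not both zero.
#' @return A list with `asymmetry_index`, `p_two_sided`, `n`.
#' @export
strand_asymmetry_test <- function(n_sense, n_antisense) {
  n <- n_sense + n_antisense
  if (n < 1L) stop("strand_asymmetry_test: both counts are zero")
  list(asymmetry_index = abs(n_sense - n_antisense) / n,
       p_two_sided = stats::binom.test(n_sense, n, p = 0.5)$p.value,
       n = n)
}
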