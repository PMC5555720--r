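#' Binomial allelic score
#'
#' The allelic score is `-log10` of the two-sided binomial p-value for a
#' deviation of summed allele-resolved read counts from the balanced ratio
#' 0.5. The two-sided p-value is `min(1, 2 * P(X >= max(a, b)))` with
#' `X ~ Binomial(a + b, 0.5)`, so the score is symmetric in its arguments and
#' 0 for perfectly balanced counts.
#'
#' Computed in log space (`pbinom(..., log.p = TRUE)`), so scores remain exact
#' for arbitrarily deep coverage where the p-value itself would underflow.
#'
#' @param reads_a,reads_b Non-negative read counts for the two alleles
#'   (vectorised; recycled to common length). Each pair must have
#'   `reads_a + reads_b >= 1`.
#' @return Numeric vector of non-negative scores.
#' @examples
#' allelic_score(5, 5)   # 0: balanced
#' allelic_score(20, 0)  # 5.72: p = 2 * 0.5^20
#' @export
allelic_score <- function(reads_a, reads_b) {
  if (any(reads_a < 0 | reads_b < 0)) stop("allele read counts must be >= 0")
  n <- reads_a + reads_b
  if (any(n < 1)) stop("allelic_score undefined when both counts are zero")
  k <- pmax(reads_a, reads_b)
  log_upper <- pbinom(k - 1, n, 0.5, lower.tail = FALSE, log.p = TRUE)
  log_p2 <- pmin(0, log(2) + log_upper)
  -log_p2 / log(10)
}

#' Minimum informative SNP coverage
#'
#' The smallest total SNP coverage `n` at which a gene sitting exactly at the
#' allelic-ratio cutoff would still pass the FDR score cutoff: the smallest
#' `n` with `allelic_score(k, n - k) >= score_cutoff` for
#' `k = ceiling(ratio_cutoff * n)`. Genes with any replicate below this
#' coverage are classified not informative (NI), which ties informativeness
#' to the empirical FDR rather than to an arbitrary expression cutoff.
#'
#' @param score_cutoff Non-negative score cutoff (typically from
#'   [mock_fdr_cutoff()]). `Inf` is allowed and returns `Inf`.
#' @param ratio_cutoff Allelic-ratio cutoff in (0.5, 1].
#' @param max_n Upper bound for the coverage scan.
#' @return Integer coverage (or `Inf` if unattainable within `max_n`).
#' @export
min_informative_coverage <- function(score_cutoff, ratio_cutoff, max_n = 100000L) {
  stopifnot(length(score_cutoff) == 1L, score_cutoff >= 0,
            length(ratio_cutoff) == 1L, ratio_cutoff > 0.5, ratio_cutoff <= 1)
  if (!is.finite(score_cutoff)) return(Inf)
  if (score_cutoff <= 0) return(1L)
  ## the score at fixed ratio is not pointwise monotone in n (the rounded-up
  ## biased count jumps), so scan exhaustively in chunks
  from <- 1L
  chunk <- 4096L
  while (from <= max_n) {
    n <- from:min(max_n, from + chunk - 1L)
    k <- ceiling(ratio_cutoff * n)
    hit <- which(allelic_score(k, n - k) >= score_cutoff)
    if (length(hit)) return(n[hit[1L]])
    from <- from + chunk
  }
  Inf
}
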