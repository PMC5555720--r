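## Signed summary score over replicate columns of a signed-score matrix:
## the minimum magnitude, carrying the shared sign, when every replicate has
## the same (nonzero) direction of bias; 0 on any disagreement.
summary_score_matrix <- function(m) {
  k <- ncol(m)
  all_pos <- rowSums(m > 0) == k
  all_neg <- rowSums(m < 0) == k
  min_abs <- Reduce(pmin, lapply(seq_len(k), function(j) abs(m[, j])))
  out <- numeric(nrow(m))
  out[all_pos] <- min_abs[all_pos]
  out[all_neg] <- -min_abs[all_neg]
  out
}

## Reshape gene-replicate summaries into a genes x replicates matrix of one
## score column, with the replicate -> cross mapping attached.
score_matrix <- function(summaries, col) {
  dt <- as.data.table(summaries)
  reps <- unique(dt[, .(replicate_id, cross)])
  setorder(reps, cross, replicate_id)
  wide <- dcast(dt, gene_id ~ replicate_id, value.var = col, fill = 0)
  m <- as.matrix(wide[, reps$replicate_id, with = FALSE])
  rownames(m) <- wide$gene_id
  list(m = m, reps = reps)
}

#' Empirical FDR score cutoff from mock comparisons
#'
#' Mock comparisons estimate the null distribution of the summary allelic
#' score by relabelling the two alleles in exactly one replicate of each
#' reciprocal cross. Flipping one replicate per cross cancels both consistent
#' imprinted signal and consistent strain signal (the flipped replicate's
#' direction reverses, breaking the all-replicates agreement required for a
#' nonzero summary score), so the pooled mock summary scores behave as a null
#' cohort. All `n1 * n2` single-flip patterns are enumerated and pooled.
#'
#' The cutoff returned is the smallest observed summary score `c` such that
#'
#' `mean mock genes with |summary| >= c  /  real genes with |summary| >= c`
#'
#' is at or below `fdr_target` (mock counts averaged over flip patterns).
#' Relabelling a replicate's alleles negates its signed scores but leaves the
#' magnitudes unchanged, so the mock scores are computed directly from the
#' signed per-replicate scores.
#'
#' @param summaries Gene-replicate summaries from [aggregate_replicates()],
#'   with at least 2 replicates in each cross orientation.
#' @param fdr_target Target false discovery rate in (0, 1]; a target of 1
#'   returns cutoff 0 (everything passes).
#' @param comparison `"imprinted"` (uses `i_score`) or `"strain"`
#'   (uses `s_score`).
#' @return A single score cutoff; `Inf` when no cutoff achieves the target
#'   (e.g. a pure-null cohort) or when no gene has a nonzero real summary
#'   score.
#' @export
mock_fdr_cutoff <- function(summaries, fdr_target = 0.01,
                            comparison = c("imprinted", "strain")) {
  comparison <- match.arg(comparison)
  stopifnot(fdr_target > 0)
  if (fdr_target >= 1) return(0)

  sm <- score_matrix(summaries, if (comparison == "imprinted") "i_score" else "s_score")
  reps <- sm$reps
  by_cross <- split(seq_len(nrow(reps)), reps$cross)
  if (length(by_cross) != 2L || any(lengths(by_cross) < 2L))
    stop("mock comparisons require >= 2 replicates in each of the two cross orientations")

  real <- abs(summary_score_matrix(sm$m))
  real <- real[real > 0]
  if (!length(real)) return(Inf)

  mock <- numeric(0)
  n_pat <- 0L
  for (i in by_cross[[1L]]) {
    for (j in by_cross[[2L]]) {
      mm <- sm$m
      mm[, c(i, j)] <- -mm[, c(i, j)]
      s <- abs(summary_score_matrix(mm))
      mock <- c(mock, s[s > 0])
      n_pat <- n_pat + 1L
    }
  }

  ## candidate cutoffs: every observed real or mock summary score plus a
  ## point just above each, so the smallest admissible cutoff can sit
  ## immediately above a mock score (scores are continuous; "just above the
  ## largest mock score" is a legitimate and often optimal cutoff)
  obs <- sort(unique(c(real, mock)))
  cand <- sort(unique(c(obs, obs * (1 + 1e-9) + 1e-12)))
  real_sorted <- sort(real)
  mock_sorted <- sort(mock)
  n_ge <- function(x, cutoffs) {
    length(x) - findInterval(cutoffs, x, left.open = TRUE)
  }
  n_real <- n_ge(real_sorted, cand)
  n_mock <- n_ge(mock_sorted, cand) / n_pat
  fdr <- ifelse(n_real > 0, n_mock / n_real, Inf)
  ok <- which(fdr <= fdr_target)
  if (!length(ok)) return(Inf)
  cand[ok[1L]]
}
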