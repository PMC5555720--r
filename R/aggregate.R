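#' Aggregate SNP-level allelic counts to gene-replicate summaries
#'
#' Within each replicate, SNPs whose total coverage (both alleles summed) is
#' below `minread` are dropped; the surviving counts are summed per allele and
#' the allelic ratios and signed allelic scores computed on the sums. The
#' replicate's cross orientation maps strain counts to parental counts: in a
#' `CASTxFVB` replicate (CAST mother, maternal strain listed first) the CAST
#' reads are maternal, in `FVBxCAST` the FVB reads are.
#'
#' Two signed scores are attached to each gene-replicate: the strain-biased
#' score `s_score` (positive toward CAST, negative toward FVB) and the
#' imprinted score `i_score` (positive toward maternal, negative toward
#' paternal). Both share the magnitude [allelic_score()] of the summed counts;
#' the sign follows the direction of the corresponding ratio, and is 0 at an
#' exactly balanced ratio.
#'
#' @param counts A data frame with columns `replicate_id`, `cross`
#'   (`"CASTxFVB"` or `"FVBxCAST"`), `gene_id`, `snp_id`, `reads_CAST`,
#'   `reads_FVB`.
#' @param minread Minimum total reads covering a SNP for it to be retained
#'   (default 2).
#' @param gene_ids Optional character vector of all annotated genes; summaries
#'   with `total = 0` are emitted for gene-replicate pairs absent from
#'   `counts` (genes with no retained SNP), so every gene is represented in
#'   every replicate.
#' @return A `data.table` with one row per gene and replicate: `gene_id`,
#'   `replicate_id`, `cross`, `total`, `n_snps_retained`, `i_ratio`,
#'   `s_ratio`, `i_score`, `s_score`. Ratios are `NA` when `total = 0`.
#' @export
aggregate_replicates <- function(counts, minread = 2L, gene_ids = NULL) {
  dt <- as.data.table(counts)
  need <- c("replicate_id", "cross", "gene_id", "snp_id", "reads_CAST", "reads_FVB")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("counts is missing columns: ", paste(miss, collapse = ", "))
  if (!all(dt$cross %in% c("CASTxFVB", "FVBxCAST")))
    stop("cross must be 'CASTxFVB' or 'FVBxCAST' (maternal strain first)")
  if (minread < 1) stop("minread must be >= 1")

  dt <- dt[reads_CAST + reads_FVB >= minread]
  agg <- dt[, .(reads_CAST = sum(reads_CAST), reads_FVB = sum(reads_FVB),
                n_snps_retained = .N),
            by = .(gene_id, replicate_id, cross)]

  ## complete the gene x replicate grid with empty summaries
  reps <- unique(as.data.table(counts)[, .(replicate_id, cross)])
  genes <- unique(c(if (!is.null(gene_ids)) as.character(gene_ids),
                    as.character(counts$gene_id)))
  grid <- CJ(gene_id = genes, replicate_id = reps$replicate_id, unique = TRUE)
  grid <- merge(grid, reps, by = "replicate_id")
  agg <- merge(grid, agg, by = c("gene_id", "replicate_id", "cross"),
               all.x = TRUE)
  agg[is.na(reads_CAST), `:=`(reads_CAST = 0L, reads_FVB = 0L,
                              n_snps_retained = 0L)]

  agg[, total := reads_CAST + reads_FVB]
  agg[, s_ratio := ifelse(total > 0, reads_CAST / total, NA_real_)]
  agg[, mat_reads := ifelse(cross == "CASTxFVB", reads_CAST, reads_FVB)]
  agg[, i_ratio := ifelse(total > 0, mat_reads / total, NA_real_)]
  mag <- rep(0, nrow(agg))
  pos <- agg$total > 0
  mag[pos] <- allelic_score(agg$reads_CAST[pos], agg$reads_FVB[pos])
  agg[, s_score := ifelse(is.na(s_ratio), 0, sign(s_ratio - 0.5)) * mag]
  agg[, i_score := ifelse(is.na(i_ratio), 0, sign(i_ratio - 0.5)) * mag]
  agg[, mat_reads := NULL]
  setkey(agg, gene_id, replicate_id)
  agg[, .(gene_id, replicate_id, cross, total, n_snps_retained,
          i_ratio, s_ratio, i_score, s_score)]
}
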