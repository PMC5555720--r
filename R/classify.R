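#' Classification settings
#'
#' Bundles the tunable parameters of the allelic classification: the target
#' empirical FDR for the mock-comparison score cutoff, the allelic-ratio
#' cutoff a monoallelic call must reach, and the minimum reads covering a SNP
#' for it to be retained. The derived quantities (score cutoffs per
#' comparison, minimum informative coverage) are filled in by
#' [allelome_classify()].
#'
#' @param fdr_target Target FDR in (0, 1) (default 0.01).
#' @param ratio_cutoff Median allelic-ratio cutoff in (0.5, 1] (default 0.7;
#'   0.6 is used for the XCI escaper analysis).
#' @param minread Minimum SNP coverage within a replicate (default 2).
#' @return An object of class `allelome_config`.
#' @export
allelome_config <- function(fdr_target = 0.01, ratio_cutoff = 0.7, minread = 2L) {
  if (!is.numeric(fdr_target) || fdr_target <= 0 || fdr_target >= 1)
    stop("fdr_target must be in (0, 1)")
  if (!is.numeric(ratio_cutoff) || ratio_cutoff <= 0.5 || ratio_cutoff > 1)
    stop("ratio_cutoff must be in (0.5, 1]")
  if (!is.numeric(minread) || minread < 1)
    stop("minread must be >= 1")
  structure(list(fdr_target = fdr_target, ratio_cutoff = ratio_cutoff,
                 minread = as.integer(minread),
                 score_cutoff_i = NULL, score_cutoff_s = NULL,
                 min_informative_coverage = NULL),
            class = "allelome_config")
}

## Decide one category per gene from replicate matrices. Imprinted
## classification is evaluated before strain classification; a gene meeting
## neither is biallelic (BAE) when informative.
classify_matrixwise <- function(mats, n_snps, config) {
  n_gene <- nrow(mats$i_score)
  category <- rep("BAE", n_gene)
  k <- ncol(mats$i_score)

  med_i <- apply(mats$i_ratio, 1L, median)
  med_s <- apply(mats$s_ratio, 1L, median)
  sum_i <- summary_score_matrix(mats$i_score)
  sum_s <- summary_score_matrix(mats$s_score)

  informative <- rowSums(mats$total >= config$min_informative_coverage) == k

  imp_pass <- abs(sum_i) >= config$score_cutoff_i & sum_i != 0 &
    ifelse(sum_i > 0, med_i, 1 - med_i) >= config$ratio_cutoff
  str_pass <- abs(sum_s) >= config$score_cutoff_s & sum_s != 0 &
    ifelse(sum_s > 0, med_s, 1 - med_s) >= config$ratio_cutoff

  category[informative & str_pass] <-
    ifelse(sum_s[informative & str_pass] > 0, "CAST", "FVB")
  category[informative & imp_pass] <-
    ifelse(sum_i[informative & imp_pass] > 0, "MAT", "PAT")
  category[!informative] <- "NI"
  category[n_snps == 0L] <- "NS"

  data.table(gene_id = rownames(mats$i_score), category = category,
             median_i_ratio = ifelse(category %in% c("NS", "NI"), NA_real_, med_i),
             median_s_ratio = ifelse(category %in% c("NS", "NI"), NA_real_, med_s),
             summary_i_score = ifelse(category %in% c("NS", "NI"), 0, sum_i),
             summary_s_score = ifelse(category %in% c("NS", "NI"), 0, sum_s))
}

#' Classify biallelic genes into subtypes
#'
#' Splits biallelic (BAE) genes by the behaviour of their per-replicate
#' strain ratios relative to the ratio cutoff: a consistent strain direction
#' with every replicate's biased-allele ratio below the cutoff
#' (`consistent_below_cutoff`), fluctuating direction with at least one
#' replicate at or above the cutoff (`fluctuating_above_cutoff`), or
#' fluctuating below it (`fluctuating_below_cutoff`).
#'
#' @param s_ratios Numeric vector (or matrix rows = genes) of per-replicate
#'   CAST ratios of a BAE gene.
#' @param ratio_cutoff Allelic-ratio cutoff (default 0.7).
#' @return Character subtype (vector if `s_ratios` is a matrix).
#' @export
classify_biallelic_subtype <- function(s_ratios, ratio_cutoff = 0.7) {
  if (is.matrix(s_ratios)) {
    return(apply(s_ratios, 1L, classify_biallelic_subtype,
                 ratio_cutoff = ratio_cutoff))
  }
  dir <- sign(s_ratios - 0.5)
  biased <- pmax(s_ratios, 1 - s_ratios)
  consistent <- all(dir == dir[1L]) && dir[1L] != 0
  if (consistent && all(biased < ratio_cutoff)) return("consistent_below_cutoff")
  if (!consistent && any(biased >= ratio_cutoff)) return("fluctuating_above_cutoff")
  "fluctuating_below_cutoff"
}

#' Classify genes into allelic expression categories
#'
#' The central operation: every annotated gene in a tissue is assigned exactly
#' one of seven categories. `NS` (no SNPs) when the gene carries no SNP; `NI`
#' (not informative) when any replicate's retained SNP coverage is below the
#' minimum informative coverage; `MAT`/`PAT` (imprinted) when all replicates
#' agree in the maternal/paternal direction, every replicate's imprinted
#' score passes the FDR cutoff, and the median allelic ratio toward that
#' allele is at or above the ratio cutoff; `CAST`/`FVB` (strain-biased)
#' analogously on the strain scores; `BAE` (biallelic) otherwise. Imprinted
#' classification takes precedence over strain classification.
#'
#' Summary scores follow the minimum-of-replicates rule: the smallest
#' replicate score magnitude with the shared sign when all replicates agree
#' in direction, 0 on any disagreement, so at most one of the two summary
#' scores is nonzero.
#'
#' @param summaries Gene-replicate summaries from [aggregate_replicates()].
#' @param config An [allelome_config()] whose derived fields
#'   (`score_cutoff_i`, `score_cutoff_s`, `min_informative_coverage`) are set.
#' @param n_snps Named integer vector: number of annotated SNPs per gene
#'   (genes with 0 become `NS`). Genes absent from `summaries` but named here
#'   are classified as well.
#' @param tissue Optional tissue label carried into the output.
#' @return `data.table` of allelic calls: `gene_id`, `tissue`, `category`,
#'   median ratios, summary scores, `biallelic_subtype`, `n_snps`.
#' @export
classify_genes <- function(summaries, config, n_snps, tissue = NA_character_) {
  stopifnot(inherits(config, "allelome_config"),
            !is.null(config$score_cutoff_i), !is.null(config$score_cutoff_s),
            !is.null(config$min_informative_coverage))
  dt <- as.data.table(summaries)
  n_reps <- uniqueN(dt$replicate_id)
  cnt <- dt[, .N, by = gene_id]
  if (any(cnt$N != n_reps))
    stop("every gene must appear in every replicate; run aggregate_replicates with gene_ids")

  cols <- c("i_score", "s_score", "i_ratio", "s_ratio", "total")
  mats <- lapply(setNames(cols, cols), function(cl) {
    sm <- score_matrix(dt, cl)$m
    if (cl %in% c("i_ratio", "s_ratio")) sm[is.na(sm)] <- 0.5
    sm
  })
  ## ratios of empty replicates are undefined; 0.5 keeps median math neutral,
  ## and such genes are NI regardless

  ids <- rownames(mats$i_score)
  ns <- rep(0L, length(ids))
  if (!is.null(n_snps)) {
    ns <- as.integer(n_snps[ids])
    ns[is.na(ns)] <- 0L
  }
  calls <- classify_matrixwise(mats, ns, config)
  calls[, n_snps := ns]
  calls[, tissue := tissue]

  sub <- rep("n/a", nrow(calls))
  is_bae <- calls$category == "BAE"
  if (any(is_bae)) {
    sub[is_bae] <- classify_biallelic_subtype(
      mats$s_ratio[is_bae, , drop = FALSE], config$ratio_cutoff)
  }
  calls[, biallelic_subtype := sub]
  setcolorder(calls, c("gene_id", "tissue", "category"))
  calls[]
}

#' Run the full allelic classification on one tissue
#'
#' Convenience wrapper chaining the stages: aggregate SNP counts to
#' gene-replicate summaries, derive the empirical FDR score cutoffs for the
#' imprinted and strain comparisons by mock relabelling, derive the minimum
#' informative coverage from the stricter of the two cutoffs at the ratio
#' cutoff, and classify every gene.
#'
#' @param counts SNP-level allelic counts (see [aggregate_replicates()]).
#' @param snps Optional SNP table with columns `gene_id`, `snp_id`; used to
#'   count SNPs per gene (`NS` detection). When `NULL`, all genes in `counts`
#'   are assumed to carry SNPs.
#' @param gene_ids All annotated genes (defaults to the genes in `snps`
#'   or `counts`). Genes without SNPs are classified `NS`.
#' @param config An [allelome_config()].
#' @param tissue Optional tissue label.
#' @return List of class `allelome_result`: `calls`, `summaries`, and the
#'   `config` with derived cutoffs filled in.
#' @export
allelome_classify <- function(counts, snps = NULL, gene_ids = NULL,
                              config = allelome_config(), tissue = NA_character_) {
  if (is.null(gene_ids)) {
    gene_ids <- if (!is.null(snps)) unique(c(as.character(snps$gene_id),
                                             as.character(counts$gene_id)))
    else unique(as.character(counts$gene_id))
  }
  summ <- aggregate_replicates(counts, minread = config$minread,
                               gene_ids = gene_ids)
  config$score_cutoff_i <- mock_fdr_cutoff(summ, config$fdr_target, "imprinted")
  config$score_cutoff_s <- mock_fdr_cutoff(summ, config$fdr_target, "strain")
  ## informativeness must not depend on the direction examined: derive the
  ## coverage bar from the stricter (larger) of the two cutoffs. An infinite
  ## cutoff means that comparison can produce no calls at all (e.g. no
  ## imprinted signal on a skewed X); it must not render every gene NI, so
  ## only finite cutoffs enter the coverage bar.
  finite_cut <- Filter(is.finite, list(config$score_cutoff_i,
                                       config$score_cutoff_s))
  config$min_informative_coverage <- if (length(finite_cut))
    min_informative_coverage(max(unlist(finite_cut)), config$ratio_cutoff)
  else Inf

  n_snps <- if (!is.null(snps)) {
    tab <- table(factor(as.character(snps$gene_id), levels = gene_ids))
    setNames(as.integer(tab), gene_ids)
  } else {
    setNames(rep(1L, length(gene_ids)), gene_ids)
  }
  calls <- classify_genes(summ, config, n_snps, tissue = tissue)
  structure(list(calls = calls, summaries = summ, config = config),
            class = "allelome_result")
}

#' @export
print.allelome_result <- function(x, ...) {
  cat("Allelic classification", if (!is.na(x$calls$tissue[1L]))
    paste0("(", x$calls$tissue[1L], ")"), "\n")
  cat(sprintf("  %d genes | score cutoffs i=%.3g s=%.3g | min coverage %s | ratio cutoff %.2f\n",
              nrow(x$calls), x$config$score_cutoff_i, x$config$score_cutoff_s,
              format(x$config$min_informative_coverage), x$config$ratio_cutoff))
  print(x$calls[, .N, by = category][order(-N)])
  invisible(x)
}
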