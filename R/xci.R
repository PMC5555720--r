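#' XCI context for a tissue
#'
#' The expected direction of X inactivation in a female tissue: under skewed
#' random XCI in CAST/FVB F1 mice the FVB X is preferentially inactivated, so
#' informative X-linked genes are expected CAST-biased (allelic ratio around
#' 0.7); in extra-embryonic tissues XCI is imprinted (paternal X silenced),
#' so genes are expected maternally expressed (ratio near 1).
#'
#' @param tissue Tissue label.
#' @param xci_mode `"random_skewed"` or `"imprinted"`.
#' @param ratio_cutoff Allelic-ratio cutoff used for the escaper analysis
#'   (default 0.6, more stringent for calling biallelic escapers than the
#'   0.7 used elsewhere).
#' @return Object of class `xci_context` with the implied
#'   `expected_category` (`CAST` or `MAT`).
#' @export
xci_context <- function(tissue, xci_mode = c("random_skewed", "imprinted"),
                        ratio_cutoff = 0.6) {
  xci_mode <- match.arg(xci_mode)
  structure(list(tissue = tissue, xci_mode = xci_mode,
                 expected_category = if (xci_mode == "imprinted") "MAT" else "CAST",
                 ratio_cutoff = ratio_cutoff),
            class = "xci_context")
}

#' Call X-inactivation escapers
#'
#' Partitions informative X-linked genes of one female tissue into escapers
#' and non-escapers given the tissue's XCI context. A gene whose category
#' equals the expected bias (`CAST` under skewed random XCI, `MAT` under
#' imprinted XCI) is a non-escaper. A gene is excluded — rather than called
#' an escaper — when it was classified biallelic although all replicates
#' showed the expected direction of bias and the median ratio toward the
#' expected allele is at or above the cutoff: such genes failed only the FDR
#' score cutoff through low expression, and excluding them avoids an
#' arbitrary expression cutoff. Every other informative gene escapes:
#' genuinely biallelic genes and genes with an unexpected bias (opposite
#' strain, opposite parent — as Xist itself, paternally expressed under
#' imprinted XCI). `NI`/`NS` genes pass through as `not_informative`.
#'
#' @param result An `allelome_result` from [allelome_classify()] run on chrX
#'   genes with the context's ratio cutoff, or its `calls` plus `summaries`.
#' @param context An [xci_context()].
#' @param chrom Optional named chromosome vector for the genes; when
#'   supplied, non-chrX genes raise an error.
#' @return `data.table`: `gene_id`, `tissue`, `status`
#'   (`escaper`/`non_escaper`/`excluded`/`not_informative`),
#'   `observed_category`, `median_expected_ratio`.
#' @export
call_escapers <- function(result, context, chrom = NULL) {
  stopifnot(inherits(context, "xci_context"))
  calls <- as.data.table(result$calls)
  summaries <- as.data.table(result$summaries)
  if (!is.null(chrom)) {
    bad <- names(chrom)[chrom != "chrX" & names(chrom) %in% calls$gene_id]
    if (length(bad))
      stop("escaper calling is X-only; autosomal gene(s) supplied: ",
           paste(head(bad, 5L), collapse = ", "))
  }

  expected <- context$expected_category
  ratio_col <- if (expected == "MAT") "i_ratio" else "s_ratio"
  med_col <- if (expected == "MAT") "median_i_ratio" else "median_s_ratio"

  ## per-gene: do all replicates lean in the expected direction?
  dir <- summaries[, .(all_expected = all(get(ratio_col) > 0.5) && .N > 0,
                       n_rep = .N), by = gene_id]
  calls <- merge(calls, dir, by = "gene_id", all.x = TRUE)

  calls[, status := "escaper"]
  calls[category == expected, status := "non_escaper"]
  calls[category == "BAE" & all_expected == TRUE &
          get(med_col) >= context$ratio_cutoff, status := "excluded"]
  calls[category %in% c("NI", "NS"), status := "not_informative"]
  med_exp <- calls[[med_col]]
  out <- calls[, .(gene_id, tissue = context$tissue, status,
                   observed_category = category,
                   median_expected_ratio = med_exp)]
  setorder(out, gene_id)
  out[]
}

#' Summarise escaper calls for one tissue
#'
#' Percent escaping is computed over informative genes only
#' (escapers / (escapers + non-escapers), one decimal); excluded and
#' non-informative genes do not enter the denominator. Optionally split by
#' gene biotype (protein-coding vs non-coding).
#'
#' @param escaper_calls Output of [call_escapers()].
#' @param biotype Optional named character vector (`pc`/`nc`) per gene.
#' @return `data.table` with `group`, `n_escaper`, `n_non_escaper`,
#'   `n_informative`, `pct_escaping` (NA when no informative genes).
#' @export
escaper_summary <- function(escaper_calls, biotype = NULL) {
  dt <- as.data.table(escaper_calls)
  dt[, group := if (is.null(biotype)) "all" else
    unname(biotype[gene_id])]
  smry <- dt[, .(n_escaper = sum(status == "escaper"),
                 n_non_escaper = sum(status == "non_escaper")),
             by = group]
  smry[, n_informative := n_escaper + n_non_escaper]
  smry[, pct_escaping := ifelse(n_informative > 0,
                                round(100 * n_escaper / n_informative, 1),
                                NA_real_)]
  smry[]
}

#' Escaper overlap between two tissues or datasets
#'
#' @param escapers_a,escapers_b Character vectors of escaping gene ids.
#' @return List: `n_both`, `n_a`, `n_b`, `n_either`, and `pct_of_a`
#'   (`100 * |A n B| / |A|`, rounded to integer; NA when A is empty).
#' @export
overlap_stats <- function(escapers_a, escapers_b) {
  a <- unique(as.character(escapers_a))
  b <- unique(as.character(escapers_b))
  n_both <- length(intersect(a, b))
  list(n_both = n_both, n_a = length(a), n_b = length(b),
       n_either = length(union(a, b)),
       pct_of_a = if (length(a)) round(100 * n_both / length(a)) else NA_real_)
}

#' Count tissues in which each gene escapes
#'
#' Supports ubiquitous-vs-tissue-specific tallies (e.g. how many genes
#' escape in a single tissue vs in all tissues).
#'
#' @param escaper_sets Named list of per-tissue escaping gene-id vectors.
#' @return `data.table`: `gene_id`, `n_tissues`.
#' @export
count_escape_tissues <- function(escaper_sets) {
  all_ids <- unlist(lapply(escaper_sets, unique))
  if (!length(all_ids))
    return(data.table(gene_id = character(), n_tissues = integer()))
  dt <- data.table(gene_id = all_ids)[, .(n_tissues = .N), by = gene_id]
  setorder(dt, -n_tissues, gene_id)
  dt[]
}

#' Percent escaping by expression bin
#'
#' Normalisation control: bins informative X-linked genes by expression level
#' and reports the percent escaping within each bin, so an excess of escapers
#' among lowly expressed genes can be distinguished from a detection
#' artifact.
#'
#' @param escaper_calls Output of [call_escapers()].
#' @param expression Named numeric vector of expression levels per gene.
#' @param n_bins Number of equal-occupancy bins (default 5).
#' @return `data.table`: `bin`, `n_informative`, `n_escaper`, `pct_escaping`.
#' @export
escaper_by_expression <- function(escaper_calls, expression, n_bins = 5L) {
  dt <- as.data.table(escaper_calls)[status %in% c("escaper", "non_escaper")]
  dt[, expr := unname(expression[gene_id])]
  dt <- dt[!is.na(expr)]
  if (!nrow(dt)) return(data.table(bin = integer(), n_informative = integer(),
                                   n_escaper = integer(), pct_escaping = numeric()))
  qs <- unique(quantile(dt$expr, probs = seq(0, 1, length.out = n_bins + 1L)))
  dt[, bin := cut(expr, breaks = qs, labels = FALSE, include.lowest = TRUE)]
  out <- dt[, .(n_informative = .N, n_escaper = sum(status == "escaper")),
            by = bin]
  out[, pct_escaping := round(100 * n_escaper / n_informative, 1)]
  setorder(out, bin)
  out[]
}
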