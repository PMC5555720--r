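#' Classify genes separately on exonic and intronic SNPs
#'
#' Intronic reads report the nascent transcript, exonic reads the mature
#' one: a gene transcribed equally from both alleles but degraded
#' allele-specifically shows a biallelic intron call and a biased exon call.
#' Runs the full classification twice, restricted to each SNP subset, with
#' the same configuration.
#'
#' @param counts SNP-level allelic counts.
#' @param snps SNP table with a `region` column (`exonic`/`intronic`).
#' @param gene_ids All annotated genes.
#' @param config An [allelome_config()].
#' @param tissue Optional tissue label.
#' @return List with `exon` and `intron` `allelome_result`s.
#' @export
split_region_calls <- function(counts, snps, gene_ids = NULL,
                               config = allelome_config(),
                               tissue = NA_character_) {
  snps <- as.data.table(snps)
  cts <- as.data.table(counts)
  if (is.null(gene_ids)) gene_ids <- unique(as.character(snps$gene_id))
  run <- function(reg) {
    sub <- snps[region == reg]
    allelome_classify(cts[snp_id %in% sub$snp_id], snps = sub,
                      gene_ids = gene_ids, config = config, tissue = tissue)
  }
  list(exon = run("exonic"), intron = run("intronic"))
}

#' Attribute strain bias to a transcriptional or post-transcriptional cause
#'
#' For genes strain-biased at the whole-gene level, contrasts the intron-only
#' and exon-only classifications with the allelic status of the promoter
#' H3K4me3 mark. Biallelic promoter enrichment with biallelic introns but
#' strain-biased exons indicates a post-transcriptional cause (equal
#' transcription, allele-specific transcript fate); monoallelic promoter
#' enrichment matching the expression bias with the same bias in introns and
#' exons indicates a transcriptional cause. Everything else — including an
#' absent or mismatching promoter call — is reported as ambiguous. Genes not
#' classified BAE or strain-biased in both SNP subsets are dropped.
#'
#' @param whole_calls Whole-gene calls (`gene_id`, `category`), typically
#'   restricted downstream to `CAST`/`FVB` genes.
#' @param exon_calls,intron_calls Calls from [split_region_calls()].
#' @param promoter Data frame `gene_id`, `category` of promoter H3K4me3
#'   peaks (`BAE` or an allele); genes without a row are `absent`.
#' @return `data.table`: `gene_id`, `promoter_status`, `intron_category`,
#'   `exon_category`, `intron_ratio`, `exon_ratio`, `mechanism`
#'   (`transcriptional`/`post_transcriptional`/`ambiguous`), `dropped_reason`
#'   (NA for mechanism-called genes).
#' @export
classify_mechanism <- function(whole_calls, exon_calls, intron_calls,
                               promoter) {
  wc <- as.data.table(whole_calls)[category %in% c("CAST", "FVB")]
  ex <- as.data.table(exon_calls$calls)
  int <- as.data.table(intron_calls$calls)
  prom <- as.data.table(promoter)

  dt <- merge(wc[, .(gene_id, whole = category)],
              ex[, .(gene_id, exon_category = category,
                     exon_ratio = median_s_ratio)], by = "gene_id")
  dt <- merge(dt, int[, .(gene_id, intron_category = category,
                          intron_ratio = median_s_ratio)], by = "gene_id")
  dt <- merge(dt, prom[, .(gene_id, prom_cat = category)],
              by = "gene_id", all.x = TRUE)

  dt[, promoter_status := fcase(
    is.na(prom_cat), "absent",
    prom_cat == "BAE", "biallelic",
    prom_cat == whole, "monoallelic_matching",
    default = "monoallelic_mismatching")]

  ok <- c("BAE", "CAST", "FVB")
  dt[, dropped_reason := fcase(
    !(exon_category %in% ok) & !(intron_category %in% ok),
    "uninformative in exons and introns",
    !(exon_category %in% ok), "uninformative in exons",
    !(intron_category %in% ok), "uninformative in introns",
    default = NA_character_)]

  dt[, mechanism := NA_character_]
  callable <- is.na(dt$dropped_reason)
  dt[callable, mechanism := fcase(
    promoter_status == "biallelic" & intron_category == "BAE" &
      exon_category == whole, "post_transcriptional",
    promoter_status == "monoallelic_matching" & intron_category == whole &
      exon_category == whole, "transcriptional",
    default = "ambiguous")]
  dt[, .(gene_id, promoter_status, intron_category, exon_category,
         intron_ratio, exon_ratio, mechanism, dropped_reason)]
}
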