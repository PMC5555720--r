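#' Write a simulated experiment to disk
#'
#' Standard plain-text formats: the annotation as GTF (gene and exon
#' features) and BED6, SNPs and replicate counts as TSV, the truth table as
#' TSV, and (when present) ChIP windows as BED plus a counts TSV.
#'
#' @param sim An `allelome_sim` from [simulate_allelome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_simulated_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- sim$annotation$genes
  exons <- sim$annotation$exons
  files <- character()

  put <- function(x, name) {
    f <- file.path(dir, name)
    fwrite(x, f, sep = "\t")
    files <<- c(files, f)
  }

  ## GTF via rtracklayer (1-based closed on export)
  exons2 <- merge(exons, genes[, .(gene_id, chrom, strand)], by = "gene_id")
  gr_gene <- gr0(genes$chrom, genes$start, genes$end)
  S4Vectors::mcols(gr_gene) <- S4Vectors::DataFrame(
    source = "allelome_sim", type = "gene", gene_id = genes$gene_id,
    gene_biotype = genes$biotype)
  GenomicRanges::strand(gr_gene) <- genes$strand
  gr_ex <- gr0(exons2$chrom, exons2$start, exons2$end)
  S4Vectors::mcols(gr_ex) <- S4Vectors::DataFrame(
    source = "allelome_sim", type = "exon", gene_id = exons2$gene_id,
    gene_biotype = NA_character_)
  GenomicRanges::strand(gr_ex) <- exons2$strand
  gtf <- file.path(dir, "annotation.gtf")
  rtracklayer::export(c(gr_gene, gr_ex), gtf, format = "gtf")
  files <- c(files, gtf)

  bed <- file.path(dir, "annotation.bed")
  gr_bed <- gr_gene
  names(gr_bed) <- genes$gene_id
  rtracklayer::export(gr_bed, bed, format = "bed")
  files <- c(files, bed)

  put(sim$snps, "snps.tsv")
  put(sim$counts, "counts.tsv")
  put(sim$truth, "truth.tsv")
  if (!is.null(sim$anchors) && nrow(sim$anchors)) put(sim$anchors, "anchors.tsv")

  if (!is.null(sim$chip)) {
    wbed <- file.path(dir, "chip_windows.bed")
    w <- sim$chip$windows
    grw <- gr0(w$chrom, w$start, w$end)
    names(grw) <- w$window_id
    rtracklayer::export(grw, wbed, format = "bed")
    files <- c(files, wbed)
    put(w, "chip_windows.tsv")
    put(sim$chip$promoter_peaks, "promoter_peaks.tsv")
  }
  invisible(files)
}

#' Read SNP-level allelic counts
#'
#' @param path TSV with columns `replicate_id`, `cross`, `gene_id`,
#'   `snp_id`, `reads_CAST`, `reads_FVB` (the schema written by
#'   [write_simulated_data()]; real data in the same schema is accepted).
#' @return `data.table` of counts.
#' @export
read_allelic_counts <- function(path) {
  dt <- fread(path)
  need <- c("replicate_id", "cross", "gene_id", "snp_id",
            "reads_CAST", "reads_FVB")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop(path, " is missing columns: ",
                         paste(miss, collapse = ", "))
  dt
}

#' Write per-tissue allelic calls
#'
#' @param result An `allelome_result`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_allelic_calls <- function(result, path) {
  calls <- copy(as.data.table(result$calls))
  calls[, min_coverage_used := result$config$min_informative_coverage]
  fwrite(calls, path, sep = "\t")
  invisible(path)
}
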