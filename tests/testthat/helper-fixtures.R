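## Shared fixture builders. Everything is generated in code; deterministic
## builders give rule-forced expectations, the seeded simulator gives
## statistical cohorts.

## Deterministic SNP-level counts for a hand-specified cohort.
## genes: data.frame(gene_id, type ("BAE"|"CAST"|"FVB"|"MAT"|"PAT"),
##        ratio (toward the favoured allele), n_exonic, n_intronic, cov)
## Four replicates, two per cross; counts are expected values (rounded), so
## scores are exact functions of the design.
det_counts <- function(genes, jitter = NULL) {
  genes <- as.data.frame(genes)
  if (is.null(genes$n_exonic)) genes$n_exonic <- 2L
  if (is.null(genes$n_intronic)) genes$n_intronic <- 0L
  if (is.null(genes$cov)) genes$cov <- 100L
  reps <- data.frame(replicate_id = c("CxF_rep1", "CxF_rep2", "FxC_rep1", "FxC_rep2"),
                     cross = rep(c("CASTxFVB", "FVBxCAST"), each = 2L))
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    n_snp <- g$n_exonic + g$n_intronic
    if (n_snp == 0L) next
    snp_ids <- paste0(g$gene_id, "_s", seq_len(n_snp))
    for (j in seq_len(nrow(reps))) {
      cast_frac <- switch(g$type,
        BAE = 0.5,
        CAST = g$ratio, FVB = 1 - g$ratio,
        MAT = if (reps$cross[j] == "CASTxFVB") g$ratio else 1 - g$ratio,
        PAT = if (reps$cross[j] == "CASTxFVB") 1 - g$ratio else g$ratio)
      cast <- round(cast_frac * g$cov)
      if (!is.null(jitter)) cast <- pmax(0L, pmin(g$cov, cast + jitter[[j]]))
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = reps$replicate_id[j], cross = reps$cross[j],
        gene_id = g$gene_id, snp_id = snp_ids,
        reads_CAST = as.integer(cast), reads_FVB = as.integer(g$cov - cast))
    }
  }
  do.call(rbind, rows)
}

## SNP table matching det_counts (exonic SNPs first, then intronic)
det_snps <- function(genes) {
  genes <- as.data.frame(genes)
  if (is.null(genes$n_exonic)) genes$n_exonic <- 2L
  if (is.null(genes$n_intronic)) genes$n_intronic <- 0L
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    n_snp <- g$n_exonic + g$n_intronic
    if (n_snp == 0L) return(NULL)
    data.frame(snp_id = paste0(g$gene_id, "_s", seq_len(n_snp)),
               chrom = "chr1", pos = seq_len(n_snp) * 100L,
               gene_id = g$gene_id,
               region = rep(c("exonic", "intronic"),
                            c(g$n_exonic, g$n_intronic)),
               CAST_allele = "A", FVB_allele = "G")
  })
  do.call(rbind, rows)
}

## A noisy null background plus a few strong signal genes, so mock-FDR
## cutoffs are finite and realistic in rule-level tests.
noisy_cohort <- function(n_null = 200L, seed = 42L, cov = 100L) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    reps <- data.frame(replicate_id = c("CxF_rep1", "CxF_rep2", "FxC_rep1", "FxC_rep2"),
                       cross = rep(c("CASTxFVB", "FVBxCAST"), each = 2L))
    rows <- lapply(seq_len(n_null), function(i) {
      do.call(rbind, lapply(seq_len(4L), function(j) {
        cast <- rbinom(2L, cov, 0.5)
        data.frame(replicate_id = reps$replicate_id[j], cross = reps$cross[j],
                   gene_id = sprintf("null%04d", i),
                   snp_id = sprintf("null%04d_s%d", i, 1:2),
                   reads_CAST = cast, reads_FVB = cov - cast)
      }))
    })
    do.call(rbind, rows)
  })
}

## Escaper-call table with a given composition (for summary arithmetic)
esc_fixture <- function(n_escaper, n_non_escaper, n_excluded = 0L,
                        n_not_informative = 0L, tissue = "t") {
  status <- rep(c("escaper", "non_escaper", "excluded", "not_informative"),
                c(n_escaper, n_non_escaper, n_excluded, n_not_informative))
  data.frame(gene_id = sprintf("g%04d", seq_along(status)), tissue = tissue,
             status = status, observed_category = "BAE",
             median_expected_ratio = 0.5)
}
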