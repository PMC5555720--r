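#' Reads per kilobase per million mapped reads
#'
#' @param counts Read counts (vector or matrix, genes x samples).
#' @param gene_length Gene lengths in bp.
#' @param total_mapped Total mapped reads per sample.
#' @return RPKM values, `counts * 1e9 / (gene_length * total_mapped)`.
#' @export
rpkm <- function(counts, gene_length, total_mapped) {
  counts * 1e9 / (gene_length * total_mapped)
}

#' Maternal-contamination screen for placental candidates
#'
#' Maternal decidua, blood and blood vessels 'contaminate' dissected
#' placenta, so a maternally expressed placenta-restricted candidate may be
#' maternal tissue rather than imprinted expression. The candidate is
#' flagged when mean decidua RPKM exceeds mean placenta RPKM more than
#' `ratio_cutoff`-fold (default 5), or when the gene is blood-specific.
#'
#' @param decidua_rpkm,placenta_rpkm Replicate RPKM vectors.
#' @param blood_specific Is the gene expressed specifically in blood?
#' @param ratio_cutoff Decidua/placenta ratio above which the candidate is
#'   flagged.
#' @return List: `flagged`, `ratio` (decidua/placenta, `Inf` when placenta
#'   is silent), `log2_ratio`.
#' @export
contamination_screen <- function(decidua_rpkm, placenta_rpkm,
                                 blood_specific = FALSE, ratio_cutoff = 5) {
  d <- mean(decidua_rpkm)
  p <- mean(placenta_rpkm)
  ratio <- if (p > 0) d / p else Inf
  list(flagged = ratio > ratio_cutoff || isTRUE(blood_specific),
       ratio = ratio, log2_ratio = log2(ratio))
}

#' Embryo-transfer check for maternal imprinted expression
#'
#' In the embryo-transfer design, CAST(mother) x FVB(father) blastocysts
#' develop in an FVB host mother: true maternal imprinted expression keeps
#' its CAST bias, while transcripts from maternal host tissue carry the
#' host's FVB alleles. The design has a single cross orientation, so only
#' the strain direction is interpretable.
#'
#' @param counts Per-replicate allelic counts: data frame with `reads_CAST`,
#'   `reads_FVB` (one row per replicate), pre-summed over the gene's SNPs.
#' @param ratio_cutoff Allelic-ratio cutoff (default 0.7).
#' @param score_cutoff Per-replicate allelic-score cutoff (default 2).
#' @param min_coverage Minimum per-replicate coverage to be informative.
#' @return List with `verdict` (`maternal_confirmed` / `contamination` /
#'   `supportive_below_cutoff` / `not_informative`) and `median_cast_ratio`.
#' @export
embryo_transfer_check <- function(counts, ratio_cutoff = 0.7,
                                  score_cutoff = 2, min_coverage = 12L) {
  dt <- as.data.table(counts)
  tot <- dt$reads_CAST + dt$reads_FVB
  if (any(tot < min_coverage))
    return(list(verdict = "not_informative", median_cast_ratio = NA_real_))
  ratio <- dt$reads_CAST / tot
  med <- median(ratio)
  scores <- allelic_score(dt$reads_CAST, dt$reads_FVB)
  pass <- all(scores >= score_cutoff)
  verdict <- if (med >= ratio_cutoff && pass && all(ratio > 0.5)) {
    "maternal_confirmed"
  } else if ((1 - med) >= ratio_cutoff && pass && all(ratio < 0.5)) {
    "contamination"
  } else if (med > 0.5) {
    "supportive_below_cutoff"
  } else {
    "not_informative"
  }
  list(verdict = verdict, median_cast_ratio = med)
}

#' Differential expression by Welch t-test on log2(RPKM + 1)
#'
#' A self-contained two-group test used where the study design compares
#' expression between genotypes (e.g. wild type vs an imprint-control-
#' element deletion): per-gene Welch t-test on log2(RPKM + 1) with
#' Benjamini-Hochberg adjustment across genes.
#'
#' @param rpkm_a,rpkm_b Matrices (genes x replicates) of RPKM, same genes in
#'   the same order, >= 2 replicates each.
#' @return `data.table`: `gene_id`, `log2_fc` (b over a), `p`, `padj`.
#' @export
de_welch_test <- function(rpkm_a, rpkm_b) {
  stopifnot(nrow(rpkm_a) == nrow(rpkm_b), ncol(rpkm_a) >= 2, ncol(rpkm_b) >= 2)
  la <- log2(rpkm_a + 1)
  lb <- log2(rpkm_b + 1)
  p <- vapply(seq_len(nrow(la)), function(i) {
    if (sd(la[i, ]) == 0 && sd(lb[i, ]) == 0) return(1)
    t.test(la[i, ], lb[i, ])$p.value
  }, numeric(1L))
  data.table(gene_id = if (!is.null(rownames(rpkm_a))) rownames(rpkm_a)
             else as.character(seq_len(nrow(la))),
             log2_fc = rowMeans(lb) - rowMeans(la),
             p = p, padj = p.adjust(p, method = "BH"))
}

#' Imprint-control-element deletion check
#'
#' A candidate near an imprinted cluster is regulated by the cluster's
#' non-coding RNA when deleting the imprint control element (paternal
#' allele) releases its silenced allele: the wild-type maternal bias
#' collapses to biallelic, and/or expression increases significantly.
#'
#' @param wt_category,mut_category Allelic categories of the gene in the
#'   wild-type and mutant crosses (`NA`/`"NI"` when SNP coverage is
#'   insufficient).
#' @param expr_log2_fc,expr_padj Expression change (mutant over wild type)
#'   and its adjusted p-value from [de_welch_test()] (optional).
#' @param alpha Significance level for the expression test (default 0.05).
#' @return Verdict: `regulated`, `unchanged`, or `not_informative`.
#' @export
ice_deletion_check <- function(wt_category, mut_category,
                               expr_log2_fc = NA_real_, expr_padj = NA_real_,
                               alpha = 0.05) {
  uninf <- function(x) is.na(x) || x %in% c("NI", "NS")
  if (uninf(wt_category) || uninf(mut_category)) return("not_informative")
  ratio_released <- wt_category == "MAT" && mut_category == "BAE"
  expr_up <- !is.na(expr_padj) && expr_padj < alpha &&
    !is.na(expr_log2_fc) && expr_log2_fc > 0
  if (ratio_released || expr_up) "regulated" else "unchanged"
}

#' Categorise an imprinted candidate from its evidence
#'
#' Deterministic precedence: a placenta-restricted maternal candidate with a
#' high decidua/placenta ratio or blood-specific expression and no
#' independent validation is `maternal_contamination`; otherwise any direct
#' validation (ICE-deletion regulation, parental H3K4me3 promoter support,
#' embryo-transfer confirmation, confirmation in a second F1 cross) makes it
#' `validated`; otherwise detection in two or more tissues, proximity to a
#' known imprint anchor (< `proximity_mb`), or gDMR/sDMR overlap makes it
#' `supported`; otherwise `candidate`. Non-coding candidates that are not
#' supported as independent transcripts (no own promoter peak) and share
#' direction with a neighbouring known imprinted nc-gene get the
#' `fragment_` prefix.
#'
#' @param evidence Named list with (all optional): `tissues_imprinted`
#'   (character), `placenta_restricted_maternal`, `decidua_placenta_ratio`,
#'   `blood_specific`, `h3k4me3_support`, `embryo_transfer_verdict`,
#'   `second_cross_confirmed`, `ice_deletion_verdict`,
#'   `distance_to_anchor_bp`, `dmr_overlap`, `independent_transcript`,
#'   `neighbor_same_direction`.
#' @param proximity_bp Proximity radius to an imprint anchor (default 7 Mb).
#' @param contamination_ratio Decidua/placenta ratio cutoff (default 5).
#' @return Category string, possibly `fragment_`-prefixed.
#' @export
categorize_candidate <- function(evidence, proximity_bp = 7e6,
                                 contamination_ratio = 5) {
  gv <- function(name, default) {
    v <- evidence[[name]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) default else v
  }
  validated <- identical(gv("ice_deletion_verdict", ""), "regulated") ||
    isTRUE(gv("h3k4me3_support", FALSE)) ||
    identical(gv("embryo_transfer_verdict", ""), "maternal_confirmed") ||
    isTRUE(gv("second_cross_confirmed", FALSE))
  contaminated <- isTRUE(gv("placenta_restricted_maternal", FALSE)) &&
    (gv("decidua_placenta_ratio", 0) > contamination_ratio ||
       isTRUE(gv("blood_specific", FALSE))) && !validated
  supported <- length(gv("tissues_imprinted", character())) >= 2L ||
    gv("distance_to_anchor_bp", Inf) < proximity_bp ||
    isTRUE(gv("dmr_overlap", FALSE))

  base <- if (contaminated) "maternal_contamination"
  else if (validated) "validated"
  else if (supported) "supported"
  else "candidate"

  fragment <- !isTRUE(gv("independent_transcript", TRUE)) &&
    isTRUE(gv("neighbor_same_direction", FALSE))
  if (fragment && base != "maternal_contamination") paste0("fragment_", base)
  else base
}

#' Assign genes to imprinted regions by nearest anchor
#'
#' @param genes Data frame `gene_id`, `chrom`, `start`, `end`.
#' @param anchors Data frame `region_id`, `chrom`, `pos` (gDMR/ICE
#'   positions).
#' @param max_dist Maximum gene-anchor distance (default 7 Mb).
#' @return `data.table`: `gene_id`, `region_id`, `distance`; errors listing
#'   the genes with no anchor within range.
#' @export
assign_to_region <- function(genes, anchors, max_dist = 7e6) {
  gen <- as.data.table(genes)
  anc <- as.data.table(anchors)
  res <- rbindlist(lapply(seq_len(nrow(gen)), function(i) {
    cand <- anc[chrom == gen$chrom[i]]
    if (!nrow(cand))
      return(data.table(gene_id = gen$gene_id[i], region_id = NA_character_,
                        distance = NA_real_))
    d <- pmax(0, pmax(cand$pos - gen$end[i], gen$start[i] - cand$pos))
    j <- which.min(d)
    data.table(gene_id = gen$gene_id[i], region_id = cand$region_id[j],
               distance = d[j])
  }))
  bad <- res[is.na(distance) | distance > max_dist, gene_id]
  if (length(bad))
    stop("no imprint anchor within ", max_dist, " bp for: ",
         paste(head(bad, 10L), collapse = ", "))
  res[]
}

#' Genomic extent of imprinted clusters per tissue
#'
#' The span of each imprinted region in a tissue runs from the most proximal
#' to the most distal member gene detected as imprinted there, so the series
#' across tissues shows clusters expanding (typically in extra-embryonic
#' tissues) and contracting.
#'
#' @param calls Imprinted gene calls across tissues: data frame `gene_id`,
#'   `tissue`, `category` (only `MAT`/`PAT` rows contribute).
#' @param genes Gene coordinates (`gene_id`, `chrom`, `start`, `end`).
#' @param region_assignment From [assign_to_region()] (`gene_id`,
#'   `region_id`).
#' @return `data.table`: `region_id`, `tissue`, `chrom`, `start`, `end`,
#'   `size_bp`, `n_member_genes`. Tissues where a region has no imprinted
#'   member are omitted.
#' @export
cluster_extent <- function(calls, genes, region_assignment) {
  dt <- as.data.table(calls)[category %in% c("MAT", "PAT")]
  asg <- as.data.table(region_assignment)[, .(gene_id, region_id)]
  unassigned <- setdiff(dt$gene_id, asg[!is.na(region_id), gene_id])
  if (length(unassigned))
    stop("imprinted gene(s) without region assignment: ",
         paste(head(unassigned, 10L), collapse = ", "))
  dt <- merge(dt, asg, by = "gene_id")
  dt <- merge(dt, as.data.table(genes)[, .(gene_id, chrom, start, end)],
              by = "gene_id")
  out <- dt[, .(chrom = chrom[1L], start = min(start), end = max(end),
                n_member_genes = uniqueN(gene_id)),
            by = .(region_id, tissue)]
  out[, size_bp := end - start]
  setorder(out, region_id, tissue)
  out[]
}

#' Fold variation of per-tissue counts
#'
#' @param counts Integer vector of per-tissue counts (all > 0).
#' @return List: `fold` (max/min, exact) and `fold_rounded` (1 decimal,
#'   round-half-even); `NA`s when the minimum is 0.
#' @export
fold_variation <- function(counts) {
  if (!length(counts) || min(counts) == 0)
    return(list(fold = NA_real_, fold_rounded = NA_real_))
  f <- max(counts) / min(counts)
  list(fold = f, fold_rounded = round(f, 1))
}

#' Summary statistics over tissues
#'
#' Per-tissue per-category tallies with the derived presentation numbers:
#' fold variation of each category's count across tissues (max/min, one
#' decimal), percent of annotated genes per category and tissue (one
#' decimal), and per-gene maintenance (the fraction of informative tissues
#' in which a gene keeps a given category).
#'
#' @param calls Calls across tissues: data frame `gene_id`, `tissue`,
#'   `category`.
#' @return List: `counts` (tissue x category table), `fold` (per category),
#'   `percent` (per tissue and category, of all annotated genes),
#'   `maintenance` (`gene_id`, `category`, `n_with_category`,
#'   `n_informative_tissues`, `fraction`).
#' @export
report_statistics <- function(calls) {
  dt <- as.data.table(calls)
  stopifnot(all(c("gene_id", "tissue", "category") %in% names(dt)))
  n_genes <- uniqueN(dt$gene_id)
  counts <- dt[, .N, by = .(tissue, category)]
  counts_w <- dcast(counts, tissue ~ category, value.var = "N", fill = 0L)

  fold <- counts[, {
    fv <- fold_variation(N)
    .(min = min(N), max = max(N), fold = fv$fold,
      fold_rounded = fv$fold_rounded)
  }, by = category]

  percent <- counts[, .(tissue, category, n = N,
                        pct_of_total = round(100 * N / n_genes, 1))]

  inf_cats <- c("BAE", "CAST", "FVB", "MAT", "PAT")
  maint <- dt[, .(n_informative_tissues = sum(category %in% inf_cats)),
              by = gene_id]
  per_cat <- dt[category %in% c("CAST", "FVB", "MAT", "PAT"),
                .(n_with_category = .N), by = .(gene_id, category)]
  maint <- merge(per_cat, maint, by = "gene_id")
  maint[, fraction := n_with_category / n_informative_tissues]

  list(counts = counts_w, fold = fold, percent = percent,
       maintenance = maint[])
}

#' Percentage with one-decimal presentation
#'
#' @param n,total Numerator and denominator.
#' @param digits Decimals (default 1).
#' @return `round(100 * n / total, digits)`; `NA` when `total` is 0.
#' @export
percent_of <- function(n, total, digits = 1L) {
  ifelse(total > 0, round(100 * n / total, digits), NA_real_)
}
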