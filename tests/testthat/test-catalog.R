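test_that("the contamination screen applies the ratio and blood rules", {
  r1 <- contamination_screen(decidua_rpkm = c(12, 12), placenta_rpkm = c(2, 2))
  expect_true(r1$flagged)
  expect_equal(r1$ratio, 6)
  r2 <- contamination_screen(c(4, 4), c(2, 2), blood_specific = TRUE)
  expect_true(r2$flagged)
  r3 <- contamination_screen(c(4, 4), c(2, 2), blood_specific = FALSE)
  expect_false(r3$flagged)
  r4 <- contamination_screen(c(4, 4), c(0, 0))
  expect_true(r4$flagged)
  expect_equal(r4$ratio, Inf)
  expect_equal(r1$log2_ratio, log2(6))
})

test_that("embryo-transfer verdicts follow the host-allele logic", {
  mk <- function(frac, cov = 100) data.frame(
    reads_CAST = round(frac * cov), reads_FVB = cov - round(frac * cov))
  expect_equal(embryo_transfer_check(mk(0.95))$verdict, "maternal_confirmed")
  expect_equal(embryo_transfer_check(mk(0.10))$verdict, "contamination")
  expect_equal(embryo_transfer_check(mk(0.65))$verdict,
               "supportive_below_cutoff")
  expect_equal(embryo_transfer_check(mk(0.95, cov = 6))$verdict,
               "not_informative")
})

test_that("the differential-expression test finds planted changes", {
  set.seed(2)
  a <- matrix(2^rnorm(300, 5, 0.2), nrow = 100)
  b <- a * 2^matrix(rnorm(300, 0, 0.2), nrow = 100)
  b[1:5, ] <- b[1:5, ] * 8
  rownames(a) <- rownames(b) <- paste0("g", 1:100)
  de <- de_welch_test(a, b)
  expect_true(all(de$padj[1:5] < 0.05))
  expect_true(all(de$log2_fc[1:5] > 1))
  expect_lt(mean(de$p[6:100] < 0.05), 0.15)
  expect_true(all(de$padj >= de$p))
})

test_that("ICE-deletion verdicts integrate allelic and expression evidence", {
  expect_equal(ice_deletion_check("MAT", "BAE"), "regulated")
  expect_equal(ice_deletion_check("MAT", "MAT"), "unchanged")
  expect_equal(ice_deletion_check("MAT", "MAT", expr_log2_fc = 2,
                                  expr_padj = 0.001), "regulated")
  expect_equal(ice_deletion_check("MAT", "MAT", expr_log2_fc = -2,
                                  expr_padj = 0.001), "unchanged")
  expect_equal(ice_deletion_check("MAT", "NI"), "not_informative")
  expect_equal(ice_deletion_check(NA, "BAE"), "not_informative")
})

test_that("candidate categories follow the evidence precedence", {
  expect_equal(categorize_candidate(list(ice_deletion_verdict = "regulated")),
               "validated")
  expect_equal(categorize_candidate(list(h3k4me3_support = TRUE)), "validated")
  expect_equal(categorize_candidate(list(
    tissues_imprinted = c("placenta", "VE"), distance_to_anchor_bp = 3e6)),
    "supported")
  expect_equal(categorize_candidate(list(distance_to_anchor_bp = 8e6)),
               "candidate")
  expect_equal(categorize_candidate(list(
    placenta_restricted_maternal = TRUE, decidua_placenta_ratio = 8)),
    "maternal_contamination")
  ## any direct validation rescues a high-ratio candidate
  expect_equal(categorize_candidate(list(
    placenta_restricted_maternal = TRUE, decidua_placenta_ratio = 8,
    embryo_transfer_verdict = "maternal_confirmed")), "validated")
  ## fragments: dependent nc transcripts sharing a neighbour's direction
  expect_equal(categorize_candidate(list(
    tissues_imprinted = c("a", "b"), independent_transcript = FALSE,
    neighbor_same_direction = TRUE)), "fragment_supported")
})

test_that("candidate categorisation ignores evidence-field order", {
  ev <- list(tissues_imprinted = c("a", "b"), h3k4me3_support = TRUE,
             distance_to_anchor_bp = 1e6, blood_specific = FALSE,
             placenta_restricted_maternal = FALSE)
  base <- categorize_candidate(ev)
  set.seed(5)
  for (i in 1:10) {
    expect_equal(categorize_candidate(ev[sample(names(ev))]), base)
  }
})

test_that("region assignment respects the proximity radius", {
  genes <- data.frame(gene_id = c("near", "inside"), chrom = "chr1",
                      start = c(4e6, 9.9e6), end = c(4.01e6, 10.1e6))
  anchors <- data.frame(region_id = "Igf2r_like", chrom = "chr1", pos = 1e7)
  asg <- assign_to_region(genes, anchors)
  expect_equal(asg$region_id, c("Igf2r_like", "Igf2r_like"))
  expect_equal(asg$distance[2], 0)
  far <- data.frame(gene_id = "far", chrom = "chr1", start = 5e7, end = 5.1e7)
  expect_error(assign_to_region(far, anchors), "far")
})

test_that("cluster extents span member genes and never shrink", {
  genes <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                      start = c(100000, 500000, 5000000),
                      end = c(110000, 520000, 5050000))
  asg <- data.frame(gene_id = c("a", "b", "c"), region_id = "r1")
  calls1 <- data.frame(gene_id = "a", tissue = "liver", category = "MAT")
  e1 <- cluster_extent(calls1, genes, asg)
  expect_equal(e1$size_bp, 10000)

  calls2 <- data.frame(gene_id = c("a", "b", "c"), tissue = "placenta",
                       category = c("MAT", "MAT", "PAT"))
  e2 <- cluster_extent(calls2, genes, asg)
  expect_equal(e2$size_bp, 5050000 - 100000)
  expect_equal(e2$n_member_genes, 3L)
  expect_gte(e2$size_bp, e1$size_bp)

  ## identical members in two tissues give identical spans
  calls3 <- rbind(calls2, transform(calls2, tissue = "VE"))
  e3 <- cluster_extent(calls3, genes, asg)
  expect_equal(e3$size_bp[1], e3$size_bp[2])

  expect_error(cluster_extent(data.frame(gene_id = "zz", tissue = "t",
                                         category = "MAT"),
                              genes, asg), "zz|assignment")
})

test_that("fold variation and percentages reproduce printed arithmetic", {
  expect_equal(fold_variation(c(825, 400, 174))$fold_rounded, 4.7)
  expect_equal(fold_variation(c(26, 10, 4))$fold_rounded, 6.5)
  expect_equal(fold_variation(c(970, 500, 262))$fold_rounded, 3.7)
  expect_equal(fold_variation(c(10, 10, 10))$fold_rounded, 1.0)
  expect_true(is.na(fold_variation(c(0, 5))$fold))

  expect_equal(percent_of(723, 19772), 3.7)
  expect_equal(percent_of(178, 1222), 14.6)
  expect_true(is.na(percent_of(1, 0)))
})

test_that("summary statistics tally categories and maintenance", {
  calls <- rbind(
    data.frame(gene_id = c("a", "b", "c"), tissue = "t1",
               category = c("CAST", "BAE", "MAT")),
    data.frame(gene_id = c("a", "b", "c"), tissue = "t2",
               category = c("CAST", "BAE", "BAE")),
    data.frame(gene_id = c("a", "b", "c"), tissue = "t3",
               category = c("BAE", "NI", "NS")))
  st <- report_statistics(calls)
  expect_equal(st$counts$CAST[st$counts$tissue == "t1"], 1L)
  maint <- st$maintenance
  ## gene a: CAST in 2 of 3 informative tissues
  expect_equal(maint$fraction[maint$gene_id == "a"], 2 / 3)
  ## gene c: MAT in 1 of 2 informative tissues
  expect_equal(maint$fraction[maint$gene_id == "c" & maint$category == "MAT"],
               1 / 2)
  expect_equal(fold_variation(c(1, 1, 1))$fold, 1)
})
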