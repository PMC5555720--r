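test_that("the generator is deterministic for a fixed seed and leaves the RNG alone", {
  cfg <- sim_config(n_autosomal_genes = 50, n_x_genes = 10, seed = 3)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  a <- simulate_allelome(cfg)
  after <- runif(1)
  b <- simulate_allelome(cfg)
  expect_identical(a$annotation$genes, b$annotation$genes)
  expect_identical(a$snps, b$snps)
  expect_identical(a$counts, b$counts)
  expect_identical(before, after)  # no RNG state leaked
  d <- simulate_allelome(sim_config(n_autosomal_genes = 50, n_x_genes = 10,
                                    seed = 4))
  expect_false(identical(a$counts, d$counts))
})

test_that("gene counts and placement follow the configuration", {
  one_x <- generate_annotation(sim_config(n_autosomal_genes = 0, n_x_genes = 1))
  expect_equal(nrow(one_x$genes), 1L)
  expect_equal(one_x$genes$chrom, "chrX")

  auto <- generate_annotation(sim_config(n_autosomal_genes = 100, n_x_genes = 0))
  expect_equal(sum(auto$genes$chrom != "chrX"), 100L)

  ## genes do not overlap within a chromosome; TSS sits at the strand-aware end
  g <- auto$genes
  by_chr <- split(g, g$chrom)
  for (cc in by_chr) {
    cc <- cc[order(cc$start), ]
    if (nrow(cc) > 1) expect_true(all(cc$start[-1] >= cc$end[-nrow(cc)]))
  }
  expect_equal(g$tss, ifelse(g$strand == "+", g$start, g$end))
})

test_that("exons and introns partition each gene body", {
  ann <- generate_annotation(sim_config(n_autosomal_genes = 40, n_x_genes = 0,
                                        seed = 9))
  ex <- ann$exons
  for (gid in sample(ann$genes$gene_id, 10)) {
    e <- ex[ex$gene_id == gid, ]
    e <- e[order(e$start), ]
    g <- ann$genes[ann$genes$gene_id == gid, ]
    expect_equal(e$start[1], g$start)
    expect_equal(e$end[nrow(e)], g$end)
    if (nrow(e) > 1) expect_true(all(e$start[-1] > e$end[-nrow(e)]))
  }
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(frac_strain_biased = 1.2), "frac_strain_biased")
  expect_error(sim_config(frac_strain_biased = 0.6, frac_imprinted = 0.6),
               "frac_strain_biased")
  expect_error(sim_config(true_biased_ratio = 0.4), "true_biased_ratio")
  expect_error(sim_config(n_replicates_per_cross = 0), "n_replicates_per_cross")
  expect_error(sim_config(mean_coverage_per_snp = 0), "mean_coverage_per_snp")
})

test_that("the SNP-free gene fraction matches its target", {
  cfg <- sim_config(n_autosomal_genes = 1000, n_x_genes = 0,
                    frac_no_snp = 0.1, seed = 17)
  ann <- generate_annotation(cfg)
  snps <- generate_snps(ann, cfg)
  n_zero <- sum(!ann$genes$gene_id %in% snps$gene_id)
  ## 99.9% binomial interval around 0.1 * 1000 (qbinom at 5e-4 and 1 - 5e-4)
  expect_gte(n_zero, qbinom(5e-4, 1000, 0.1))
  expect_lte(n_zero, qbinom(1 - 5e-4, 1000, 0.1))
})

test_that("a fully maternal gene yields reads only from the mother's strain", {
  cfg <- sim_config(n_autosomal_genes = 40, n_x_genes = 0,
                    frac_imprinted = 1, frac_strain_biased = 0,
                    true_biased_ratio = 1, frac_no_snp = 0, seed = 2)
  sim <- simulate_allelome(cfg)
  mat <- sim$truth$gene_id[sim$truth$true_category == "MAT"]
  fwd <- sim$counts[sim$counts$cross == "CASTxFVB" &
                      sim$counts$gene_id %in% mat, ]
  expect_true(all(fwd$reads_FVB == 0))
  rev <- sim$counts[sim$counts$cross == "FVBxCAST" &
                      sim$counts$gene_id %in% mat, ]
  expect_true(all(rev$reads_CAST == 0))
})

test_that("strain bias keeps its strain fraction across reciprocal crosses", {
  cfg <- sim_config(n_autosomal_genes = 200, n_x_genes = 0,
                    frac_strain_biased = 0.5, frac_imprinted = 0,
                    true_biased_ratio = 0.9, frac_no_snp = 0,
                    mean_coverage_per_snp = 200, seed = 6)
  sim <- simulate_allelome(cfg)
  cast_genes <- sim$truth$gene_id[sim$truth$true_category == "CAST"]
  agg <- aggregate_replicates(sim$counts[sim$counts$gene_id %in% cast_genes, ],
                              minread = 1)
  by_cross <- tapply(agg$s_ratio, agg$cross, mean)
  expect_equal(unname(by_cross["CASTxFVB"]), unname(by_cross["FVBxCAST"]),
               tolerance = 0.02)
  mat_by_cross <- tapply(agg$i_ratio, agg$cross, mean)
  expect_gt(mat_by_cross["CASTxFVB"], 0.85)
  expect_lt(mat_by_cross["FVBxCAST"], 0.15)
})

test_that("empirical ratios converge to truth as coverage grows (rho = 0)", {
  cfg <- sim_config(n_autosomal_genes = 50, n_x_genes = 0,
                    frac_strain_biased = 0.3, frac_imprinted = 0,
                    true_biased_ratio = 0.8, frac_no_snp = 0,
                    mean_snps_per_gene = 20, mean_coverage_per_snp = 2000,
                    overdispersion_rho = 0, seed = 8)
  sim <- simulate_allelome(cfg)
  per_gene <- aggregate(cbind(reads_CAST, reads_FVB) ~ gene_id, sim$counts, sum)
  m <- merge(per_gene, sim$truth, by = "gene_id")
  truth_cast <- ifelse(m$true_category == "CAST", m$true_ratio,
                       ifelse(m$true_category == "FVB", 1 - m$true_ratio, 0.5))
  total <- m$reads_CAST + m$reads_FVB
  se <- sqrt(truth_cast * (1 - truth_cast) / total)
  expect_true(all(abs(m$reads_CAST / total - truth_cast) <= 3 * se))
})

test_that("a summed megaread balanced gene sits within the binomial bound", {
  cfg <- sim_config(n_autosomal_genes = 1, n_x_genes = 0, frac_no_snp = 0,
                    frac_strain_biased = 0, frac_imprinted = 0,
                    mean_snps_per_gene = 100, mean_coverage_per_snp = 10000,
                    overdispersion_rho = 0, seed = 14)
  sim <- simulate_allelome(cfg)
  agg <- aggregate_replicates(sim$counts, minread = 1)
  expect_true(all(agg$total > 1e5))
  expect_true(all(abs(agg$s_ratio - 0.5) < 0.01))
})

test_that("truth covers every gene once; escapers are X-linked only", {
  cfg <- sim_config(n_autosomal_genes = 300, n_x_genes = 80,
                    frac_escaper = 0.25, seed = 10)
  sim <- simulate_allelome(cfg)
  expect_setequal(sim$truth$gene_id, sim$annotation$genes$gene_id)
  expect_equal(anyDuplicated(sim$truth$gene_id), 0L)
  esc <- sim$truth$gene_id[sim$truth$true_category == "escaper"]
  chrom <- setNames(sim$annotation$genes$chrom, sim$annotation$genes$gene_id)
  expect_true(all(chrom[esc] == "chrX"))
  expect_error(simulate_allelic_counts(sim$annotation, sim$snps,
                                       sim$truth[sim$truth$gene_id != sim$snps$gene_id[1], ],
                                       cfg),
               "missing genes")
})

test_that("window tiling follows the 4 kb / 2 kb scheme", {
  w <- tile_windows(c(chr1 = 10000L))
  expect_equal(w$start, c(0L, 2000L, 4000L, 6000L))
  expect_equal(w$end, c(4000L, 6000L, 8000L, 10000L))
  expect_true(all(w$end - w$start == 4000L))
})

test_that("planted ChIP windows are recoverable near their gene", {
  cfg <- sim_config(n_autosomal_genes = 60, n_x_genes = 0, seed = 12)
  ann <- generate_annotation(cfg)
  tr <- generate_truth(ann, cfg)
  g <- ann$genes$gene_id[1]
  chip <- simulate_chip_windows(ann, tr$truth, cfg, prob_biased = 0,
                                plant = data.frame(gene_id = g,
                                                   category = "CAST",
                                                   n_windows = 5,
                                                   max_dist = 50000))
  w <- chip$windows
  cast_w <- w[w$category == "CAST", ]
  expect_equal(nrow(cast_w), 5L)
  tss <- ann$genes$tss[ann$genes$gene_id == g]
  expect_true(all(abs(cast_w$midpoint - tss) <= 50000))
})

test_that("antisense bleed-through contaminates the partner's counts", {
  cfg_off <- sim_config(n_autosomal_genes = 60, n_x_genes = 0,
                        frac_antisense = 0.3, antisense_bleed = 0,
                        frac_no_snp = 0, seed = 19)
  cfg_on <- sim_config(n_autosomal_genes = 60, n_x_genes = 0,
                       frac_antisense = 0.3, antisense_bleed = 0.2,
                       frac_no_snp = 0, seed = 19)
  off <- simulate_allelome(cfg_off)
  on <- simulate_allelome(cfg_on)
  expect_gt(nrow(off$annotation$antisense), 0)
  expect_gt(sum(on$counts$reads_CAST + on$counts$reads_FVB),
            sum(off$counts$reads_CAST + off$counts$reads_FVB))
})
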