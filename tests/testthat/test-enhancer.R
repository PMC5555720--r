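test_that("TSS-proximal windows are removed, distal windows kept", {
  win <- data.frame(window_id = c("a", "b"), chrom = "chr1",
                    start = c(0L, 10000L), end = c(4000L, 14000L))
  tss <- data.frame(chrom = "chr1", tss = c(3000L, 2000L))
  kept <- filter_chip_windows(win, tss)
  expect_equal(kept$window_id, "b")

  xwin <- rbind(win, data.frame(window_id = "x", chrom = "chrX",
                                start = 50000L, end = 54000L))
  expect_false("x" %in%
                 filter_chip_windows(xwin, tss, drop_chrX = TRUE)$window_id)
  expect_true("x" %in% filter_chip_windows(xwin, tss)$window_id)
})

test_that("Fisher sumlog matches direct chi-square evaluation", {
  p <- rep(0.5, 10)
  r <- fisher_sumlog(p)
  expect_equal(r$chisq, -2 * 10 * log(0.5), tolerance = 1e-12)
  expect_equal(r$chisq, 13.8629, tolerance = 1e-4)
  expect_equal(r$df, 20L)
  expect_equal(r$p, pchisq(13.862944, df = 20, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(r$p, 0.8372, tolerance = 1e-3)

  set.seed(4)
  for (i in 1:20) {
    pv <- runif(sample(2:15, 1))
    r2 <- fisher_sumlog(pv)
    expect_equal(r2$p, pchisq(-2 * sum(log(pv)), 2 * length(pv),
                              lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_error(fisher_sumlog(c(0.5, 0)), "0, 1")
  expect_error(fisher_sumlog(c(0.5, 1.2)), "0, 1")
})

test_that("enrichment profile bins tile the TSS interval and respect totals", {
  set.seed(11)
  win <- data.frame(window_id = paste0("w", 1:400), chrom = "chr1",
                    start = seq(0, by = 2000, length.out = 400))
  win$end <- win$start + 4000
  win$category <- sample(c("BAE", "CAST", "FVB"), 400, TRUE, c(0.8, 0.1, 0.1))
  genes <- data.frame(gene_id = paste0("g", 1:20), chrom = "chr1",
                      tss = sample(seq(60000, 700000, by = 1000), 20),
                      strand = sample(c("+", "-"), 20, TRUE))
  pr <- tss_enrichment_profile(win, genes, n_shuffles = 25, seed = 5)
  prof <- pr$profile
  expect_equal(sort(unique(prof$bin_lo)), seq(-50000, 46000, by = 4000))
  expect_true(all(prof$bin_hi - prof$bin_lo == 4000))
  ## per-bin totals are preserved exactly by the label shuffles
  obs_tot <- tapply(prof$observed, prof$bin_lo, sum)
  exp_tot <- tapply(prof$expected, prof$bin_lo, sum)
  expect_equal(unname(obs_tot), unname(exp_tot), tolerance = 1e-9)
  ## expected counts split the bin total by overall category frequency
  cat_freq <- prop.table(table(win$category))
  tot <- sum(prof$observed[prof$category == "BAE"]) /
    unname(cat_freq["BAE"])
  for (cc in names(cat_freq)) {
    expect_equal(sum(prof$expected[prof$category == cc]),
                 tot * unname(cat_freq[cc]), tolerance = 0.05 * tot)
  }
})

test_that("profiles are biallelic-only when no window is biased", {
  win <- data.frame(window_id = paste0("w", 1:100), chrom = "chr1",
                    start = seq(0, by = 2000, length.out = 100))
  win$end <- win$start + 4000
  win$category <- "BAE"
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 100000,
                      strand = "+")
  pr <- tss_enrichment_profile(win, genes, n_shuffles = 5, seed = 1)
  expect_true(all(pr$profile$observed[pr$profile$category %in%
                                        c("CAST", "FVB")] == 0))
})

test_that("planted biased windows near switcher TSSs enrich the right bin", {
  ## 10 switcher genes, 5 CAST windows planted at +10 kb of each TSS
  genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                      tss = seq(100000, by = 150000, length.out = 10),
                      strand = "+")
  bg <- data.frame(window_id = paste0("bg", 1:500), chrom = "chr1",
                   start = seq(0, by = 3000, length.out = 500))
  bg$end <- bg$start + 4000
  bg$category <- "BAE"
  planted <- data.frame(window_id = paste0("pl", 1:10), chrom = "chr1",
                        start = genes$tss + 10000 - 2000)
  planted$end <- planted$start + 4000
  planted$category <- "CAST"
  pr <- tss_enrichment_profile(rbind(bg, planted), genes,
                               n_shuffles = 50, seed = 9)
  prof <- pr$profile[pr$profile$category == "CAST", ]
  ## midpoint sits at TSS + 10 kb, i.e. in the [10 kb, 14 kb) bin
  target <- prof[prof$bin_lo == 10000, ]
  expect_gte(target$observed, 10)
  expect_gt(target$enrichment, 5)
  ## elsewhere the CAST profile stays at background
  expect_lte(max(prof$observed[prof$bin_lo != 10000]), 2)
})

test_that("escaper distance test flags planted geometry and validates input", {
  set.seed(3)
  ## maternal windows sit on top of non-escapers; escapers are ~10x farther
  non <- data.frame(gene_id = paste0("n", 1:60), chrom = "chrX",
                    start = seq(100000, by = 100000, length.out = 60))
  non$end <- non$start + 10000
  esc <- data.frame(gene_id = paste0("e", 1:15), chrom = "chrX",
                    start = non$start[1:15] + 45000)
  esc$end <- esc$start + 10000
  win <- data.frame(chrom = "chrX", start = non$start + 11000)
  win$end <- win$start + 4000
  r <- escaper_distance_test(win, esc, non, n_subsamples = 10, seed = 2)
  expect_length(r$p_values, 10L)
  expect_lt(r$p_combined, 0.01)
  expect_true(all(r$escaper_distances <= 500000))
  expect_error(escaper_distance_test(win, esc[0, ], non), "non-empty")
})

test_that("distances scale linearly with coordinates", {
  set.seed(6)
  non <- data.frame(gene_id = paste0("n", 1:5), chrom = "chrX",
                    start = c(10000, 33000, 61000, 92000, 140000))
  non$end <- non$start + 5000
  esc <- data.frame(gene_id = paste0("e", 1:5), chrom = "chrX",
                    start = c(21000, 47000, 76000, 118000, 160000))
  esc$end <- esc$start + 5000
  win <- data.frame(chrom = "chrX",
                    start = c(17000, 29000, 55000, 86000, 131000, 172000))
  win$end <- win$start + 4000
  r1 <- escaper_distance_test(win, esc, non, n_subsamples = 3, seed = 1)
  double0 <- function(d) transform(d, start = start * 2, end = end * 2)
  r2 <- escaper_distance_test(double0(win), double0(esc), double0(non),
                              n_subsamples = 3, seed = 1)
  expect_equal(sort(r2$escaper_distances), 2 * sort(r1$escaper_distances))
  expect_equal(sort(r2$non_escaper_distances),
               2 * sort(r1$non_escaper_distances))
})

test_that("imprinted-region enrichment separates planted densities", {
  cfg <- sim_config(n_autosomal_genes = 200, n_x_genes = 0, seed = 23)
  ann <- generate_annotation(cfg)
  tr <- generate_truth(ann, cfg)
  regions <- data.frame(chrom = "chr1", start = 0L,
                        end = 1000000L)
  chip <- simulate_chip_windows(ann, tr$truth, cfg, prob_biased = 0,
                                region_windows = list(
                                  regions = regions, density_in = 3.4,
                                  density_out = 0.1, category = "MAT"))
  mat <- chip$windows[chip$windows$category %in% c("MAT", "PAT"), ]
  r <- imprinted_region_enrichment(mat, regions, ann$chrom_sizes)
  expect_gt(r$mean_inside, r$mean_outside)
  expect_gt(r$t, 0)
  expect_gt(r$cohens_d, 0.8)
  expect_true(all(r$enriched_tiles$count > r$background_cutoff))
  expect_true(all(r$enriched_tiles$inside))
})

test_that("imprinted-region enrichment handles degenerate inputs", {
  expect_error(imprinted_region_enrichment(
    data.frame(chrom = character(), start = integer(), end = integer()),
    data.frame(chrom = "chr1", start = 0, end = 1e5), c(chr1 = 1e6)),
    "no parental")
  ## all windows inside regions: background cutoff 0, all tiles reported
  win <- data.frame(chrom = "chr1", start = c(10000, 30000, 220000),
                    end = c(14000, 34000, 224000))
  reg <- data.frame(chrom = "chr1", start = 0, end = 400000)
  r <- imprinted_region_enrichment(win, reg, c(chr1 = 1000000))
  expect_equal(r$background_cutoff, 0L)
  expect_equal(nrow(r$enriched_tiles), nrow(r$tiles[r$tiles$inside, ]))
})
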