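## GRanges from 0-based half-open coordinates
gr0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

#' Filter ChIP windows for the enrichment analyses
#'
#' Removes windows intersecting the TSS-proximal interval
#' (TSS +/- `tss_pad`, default 2 kb) of any annotated isoform, so promoter
#' H3K4me3-like signal cannot masquerade as enhancer signal; optionally
#' removes chrX windows (done for the autosomal strain-bias analysis, not
#' for the XCI distance analysis).
#'
#' @param windows Window table (`chrom`, `start`, `end`, 0-based half-open).
#' @param tss Data frame of TSS positions (`chrom`, `tss`), one row per
#'   isoform/locus.
#' @param tss_pad Half-width of the removed interval (bp).
#' @param drop_chrX Remove chrX windows.
#' @return The filtered window table.
#' @export
filter_chip_windows <- function(windows, tss, tss_pad = 2000L, drop_chrX = FALSE) {
  win <- as.data.table(windows)
  if (drop_chrX) win <- win[chrom != "chrX"]
  if (!nrow(win)) return(win)
  tssdt <- as.data.table(tss)
  if (nrow(tssdt)) {
    wgr <- gr0(win$chrom, win$start, win$end)
    tgr <- gr0(tssdt$chrom, pmax(0L, tssdt$tss - tss_pad), tssdt$tss + tss_pad + 1L)
    hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(wgr, tgr)))
    if (length(hit)) win <- win[-hit]
  }
  win[]
}

#' Allelic enrichment of windows around TSSs
#'
#' Assigns each retained window to every gene whose TSS lies within
#' `max_dist` (default 50 kb) of the window midpoint (one window may serve
#' several genes), bins the signed TSS distance (midpoint - TSS, negated on
#' the minus strand) into `2 * max_dist / bin_width` bins (default 25 bins
#' of 4 kb), and contrasts the observed per-bin, per-category window counts
#' with the mean over `n_shuffles` random datasets in which the windows'
#' allelic categories are permuted without replacement (preserving the
#' category frequency spectrum). Enrichment is observed over mean shuffled;
#' significance per category is a one-sample t-test of the observed bin
#' counts against the grand shuffled mean.
#'
#' @param windows Filtered window calls (`window_id`, `chrom`, `start`,
#'   `end`, `category`).
#' @param genes Data frame `gene_id`, `chrom`, `tss`, `strand`.
#' @param n_shuffles Number of label permutations (default 100).
#' @param seed Seed for the permutations.
#' @param max_dist,bin_width Profile half-width and bin width (bp).
#' @return List: `profile` (`category`, `bin_lo`, `bin_hi`, `observed`,
#'   `expected`, `enrichment`) and `tests` (`category`, `t`, `p`).
#' @export
tss_enrichment_profile <- function(windows, genes, n_shuffles = 100L, seed = 1L,
                                   max_dist = 50000L, bin_width = 4000L) {
  win <- as.data.table(windows)
  gen <- as.data.table(genes)
  stopifnot(nrow(win) > 0, nrow(gen) > 0)
  win[, midpoint := (start + end) / 2]
  n_bins <- as.integer(2 * max_dist / bin_width)

  ## (window, gene) pairs with |midpoint - TSS| <= max_dist
  mgr <- gr0(win$chrom, floor(win$midpoint), floor(win$midpoint) + 1L)
  tgr <- gr0(gen$chrom, pmax(0L, gen$tss - max_dist), gen$tss + max_dist)
  ov <- GenomicRanges::findOverlaps(mgr, tgr)
  wi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  d <- win$midpoint[wi] - gen$tss[gi]
  d <- ifelse(gen$strand[gi] == "-", -d, d)
  keep <- d >= -max_dist & d < max_dist
  wi <- wi[keep]
  bin <- as.integer(floor((d[keep] + max_dist) / bin_width)) + 1L

  cats <- sort(unique(c(win$category, "BAE", "CAST", "FVB", "MAT", "PAT")))
  bin_f <- factor(bin, levels = seq_len(n_bins))
  tab_by <- function(labels) {
    table(factor(labels[wi], levels = cats), bin_f)
  }
  obs <- tab_by(win$category)

  exp_sum <- matrix(0, nrow = length(cats), ncol = n_bins,
                    dimnames = dimnames(obs))
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      exp_sum <- exp_sum + tab_by(sample(win$category))
    }
  })
  expm <- exp_sum / n_shuffles

  prof <- data.table(
    category = rep(cats, n_bins),
    bin_lo = rep(seq_len(n_bins) - 1L, each = length(cats)) * bin_width - max_dist,
    observed = as.vector(obs), expected = as.vector(expm))
  prof[, bin_hi := bin_lo + bin_width]
  prof[, enrichment := ifelse(expected > 0, observed / expected, NA_real_)]

  tests <- rbindlist(lapply(cats, function(cc) {
    o <- as.numeric(obs[cc, ])
    mu <- mean(expm[cc, ])
    if (sd(o) == 0) return(data.table(category = cc, t = NA_real_, p = NA_real_))
    tt <- t.test(o, mu = mu)
    data.table(category = cc, t = unname(tt$statistic), p = tt$p.value)
  }))
  list(profile = prof[, .(category, bin_lo, bin_hi, observed, expected,
                          enrichment)],
       tests = tests)
}

#' Combine p-values by Fisher's sumlog method
#'
#' `X = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom.
#'
#' @param p Vector of p-values in (0, 1].
#' @return List: `chisq`, `df`, `p`.
#' @export
fisher_sumlog <- function(p) {
  p <- as.numeric(p)
  if (!length(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  x <- -2 * sum(log(p))
  list(chisq = x, df = 2L * length(p),
       p = pchisq(x, df = 2L * length(p), lower.tail = FALSE))
}

## Distance from window midpoints to the nearest gene of a set: 0 when the
## midpoint falls inside a gene body, else the 0-based offset to the nearer
## gene edge (purely linear in the coordinates, no gap convention).
window_gene_distance <- function(win, genes) {
  mgr <- gr0(win$chrom, floor(win$midpoint), floor(win$midpoint) + 1L)
  ggr <- gr0(genes$chrom, genes$start, genes$end)
  j <- GenomicRanges::nearest(mgr, ggr, select = "arbitrary")
  ok <- !is.na(j)
  d <- rep(NA_real_, nrow(win))
  d[ok] <- pmax(0, genes$start[j[ok]] - win$midpoint[ok],
                win$midpoint[ok] - genes$end[j[ok]])
  d
}

#' Distance of maternal windows to escapers vs non-escapers
#'
#' Tests whether maternally biased histone-mark windows lie farther from
#' escaper genes than from non-escaper genes on the X. For each window the
#' distance to the nearest gene of each class is computed (interval gap,
#' first match in coordinate order on ties); distances above `max_dist`
#' (default 500 kb) are excluded. To correct for the class imbalance, the
#' non-escaper class is subsampled to the escaper class size `n_subsamples`
#' times (default 10); each iteration yields a Welch t-test p-value and the
#' p-values are combined with Fisher's sumlog method.
#'
#' @param maternal_windows Window table (`chrom`, `start`, `end`), already
#'   TSS-filtered.
#' @param escapers,non_escapers Gene tables (`gene_id`, `chrom`, `start`,
#'   `end`), both non-empty.
#' @param n_subsamples Number of subsampling iterations.
#' @param seed Seed for the subsampling.
#' @param max_dist Maximum distance retained (bp).
#' @param direction `"window_to_gene"` (default; each window's distance to
#'   its nearest class member) or `"gene_to_window"` (each gene's distance
#'   to its nearest maternal window).
#' @return List: `p_values`, `chisq`, `df`, `p_combined`,
#'   `escaper_distances`, `non_escaper_distances` (full class, for
#'   plotting).
#' @export
escaper_distance_test <- function(maternal_windows, escapers, non_escapers,
                                  n_subsamples = 10L, seed = 1L,
                                  max_dist = 500000L,
                                  direction = c("window_to_gene",
                                                "gene_to_window")) {
  direction <- match.arg(direction)
  win <- as.data.table(maternal_windows)
  esc <- as.data.table(escapers)
  non <- as.data.table(non_escapers)
  if (!nrow(esc) || !nrow(non))
    stop("both gene classes must be non-empty")
  win[, midpoint := (start + end) / 2]

  dist_to <- function(genes) {
    if (direction == "window_to_gene") {
      window_gene_distance(win, genes)
    } else {
      ggr <- gr0(genes$chrom, genes$start, genes$end)
      mgr <- gr0(win$chrom, floor(win$midpoint), floor(win$midpoint) + 1L)
      j <- GenomicRanges::nearest(ggr, mgr, select = "arbitrary")
      ok <- !is.na(j)
      d <- rep(NA_real_, nrow(genes))
      d[ok] <- pmax(0, genes$start[ok] - win$midpoint[j[ok]],
                    win$midpoint[j[ok]] - genes$end[ok])
      d
    }
  }
  d_esc <- dist_to(esc)
  d_non_full <- dist_to(non)

  keep_d <- function(d) d[!is.na(d) & d <= max_dist]
  p_vals <- with_seed(seed, vapply(seq_len(n_subsamples), function(i) {
    sub <- non[sample(nrow(non), min(nrow(esc), nrow(non)))]
    a <- keep_d(d_esc)
    b <- keep_d(dist_to(sub))
    t.test(a, b)$p.value
  }, numeric(1L)))
  comb <- fisher_sumlog(p_vals)
  list(p_values = p_vals, chisq = comb$chisq, df = comb$df,
       p_combined = comb$p,
       escaper_distances = keep_d(d_esc),
       non_escaper_distances = keep_d(d_non_full))
}

#' Parental-specific window enrichment in imprinted regions
#'
#' Tiles the autosomes with non-overlapping count tiles (default 100 kb),
#' counts the parental-specific 4 kb windows falling in each tile (by
#' midpoint), restricts to tiles containing at least one window, and
#' contrasts tiles inside vs outside the supplied imprinted regions with a
#' Welch t-test and Cohen's d. The maximum count observed outside the
#' regions defines the background cutoff; inside tiles exceeding it are
#' reported.
#'
#' @param parental_windows Autosomal TSS-filtered parental-specific windows
#'   (`chrom`, `start`, `end`).
#' @param imprinted_regions Regions table (`chrom`, `start`, `end`).
#' @param chrom_sizes Named vector of autosome lengths.
#' @param tile_width Count-tile width (bp, default 100 kb).
#' @return List: `tiles` (informative tiles with `count` and `inside`),
#'   `mean_inside`, `mean_outside`, `t`, `p`, `cohens_d`,
#'   `background_cutoff`, `enriched_tiles` (inside tiles above cutoff).
#' @export
imprinted_region_enrichment <- function(parental_windows, imprinted_regions,
                                        chrom_sizes, tile_width = 100000L) {
  win <- as.data.table(parental_windows)
  if (!nrow(win)) stop("no parental-specific windows supplied")
  win <- win[chrom != "chrX"]
  if (!nrow(win)) stop("no autosomal parental-specific windows supplied")
  win[, midpoint := (start + end) / 2]
  reg <- as.data.table(imprinted_regions)

  sizes <- chrom_sizes[names(chrom_sizes) != "chrX"]
  tiles <- rbindlist(lapply(names(sizes), function(ch) {
    s <- seq.int(0L, sizes[[ch]], by = tile_width)
    s <- s[s < sizes[[ch]]]
    data.table(chrom = ch, start = s,
               end = pmin(s + tile_width, as.integer(sizes[[ch]])))
  }))
  mgr <- gr0(win$chrom, floor(win$midpoint), floor(win$midpoint) + 1L)
  tgr <- gr0(tiles$chrom, tiles$start, tiles$end)
  tiles[, count := GenomicRanges::countOverlaps(tgr, mgr)]
  tiles <- tiles[count >= 1L]
  if (!nrow(tiles)) stop("no tiles contain parental-specific windows")

  if (nrow(reg)) {
    rgr <- gr0(reg$chrom, reg$start, reg$end)
    tgr2 <- gr0(tiles$chrom, tiles$start, tiles$end)
    tiles[, inside := GenomicRanges::countOverlaps(tgr2, rgr) > 0]
  } else tiles[, inside := FALSE]

  ins <- tiles[inside == TRUE, count]
  out <- tiles[inside == FALSE, count]
  tt <- if (length(ins) > 1 && length(out) > 1 &&
            (sd(ins) > 0 || sd(out) > 0)) t.test(ins, out) else NULL
  pooled_sd <- if (length(ins) > 1 && length(out) > 1)
    sqrt(((length(ins) - 1) * stats::var(ins) +
            (length(out) - 1) * stats::var(out)) /
           (length(ins) + length(out) - 2)) else NA_real_
  cutoff <- if (length(out)) max(out) else 0L
  list(tiles = tiles[],
       mean_inside = if (length(ins)) mean(ins) else NA_real_,
       mean_outside = if (length(out)) mean(out) else NA_real_,
       t = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
       p = if (!is.null(tt)) tt$p.value else NA_real_,
       cohens_d = if (!is.na(pooled_sd) && pooled_sd > 0)
         (mean(ins) - mean(out)) / pooled_sd else NA_real_,
       background_cutoff = cutoff,
       enriched_tiles = tiles[inside == TRUE & count > cutoff])
}
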