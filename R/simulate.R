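#' Simulation settings
#'
#' Parameters of the synthetic reciprocal-cross experiment. The design mirrors
#' the study layout the classifier expects: two reciprocal F1 crosses
#' (`CASTxFVB` and `FVBxCAST`, maternal strain first) with
#' `n_replicates_per_cross` replicates each, autosomal genes that are
#' biallelic, strain-biased or imprinted, and X-linked genes subject to
#' skewed random XCI (CAST allele preferentially active, ratio
#' `xci_skew_ratio`) or imprinted XCI (maternal allele active, ratio 1) with
#' a planted fraction of escapers expressing both alleles.
#'
#' @param n_autosomal_genes,n_x_genes Gene counts per chromosome class.
#' @param frac_strain_biased,frac_imprinted Fractions of autosomal genes that
#'   are strain-biased (half CAST, half FVB) and imprinted (half MAT, half
#'   PAT); must sum to at most 1.
#' @param frac_escaper Fraction of X-linked genes escaping XCI.
#' @param true_biased_ratio True allelic ratio of biased genes toward their
#'   favoured allele, in (0.5, 1].
#' @param xci_skew_ratio Active-X skew toward CAST under random XCI
#'   (default 0.7).
#' @param xci_mode `"random_skewed"` (epiblast-derived tissues) or
#'   `"imprinted"` (extra-embryonic tissues, maternal allele active).
#' @param mean_snps_per_gene Mean SNPs per gene (Poisson).
#' @param frac_no_snp Fraction of genes carrying zero SNPs (exercises the NS
#'   category).
#' @param mean_coverage_per_snp Mean read coverage per SNP; coverage is drawn
#'   negative-binomial with dispersion `coverage_dispersion` (size parameter),
#'   creating realistically non-informative low-coverage genes.
#' @param coverage_dispersion Negative-binomial size; larger is closer to
#'   Poisson.
#' @param overdispersion_rho Beta-binomial intra-class correlation of the
#'   allelic split in \[0, 1); 0 recovers the pure binomial assumed by the
#'   allelic score.
#' @param n_replicates_per_cross Replicates per cross orientation
#'   (default 2).
#' @param frac_antisense Fraction of genes given an overlapping antisense
#'   partner gene.
#' @param antisense_bleed Fraction of an antisense partner's reads leaking
#'   into a gene (strand bleed-through artifact); default 0 (off).
#' @param seed Master seed; all randomness flows from it through derived
#'   per-stage streams.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_autosomal_genes = 1000L, n_x_genes = 100L,
                       frac_strain_biased = 0.05, frac_imprinted = 0.01,
                       frac_escaper = 0.15, true_biased_ratio = 0.9,
                       xci_skew_ratio = 0.7,
                       xci_mode = c("random_skewed", "imprinted"),
                       mean_snps_per_gene = 10, frac_no_snp = 0.05,
                       mean_coverage_per_snp = 50, coverage_dispersion = 2,
                       overdispersion_rho = 0, n_replicates_per_cross = 2L,
                       frac_antisense = 0, antisense_bleed = 0, seed = 1L) {
  xci_mode <- match.arg(xci_mode)
  chk <- function(ok, field, what) if (!ok) stop("invalid sim_config: ", field, " ", what)
  chk(n_autosomal_genes >= 0, "n_autosomal_genes", "must be >= 0")
  chk(n_x_genes >= 0, "n_x_genes", "must be >= 0")
  chk(n_autosomal_genes + n_x_genes >= 1, "n_autosomal_genes", "+ n_x_genes must be >= 1")
  for (f in c("frac_strain_biased", "frac_imprinted", "frac_escaper",
              "frac_no_snp", "frac_antisense", "antisense_bleed")) {
    v <- get(f)
    chk(is.numeric(v) && v >= 0 && v <= 1, f, "must be a fraction in [0, 1]")
  }
  chk(frac_strain_biased + frac_imprinted <= 1, "frac_strain_biased",
      "+ frac_imprinted must be <= 1")
  chk(true_biased_ratio > 0.5 && true_biased_ratio <= 1, "true_biased_ratio",
      "must be in (0.5, 1]")
  chk(xci_skew_ratio > 0.5 && xci_skew_ratio <= 1, "xci_skew_ratio",
      "must be in (0.5, 1]")
  chk(mean_snps_per_gene >= 0, "mean_snps_per_gene", "must be >= 0")
  chk(mean_coverage_per_snp > 0, "mean_coverage_per_snp", "must be > 0")
  chk(coverage_dispersion > 0, "coverage_dispersion", "must be > 0")
  chk(overdispersion_rho >= 0 && overdispersion_rho < 1, "overdispersion_rho",
      "must be in [0, 1)")
  chk(n_replicates_per_cross >= 1, "n_replicates_per_cross", "must be >= 1")
  structure(list(
    n_autosomal_genes = as.integer(n_autosomal_genes),
    n_x_genes = as.integer(n_x_genes),
    frac_strain_biased = frac_strain_biased, frac_imprinted = frac_imprinted,
    frac_escaper = frac_escaper, true_biased_ratio = true_biased_ratio,
    xci_skew_ratio = xci_skew_ratio, xci_mode = xci_mode,
    mean_snps_per_gene = mean_snps_per_gene, frac_no_snp = frac_no_snp,
    mean_coverage_per_snp = mean_coverage_per_snp,
    coverage_dispersion = coverage_dispersion,
    overdispersion_rho = overdispersion_rho,
    n_replicates_per_cross = as.integer(n_replicates_per_cross),
    frac_antisense = frac_antisense, antisense_bleed = antisense_bleed,
    seed = as.integer(seed)), class = "sim_config")
}

## Lay out non-overlapping genes along a set of chromosomes (0-based
## half-open), with exons/introns partitioning each gene body.
place_genes <- function(n, chroms, prefix, start_id = 1L) {
  if (n == 0L)
    return(list(genes = data.table(gene_id = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   strand = character(), tss = integer(),
                                   biotype = character()),
                exons = data.table(gene_id = character(), start = integer(),
                                   end = integer())))
  chrom <- rep(chroms, length.out = n)
  len <- pmin(pmax(round(exp(rnorm(n, log(15000), 0.5))), 2000L), 100000L)
  gap <- round(runif(n, 5000, 50000))
  dt <- data.table(gene_id = sprintf("%s%05d", prefix, seq_len(n) + start_id - 1L),
                   chrom = chrom, len = len, gap = gap)
  dt[, start := cumsum(shift(len, fill = 0L) + gap) - gap[1L] + 1000L, by = chrom]
  dt[, end := start + len]
  dt[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  dt[, tss := ifelse(strand == "+", start, end)]
  dt[, biotype := sample(c("pc", "nc"), .N, replace = TRUE, prob = c(0.7, 0.3))]

  ## exon/intron structure: 1 + Pois(3) exons per gene, random interior breaks
  n_ex <- 1L + rpois(n, 3)
  exons <- lapply(seq_len(n), function(i) {
    e <- n_ex[i]
    if (e == 1L) return(cbind(dt$start[i], dt$end[i]))
    b <- sort(sample(seq_len(len[i] - 1L), 2L * (e - 1L))) + dt$start[i]
    bounds <- c(dt$start[i], b, dt$end[i])
    odd <- seq(1L, length(bounds), by = 2L)
    cbind(bounds[odd], bounds[odd + 1L])
  })
  exdt <- data.table(gene_id = rep(dt$gene_id, vapply(exons, nrow, 1L)),
                     start = unlist(lapply(exons, function(m) m[, 1L])),
                     end = unlist(lapply(exons, function(m) m[, 2L])))
  list(genes = dt[, .(gene_id, chrom, start, end, strand, tss, biotype)],
       exons = exdt)
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes along four autosomes and chrX (0-based
#' half-open coordinates), each with an exon/intron structure partitioning
#' the gene body and a TSS at the start (+ strand) or end (- strand).
#' Optionally a fraction of genes receive an overlapping antisense partner.
#'
#' @param config A [sim_config()].
#' @return List of class `annotation_set`: `genes` (gene_id, chrom, start,
#'   end, strand, tss, biotype), `exons`, `chrom_sizes` (named vector), and
#'   `antisense` (pairs table, possibly empty).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    auto <- place_genes(config$n_autosomal_genes,
                        paste0("chr", 1:4), "gene_a")
    xx <- place_genes(config$n_x_genes, "chrX", "gene_x")
    genes <- rbind(auto$genes, xx$genes)
    exons <- rbind(auto$exons, xx$exons)

    anti <- data.table(gene_id = character(), partner_id = character())
    if (config$frac_antisense > 0 && nrow(genes)) {
      pick <- genes$gene_id[runif(nrow(genes)) < config$frac_antisense]
      if (length(pick)) {
        host <- genes[gene_id %in% pick]
        part <- copy(host)
        part[, gene_id := paste0(gene_id, "_as")]
        part[, strand := ifelse(strand == "+", "-", "+")]
        ## shifted half a gene length so the pair overlaps ~50%
        part[, start := start + (end - start) %/% 2L]
        part[, end := end + (end - start) %/% 2L]
        part[, tss := ifelse(strand == "+", start, end)]
        part[, biotype := "nc"]
        genes <- rbind(genes, part)
        exons <- rbind(exons, part[, .(gene_id, start, end)])
        anti <- data.table(gene_id = host$gene_id, partner_id = part$gene_id)
      }
    }
    setorder(genes, chrom, start)
    sizes <- genes[, max(end) + 10000L, by = chrom]
    list(genes = genes, exons = exons,
         chrom_sizes = setNames(sizes$V1, sizes$chrom), antisense = anti)
  })
}

#' Generate the truth table
#'
#' Assigns every simulated gene a true allelic category and true allelic
#' ratio: autosomal genes are BAE (ratio 0.5), strain-biased (CAST/FVB at
#' `true_biased_ratio` toward the favoured strain) or imprinted (MAT/PAT at
#' `true_biased_ratio` toward the favoured parent); X-linked genes are
#' `silenced-X` non-escapers (CAST ratio `xci_skew_ratio` under random XCI,
#' maternal ratio 1 under imprinted XCI) or `escaper` (ratio 0.5). Imprinted
#' genes are grouped into clusters of up to 3 consecutive genes per
#' chromosome (`region_id`), each with an anchor position.
#'
#' @param annotation From [generate_annotation()].
#' @param config A [sim_config()].
#' @return List of class `truth_table`: `truth` (gene_id, true_category,
#'   true_ratio, region_id) and `anchors` (region_id, chrom, pos).
#' @export
generate_truth <- function(annotation, config) {
  genes <- annotation$genes
  with_seed(derive_seed(config$seed, 2L), {
    is_x <- genes$chrom == "chrX"
    truth <- data.table(gene_id = genes$gene_id, chrom = genes$chrom,
                        true_category = "BAE", true_ratio = 0.5)

    auto_ids <- genes$gene_id[!is_x]
    n_auto <- length(auto_ids)
    n_imp <- round(config$frac_imprinted * n_auto)
    n_str <- round(config$frac_strain_biased * n_auto)
    pick <- sample(auto_ids, n_imp + n_str)
    imp <- pick[seq_len(n_imp)]
    str <- setdiff(pick, imp)
    truth[gene_id %in% imp,
          true_category := rep_len(c("MAT", "PAT"), .N)]
    truth[gene_id %in% str,
          true_category := rep_len(c("CAST", "FVB"), .N)]
    truth[true_category %in% c("MAT", "PAT", "CAST", "FVB"),
          true_ratio := config$true_biased_ratio]

    x_ids <- genes$gene_id[is_x]
    if (length(x_ids)) {
      n_esc <- round(config$frac_escaper * length(x_ids))
      esc <- sample(x_ids, n_esc)
      truth[gene_id %in% x_ids, `:=`(true_category = "silenced-X",
                                     true_ratio = if (config$xci_mode == "imprinted") 1
                                     else config$xci_skew_ratio)]
      truth[gene_id %in% esc, `:=`(true_category = "escaper", true_ratio = 0.5)]
    }

    ## cluster imprinted genes: consecutive (by position) imprinted genes on a
    ## chromosome share a region, up to 3 members
    truth[, region_id := NA_character_]
    impg <- merge(truth[true_category %in% c("MAT", "PAT")],
                  genes[, .(gene_id, start)], by = "gene_id")
    setorder(impg, chrom, start)
    if (nrow(impg)) {
      impg[, region_id := paste0("region_", chrom, "_",
                                 ceiling(seq_len(.N) / 3)), by = chrom]
      truth[impg, region_id := i.region_id, on = "gene_id"]
    }
    anchors <- merge(truth[!is.na(region_id), .(gene_id, region_id)],
                     genes[, .(gene_id, chrom, start)], by = "gene_id")
    anchors <- if (nrow(anchors))
      anchors[, .(pos = min(start)), by = .(region_id, chrom)]
    else data.table(region_id = character(), chrom = character(),
                    pos = integer())
    list(truth = truth[, .(gene_id, true_category, true_ratio, region_id)],
         anchors = anchors[, .(region_id, chrom, pos)])
  })
}

#' Generate synthetic SNPs
#'
#' Draws a Poisson number of SNPs per gene around `mean_snps_per_gene`; a
#' fraction `frac_no_snp` of genes receive none (these must later be
#' classified NS). SNP positions are uniform within the gene body and tagged
#' exonic or intronic by the annotation's exon intervals.
#'
#' @param annotation From [generate_annotation()].
#' @param config A [sim_config()].
#' @return `data.table`: `snp_id`, `chrom`, `pos` (1-based), `gene_id`,
#'   `region` (`exonic`/`intronic`), `CAST_allele`, `FVB_allele`.
#' @export
generate_snps <- function(annotation, config) {
  genes <- annotation$genes
  if (!nrow(genes)) stop("annotation is empty")
  with_seed(derive_seed(config$seed, 3L), {
    n_snp <- rpois(nrow(genes), config$mean_snps_per_gene)
    n_snp[runif(nrow(genes)) < config$frac_no_snp] <- 0L
    idx <- rep(seq_len(nrow(genes)), n_snp)
    if (!length(idx))
      return(data.table(snp_id = character(), chrom = character(),
                        pos = integer(), gene_id = character(),
                        region = character(), CAST_allele = character(),
                        FVB_allele = character()))
    pos0 <- genes$start[idx] +
      floor(runif(length(idx)) * (genes$end[idx] - genes$start[idx]))
    snps <- data.table(chrom = genes$chrom[idx], pos = as.integer(pos0) + 1L,
                       gene_id = genes$gene_id[idx])
    snps[, snp_id := paste0(gene_id, "_s", seq_len(.N)), by = gene_id]
    ## exonic if the 0-based position falls in an exon interval of its gene
    ex <- as.data.table(annotation$exons)
    setkey(ex, gene_id, start, end)
    snps[, region := "intronic"]
    hit <- ex[snps, on = .(gene_id, start <= pos, end >= pos), nomatch = NULL,
              .(snp_id = i.snp_id)]
    snps[snp_id %in% hit$snp_id, region := "exonic"]
    bases <- c("A", "C", "G", "T")
    snps[, CAST_allele := sample(bases, .N, replace = TRUE)]
    snps[, FVB_allele := vapply(CAST_allele, function(b)
      sample(setdiff(bases, b), 1L), "")]
    snps[, .(snp_id, chrom, pos, gene_id, region, CAST_allele, FVB_allele)]
  })
}

## True CAST-allele fraction of each gene in a given cross orientation.
## Strain bias is orientation-invariant; parental bias flips with the cross.
cast_fraction <- function(truth, cross, config) {
  r <- truth$true_ratio
  maternal_is_cast <- cross == "CASTxFVB"
  vapply(seq_len(nrow(truth)), function(i) {
    switch(truth$true_category[i],
           BAE = 0.5, escaper = 0.5,
           CAST = r[i], FVB = 1 - r[i],
           MAT = if (maternal_is_cast) r[i] else 1 - r[i],
           PAT = if (maternal_is_cast) 1 - r[i] else r[i],
           `silenced-X` = if (config$xci_mode == "imprinted") {
             if (maternal_is_cast) r[i] else 1 - r[i]
           } else r[i],
           stop("unknown truth category: ", truth$true_category[i]))
  }, numeric(1L))
}

## Beta-binomial draw: n trials, mean p, intra-class correlation rho.
## rho = 0 degenerates to the binomial; p in {0, 1} is exact.
rbetabinom <- function(n_draws, size, p, rho) {
  if (rho <= 0) return(rbinom(n_draws, size, p))
  edge <- p <= 0 | p >= 1
  out <- integer(n_draws)
  if (any(edge)) out[edge] <- ifelse(p[if (length(p) > 1) edge else 1] >= 1,
                                     size[edge], 0L)
  if (any(!edge)) {
    pp <- if (length(p) > 1) p[!edge] else rep(p, sum(!edge))
    a <- pp * (1 - rho) / rho
    b <- (1 - pp) * (1 - rho) / rho
    out[!edge] <- rbinom(sum(!edge), size[!edge], rbeta(sum(!edge), a, b))
  }
  out
}

#' Simulate replicate-level SNP allelic counts
#'
#' For each replicate of each reciprocal cross, each SNP's total coverage is
#' drawn negative-binomial around `mean_coverage_per_snp` and split between
#' the CAST and FVB alleles by a beta-binomial whose mean is the gene's true
#' allelic ratio expressed in that replicate's orientation and whose
#' intra-class correlation is `overdispersion_rho`.
#'
#' @param annotation From [generate_annotation()].
#' @param snps From [generate_snps()].
#' @param truth The `truth` table of [generate_truth()] (must cover every
#'   gene carrying SNPs).
#' @param config A [sim_config()].
#' @return `data.table`: `replicate_id`, `cross`, `gene_id`, `snp_id`,
#'   `reads_CAST`, `reads_FVB`.
#' @export
simulate_allelic_counts <- function(annotation, snps, truth, config) {
  truth <- as.data.table(truth)
  missing_genes <- setdiff(unique(snps$gene_id), truth$gene_id)
  if (length(missing_genes))
    stop("truth table missing genes: ",
         paste(head(missing_genes, 5L), collapse = ", "))
  crosses <- rep(c("CASTxFVB", "FVBxCAST"), each = config$n_replicates_per_cross)
  rep_ids <- paste0(rep(c("CxF", "FxC"), each = config$n_replicates_per_cross),
                    "_rep", rep(seq_len(config$n_replicates_per_cross), 2L))

  pmap <- list(
    CASTxFVB = setNames(cast_fraction(truth, "CASTxFVB", config), truth$gene_id),
    FVBxCAST = setNames(cast_fraction(truth, "FVBxCAST", config), truth$gene_id))

  with_seed(derive_seed(config$seed, 4L), {
    out <- vector("list", length(rep_ids))
    for (i in seq_along(rep_ids)) {
      cov <- rnbinom(nrow(snps), mu = config$mean_coverage_per_snp,
                     size = config$coverage_dispersion)
      p <- unname(pmap[[crosses[i]]][as.character(snps$gene_id)])
      cast <- rbetabinom(nrow(snps), cov, p, config$overdispersion_rho)
      out[[i]] <- data.table(replicate_id = rep_ids[i], cross = crosses[i],
                             gene_id = snps$gene_id, snp_id = snps$snp_id,
                             reads_CAST = cast, reads_FVB = cov - cast)
    }
    counts <- rbindlist(out)

    ## optional strand bleed-through: a fraction of an antisense partner's
    ## reads leaks into the host gene's SNPs (and vice versa)
    if (config$antisense_bleed > 0 && nrow(annotation$antisense)) {
      pairs <- rbind(annotation$antisense,
                     annotation$antisense[, .(gene_id = partner_id,
                                              partner_id = gene_id)])
      tot <- counts[, .(pc = sum(reads_CAST), pf = sum(reads_FVB)),
                    by = .(replicate_id, gene_id)]
      leak <- merge(pairs, tot, by.x = "partner_id", by.y = "gene_id",
                    allow.cartesian = TRUE)
      leak[, `:=`(pc = round(pc * config$antisense_bleed),
                  pf = round(pf * config$antisense_bleed))]
      first_snp <- counts[, .(snp_id = snp_id[1L]),
                          by = .(replicate_id, gene_id)]
      leak <- merge(leak, first_snp, by = c("replicate_id", "gene_id"))
      counts[leak, `:=`(reads_CAST = reads_CAST + i.pc,
                        reads_FVB = reads_FVB + i.pf),
             on = c("replicate_id", "snp_id")]
    }
    counts[]
  })
}

#' Tile chromosomes with sliding windows
#'
#' 4 kb windows advanced in 2 kb steps by default (0-based half-open); the
#' last window ends at or before the chromosome end.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param width,step Window width and step in bp.
#' @return `data.table`: `window_id`, `chrom`, `start`, `end`, `midpoint`.
#' @export
tile_windows <- function(chrom_sizes, width = 4000L, step = 2000L) {
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    if (len < width) return(NULL)
    s <- seq.int(0L, len - width, by = step)
    data.table(chrom = ch, start = s, end = s + width)
  })
  dt <- rbindlist(out)
  if (!nrow(dt)) return(data.table(window_id = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   midpoint = numeric()))
  dt[, window_id := paste0(chrom, ":", start, "-", end)]
  dt[, midpoint := (start + end) / 2]
  dt[, .(window_id, chrom, start, end, midpoint)]
}

#' Simulate allele-resolved histone-mark windows
#'
#' Tiles every chromosome with 4 kb / 2 kb-step windows and assigns each an
#' allelic category: a background of biallelic (`BAE`), non-informative
#' (`NI`) and rare biased windows, plus planted signal — strain- or
#' parental-biased windows near designated genes' TSSs (`plant`) and
#' parental-biased windows inside designated regions at a chosen density
#' (`region_windows`). Also emits promoter H3K4me3 peaks whose allelic
#' status matches each gene's true expression category.
#'
#' @param annotation From [generate_annotation()].
#' @param truth The `truth` table of [generate_truth()].
#' @param config A [sim_config()].
#' @param mark Histone mark label.
#' @param prob_informative Background probability a window is informative
#'   (`BAE`); the rest are `NI`.
#' @param prob_biased Background probability an informative window is
#'   allele-biased (category drawn from CAST/FVB/MAT/PAT).
#' @param plant Optional `data.frame(gene_id, category, n_windows, max_dist)`:
#'   for each row, `n_windows` windows within `max_dist` of the gene's TSS
#'   are set to `category`.
#' @param region_windows Optional list with elements `regions` (a
#'   `data.frame(chrom, start, end)`), `density_in`, `density_out` (expected
#'   parental windows per 100 kb inside/outside the regions) and `category`;
#'   overrides the background parental rate.
#' @return List: `windows` (window calls with `category` and `mark`) and
#'   `promoter_peaks` (gene_id, chrom, start, end, category).
#' @export
simulate_chip_windows <- function(annotation, truth, config,
                                  mark = "H3K27ac", prob_informative = 0.4,
                                  prob_biased = 0.01, plant = NULL,
                                  region_windows = NULL) {
  truth <- as.data.table(truth)
  with_seed(derive_seed(config$seed, 5L), {
    win <- tile_windows(annotation$chrom_sizes)
    win[, mark := mark]
    u <- runif(nrow(win))
    win[, category := ifelse(u < prob_informative, "BAE", "NI")]
    biased <- u < prob_informative * prob_biased
    win[biased, category := sample(c("CAST", "FVB", "MAT", "PAT"),
                                   sum(biased), replace = TRUE)]

    if (!is.null(plant)) {
      plant <- as.data.table(plant)
      genes <- annotation$genes
      for (i in seq_len(nrow(plant))) {
        g <- genes[gene_id == plant$gene_id[i]]
        if (!nrow(g)) stop("plant refers to unknown gene: ", plant$gene_id[i])
        cand <- win[chrom == g$chrom &
                      abs(midpoint - g$tss) <= plant$max_dist[i]]
        take <- head(cand$window_id, plant$n_windows[i])
        win[window_id %in% take, category := plant$category[i]]
      }
    }

    if (!is.null(region_windows)) {
      rw <- region_windows
      reg <- as.data.table(rw$regions)
      auto <- win[chrom != "chrX"]
      inside_ids <- unique(unlist(lapply(seq_len(nrow(reg)), function(i)
        auto[chrom == reg$chrom[i] & midpoint >= reg$start[i] &
               midpoint < reg$end[i], window_id])))
      p_in <- rw$density_in / (100000 / 2000)    # per-window probability
      p_out <- rw$density_out / (100000 / 2000)
      is_in <- win$window_id %in% inside_ids
      hit <- runif(nrow(win)) < ifelse(is_in, p_in, p_out)
      hit <- hit & win$chrom != "chrX"
      win[hit, category := if (!is.null(rw$category)) rw$category else
        sample(c("MAT", "PAT"), sum(hit), replace = TRUE)]
    }

    genes <- merge(annotation$genes, truth, by = "gene_id")
    peaks <- genes[, .(gene_id, chrom, start = pmax(0L, tss - 1000L),
                       end = tss + 1000L)]
    peaks[, category := fifelse(genes$true_category %in%
                                  c("CAST", "FVB", "MAT", "PAT"),
                                genes$true_category, "BAE")]
    list(windows = win[], promoter_peaks = peaks[])
  })
}

#' Simulate allele-resolved counts for ChIP windows
#'
#' Gives each window one pseudo-SNP per replicate whose coverage and allelic
#' split follow the window's category (`BAE` 0.5, biased categories at
#' `true_biased_ratio`, `NI` near-zero coverage), so window calls can be made
#' by the same classification machinery as genes (with `minread = 1`).
#'
#' @param windows The `windows` table of [simulate_chip_windows()].
#' @param config A [sim_config()].
#' @return SNP-level counts table keyed by `window_id` in the `gene_id` role.
#' @export
simulate_window_counts <- function(windows, config) {
  win <- as.data.table(windows)
  truth <- data.table(gene_id = win$window_id,
                      true_category = fifelse(win$category == "NI", "BAE",
                                              win$category),
                      true_ratio = fifelse(win$category %in%
                                             c("CAST", "FVB", "MAT", "PAT"),
                                           config$true_biased_ratio, 0.5))
  cfg <- config
  cfg$seed <- derive_seed(config$seed, 6L)
  snps <- data.table(snp_id = paste0(win$window_id, "_w"), chrom = win$chrom,
                     pos = as.integer(win$midpoint), gene_id = win$window_id,
                     region = "exonic", CAST_allele = "A", FVB_allele = "G")
  counts <- simulate_allelic_counts(list(antisense = data.table()), snps,
                                    truth, cfg)
  ## NI windows: knock coverage below any informative threshold
  ni <- win[category == "NI", window_id]
  counts[gene_id %in% ni, `:=`(reads_CAST = 0L, reads_FVB = 1L)]
  counts[]
}

#' Simulate a complete reciprocal-cross experiment
#'
#' Master generator: annotation, truth table, SNPs, replicate allelic counts
#' and (optionally) histone-mark windows with promoter peaks, all from one
#' seed via derived per-stage streams, so identical configs reproduce
#' identical outputs.
#'
#' @param config A [sim_config()].
#' @param chip Also simulate ChIP windows (default `FALSE`).
#' @return List of class `allelome_sim` with elements `annotation`, `truth`,
#'   `anchors`, `snps`, `counts`, optionally `chip`, and the `config`.
#' @export
simulate_allelome <- function(config = sim_config(), chip = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  ann <- generate_annotation(config)
  tr <- generate_truth(ann, config)
  snps <- generate_snps(ann, config)
  counts <- simulate_allelic_counts(ann, snps, tr$truth, config)
  out <- list(annotation = ann, truth = tr$truth, anchors = tr$anchors,
              snps = snps, counts = counts, config = config)
  if (chip) out$chip <- simulate_chip_windows(ann, tr$truth, config)
  structure(out, class = "allelome_sim")
}
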