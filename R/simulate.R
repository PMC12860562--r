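## Synthetic multi-omics generator with planted ground truth.
##
## Emulates a 3-season (SPS/SUS/AUS) x 3-replicate design: RNA-seq and
## ATAC-seq counts from a negative-binomial (Poisson-gamma) model,
## per-cytosine beta-binomial methylation with context-specific baselines
## (CG > CHG > CHH) and a mild upward seasonal drift, and two-block
## checkerboard Hi-C matrices with distance decay and planted
## compartment-switch bins. The planted master-regulator TF carries the
## four-layer signature: high-low-high expression, a promoter peak with
## reduced summer counts, summer promoter CG/CHG hypermethylation, and a
## TSS bin that stays in the A compartment in all seasons.

#' Reserved gene ids of the planted regulators and structural genes
#' @export
PLANTED_IDS <- c(master = "TF_MYB2_like", positive = "TF_WRKY_like",
                 negative = "TF_ERF_like",
                 chs = "CHS_like", f3ph = "F3pH_like", ans = "ANS_like")

#' Reserved ids of the planted anthocyanin structural genes
#' @export
STRUCTURAL_IDS <- unname(PLANTED_IDS[c("chs", "f3ph", "ans")])

#' Simulate a toy genome annotation with planted regulator genes
#'
#' Places non-overlapping genes on each chromosome, skewed towards the
#' gene-dense half that forms the A-compartment block; flags `n_tfs` genes
#' as TFs across families; assigns reserved ids to the planted master
#' regulator (MYB-like), a positive (WRKY-like) and a negative (ERF-like)
#' TF, and three anthocyanin structural genes (CHS/F3'H/ANS-like), all in
#' compartment-stable bins where their signature requires it. Also fixes
#' the per-season compartment block labels and the planted switch bins.
#'
#' @param config a [simulation_config()]. Uses the current RNG state; seed
#'   handling is done by [simulate_dataset()].
#' @return list with `genes` (annotation data.frame) and `truth` (skeleton
#'   manifest: block label matrices, switch-bin table, planted ids).
#' @export
simulate_genome <- function(config) {
  n_bins <- as.integer(ceiling(config$chrom_length / config$bin_size))
  chroms <- paste0("chr", seq_len(config$n_chrom))
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
  half_bins <- n_bins %/% 2
  genes_list <- list()
  block_base <- list()
  for (ci in seq_along(chroms)) {
    n_c <- per_chrom[ci]
    nA <- round(0.7 * n_c); nB <- n_c - nA
    half <- config$chrom_length %/% 2
    place <- function(n, lo, hi) {
      width <- (hi - lo) %/% n
      len <- round(stats::runif(n, 800, 1600))
      if (any(width - len < 2))
        stop("n_genes too large to place without overlap")
      start <- lo + (seq_len(n) - 1L) * width +
        floor(stats::runif(n) * (width - len - 1))
      cbind(start, start + len)
    }
    coordsA <- place(nA, 0L, half)
    coordsB <- place(nB, half, config$chrom_length)
    co <- rbind(coordsA, coordsB)
    strand <- sample(c("+", "-"), n_c, replace = TRUE)
    genes_list[[ci]] <- data.frame(
      gene_id = "", chrom = chroms[ci],
      start = as.integer(co[, 1]), end = as.integer(co[, 2]),
      strand = strand,
      tss = as.integer(ifelse(strand == "-", co[, 2] - 1L, co[, 1])),
      is_tf = FALSE, tf_family = NA_character_,
      stringsAsFactors = FALSE)
    ## base compartment blocks: gene-dense first half = A
    block_base[[chroms[ci]]] <- c(rep("A", half_bins), rep("B", n_bins - half_bins))
  }
  genes <- do.call(rbind, genes_list)
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  rownames(genes) <- NULL

  ## planted switch bins: per chromosome, alternate A2A2B (A-block bin
  ## switching to B in autumn) and B2A2B patterns
  switch_rows <- list()
  blocks <- list()
  for (ch in chroms) {
    base <- block_base[[ch]]
    lab <- matrix(rep(base, 3), ncol = 3, dimnames = list(NULL, SEASONS))
    a_bins <- which(base == "A"); b_bins <- which(base == "B")
    picks_a <- sample(a_bins, ceiling(config$n_switch_per_chrom / 2))
    picks_b <- sample(b_bins, config$n_switch_per_chrom %/% 2)
    for (b in picks_a) lab[b, ] <- c("A", "A", "B")
    for (b in picks_b) lab[b, ] <- c("B", "A", "B")
    blocks[[ch]] <- lab
    if (length(c(picks_a, picks_b)))
      switch_rows[[ch]] <- data.frame(
        chrom = ch, bin = c(picks_a, picks_b),
        pattern = c(rep("A2A2B", length(picks_a)), rep("B2A2B", length(picks_b))),
        stringsAsFactors = FALSE)
  }
  switches <- do.call(rbind, switch_rows)
  rownames(switches) <- NULL

  ## per-gene TSS bin and A-stable status
  tss_bin <- genes$tss %/% config$bin_size + 1L
  stable_a <- vapply(seq_len(nrow(genes)), function(i)
    all(blocks[[genes$chrom[i]]][tss_bin[i], ] == "A"), logical(1))

  ## planted gene assignment (ids are reserved; placement respects the
  ## compartment constraints of the planted signatures)
  pool_a <- which(stable_a)
  stopifnot(length(pool_a) >= 4)
  picks <- sample(pool_a, 4)
  master <- picks[1]; structural <- picks[2:4]
  rest <- setdiff(seq_len(nrow(genes)), c(master, structural))
  others <- sample(rest, 2 + (config$n_tfs - 3))
  positive <- others[1]; negative <- others[2]
  extra_tfs <- others[-(1:2)]
  genes$gene_id[master] <- PLANTED_IDS[["master"]]
  genes$gene_id[positive] <- PLANTED_IDS[["positive"]]
  genes$gene_id[negative] <- PLANTED_IDS[["negative"]]
  genes$gene_id[structural] <- STRUCTURAL_IDS
  genes$is_tf[c(master, positive, negative, extra_tfs)] <- TRUE
  genes$tf_family[master] <- "MYB"
  genes$tf_family[positive] <- "WRKY"
  genes$tf_family[negative] <- "ERF"
  genes$tf_family[extra_tfs] <- sample(c("MYB", "WRKY", "ERF", "bHLH", "NAC", "bZIP"),
                                       length(extra_tfs), replace = TRUE)

  list(genes = genes,
       truth = list(blocks = blocks, switches = switches,
                    tss_bin = stats::setNames(tss_bin, genes$gene_id),
                    planted = as.list(PLANTED_IDS),
                    chroms = chroms, n_bins = n_bins,
                    bin_size = config$bin_size))
}

## log2 season multipliers for the planted archetype patterns at fold f:
## the six orderings of (high, mid, low) over the three seasons
archetype_multipliers <- function(fold) {
  h <- sqrt(fold); l <- 1 / h
  perms <- list(c(h, 1, l), c(h, l, 1), c(1, h, l),
                c(l, h, 1), c(1, l, h), c(l, 1, h))
  names(perms) <- paste0("P", seq_along(perms))
  perms
}

#' Simulate the seasonal multi-omics layers over a simulated genome
#'
#' Draws RNA and ATAC counts from a negative-binomial model with planted
#' seasonal effects, per-cytosine beta-binomial methylation with planted
#' promoter hypermethylation and a methylation dip around peak summits,
#' and Hi-C matrices with two-block checkerboard structure plus planted
#' switch bins. Background genes carry no season effect.
#'
#' @param config a [simulation_config()].
#' @param genome output of [simulate_genome()].
#' @return list with rna, atac, meth, hic, gene_density and truth elements
#'   (see the methods vignette for the layout).
#' @export
simulate_multiomics <- function(config, genome) {
  genes <- genome$genes
  truth <- genome$truth
  n <- nrow(genes)
  if (!all(unlist(truth$planted) %in% genes$gene_id))
    stop("truth manifest ids do not resolve against the annotation")
  samples <- paste0(rep(SEASONS, each = config$reps_rna), "_",
                    rep(seq_len(config$reps_rna), 3))
  sample_seasons <- rep(SEASONS, each = config$reps_rna)

  ## ---- expression -----------------------------------------------------
  base <- pmin(pmax(stats::rlnorm(n, log(150), 1), 20), 5000)
  mult <- matrix(1, n, 3, dimnames = list(genes$gene_id, SEASONS))
  sf <- sqrt(config$expr_fold)
  hlh <- c(sf, 1 / sf, sf)
  for (id in c(PLANTED_IDS[["master"]], PLANTED_IDS[["positive"]], STRUCTURAL_IDS)) {
    mult[id, ] <- hlh
    base[match(id, genes$gene_id)] <- max(base[match(id, genes$gene_id)], 500)
  }
  mult[PLANTED_IDS[["negative"]], ] <- c(1 / sf, sf, 1 / sf)
  base[match(PLANTED_IDS[["negative"]], genes$gene_id)] <-
    max(base[match(PLANTED_IDS[["negative"]], genes$gene_id)], 500)
  ## planted background seasonal genes across the six archetypes
  eligible <- setdiff(genes$gene_id[!genes$is_tf], STRUCTURAL_IDS)
  seasonal_ids <- sample(eligible, min(config$n_seasonal, length(eligible)))
  arch <- archetype_multipliers(config$seasonal_fold)
  arch_of <- stats::setNames(rep(names(arch), length.out = length(seasonal_ids)),
                             seasonal_ids)
  for (id in seasonal_ids) mult[id, ] <- arch[[arch_of[id]]]
  patterns_true <- stats::setNames(
    classify_seasonal_pattern(log2(mult), deadband = 0.5), genes$gene_id)
  size_factors <- stats::runif(length(samples), 0.9, 1.1)
  rna_counts <- matrix(0L, n, length(samples),
                       dimnames = list(genes$gene_id, samples))
  for (j in seq_along(samples)) {
    mu <- base * mult[, sample_seasons[j]] * size_factors[j]
    rna_counts[, j] <- rcounts(n, mu, config$dispersion)
  }

  ## ---- ATAC peaks and counts ------------------------------------------
  coupled <- c(seasonal_ids, STRUCTURAL_IDS)   # epigenome follows expression
  atac_plant <- c(PLANTED_IDS[["master"]], STRUCTURAL_IDS)
  has_peak <- stats::runif(n) < 0.85
  has_peak[genes$gene_id %in% c(unlist(truth$planted))] <- TRUE
  prom_peaks <- data.frame(
    chrom = genes$chrom[has_peak],
    start = pmax(genes$tss[has_peak] - 250L, 0L),
    end = genes$tss[has_peak] + 250L,
    gene_id = genes$gene_id[has_peak], stringsAsFactors = FALSE)
  n_distal <- 20L * config$n_chrom
  distal_chrom <- sample(truth$chroms, n_distal, replace = TRUE)
  distal_start <- floor(stats::runif(n_distal, 0, config$chrom_length - 400))
  distal <- data.frame(chrom = distal_chrom, start = as.integer(distal_start),
                       end = as.integer(distal_start + 400L),
                       gene_id = NA_character_, stringsAsFactors = FALSE)
  peaks <- rbind(prom_peaks, distal)
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  peaks$name <- sprintf("peak_%04d", seq_len(nrow(peaks)))
  rownames(peaks) <- NULL
  np <- nrow(peaks)
  peak_base <- stats::rlnorm(np, log(100), 0.6)
  peak_base[peaks$gene_id %in% atac_plant & !is.na(peaks$gene_id)] <-
    pmax(peak_base[peaks$gene_id %in% atac_plant & !is.na(peaks$gene_id)], 400)
  peak_mult <- matrix(1, np, 3, dimnames = list(peaks$name, SEASONS))
  sa <- sqrt(config$atac_fold)
  for (i in seq_len(np)) {
    gid <- peaks$gene_id[i]
    if (is.na(gid)) next
    if (gid %in% atac_plant) peak_mult[i, ] <- c(sa, 1 / sa, sa)
    else if (gid %in% coupled) peak_mult[i, ] <- 2^(config$couple_atac * log2(mult[gid, ]))
  }
  atac_counts <- matrix(0L, np, length(samples),
                        dimnames = list(peaks$name, samples))
  for (j in seq_along(samples)) {
    mu <- peak_base * peak_mult[, sample_seasons[j]] * size_factors[j]
    atac_counts[, j] <- rcounts(np, mu, config$atac_dispersion)
  }
  peaks$summit <- as.integer((peaks$start + peaks$end) %/% 2)
  ## per-sample narrowPeak tables (shared locations, per-sample scores)
  peak_tables <- lapply(seq_along(samples), function(j) {
    data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
               name = peaks$name, score = as.numeric(atac_counts[, j]),
               strand = ".", signal = as.numeric(atac_counts[, j]),
               p = -1, q = -1, summit_offset = peaks$summit - peaks$start,
               stringsAsFactors = FALSE)
  })
  names(peak_tables) <- samples

  ## ---- methylation -----------------------------------------------------
  grid <- function(ch, from, to, by, phase) {
    p <- seq(from + phase, to - 1, by = by)
    p[p >= 0]
  }
  site_rows <- list()
  for (ch in truth$chroms) {
    L <- config$chrom_length
    bg <- list(CG = grid(ch, 0, L, 97, sample(0:96, 1)),
               CHG = grid(ch, 0, L, 89, sample(0:88, 1)),
               CHH = grid(ch, 0, L, 41, sample(0:40, 1)))
    idx <- which(genes$chrom == ch)
    prom_lo <- pmax(genes$tss[idx] - 300L, 0L); prom_hi <- genes$tss[idx] + 300L
    dense <- list(CG = 15L, CHG = 21L, CHH = 9L)
    for (ctx in METH_CONTEXTS) {
      dpos <- unlist(lapply(seq_along(idx), function(k)
        seq(prom_lo[k], prom_hi[k] - 1L, by = dense[[ctx]])))
      gene_of_d <- rep(genes$gene_id[idx],
                       vapply(seq_along(idx), function(k)
                         length(seq(prom_lo[k], prom_hi[k] - 1L, by = dense[[ctx]])),
                         integer(1)))
      pos <- c(bg[[ctx]], dpos)
      gene_of <- c(rep(NA_character_, length(bg[[ctx]])), gene_of_d)
      keep <- !duplicated(pos)
      site_rows[[paste(ch, ctx)]] <- data.frame(
        chrom = ch, pos = as.integer(pos[keep]), strand = "+", context = ctx,
        gene_id = gene_of[keep], stringsAsFactors = FALSE)
    }
  }
  sites0 <- do.call(rbind, site_rows)
  sites0 <- sites0[order(sites0$chrom, sites0$pos, sites0$context), ]
  rownames(sites0) <- NULL
  ns <- nrow(sites0)
  ## site levels per season
  lvl <- matrix(rep(config$meth_base[sites0$context], 3), ns, 3)
  colnames(lvl) <- SEASONS
  lvl <- lvl * rep(config$meth_season_shift[SEASONS], each = ns)
  ## coupling: promoter sites of seasonal/structural genes track expression
  cidx <- which(sites0$gene_id %in% coupled)
  if (length(cidx)) {
    l2m <- log2(mult[sites0$gene_id[cidx], , drop = FALSE])
    lvl[cidx, ] <- lvl[cidx, ] * pmax(1 - config$couple_meth * l2m, 0.05)
  }
  ## dip around peak summits (open chromatin is hypomethylated)
  sgr <- GenomicRanges::GRanges(sites0$chrom, IRanges::IRanges(sites0$pos + 1L, width = 1L))
  dgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(pmax(peaks$summit - 600L, 0L) + 1L,
                                                 peaks$summit + 600L))
  hits <- GenomicRanges::findOverlaps(sgr, dgr, ignore.strand = TRUE)
  if (length(hits)) {
    dist <- abs(sites0$pos[S4Vectors::queryHits(hits)] -
                  peaks$summit[S4Vectors::subjectHits(hits)])
    fac <- 1 - 0.7 * pmax(0, 1 - dist / 600)
    fmin <- stats::aggregate(fac, list(site = S4Vectors::queryHits(hits)), min)
    lvl[fmin$site, ] <- lvl[fmin$site, ] * fmin$x
  }
  ## planted promoter hypermethylation (master regulator + structural genes):
  ## CG/CHG level meth_low in SPS/AUS, meth_high in SUS
  meth_plant <- c(PLANTED_IDS[["master"]], STRUCTURAL_IDS)
  plant_regions <- do.call(rbind, lapply(meth_plant, function(id) {
    i <- match(id, genes$gene_id)
    data.frame(chrom = genes$chrom[i], start = pmax(genes$tss[i] - 400L, 0L),
               end = genes$tss[i] + 200L, gene_id = id, stringsAsFactors = FALSE)
  }))
  pidx <- which(sites0$context %in% c("CG", "CHG") &
                  IRanges::overlapsAny(sgr, as_granges(plant_regions), ignore.strand = TRUE))
  lvl[pidx, ] <- config$meth_low
  lvl[pidx, "SUS"] <- config$meth_high
  lvl <- pmin(pmax(lvl, 0.01), 0.98)
  ## per-sample beta-binomial draws
  meth_samples <- lapply(seq_along(samples), function(j) {
    p_lvl <- lvl[, sample_seasons[j]]
    shape1 <- p_lvl * config$meth_precision
    shape2 <- (1 - p_lvl) * config$meth_precision
    p <- stats::rbeta(ns, shape1, shape2)
    total <- stats::rpois(ns, config$meth_coverage)
    data.frame(chrom = sites0$chrom, pos = sites0$pos, strand = sites0$strand,
               context = sites0$context,
               methylated = stats::rbinom(ns, total, p), total = total,
               stringsAsFactors = FALSE)
  })
  names(meth_samples) <- samples

  ## ---- Hi-C ------------------------------------------------------------
  n_bins <- truth$n_bins
  dec <- 1 / (1 + abs(outer(seq_len(n_bins), seq_len(n_bins), `-`)))
  hic <- list()
  for (season in SEASONS) {
    hic[[season]] <- list()
    for (r in seq_len(config$reps_hic)) {
      per_chrom <- list()
      for (ch in truth$chroms) {
        lab <- truth$blocks[[ch]][, season]
        same <- outer(lab, lab, `==`)
        mu <- ifelse(same, config$hic_within, config$hic_between) * dec
        m <- matrix(stats::rpois(n_bins^2, mu), n_bins)
        per_chrom[[ch]] <- contact_matrix(pmax(m, t(m)), config$bin_size, ch)
      }
      hic[[season]][[r]] <- per_chrom
    }
  }
  gene_density <- lapply(truth$chroms, function(ch)
    tabulate((genes$tss[genes$chrom == ch] %/% config$bin_size) + 1L, n_bins))
  names(gene_density) <- truth$chroms

  truth$patterns <- patterns_true
  truth$seasonal_ids <- seasonal_ids
  truth$expr_multipliers <- mult
  truth$planted_dars <- prom_peaks[prom_peaks$gene_id %in% atac_plant, ]
  truth$planted_dmrs <- plant_regions
  list(rna = list(counts = rna_counts, lengths = stats::setNames(genes$end - genes$start, genes$gene_id),
                  sample_seasons = sample_seasons, samples = samples),
       atac = list(peaks = peaks, counts = atac_counts, peak_tables = peak_tables,
                   sample_seasons = sample_seasons, samples = samples),
       meth = list(samples = meth_samples, sample_seasons = sample_seasons,
                   site_annotation = sites0),
       hic = hic, gene_density = gene_density,
       truth = truth)
}

#' Simulate the targeted metabolome with calibration standards
#'
#' 87 metabolites partitioned into the eight anthocyanin-related classes
#' (24/23/11/8/7/6/6/2 by default), with a planted contrasting set
#' (down SPS->SUS, up SUS->AUS; 7 cyanidins, 5 delphinidins,
#' 2 pelargonidins, 1 peonidin by default) whose first cyanidin is the
#' C3G-like pigment at a several-hundred-fold summer depletion. Emits true
#' contents, per-analyte linear calibration standards at 14 levels spanning
#' 0.01-5000 ng/ml, and the instrument responses implied by the curves.
#'
#' @param config a [simulation_config()].
#' @return list with classes, contents (true ug/g matrix), responses,
#'   standards, sample metadata and the planted contrasting set.
#' @export
simulate_metabolome <- function(config) {
  cls <- config$class_sizes
  if (any(cls < 0) || sum(cls) <= 0) stop("invalid class sizes")
  plant <- config$contrast_plant
  if (any(plant > cls[names(plant)]))
    stop("contrasting-set class sizes exceed class sizes")
  metab <- data.frame(
    metabolite = unlist(lapply(names(cls), function(k)
      sprintf("%s_%02d", sub("s$", "", k), seq_len(cls[[k]])))),
    class = rep(names(cls), cls), stringsAsFactors = FALSE)
  nm <- nrow(metab)
  samples <- paste0(rep(SEASONS, each = 3), "_", rep(1:3, 3))
  sample_seasons <- rep(SEASONS, each = 3)
  ## planted contrasting metabolites: high-low-high content
  planted <- unlist(lapply(names(plant), function(k)
    metab$metabolite[metab$class == k][seq_len(plant[[k]])]))
  c3g <- metab$metabolite[metab$class == "cyanidins"][1]
  season_content <- matrix(0, nm, 3, dimnames = list(metab$metabolite, SEASONS))
  base_bg <- pmin(stats::rlnorm(nm, log(5), 1), 500)
  season_content[, ] <- base_bg
  for (m in planted) {
    sus <- stats::rlnorm(1, log(1), 0.3)
    fold <- if (m == c3g) config$c3g_fold else config$metab_fold
    season_content[m, ] <- c(sus * fold, sus, sus * fold)
  }
  cv <- config$metab_cv
  contents <- matrix(0, nm, length(samples),
                     dimnames = list(metab$metabolite, samples))
  for (j in seq_along(samples)) {
    mu <- season_content[, sample_seasons[j]]
    contents[, j] <- mu * stats::rlnorm(nm, -cv^2 / 2, cv)
  }
  ## per-analyte calibration curves and standards (14 levels, log-spaced)
  slope <- stats::runif(nm, 0.5, 3)
  intercept <- stats::runif(nm, 0, 5)
  levels <- exp(seq(log(config$calib_range[1]), log(config$calib_range[2]),
                    length.out = config$calib_levels))
  standards <- data.frame(
    analyte = rep(metab$metabolite, each = length(levels)),
    concentration = rep(levels, nm),
    response = NA_real_, stringsAsFactors = FALSE)
  mu_resp <- rep(slope, each = length(levels)) * standards$concentration +
    rep(intercept, each = length(levels))
  ## homoscedastic response noise (calib_sigma in ng/ml-equivalent units),
  ## matching the OLS model used downstream
  standards$response <- mu_resp +
    stats::rnorm(nrow(standards), 0, config$calib_sigma * rep(slope, each = length(levels)))
  ## sample responses implied by the content formula:
  ## c (ng/ml) = content * 100000 * m / V
  conc <- contents * 100000 * config$sample_mass / config$extraction_volume
  responses <- conc * slope + intercept
  list(classes = metab, contents = contents, responses = responses,
       standards = standards, samples = samples, sample_seasons = sample_seasons,
       contrast_set = planted, c3g = c3g,
       extraction_volume = config$extraction_volume,
       sample_mass = config$sample_mass)
}

#' Generate the full synthetic dataset, optionally writing all files
#'
#' Runs [simulate_genome()], [simulate_multiomics()] and
#' [simulate_metabolome()] under the config seed. With `outdir` set, emits
#' every layer in the package's on-disk formats plus `truth_manifest.tsv`;
#' a fixed seed yields byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param outdir optional output directory.
#' @return list with genes, omics layers, metabolome and the truth manifest.
#' @export
simulate_dataset <- function(config = simulation_config(), outdir = NULL) {
  set.seed(config$seed)
  genome <- simulate_genome(config)
  omics <- simulate_multiomics(config, genome)
  metab <- simulate_metabolome(config)
  manifest <- truth_manifest(genome$genes, omics$truth, metab)
  out <- list(config = config, genes = genome$genes, rna = omics$rna,
              atac = omics$atac, meth = omics$meth, hic = omics$hic,
              gene_density = omics$gene_density, truth = omics$truth,
              metab = metab, manifest = manifest)
  if (!is.null(outdir)) write_dataset(out, outdir)
  out
}

## Flatten the planted truth into the emitted manifest table
truth_manifest <- function(genes, truth, metab) {
  rows <- list()
  add <- function(type, id, chrom = NA, start = NA, end = NA, value = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      type = type, id = id, chrom = chrom, start = start, end = end,
      value = as.character(value), stringsAsFactors = FALSE)
  }
  for (role in names(truth$planted))
    add("planted_gene", truth$planted[[role]], value = role)
  for (id in truth$seasonal_ids)
    add("seasonal_gene", id, value = truth$patterns[[id]])
  for (i in seq_len(nrow(truth$planted_dars)))
    add("planted_dar", truth$planted_dars$gene_id[i], truth$planted_dars$chrom[i],
        truth$planted_dars$start[i], truth$planted_dars$end[i], "loss_then_gain")
  for (i in seq_len(nrow(truth$planted_dmrs)))
    add("planted_dmr", truth$planted_dmrs$gene_id[i], truth$planted_dmrs$chrom[i],
        truth$planted_dmrs$start[i], truth$planted_dmrs$end[i], "SUS_hyper")
  if (!is.null(truth$switches))
    for (i in seq_len(nrow(truth$switches)))
      add("switch_bin", paste0(truth$switches$chrom[i], "_bin", truth$switches$bin[i]),
          truth$switches$chrom[i],
          (truth$switches$bin[i] - 1L) * truth$bin_size,
          (truth$switches$bin[i]) * truth$bin_size,
          value = truth$switches$pattern[i])
  for (m in metab$contrast_set)
    add("contrast_metabolite", m,
        value = metab$classes$class[match(m, metab$classes$metabolite)])
  add("c3g_like", metab$c3g, value = "cyanidins")
  do.call(rbind, rows)
}

## Write every simulated layer in the package's on-disk formats
write_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(outdir, "methylation"), showWarnings = FALSE)
  dir.create(file.path(outdir, "hic"), showWarnings = FALSE)
  write_annotation(sim$genes, file.path(outdir, "genes.gff3"))
  write_matrix_tsv(sim$rna$counts, file.path(outdir, "rna_counts.tsv"), "gene_id")
  write_matrix_tsv(sim$atac$counts, file.path(outdir, "atac_counts.tsv"), "peak")
  for (s in names(sim$atac$peak_tables))
    write_peaks(sim$atac$peak_tables[[s]],
                file.path(outdir, "peaks", paste0(s, ".narrowPeak")))
  for (s in names(sim$meth$samples))
    write_methylation(sim$meth$samples[[s]],
                      file.path(outdir, "methylation", paste0(s, ".tsv")))
  for (season in names(sim$hic))
    for (r in seq_along(sim$hic[[season]]))
      for (ch in names(sim$hic[[season]][[r]]))
        write_contacts(sim$hic[[season]][[r]][[ch]],
                       file.path(outdir, "hic",
                                 sprintf("%s_rep%d_%s.tsv", season, r, ch)))
  write_matrix_tsv(sim$metab$responses,
                   file.path(outdir, "metabolite_responses.tsv"), "metabolite")
  utils::write.table(sim$metab$classes, file.path(outdir, "metabolite_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$metab$standards, file.path(outdir, "calibration_standards.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$manifest, file.path(outdir, "truth_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Null count matrix for type-I error checks
#'
#' Negative-binomial counts with no group effect, same generative model as
#' the main simulator.
#'
#' @param n_features number of features (genes/peaks).
#' @param n_a,n_b replicates per group.
#' @param meanlog,sdlog log-normal parameters of the feature means.
#' @param dispersion NB dispersion.
#' @return feature x sample count matrix; columns grouped a then b.
#' @export
simulate_null_counts <- function(n_features, n_a = 3, n_b = 3,
                                 meanlog = log(150), sdlog = 1,
                                 dispersion = 0.05) {
  mu <- stats::rlnorm(n_features, meanlog, sdlog)
  m <- vapply(seq_len(n_a + n_b), function(j) rcounts(n_features, mu, dispersion),
              numeric(n_features))
  m <- matrix(as.integer(m), n_features, n_a + n_b,
              dimnames = list(sprintf("f%05d", seq_len(n_features)),
                              c(paste0("a_", seq_len(n_a)), paste0("b_", seq_len(n_b)))))
  m
}

#' Null metabolite content matrix (no group effect)
#' @param n_metab number of metabolites.
#' @param n_a,n_b replicates per group.
#' @param cv replicate coefficient of variation.
#' @return metabolite x sample content matrix.
#' @export
simulate_null_contents <- function(n_metab, n_a = 3, n_b = 3, cv = 0.1) {
  mu <- stats::rlnorm(n_metab, log(5), 1)
  m <- vapply(seq_len(n_a + n_b), function(j) mu * stats::rlnorm(n_metab, -cv^2 / 2, cv),
              numeric(n_metab))
  dimnames(m) <- list(sprintf("m%05d", seq_len(n_metab)),
                      c(paste0("a_", seq_len(n_a)), paste0("b_", seq_len(n_b))))
  m
}

#' Planted-DMR benchmark dataset
#'
#' One chromosome with CG sites every `spacing` bp; `n_regions` regions of
#' `region_width` bp are planted at level `level_b` in sample B versus
#' `level_a` in sample A, on a uniform background of `level_bg` in both.
#' The default layout keeps the planted-region count large relative to the
#' number of background windows, so that the q < 0.05 window test's
#' expected false discoveries stay well below the planted truth.
#'
#' @param n_regions,region_width,chrom_length,spacing layout parameters.
#' @param level_a,level_b,level_bg methylation levels.
#' @param coverage mean per-site read depth.
#' @param precision beta precision of site-level noise (large = binomial).
#' @return list with sites_a, sites_b and `regions` (the planted truth).
#' @export
simulate_dmr_benchmark <- function(n_regions = 40, region_width = 300,
                                   chrom_length = 60000, spacing = 20,
                                   level_a = 0.2, level_b = 0.8, level_bg = 0.5,
                                   coverage = 30, precision = 1000) {
  pos <- seq(0L, chrom_length - 1L, by = spacing)
  ns <- length(pos)
  gap <- chrom_length %/% n_regions
  stopifnot(gap > 2 * region_width)
  reg_start <- (seq_len(n_regions) - 1L) * gap +
    floor(stats::runif(n_regions, region_width, gap - 2 * region_width))
  regions <- data.frame(chrom = "chr1", start = as.integer(reg_start),
                        end = as.integer(reg_start + region_width))
  in_reg <- rep(FALSE, ns)
  for (i in seq_len(n_regions))
    in_reg <- in_reg | (pos >= regions$start[i] & pos < regions$end[i])
  draw <- function(lvl_vec) {
    p <- stats::rbeta(ns, lvl_vec * precision, (1 - lvl_vec) * precision)
    total <- stats::rpois(ns, coverage)
    data.frame(chrom = "chr1", pos = pos, strand = "+", context = "CG",
               methylated = stats::rbinom(ns, total, p), total = total,
               stringsAsFactors = FALSE)
  }
  list(sites_a = draw(ifelse(in_reg, level_a, level_bg)),
       sites_b = draw(ifelse(in_reg, level_b, level_bg)),
       regions = regions)
}
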