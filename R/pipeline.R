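## End-to-end driver over a simulated dataset: every seasonal screen, the
## compartment calls, the correlation network and the candidate ranking.

#' Pool methylation replicates by season
#' @param meth_samples named list of site tables (names SEASON_rep).
#' @param sample_seasons season per table.
#' @return named list (per season) of pooled site tables.
#' @export
pool_methylation <- function(meth_samples, sample_seasons) {
  out <- list()
  for (s in intersect(SEASONS, unique(sample_seasons))) {
    tabs <- meth_samples[sample_seasons == s]
    pooled <- tabs[[1]]
    for (t2 in tabs[-1]) {
      stopifnot(identical(pooled$pos, t2$pos), identical(pooled$chrom, t2$chrom))
      pooled$methylated <- pooled$methylated + t2$methylated
      pooled$total <- pooled$total + t2$total
    }
    out[[s]] <- pooled
  }
  out
}

#' Pooled promoter methylation level per gene and season
#' @param pooled output of [pool_methylation()].
#' @param genes gene annotation.
#' @param upstream,downstream promoter window.
#' @param contexts contexts to include.
#' @return gene x season matrix of levels (NA when no covered site).
#' @export
promoter_methylation <- function(pooled, genes, upstream = 3000, downstream = 3000,
                                 contexts = c("CG", "CHG")) {
  prom <- promoter_ranges(genes, upstream, downstream)
  out <- matrix(NA_real_, nrow(genes), length(pooled),
                dimnames = list(genes$gene_id, names(pooled)))
  for (s in names(pooled)) {
    sites <- pooled[[s]]
    sites <- sites[sites$context %in% contexts, , drop = FALSE]
    sgr <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(sgr, prom, ignore.strand = TRUE)
    if (!length(hits)) next
    gi <- S4Vectors::subjectHits(hits); si <- S4Vectors::queryHits(hits)
    agg <- rowsum(cbind(m = sites$methylated[si], t = sites$total[si]), group = gi)
    rows <- as.integer(rownames(agg))
    out[rows, s] <- agg[, "m"] / pmax(agg[, "t"], 1)
  }
  out
}

#' Pool Hi-C replicates and call compartments for every season
#' @param hic nested list season -> replicate -> chromosome of
#'   `contact_matrix` objects.
#' @param gene_density per-chromosome per-bin gene counts.
#' @param config a [default_config()].
#' @return list: `tracks[[season]][[chrom]]` compartment tracks and
#'   `switches[[chrom]]` (per-bin switch strings + counts).
#' @export
call_all_compartments <- function(hic, gene_density, config = default_config()) {
  tracks <- list()
  for (season in names(hic)) {
    tracks[[season]] <- list()
    for (ch in names(hic[[season]][[1]])) {
      m <- Reduce(`+`, lapply(hic[[season]], function(rep) rep[[ch]]$matrix))
      cm <- contact_matrix(m, hic[[season]][[1]][[ch]]$bin_size, ch)
      tracks[[season]][[ch]] <- compartment_track(cm, gene_density[[ch]], config)
    }
  }
  switches <- list()
  for (ch in names(tracks[[1]]))
    switches[[ch]] <- classify_switches(lapply(tracks, `[[`, ch))
  list(tracks = tracks, switches = switches)
}

#' Per-gene compartment labels across seasons
#' @param tracks `tracks` element of [call_all_compartments()].
#' @param genes gene annotation.
#' @param bin_size Hi-C bin size.
#' @return gene x season character matrix (A/B/NaN).
#' @export
gene_compartment_matrix <- function(tracks, genes, bin_size) {
  seasons <- names(tracks)
  out <- matrix("NaN", nrow(genes), length(seasons),
                dimnames = list(genes$gene_id, seasons))
  for (s in seasons) {
    for (ch in names(tracks[[s]])) {
      sub <- genes[genes$chrom == ch, , drop = FALSE]
      if (!nrow(sub)) next
      out[sub$gene_id, s] <- assign_gene_compartments(tracks[[s]][[ch]], sub, bin_size)
    }
  }
  out
}

#' Run the full inference chain on a synthetic dataset
#'
#' Simulates the dataset under `sim_config`, then runs metabolite
#' quantification and the contrasting-metabolite screen, differential
#' expression and pattern labels, DAR and DMR calling, compartment calls
#' and switch strings, the TF-target correlation network, the four
#' contrasting-pattern filters, and the intersection ranking.
#'
#' @param sim_config a [simulation_config()].
#' @param config a [default_config()].
#' @return list with all intermediate and final results (see the methods
#'   vignette).
#' @export
run_pipeline <- function(sim_config = simulation_config(),
                         config = default_config()) {
  sim <- simulate_dataset(sim_config)
  genes <- sim$genes

  ## metabolomics: calibration -> content -> DAMs -> contrasting screen
  std <- sim$metab$standards
  curves <- lapply(split(std, std$analyte), function(s)
    fit_calibration(s$concentration, s$response))
  contents <- sim$metab$responses
  for (m in rownames(contents)) {
    conc <- invert_calibration(curves[[m]], sim$metab$responses[m, ])
    contents[m, ] <- quantify_content(conc, sim$metab$extraction_volume,
                                      sim$metab$sample_mass)
  }
  ms <- sim$metab$sample_seasons
  dams_ab <- call_dams(contents, ms == "SPS", ms == "SUS")
  dams_bc <- call_dams(contents, ms == "SUS", ms == "AUS")
  classes <- stats::setNames(sim$metab$classes$class, sim$metab$classes$metabolite)
  screen <- contrasting_metabolite_screen(dams_ab, dams_bc, classes)
  class_agg <- aggregate_by_class(cbind(sim$metab$classes,
                                        as.data.frame(contents)), ms)

  ## transcriptomics
  expr <- normalize_expression(sim$rna$counts, sim$rna$lengths,
                               sim$rna$sample_seasons,
                               pseudocount = config$pseudocount)
  de_ab <- differential_expression(expr, "SPS", "SUS", config)
  de_bc <- differential_expression(expr, "SUS", "AUS", config)
  patterns <- seasonal_patterns(expr, deadband = config$pattern_deadband)

  ## ATAC
  consensus <- consensus_peaks(sim$atac$peak_tables)
  ccounts <- consensus_counts(sim$atac$peaks, sim$atac$counts, consensus)
  dars_ab <- call_dars(consensus, ccounts, sim$atac$sample_seasons,
                       "SPS", "SUS", config)
  dars_bc <- call_dars(consensus, ccounts, sim$atac$sample_seasons,
                       "SUS", "AUS", config)

  ## WGBS
  pooled <- pool_methylation(sim$meth$samples, sim$meth$sample_seasons)
  call_all_dmrs <- function(a, b, label) {
    do.call(rbind, lapply(METH_CONTEXTS, function(ctx) {
      d <- call_dmrs(pooled[[a]], pooled[[b]], ctx, config)
      if (nrow(d)) d$comparison <- label
      d
    }))
  }
  dmrs_ab <- call_all_dmrs("SPS", "SUS", "SPS_vs_SUS")
  dmrs_bc <- call_all_dmrs("SUS", "AUS", "SUS_vs_AUS")

  ## Hi-C
  comp <- call_all_compartments(sim$hic, sim$gene_density, config)
  gene_comp <- gene_compartment_matrix(comp$tracks, genes, sim_config$bin_size)

  ## integration
  edges <- build_correlation_network(expr, genes$gene_id[genes$is_tf],
                                     STRUCTURAL_IDS, config$r_thresh,
                                     config$corr_over)
  tf_ids <- sort(unique(edges$tf_id))
  flags <- if (length(tf_ids))
    apply_contrast_filters(tf_ids, genes, de_ab, de_bc, dars_ab, dars_bc,
                           dmrs_ab, dmrs_bc, gene_comp, config)
  else NULL
  report <- if (!is.null(flags)) intersect_and_rank(edges, flags) else NULL
  deg_class <- deg_epigenome_classification(
    list(de_ab, de_bc), rbind(dars_ab, dars_bc), rbind(dmrs_ab, dmrs_bc),
    gene_comp, genes, config)
  pathway_evidence <- gene_evidence_flags(STRUCTURAL_IDS,
                                          rbind(dars_ab, dars_bc),
                                          rbind(dmrs_ab, dmrs_bc),
                                          gene_comp, genes, config)
  trend_matched <- trend_match_structural_genes(STRUCTURAL_IDS, patterns,
                                                pathway_evidence)

  ## global layer correlations over both sequential transitions
  sm <- expr$season_means
  expr_lfc <- c(sm[, "SUS"] - sm[, "SPS"], sm[, "AUS"] - sm[, "SUS"])
  al2 <- log2_cpm(ccounts, pseudocount = 0.5)
  a_means <- vapply(SEASONS, function(s)
    rowMeans(al2[, sim$atac$sample_seasons == s, drop = FALSE]),
    numeric(nrow(al2)))
  ann <- annotate_peaks_to_genes(consensus, genes, config$promoter_upstream,
                                 config$promoter_downstream)
  first_peak <- ann$assignments[!duplicated(ann$assignments$gene_id), ]
  atac_gene <- matrix(NA_real_, nrow(genes), 3,
                      dimnames = list(genes$gene_id, SEASONS))
  atac_gene[first_peak$gene_id, ] <- a_means[first_peak$peak, ]
  atac_lfc <- c(atac_gene[, "SUS"] - atac_gene[, "SPS"],
                atac_gene[, "AUS"] - atac_gene[, "SUS"])
  pm <- promoter_methylation(pooled, genes, config$promoter_upstream,
                             config$promoter_downstream)
  meth_delta <- c(pm[, "SUS"] - pm[, "SPS"], pm[, "AUS"] - pm[, "SUS"])
  layer_cor <- global_layer_correlations(expr_lfc, atac_lfc, meth_delta)

  list(sim = sim, contents = contents, dams = list(SPS_vs_SUS = dams_ab,
                                                   SUS_vs_AUS = dams_bc),
       screen = screen, class_agg = class_agg,
       expr = expr, de = list(SPS_vs_SUS = de_ab, SUS_vs_AUS = de_bc),
       patterns = patterns,
       consensus = consensus, consensus_counts = ccounts,
       dars = list(SPS_vs_SUS = dars_ab, SUS_vs_AUS = dars_bc),
       dmrs = list(SPS_vs_SUS = dmrs_ab, SUS_vs_AUS = dmrs_bc),
       compartments = comp, gene_compartments = gene_comp,
       edges = edges, flags = flags, report = report,
       deg_class = deg_class, trend_matched = trend_matched,
       layer_correlations = layer_cor)
}
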