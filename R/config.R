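#' Default analysis thresholds
#'
#' Bundles every tunable threshold of the pipeline. Defaults follow the
#' conventions of the study design this package emulates: differential
#' expression at BH FDR < 0.05 and |log2FC| > 1; differential accessibility
#' at |log2FC| >= 0.58 and raw P <= 0.01; correlation-network edges at
#' |r| > 0.8 (strict). Differential-metabolite calling mirrors the DE
#' convention. Inequality strictness matters and is applied exactly as
#' written here.
#'
#' @param ... named overrides for any field.
#' @return A list of class `seasomics_config`.
#' @export
#' @examples
#' cfg <- default_config(de_lfc = 0.5)
default_config <- function(...) {
  cfg <- list(
    # differential expression
    de_fdr = 0.05,          # strict <
    de_lfc = 1,             # strict >
    de_min_total = 10,      # min summed counts across tested samples
    pseudocount = 0.5,      # added before log2-CPM
    # differential accessibility
    dar_lfc = 0.58,         # inclusive >=
    dar_p = 0.01,           # inclusive <=, raw p
    # differential methylation
    dmr_window = 100L,      # bp
    dmr_step = 50L,         # bp
    dmr_min_sites = 5L,     # cytosines of the context per window
    dmr_delta_cg = 0.1,     # min |level difference|, CG and CHG
    dmr_delta_chh = 0.05,
    dmr_q = 0.05,
    dmr_min_coverage = 4L,  # per-site pooled coverage filter, each group
    dmr_min_run = 3L,       # min overlapping called windows per merged DMR
    dmr_method = "chisq",   # or "fisher"
    # peak/gene annotation
    promoter_upstream = 3000L,
    promoter_downstream = 3000L,
    # correlation network
    r_thresh = 0.8,         # strict >
    corr_over = "samples",  # or "means"
    # seasonal pattern labelling
    pattern_deadband = 0.5, # log2 units
    cluster_deadband = 0.25,# z-score units, for cluster centroid labels
    # Hi-C
    mask_quantile = 0.02,
    balance_tol = 1e-5,
    balance_max_iter = 500L,
    # methylation contrast mode for the regulator filter
    meth_contrast_mode = "promoter"  # or "gene_body"
  )
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(override)] <- override
  }
  structure(cfg, class = "seasomics_config")
}

#' Default simulation parameters
#'
#' Parameters of the synthetic multi-omics generator. The defaults emulate
#' the study design: three seasonal stages (SPS, SUS, AUS) with three
#' biological replicates for RNA-seq, ATAC-seq and WGBS and two Hi-C
#' replicates per season (six in total); a red-green-red anthocyanin trend;
#' and a planted master-regulator TF carrying the four-layer signature
#' (high-low-high expression, reduced summer accessibility, summer promoter
#' hypermethylation, stable A compartment). Effect sizes are the planted
#' truths the downstream screens are expected to recover.
#'
#' @param seed integer seed; a fixed seed yields byte-identical outputs.
#' @param ... named overrides for any field.
#' @return A list of class `seasomics_simconfig`.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome
    n_chrom = 2L,
    chrom_length = 400000L,     # bp per chromosome
    n_genes = 200L,             # total, split evenly across chromosomes
    n_tfs = 30L,
    bin_size = 20000L,          # Hi-C bin size
    # replicate design (per season)
    reps_rna = 3L,
    reps_atac = 3L,
    reps_wgbs = 3L,
    reps_hic = 2L,
    # planted effect sizes
    expr_fold = 8,              # planted regulator / structural genes
    seasonal_fold = 4,          # planted background seasonal genes
    n_seasonal = 54L,           # planted seasonal genes (9 per archetype)
    atac_fold = 6,              # promoter accessibility dip of planted genes
    meth_high = 0.85,           # planted promoter level in SUS
    meth_low = 0.30,            # planted promoter level in SPS/AUS
    metab_fold = 8,             # contrasting-metabolite fold (non-C3G)
    c3g_fold = 300,             # C3G-like SPS/SUS and AUS/SUS ratio
    # noise / coverage
    dispersion = 0.02,          # NB dispersion, RNA (highly reproducible replicates)
    atac_dispersion = 0.01,     # low-dispersion regime of the planted DARs
    meth_coverage = 10,         # mean per-replicate per-site read depth
    meth_precision = 50,        # beta precision of per-site levels
    metab_cv = 0.10,            # replicate CV of metabolite content
    # context baselines (CG > CHG > CHH) and seasonal drift SPS<SUS<AUS
    meth_base = c(CG = 0.60, CHG = 0.35, CHH = 0.08),
    meth_season_shift = c(SPS = 0.95, SUS = 1.00, AUS = 1.05),
    # coupling of epigenome to expression for planted seasonal/structural genes
    couple_atac = 0.6,          # d(log2 accessibility)/d(log2 expression)
    couple_meth = 0.20,         # fractional level drop per log2 expression unit
    # Hi-C block model
    hic_within = 120,           # mean contact, same compartment block
    hic_between = 12,
    n_switch_per_chrom = 2L,    # planted compartment-switch bins per chromosome
    # metabolome
    class_sizes = c(cyanidins = 24L, delphinidins = 23L, peonidins = 11L,
                    malvidins = 8L, petunidins = 7L, pelargonidins = 6L,
                    proanthocyanidins = 6L, flavonoids = 2L),
    contrast_plant = c(cyanidins = 7L, delphinidins = 5L,
                       pelargonidins = 2L, peonidins = 1L),
    calib_levels = 14L,
    calib_range = c(0.01, 5000),  # ng/ml
    calib_sigma = 0.01,           # standard noise, ng/ml-equivalent units
    extraction_volume = 1000,     # ul
    sample_mass = 0.05            # g
  )
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(cfg))
    if (length(bad)) stop("unknown simulation field(s): ", paste(bad, collapse = ", "))
    cfg[names(override)] <- override
  }
  stopifnot(cfg$n_genes > 0, cfg$n_chrom > 0, cfg$chrom_length > 0,
            cfg$reps_rna >= 1, cfg$reps_hic >= 1,
            sum(cfg$class_sizes) > 0)
  structure(cfg, class = "seasomics_simconfig")
}

#' Season labels used throughout the package
#' @export
SEASONS <- c("SPS", "SUS", "AUS")
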