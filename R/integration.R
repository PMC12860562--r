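## The core inference chain: DEG-by-epigenome classification, trend-matched
## structural genes, the TF-target correlation network, the four
## contrasting-pattern evidence filters, intersection ranking, and global
## layer-correlation summaries.

#' Per-gene epigenomic evidence flags
#'
#' For arbitrary genes, records overlap (gene body or promoter) with DARs
#' and DMRs, compartment switch status and compartment coverage.
#'
#' @param gene_ids genes to flag.
#' @param dars DAR table (rows with is_dar are used); NULL for missing.
#' @param dmrs DMR table; NULL for missing.
#' @param gene_comp gene x season compartment label matrix.
#' @param genes gene annotation.
#' @param config a [default_config()].
#' @return data.frame gene_id, has_dar, has_dmr, has_compartment,
#'   has_switch, switch_string.
#' @export
gene_evidence_flags <- function(gene_ids, dars, dmrs, gene_comp, genes,
                                config = default_config()) {
  gsub <- genes[match(gene_ids, genes$gene_id), ]
  body_gr <- as_granges(gsub)
  prom_gr <- promoter_ranges(gsub, config$promoter_upstream, config$promoter_downstream)
  overlaps_any <- function(regions) {
    if (is.null(regions) || nrow(regions) == 0) return(rep(FALSE, length(gene_ids)))
    rgr <- as_granges(regions[, c("chrom", "start", "end")])
    IRanges::overlapsAny(body_gr, rgr, ignore.strand = TRUE) |
      IRanges::overlapsAny(prom_gr, rgr, ignore.strand = TRUE)
  }
  has_dar <- overlaps_any(if (!is.null(dars)) dars[dars$is_dar, , drop = FALSE])
  has_dmr <- overlaps_any(dmrs)
  comp <- gene_comp[gene_ids, , drop = FALSE]
  data.frame(gene_id = gene_ids, has_dar = has_dar, has_dmr = has_dmr,
             has_compartment = apply(comp, 1, function(v) any(v != "NaN")),
             has_switch = apply(comp, 1, function(v) {
               u <- unique(v[v != "NaN"]); length(u) > 1
             }),
             switch_string = apply(comp, 1, paste, collapse = "2"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify DEGs by epigenomic evidence
#'
#' For every DEG (union over the supplied comparisons), records whether its
#' gene body or promoter overlaps at least one DAR, at least one DMR (any
#' context), whether its compartment label switches across seasons, and
#' whether it has any non-NaN compartment assignment; reports the fractions
#' over the DEG universe and the count with both chromatin (DAR or switch)
#' and methylation evidence.
#'
#' @param de_tables list of [differential_expression()] outputs.
#' @param dars combined DAR table (only rows with is_dar are used).
#' @param dmrs combined DMR table.
#' @param gene_comp gene x season compartment label matrix
#'   (A/B/NaN strings).
#' @param genes gene annotation.
#' @param config a [default_config()].
#' @return list with `summary` (per-DEG data.frame) and `fractions`.
#' @export
deg_epigenome_classification <- function(de_tables, dars, dmrs, gene_comp,
                                         genes, config = default_config()) {
  degs <- unique(unlist(lapply(de_tables, function(d) d$gene_id[d$is_deg])))
  if (!length(degs)) stop("empty DEG set")
  summary <- gene_evidence_flags(degs, dars, dmrs, gene_comp, genes, config)
  list(summary = summary,
       fractions = list(
         n_deg = length(degs),
         frac_dar = mean(summary$has_dar),
         frac_switch = mean(summary$has_switch),
         frac_compartment = mean(summary$has_compartment),
         frac_meth = mean(summary$has_dmr),
         n_dual = sum((summary$has_dar | summary$has_switch) & summary$has_dmr)))
}

#' Trend-matched structural genes
#'
#' Pathway genes whose seasonal expression pattern equals the anthocyanin
#' trend (high-low-high) and that carry at least one piece of epigenomic
#' evidence (DAR, DMR, or compartment switch).
#'
#' @param pathway_ids anthocyanin pathway gene ids (non-empty).
#' @param patterns named pattern labels from [seasonal_patterns()].
#' @param summary per-gene summary from [deg_epigenome_classification()]
#'   (genes absent from it count as having no evidence).
#' @param trend the metabolite trend to match.
#' @return character vector of matched gene ids (subset of pathway_ids).
#' @export
trend_match_structural_genes <- function(pathway_ids, patterns, summary,
                                         trend = "high-low-high") {
  if (!length(pathway_ids)) stop("empty pathway gene list")
  idx <- match(pathway_ids, summary$gene_id)
  evidence <- ifelse(is.na(idx), FALSE,
                     summary$has_dar[idx] | summary$has_dmr[idx] | summary$has_switch[idx])
  matched <- pathway_ids[patterns[pathway_ids] == trend & evidence]
  unname(matched[!is.na(matched)])
}

#' TF-target Pearson correlation network
#'
#' Pearson correlation between each TF and each target gene on log2-CPM
#' over all replicate samples (default) or over the three season means.
#' An edge is retained iff |r| > r_thresh (strict). Zero-variance TFs are
#' skipped with a warning.
#'
#' @param expr a `seasonal_expression`.
#' @param tf_ids,target_ids gene id vectors.
#' @param r_thresh edge threshold (strict).
#' @param over "samples" or "means".
#' @return data.frame tf_id, target_id, r, n_samples.
#' @export
build_correlation_network <- function(expr, tf_ids, target_ids, r_thresh = 0.8,
                                      over = c("samples", "means")) {
  over <- match.arg(over)
  m <- if (over == "samples") expr$log2cpm else expr$season_means
  if (ncol(m) < 3) stop("need >= 3 shared samples for correlation")
  tf_ids <- intersect(tf_ids, rownames(m))
  target_ids <- intersect(target_ids, rownames(m))
  tf_sd <- apply(m[tf_ids, , drop = FALSE], 1, stats::sd)
  if (any(tf_sd == 0)) {
    warning("skipping zero-variance TF(s): ",
            paste(tf_ids[tf_sd == 0], collapse = ", "))
    tf_ids <- tf_ids[tf_sd > 0]
  }
  if (!length(tf_ids) || !length(target_ids))
    return(data.frame(tf_id = character(), target_id = character(),
                      r = numeric(), n_samples = integer()))
  r <- stats::cor(t(m[tf_ids, , drop = FALSE]), t(m[target_ids, , drop = FALSE]))
  idx <- which(abs(r) > r_thresh, arr.ind = TRUE)
  out <- data.frame(tf_id = tf_ids[idx[, 1]], target_id = target_ids[idx[, 2]],
                    r = r[idx], n_samples = ncol(m), stringsAsFactors = FALSE)
  out <- out[order(out$tf_id, out$target_id), ]
  rownames(out) <- NULL
  out
}

## which of `ids` have a promoter (or gene-body) overlap with rows of
## `regions` satisfying `cond`
overlap_flag <- function(ids, genes, regions, cond, mode, config) {
  if (is.null(regions)) return(rep(NA, length(ids)))
  keep <- regions[cond(regions), , drop = FALSE]
  gsub <- genes[match(ids, genes$gene_id), ]
  gr <- if (mode == "promoter")
    promoter_ranges(gsub, config$promoter_upstream, config$promoter_downstream)
  else as_granges(gsub)
  if (nrow(keep) == 0) return(rep(FALSE, length(ids)))
  IRanges::overlapsAny(gr, as_granges(keep[, c("chrom", "start", "end")]),
                       ignore.strand = TRUE)
}

#' Apply the four contrasting-pattern filters to candidate TFs
#'
#' Flags per TF: `expr_contrast` (DEG down in SPS->SUS and DEG up in
#' SUS->AUS), `atac_contrast` (promoter DAR loss then gain),
#' `meth_contrast` (promoter methylation summer-peaked: hyper DMR in
#' SPS->SUS and hypo DMR in SUS->AUS), `compartment_A_stable` (label A in
#' all three seasons; NaN counts as failure, annotated missing). A missing
#' layer (NULL input) yields NA flags for that layer, not FALSE.
#'
#' @param tf_ids candidate TF gene ids.
#' @param genes gene annotation.
#' @param de_ab,de_bc DE tables for SPS vs SUS and SUS vs AUS.
#' @param dars_ab,dars_bc DAR tables for the two comparisons.
#' @param dmrs_ab,dmrs_bc combined-context DMR tables for the two
#'   comparisons.
#' @param gene_comp gene x season compartment label matrix.
#' @param config a [default_config()]; `meth_contrast_mode` picks promoter
#'   or gene-body methylation evidence.
#' @return data.frame with the four flags, n_layers_passed and a note.
#' @export
apply_contrast_filters <- function(tf_ids, genes, de_ab, de_bc,
                                   dars_ab, dars_bc, dmrs_ab, dmrs_bc,
                                   gene_comp, config = default_config()) {
  de_flag <- function(de, dir) {
    if (is.null(de)) return(rep(NA, length(tf_ids)))
    i <- match(tf_ids, de$gene_id)
    out <- de$is_deg[i] & (if (dir == "down") de$log2fc[i] < 0 else de$log2fc[i] > 0)
    out[is.na(i)] <- FALSE
    out
  }
  expr_contrast <- de_flag(de_ab, "down") & de_flag(de_bc, "up")
  mode <- config$meth_contrast_mode
  atac_contrast <-
    overlap_flag(tf_ids, genes, dars_ab,
                 function(d) d$is_dar & d$direction == "loss", "promoter", config) &
    overlap_flag(tf_ids, genes, dars_bc,
                 function(d) d$is_dar & d$direction == "gain", "promoter", config)
  meth_contrast <-
    overlap_flag(tf_ids, genes, dmrs_ab,
                 function(d) d$direction == "hyper", mode, config) &
    overlap_flag(tf_ids, genes, dmrs_bc,
                 function(d) d$direction == "hypo", mode, config)
  if (is.null(gene_comp)) {
    compartment_A_stable <- rep(NA, length(tf_ids))
    comp_missing <- rep(TRUE, length(tf_ids))
  } else {
    comp <- gene_comp[tf_ids, , drop = FALSE]
    compartment_A_stable <- apply(comp, 1, function(v) all(v == "A"))
    comp_missing <- apply(comp, 1, function(v) any(v == "NaN"))
  }
  flags <- cbind(expr_contrast, atac_contrast, meth_contrast, compartment_A_stable)
  note <- ifelse(comp_missing, "compartment_missing", "")
  note[rowSums(is.na(flags)) > 0] <- paste0(note[rowSums(is.na(flags)) > 0],
                                            ";layer_missing")
  data.frame(tf_id = tf_ids,
             expr_contrast = expr_contrast, atac_contrast = atac_contrast,
             meth_contrast = meth_contrast,
             compartment_A_stable = compartment_A_stable,
             n_layers_passed = rowSums(flags, na.rm = TRUE),
             note = note, stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect the evidence layers and rank candidate TFs
#'
#' TFs with at least one network edge, ranked by the number of evidence
#' layers passed (0-4), ties broken by the maximal |r| of their edges and
#' then by tf_id. Also reports the per-layer set sizes.
#'
#' @param edges [build_correlation_network()] output.
#' @param flags [apply_contrast_filters()] output.
#' @return list of class `candidate_report`: `ranked` data.frame (with
#'   rank, indicator columns, max_abs_r, n_layers_passed) and
#'   `layer_counts`.
#' @export
intersect_and_rank <- function(edges, flags) {
  if (nrow(edges) == 0) {
    warning("empty correlation edge list: empty candidate report")
    return(structure(list(ranked = flags[0, ], layer_counts = NULL,
                          edges = edges), class = "candidate_report"))
  }
  max_r <- tapply(abs(edges$r), edges$tf_id, max)
  keep <- flags[flags$tf_id %in% names(max_r), , drop = FALSE]
  keep$max_abs_r <- as.numeric(max_r[keep$tf_id])
  ord <- order(-keep$n_layers_passed, -keep$max_abs_r, keep$tf_id)
  ranked <- keep[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  layer_counts <- c(
    expr = sum(ranked$expr_contrast, na.rm = TRUE),
    atac = sum(ranked$atac_contrast, na.rm = TRUE),
    meth = sum(ranked$meth_contrast, na.rm = TRUE),
    compartment = sum(ranked$compartment_A_stable, na.rm = TRUE),
    all_four = sum(ranked$n_layers_passed == 4, na.rm = TRUE))
  stopifnot(layer_counts[["all_four"]] <= min(layer_counts[1:4]))
  structure(list(ranked = ranked, layer_counts = layer_counts, edges = edges),
            class = "candidate_report")
}

#' Global cross-layer correlation of seasonal fold changes
#'
#' Spearman correlation between per-gene season-to-season log-fold-changes
#' of expression and accessibility, and between expression fold changes
#' and promoter methylation-level changes, with approximate Fisher-z
#' confidence intervals.
#'
#' @param expr_lfc,atac_lfc,meth_delta numeric vectors aligned on the same
#'   genes (and transitions); NA pairs are dropped.
#' @return data.frame layer_pair, rho, p, ci_lo, ci_hi, n.
#' @export
global_layer_correlations <- function(expr_lfc, atac_lfc = NULL, meth_delta = NULL) {
  one <- function(x, y, label) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 10) stop("fewer than 10 matched genes for ", label)
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
    rho <- unname(ct$estimate)
    z <- atanh(pmin(pmax(rho, -0.9999), 0.9999))
    se <- 1 / sqrt(sum(ok) - 3)
    data.frame(layer_pair = label, rho = rho, p = ct$p.value,
               ci_lo = tanh(z - 1.96 * se), ci_hi = tanh(z + 1.96 * se),
               n = sum(ok), stringsAsFactors = FALSE)
  }
  out <- list()
  if (!is.null(atac_lfc))
    out$atac <- one(expr_lfc, atac_lfc, "expression_vs_accessibility")
  if (!is.null(meth_delta))
    out$meth <- one(expr_lfc, meth_delta, "expression_vs_methylation")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
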