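## Seasonal expression analysis: normalization, differential expression,
## pattern labelling and profile clustering.

#' Normalize a count matrix into a seasonal expression object
#'
#' Computes FPKM (1e9 * count / (library_size * length)), log2-CPM with a
#' pseudocount, per-season means of log2-CPM over replicates, and per-gene
#' Z-scores of the season-mean vector.
#'
#' @param counts gene x sample matrix of nonnegative integer counts.
#' @param lengths gene lengths in bp, named by or aligned with rows.
#' @param sample_seasons character vector mapping columns to seasons
#'   (values among SPS/SUS/AUS).
#' @param lib_sizes optional explicit library sizes; defaults to column sums.
#' @param pseudocount pseudocount for log2-CPM.
#' @return list of class `seasonal_expression` with elements counts, fpkm,
#'   log2cpm, season_means, zscores, sample_seasons, lengths.
#' @export
normalize_expression <- function(counts, lengths, sample_seasons,
                                 lib_sizes = NULL, pseudocount = 0.5) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            length(lengths) == nrow(counts), all(lengths > 0),
            length(sample_seasons) == ncol(counts))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("zero library size")
  fpkm <- 1e9 * t(t(counts) / lib_sizes) / lengths
  l2 <- log2_cpm(counts, lib_sizes, pseudocount)
  u <- unique(sample_seasons)
  seasons <- c(intersect(SEASONS, u), setdiff(u, SEASONS))
  sm <- vapply(seasons, function(s)
    rowMeans(l2[, sample_seasons == s, drop = FALSE]), numeric(nrow(counts)))
  if (!is.matrix(sm))
    sm <- matrix(sm, nrow = nrow(counts), ncol = length(seasons),
                 dimnames = list(rownames(counts), seasons))
  centred <- sm - rowMeans(sm)
  s <- if (ncol(sm) > 1) sqrt(rowSums(centred^2) / (ncol(sm) - 1)) else rep(0, nrow(sm))
  z <- centred / ifelse(s > 0, s, Inf)
  dimnames(z) <- dimnames(sm)
  structure(list(counts = counts, fpkm = fpkm, log2cpm = l2,
                 season_means = sm, zscores = z,
                 sample_seasons = sample_seasons, lengths = lengths,
                 lib_sizes = lib_sizes),
            class = "seasonal_expression")
}

#' Seasonal differential expression (Welch test on log2-CPM)
#'
#' Per-gene Welch t-test on log2-CPM between two seasons, BH correction
#' over all tested genes, log2FC as the mean log2-CPM difference
#' (season_b - season_a). Genes whose summed counts across the tested
#' samples fall below `min_total` are excluded from testing. A gene is a
#' DEG iff fdr < de_fdr and |log2fc| > de_lfc (both strict, as printed).
#'
#' @param expr a `seasonal_expression`.
#' @param season_a,season_b season labels; log2fc is b relative to a.
#' @param config a [default_config()] bundle.
#' @return data.frame gene_id, comparison, log2fc, p, fdr, is_deg.
#' @export
differential_expression <- function(expr, season_a, season_b,
                                    config = default_config()) {
  ia <- expr$sample_seasons == season_a
  ib <- expr$sample_seasons == season_b
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("need >= 2 replicates per season for differential expression")
  tested <- rowSums(expr$counts[, ia | ib, drop = FALSE]) >= config$de_min_total
  a <- expr$log2cpm[tested, ia, drop = FALSE]
  b <- expr$log2cpm[tested, ib, drop = FALSE]
  w <- welch_rows(a, b)
  fdr <- stats::p.adjust(w$p, method = "BH")
  res <- data.frame(
    gene_id = rownames(expr$counts)[tested],
    comparison = paste0(season_a, "_vs_", season_b),
    log2fc = w$diff, p = w$p, fdr = fdr,
    is_deg = fdr < config$de_fdr & abs(w$diff) > config$de_lfc,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Label the seasonal pattern of a gene (or of any 3-season profile)
#'
#' Labels derive from the signs of the two sequential differences
#' (SUS - SPS, AUS - SUS) of the season-mean log2 profile, with a
#' minimal-effect deadband delta below which a difference counts as flat.
#'
#' @param means numeric length-3 vector (SPS, SUS, AUS) on a log2-like
#'   scale, or a matrix with 3 columns.
#' @param deadband minimal-effect deadband in the units of `means`.
#' @return character label(s) among high-low-high, low-high-low,
#'   monotone-up, monotone-down, flat, other.
#' @export
classify_seasonal_pattern <- function(means, deadband = 0.5) {
  if (is.matrix(means)) {
    stopifnot(ncol(means) == 3)
    return(apply(means, 1, classify_seasonal_pattern, deadband = deadband))
  }
  stopifnot(length(means) == 3)
  d1 <- means[2] - means[1]
  d2 <- means[3] - means[2]
  s1 <- if (d1 > deadband) 1L else if (d1 < -deadband) -1L else 0L
  s2 <- if (d2 > deadband) 1L else if (d2 < -deadband) -1L else 0L
  if (s1 == -1 && s2 == 1) "high-low-high"
  else if (s1 == 1 && s2 == -1) "low-high-low"
  else if (s1 >= 0 && s2 >= 0 && (s1 + s2) > 0) "monotone-up"
  else if (s1 <= 0 && s2 <= 0 && (s1 + s2) < 0) "monotone-down"
  else if (s1 == 0 && s2 == 0) "flat"
  else "other"
}

#' Label seasonal patterns for genes in an expression object
#' @param expr a `seasonal_expression`.
#' @param gene_ids genes to label (default all).
#' @param deadband log2 deadband (see [classify_seasonal_pattern()]).
#' @return named character vector of labels.
#' @export
seasonal_patterns <- function(expr, gene_ids = rownames(expr$counts),
                              deadband = 0.5) {
  missing <- setdiff(gene_ids, rownames(expr$season_means))
  if (length(missing)) stop("unknown gene(s): ", paste(utils::head(missing, 3), collapse = ", "))
  m <- expr$season_means[gene_ids, SEASONS, drop = FALSE]
  stats::setNames(classify_seasonal_pattern(m, deadband), gene_ids)
}

#' Hierarchical clustering of seasonal expression profiles
#'
#' Ward-linkage hierarchical clustering (Euclidean distance on per-gene
#' Z-scored season means), tree cut at k clusters. Genes are processed in
#' deterministic gene_id order so results do not depend on input order.
#' Each cluster is labelled by the seasonal pattern of its centroid
#' (deadband in Z units).
#'
#' @param expr a `seasonal_expression`.
#' @param gene_ids genes to cluster (default all).
#' @param k number of clusters (>= 1).
#' @param centroid_deadband deadband for centroid pattern labels, Z units.
#' @return list with `assignment` (data.frame gene_id, cluster) and
#'   `cluster_patterns` (named character vector).
#' @export
cluster_profiles <- function(expr, gene_ids = rownames(expr$counts), k,
                             centroid_deadband = 0.25) {
  stopifnot(k >= 1)
  gene_ids <- sort(unique(gene_ids))
  z <- expr$zscores[gene_ids, SEASONS, drop = FALSE]
  if (k > 1) {
    if (nrow(unique(as.data.frame(z))) < k)
      stop("fewer distinct profiles than k = ", k)
    hc <- stats::hclust(stats::dist(z), method = "ward.D2")
    cl <- stats::cutree(hc, k = k)
  } else {
    cl <- stats::setNames(rep(1L, length(gene_ids)), gene_ids)
  }
  centroids <- vapply(sort(unique(cl)), function(ci)
    colMeans(z[cl == ci, , drop = FALSE]), numeric(3))
  labels <- classify_seasonal_pattern(t(centroids), deadband = centroid_deadband)
  names(labels) <- paste0("C", sort(unique(cl)))
  list(assignment = data.frame(gene_id = gene_ids,
                               cluster = paste0("C", unname(cl)),
                               stringsAsFactors = FALSE),
       cluster_patterns = labels)
}
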