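## ATAC-seq side: peak-to-gene annotation, TSS enrichment, differential
## accessibility (DARs), replicate overlap. WGBS side: context-level
## methylation, a transparent window/merge DMR caller, direction tallies,
## and summit-centred methylation profiles.

## Strand-aware promoter windows as a GRanges: [tss - upstream, tss + downstream)
## in the gene's orientation ('.' treated as '+').
promoter_ranges <- function(genes, upstream = 3000, downstream = 3000) {
  if (upstream < 0 || downstream < 0) stop("promoter window sizes must be nonnegative")
  gr <- as_granges(genes)
  GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(gr, upstream = upstream, downstream = downstream)))
}

#' Assign peaks to genes via promoter overlap
#'
#' A peak is promoter-assigned to a gene iff it overlaps the strand-aware
#' window [tss - upstream, tss + downstream). Peaks may hit several genes;
#' peaks hitting none are labelled distal.
#'
#' @param peaks peak data.frame (chrom/start/end at least).
#' @param genes gene models from [read_annotation()].
#' @param upstream,downstream promoter window half-widths in bp.
#' @return list: `assignments` (data.frame peak row index, peak name if
#'   present, gene_id), `peak_type` (promoter/distal per peak),
#'   `genes_with_promoter_peak` (character vector).
#' @export
annotate_peaks_to_genes <- function(peaks, genes, upstream = 3000, downstream = 3000) {
  prom <- promoter_ranges(genes, upstream, downstream)
  pk <- as_granges(peaks[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(pk, prom, ignore.strand = TRUE)
  assignments <- data.frame(
    peak = S4Vectors::queryHits(hits),
    peak_name = if ("name" %in% names(peaks)) peaks$name[S4Vectors::queryHits(hits)] else NA_character_,
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  peak_type <- rep("distal", nrow(peaks))
  peak_type[unique(S4Vectors::queryHits(hits))] <- "promoter"
  list(assignments = assignments, peak_type = peak_type,
       genes_with_promoter_peak = sort(unique(assignments$gene_id)))
}

#' Average accessibility profile around TSS
#'
#' Strand-oriented per-bp coverage averaged over all TSS; positions falling
#' outside a chromosome are ignored (NA-averaged).
#'
#' @param coverage named list (per chromosome) of per-bp coverage vectors;
#'   element i covers 0-based position i - 1.
#' @param genes gene models (need chrom, tss, strand).
#' @param flank half-width in bp (> 0).
#' @return numeric vector of length 2 * flank + 1 (positions -flank..flank).
#' @export
tss_enrichment_profile <- function(coverage, genes, flank) {
  stopifnot(flank > 0)
  if (nrow(genes) == 0) stop("empty TSS list")
  offs <- -flank:flank
  acc <- matrix(NA_real_, nrow(genes), length(offs))
  for (i in seq_len(nrow(genes))) {
    cov <- coverage[[genes$chrom[i]]]
    if (is.null(cov)) next
    pos <- genes$tss[i] + offs
    ok <- pos >= 0 & pos < length(cov)
    v <- rep(NA_real_, length(offs))
    v[ok] <- cov[pos[ok] + 1L]
    if (genes$strand[i] == "-") v <- rev(v)
    acc[i, ] <- v
  }
  stats::setNames(colMeans(acc, na.rm = TRUE), offs)
}

#' Merge per-sample peak sets into a consensus
#'
#' Union of all peaks, merged at >= 1 bp overlap.
#' @param peak_list list of peak data.frames.
#' @return data.frame of consensus intervals with a `name` column.
#' @export
consensus_peaks <- function(peak_list) {
  all <- do.call(rbind, lapply(peak_list, function(p) p[, c("chrom", "start", "end")]))
  if (is.null(all) || nrow(all) == 0) stop("empty consensus peak set")
  merged <- from_granges(GenomicRanges::reduce(as_granges(all), ignore.strand = TRUE))
  merged <- merged[order(merged$chrom, merged$start), ]
  merged$name <- sprintf("cons_%04d", seq_len(nrow(merged)))
  rownames(merged) <- NULL
  merged
}

#' Sum a peak-level count matrix onto a consensus peak set
#' @param peaks peak data.frame whose rows match `counts` rows.
#' @param counts peak x sample count matrix.
#' @param consensus consensus intervals from [consensus_peaks()].
#' @return consensus x sample count matrix (zero rows for unmatched).
#' @export
consensus_counts <- function(peaks, counts, consensus) {
  stopifnot(nrow(peaks) == nrow(counts))
  hits <- GenomicRanges::findOverlaps(as_granges(peaks[, c("chrom", "start", "end")]),
                                      as_granges(consensus), ignore.strand = TRUE)
  out <- matrix(0, nrow(consensus), ncol(counts),
                dimnames = list(consensus$name, colnames(counts)))
  if (length(hits)) {
    part <- rowsum(counts[S4Vectors::queryHits(hits), , drop = FALSE],
                   group = S4Vectors::subjectHits(hits))
    out[as.integer(rownames(part)), ] <- part
  }
  out
}

#' Call differentially accessible regions (DARs)
#'
#' Library-size-normalized log2 counts over a shared consensus peak set;
#' per-peak Welch test between seasons. A peak is a DAR iff
#' |log2fc| >= dar_lfc (inclusive) and raw p <= dar_p (inclusive).
#' Direction is gain when season_b exceeds season_a.
#'
#' @param consensus consensus peak intervals.
#' @param counts consensus x sample count matrix.
#' @param sample_seasons season label per column.
#' @param season_a,season_b seasons to compare (b relative to a).
#' @param config a [default_config()].
#' @return data.frame with interval columns, log2fc, p, direction, is_dar.
#' @export
call_dars <- function(consensus, counts, sample_seasons, season_a, season_b,
                      config = default_config()) {
  if (nrow(consensus) == 0) stop("empty consensus peak set")
  ia <- sample_seasons == season_a
  ib <- sample_seasons == season_b
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("need >= 2 replicates per season for DAR calling")
  l2 <- log2_cpm(counts, pseudocount = 0.5)
  w <- welch_rows(l2[, ia, drop = FALSE], l2[, ib, drop = FALSE])
  res <- cbind(consensus[, c("chrom", "start", "end", "name")],
               data.frame(comparison = paste0(season_a, "_vs_", season_b),
                          log2fc = w$diff, p = w$p,
                          direction = ifelse(w$diff >= 0, "gain", "loss"),
                          is_dar = abs(w$diff) >= config$dar_lfc & w$p <= config$dar_p,
                          stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

#' Overlap two peak sets (replicate agreement)
#'
#' Pairs peaks by >= `min_overlap` bp reciprocal overlap and reports how
#' many peaks of each set are shared versus unique.
#'
#' @param peaks_a,peaks_b peak data.frames on the same genome.
#' @param min_overlap minimal overlap in bp (default 1).
#' @return list with a_total, b_total, a_shared, b_shared, a_only, b_only.
#' @export
replicate_overlap <- function(peaks_a, peaks_b, min_overlap = 1L) {
  ga <- as_granges(peaks_a[, c("chrom", "start", "end")])
  gb <- as_granges(peaks_b[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  a_shared <- length(unique(S4Vectors::queryHits(hits)))
  b_shared <- length(unique(S4Vectors::subjectHits(hits)))
  list(a_total = nrow(peaks_a), b_total = nrow(peaks_b),
       a_shared = a_shared, b_shared = b_shared,
       a_only = nrow(peaks_a) - a_shared, b_only = nrow(peaks_b) - b_shared)
}

## ---- WGBS ------------------------------------------------------------------

#' Coverage-weighted methylation level per context
#'
#' level(context) = sum(methylated) / sum(total) over the sites of that
#' context, optionally restricted to a region set. Absent contexts are NA
#' (missing), never zero.
#'
#' @param sites methylation site table (see [read_methylation()]).
#' @param regions optional interval data.frame restricting the sites.
#' @return named numeric vector over CG/CHG/CHH.
#' @export
methylation_level_by_context <- function(sites, regions = NULL) {
  stopifnot(nrow(sites) > 0)
  if (!is.null(regions)) {
    if (nrow(regions) == 0) {
      return(stats::setNames(rep(NA_real_, 3), METH_CONTEXTS))
    }
    sgr <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos + 1L, width = 1L))
    keep <- IRanges::overlapsAny(sgr, as_granges(regions), ignore.strand = TRUE)
    sites <- sites[keep, , drop = FALSE]
  }
  vapply(METH_CONTEXTS, function(ctx) {
    s <- sites[sites$context == ctx, , drop = FALSE]
    if (nrow(s) == 0 || sum(s$total) == 0) NA_real_ else sum(s$methylated) / sum(s$total)
  }, numeric(1))
}

## Pearson chi-square p-values (Yates-corrected, as stats::chisq.test does
## for 2x2 tables) for a vector of 2x2 tables given as
## (methylated_a, total_a, methylated_b, total_b); degenerate margins -> 1.
chisq_2x2_p <- function(ma, ta, mb, tb) {
  n <- ta + tb
  mm <- ma + mb
  uu <- n - mm
  denom <- as.numeric(ta) * tb * mm * uu
  num <- pmax(abs(as.numeric(ma) * (tb - mb) - as.numeric(mb) * (ta - ma)) - n / 2, 0)
  stat <- ifelse(denom > 0, n * num^2 / denom, 0)
  ifelse(denom > 0, stats::pchisq(stat, df = 1, lower.tail = FALSE), 1)
}

#' Call differentially methylated regions (DMRs)
#'
#' Transparent sliding-window procedure: windows of `dmr_window` bp every
#' `dmr_step` bp that contain >= `dmr_min_sites` cytosines of the context
#' (covered in both samples) are tested on pooled counts (chi-square by
#' default, Fisher optionally); windows with BH q < dmr_q and
#' |level difference| >= delta are called and overlapping same-direction
#' windows are merged. Direction is hyper when sample b exceeds sample a.
#'
#' @param sites_a,sites_b methylation tables of the two samples (or pooled
#'   season groups) for one context.
#' @param context CG, CHG or CHH; must match the tables.
#' @param config a [default_config()].
#' @return data.frame chrom, start, end, context, level_a, level_b, q,
#'   direction.
#' @export
call_dmrs <- function(sites_a, sites_b, context, config = default_config()) {
  stopifnot(context %in% METH_CONTEXTS)
  a <- sites_a[sites_a$context == context, , drop = FALSE]
  b <- sites_b[sites_b$context == context, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("context mismatch: no ", context, " sites in one of the samples")
  j <- merge(a[, c("chrom", "pos", "methylated", "total")],
             b[, c("chrom", "pos", "methylated", "total")],
             by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  j <- j[j$total_a >= config$dmr_min_coverage & j$total_b >= config$dmr_min_coverage, ]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      context = character(), level_a = numeric(),
                      level_b = numeric(), q = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (nrow(j) == 0) return(empty)
  win <- as.integer(config$dmr_window); step <- as.integer(config$dmr_step)
  stopifnot(win %% step == 0)
  ratio <- win %/% step
  ## each site belongs to `ratio` windows; window w spans [w*step, w*step + win)
  reps <- do.call(rbind, lapply(0:(ratio - 1), function(k) {
    w <- j$pos %/% step - k
    cbind(j, w = w)[w >= 0, , drop = FALSE]
  }))
  key <- paste(reps$chrom, reps$w, sep = "\r")
  agg <- rowsum(cbind(ma = reps$methylated_a, ta = reps$total_a,
                      mb = reps$methylated_b, tb = reps$total_b,
                      n = 1), group = key)
  agg <- as.data.frame(agg)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  agg$chrom <- vapply(parts, `[`, character(1), 1)
  agg$w <- as.integer(vapply(parts, `[`, character(1), 2))
  agg <- agg[agg$n >= config$dmr_min_sites, , drop = FALSE]
  if (nrow(agg) == 0) return(empty)
  agg$level_a <- agg$ma / agg$ta
  agg$level_b <- agg$mb / agg$tb
  agg$diff <- agg$level_b - agg$level_a
  if (identical(config$dmr_method, "fisher")) {
    agg$p <- mapply(function(ma, ta, mb, tb)
      stats::fisher.test(matrix(c(ma, ta - ma, mb, tb - mb), 2))$p.value,
      agg$ma, agg$ta, agg$mb, agg$tb)
  } else {
    agg$p <- chisq_2x2_p(agg$ma, agg$ta, agg$mb, agg$tb)
  }
  agg$q <- stats::p.adjust(agg$p, method = "BH")
  delta <- if (context == "CHH") config$dmr_delta_chh else config$dmr_delta_cg
  called <- agg[agg$q < config$dmr_q & abs(agg$diff) >= delta, , drop = FALSE]
  if (nrow(called) == 0) return(empty)
  called$start <- called$w * step
  called$end <- called$start + win
  called$direction <- ifelse(called$diff > 0, "hyper", "hypo")
  called <- called[order(called$chrom, called$start), ]
  ## merge overlapping same-direction windows per chromosome
  out <- list()
  for (ch in unique(called$chrom)) {
    for (dir in unique(called$direction)) {
      cw <- called[called$chrom == ch & called$direction == dir, , drop = FALSE]
      if (!nrow(cw)) next
      grp <- cumsum(c(1, cw$start[-1] > cummax(cw$end)[-nrow(cw)]))
      for (g in unique(grp)) {
        sub <- cw[grp == g, , drop = FALSE]
        ## a reported DMR must span a sustained run of called windows
        ## (>= dmr_min_run), the analogue of a minimum-CpG rule
        if (nrow(sub) < config$dmr_min_run) next
        s0 <- min(sub$start); e0 <- max(sub$end)
        in_reg <- j$chrom == ch & j$pos >= s0 & j$pos < e0
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = s0, end = e0, context = context,
          level_a = sum(j$methylated_a[in_reg]) / sum(j$total_a[in_reg]),
          level_b = sum(j$methylated_b[in_reg]) / sum(j$total_b[in_reg]),
          q = min(sub$q), direction = dir, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Tally DMRs by direction
#' @param dmrs DMR table(s) from [call_dmrs()]; may carry extra grouping
#'   columns (comparison, context).
#' @return data.frame of hyper/hypo counts per present grouping.
#' @export
classify_dmr_direction <- function(dmrs) {
  if (nrow(dmrs) == 0)
    return(data.frame(direction = c("hyper", "hypo"), n = c(0L, 0L)))
  grp_cols <- intersect(c("comparison", "context"), names(dmrs))
  f <- c(lapply(dmrs[grp_cols], identity),
         list(direction = factor(dmrs$direction, c("hyper", "hypo"))))
  out <- as.data.frame(table(f), stringsAsFactors = FALSE)
  names(out)[ncol(out)] <- "n"
  out
}

#' Methylation profile around peak summits
#'
#' Coverage-weighted per-context level in bins of `bin_size` bp over
#' [-flank, flank] around each summit, averaged over summits (sites near
#' several summits contribute to each).
#'
#' @param sites methylation table.
#' @param summits data.frame with chrom and pos (0-based summit positions).
#' @param flank half-width in bp (default 1000).
#' @param bin_size bin width in bp (default 50).
#' @return matrix contexts x (2 * flank / bin_size + 1) of levels (NA where
#'   a context has no sites in a bin).
#' @export
methylation_profile_around_summits <- function(sites, summits, flank = 1000,
                                               bin_size = 50) {
  stopifnot(flank > 0, bin_size > 0)
  k <- as.integer(round(flank / bin_size))
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, width = 1L))
  wgr <- GenomicRanges::GRanges(summits$chrom,
                                IRanges::IRanges(pmax(summits$pos - flank, 0) + 1L,
                                                 summits$pos + flank + 1L))
  hits <- GenomicRanges::findOverlaps(sgr, wgr, ignore.strand = TRUE)
  if (!length(hits)) stop("no summit has any methylation site within the flank")
  si <- S4Vectors::queryHits(hits); wi <- S4Vectors::subjectHits(hits)
  offset <- sites$pos[si] - summits$pos[wi]
  bin <- pmin(pmax(as.integer(round(offset / bin_size)), -k), k)
  key <- paste(sites$context[si], bin, sep = "\r")
  agg <- rowsum(cbind(m = sites$methylated[si], t = sites$total[si]), group = key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  prof <- matrix(NA_real_, 3, 2 * k + 1,
                 dimnames = list(METH_CONTEXTS, seq(-k, k) * bin_size))
  prof[cbind(match(parts[, 1], METH_CONTEXTS),
             as.integer(parts[, 2]) + k + 1L)] <- agg[, "m"] / agg[, "t"]
  prof
}
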