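## Hi-C: matrix balancing (iterative proportional fitting), distance
## normalization (observed/expected), A/B compartment eigenvector calling
## with gene-density sign orientation, and three-season switch strings.

## Mask bad bins: zero marginal, or marginal strictly below the type-1
## empirical quantile of the nonzero marginals.
mask_bad_bins <- function(cm, mask_quantile = 0.02) {
  marg <- rowSums(cm$matrix)
  thr <- if (any(marg > 0))
    stats::quantile(marg[marg > 0], mask_quantile, type = 1, names = FALSE)
  else Inf
  cm$mask <- cm$mask | marg == 0 | marg < thr
  cm
}

#' Balance a contact matrix by iterative proportional fitting
#'
#' Scales rows/columns symmetrically until all unmasked marginals are equal
#' (max relative deviation < tol). Bins with zero marginal (and those below
#' the masking quantile) are masked first and excluded.
#'
#' @param cm a `contact_matrix`.
#' @param tol convergence tolerance on relative marginal deviation.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param mask_quantile marginal quantile below which bins are masked.
#' @return balanced `contact_matrix` (masked rows/columns set to 0).
#' @export
balance_matrix <- function(cm, tol = 1e-5, max_iter = 500, mask_quantile = 0.02) {
  stopifnot(inherits(cm, "contact_matrix"))
  cm <- mask_bad_bins(cm, mask_quantile)
  keep <- !cm$mask
  if (sum(keep) < 2) stop("fewer than 2 unmasked bins")
  m <- cm$matrix[keep, keep, drop = FALSE]
  bias <- rep(1, nrow(m))
  resid <- Inf
  for (it in seq_len(max_iter)) {
    marg <- rowSums(m)
    resid <- max(abs(marg / mean(marg) - 1))
    if (resid < tol) break
    s <- sqrt(marg / mean(marg))
    m <- m / outer(s, s)
    bias <- bias * s
  }
  if (resid >= tol)
    stop("balancing did not converge in ", max_iter,
         " iterations (residual ", signif(resid, 3), ")")
  out <- matrix(0, nrow(cm$matrix), ncol(cm$matrix))
  out[keep, keep] <- m
  contact_matrix(out, cm$bin_size, cm$chrom, mask = cm$mask)
}

#' Observed-over-expected transformation
#'
#' Divides each entry by the mean of its |i - j| diagonal over unmasked
#' entries. Empty diagonals yield NA.
#'
#' @param cm a (balanced) `contact_matrix`.
#' @return `contact_matrix` whose matrix holds O/E ratios.
#' @export
observed_over_expected <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- nrow(cm$matrix)
  keep <- !cm$mask
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  ok <- outer(keep, keep, `&`)
  sums <- rowsum(cm$matrix[ok], d[ok])
  cnts <- rowsum(rep(1, sum(ok)), d[ok])
  expd <- stats::setNames(as.numeric(sums / cnts), rownames(sums))
  e <- matrix(expd[as.character(d)], n, n)
  oe <- ifelse(ok & e > 0, cm$matrix / e, NA_real_)
  out <- cm
  out$matrix <- oe
  out
}

#' Call A/B compartments from an O/E matrix
#'
#' First principal eigenvector of the Pearson correlation matrix of the
#' O/E matrix (unmasked bins); the sign is oriented so the eigenvector
#' correlates positively with gene density (A compartment = gene dense).
#' A iff oriented value > 0; masked bins are NaN.
#'
#' @param oe O/E `contact_matrix` from [observed_over_expected()].
#' @param gene_density numeric per-bin gene counts (or any reference track
#'   whose high values mark the A compartment).
#' @return data.frame bin (1-based), value, label (A/B/NaN character).
#' @export
call_compartments <- function(oe, gene_density) {
  stopifnot(inherits(oe, "contact_matrix"))
  n <- nrow(oe$matrix)
  stopifnot(length(gene_density) == n)
  keep <- !oe$mask
  if (sum(keep) < 4) stop("need >= 4 unmasked bins")
  sub <- oe$matrix[keep, keep, drop = FALSE]
  sds <- apply(sub, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("degenerate correlation matrix: zero-variance bin(s) in O/E")
  cc <- stats::cor(sub, use = "pairwise.complete.obs")
  if (any(!is.finite(cc))) stop("degenerate correlation matrix")
  ev <- eigen(cc, symmetric = TRUE)
  e1 <- ev$vectors[, 1]
  orient <- stats::cor(e1, gene_density[keep])
  if (is.finite(orient) && orient < 0) e1 <- -e1
  value <- rep(NA_real_, n)
  value[keep] <- e1
  label <- rep("NaN", n)
  label[keep] <- ifelse(e1 > 0, "A", "B")
  data.frame(bin = seq_len(n), value = value, label = label,
             stringsAsFactors = FALSE)
}

#' Classify per-bin compartment switches across three seasons
#'
#' Concatenates the per-season labels into strings like "A2A2B" and counts
#' each pattern; any NaN label yields a NaN-containing pattern.
#'
#' @param tracks named list of compartment tracks (SPS, SUS, AUS) sharing
#'   the same binning.
#' @return list with `labels` (per-bin strings) and `counts` (table).
#' @export
classify_switches <- function(tracks) {
  stopifnot(length(tracks) == 3)
  nb <- vapply(tracks, nrow, integer(1))
  if (length(unique(nb)) != 1) stop("binning mismatch between seasons")
  lab <- do.call(paste, c(lapply(tracks, `[[`, "label"), sep = "2"))
  list(labels = lab, counts = table(lab))
}

#' Assign genes to compartments by TSS bin
#'
#' A gene inherits the label of the bin containing its TSS; a TSS outside
#' the binned range yields NaN with a warning.
#'
#' @param track compartment track from [call_compartments()] for one
#'   chromosome.
#' @param genes gene models on that chromosome.
#' @param bin_size bin width in bp.
#' @return named character vector gene_id -> label.
#' @export
assign_gene_compartments <- function(track, genes, bin_size) {
  bin <- genes$tss %/% bin_size + 1L
  out <- rep("NaN", nrow(genes))
  inside <- bin >= 1 & bin <= nrow(track)
  if (any(!inside)) warning(sum(!inside), " TSS outside binned range -> NaN")
  out[inside] <- track$label[bin[inside]]
  stats::setNames(out, genes$gene_id)
}

#' Full per-chromosome compartment calling
#'
#' Convenience wrapper: balance, O/E, eigenvector call.
#' @param cm raw `contact_matrix`.
#' @param gene_density per-bin gene counts.
#' @param config a [default_config()].
#' @return compartment track data.frame.
#' @export
compartment_track <- function(cm, gene_density, config = default_config()) {
  bal <- balance_matrix(cm, tol = config$balance_tol,
                        max_iter = config$balance_max_iter,
                        mask_quantile = config$mask_quantile)
  call_compartments(observed_over_expected(bal), gene_density)
}
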