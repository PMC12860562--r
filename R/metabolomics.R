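## Targeted metabolomics: external calibration, content quantification,
## class aggregation, differential-accumulation calling, and the
## contrasting-pattern screen (down in SPS->SUS, up in SUS->AUS).

#' Fixed metabolite class vocabulary
#' @export
METABOLITE_CLASSES <- c("cyanidins", "delphinidins", "peonidins", "malvidins",
                        "petunidins", "pelargonidins", "proanthocyanidins",
                        "flavonoids")

#' Fit an external calibration curve
#'
#' Ordinary least squares of instrument response on standard concentration.
#' The fitted curve supports inversion (response -> concentration) for
#' sample quantification.
#'
#' @param concentrations standard concentrations (ng/ml), >= 3 distinct.
#' @param responses instrument responses at those concentrations.
#' @return list of class `calibration_curve`: slope, intercept, r_squared,
#'   level_range.
#' @export
fit_calibration <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 3)
    stop("insufficient data: calibration needs >= 3 standards")
  if (stats::sd(concentrations) == 0)
    stop("degenerate fit: standards have zero concentration variance")
  fit <- stats::lm(responses ~ concentrations)
  co <- stats::coef(fit)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((responses - mean(responses))^2)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = if (sst > 0) 1 - ssr / sst else 1,
                 level_range = range(concentrations)),
            class = "calibration_curve")
}

#' Invert a calibration curve: response to concentration
#' @param curve a `calibration_curve`.
#' @param response instrument response(s).
#' @return concentration(s) in ng/ml; negative inversions clamp to 0.
#' @export
invert_calibration <- function(curve, response) {
  pmax((response - curve$intercept) / curve$slope, 0)
}

#' Compute analyte content from curve concentration
#'
#' content (ug/g) = (c * V) / (100000 * m), with c the curve-derived
#' concentration (ng/ml), V the extraction volume (ul) and m the sample
#' mass (g).
#'
#' @param c_ngml concentration from the calibration curve (ng/ml), >= 0.
#' @param volume_ul extraction volume V (ul), > 0.
#' @param mass_g sample mass m (g), > 0.
#' @return content in ug/g.
#' @export
quantify_content <- function(c_ngml, volume_ul, mass_g) {
  if (any(volume_ul <= 0) || any(mass_g <= 0))
    stop("extraction volume and sample mass must be positive")
  if (any(c_ngml < 0)) stop("negative concentration")
  (c_ngml * volume_ul) / (100000 * mass_g)
}

#' Aggregate a metabolite table by compound class
#'
#' @param table data.frame with columns metabolite, class and one numeric
#'   column per sample.
#' @param sample_seasons optional season for each sample column, for
#'   per-season content sums.
#' @return list with `counts` (named integer vector over the fixed class
#'   vocabulary), `total` metabolites, and `content_by_season` (class x
#'   season summed content) when seasons are given.
#' @export
aggregate_by_class <- function(table, sample_seasons = NULL) {
  stopifnot(nrow(table) > 0, all(c("metabolite", "class") %in% names(table)))
  bad <- !table$class %in% METABOLITE_CLASSES
  if (any(bad)) stop("unknown metabolite class '", table$class[which(bad)[1]], "'")
  counts <- vapply(METABOLITE_CLASSES, function(cl) sum(table$class == cl), integer(1))
  out <- list(counts = counts, total = nrow(table))
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  if (!is.null(sample_seasons) && length(num_cols)) {
    stopifnot(length(sample_seasons) == length(num_cols))
    seasons <- intersect(SEASONS, unique(sample_seasons))
    m <- as.matrix(table[, num_cols, drop = FALSE])
    per_season <- vapply(seasons, function(s)
      rowSums(m[, sample_seasons == s, drop = FALSE]), numeric(nrow(table)))
    out$content_by_season <- rowsum(per_season, group = factor(table$class, METABOLITE_CLASSES))
  }
  out
}

#' Call differentially accumulated metabolites (DAMs)
#'
#' log2 fold change on group means with a pseudocount; Welch t-test on
#' log2-transformed contents; BH correction. A metabolite is a DAM iff
#' q < q_thresh and |log2fc| >= lfc_thresh. The direction is the sign of
#' log2fc (group_b relative to group_a).
#'
#' @param contents metabolite x sample matrix of contents (ug/g).
#' @param group_a,group_b column indices or logical masks of the two groups
#'   (>= 2 replicates each).
#' @param q_thresh,lfc_thresh,pseudocount calling parameters.
#' @return data.frame metabolite, log2fc, p, q, is_dam, direction.
#' @export
call_dams <- function(contents, group_a, group_b,
                      q_thresh = 0.05, lfc_thresh = 1, pseudocount = 0.01) {
  a <- contents[, group_a, drop = FALSE]
  b <- contents[, group_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stop("insufficient replication: need >= 2 replicates per group")
  la <- log2(a + pseudocount)
  lb <- log2(b + pseudocount)
  w <- welch_rows(la, lb)
  lfc <- log2(rowMeans(b) + pseudocount) - log2(rowMeans(a) + pseudocount)
  q <- stats::p.adjust(w$p, method = "BH")
  data.frame(metabolite = rownames(contents),
             log2fc = lfc, p = w$p, q = q,
             is_dam = q < q_thresh & abs(lfc) >= lfc_thresh,
             direction = ifelse(lfc >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Contrasting-pattern metabolite screen
#'
#' Intersects metabolites called down in the SPS->SUS comparison with
#' those called up in the SUS->AUS comparison - the signature of pigments
#' depleted in green summer leaves and restored in autumn.
#'
#' @param dams_sps_sus,dams_sus_aus DAM tables from [call_dams()] over the
#'   same metabolite universe.
#' @param classes optional named class vector for the per-class breakdown.
#' @return list with `metabolites` (character vector) and `class_counts`.
#' @export
contrasting_metabolite_screen <- function(dams_sps_sus, dams_sus_aus,
                                          classes = NULL) {
  down <- dams_sps_sus$metabolite[dams_sps_sus$is_dam & dams_sps_sus$direction == "down"]
  up <- dams_sus_aus$metabolite[dams_sus_aus$is_dam & dams_sus_aus$direction == "up"]
  hits <- sort(intersect(down, up))
  out <- list(metabolites = hits)
  if (!is.null(classes)) {
    cc <- table(factor(classes[hits], METABOLITE_CLASSES))
    out$class_counts <- stats::setNames(as.integer(cc), names(cc))
  }
  out
}
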