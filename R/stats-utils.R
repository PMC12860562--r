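## Row-wise Welch t-tests over feature matrices.
##
## Closed-form Welch statistic with Satterthwaite degrees of freedom,
## vectorized over features; degenerate rows (zero pooled standard error)
## get p = 1 when the means agree and p = 0 otherwise, so that identical
## groups yield no calls instead of an error. Cross-checked against
## stats::t.test() in the test suite.

#' Row-wise Welch two-sample t-test
#'
#' @param a,b numeric matrices (features x replicates) on a log-like scale.
#' @return data.frame with columns diff (mean b - mean a), t, df, p.
#' @export
welch_rows <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), nrow(a) == nrow(b),
            ncol(a) >= 2, ncol(b) >= 2)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  d <- mb - ma
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degen <- !is.finite(se2) | se2 == 0
  p[degen] <- ifelse(abs(d[degen]) < .Machine$double.eps^0.5, 1, 0)
  t[degen] <- ifelse(abs(d[degen]) < .Machine$double.eps^0.5, 0, Inf * sign(d[degen]))
  df[degen] <- NA_real_
  data.frame(diff = d, t = t, df = df, p = p)
}

## Negative-binomial (Poisson-gamma) count draw with mean mu and
## dispersion phi (Var = mu + phi * mu^2); phi = 0 falls back to Poisson.
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

## log2 counts-per-million with pseudocount
log2_cpm <- function(counts, lib_sizes = NULL, pseudocount = 0.5) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("zero library size")
  log2(t(t(counts + pseudocount) / lib_sizes) * 1e6)
}
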