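# Shared fixtures. The default-seed pipeline run is expensive (~5 s), so it
# is computed once per test session and shared across files.

.cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (is.null(.cache$pipeline))
    .cache$pipeline <- run_pipeline(simulation_config(seed = 1))
  .cache$pipeline
}

default_sim <- function() default_pipeline()$sim

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                             max_len = 500) {
  start <- floor(runif(n, 0, max_pos))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = as.integer(start),
             end = as.integer(start + ceiling(runif(n, 1, max_len))),
             stringsAsFactors = FALSE)
}

# O(n*m) brute-force interval overlap oracle (half-open coordinates)
brute_overlap_pairs <- function(a, b) {
  hits <- which(outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
    a$chrom[i] == b$chrom[j] & a$start[i] < b$end[j] & b$start[j] < a$end[i]),
    arr.ind = TRUE)
  hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
}

toy_genes <- function(df) {
  df$gene_id <- sprintf("g%03d", seq_len(nrow(df)))
  df$is_tf <- FALSE
  df$tf_family <- NA_character_
  df
}

# adjusted Rand index, computed from the contingency-table formula
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  a <- sum_comb(tab)
  b1 <- sum_comb(rowSums(tab)); b2 <- sum_comb(colSums(tab))
  expected <- b1 * b2 / choose(n, 2)
  (a - expected) / ((b1 + b2) / 2 - expected)
}
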