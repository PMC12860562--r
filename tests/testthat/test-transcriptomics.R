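make_expr <- function(counts, lengths = NULL, seasons = NULL, ...) {
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  if (is.null(seasons)) seasons <- rep(SEASONS, each = ncol(counts) / 3)
  normalize_expression(counts, lengths, seasons, ...)
}

test_that("FPKM follows its definition and is library-size invariant", {
  counts <- matrix(c(100, 900), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  e <- normalize_expression(counts, lengths = c(1000, 1000), "SPS",
                            lib_sizes = 1e6)
  expect_equal(e$fpkm["g1", 1], 100)
  expect_equal(normalize_expression(matrix(0, 1, 1), 500, "SPS",
                                    lib_sizes = 10)$fpkm[1, 1], 0)
  counts9 <- matrix(rpois(90, 50), 10, 9,
                    dimnames = list(sprintf("g%02d", 1:10), NULL))
  e1 <- make_expr(counts9)
  e2 <- make_expr(counts9 * 2)
  expect_equal(e1$fpkm, e2$fpkm)
  expect_error(normalize_expression(matrix(0, 1, 1), 500, "SPS"), "library")
})

test_that("Z-scores of season means are centred unless degenerate", {
  counts <- matrix(rpois(45, 100), 5, 9,
                   dimnames = list(sprintf("g%d", 1:5), NULL))
  e <- make_expr(counts)
  expect_true(all(abs(rowMeans(e$zscores)) < 1e-10))
})

test_that("identical groups give null DE results; swap negates log2fc", {
  counts <- matrix(rpois(60, 80), 10, 6,
                   dimnames = list(sprintf("g%02d", 1:10), NULL))
  counts <- cbind(counts[, 1:3], counts[, 1:3])
  e <- normalize_expression(counts, rep(1000, 10),
                            c("SPS", "SPS", "SPS", "SUS", "SUS", "SUS"))
  d <- differential_expression(e, "SPS", "SUS")
  expect_equal(d$log2fc, rep(0, nrow(d)))
  expect_equal(sum(d$is_deg), 0)
  ## antisymmetry on real data
  sim <- default_sim()
  e2 <- normalize_expression(sim$rna$counts, sim$rna$lengths,
                             sim$rna$sample_seasons)
  ab <- differential_expression(e2, "SPS", "SUS")
  ba <- differential_expression(e2, "SUS", "SPS")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$is_deg, ba$is_deg)
  expect_error(differential_expression(e2, "SPS", "nope"), "replicates")
})

test_that("planted 8x genes are recovered as DEGs with the right sign", {
  p <- default_pipeline()
  de <- p$de$SPS_vs_SUS
  master <- de[de$gene_id == PLANTED_IDS[["master"]], ]
  expect_true(master$is_deg)
  expect_lt(master$log2fc, 0)    # summer-repressed
  neg <- de[de$gene_id == PLANTED_IDS[["negative"]], ]
  expect_true(neg$is_deg)
  expect_gt(neg$log2fc, 0)       # summer-induced
})

test_that("null DE simulation keeps the q < 0.05 fraction at the nominal rate", {
  set.seed(55)
  counts <- simulate_null_counts(2000, dispersion = 0.05)
  e <- normalize_expression(counts, rep(1000, 2000),
                            c(rep("SPS", 3), rep("SUS", 3)))
  d <- differential_expression(e, "SPS", "SUS", default_config(de_lfc = 0))
  mc_sigma <- sqrt(0.05 * 0.95 / nrow(d))
  expect_lte(mean(d$fdr < 0.05), 0.05 + 3 * mc_sigma)
})

test_that("pattern labels follow the two-difference sign rule with deadband", {
  expect_equal(classify_seasonal_pattern(log2(c(10, 2, 11)), 0.5), "high-low-high")
  expect_equal(classify_seasonal_pattern(log2(c(5, 5, 5)), 0.5), "flat")
  expect_equal(classify_seasonal_pattern(c(0, 2, 0), 0.5), "low-high-low")
  expect_equal(classify_seasonal_pattern(c(0, 1, 2), 0.5), "monotone-up")
  expect_equal(classify_seasonal_pattern(c(2, 1.8, 0), 0.5), "monotone-down")
  sim <- default_sim()
  e <- normalize_expression(sim$rna$counts, sim$rna$lengths, sim$rna$sample_seasons)
  expect_error(seasonal_patterns(e, "not_a_gene"), "unknown")
  ## scaling invariance: labels unchanged when all counts double
  ## (away from the deadband boundary, where the log pseudocount can
  ## nudge a borderline gene across)
  e2 <- normalize_expression(sim$rna$counts * 2L, sim$rna$lengths,
                             sim$rna$sample_seasons)
  d <- cbind(e$season_means[, "SUS"] - e$season_means[, "SPS"],
             e$season_means[, "AUS"] - e$season_means[, "SUS"])
  clear <- rownames(d)[apply(abs(abs(d) - 0.5), 1, min) > 0.06]
  expect_gt(length(clear), 100)
  expect_equal(seasonal_patterns(e)[clear], seasonal_patterns(e2)[clear])
})

test_that("pattern labels recover the planted truth for >= 95% of seasonal genes", {
  p <- default_pipeline()
  truth <- p$sim$truth$patterns
  ids <- c(p$sim$truth$seasonal_ids, unlist(p$sim$truth$planted))
  agree <- mean(p$patterns[ids] == truth[ids])
  expect_gte(agree, 0.95)
})

test_that("profile clustering separates archetypes and labels centroids", {
  set.seed(30)
  arch <- seasomics:::archetype_multipliers(8)
  counts <- do.call(rbind, lapply(seq_along(arch), function(i)
    matrix(rep(round(500 * rep(arch[[i]], each = 3)), 10), 10, 9, byrow = TRUE)))
  rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  truth <- rep(seq_along(arch), each = 10)
  e <- make_expr(counts)
  cl <- cluster_profiles(e, k = 6)
  expect_equal(adjusted_rand(cl$assignment$cluster, truth), 1)
  expect_equal(length(unique(cl$assignment$cluster)), 6)
  ## noisy archetypes still recover the partition well
  noisy <- round(counts * matrix(2^rnorm(length(counts), 0, 0.2), nrow(counts)))
  en <- make_expr(noisy)
  cln <- cluster_profiles(en, k = 6)
  expect_gte(adjusted_rand(cln$assignment$cluster, truth), 0.9)
  ## k = 1 puts everything together
  cl1 <- cluster_profiles(e, k = 1)
  expect_equal(unique(cl1$assignment$cluster), "C1")
  expect_error(cluster_profiles(e, gene_ids = rownames(counts)[1:3], k = 5),
               "distinct profiles")
})

test_that("BH-adjusted values are monotone in p and never smaller than p", {
  p <- default_pipeline()
  d <- p$de$SPS_vs_SUS
  expect_true(all(d$fdr >= d$p - 1e-12))
  o <- order(d$p)
  expect_true(all(diff(d$fdr[o]) >= -1e-12))
})
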