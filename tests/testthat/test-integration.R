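test_that("DEG epigenome classification computes fractions from overlaps", {
  genes <- toy_genes(data.frame(chrom = "chr1",
                                start = seq(0, 9000, 1000),
                                end = seq(0, 9000, 1000) + 500,
                                strand = "+", tss = seq(0, 9000, 1000),
                                stringsAsFactors = FALSE))
  de <- data.frame(gene_id = genes$gene_id, comparison = "SPS_vs_SUS",
                   log2fc = 2, p = 0.001, fdr = 0.001, is_deg = TRUE,
                   stringsAsFactors = FALSE)
  dars <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                     end = c(100, 1100, 2100), is_dar = TRUE,
                     stringsAsFactors = FALSE)
  comp <- matrix("A", 10, 3, dimnames = list(genes$gene_id, SEASONS))
  cfg <- default_config(promoter_upstream = 100, promoter_downstream = 100)
  out <- deg_epigenome_classification(list(de), dars, NULL, comp, genes, cfg)
  expect_equal(out$fractions$frac_dar, 0.3)
  expect_equal(out$fractions$frac_meth, 0)
  expect_equal(out$fractions$frac_switch, 0)
  expect_equal(out$fractions$n_dual, 0)
  ## permutation invariance of the DEG input
  out2 <- deg_epigenome_classification(list(de[10:1, ]), dars, NULL, comp,
                                       genes, cfg)
  expect_equal(out2$fractions, out$fractions)
  de0 <- de; de0$is_deg <- FALSE
  expect_error(deg_epigenome_classification(list(de0), dars, NULL, comp,
                                            genes, cfg), "empty DEG")
})

test_that("correlation edges follow |r| with a strict threshold", {
  counts <- matrix(rpois(5 * 9, 200), 5, 9,
                   dimnames = list(c("tf1", "tf2", "tf3", "t1", "t2"), NULL))
  counts["tf1", ] <- counts["t1", ]                       # identical profile
  e <- normalize_expression(counts, rep(1000, 5), rep(SEASONS, each = 3))
  ## tf2 = negated-centred target on the log scale; tf3 = constant (skipped)
  l2 <- e$log2cpm
  e$log2cpm["tf2", ] <- 2 * mean(l2["t2", ]) - l2["t2", ]
  e$log2cpm["tf1", ] <- l2["t1", ]
  e$log2cpm["tf3", ] <- 5
  expect_warning(edges <- build_correlation_network(e, c("tf1", "tf2", "tf3"),
                                                    c("t1", "t2"), 0.8),
                 "zero-variance")
  e11 <- edges[edges$tf_id == "tf1" & edges$target_id == "t1", ]
  expect_equal(e11$r, 1)
  e22 <- edges[edges$tf_id == "tf2" & edges$target_id == "t2", ]
  expect_equal(e22$r, -1)
  expect_false("tf3" %in% edges$tf_id)
})

test_that("Pearson r matches the textbook formula on a 9-sample toy", {
  set.seed(10)
  counts <- matrix(rpois(18, 300), 2, 9, dimnames = list(c("tf", "t"), NULL))
  e <- normalize_expression(counts, c(1000, 1500), rep(SEASONS, each = 3))
  edges <- build_correlation_network(e, "tf", "t", r_thresh = -1)
  x <- e$log2cpm["tf", ]; y <- e$log2cpm["t", ]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(edges$r, r_hand, tolerance = 1e-12)
})

test_that("the planted master regulator passes all four filters; the negative TF fails expression", {
  p <- default_pipeline()
  rk <- p$report$ranked
  master <- rk[rk$tf_id == PLANTED_IDS[["master"]], ]
  expect_true(master$expr_contrast)
  expect_true(master$atac_contrast)
  expect_true(master$meth_contrast)
  expect_true(master$compartment_A_stable)
  expect_equal(master$rank, 1L)
  neg <- rk[rk$tf_id == PLANTED_IDS[["negative"]], ]
  expect_false(neg$expr_contrast)
  ## per-layer counts dominate the all-layer intersection
  lc <- p$report$layer_counts
  expect_true(all(lc[["all_four"]] <= lc[c("expr", "atac", "meth", "compartment")]))
})

test_that("a TF without any promoter peak cannot pass the accessibility filter", {
  genes <- toy_genes(data.frame(chrom = "chr1", start = c(1000, 50000),
                                end = c(2000, 51000), strand = "+",
                                tss = c(1000, 50000), stringsAsFactors = FALSE))
  comp <- matrix("A", 2, 3, dimnames = list(genes$gene_id, SEASONS))
  dars <- data.frame(chrom = "chr1", start = 900, end = 1100,
                     log2fc = -1, p = 0.001, direction = "loss", is_dar = TRUE,
                     stringsAsFactors = FALSE)
  fl <- apply_contrast_filters(genes$gene_id, genes, NULL, NULL,
                               dars, dars, NULL, NULL, comp)
  expect_false(fl$atac_contrast[2])
  expect_true(all(is.na(fl$expr_contrast)))
  expect_true(grepl("layer_missing", fl$note[1]))
})

test_that("ranking is by layers passed, then max |r|, then tf_id", {
  flags <- data.frame(tf_id = c("tfA", "tfB", "tfC"),
                      expr_contrast = c(TRUE, TRUE, TRUE),
                      atac_contrast = c(TRUE, FALSE, FALSE),
                      meth_contrast = c(TRUE, FALSE, FALSE),
                      compartment_A_stable = c(TRUE, TRUE, TRUE),
                      n_layers_passed = c(4, 2, 2),
                      note = "", stringsAsFactors = FALSE)
  edges <- data.frame(tf_id = c("tfA", "tfB", "tfC"),
                      target_id = "t", r = c(0.9, 0.85, 0.95), n_samples = 9)
  rep <- intersect_and_rank(edges, flags)
  expect_equal(rep$ranked$tf_id, c("tfA", "tfC", "tfB"))
  expect_equal(rep$ranked$rank, 1:3)
  expect_warning(intersect_and_rank(edges[0, ], flags), "empty")
})

test_that("trend matching needs both the pattern and epigenomic evidence", {
  patterns <- c(g1 = "high-low-high", g2 = "flat", g3 = "high-low-high")
  summary <- data.frame(gene_id = c("g1", "g2", "g3"),
                        has_dar = c(TRUE, TRUE, FALSE),
                        has_dmr = FALSE, has_compartment = TRUE,
                        has_switch = FALSE, stringsAsFactors = FALSE)
  out <- trend_match_structural_genes(c("g1", "g2", "g3"), patterns, summary)
  expect_equal(out, "g1")
  expect_true(all(out %in% c("g1", "g2", "g3")))
  expect_error(trend_match_structural_genes(character(), patterns, summary),
               "empty")
  ## planted structural genes all match on generator output
  p <- default_pipeline()
  expect_setequal(p$trend_matched, STRUCTURAL_IDS)
})

test_that("layer correlations have the constructed signs", {
  set.seed(16)
  x <- rnorm(50)
  out <- global_layer_correlations(x, atac_lfc = 2 * x, meth_delta = -x^3)
  expect_equal(out$rho[out$layer_pair == "expression_vs_accessibility"], 1)
  expect_equal(out$rho[out$layer_pair == "expression_vs_methylation"], -1)
  expect_error(global_layer_correlations(x[1:5], atac_lfc = x[1:5]), "fewer")
})
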