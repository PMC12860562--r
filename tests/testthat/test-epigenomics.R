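test_that("promoter assignment is strand-aware and distal peaks are labelled", {
  genes <- toy_genes(data.frame(chrom = "chr1", start = c(5000, 50000),
                                end = c(6000, 51000), strand = c("+", "-"),
                                tss = c(5000, 50999), stringsAsFactors = FALSE))
  peaks <- data.frame(chrom = "chr1", start = c(4950, 30000),
                      end = c(5050, 30100), name = c("p1", "p2"),
                      stringsAsFactors = FALSE)
  ann <- annotate_peaks_to_genes(peaks, genes, 3000, 3000)
  expect_equal(ann$peak_type, c("promoter", "distal"))
  expect_equal(ann$assignments$gene_id, "g001")
  expect_error(annotate_peaks_to_genes(peaks, genes, -5, 100), "nonnegative")
})

test_that("promoter assignment over 1000 random peaks matches the brute-force oracle", {
  set.seed(17)
  genes <- toy_genes(random_intervals(100, max_pos = 5e4))
  genes$strand <- sample(c("+", "-"), 100, TRUE)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  peaks <- random_intervals(1000, max_pos = 5e4)
  peaks$name <- sprintf("p%04d", 1:1000)
  up <- 500; down <- 500
  ann <- annotate_peaks_to_genes(peaks, genes, up, down)
  ## oracle: strand-aware promoter windows, naive all-pairs overlap
  plo <- ifelse(genes$strand == "-", genes$tss - down + 1L, genes$tss - up)
  phi <- ifelse(genes$strand == "-", genes$tss + up + 1L, genes$tss + down)
  plo <- pmax(plo, 0)
  prom <- data.frame(chrom = genes$chrom, start = plo, end = phi)
  oracle <- brute_overlap_pairs(peaks, prom)
  got <- as.matrix(ann$assignments[, c("peak", "gene_id")])
  got <- cbind(as.integer(got[, 1]), match(got[, 2], genes$gene_id))
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(oracle))
})

test_that("TSS profiles are flat under uniform coverage and peak at planted bumps", {
  genes <- toy_genes(data.frame(chrom = "chr1", start = c(2000, 7000),
                                end = c(2500, 7500), strand = c("+", "-"),
                                tss = c(2000, 7499), stringsAsFactors = FALSE))
  flat <- list(chr1 = rep(3, 10000))
  prof <- tss_enrichment_profile(flat, genes, flank = 100)
  expect_equal(unname(prof), rep(3, 201))
  ## Gaussian bump centred on each TSS
  cov <- rep(1, 10000)
  for (t in c(2000, 7499)) {
    x <- seq(-300, 300)
    cov[t + x + 1] <- cov[t + x + 1] + 10 * exp(-x^2 / (2 * 50^2))
  }
  prof2 <- tss_enrichment_profile(list(chr1 = cov), genes, flank = 300)
  expect_equal(unname(which.max(prof2)), 301)
  ## symmetric input: flipping every strand changes nothing
  flipped <- genes
  flipped$strand <- c("-", "+")
  expect_equal(tss_enrichment_profile(list(chr1 = cov), flipped, 300), prof2)
  expect_error(tss_enrichment_profile(flat, genes[0, ], 100), "empty")
})

test_that("DAR calling honours both thresholds and the null identity", {
  cons <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(500, 1500),
                     name = c("c1", "c2"), stringsAsFactors = FALSE)
  same <- matrix(rep(c(100, 110, 105), 4), 2, 6, byrow = TRUE,
                 dimnames = list(cons$name, NULL))
  seasons <- c(rep("SPS", 3), rep("SUS", 3))
  same <- cbind(same[, 1:3], same[, 1:3])
  d0 <- call_dars(cons, same, seasons, "SPS", "SUS")
  expect_equal(sum(d0$is_dar), 0)
  ## planted 2x peak (log2fc = 1), tiny dispersion -> called gain; the
  ## second (anchor) peak keeps library sizes stable
  set.seed(4)
  cts <- rbind(c1 = c(rpois(3, 400), rpois(3, 800)),
               c2 = rpois(6, 20000))
  d1 <- call_dars(cons, cts, seasons, "SPS", "SUS")
  expect_true(d1$is_dar[1] && d1$direction[1] == "gain")
  ## true log2fc ~0.4 with near-zero noise: significant but below the bound
  target <- round(c(rep(1000, 3), rep(1000 * 2^0.4, 3)) + c(-1, 0, 1))
  anchor <- rep(10000, 6)   # stabilizes the library size
  cts2 <- rbind(c1 = target, c2 = anchor)
  d2 <- call_dars(cons, cts2, seasons, "SPS", "SUS")
  expect_lt(d2$p[1], 0.01)
  expect_gt(abs(d2$log2fc[1]), 0.2)
  expect_false(d2$is_dar[1])
  ## antisymmetry under season swap
  d1r <- call_dars(cons, cts, seasons, "SUS", "SPS")
  expect_equal(d1$log2fc, -d1r$log2fc)
  expect_equal(d1$is_dar, d1r$is_dar)
  expect_error(call_dars(cons[0, ], cts, seasons, "SPS", "SUS"), "empty")
})

test_that("replicate overlap counts match the brute-force oracle", {
  a <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 150))
  expect_equal(replicate_overlap(a, a)$a_only, 0)
  b <- data.frame(chrom = "chr1", start = 500, end = 600)
  expect_equal(replicate_overlap(a, b)$a_shared, 0)
  set.seed(23)
  ra <- random_intervals(400); rb <- random_intervals(300)
  ov <- replicate_overlap(ra, rb)
  pairs <- brute_overlap_pairs(ra, rb)
  expect_equal(ov$a_shared, length(unique(pairs[, 1])))
  expect_equal(ov$b_shared, length(unique(pairs[, 2])))
  expect_equal(ov$a_only, nrow(ra) - ov$a_shared)
})

test_that("context-level methylation is coverage-weighted and NA when absent", {
  sites <- data.frame(chrom = "chr1", pos = c(10, 20, 30), strand = "+",
                      context = c("CG", "CG", "CHG"),
                      methylated = c(9, 1, 5), total = c(10, 10, 10),
                      stringsAsFactors = FALSE)
  lv <- methylation_level_by_context(sites)
  expect_equal(unname(lv["CG"]), 0.5)
  expect_equal(unname(lv["CHG"]), 0.5)
  expect_true(is.na(lv["CHH"]))
  ## restriction to an empty region reports missing, not zero
  lv2 <- methylation_level_by_context(sites, data.frame(chrom = "chr1",
                                                        start = 5000, end = 6000))
  expect_true(all(is.na(lv2)))
  ## whole-genome restriction equals the unrestricted value
  lv3 <- methylation_level_by_context(sites, data.frame(chrom = "chr1",
                                                        start = 0, end = 1e6))
  expect_equal(lv3, lv)
})

test_that("DMR calling: null identity, planted recovery, min-site filter", {
  set.seed(19)
  pos <- seq(0, 5000, by = 20)
  mk <- function(p) data.frame(chrom = "chr1", pos = pos, strand = "+",
                               context = "CG",
                               methylated = rbinom(length(pos), 30, p),
                               total = 30, stringsAsFactors = FALSE)
  a <- mk(0.5)
  expect_equal(nrow(call_dmrs(a, a, "CG")), 0)
  ## planted 300 bp hyper region
  b <- a
  reg <- b$pos >= 2000 & b$pos < 2300
  b$methylated[reg] <- rbinom(sum(reg), 30, 0.9)
  dm <- call_dmrs(a, b, "CG")
  expect_equal(nrow(dm), 1)
  expect_equal(dm$direction, "hyper")
  expect_lt(dm$start, 2300)
  expect_gt(dm$end, 2000)
  expect_gt(dm$level_b, dm$level_a)
  ## a window with min_sites - 1 cytosines is never tested
  sparse_pos <- c(0, 25, 50, 75)   # 4 sites in any 100 bp window
  sa <- data.frame(chrom = "chr1", pos = sparse_pos, strand = "+", context = "CG",
                   methylated = 0, total = 30, stringsAsFactors = FALSE)
  sb <- sa; sb$methylated <- 30
  expect_equal(nrow(call_dmrs(sa, sb, "CG")), 0)
  expect_error(call_dmrs(a[a$context == "CHH", ], a, "CHH"), "context")
})

test_that("merged DMRs never overlap within a context", {
  set.seed(29)
  bench <- simulate_dmr_benchmark(n_regions = 10)
  dm <- call_dmrs(bench$sites_a, bench$sites_b, "CG")
  if (nrow(dm) > 1) {
    dm <- dm[order(dm$start), ]
    expect_true(all(dm$start[-1] >= dm$end[-nrow(dm)]))
  }
  expect_gt(nrow(dm), 0)
})

test_that("direction tallies partition hyper and hypo", {
  expect_equal(sum(classify_dmr_direction(data.frame())$n), 0)
  set.seed(9)
  dmrs <- data.frame(chrom = "chr1", start = 1:50 * 100, end = 1:50 * 100 + 50,
                     context = sample(METH_CONTEXTS, 50, TRUE),
                     direction = sample(c("hyper", "hypo"), 50, TRUE),
                     stringsAsFactors = FALSE)
  out <- classify_dmr_direction(dmrs)
  expect_equal(sum(out$n), 50)
  naive <- sum(dmrs$direction == "hyper" & dmrs$context == "CG")
  expect_equal(sum(out$n[out$direction == "hyper" & out$context == "CG"]), naive)
})

test_that("summit-centred methylation profiles dip at open chromatin", {
  sites <- data.frame(chrom = "chr1", pos = seq(0, 20000, 10), strand = "+",
                      context = "CG", methylated = 5, total = 10,
                      stringsAsFactors = FALSE)
  summits <- data.frame(chrom = "chr1", pos = c(5000, 15000))
  prof <- methylation_profile_around_summits(sites, summits, flank = 1000,
                                             bin_size = 50)
  expect_equal(ncol(prof), 2 * 1000 / 50 + 1)
  expect_true(all(abs(prof["CG", ] - 0.5) < 1e-12))
  ## planted dip in the default generator, pooled over all samples
  sim <- default_sim()
  all_sites <- do.call(rbind, sim$meth$samples)
  pk <- sim$atac$peaks
  prof2 <- methylation_profile_around_summits(
    all_sites, data.frame(chrom = pk$chrom, pos = pk$summit), 1000, 50)
  for (ctx in METH_CONTEXTS)
    expect_equal(which.min(prof2[ctx, ]), 21, ignore_attr = TRUE,
                 label = paste("central dip,", ctx))
  expect_error(suppressWarnings(methylation_profile_around_summits(
    sites, data.frame(chrom = "chr9", pos = 1), 1000, 50)), "no summit")
})
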