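checkerboard <- function(n = 20, within = 60, between = 6, noise = NULL) {
  lab <- rep(c("A", "B"), each = n / 2)
  dec <- 1 / (1 + abs(outer(seq_len(n), seq_len(n), `-`)))
  mu <- ifelse(outer(lab, lab, `==`), within, between) * dec
  m <- if (is.null(noise)) mu else matrix(rpois(n^2, mu), n)
  contact_matrix(pmax(m, t(m)), 10000, "chr1")
}

test_that("balancing reaches equal marginals and fixes balanced input", {
  set.seed(41)
  m <- matrix(runif(16, 1, 10), 4)
  cm <- contact_matrix(pmax(m, t(m)), 10, "chr1")
  bal <- balance_matrix(cm, tol = 1e-6)
  marg <- rowSums(bal$matrix)
  expect_lt(max(abs(marg / mean(marg) - 1)), 1e-5)
  ## a doubly-balanced matrix is a fixed point
  bal2 <- balance_matrix(bal, tol = 1e-5)
  expect_equal(bal2$matrix / mean(bal2$matrix), bal$matrix / mean(bal$matrix),
               tolerance = 1e-4)
  ## symmetry is preserved exactly
  expect_identical(bal$matrix, t(bal$matrix))
})

test_that("zero-marginal bins are masked, not divided by zero", {
  m <- matrix(5, 5, 5); m[3, ] <- 0; m[, 3] <- 0
  cm <- contact_matrix(m, 10, "chr1")
  bal <- balance_matrix(cm)
  expect_true(bal$mask[3])
  expect_true(all(bal$matrix[3, ] == 0))
  expect_error(balance_matrix(contact_matrix(matrix(0, 3, 3), 10)), "unmasked")
})

test_that("observed/expected divides by diagonal means and is idempotent", {
  ## matrix exactly equal to its diagonal means -> all ones
  n <- 5
  m <- 1 / (1 + abs(outer(1:n, 1:n, `-`)))
  cm <- contact_matrix(m, 10, "chr1")
  oe <- observed_over_expected(cm)
  expect_equal(oe$matrix, matrix(1, n, n))
  ## hand-computed small case
  m2 <- matrix(c(2, 4, 4, 8), 2)
  oe2 <- observed_over_expected(contact_matrix(m2, 10, "chr1"))
  expect_equal(oe2$matrix, matrix(c(2 / 5, 1, 1, 8 / 5), 2))
  ## idempotence on unmasked entries
  set.seed(2)
  cm3 <- checkerboard(10, noise = TRUE)
  o1 <- observed_over_expected(cm3)
  o2 <- observed_over_expected(o1)
  expect_equal(o1$matrix, o2$matrix, tolerance = 1e-12)
})

test_that("compartment calls recover planted blocks and obey the orientation rule", {
  set.seed(12)
  cm <- checkerboard(20, noise = TRUE)
  dens <- c(rep(5, 10), rep(1, 10))  # A half gene-dense
  bal <- balance_matrix(cm)
  track <- call_compartments(observed_over_expected(bal), dens)
  expect_equal(track$label[!bal$mask][1:10], rep("A", 10))
  expect_equal(track$label[!bal$mask][11:20], rep("B", 10))
  ## flipping the reference track flips labels: orientation is by gene density
  track2 <- call_compartments(observed_over_expected(bal), rev(dens))
  expect_equal(track2$label[track$label == "A"], rep("B", 10))
  ## scalar invariance
  cm3 <- contact_matrix(cm$matrix * 7, cm$bin_size, cm$chrom)
  track3 <- compartment_track(cm3, dens)
  expect_equal(track3$label, compartment_track(cm, dens)$label)
  ## uniform matrix has no compartment signal
  expect_error(call_compartments(
    observed_over_expected(balance_matrix(contact_matrix(matrix(1, 8, 8), 10))),
    rep(1, 8)), "degenerate")
})

test_that("switch strings concatenate per-season labels and tally correctly", {
  t1 <- data.frame(bin = 1:4, value = 1, label = c("A", "A", "B", "NaN"))
  same <- classify_switches(list(SPS = t1, SUS = t1, AUS = t1))
  expect_true(all(names(same$counts) %in% c("A2A2A", "B2B2B", "NaN2NaN2NaN")))
  t2 <- t1; t2$label[1] <- "B"
  sw <- classify_switches(list(SPS = t1, SUS = t1, AUS = t2))
  expect_equal(sw$labels[1], "A2A2B")
  expect_error(classify_switches(list(SPS = t1, SUS = t1, AUS = t1[1:2, ])),
               "mismatch")
  ## random tracks vs naive per-bin tally
  set.seed(6)
  tr <- lapply(1:3, function(i)
    data.frame(bin = 1:50, value = 0,
               label = sample(c("A", "B"), 50, TRUE)))
  names(tr) <- SEASONS
  sw2 <- classify_switches(tr)
  naive <- table(paste(tr[[1]]$label, tr[[2]]$label, tr[[3]]$label, sep = "2"))
  expect_equal(as.vector(sw2$counts[names(naive)]), as.vector(naive))
})

test_that("genes inherit the compartment label of their TSS bin", {
  track <- data.frame(bin = 1:10, value = c(rep(1, 5), rep(-1, 4), NA),
                      label = c(rep("A", 5), rep("B", 4), "NaN"))
  genes <- toy_genes(data.frame(chrom = "chr1",
                                start = c(25000, 95000), end = c(26000, 96000),
                                strand = "+", tss = c(25000, 95000),
                                stringsAsFactors = FALSE))
  lab <- assign_gene_compartments(track, genes, 10000)
  expect_equal(unname(lab), c("A", "NaN"))
  out <- toy_genes(data.frame(chrom = "chr1", start = 2e5, end = 2e5 + 100,
                              strand = "+", tss = 2e5, stringsAsFactors = FALSE))
  expect_warning(lab2 <- assign_gene_compartments(track, out, 10000), "outside")
  expect_equal(unname(lab2), "NaN")
  ## 500 genes against a naive lookup
  set.seed(3)
  g <- toy_genes(data.frame(chrom = "chr1", start = s <- sample.int(99000, 500),
                            end = s + 100, strand = "+", tss = s,
                            stringsAsFactors = FALSE))
  lab3 <- assign_gene_compartments(track, g, 10000)
  expect_equal(unname(lab3), track$label[g$tss %/% 10000 + 1])
})

test_that("planted blocks and switch bins are recovered on generator output", {
  p <- default_pipeline()
  truth <- p$sim$truth
  for (season in SEASONS) {
    for (ch in truth$chroms) {
      track <- p$compartments$tracks[[season]][[ch]]
      true_lab <- truth$blocks[[ch]][, season]
      ok <- track$label != "NaN"
      expect_gte(mean(track$label[ok] == true_lab[ok]), 0.95)
    }
  }
  for (i in seq_len(nrow(truth$switches))) {
    ch <- truth$switches$chrom[i]
    bin <- truth$switches$bin[i]
    expect_equal(p$compartments$switches[[ch]]$labels[bin],
                 truth$switches$pattern[i])
  }
})
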