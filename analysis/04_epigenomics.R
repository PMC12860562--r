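#!/usr/bin/env Rscript
# ATAC-seq: consensus peaks, promoter annotation, differential accessibility,
# replicate overlap. WGBS: context-level methylation by season, DMR calling,
# methylation profile around peak summits.

suppressMessages(library(seasomics))
dir.create("results/epigenomics", recursive = TRUE, showWarnings = FALSE)

genes <- read_annotation("results/data/genes.gff3")
peak_files <- list.files("results/data/peaks", full.names = TRUE)
peak_sets <- lapply(peak_files, read_peaks)
names(peak_sets) <- sub("\\.narrowPeak$", "", basename(peak_files))
atac_counts <- read_matrix_tsv("results/data/atac_counts.tsv")
atac_seasons <- sub("_[0-9]+$", "", colnames(atac_counts))

cons <- consensus_peaks(peak_sets)
cat("Consensus:", nrow(cons), "peaks from", length(peak_sets), "samples\n")
ann <- annotate_peaks_to_genes(cons, genes)
cat("Promoter peaks:", sum(ann$peak_type == "promoter"),
    "| distal:", sum(ann$peak_type == "distal"), "\n")

ccounts <- consensus_counts(peak_sets[[1]], atac_counts, cons)
for (cmp in list(c("SPS", "SUS"), c("SUS", "AUS"))) {
  dars <- call_dars(cons, ccounts, atac_seasons, cmp[1], cmp[2])
  cat(cmp[1], "vs", cmp[2], ":", sum(dars$is_dar), "DARs (",
      sum(dars$is_dar & dars$direction == "gain"), "gain /",
      sum(dars$is_dar & dars$direction == "loss"), "loss )\n")
  write.table(dars[dars$is_dar, ],
              sprintf("results/epigenomics/dars_%s_vs_%s.tsv", cmp[1], cmp[2]),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

ov <- replicate_overlap(peak_sets[[1]], peak_sets[[2]])
cat("Replicate overlap (", names(peak_sets)[1], "vs", names(peak_sets)[2],
    "):", ov$a_shared, "shared of", ov$a_total, "\n")

## WGBS
meth_files <- list.files("results/data/methylation", full.names = TRUE)
meth <- lapply(meth_files, read_methylation)
meth_seasons <- sub("_[0-9]+\\.tsv$", "", basename(meth_files))
pooled <- pool_methylation(meth, meth_seasons)
lv <- sapply(pooled, methylation_level_by_context)
cat("Methylation level by context and season:\n")
print(round(lv, 4))
write.table(cbind(context = rownames(lv), as.data.frame(round(lv, 5))),
            "results/epigenomics/methylation_levels.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

all_dmrs <- list()
for (cmp in list(c("SPS", "SUS"), c("SUS", "AUS"))) {
  for (ctx in METH_CONTEXTS) {
    d <- call_dmrs(pooled[[cmp[1]]], pooled[[cmp[2]]], ctx)
    if (nrow(d)) d$comparison <- paste0(cmp[1], "_vs_", cmp[2])
    all_dmrs[[paste(cmp[1], ctx)]] <- d
  }
}
dmrs <- do.call(rbind, all_dmrs)
cat("DMRs:\n")
print(classify_dmr_direction(dmrs))
write.table(dmrs, "results/epigenomics/dmrs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## methylation dips at open chromatin (pooled over seasons)
all_sites <- do.call(rbind, pooled)
prof <- methylation_profile_around_summits(
  all_sites, data.frame(chrom = peak_sets[[1]]$chrom,
                        pos = peak_sets[[1]]$summit))
cat("Summit profile minima (bp offset of minimum per context):\n")
print(apply(prof, 1, function(v) as.integer(names(which.min(v)))))
write.table(cbind(context = rownames(prof), as.data.frame(round(prof, 5))),
            "results/epigenomics/summit_methylation_profile.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
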