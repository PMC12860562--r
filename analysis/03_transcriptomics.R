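#!/usr/bin/env Rscript
# Seasonal differential expression, pattern labelling, and six-cluster
# profile clustering of the simulated transcriptome.

suppressMessages(library(seasomics))
dir.create("results/transcriptomics", recursive = TRUE, showWarnings = FALSE)

genes <- read_annotation("results/data/genes.gff3")
counts <- read_matrix_tsv("results/data/rna_counts.tsv")
storage.mode(counts) <- "integer"
seasons <- sub("_[0-9]+$", "", colnames(counts))
lengths <- setNames(genes$end - genes$start, genes$gene_id)[rownames(counts)]

expr <- normalize_expression(counts, lengths, seasons)
for (cmp in list(c("SPS", "SUS"), c("SUS", "AUS"))) {
  de <- differential_expression(expr, cmp[1], cmp[2])
  cat(cmp[1], "vs", cmp[2], ":", sum(de$is_deg), "DEGs (",
      sum(de$is_deg & de$log2fc < 0), "down,",
      sum(de$is_deg & de$log2fc > 0), "up )\n")
  write.table(de, sprintf("results/transcriptomics/de_%s_vs_%s.tsv",
                          cmp[1], cmp[2]),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

patterns <- seasonal_patterns(expr)
cat("Pattern labels:\n")
print(table(patterns))
write.table(data.frame(gene_id = names(patterns), pattern = patterns),
            "results/transcriptomics/patterns.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## six-module clustering of the seasonally variable genes
variable <- rownames(counts)[apply(expr$season_means, 1, function(v)
  diff(range(v)) > 0.5)]
cl <- cluster_profiles(expr, variable, k = 6)
cat("Clustered", length(variable), "variable genes into 6 modules:\n")
print(cl$cluster_patterns)
write.table(cl$assignment, "results/transcriptomics/clusters.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
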