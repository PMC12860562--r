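#!/usr/bin/env Rscript
# Generate the synthetic three-season multi-omics dataset (with its planted
# ground truth) that all downstream analyses consume. Files land under
# results/data/ in the package's on-disk formats; truth_manifest.tsv records
# every planted effect.

suppressMessages(library(seasomics))

cfg <- simulation_config(seed = 1)
sim <- simulate_dataset(cfg, outdir = "results/data")

cat("Simulated", nrow(sim$genes), "genes on", cfg$n_chrom, "chromosomes;",
    sum(sim$genes$is_tf), "TFs.\n")
cat("Assays: RNA", ncol(sim$rna$counts), "samples; ATAC",
    nrow(sim$atac$peaks), "peaks x", ncol(sim$atac$counts), "samples; WGBS",
    length(sim$meth$samples), "samples x", nrow(sim$meth$samples[[1]]),
    "cytosines; Hi-C", length(sim$hic) * length(sim$hic[[1]]), "matrices.\n")
cat("Planted: master regulator", PLANTED_IDS[["master"]],
    "| structural genes", paste(STRUCTURAL_IDS, collapse = ", "), "\n")
cat("Truth manifest:", nrow(sim$manifest), "entries -> results/data/truth_manifest.tsv\n")
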