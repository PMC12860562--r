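#!/usr/bin/env Rscript
# Metabolite quantification from calibration curves, seasonal DAM calling,
# and the contrasting-pattern screen (down in SPS->SUS, up in SUS->AUS).
# Reads the files emitted by 01_simulate.R.

suppressMessages(library(seasomics))
dir.create("results/metabolomics", recursive = TRUE, showWarnings = FALSE)

standards <- read.delim("results/data/calibration_standards.tsv")
responses <- read_matrix_tsv("results/data/metabolite_responses.tsv")
classes <- read.delim("results/data/metabolite_classes.tsv")
seasons <- sub("_[0-9]+$", "", colnames(responses))

## external calibration: per-analyte OLS, then content = c*V/(1e5*m)
curves <- lapply(split(standards, standards$analyte), function(s)
  fit_calibration(s$concentration, s$response))
r2 <- vapply(curves, `[[`, numeric(1), "r_squared")
cat("Calibration: ", length(curves), "curves, median r^2 =",
    signif(median(r2), 4), "\n")

contents <- responses
for (m in rownames(contents))
  contents[m, ] <- quantify_content(
    invert_calibration(curves[[m]], responses[m, ]),
    volume_ul = 1000, mass_g = 0.05)
write_matrix_tsv(contents, "results/metabolomics/contents_ug_per_g.tsv",
                 "metabolite")

dams_ab <- call_dams(contents, seasons == "SPS", seasons == "SUS")
dams_bc <- call_dams(contents, seasons == "SUS", seasons == "AUS")
write.table(dams_ab, "results/metabolomics/dams_SPS_vs_SUS.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(dams_bc, "results/metabolomics/dams_SUS_vs_AUS.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("DAMs:", sum(dams_ab$is_dam), "in SPS vs SUS;",
    sum(dams_bc$is_dam), "in SUS vs AUS\n")

cls <- setNames(classes$class, classes$metabolite)
screen <- contrasting_metabolite_screen(dams_ab, dams_bc, cls)
cat("Contrasting screen:", length(screen$metabolites),
    "metabolites depleted in summer and restored in autumn\n")
print(screen$class_counts[screen$class_counts > 0])
write.table(data.frame(metabolite = screen$metabolites,
                       class = cls[screen$metabolites]),
            "results/metabolomics/contrasting_set.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
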