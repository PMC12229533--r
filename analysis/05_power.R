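#!/usr/bin/env Rscript
# Power analysis for the PRS association test: power as a function of
# total sample size under the headline configuration (90 markers,
# liability h2 0.22, prevalence 0.005, 1:1 case-control sampling in
# training and target), and the minimum n reaching 80% power.

suppressPackageStartupMessages(library(prsbench))

spec <- power_spec(n_markers = 90, h2 = 0.22, prevalence = 0.005,
                   case_fraction_train = 0.5, case_fraction_target = 0.5,
                   alpha = 0.05, target_power = 0.8)

ns <- c(10, 20, 30, 40, 50, 66, 80, 100, 150, 250, 550)
tab <- data.frame(n_total = ns,
                  power = round(sapply(ns, prs_association_power,
                                       spec = spec), 4))
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/power_curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, row.names = FALSE)

n_min <- min_sample_size(spec)
message(sprintf("minimum total sample size for %.0f%% power: %d",
                100 * spec$target_power, n_min))
message("note: with the full heritability (0.22) attributed to the ",
        "90-marker score and 1:1 ascertainment in both samples, the ",
        "association test is well powered at modest n; see the package ",
        "vignette for the conventions behind this configuration.")
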