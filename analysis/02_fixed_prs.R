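#!/usr/bin/env Rscript
# Fixed-panel PRS: score every target cohort with every ancestry-specific
# base GWAS, evaluate each model, and decompose per-variant contributions.
# Writes a per-cohort-per-base metrics table and the top contribution
# rows under results/.

suppressPackageStartupMessages(library(prsbench))

simdir <- "results/sim"
stopifnot(dir.exists(simdir))  # run 01_simulate.R first
panel <- read_panel(file.path(simdir, "panel.txt"))

targets <- c(pop1 = "target_pop1.tsv", pop2 = "target_pop2.tsv",
             pop3 = "target_pop3.tsv", admix = "target_admix.tsv")
bases <- c(pop1 = "base_pop1.tsv", pop2 = "base_pop2.tsv",
           pop3 = "base_pop3.tsv")

rows <- list(); top_effects <- list()
for (tg in names(targets)) {
  co <- read_genotypes(file.path(simdir, targets[tg]), format = "dosage",
                       ancestry_label = toupper(tg))
  co <- attach_phenotypes(co, file.path(simdir, paste0("pheno_", tg, ".tsv")))
  co <- qc_filter(co, maf_min = 0.01, hwe_alpha = 1e-6)$cohort
  co <- suppressWarnings(compute_pcs(co, 10))
  covset <- if (tg == "admix") "admixture" else "pcs"
  for (bs in names(bases)) {
    base <- read_sumstats(file.path(simdir, bases[bs]))
    h <- harmonize_sumstats(base, co$variants)
    prs <- score_fixed_panel(co, h$sumstats, panel)
    ev <- evaluate_prs(co, prs, covset)
    rows[[paste(tg, bs)]] <- data.frame(
      target = toupper(tg), base = toupper(bs),
      n_valid = attr(prs, "n_valid_predictors"),
      auc = round(ev$auc, 3),
      or_per_sd = round(ev$or_per_sd, 2),
      or_low = round(ev$or_ci[1], 2), or_high = round(ev$or_ci[2], 2),
      balanced_accuracy = round(ev$balanced_accuracy, 3),
      sensitivity = round(ev$sensitivity, 3),
      specificity = round(ev$specificity, 3))
    ve <- variant_effects(co, h$sumstats, panel)
    top_effects[[paste(tg, bs)]] <- cbind(target = toupper(tg),
                                          base = toupper(bs), head(ve, 5))
  }
}

tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/fixed_panel_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, top_effects), "results/variant_effects_top5.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("fixed-panel PRS metrics (AUC by target x base):")
print(tab, row.names = FALSE)
message("note how AUC decays as base and target ancestries diverge; ",
        "the matched-base models lead.")
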