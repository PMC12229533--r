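#!/usr/bin/env Rscript
# Simulate the study's data layer: three diverged target cohorts plus an
# admixed one, matching ancestry-specific base GWAS, and the fixed risk
# panel. Everything is written as plain text under results/sim/ so the
# later steps (and any outside tool) can consume it.

suppressPackageStartupMessages(library(prsbench))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_ancestries = 3, fst = c(0.02, 0.08, 0.15),
  n_variants = 400, n_causal = 40,
  h2_liability = 0.22, prevalence = 0.005,
  n_cases = 500, n_controls = 500,
  seed = 20260101
)

message("drawing cohorts (rejection sampling at prevalence 0.005)...")
for (k in 1:3) {
  sim <- simulate_cohort(cfg, ancestry = k)
  co <- sim$cohort
  write_dosage(co, file.path(out, sprintf("target_pop%d.tsv", k)))
  ph <- data.frame(sample_id = co$samples$sample_id,
                   PHENO = co$samples$phenotype,
                   SEX = co$samples$sex, AGE = co$samples$age)
  write.table(ph, file.path(out, sprintf("pheno_pop%d.tsv", k)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (k == 1) {
    tv <- sim$truth$variants
    panel <- variant_key(tv$chrom, tv$pos, tv$counted_allele,
                         tv$other_allele)[tv$causal]
    writeLines(panel, file.path(out, "panel.txt"))
    write.table(tv, file.path(out, "truth_variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message(sprintf("  POP%d: %d cases / %d controls", k,
                  sum(co$samples$phenotype == 1),
                  sum(co$samples$phenotype == 0)))
}

# admixed cohort drawing haplotype blocks from all three ancestries
cfg_adm <- cfg
cfg_adm$admixture_alpha <- c(4, 2, 1)
adm <- simulate_cohort(cfg_adm)$cohort
write_dosage(adm, file.path(out, "target_admix.tsv"))
write.table(data.frame(sample_id = adm$samples$sample_id,
                       PHENO = adm$samples$phenotype,
                       SEX = adm$samples$sex, AGE = adm$samples$age,
                       adm$samples[grep("^ADM", names(adm$samples))]),
            file.path(out, "pheno_admix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  ADMIX: mean admixture %s",
                paste(round(colMeans(adm$samples[grep("^ADM",
                      names(adm$samples))]), 2), collapse = "/")))

message("training ancestry-specific base GWAS (independent draws)...")
for (k in 1:3) {
  ss <- simulate_base_gwas(cfg, n_train = 3000, ancestry = k)
  write_sumstats(ss, file.path(out, sprintf("base_pop%d.tsv", k)))
  message(sprintf("  base POP%d: %d variants, %d with p < 5e-8",
                  k, nrow(ss), sum(ss$pvalue < 5e-8)))
}
message("done; inputs in ", out)
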