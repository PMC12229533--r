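test_that("VCF genotypes convert to counted-allele dosages", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trs1\tG\tA\t.\t.\t.\tGT\t0/1\t1/1\t0/0",
    "1\t200\trs2\tT\tC\t.\t.\t.\tGT\t./.\t0|1\t1/1"), f)
  co <- read_genotypes(f)
  expect_equal(unname(co$dosage[, "rs1"]), c(1, 2, 0))
  expect_equal(unname(co$dosage[, "rs2"]), c(NA, 1, 2))
  expect_equal(co$variants$counted_allele, c("A", "C"))  # ALT is counted
  # dosage of counted allele plus dosage of other allele is 2 when observed
  expect_true(all(co$dosage + (2 - co$dosage) == 2, na.rm = TRUE))
})

test_that("the same cohort round-trips identically through VCF and dosage TSV", {
  sh <- shared_sim()
  co <- sh$sim$cohort
  small <- cohort_data(co$dosage[1:40, 1:30], co$variants[1:30, ],
                       co$samples[1:40, c("sample_id", "phenotype")], "POP1")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_vcf(small, vcf)
  write_dosage(small, tsv)
  from_vcf <- read_genotypes(vcf, ancestry_label = "POP1")
  from_tsv <- read_genotypes(tsv, format = "dosage", ancestry_label = "POP1")
  expect_equal(from_vcf$dosage, from_tsv$dosage)
  expect_equal(unname(from_vcf$dosage), unname(small$dosage))
  expect_equal(from_vcf$variants[, 1:5], from_tsv$variants[, 1:5])
})

test_that("PLINK bed/bim/fam reads match the dosage representation", {
  # hand-written 4-sample, 3-variant bed (SNP-major), A1 counted
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "toy")
  writeLines(c("1\trs1\t0\t100\tA\tG", "1\trs2\t0\t200\tC\tT",
               "2\trs3\t0\t300\tT\tG"), paste0(stem, ".bim"))
  writeLines(sprintf("f%d i%d 0 0 1 %d", 1:4, 1:4, c(2, 1, 1, 2)),
             paste0(stem, ".fam"))
  # genotype codes per variant across 4 samples (2 bits each, LSB first):
  # rs1: hom A1, het, missing, hom A2 -> 00 10 01 11
  # rs2: all het; rs3: all hom A1
  con <- file(paste0(stem, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(c(
    bitwOr(bitwOr(0x0, bitwShiftL(0x2, 2)), bitwOr(bitwShiftL(0x1, 4), bitwShiftL(0x3, 6))),
    bitwOr(bitwOr(0x2, bitwShiftL(0x2, 2)), bitwOr(bitwShiftL(0x2, 4), bitwShiftL(0x2, 6))),
    0x00)), con)
  close(con)
  co <- read_genotypes(paste0(stem, ".bed"))
  expect_equal(unname(co$dosage[, "rs1"]), c(2, 1, NA, 0))
  expect_equal(unname(co$dosage[, "rs2"]), rep(1, 4))
  expect_equal(unname(co$dosage[, "rs3"]), rep(2, 4))
  expect_equal(co$variants$counted_allele, c("A", "C", "T"))
  expect_equal(co$samples$phenotype, c(1, 0, 0, 1))  # fam 1/2 coding
})

test_that("QC filters apply the documented thresholds and order", {
  set.seed(21)
  n <- 200
  g_common <- matrix(rbinom(n * 3, 2, 0.3), n)
  g_rare <- rbinom(n, 2, 0.01)                    # fails MAF at 0.05
  g_gappy <- rbinom(n, 2, 0.4); g_gappy[1:20] <- NA  # 90% call rate
  g_hwe <- rep(c(0, 2), 100)                      # extreme HWE failure
  co <- toy_cohort(cbind(g_common, g_rare, g_gappy, g_hwe),
                   phenotype = rep(c(1, 0), each = 100))
  res <- qc_filter(co, maf_min = 0.05, hwe_alpha = 1e-4,
                   var_call_min = 0.98, sample_call_min = 0)
  expect_equal(res$report$n_removed_maf, 1L)
  expect_equal(res$report$n_removed_callrate, 1L)
  expect_equal(res$report$n_removed_hwe, 1L)
  expect_equal(ncol(res$cohort$dosage), 3L)
  expect_equal(res$report$n_variants_in - res$report$n_removed_maf -
                 res$report$n_removed_hwe - res$report$n_removed_callrate,
               ncol(res$cohort$dosage))

  # no-op thresholds leave the cohort untouched
  res0 <- qc_filter(co, maf_min = 0, hwe_alpha = 0,
                    var_call_min = 0, sample_call_min = 0)
  expect_equal(res0$cohort$dosage, co$dosage)

  # QC is order-stable: re-running removes nothing
  res2 <- qc_filter(res$cohort, maf_min = 0.05, hwe_alpha = 1e-4,
                    var_call_min = 0.98, sample_call_min = 0)
  expect_equal(ncol(res2$cohort$dosage), ncol(res$cohort$dosage))
  expect_equal(res2$report$n_removed_maf + res2$report$n_removed_hwe +
                 res2$report$n_removed_callrate, 0L)
})

test_that("HWE exact test matches enumeration and the balanced example", {
  # control counts 25 AA / 50 Aa / 25 aa sit exactly at equilibrium
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)
  g <- c(rep(2, 25), rep(1, 50), rep(0, 25))
  co <- toy_cohort(cbind(g, rbinom(100, 2, 0.5)),
                   phenotype = rep(0, 100))
  res <- qc_filter(co, maf_min = 0, hwe_alpha = 1e-4,
                   var_call_min = 0, sample_call_min = 0)
  expect_equal(res$report$n_removed_hwe, 0L)

  for (counts in list(c(25, 50, 25), c(5, 20, 75), c(0, 10, 40),
                      c(12, 1, 13), c(3, 3, 3))) {
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 hwe_enumeration(counts[1], counts[2], counts[3]),
                 tolerance = 1e-10)
  }
  # HWE is computed on controls only: a case-only distortion must not
  # remove the variant
  g_ctrl <- c(rep(2, 25), rep(1, 50), rep(0, 25))
  g_case <- c(rep(0, 50), rep(2, 50))
  co2 <- toy_cohort(cbind(c(g_case, g_ctrl), rbinom(200, 2, 0.5)),
                    phenotype = rep(c(1, 0), each = 100))
  res2 <- qc_filter(co2, maf_min = 0, hwe_alpha = 1e-4,
                    var_call_min = 0, sample_call_min = 0)
  expect_equal(res2$report$n_removed_hwe, 0L)
})

test_that("principal components separate diverged populations and are stable", {
  cfg <- sim_config(n_ancestries = 2, fst = 0.1, n_variants = 300,
                    n_causal = 10, h2_liability = 0.2, prevalence = 0.2,
                    n_cases = 60, n_controls = 60, seed = 33)
  a <- simulate_cohort(cfg, ancestry = 1)$cohort
  b <- simulate_cohort(cfg, ancestry = 2)$cohort
  b$samples$sample_id <- paste0("b_", b$samples$sample_id)
  comb <- cohort_data(rbind(a$dosage, b$dosage), a$variants,
                      rbind(a$samples, b$samples), "MIX")
  comb <- suppressWarnings(compute_pcs(comb, 4))
  pop <- rep(c(0, 1), each = 120)
  pc_auc <- auc_bruteforce(comb$samples$PC1, pop)
  expect_gt(max(pc_auc, 1 - pc_auc), 0.95)

  # duplicated samples get identical PC rows
  dup <- cohort_data(a$dosage[c(1, 1, 2:30), ], a$variants,
                     data.frame(sample_id = paste0("d", 1:31)), "DUP")
  dup <- suppressWarnings(compute_pcs(dup, 3))
  expect_equal(unlist(dup$samples[1, c("PC1", "PC2", "PC3")]),
               unlist(dup$samples[2, c("PC1", "PC2", "PC3")]))

  # n_pcs = 0 leaves the cohort unchanged apart from removing PCs
  none <- compute_pcs(a, 0)
  expect_false(any(grepl("^PC", names(none$samples))))
  expect_equal(none$dosage, a$dosage)

  # invariant to sample order up to row permutation
  perm <- sample(nrow(a$dosage))
  ap <- cohort_data(a$dosage[perm, ], a$variants, a$samples[perm, ], "PERM")
  p1 <- suppressWarnings(compute_pcs(a, 2))$samples
  p2 <- suppressWarnings(compute_pcs(ap, 2))$samples
  expect_equal(p2$PC1[match(p1$sample_id, p2$sample_id)], p1$PC1,
               tolerance = 1e-8)
})
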