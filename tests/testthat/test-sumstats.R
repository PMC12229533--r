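test_that("read_sumstats validates, filters and respects column maps", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tA1\tA2\tBETA\tSE\tP",
               "rs1\t1\t100\ta\tg\t0.5\t0.1\t0.01",
               "rs2\t1\t200\tC\tT\t-0.2\t0\t0.5",
               "rs3\t2\t300\tA\tC\t0.1\t0.2\t0.9"), f)
  ss <- read_sumstats(f)
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss), 2L)                    # se = 0 row dropped
  expect_equal(attr(ss, "n_dropped"), 1L)
  expect_equal(ss$effect_allele, c("A", "A"))   # upper-cased

  # shuffled column order via a column map gives identical records
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pval\teffect\tstderr\tchrom\tid\tposition\tref\talt",
               "0.01\t0.5\t0.1\t1\trs1\t100\tg\ta",
               "0.9\t0.1\t0.2\t2\trs3\t300\tc\ta"), f2)
  ss2 <- read_sumstats(f2, column_map = c(
    variant_id = "id", chrom = "chrom", pos = "position",
    effect_allele = "alt", other_allele = "ref",
    beta = "effect", se = "stderr", pvalue = "pval"))
  expect_equal(ss2$beta, ss$beta)
  expect_equal(ss2$pos, ss$pos)
  expect_equal(ss2$effect_allele, ss$effect_allele)

  # duplicated variant key errors and names the key
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tA1\tA2\tBETA\tSE\tP",
               "rs1\t1\t100\tA\tG\t0.5\t0.1\t0.01",
               "rs1b\t1\t100\tG\tA\t-0.5\t0.1\t0.01"), f3)
  expect_error(read_sumstats(f3), "1:100:A:G")

  # missing mandatory column is a configuration error
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tA1\tA2\tBETA\tSE", "rs1\t1\t1\tA\tG\t1\t0.1"), f4)
  expect_error(read_sumstats(f4), "missing mandatory")
})

test_that("harmonization matches a hand-built allele-configuration truth table", {
  target <- data.frame(variant_id = paste0("t", 1:8), chrom = "1",
                       pos = 1:8 * 100L,
                       counted_allele = c("C", "C", "C", "C", "A", "C", "C", "C"),
                       other_allele   = c("T", "T", "T", "T", "T", "G", "T", "T"))
  # base configurations at the matching loci
  base <- toy_sumstats(chrom = "1", pos = 1:8 * 100L,
                       a1 = c("C", "T", "G", "A", "A", "G", "A", "AT"),
                       a2 = c("T", "C", "A", "G", "T", "C", "C", "A"),
                       beta = rep(0.5, 8))
  # expectations: 1 same; 2 swapped (sign flip); 3 strand-flip same
  # (G/A -> C/T); 4 strand-flip swapped; 5 palindromic A/T dropped;
  # 6 palindromic G/C dropped; 7 alleles do not pair -> unmatched;
  # 8 indel -> unmatched (indels are never strand-flipped)
  h <- harmonize_sumstats(base, target)
  expect_equal(h$report$n_input, 8L)
  expect_equal(h$report$n_matched, 4L)
  expect_equal(h$report$n_allele_flipped, 2L)
  expect_equal(h$report$n_strand_flipped, 2L)
  expect_equal(h$report$n_palindromic_dropped, 2L)
  expect_equal(h$report$n_unmatched, 2L)
  expect_equal(h$report$n_matched + h$report$n_palindromic_dropped +
                 h$report$n_unmatched, h$report$n_input)
  expect_equal(h$sumstats$pos, c(100L, 200L, 300L, 400L))
  expect_equal(h$sumstats$beta, c(0.5, -0.5, 0.5, -0.5))
  expect_true(all(h$sumstats$effect_allele == "C"))

  # swapped alleles flip beta and eaf
  b2 <- toy_sumstats("1", 100L, "G", "A", beta = 0.5, eaf = 0.3)
  t2 <- data.frame(chrom = "1", pos = 100L, counted_allele = "A",
                   other_allele = "G")
  h2 <- harmonize_sumstats(b2, t2)
  expect_equal(h2$sumstats$beta, -0.5)
  expect_equal(h2$sumstats$eaf, 0.7)

  # empty intersection errors naming both sources
  expect_error(harmonize_sumstats(b2, data.frame(
    chrom = "9", pos = 5L, counted_allele = "A", other_allele = "G")),
    "no variants shared")
})

test_that("harmonization is idempotent and supports frequency rescue", {
  sh <- shared_sim()
  h1 <- harmonize_sumstats(sh$base, sh$cohort$variants)
  h2 <- harmonize_sumstats(h1$sumstats, sh$cohort$variants)
  expect_equal(as.data.frame(h2$sumstats), as.data.frame(h1$sumstats))
  expect_equal(h2$report$n_allele_flipped, 0L)
  expect_equal(h2$report$n_strand_flipped, 0L)

  # palindromic rescue: concordant far-from-0.5 frequencies are kept,
  # near-0.5 or missing frequencies are not
  base <- toy_sumstats("1", c(100L, 200L, 300L), a1 = "A", a2 = "T",
                       beta = c(1, 1, 1), eaf = c(0.1, 0.48, NA))
  target <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                       counted_allele = "A", other_allele = "T",
                       freq = c(0.12, 0.47, 0.1))
  h <- harmonize_sumstats(base, target, freq_rescue = TRUE)
  expect_equal(h$report$n_matched, 1L)
  expect_equal(h$report$n_palindromic_dropped, 2L)
  expect_equal(h$sumstats$pos, 100L)
})

test_that("fixed-effects meta-analysis reproduces inverse-variance arithmetic", {
  s1 <- toy_sumstats("1", 100L, "A", "G", beta = 0.1, se = 0.1)
  s2 <- toy_sumstats("1", 100L, "A", "G", beta = 0.3, se = 0.2)
  m <- meta_fixed(list(s1, s2))
  # hand arithmetic: w = (100, 25); beta = (10 + 7.5)/125
  expect_equal(m$beta, 0.14)
  expect_equal(m$se, sqrt(1 / 125))
  expect_equal(m$se, 0.0894427, tolerance = 1e-6)
  expect_equal(m$pvalue, 2 * pnorm(-abs(0.14 / sqrt(1 / 125))))
  expect_equal(m$n_studies, 2L)

  # equal effects meta to the same effect whatever the SEs
  s3 <- toy_sumstats("1", 100L, "A", "G", beta = 0.2, se = 0.05)
  s4 <- toy_sumstats("1", 100L, "A", "G", beta = 0.2, se = 0.31)
  expect_equal(meta_fixed(list(s3, s4))$beta, 0.2)

  # a single study is a precondition violation
  expect_error(meta_fixed(list(s1)), ">= 2")

  # cross-check against an established fixed-effects implementation
  skip_if_not_installed("metafor")
  ref <- metafor::rma(yi = c(0.1, 0.3), sei = c(0.1, 0.2), method = "FE")
  expect_equal(m$beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(m$se, ref$se, tolerance = 1e-10)
  expect_equal(m$heterogeneity_q, as.numeric(ref$QE), tolerance = 1e-10)
})

test_that("meta SE never exceeds the smallest input SE; k duplicates give se/sqrt(k)", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    ses <- runif(k, 0.05, 0.5)
    studies <- lapply(seq_len(k), function(i)
      toy_sumstats("1", 100L, "A", "G", beta = rnorm(1), se = ses[i]))
    m <- meta_fixed(studies)
    expect_lte(m$se, min(ses))
  }
  s <- toy_sumstats("1", 100L, "A", "G", beta = 0.12, se = 0.2)
  expect_equal(meta_fixed(list(s, s, s))$se, 0.2 / sqrt(3))

  # variant in only one study passes through flagged
  s1 <- toy_sumstats("1", c(100L, 200L), "A", "G", beta = c(0.1, 0.4),
                     se = c(0.1, 0.1), p = c(0.5, 0.02))
  s2 <- toy_sumstats("1", 100L, "A", "G", beta = 0.3, se = 0.2)
  m <- meta_fixed(list(s1, s2))
  expect_equal(nrow(m), 2L)
  solo <- m[m$pos == 200L, ]
  expect_equal(solo$n_studies, 1L)
  expect_true(solo$flagged)
  expect_equal(solo$beta, 0.4)
  expect_equal(solo$pvalue, 0.02)
})
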