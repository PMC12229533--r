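test_that("AUC equals exhaustive pair enumeration", {
  # worked example: 4 case-control pairs, 3 concordant
  r <- roc_auc(c(2, 3, 1, 2.5), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.75)
  # perfectly separated scores
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  # ties contribute 1/2
  expect_equal(roc_auc(c(1, 1), c(1, 0))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")

  set.seed(61)
  for (rep in 1:40) {
    n <- sample(10:200, 1)
    sc <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # force ties
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc, auc_bruteforce(sc, lb))
  }
})

test_that("AUC and its DeLong variance agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(67)
  sc <- rnorm(300) + rep(c(0.6, 0), c(120, 180))
  lb <- rep(c(1, 0), c(120, 180))
  ours <- roc_auc(sc, lb)
  ref <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(ours$var_auc, as.numeric(pROC::var(ref, method = "delong")),
               tolerance = 1e-12)

  sc2 <- 0.5 * sc + rnorm(300)
  ours2 <- delong_compare(sc, sc2, lb)
  ref2 <- pROC::roc.test(pROC::roc(lb, sc, quiet = TRUE, direction = "<"),
                         pROC::roc(lb, sc2, quiet = TRUE, direction = "<"),
                         method = "delong", paired = TRUE)
  expect_equal(ours2$pvalue, ref2$p.value, tolerance = 1e-10)
})

test_that("null scores give AUC near 1/2", {
  set.seed(71)
  a <- roc_auc(rnorm(2000), rbinom(2000, 1, 0.5))
  expect_lt(abs(a$auc - 0.5), 3 * a$auc_se)
})

test_that("the operating point minimizes distance to the (0,1) corner", {
  # two candidate points: (sens .8, spec .9) beats (sens .6, spec .95)
  curve <- data.frame(threshold = c(0.7, 0.5), fpr = c(0.05, 0.1),
                      tpr = c(0.6, 0.8))
  d <- sqrt(curve$fpr^2 + (1 - curve$tpr)^2)
  expect_equal(round(d, 4), c(0.4031, 0.2236))
  op <- operating_point(list(curve = curve),
                        scores = c(0.9, 0.6, 0.4, 0.2),
                        labels = c(1, 1, 0, 0))
  expect_equal(op$sensitivity, 0.8)
  expect_equal(op$specificity, 0.9)
  expect_equal(op$balanced_accuracy, (0.8 + 0.9) / 2)
  # balanced accuracy identity, to the reported precision
  expect_equal(round((0.597 + 0.594) / 2, 4), 0.5955)

  # perfect classifier: all metrics 1 at the separating value
  r <- roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))
  op2 <- operating_point(r, c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(op2$sensitivity, 1)
  expect_equal(op2$specificity, 1)
  expect_equal(op2$accuracy, 1)
  expect_true(op2$accuracy_ci[1] <= 1 & op2$accuracy_ci[2] == 1)
  # accuracy CI is exact Clopper-Pearson
  set.seed(3)
  sc <- rnorm(50); lb <- rbinom(50, 1, 0.5)
  r3 <- roc_auc(sc, lb)
  op3 <- operating_point(r3, sc, lb)
  k <- round(op3$accuracy * 50)
  expect_equal(op3$accuracy_ci, as.numeric(binom.test(k, 50)$conf.int),
               tolerance = 1e-10)
})

test_that("delong_compare is symmetric, self-consistent and calibrated", {
  set.seed(73)
  sc <- rnorm(200); lb <- rbinom(200, 1, 0.5)
  # identical scores: delta 0, p 1
  d0 <- delong_compare(sc, sc, lb)
  expect_equal(d0$delta, 0)
  expect_equal(d0$pvalue, 1)
  # swapping negates z, p unchanged
  sc2 <- rnorm(200)
  d1 <- delong_compare(sc, sc2, lb)
  d2 <- delong_compare(sc2, sc, lb)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$pvalue, d2$pvalue)
  expect_gte(d1$var_a + d1$var_b - 2 * d1$cov_ab, 0)
  expect_error(delong_compare(sc, sc2[-1], lb), "same samples")

  # type-I calibration on independent null scores (small-scale check;
  # the full 500-replicate version lives in the acceptance suite)
  rej <- 0
  for (r in 1:150) {
    lbr <- rep(c(1, 0), each = 60)
    rej <- rej + (delong_compare(rnorm(120), rnorm(120), lbr)$pvalue < 0.05)
  }
  expect_lt(abs(rej / 150 - 0.05), 0.06)
})

test_that("association fits recover scale and shrink correctly", {
  sh <- shared_sim()
  co <- sh$cohort
  h <- harmonize_sumstats(sh$base, co$variants)$sumstats
  tv <- co$variants
  panel <- variant_key(tv$chrom, tv$pos, tv$counted_allele, tv$other_allele)
  prs <- score_fixed_panel(co, h, panel)
  fa <- fit_association(co, prs, "pcs")
  expect_equal(fa$or_per_sd, exp(fa$coefficient))
  expect_true(fa$or_ci[1] < fa$or_per_sd & fa$or_per_sd < fa$or_ci[2])

  # duplicating every sample leaves the coefficient, halves the variance
  co2 <- cohort_data(rbind(co$dosage, co$dosage),
                     co$variants,
                     transform(rbind(co$samples, co$samples),
                               sample_id = paste0("r", seq_len(2 * nrow(co$samples)))),
                     co$ancestry_label)
  prs2 <- rbind(prs, prs)
  prs2$sample_id <- co2$samples$sample_id
  fa2 <- fit_association(co2, prs2, "pcs")
  expect_equal(fa2$coefficient, fa$coefficient, tolerance = 1e-6)
  expect_equal(fa2$se, fa$se / sqrt(2), tolerance = 1e-4)

  # separation raises an instructive error
  sep <- co
  n <- nrow(sep$dosage)
  sep_prs <- prs
  sep_prs$z_score <- ifelse(sep$samples$phenotype == 1, 5, -5) + 0
  expect_error(suppressWarnings(fit_association(sep, sep_prs, "pcs")),
               "separation")
})

test_that("null PRS association is calibrated near OR = 1", {
  set.seed(79)
  inside <- 0
  for (r in 1:60) {
    n <- 1200
    samples <- data.frame(sample_id = paste0("s", 1:n),
                          phenotype = rbinom(n, 1, 0.5),
                          sex = rbinom(n, 1, 0.5), age = rnorm(n, 60, 10),
                          PC1 = rnorm(n))
    co <- cohort_data(matrix(rbinom(n, 2, 0.5), n, 1),
                      data.frame(variant_id = "rs1", chrom = "1", pos = 1L,
                                 counted_allele = "A", other_allele = "G"),
                      samples, "NULL")
    prs <- data.frame(sample_id = samples$sample_id,
                      z_score = rnorm(n))
    fa <- fit_association(co, prs, "pcs")
    inside <- inside + (fa$or_ci[1] <= 1 && 1 <= fa$or_ci[2])
  }
  expect_gte(inside / 60, 0.9)
})

test_that("admixture covariates drop one simplex component", {
  set.seed(83)
  n <- 300
  adm <- matrix(rgamma(3 * n, 1), n)
  adm <- adm / rowSums(adm)
  samples <- data.frame(sample_id = paste0("s", 1:n),
                        phenotype = rbinom(n, 1, 0.5),
                        sex = rbinom(n, 1, 0.5), age = rnorm(n, 60, 8),
                        ADM1 = adm[, 1], ADM2 = adm[, 2], ADM3 = adm[, 3])
  co <- cohort_data(matrix(rbinom(n, 2, 0.5), n, 1),
                    data.frame(variant_id = "rs1", chrom = "1", pos = 1L,
                               counted_allele = "A", other_allele = "G"),
                    samples, "ADMIX")
  X <- covariate_matrix(co, "admixture")
  expect_true(all(c("ADM1", "ADM2") %in% colnames(X)))
  expect_false("ADM3" %in% colnames(X))
  prs <- data.frame(sample_id = samples$sample_id, z_score = rnorm(n))
  fa <- fit_association(co, prs, "admixture")
  expect_equal(fa$covariate_set, "admixture")
})

test_that("comparison matrices enumerate the model pairs", {
  set.seed(89)
  lb <- rbinom(150, 1, 0.5)
  scores <- list(a = rnorm(150), b = rnorm(150), c = rnorm(150))
  cm <- comparison_matrix(scores, lb, target = "X")
  expect_equal(nrow(cm), 3L)          # k (k-1) / 2
  expect_equal(nrow(comparison_matrix(scores[1:2], lb)), 1L)
  # antisymmetric in delta under model swap
  d_ab <- cm$delta_auc[cm$model_a == "a" & cm$model_b == "b"]
  d2 <- delong_compare(scores$b, scores$a, lb)
  expect_equal(d_ab, -d2$delta)
})

test_that("AUC rises with the simulated effect size alongside the OR", {
  set.seed(97)
  aucs <- ors <- numeric(0)
  for (b in c(0.1, 0.35, 0.7, 1.2)) {
    n <- 800
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.1 + b * z))
    aucs <- c(aucs, roc_auc(z, y)$auc)
    ors <- c(ors, coef(glm(y ~ z, family = binomial()))["z"])
  }
  expect_equal(order(aucs), order(abs(ors)))
})
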