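# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct integration,
# or Monte Carlo on the generative model.

# AUC by exhaustive case-control pair enumeration
auc_bruteforce <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

# Greedy clumping re-derived from scratch on a precomputed r2 matrix
clump_bruteforce <- function(chrom, pos, pvalue, key, r2mat, window_bp, r2_max) {
  ord <- order(pvalue, pos, key)
  removed <- rep(FALSE, length(pvalue))
  index <- character(0)
  for (i in ord) {
    if (removed[i]) next
    index <- c(index, key[i])
    removed[i] <- TRUE  # consumed as index
    for (j in ord) {
      if (removed[j]) next
      if (chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= window_bp &&
          r2mat[i, j] >= r2_max) {
        removed[j] <- TRUE
      }
    }
  }
  index
}

# Exact HWE p-value by direct enumeration of heterozygote counts using
# multinomial probabilities under HWE conditioned on the allele count
# (normalized by summation, computed with plain factorials on small tables)
hwe_enumeration <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na <- 2 * n_hom1 + n_het
  rare <- min(na, 2 * n - na)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- sapply(hets, function(h) {
    r <- (rare - h) / 2
    c2 <- n - h - r
    # unnormalized count of allele arrangements giving this table
    exp(lfactorial(n) - lfactorial(r) - lfactorial(h) - lfactorial(c2) +
          h * log(2))
  })
  probs <- probs / sum(probs)
  p_obs <- probs[hets == n_het]
  sum(probs[probs <= p_obs + 1e-12])
}

# AUC of a true-effect score under the liability-threshold model by
# numerical integration: score s ~ N(0, vg), case given s with
# probability 1 - pnorm((t - s) / sqrt(1 - vg)).
liability_auc_oracle <- function(vg, prevalence) {
  t <- qnorm(1 - prevalence)
  s <- seq(-6 * sqrt(vg), 6 * sqrt(vg), length.out = 4001)
  ds <- diff(s[1:2])
  phi <- dnorm(s, 0, sqrt(vg))
  pcase <- pnorm((t - s) / sqrt(1 - vg), lower.tail = FALSE)
  fcase <- phi * pcase; fcase <- fcase / sum(fcase * ds)
  fctrl <- phi * (1 - pcase); fctrl <- fctrl / sum(fctrl * ds)
  Fctrl <- cumsum(fctrl * ds)
  sum((Fctrl - 0.5 * fctrl * ds) * fcase * ds)
}

# Adjacent-haplotype allele correlation for a thresholded AR(1) latent
# Gaussian, by Monte Carlo on the latent pair
latent_ld_oracle <- function(rho, f, n = 400000) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  a1 <- z1 < qnorm(f)
  a2 <- z2 < qnorm(f)
  cor(a1, a2)^2
}

# Population (asymptotic) logistic coefficient of a standardized score in
# an ascertained case-control sample, by weighted ML on a fine grid
population_logistic_slope <- function(r, prevalence, case_fraction) {
  t <- qnorm(1 - prevalence)
  s <- seq(-7, 7, length.out = 2001)
  phi <- dnorm(s)
  pcase <- pnorm((t - r * s) / sqrt(1 - r^2), lower.tail = FALSE)
  w_case <- phi * pcase / prevalence * case_fraction
  w_ctrl <- phi * (1 - pcase) / (1 - prevalence) * (1 - case_fraction)
  # standardize the score to the ascertained mixture
  wt <- c(w_case, w_ctrl)
  mu <- sum(c(s, s) * wt) / sum(wt)
  sdv <- sqrt(sum((c(s, s) - mu)^2 * wt) / sum(wt))
  dat <- data.frame(y = rep(c(1, 0), each = length(s)),
                    x = (c(s, s) - mu) / sdv, w = wt)
  fit <- suppressWarnings(glm(y ~ x, weights = w, data = dat, family = binomial()))
  unname(coef(fit)["x"])
}

# ---- fixture builders ------------------------------------------------------

toy_cohort <- function(dosage, phenotype = NULL, chrom = "1",
                       pos = seq_len(ncol(dosage)) * 1000L,
                       counted = "A", other = "G", label = "TOY") {
  m <- ncol(dosage)
  variants <- data.frame(variant_id = paste0("rs", seq_len(m)),
                         chrom = rep_len(chrom, m), pos = pos,
                         counted_allele = rep_len(counted, m),
                         other_allele = rep_len(other, m),
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("s", seq_len(nrow(dosage))),
                        stringsAsFactors = FALSE)
  if (!is.null(phenotype)) samples$phenotype <- phenotype
  cohort_data(dosage, variants, samples, label)
}

toy_sumstats <- function(chrom, pos, a1, a2, beta,
                         se = rep(0.1, length(beta)),
                         p = rep(0.5, length(beta)), eaf = NA, n = NA) {
  summary_stats(data.frame(
    variant_id = paste0("rs", seq_along(beta)), chrom = chrom, pos = pos,
    effect_allele = a1, other_allele = a2, beta = beta, se = se,
    pvalue = p, eaf = eaf, n = n, stringsAsFactors = FALSE))
}

# small simulated cohort shared by several test files (cached per session)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_ancestries = 2, fst = 0.05, n_variants = 200,
                        n_causal = 20, h2_liability = 0.3, prevalence = 0.1,
                        n_cases = 300, n_controls = 300, seed = 101)
      sim <- simulate_cohort(cfg, ancestry = 1)
      base <- simulate_base_gwas(cfg, n_train = 2000, ancestry = 1)
      cohort <- suppressWarnings(compute_pcs(sim$cohort, 5))
      cache <<- list(cfg = cfg, sim = sim, base = base, cohort = cohort)
    }
    cache
  }
})
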