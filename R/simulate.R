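#' Configuration for the multi-ancestry cohort simulator
#'
#' Defines the generative model used throughout the package's tests and
#' analysis scripts: ancestries diverge from a common ancestral
#' population under the Balding-Nichols model (per-ancestry allele
#' frequencies Beta-distributed around the ancestral frequency with
#' divergence `fst`); haplotypes carry blockwise linkage disequilibrium
#' from a thresholded AR(1) latent Gaussian; disease follows a
#' liability-threshold architecture in which causal variants contribute
#' `h2_liability` of unit liability variance and a sample is a case when
#' liability exceeds the quantile set by `prevalence`.
#'
#' Defaults mirror the study conditions this package emulates: disease
#' prevalence 0.005 and liability-scale heritability 0.22, with a fixed
#' panel of 90 causal risk variants; case/control ages are drawn from
#' normal distributions patterned on the cohorts' demographics (cases
#' 58.9 +/- 11.8 years at onset, controls 62.4 +/- 13.0 at collection).
#'
#' @param n_ancestries number of ancestral populations.
#' @param fst Balding-Nichols divergence per ancestry (recycled).
#' @param n_variants total variants (one chromosome, 5 kb spacing).
#' @param n_causal causal variants (placed at most one per LD block when
#'   possible, keeping causal variants linkage-independent so their
#'   standardized effects sum exactly to `h2_liability`).
#' @param h2_liability liability-scale variance explained by the causal
#'   panel.
#' @param prevalence population disease prevalence K.
#' @param ld_block_size variants per LD block.
#' @param ld_rho AR(1) correlation of the latent haplotype Gaussian.
#' @param n_cases,n_controls per-cohort case/control counts under
#'   ascertained sampling.
#' @param admixture_alpha Dirichlet concentration vector for per-sample
#'   admixture proportions, or `NULL` for unadmixed cohorts.
#' @param ancestral_freq optional vector of ancestral frequencies
#'   (default Uniform(0.05, 0.95)).
#' @param causal_beta optional length-`n_causal` vector of relative
#'   causal effects on the standardized-liability scale (default
#'   standard-normal draws); always rescaled so the squared effects sum
#'   to `h2_liability`.
#' @param age_case,age_control `c(mean, sd)` of case/control ages.
#' @param max_attempts rejection-sampling budget for ascertained
#'   cohorts; default scales with `n_cases / prevalence`.
#' @param seed integer master seed; all randomness flows from it through
#'   fixed per-operation sub-streams.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_ancestries = 2, fst = 0.1, n_variants = 500,
                       n_causal = 90, h2_liability = 0.22, prevalence = 0.005,
                       ld_block_size = 10, ld_rho = 0.7,
                       n_cases = 500, n_controls = 500,
                       admixture_alpha = NULL, ancestral_freq = NULL,
                       causal_beta = NULL,
                       age_case = c(58.9, 11.8), age_control = c(62.4, 13.0),
                       max_attempts = NULL, seed = 42) {
  stopifnot(n_causal <= n_variants, h2_liability >= 0, h2_liability < 1,
            prevalence > 0, prevalence < 1, ld_rho >= 0, ld_rho < 1,
            all(fst >= 0), all(fst < 0.5))
  fst <- rep_len(fst, n_ancestries)
  if (is.null(max_attempts))
    max_attempts <- ceiling(3 * (n_cases / prevalence +
                                   n_controls / (1 - prevalence))) + 10000
  structure(list(n_ancestries = n_ancestries, fst = fst,
                 n_variants = n_variants, n_causal = n_causal,
                 h2_liability = h2_liability, prevalence = prevalence,
                 ld_block_size = ld_block_size, ld_rho = ld_rho,
                 n_cases = n_cases, n_controls = n_controls,
                 admixture_alpha = admixture_alpha,
                 ancestral_freq = ancestral_freq, causal_beta = causal_beta,
                 age_case = age_case, age_control = age_control,
                 max_attempts = max_attempts, seed = as.integer(seed)),
            class = "sim_config")
}

# fixed per-operation sub-stream seeds
sub_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Draw ancestry-diverged allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95) unless supplied;
#' per-ancestry frequencies follow the Balding-Nichols model,
#' `Beta(f(1-F)/F, (1-f)(1-F)/F)`, whose mean is the ancestral
#' frequency. `F = 0` is the degenerate no-divergence limit and returns
#' the ancestral frequencies exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with `ancestral` (length `n_variants`) and `freq`
#'   (`n_variants` x `n_ancestries` matrix), frozen by `cfg$seed`.
#' @export
draw_frequencies <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg, 101L))
  f0 <- cfg$ancestral_freq %||% runif(cfg$n_variants, 0.05, 0.95)
  stopifnot(length(f0) == cfg$n_variants)
  freq <- matrix(NA_real_, cfg$n_variants, cfg$n_ancestries)
  for (k in seq_len(cfg$n_ancestries)) {
    F <- cfg$fst[k]
    if (F == 0) {
      freq[, k] <- f0
    } else {
      freq[, k] <- rbeta(cfg$n_variants, f0 * (1 - F) / F,
                         (1 - f0) * (1 - F) / F)
      # keep variants polymorphic in every ancestry
      freq[, k] <- pmin(pmax(freq[, k], 1e-4), 1 - 1e-4)
    }
  }
  list(ancestral = f0, freq = freq)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Deterministic ground truth shared by cohort and base-GWAS draws:
# frequencies, causal panel, standardized effects, block structure.
sim_truth <- function(cfg) {
  fr <- draw_frequencies(cfg)
  m <- cfg$n_variants
  block_id <- (seq_len(m) - 1L) %/% cfg$ld_block_size
  n_blocks <- max(block_id) + 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg, 307L))
  if (cfg$n_causal <= n_blocks) {
    # one causal per block, evenly spread: keeps causals LD-independent
    blocks <- unique(round(seq(0, n_blocks - 1, length.out = cfg$n_causal)))
    while (length(blocks) < cfg$n_causal)
      blocks <- sort(union(blocks, sample(setdiff(seq_len(n_blocks) - 1L, blocks), 1)))
    causal <- vapply(blocks, function(b) {
      j <- which(block_id == b)
      j[ceiling(length(j) / 2)]
    }, integer(1))
  } else {
    causal <- sort(sample.int(m, cfg$n_causal))
  }
  beta_std <- numeric(m)
  if (cfg$h2_liability > 0 && cfg$n_causal > 0) {
    raw <- cfg$causal_beta %||% rnorm(cfg$n_causal)
    stopifnot(length(raw) == cfg$n_causal)
    beta_std[causal] <- raw * sqrt(cfg$h2_liability / sum(raw^2))
  }
  variants <- data.frame(
    variant_id = sprintf("v%05d", seq_len(m)),
    chrom = "1",
    pos = (seq_len(m) - 1L) * 5000L + 1L,
    counted_allele = "A", other_allele = "G",
    stringsAsFactors = FALSE
  )
  list(ancestral = fr$ancestral, freq = fr$freq, block_id = block_id,
       causal = causal, beta_std = beta_std,
       threshold = qnorm(1 - cfg$prevalence), variants = variants)
}

#' Simulate a case-control cohort with known ground truth
#'
#' Draws a cohort from the liability-threshold model of a
#' [sim_config()]. Under ascertained sampling (the default), individuals
#' are drawn from the population until `n_cases` cases and `n_controls`
#' controls accumulate (rejection sampling, exact); the unascertained
#' branch returns the first `n_total` population draws. Causal effects
#' are shared across ancestries on the standardized-dosage scale while
#' allele frequencies (and hence per-allele effects and LD) diverge.
#' Sex is Bernoulli(0.5) and age normal with distinct case/control
#' means. For admixed cohorts (`admixture_alpha` set), each haplotype
#' block independently originates from one ancestry drawn with the
#' sample's Dirichlet admixture proportions, and liability is
#' standardized at the admixture-averaged frequencies.
#'
#' @param cfg a [sim_config()].
#' @param ancestry 1-based ancestry index of the cohort (ignored for
#'   admixed cohorts).
#' @param ascertain draw to case/control quotas (default) or take a
#'   population sample.
#' @param n_total population sample size when `ascertain = FALSE`.
#' @param seed_offset internal sub-stream offset, distinguishing
#'   independent draws that share the same ground truth.
#' @return list with `cohort` (a [cohort_data()] with phenotype, sex,
#'   age and any admixture columns attached) and `truth` (per-variant
#'   frequencies and liability-scale effects, per-sample liability, the
#'   case threshold).
#' @export
simulate_cohort <- function(cfg, ancestry = 1, ascertain = TRUE,
                            n_total = cfg$n_cases + cfg$n_controls,
                            seed_offset = 0L) {
  tr <- sim_truth(cfg)
  admixed <- !is.null(cfg$admixture_alpha)
  if (admixed && length(cfg$admixture_alpha) != cfg$n_ancestries)
    stop_input("admixture_alpha must have length n_ancestries")
  if (admixed) {
    abar <- cfg$admixture_alpha / sum(cfg$admixture_alpha)
    fref <- as.vector(tr$freq %*% abar)
  } else {
    fref <- tr$freq[, ancestry]
  }
  scale_j <- sqrt(2 * fref * (1 - fref))
  beta_allele <- ifelse(scale_j > 0, tr$beta_std / scale_j, 0)
  center <- 2 * fref

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg, 211L + 17L * ancestry + seed_offset))
  res <- sample_cohort_cpp(
    qthr = qnorm(tr$freq), block_id = tr$block_id, rho = cfg$ld_rho,
    beta = beta_allele, center = center,
    resid_sd = sqrt(1 - cfg$h2_liability), threshold = tr$threshold,
    admix_alpha = if (admixed) cfg$admixture_alpha else numeric(0),
    anc_fixed = ancestry - 1L,
    ascertain = ascertain, n_cases = cfg$n_cases,
    n_controls = cfg$n_controls, n_total = n_total,
    max_attempts = if (ascertain) cfg$max_attempts else n_total)
  n_need <- if (ascertain) cfg$n_cases + cfg$n_controls else n_total
  if (res$n_kept < n_need)
    stop(sprintf(paste0(
      "could not accumulate %d samples in %d attempts (prevalence %.4g); ",
      "increase max_attempts in sim_config"),
      n_need, cfg$max_attempts, cfg$prevalence), call. = FALSE)

  n <- res$n_kept
  pheno <- res$is_case[seq_len(n)]
  age_par <- ifelse(pheno == 1, 1, 0)
  samples <- data.frame(
    sample_id = sprintf("s%05d", seq_len(n)),
    phenotype = pheno,
    sex = rbinom(n, 1, 0.5),
    age = round(rnorm(n,
                      ifelse(pheno == 1, cfg$age_case[1], cfg$age_control[1]),
                      ifelse(pheno == 1, cfg$age_case[2], cfg$age_control[2])), 1),
    stringsAsFactors = FALSE
  )
  if (admixed) {
    adm <- res$admixture[seq_len(n), , drop = FALSE]
    colnames(adm) <- paste0("ADM", seq_len(ncol(adm)))
    samples <- cbind(samples, as.data.frame(adm))
  }
  cohort <- cohort_data(res$dosage[seq_len(n), , drop = FALSE], tr$variants,
                        samples,
                        ancestry_label = if (admixed) "ADMIX"
                        else paste0("POP", ancestry))
  truth <- list(
    variants = data.frame(tr$variants,
                          ancestral_freq = tr$ancestral,
                          freq = tr$freq,
                          beta_std = tr$beta_std,
                          beta_allele = beta_allele,
                          causal = seq_len(cfg$n_variants) %in% tr$causal),
    liability = res$liability[seq_len(n)],
    threshold = tr$threshold,
    admixture = if (admixed) res$admixture[seq_len(n), , drop = FALSE] else NULL
  )
  list(cohort = cohort, truth = truth)
}

#' Simulate base GWAS summary statistics
#'
#' Draws an independent ascertained training cohort (half cases, half
#' controls) from the same ground truth as [simulate_cohort()] and runs
#' a per-variant logistic association (Wald beta, SE, p of dosage on
#' case status, unadjusted), emitting results in the summary-statistics
#' dialect. Variants monomorphic in the training sample cannot be
#' estimated; they are omitted from the returned records and their keys
#' listed in the `monomorphic` attribute.
#'
#' @param cfg a [sim_config()].
#' @param n_train training-sample size (cases + controls).
#' @param ancestry 1-based ancestry index of the training sample.
#' @return a `summary_stats` data frame.
#' @export
simulate_base_gwas <- function(cfg, n_train, ancestry = 1) {
  cfg2 <- cfg
  cfg2$n_cases <- ceiling(n_train / 2)
  cfg2$n_controls <- n_train - cfg2$n_cases
  cfg2$max_attempts <- ceiling(3 * (cfg2$n_cases / cfg$prevalence +
                                      cfg2$n_controls)) + 10000
  sim <- simulate_cohort(cfg2, ancestry = ancestry,
                         seed_offset = 100000L + 7L * ancestry)
  g <- sim$cohort$dosage
  y <- sim$cohort$samples$phenotype
  m <- ncol(g)
  beta <- se <- pval <- rep(NA_real_, m)
  mono <- logical(m)
  for (j in seq_len(m)) {
    x <- g[, j]
    if (var(x) == 0) { mono[j] <- TRUE; next }
    fit <- suppressWarnings(
      glm.fit(cbind(1, x), y, family = binomial()))
    cf <- fit$coefficients[2]
    # Wald SE from the unscaled covariance of the IRLS fit
    w <- fit$weights
    xm <- cbind(1, x)
    xtwx <- crossprod(xm * sqrt(w))
    v <- tryCatch(solve(xtwx)[2, 2], error = function(e) NA_real_)
    if (is.na(v) || v <= 0 || !fit$converged) { mono[j] <- TRUE; next }
    beta[j] <- cf
    se[j] <- sqrt(v)
    pval[j] <- 2 * pnorm(-abs(cf / sqrt(v)))
  }
  v <- sim$cohort$variants
  ok <- !mono
  ss <- summary_stats(data.frame(
    variant_id = v$variant_id[ok], chrom = v$chrom[ok], pos = v$pos[ok],
    effect_allele = v$counted_allele[ok], other_allele = v$other_allele[ok],
    beta = beta[ok], se = se[ok], pvalue = pmax(pval[ok], 1e-300),
    eaf = colMeans(g[, ok, drop = FALSE]) / 2,
    n = n_train, stringsAsFactors = FALSE))
  attr(ss, "monomorphic") <- v$variant_id[mono]
  ss
}
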