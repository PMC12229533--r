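#' Clumping parameters
#'
#' Defaults follow the standard clumping-and-thresholding convention:
#' a 250 kb window around each index variant and an LD threshold of
#' r^2 < 0.1, with no p-value pre-filter.
#'
#' @param window_kb half-window in kb around the index variant; a
#'   variant is in range when its bp distance is `<= window_kb * 1000`.
#' @param r2_max variants with LD `r^2 >= r2_max` to an index variant
#'   within the window are clumped away.
#' @param p_max only variants with `p <= p_max` enter clumping.
#' @return a `clump_params` list.
#' @export
clump_params <- function(window_kb = 250, r2_max = 0.1, p_max = 1) {
  stopifnot(window_kb > 0, r2_max > 0, r2_max <= 1, p_max > 0, p_max <= 1)
  structure(list(window_kb = window_kb, r2_max = r2_max, p_max = p_max),
            class = "clump_params")
}

#' Greedy LD clumping
#'
#' Iterates association records by ascending p-value (ties broken by
#' position, then variant key); each not-yet-clumped variant becomes an
#' index variant and removes all unclumped variants on the same
#' chromosome within the window whose dosage correlation squared
#' (computed from the target cohort, the LD reference) meets `r2_max`.
#'
#' @param assoc data frame with columns `chrom`, `pos`, `pvalue` and a
#'   variant identity resolvable against the cohort (`variant_id`, or
#'   alleles for key matching); typically a harmonized `summary_stats`.
#' @param cohort the [cohort_data()] supplying LD (missing dosages
#'   mean-imputed before correlation).
#' @param params a [clump_params()].
#' @return character vector of index `variant_id`s, in ascending-p order.
#' @export
clump <- function(assoc, cohort, params = clump_params()) {
  if (any(is.na(assoc$pos))) stop_input("association records lack positions")
  keep <- assoc$pvalue <= params$p_max
  a <- assoc[keep, , drop = FALSE]
  if (!nrow(a)) return(character(0))
  ti <- match_assoc_to_cohort(a, cohort)
  ok <- !is.na(ti)
  a <- a[ok, , drop = FALSE]; ti <- ti[ok]
  if (!nrow(a)) return(character(0))
  key <- cohort$variants$variant_id[ti]
  ord <- order(a$pvalue, a$pos, key)
  a <- a[ord, , drop = FALSE]; ti <- ti[ord]; key <- key[ord]

  g <- cohort$dosage[, ti, drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]

  n <- nrow(a)
  clumped <- rep(FALSE, n)
  index <- logical(n)
  win <- params$window_kb * 1000
  for (i in seq_len(n)) {
    if (clumped[i]) next
    index[i] <- TRUE
    near <- which(!clumped & !index & a$chrom == a$chrom[i] &
                    abs(a$pos - a$pos[i]) <= win)
    if (length(near)) {
      r <- suppressWarnings(cor(g[, i], g[, near, drop = FALSE]))
      r2 <- as.vector(r)^2
      r2[is.na(r2)] <- 0
      clumped[near[r2 >= params$r2_max]] <- TRUE
    }
  }
  key[index]
}

match_assoc_to_cohort <- function(assoc, cohort) {
  tv <- cohort$variants
  if (!is.null(assoc$effect_allele)) {
    match(pair_key(assoc$chrom, assoc$pos, assoc$effect_allele,
                   assoc$other_allele),
          pair_key(tv$chrom, tv$pos, tv$counted_allele, tv$other_allele))
  } else if (!is.null(assoc$variant_id)) {
    match(assoc$variant_id, tv$variant_id)
  } else {
    match(locus_key(assoc$chrom, assoc$pos), locus_key(tv$chrom, tv$pos))
  }
}

#' Nagelkerke pseudo-R-squared
#'
#' `R2_CS = 1 - exp(-(2/n) (ll_full - ll_null))` normalized by its
#' maximum `1 - exp((2/n) ll_null)`.
#'
#' @param ll_full,ll_null log-likelihoods of the full and null models.
#' @param n number of observations.
#' @return Nagelkerke R^2 in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(ll_full, ll_null, n) {
  stopifnot(n > 0)
  if (ll_full < ll_null - 1e-8)
    stop_input("ll_full (%.4f) below ll_null (%.4f): models not nested or misfit",
               ll_full, ll_null)
  denom <- 1 - exp(2 * ll_null / n)
  if (denom <= 0)
    stop_input("degenerate null likelihood (ll_null = %g)", ll_null)
  r2_cs <- 1 - exp(-(2 / n) * (ll_full - ll_null))
  max(r2_cs, 0) / denom
}

#' Liability-scale R-squared with ascertainment correction
#'
#' Converts an observed-scale case-control R^2 to the liability scale
#' (Lee et al. 2012): with prevalence `K`, case fraction `P`,
#' `t = qnorm(1-K)`, `z = dnorm(t)`, `i = z/K`,
#' `C = K^2 (1-K)^2 / (z^2 P (1-P))` and
#' `theta = i ((P-K)/(1-K)) (i ((P-K)/(1-K)) - t)`, the liability-scale
#' value is `C r2 / (1 + C theta r2)`. When the sample is unascertained
#' (`P = K`), `theta = 0` and the transformation reduces to
#' `r2 K (1-K) / z^2`.
#'
#' @param r2_obs observed-scale R^2 (e.g. incremental Nagelkerke R^2).
#' @param prevalence population prevalence K.
#' @param case_fraction sample case proportion P.
#' @return liability-scale R^2.
#' @export
liability_r2 <- function(r2_obs, prevalence, case_fraction) {
  stopifnot(prevalence > 0, prevalence < 1,
            case_fraction > 0, case_fraction < 1)
  if (r2_obs == 0) return(0)
  stopifnot(r2_obs > 0, r2_obs < 1)
  K <- prevalence; P <- case_fraction
  t <- qnorm(1 - K); z <- dnorm(t); i <- z / K
  C <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  u <- i * (P - K) / (1 - K)
  theta <- u * (u - t)
  C * r2_obs / (1 + C * theta * r2_obs)
}

#' Clumping + thresholding PRS with best-fit threshold selection
#'
#' Clumps once at the loosest threshold, then, for each p-value
#' threshold, scores the index variants with `p <= threshold`,
#' standardizes the score, and fits logistic full (PRS + covariates)
#' and null (covariates only) models. The grid records Nagelkerke R^2
#' of both models, the incremental PRS R^2 (full minus null), its
#' liability-scale conversion at the given prevalence, and the
#' coefficient and SE of the standardized PRS. The best-fit row
#' maximizes incremental PRS R^2 among thresholds retaining fewer SNPs
#' than samples (an overfitting guard); ties go to the stricter
#' threshold. Rows whose logistic fit does not converge are flagged and
#' excluded from selection; rows with zero SNPs are omitted.
#'
#' @param cohort a [cohort_data()] with phenotype and covariates.
#' @param base harmonized `summary_stats` providing weights and p-values.
#' @param thresholds p-value thresholds; default 5e-8 to 5e-2 by decades.
#' @param params a [clump_params()].
#' @param covariate_set `"pcs"` or `"admixture"` (see
#'   [fit_association()]).
#' @param prevalence population prevalence used for the liability-scale
#'   adjustment (default 0.005).
#' @return a `ct_fit`: list with `grid` (one row per non-empty
#'   threshold), `best_threshold`, `best_row`, `index_variants`, and
#'   `prs` (the `prs_result` at the best threshold).
#' @export
fit_ct <- function(cohort, base, thresholds = 5 * 10^seq(-8, -2),
                   params = clump_params(), covariate_set = "pcs",
                   prevalence = 0.005) {
  stopifnot(inherits(base, "summary_stats"))
  thresholds <- sort(unique(thresholds))
  p2 <- params
  p2$p_max <- min(p2$p_max, max(thresholds))
  index_ids <- clump(base, cohort, p2)
  if (!length(index_ids))
    stop_input("no variant passes the loosest threshold %g", max(thresholds))
  tv <- cohort$variants
  bi <- match_assoc_to_cohort(base, cohort)
  base_p <- setNames(base$pvalue, tv$variant_id[bi])[index_ids]

  X <- covariate_matrix(cohort, covariate_set)
  y <- cohort$samples$phenotype
  null_fit <- glm.fit(cbind(`(Intercept)` = 1, X), y, family = binomial())
  ll_null <- binomial_ll(y, null_fit$fitted.values)
  n <- length(y)
  null_r2 <- nagelkerke_r2(ll_null, binomial_ll_null_only(y), n)

  rows <- list()
  best_prs <- NULL
  for (thr in thresholds) {
    ids <- index_ids[base_p <= thr]
    if (!length(ids)) next
    keys <- with(tv[match(ids, tv$variant_id), ],
                 variant_key(chrom, pos, counted_allele, other_allele))
    prs <- score_fixed_panel(cohort, base, keys)
    full_fit <- glm.fit(cbind(`(Intercept)` = 1, prs = prs$z_score, X), y,
                        family = binomial())
    ll_full <- binomial_ll(y, full_fit$fitted.values)
    se <- glm_fit_se(full_fit, 2)
    full_r2 <- nagelkerke_r2(max(ll_full, ll_null), binomial_ll_null_only(y), n)
    prs_r2 <- max(full_r2 - null_r2, 0)
    rows[[length(rows) + 1]] <- data.frame(
      threshold = thr, n_snps = length(ids),
      prs_r2_obs = prs_r2,
      prs_r2_liab = liability_r2(prs_r2, prevalence, mean(y)),
      full_r2 = full_r2, null_r2 = null_r2,
      coefficient = unname(full_fit$coefficients[2]), se = se,
      converged = full_fit$converged && is.finite(se))
    attr(rows[[length(rows)]], "prs") <- prs
  }
  if (!length(rows)) stop_input("no threshold retains any clumped variant")
  grid <- do.call(rbind, lapply(rows, function(r) { attr(r, "prs") <- NULL; r }))
  eligible <- grid$converged & grid$n_snps < n
  if (!any(eligible))
    stop_input("no eligible threshold (all rows non-converged or n_snps >= n_samples)")
  # max incremental R2; ties to the stricter (smaller) threshold
  cand <- which(eligible)
  best <- cand[order(-grid$prs_r2_obs[cand], grid$threshold[cand])][1]
  structure(list(grid = grid,
                 best_threshold = grid$threshold[best],
                 best_row = best,
                 index_variants = index_ids,
                 prs = attr(rows[[best]], "prs"),
                 covariate_set = covariate_set,
                 prevalence = prevalence),
            class = "ct_fit")
}

#' @export
print.ct_fit <- function(x, ...) {
  cat(sprintf("ct_fit: best threshold %.2e (%d SNPs, PRS R2 %.4f obs / %.4f liability)\n",
              x$best_threshold, x$grid$n_snps[x$best_row],
              x$grid$prs_r2_obs[x$best_row], x$grid$prs_r2_liab[x$best_row]))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Write a C+T grid as a TSV in the conventional column dialect
#'
#' @param fit a `ct_fit`.
#' @param path output path.
#' @export
write_ct_grid <- function(fit, path) {
  g <- fit$grid
  out <- data.frame(Threshold = format(g$threshold, scientific = TRUE),
                    `PRS R2 adj` = g$prs_r2_liab, `Full R2` = g$full_r2,
                    `Null R2` = g$null_r2, Coefficient = g$coefficient,
                    SE = g$se, `No. of SNP` = g$n_snps, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

binomial_ll <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

binomial_ll_null_only <- function(y) {
  p <- mean(y)
  binomial_ll(y, rep(p, length(y)))
}

glm_fit_se <- function(fit, idx) {
  w <- fit$weights
  X <- qr.X(fit$qr)
  v <- tryCatch(solve(crossprod(X))[idx, idx], error = function(e) NA_real_)
  if (is.na(v) || v < 0) return(NA_real_)
  sqrt(v)
}
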