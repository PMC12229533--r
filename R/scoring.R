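#' Fixed-panel polygenic risk score
#'
#' Scores a cohort over a fixed panel of risk variants with weights from
#' harmonized base summary statistics. The valid predictors are the
#' variants present in all three of panel, base and target; missing
#' dosages are imputed with the per-variant cohort mean. Raw scores are
#' the weighted dosage sums; z-scores standardize them over the full
#' scored cohort (cases and controls together), so downstream odds
#' ratios are per score standard deviation.
#'
#' @param cohort a [cohort_data()].
#' @param base a `summary_stats` object already aligned to the cohort's
#'   counted alleles (see [harmonize_sumstats()]).
#' @param panel character vector of variant keys (`chrom:pos:a1:a2`,
#'   allele order immaterial) or a data frame with columns
#'   `chrom`, `pos` and optionally alleles; see [read_panel()].
#' @return a `prs_result`: data frame of per-sample `sample_id`,
#'   `raw_score`, `z_score`, with attributes `used_variants`,
#'   `n_valid_predictors`, `base_label`, `target_label`.
#' @export
score_fixed_panel <- function(cohort, base, panel) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(base, "summary_stats"))
  pk <- panel_keys(panel)
  if (!length(pk)) stop_input("empty panel")
  tv <- cohort$variants
  target_keys <- pair_key(tv$chrom, tv$pos, tv$counted_allele, tv$other_allele)
  base_keys <- pair_key(base$chrom, base$pos, base$effect_allele,
                        base$other_allele)
  valid <- intersect(pk, intersect(base_keys, target_keys))
  if (!length(valid))
    stop_input(paste0("no valid predictors: panel %d, base %d, target %d ",
                      "variants share no key"),
               length(pk), length(base_keys), length(target_keys))
  ti <- match(valid, target_keys)
  bi <- match(valid, base_keys)
  # align base beta to the cohort's counted allele
  swapped <- base$effect_allele[bi] != tv$counted_allele[ti]
  beta <- ifelse(swapped, -base$beta[bi], base$beta[bi])
  g <- cohort$dosage[, ti, drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_along(valid)) g[is.na(g[, j]), j] <- mu[j]
  raw <- as.vector(g %*% beta)
  s <- sd(raw)
  if (!is.finite(s) || s == 0)
    stop_input("degenerate score: zero variance across %d samples", length(raw))
  out <- data.frame(sample_id = cohort$samples$sample_id,
                    raw_score = raw,
                    z_score = (raw - mean(raw)) / s,
                    stringsAsFactors = FALSE)
  structure(out,
            used_variants = tv$variant_id[ti],
            used_keys = valid,
            n_valid_predictors = length(valid),
            base_label = attr(base, "label") %||% "base",
            target_label = cohort$ancestry_label,
            class = c("prs_result", "data.frame"))
}

panel_keys <- function(panel) {
  if (is.character(panel)) {
    parts <- strsplit(panel, ":")
    bad <- lengths(parts) < 4
    if (any(bad)) stop_input("panel keys must be chrom:pos:a1:a2")
    return(unique(vapply(parts, function(p)
      pair_key(p[1], p[2], p[3], p[4]), character(1))))
  }
  if (is.data.frame(panel)) {
    a1 <- panel$counted_allele %||% panel$a1
    a2 <- panel$other_allele %||% panel$a2
    if (is.null(a1) || is.null(a2))
      stop_input("panel data frame needs allele columns (counted_allele/other_allele)")
    return(unique(pair_key(panel$chrom, panel$pos, a1, a2)))
  }
  stop_input("panel must be a character vector of keys or a data frame")
}

#' @rdname score_fixed_panel
#' @param path panel file: one `chrom:pos:a1:a2` key per line, or a TSV
#'   with columns `chrom`, `pos`, `counted_allele`, `other_allele`.
#' @export
read_panel <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    panel_keys(df)
  } else {
    panel_keys(readLines(path))
  }
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("prs_result: %d samples, %d valid predictors (base %s on target %s)\n",
              nrow(x), attr(x, "n_valid_predictors"),
              attr(x, "base_label"), attr(x, "target_label")))
  invisible(x)
}

#' Per-variant contribution to case-control separation
#'
#' For each valid predictor, the allele-count difference (mean case
#' dosage minus mean control dosage) is multiplied by the variant's
#' effect size, estimating the average impact of that variant on the
#' phenotype; rows are ordered by decreasing `|mean_effect|` with
#' deterministic ties broken by variant key.
#'
#' @inheritParams score_fixed_panel
#' @return data frame with columns `variant_id`, `key`,
#'   `dosage_difference`, `beta`, `mean_effect`.
#' @export
variant_effects <- function(cohort, base, panel) {
  stopifnot(!is.null(cohort$samples$phenotype))
  prs <- score_fixed_panel(cohort, base, panel)
  keys <- attr(prs, "used_keys")
  tv <- cohort$variants
  target_keys <- pair_key(tv$chrom, tv$pos, tv$counted_allele, tv$other_allele)
  base_keys <- pair_key(base$chrom, base$pos, base$effect_allele, base$other_allele)
  ti <- match(keys, target_keys)
  bi <- match(keys, base_keys)
  swapped <- base$effect_allele[bi] != tv$counted_allele[ti]
  beta <- ifelse(swapped, -base$beta[bi], base$beta[bi])
  case <- cohort$samples$phenotype == 1
  g <- cohort$dosage[, ti, drop = FALSE]
  dif <- colMeans(g[case, , drop = FALSE], na.rm = TRUE) -
    colMeans(g[!case, , drop = FALSE], na.rm = TRUE)
  out <- data.frame(variant_id = tv$variant_id[ti], key = keys,
                    dosage_difference = dif, beta = beta,
                    mean_effect = dif * beta, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$mean_effect), out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
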