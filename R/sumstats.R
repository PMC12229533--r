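#' Read GWAS summary statistics
#'
#' Reads a delimited summary-statistics file into a validated
#' `summary_stats` data frame, the container used as PRS base data.
#' Canonical columns are `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `pvalue`, `eaf`, `n`; the default header
#' names follow the common GWAS dialect (`SNP`, `CHR`, `BP`, `A1`, `A2`,
#' `BETA`, `SE`, `P`, `FREQ`, `N`).
#'
#' Records violating the container's invariants (`se > 0`, `pvalue` in
#' (0, 1], `effect_allele != other_allele`) are dropped and counted in the
#' `n_dropped` attribute. Duplicate variant keys (chrom, pos, allele pair)
#' are an error, as the same record would otherwise be scored twice.
#'
#' @param path file path to delimited text with a header row.
#' @param column_map optional named character vector mapping canonical
#'   names (e.g. `beta`) to the file's column names; unmapped canonical
#'   names fall back to the default dialect. `eaf` and `n` are optional.
#' @param sep field separator; the default `""` accepts any whitespace.
#' @return a `summary_stats` data frame.
#' @export
read_sumstats <- function(path, column_map = NULL, sep = "") {
  if (!file.exists(path)) stop_input("summary-statistics file not found: %s", path)
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  defaults <- c(variant_id = "SNP", chrom = "CHR", pos = "BP",
                effect_allele = "A1", other_allele = "A2", beta = "BETA",
                se = "SE", pvalue = "P", eaf = "FREQ", n = "N")
  map <- defaults
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(defaults))
    if (length(unknown))
      stop_input("unknown canonical column(s) in column_map: %s",
                 paste(unknown, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  mandatory <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se", "pvalue")
  missing_cols <- map[mandatory][!map[mandatory] %in% names(raw)]
  if (length(missing_cols))
    stop_input("missing mandatory column(s) in %s: %s", path,
               paste(missing_cols, collapse = ", "))
  ss <- data.frame(
    variant_id = as.character(raw[[map["variant_id"]]]),
    chrom = as.character(raw[[map["chrom"]]]),
    pos = as.integer(raw[[map["pos"]]]),
    effect_allele = toupper(as.character(raw[[map["effect_allele"]]])),
    other_allele = toupper(as.character(raw[[map["other_allele"]]])),
    beta = as.numeric(raw[[map["beta"]]]),
    se = as.numeric(raw[[map["se"]]]),
    pvalue = as.numeric(raw[[map["pvalue"]]]),
    eaf = if (map["eaf"] %in% names(raw)) as.numeric(raw[[map["eaf"]]]) else NA_real_,
    n = if (map["n"] %in% names(raw)) as.integer(raw[[map["n"]]]) else NA_integer_,
    stringsAsFactors = FALSE
  )
  summary_stats(ss)
}

#' Construct a validated summary_stats object
#'
#' @param df data frame with the canonical summary-statistics columns.
#' @return a `summary_stats` data frame; invalid rows are dropped and
#'   counted in the `n_dropped` attribute.
#' @export
summary_stats <- function(df) {
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "se", "pvalue")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("summary_stats lacks column(s): %s",
                               paste(miss, collapse = ", "))
  if (is.null(df$eaf)) df$eaf <- NA_real_
  if (is.null(df$n)) df$n <- NA_integer_
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  ok <- !is.na(df$beta) & !is.na(df$se) & df$se > 0 &
    !is.na(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1 &
    df$effect_allele != df$other_allele
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if (!nrow(df)) stop_input("no valid summary-statistics records")
  key <- pair_key(df$chrom, df$pos, df$effect_allele, df$other_allele)
  if (anyDuplicated(key))
    stop_input("duplicate variant key(s): %s",
               paste(unique(key[duplicated(key)]), collapse = ", "))
  rownames(df) <- NULL
  structure(df, n_dropped = n_dropped,
            class = c("summary_stats", "data.frame"))
}

#' Write summary statistics in the canonical dialect
#'
#' @param ss a `summary_stats` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$variant_id, CHR = ss$chrom, BP = ss$pos,
                    A1 = ss$effect_allele, A2 = ss$other_allele,
                    BETA = ss$beta, SE = ss$se, P = ss$pvalue,
                    FREQ = ss$eaf, N = ss$n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize base summary statistics to target alleles
#'
#' Aligns the base effect allele to the target's counted allele at each
#' locus (matched on chromosome and position). When the base alleles are
#' swapped relative to the target, the sign of `beta` is flipped and
#' `eaf` replaced by `1 - eaf`; when they match only after complementing
#' the strand, the strand is flipped first. Palindromic variants (A/T,
#' C/G) cannot be strand-resolved and are dropped by default; a
#' frequency-based rescue keeps them when both sources report an allele
#' frequency far from 0.5 (`|eaf - 0.5| > freq_margin` in both) and the
#' frequencies agree on orientation. Indels are matched on exact allele
#' strings and never strand-flipped.
#'
#' @param base a `summary_stats` data frame.
#' @param target_variants data frame with columns `chrom`, `pos`,
#'   `counted_allele`, `other_allele` (and optionally `variant_id`,
#'   `freq`), e.g. the `variants` table of a [cohort_data()] object.
#' @param drop_palindromic drop strand-ambiguous variants (default TRUE).
#' @param freq_rescue rescue palindromic variants on frequency evidence;
#'   requires `eaf` in `base` and `freq` in `target_variants`.
#' @param freq_margin minimum distance of both frequencies from 0.5 for
#'   rescue (default 0.1).
#' @return list with `sumstats` (aligned `summary_stats`, effect allele
#'   equal to the target counted allele) and `report` (a
#'   `harmonization_report` with counts `n_input`, `n_matched`,
#'   `n_allele_flipped`, `n_strand_flipped`, `n_palindromic_dropped`,
#'   `n_unmatched`).
#' @export
harmonize_sumstats <- function(base, target_variants, drop_palindromic = TRUE,
                               freq_rescue = FALSE, freq_margin = 0.1) {
  stopifnot(inherits(base, "summary_stats"))
  tv <- target_variants
  need <- c("chrom", "pos", "counted_allele", "other_allele")
  miss <- setdiff(need, names(tv))
  if (length(miss)) stop_input("target_variants lacks column(s): %s",
                               paste(miss, collapse = ", "))
  tv$counted_allele <- toupper(tv$counted_allele)
  tv$other_allele <- toupper(tv$other_allele)

  n_input <- nrow(base)
  idx <- match(locus_key(base$chrom, base$pos), locus_key(tv$chrom, tv$pos))
  present <- !is.na(idx)

  ea <- base$effect_allele
  oa <- base$other_allele
  ta <- tv$counted_allele[idx]
  tb <- tv$other_allele[idx]

  same <- present & ea == ta & oa == tb
  swap <- present & ea == tb & oa == ta
  # strand-complement matches, SNVs only (indels never strand-flipped)
  fea <- strand_flip(ea); foa <- strand_flip(oa)
  snv <- is_snv(ea, oa)
  flip_same <- present & snv & !same & !swap & fea == ta & foa == tb
  flip_swap <- present & snv & !same & !swap & fea == tb & foa == ta

  pal <- is_palindromic(ea, oa) & present & (same | swap)
  keep_pal <- rep(FALSE, n_input)
  if (freq_rescue && "freq" %in% names(tv)) {
    tf <- tv$freq[idx]
    bf <- ifelse(swap, 1 - base$eaf, base$eaf)  # base eaf on target counted allele
    keep_pal <- pal & !is.na(base$eaf) & !is.na(tf) &
      abs(base$eaf - 0.5) > freq_margin & abs(tf - 0.5) > freq_margin &
      (bf - 0.5) * (tf - 0.5) > 0
  } else if (!drop_palindromic) {
    keep_pal <- pal
  }
  pal_dropped <- pal & !keep_pal

  matched <- (same | swap | flip_same | flip_swap) & !pal_dropped
  n_unmatched <- sum(!matched & !pal_dropped)
  if (!any(matched) && !any(pal_dropped))
    stop_input("no variants shared between base (%d records) and target (%d variants)",
               n_input, nrow(tv))

  out <- base[matched, , drop = FALSE]
  sw <- (swap | flip_swap)[matched]
  fl <- (flip_same | flip_swap)[matched]
  out$effect_allele <- ta[matched]
  out$other_allele <- tb[matched]
  out$beta <- ifelse(sw, -out$beta, out$beta)
  out$eaf <- ifelse(sw, 1 - out$eaf, out$eaf)
  if ("variant_id" %in% names(tv)) out$variant_id <- tv$variant_id[idx][matched]
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")

  report <- structure(list(
    n_input = n_input,
    n_matched = sum(matched),
    n_allele_flipped = sum(sw),
    n_strand_flipped = sum(fl),
    n_palindromic_dropped = sum(pal_dropped),
    n_unmatched = n_unmatched
  ), class = "harmonization_report")
  list(sumstats = out, report = report)
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("Harmonization report:\n")
  cat(sprintf("  input %d | matched %d (allele-flipped %d, strand-flipped %d)\n",
              x$n_input, x$n_matched, x$n_allele_flipped, x$n_strand_flipped))
  cat(sprintf("  palindromic dropped %d | unmatched %d\n",
              x$n_palindromic_dropped, x$n_unmatched))
  invisible(x)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines two or more allele-aligned summary-statistics sets per variant
#' with inverse-variance weights \eqn{w_k = 1/se_k^2}:
#' \eqn{\beta = \sum w_k \beta_k / \sum w_k}, \eqn{se = (\sum w_k)^{-1/2}},
#' with a two-sided normal p-value and Cochran's Q heterogeneity statistic.
#' Variants present in a single study are passed through with
#' `n_studies = 1` and `flagged = TRUE`. Inputs must already be aligned to
#' a common counted allele (see [harmonize_sumstats()]); a variant whose
#' allele pair conflicts across studies is an error.
#'
#' @param studies list of two or more `summary_stats` data frames.
#' @return a `summary_stats` data frame with extra columns `n_studies`,
#'   `heterogeneity_q` and `flagged`.
#' @export
meta_fixed <- function(studies) {
  if (!is.list(studies) || length(studies) < 2)
    stop_input("meta_fixed requires a list of >= 2 studies")
  lapply(studies, function(s) stopifnot(inherits(s, "summary_stats")))
  all_rows <- do.call(rbind, lapply(seq_along(studies), function(k) {
    s <- as.data.frame(studies[[k]])
    s$study <- k
    s
  }))
  key <- variant_key(all_rows$chrom, all_rows$pos,
                     all_rows$effect_allele, all_rows$other_allele)
  pkey <- pair_key(all_rows$chrom, all_rows$pos,
                   all_rows$effect_allele, all_rows$other_allele)
  conflict <- tapply(key, pkey, function(k) length(unique(k)) > 1)
  if (any(conflict))
    stop_input("allele orientation conflicts across studies at: %s; harmonize first",
               paste(head(names(conflict)[conflict], 5), collapse = ", "))
  groups <- split(seq_len(nrow(all_rows)), key)
  res <- lapply(groups, function(i) {
    r <- all_rows[i, , drop = FALSE]
    w <- 1 / r$se^2
    b <- sum(w * r$beta) / sum(w)
    se <- sqrt(1 / sum(w))
    q <- sum(w * (r$beta - b)^2)
    data.frame(variant_id = r$variant_id[1], chrom = r$chrom[1], pos = r$pos[1],
               effect_allele = r$effect_allele[1], other_allele = r$other_allele[1],
               beta = b, se = se,
               pvalue = 2 * pnorm(-abs(b / se)),
               eaf = if (all(is.na(r$eaf))) NA_real_ else mean(r$eaf, na.rm = TRUE),
               n = if (all(is.na(r$n))) NA_integer_ else sum(r$n, na.rm = TRUE),
               n_studies = nrow(r), heterogeneity_q = q,
               flagged = nrow(r) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  # p of a single passed-through study is kept as reported
  single <- out$n_studies == 1L
  if (any(single)) {
    k <- variant_key(out$chrom, out$pos, out$effect_allele, out$other_allele)[single]
    orig_p <- all_rows$pvalue[match(k, key)]
    out$pvalue[single] <- orig_p
  }
  structure(out, class = c("summary_stats", "data.frame"))
}
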