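#' Construct a cohort (target-data) object
#'
#' The container for individual-level target data: a samples-by-variants
#' dosage matrix (counted-allele copies in `[0, 2]`, `NA` for missing),
#' a variant table, and a sample table with phenotype and covariates.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns;
#'   column names must equal `variants$variant_id`.
#' @param variants data frame with columns `variant_id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele`.
#' @param samples data frame with column `sample_id` and optionally
#'   `phenotype` (1 = case, 0 = control), `sex`, `age`, `PC*`, `ADM*`.
#' @param ancestry_label cohort-level ancestry label.
#' @return a `cohort_data` object (list with elements `dosage`,
#'   `variants`, `samples`, `ancestry_label`).
#' @export
cohort_data <- function(dosage, variants, samples, ancestry_label = "unknown") {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  need <- c("variant_id", "chrom", "pos", "counted_allele", "other_allele")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop_input("variants table lacks column(s): %s",
                               paste(miss, collapse = ", "))
  if (ncol(dosage) != nrow(variants))
    stop_input("dosage has %d columns but variants table has %d rows",
               ncol(dosage), nrow(variants))
  if (nrow(dosage) != nrow(samples))
    stop_input("dosage has %d rows but samples table has %d rows",
               nrow(dosage), nrow(samples))
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop_input("dosage values outside [0, 2]")
  bad <- variants$counted_allele == variants$other_allele
  if (any(bad)) stop_input("counted_allele equals other_allele for %s",
                           paste(head(variants$variant_id[bad], 5), collapse = ", "))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$counted_allele <- toupper(variants$counted_allele)
  variants$other_allele <- toupper(variants$other_allele)
  colnames(dosage) <- variants$variant_id
  rownames(dosage) <- samples$sample_id
  variants$freq <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(dosage = dosage, variants = variants, samples = samples,
                 ancestry_label = ancestry_label),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("cohort_data '%s': %d samples x %d variants\n",
              x$ancestry_label, nrow(x$dosage), ncol(x$dosage)))
  if (!is.null(x$samples$phenotype))
    cat(sprintf("  %d cases / %d controls\n",
                sum(x$samples$phenotype == 1, na.rm = TRUE),
                sum(x$samples$phenotype == 0, na.rm = TRUE)))
  if (!is.null(x$samples$PC1)) cat("  PCs attached\n")
  invisible(x)
}

n_samples <- function(cohort) nrow(cohort$dosage)

#' Read target genotypes
#'
#' Reads genotypes into a [cohort_data()] object from VCF (v4.x; the `DS`
#' FORMAT field is used when present, otherwise `GT` is converted to an
#' alternate-allele count), PLINK 1 binary (`.bed`/`.bim`/`.fam`; the
#' `.bim` A1 allele is the counted allele), or a dosage TSV (samples as
#' rows, header of variant ids, with a sidecar variant table written by
#' [write_dosage()]).
#'
#' @param path file path (`.vcf`, `.bed`, or a dosage `.tsv`).
#' @param format one of `"auto"`, `"vcf"`, `"plink"`, `"dosage"`.
#' @param ancestry_label cohort ancestry label.
#' @return a `cohort_data` object. Phenotypes/covariates are attached
#'   separately with [attach_phenotypes()] (except PLINK `.fam`
#'   phenotypes, which are carried over when coded 1/2).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink", "dosage"),
                           ancestry_label = "unknown") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     vcf = "vcf", bed = "plink", "dosage")
  }
  switch(format,
         vcf = read_vcf_cohort(path, ancestry_label),
         plink = read_plink_cohort(path, ancestry_label),
         dosage = read_dosage(path, ancestry_label = ancestry_label))
}

read_vcf_cohort <- function(path, ancestry_label) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  variants <- data.frame(
    variant_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    counted_allele = toupper(fix[, "ALT"]),
    other_allele = toupper(fix[, "REF"]),
    stringsAsFactors = FALSE
  )
  has_ds <- "DS" %in% unique(unlist(strsplit(fix_format(v), ":")))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- gt_to_dosage(gt)
  }
  # vcfR returns variants x samples
  dosage <- t(ds)
  samples <- data.frame(sample_id = rownames(dosage), stringsAsFactors = FALSE)
  cohort_data(dosage, variants, samples, ancestry_label)
}

fix_format <- function(v) {
  gt <- v@gt
  if (is.null(dim(gt))) gt["FORMAT"] else gt[, "FORMAT"]
}

gt_to_dosage <- function(gt) {
  conv <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a) || length(a) != 2L)
      stop_input("malformed or non-diploid GT record: '%s'", g)
    sum(a > 0)
  }
  u <- unique(as.vector(gt))
  lut <- vapply(u, conv, numeric(1))
  m <- matrix(lut[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

read_plink_cohort <- function(path, ancestry_label) {
  stem <- sub("\\.bed$", "", path)
  bim <- read.table(paste0(stem, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "variant_id", "cm", "pos", "a1", "a2"))
  fam <- read.table(paste0(stem, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  con <- file(paste0(stem, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop_input("%s is not a SNP-major PLINK .bed file", path)
  bytes_per_variant <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_variant * m)
  if (length(raw) < bytes_per_variant * m)
    stop_input("truncated .bed file: %s", path)
  # 2-bit codes per sample: 00 hom A1, 01 missing, 10 het, 11 hom A2
  codes <- matrix(NA_integer_, nrow = 4 * bytes_per_variant, ncol = m)
  rb <- as.integer(raw)
  dim(rb) <- c(bytes_per_variant, m)
  lut <- c(2, NA, 1, 0)  # dosage of A1
  for (shift in 0:3) {
    bits <- bitwAnd(bitwShiftR(rb, 2L * shift), 3L)
    codes[seq(shift + 1, by = 4, length.out = bytes_per_variant), ] <- bits
  }
  dosage <- matrix(lut[codes[seq_len(n), , drop = FALSE] + 1L], nrow = n)
  variants <- data.frame(variant_id = bim$variant_id, chrom = as.character(bim$chrom),
                         pos = as.integer(bim$pos),
                         counted_allele = toupper(bim$a1),
                         other_allele = toupper(bim$a2),
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = fam$iid, stringsAsFactors = FALSE)
  if (any(fam$pheno %in% c(1, 2)))
    samples$phenotype <- ifelse(fam$pheno %in% c(1, 2), fam$pheno - 1, NA)
  cohort_data(dosage, variants, samples, ancestry_label)
}

#' Read/write the dosage-TSV cohort interchange format
#'
#' The dosage TSV has samples as rows, a `sample_id` column and one
#' column per variant id; missing dosages are `NA`. The sidecar
#' `<path>.variants.tsv` carries the variant table.
#'
#' @param path dosage TSV path.
#' @param variants_path sidecar variant-table path (default
#'   `<path>.variants.tsv`).
#' @param ancestry_label cohort ancestry label.
#' @return `read_dosage`: a `cohort_data`; `write_dosage`: `path`,
#'   invisibly.
#' @export
read_dosage <- function(path, variants_path = paste0(path, ".variants.tsv"),
                        ancestry_label = "unknown") {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  variants <- read.table(variants_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = as.character(d$sample_id),
                        stringsAsFactors = FALSE)
  dosage <- as.matrix(d[, setdiff(names(d), "sample_id"), drop = FALSE])
  cohort_data(dosage, variants[, c("variant_id", "chrom", "pos",
                                   "counted_allele", "other_allele")],
              samples, ancestry_label)
}

#' @rdname read_dosage
#' @param cohort a `cohort_data` object.
#' @export
write_dosage <- function(cohort, path,
                         variants_path = paste0(path, ".variants.tsv")) {
  d <- data.frame(sample_id = cohort$samples$sample_id,
                  cohort$dosage, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$variants, variants_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a cohort as a minimal VCF
#'
#' Genotypes are emitted as `GT` (rounded dosage) plus a `DS` field with
#' the exact dosage; the counted allele is written as ALT.
#'
#' @param cohort a `cohort_data` object.
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", cohort$samples$sample_id),
                   collapse = "\t"), con)
  v <- cohort$variants
  for (j in seq_len(nrow(v))) {
    ds <- cohort$dosage[, j]
    gt <- ifelse(is.na(ds), "./.",
                 c("0/0", "0/1", "1/1")[pmin(pmax(round(ds), 0), 2) + 1])
    field <- ifelse(is.na(ds), "./.",
                    paste0(gt, ":", formatC(ds, format = "g", digits = 6)))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$other_allele[j],
                       v$counted_allele[j], ".", ".", ".", "GT:DS", field),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Attach phenotypes and covariates to a cohort
#'
#' @param cohort a `cohort_data` object.
#' @param pheno data frame or TSV path keyed by `sample_id` with columns
#'   `PHENO` (1 = case, 0 = control), `SEX`, `AGE` and optional `PC*` /
#'   `ADM*` covariate columns.
#' @return the cohort with its `samples` table augmented.
#' @export
attach_phenotypes <- function(cohort, pheno) {
  if (is.character(pheno))
    pheno <- read.table(pheno, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(pheno))
    stop_input("phenotype table lacks a sample_id column")
  i <- match(cohort$samples$sample_id, pheno$sample_id)
  if (anyNA(i))
    stop_input("phenotype table missing %d cohort sample(s)", sum(is.na(i)))
  ph <- pheno[i, , drop = FALSE]
  ren <- c(PHENO = "phenotype", SEX = "sex", AGE = "age")
  names(ph)[names(ph) %in% names(ren)] <- ren[names(ph)[names(ph) %in% names(ren)]]
  cohort$samples <- cbind(cohort$samples["sample_id"],
                          ph[, setdiff(names(ph), "sample_id"), drop = FALSE])
  cohort
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts (Wigginton, Cutler & Abecasis
#' 2005): the p-value sums, over all heterozygote counts compatible with
#' the observed allele counts, the probabilities no larger than that of
#' the observed table.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (hom for allele 1, het,
#'   hom for allele 2).
#' @return the exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) return(1)
  n_a <- 2 * n_hom1 + n_het          # copies of allele 1
  rare <- min(n_a, 2 * n - n_a)
  het_possible <- seq(rare %% 2, rare, by = 2)
  # log P(n_het = h | allele counts) up to a constant
  lp <- vapply(het_possible, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- which(het_possible == n_het)
  if (!length(obs)) stop_input("genotype counts inconsistent with allele counts")
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Quality-control filter for a cohort
#'
#' Applies, in a fixed order, variant filters (call rate, minor-allele
#' frequency, Hardy-Weinberg exact test) followed by the sample
#' call-rate filter. The HWE exact test is computed on controls only
#' (when phenotypes are attached), since true disease association
#' distorts case genotype frequencies; dosages are rounded to the
#' nearest genotype for the test.
#'
#' @param cohort a `cohort_data` object.
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param hwe_alpha HWE exact-test significance cutoff (default 1e-4);
#'   variants with p below it are removed.
#' @param var_call_min minimum variant call rate (default 0.98).
#' @param sample_call_min minimum sample call rate (default 0.98),
#'   applied after the variant filters.
#' @return list with the filtered `cohort` and a `report` (class
#'   `qc_report`) counting removals per filter.
#' @export
qc_filter <- function(cohort, maf_min = 0.05, hwe_alpha = 1e-4,
                      var_call_min = 0.98, sample_call_min = 0.98) {
  stopifnot(maf_min >= 0, maf_min <= 1, hwe_alpha >= 0, hwe_alpha <= 1,
            var_call_min >= 0, var_call_min <= 1,
            sample_call_min >= 0, sample_call_min <= 1)
  d <- cohort$dosage
  n_in <- ncol(d)

  callrate <- colMeans(!is.na(d))
  keep_call <- callrate >= var_call_min
  n_removed_callrate <- sum(!keep_call)

  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep_maf <- keep_call & maf >= maf_min
  n_removed_maf <- sum(keep_call & !(maf >= maf_min))

  is_control <- if (!is.null(cohort$samples$phenotype))
    cohort$samples$phenotype == 0 else rep(TRUE, nrow(d))
  if (!any(is_control)) is_control <- rep(TRUE, nrow(d))
  keep_hwe <- keep_maf
  n_removed_hwe <- 0L
  if (hwe_alpha > 0) {
    for (j in which(keep_maf)) {
      g <- round(d[is_control, j])
      g <- g[!is.na(g)]
      pv <- hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
      if (pv < hwe_alpha) {
        keep_hwe[j] <- FALSE
        n_removed_hwe <- n_removed_hwe + 1L
      }
    }
  }
  if (!any(keep_hwe)) stop_input("all variants removed by QC")

  d2 <- d[, keep_hwe, drop = FALSE]
  sample_call <- rowMeans(!is.na(d2))
  keep_samples <- sample_call >= sample_call_min
  n_samples_removed <- sum(!keep_samples)

  out <- cohort
  out$dosage <- d2[keep_samples, , drop = FALSE]
  out$variants <- cohort$variants[keep_hwe, , drop = FALSE]
  out$variants$freq <- colMeans(out$dosage, na.rm = TRUE) / 2
  out$samples <- cohort$samples[keep_samples, , drop = FALSE]
  report <- structure(list(
    n_variants_in = n_in,
    n_removed_callrate = n_removed_callrate,
    n_removed_maf = n_removed_maf,
    n_removed_hwe = n_removed_hwe,
    n_samples_removed_callrate = n_samples_removed
  ), class = "qc_report")
  list(cohort = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC: %d variants in; removed %d (call rate), %d (MAF), %d (HWE); %d samples removed\n",
    x$n_variants_in, x$n_removed_callrate, x$n_removed_maf, x$n_removed_hwe,
    x$n_samples_removed_callrate))
  invisible(x)
}

#' Principal components of the genotype matrix
#'
#' Missing dosages are mean-imputed, columns centered on twice the
#' counted-allele frequency and scaled by `sqrt(2 f (1 - f))`, and the
#' PCs taken as left singular vectors scaled by their singular values.
#' Constant variant columns are dropped with a warning. Each component's
#' sign is fixed so its largest-magnitude variant loading is positive,
#' making the result reproducible across sample orderings.
#'
#' @param cohort a `cohort_data` object.
#' @param n_pcs number of components (default 10); `0` removes any
#'   attached PCs and returns the cohort otherwise unchanged.
#' @return the cohort with `PC1..PCn` columns in its `samples` table and
#'   the loadings stored in attribute `pc_loadings`.
#' @export
compute_pcs <- function(cohort, n_pcs = 10) {
  old <- grep("^PC[0-9]+$", names(cohort$samples))
  if (length(old)) cohort$samples <- cohort$samples[, -old, drop = FALSE]
  if (n_pcs == 0) return(cohort)
  d <- cohort$dosage
  if (nrow(d) < n_pcs + 1)
    stop_input("need at least n_pcs + 1 = %d samples, have %d", n_pcs + 1, nrow(d))
  mu <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mu[j]
  f <- mu / 2
  keep <- f > 0 & f < 1 & apply(d, 2, sd) > 0
  if (!all(keep)) warning(sprintf("dropping %d constant variant column(s) before PCA",
                                  sum(!keep)))
  d <- d[, keep, drop = FALSE]
  x <- sweep(d, 2, mu[keep]) / rep(sqrt(2 * f[keep] * (1 - f[keep])),
                                   each = nrow(d))
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  pcs <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  load <- sv$v
  for (k in seq_len(n_pcs)) {
    s <- sign(load[which.max(abs(load[, k])), k])
    if (s < 0) { pcs[, k] <- -pcs[, k]; load[, k] <- -load[, k] }
  }
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  cohort$samples <- cbind(cohort$samples, as.data.frame(pcs))
  attr(cohort, "pc_loadings") <- load
  cohort
}
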