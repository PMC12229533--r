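#' Pipeline run configuration
#'
#' A plain-text `key = value` configuration (or an equivalent named
#' list) describing one end-to-end run: base summary statistics (one or
#' many, ancestry-labelled), a target cohort, an optional fixed panel,
#' model selection and evaluation settings.
#'
#' Recognized keys: `base.<LABEL>` (path to a summary-statistics file,
#' repeatable), `genotypes` (VCF/PLINK/dosage path), `phenotypes`
#' (TSV path), `panel` (panel file, required for the fixed model),
#' `model` (`fixed`, `ct` or `both`), `covariate_set` (`pcs`,
#' `admixture` or `both`), `prevalence`, `thresholds`
#' (comma-separated), `clump_window_kb`, `clump_r2`, `n_pcs`,
#' `maf_min`, `hwe_alpha`, `var_call_min`, `sample_call_min`,
#' `meta` (`true` to meta-analyze the base sets for the C+T model),
#' `seed`, `out_dir`.
#'
#' @param x path to a configuration file or a named list.
#' @return a validated `run_config` list.
#' @export
run_config <- function(x) {
  if (is.character(x)) {
    lines <- readLines(x)
    lines <- sub("#.*", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
    bad <- vapply(kv, length, 1L) != 3
    if (any(bad)) stop_input("malformed config line(s): %s",
                             paste(lines[bad], collapse = "; "))
    x <- setNames(lapply(kv, function(p) trimws(p[3])),
                  vapply(kv, function(p) trimws(p[2]), ""))
  }
  stopifnot(is.list(x))
  base_keys <- grep("^base\\.", names(x), value = TRUE)
  if (!length(base_keys)) stop_input("config needs at least one base.<LABEL> entry")
  cfg <- list(
    base = setNames(unlist(x[base_keys]), sub("^base\\.", "", base_keys)),
    genotypes = x$genotypes %||% stop_input("config needs 'genotypes'"),
    phenotypes = x$phenotypes,
    panel = x$panel,
    model = match.arg(x$model %||% "both", c("both", "fixed", "ct")),
    covariate_set = match.arg(x$covariate_set %||% "pcs",
                              c("pcs", "admixture", "both")),
    prevalence = as.numeric(x$prevalence %||% 0.005),
    thresholds = if (is.null(x$thresholds)) 5 * 10^seq(-8, -2)
                 else as.numeric(strsplit(x$thresholds, ",")[[1]]),
    clump_window_kb = as.numeric(x$clump_window_kb %||% 250),
    clump_r2 = as.numeric(x$clump_r2 %||% 0.1),
    n_pcs = as.integer(x$n_pcs %||% 10),
    maf_min = as.numeric(x$maf_min %||% 0.05),
    hwe_alpha = as.numeric(x$hwe_alpha %||% 1e-4),
    var_call_min = as.numeric(x$var_call_min %||% 0.98),
    sample_call_min = as.numeric(x$sample_call_min %||% 0.98),
    meta = isTRUE(as.logical(x$meta %||% TRUE)),
    seed = as.integer(x$seed %||% 1),
    out_dir = x$out_dir %||% "prsbench_out"
  )
  if (any(diff(sort(cfg$thresholds)) <= 0)) stop_input("duplicate thresholds")
  for (p in c(cfg$base, cfg$genotypes, cfg$phenotypes, cfg$panel)) {
    if (!is.null(p) && !file.exists(p)) stop_input("input not found: %s", p)
  }
  if (cfg$model %in% c("both", "fixed") && is.null(cfg$panel))
    stop_input("fixed model requested but no 'panel' configured")
  structure(cfg, class = "run_config")
}

#' Run the PRS benchmarking pipeline end-to-end
#'
#' Executes harmonize -> (optional meta-analysis) -> QC -> PCs ->
#' score/fit -> evaluate -> compare, writing evaluation reports, the
#' C+T grid, the variant-effect table, the pairwise comparison matrix,
#' and a JSON manifest (inputs with MD5 hashes, seed, package version,
#' artifact list) under `cfg$out_dir`. Deterministic given `cfg$seed`.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  artifacts <- character(0)
  note <- function(path) { artifacts <<- c(artifacts, path); path }

  cohort <- stage("read-target", {
    co <- read_genotypes(cfg$genotypes)
    if (!is.null(cfg$phenotypes)) co <- attach_phenotypes(co, cfg$phenotypes)
    co
  })
  bases <- stage("read-base", lapply(cfg$base, read_sumstats))
  for (i in seq_along(bases)) attr(bases[[i]], "label") <- names(cfg$base)[i]

  qc <- stage("qc", qc_filter(cohort, cfg$maf_min, cfg$hwe_alpha,
                              cfg$var_call_min, cfg$sample_call_min))
  cohort <- qc$cohort
  cohort <- stage("pcs", compute_pcs(cohort, cfg$n_pcs))

  harm <- stage("harmonize", lapply(bases, function(b) {
    h <- harmonize_sumstats(b, cohort$variants)
    attr(h$sumstats, "label") <- attr(b, "label")
    h
  }))

  covsets <- if (cfg$covariate_set == "both") c("pcs", "admixture")
             else cfg$covariate_set
  reports <- list()
  scores <- list()

  if (cfg$model %in% c("both", "fixed")) {
    panel <- stage("panel", read_panel(cfg$panel))
    for (h in harm) {
      lab <- attr(h$sumstats, "label")
      prs <- stage(paste0("score-fixed-", lab),
                   score_fixed_panel(cohort, h$sumstats, panel))
      ve <- stage(paste0("variant-effects-", lab),
                  variant_effects(cohort, h$sumstats, panel))
      write.table(ve, note(file.path(cfg$out_dir,
                                     paste0("variant_effects_", lab, ".tsv"))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      for (cs in covsets) {
        rep <- stage(paste0("evaluate-fixed-", lab, "-", cs),
                     evaluate_prs(cohort, prs, cs, cfg$prevalence))
        reports[[paste("fixed", lab, cs, sep = ".")]] <- rep
        if (cs == covsets[1]) scores[[paste0("fixed_", lab)]] <- rep$scores
      }
    }
  }

  if (cfg$model %in% c("both", "ct")) {
    ct_base <- if (cfg$meta && length(harm) > 1) {
      stage("meta", {
        mb <- meta_fixed(lapply(harm, `[[`, "sumstats"))
        write_sumstats(mb, note(file.path(cfg$out_dir, "meta_base.tsv")))
        attr(mb, "label") <- "meta"
        mb
      })
    } else {
      harm[[1]]$sumstats
    }
    for (cs in covsets) {
      ct <- stage(paste0("fit-ct-", cs),
                  fit_ct(cohort, ct_base, cfg$thresholds,
                         clump_params(cfg$clump_window_kb, cfg$clump_r2),
                         cs, cfg$prevalence))
      if (cs == covsets[1]) {
        write_ct_grid(ct, note(file.path(cfg$out_dir, "ct_grid.tsv")))
        writeLines(ct$index_variants,
                   note(file.path(cfg$out_dir, "ct_index_variants.txt")))
      }
      rep <- stage(paste0("evaluate-ct-", cs),
                   evaluate_prs(cohort, ct$prs, cs, cfg$prevalence))
      reports[[paste("ct", attr(ct_base, "label") %||% "base", cs, sep = ".")]] <- rep
      if (cs == covsets[1]) scores[["ct"]] <- rep$scores
    }
  }

  write_eval_reports(reports, note(file.path(cfg$out_dir, "eval_reports.tsv")))
  if (length(scores) >= 2) {
    cmp <- stage("compare",
                 comparison_matrix(scores, cohort$samples$phenotype,
                                   target = cohort$ancestry_label))
    write.table(cmp, note(file.path(cfg$out_dir, "comparison_matrix.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  inputs <- c(cfg$base, genotypes = cfg$genotypes,
              phenotypes = cfg$phenotypes, panel = cfg$panel)
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  manifest <- list(
    package = "prsbench",
    version = as.character(utils::packageVersion("prsbench")),
    seed = cfg$seed,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    artifacts = artifacts,
    models = names(reports)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
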