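covariate_matrix <- function(cohort, covariate_set = c("pcs", "admixture")) {
  covariate_set <- match.arg(covariate_set)
  s <- cohort$samples
  base_cols <- intersect(c("sex", "age"), names(s))
  if (covariate_set == "pcs") {
    cols <- grep("^PC[0-9]+$", names(s), value = TRUE)
    if (!length(cols))
      stop_input("no PC columns attached; run compute_pcs() first")
  } else {
    cols <- grep("^ADM[0-9]+$", names(s), value = TRUE)
    if (!length(cols))
      stop_input("no admixture columns (ADM*) attached")
    cols <- cols[-length(cols)]  # drop one simplex component (collinearity)
  }
  X <- as.matrix(s[, c(base_cols, cols), drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Logistic association of a standardized PRS with disease
#'
#' Maximum-likelihood logistic regression of case status on the
#' z-scored PRS, adjusted by sex, age and either principal components
#' (`PC*` columns) or ancestral admixture proportions (`ADM*` columns,
#' one simplex component dropped to avoid collinearity). The odds ratio
#' per score standard deviation is `exp(coefficient)` with a 95% Wald
#' interval.
#'
#' @param cohort a [cohort_data()] with phenotype and covariates.
#' @param prs a `prs_result` (or any data frame with `sample_id` and
#'   `z_score`).
#' @param covariate_set `"pcs"` or `"admixture"`.
#' @return list with `coefficient`, `se`, `or_per_sd`, `or_ci`,
#'   `pvalue`, `fitted` (per-sample disease probabilities from the full
#'   model) and `model` (the `glm` fit).
#' @export
fit_association <- function(cohort, prs, covariate_set = c("pcs", "admixture")) {
  covariate_set <- match.arg(covariate_set)
  y <- cohort$samples$phenotype
  if (is.null(y) || length(unique(y[!is.na(y)])) < 2)
    stop_input("phenotype with both classes required")
  i <- match(cohort$samples$sample_id, prs$sample_id)
  if (anyNA(i)) stop_input("PRS missing for %d cohort sample(s)", sum(is.na(i)))
  X <- covariate_matrix(cohort, covariate_set)
  dat <- data.frame(y = y, prs = prs$z_score[i], X)
  fit <- glm(y ~ ., data = dat, family = binomial())
  cf <- coef(fit)["prs"]
  se <- sqrt(vcov(fit)["prs", "prs"])
  if (!fit$converged || abs(cf) > 15)
    stop_input(paste0("(quasi-)separation detected (|coefficient| = %.2f); ",
                      "refit with a penalized model"), abs(cf))
  ci <- cf + c(-1, 1) * qnorm(0.975) * se
  list(coefficient = unname(cf), se = unname(se),
       or_per_sd = exp(unname(cf)), or_ci = exp(unname(ci)),
       pvalue = 2 * pnorm(-abs(unname(cf) / unname(se))),
       fitted = unname(fit$fitted.values), model = fit,
       covariate_set = covariate_set)
}

#' ROC curve, AUC and DeLong variance
#'
#' The AUC is the two-sample concordance probability: the mean over
#' case-control pairs of 1 (case score higher), 1/2 (tie), 0
#' (lower), computed via mid-ranks. Its variance follows DeLong's
#' structural components (per-case and per-control placement values).
#'
#' @param scores per-sample scores or fitted probabilities.
#' @param labels binary labels (1 = case).
#' @return a `roc_result`: list with `auc`, `var_auc` (DeLong),
#'   `auc_se`, `curve` (data frame `threshold`, `fpr`, `tpr`), and the
#'   structural components `v_case`, `v_control`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2)
    stop_input("both classes required to form an ROC curve")
  case <- labels == 1
  x <- scores[case]; yv <- scores[!case]
  n1 <- length(x); n0 <- length(yv)
  r <- rank(c(x, yv), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # placement values: V10_i = P(X_i > Y) + 0.5 P(X_i = Y), via ranks
  rx_within <- rank(x, ties.method = "average")
  v_case <- (r[seq_len(n1)] - rx_within) / n0
  ry_within <- rank(yv, ties.method = "average")
  v_control <- 1 - (r[n1 + seq_len(n0)] - ry_within) / n1
  var_auc <- var(v_case) / n1 + var(v_control) / n0
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(x >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(yv >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(auc = auc, var_auc = var_auc, auc_se = sqrt(var_auc),
                 curve = curve, v_case = v_case, v_control = v_control),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (DeLong SE %.4f), %d ROC points\n",
              x$auc, x$auc_se, nrow(x$curve)))
  invisible(x)
}

#' Top-leftmost ROC operating point
#'
#' Selects the threshold minimizing the Euclidean distance of
#' (FPR, TPR) to the perfect classifier (0, 1); ties are broken toward
#' higher sensitivity. Accuracy at that threshold carries an exact
#' Clopper-Pearson 95% interval.
#'
#' @param roc a `roc_result` from [roc_auc()], computed with the
#'   original scores retained, or a list with `curve`; to obtain
#'   accuracy the underlying scores and labels must be re-supplied.
#' @param scores,labels the vectors the ROC was computed from.
#' @return list with `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `accuracy_ci`, `balanced_accuracy`.
#' @export
operating_point <- function(roc, scores, labels) {
  cv <- roc$curve
  if (!nrow(cv)) stop_input("empty ROC curve")
  d2 <- cv$fpr^2 + (1 - cv$tpr)^2
  best <- which(d2 == min(d2))
  if (length(best) > 1) best <- best[which.max(cv$tpr[best])]
  thr <- cv$threshold[best]
  sens <- cv$tpr[best]
  spec <- 1 - cv$fpr[best]
  pred <- scores >= thr
  correct <- sum(pred == (labels == 1))
  ci <- binom.test(correct, length(labels))$conf.int
  list(threshold = thr, sensitivity = sens, specificity = spec,
       accuracy = correct / length(labels),
       accuracy_ci = c(ci[1], ci[2]),
       balanced_accuracy = (sens + spec) / 2)
}

#' DeLong test for two correlated AUCs
#'
#' Pairs two score vectors over the same samples and labels; the
#' difference in AUCs is tested with the paired DeLong variance
#' `var_a + var_b - 2 cov_ab` from the structural components.
#'
#' @param scores_a,scores_b per-sample scores on identical samples.
#' @param labels binary labels (1 = case).
#' @return a `delong_result`: list with `auc_a`, `auc_b`, `delta`
#'   (`auc_a - auc_b`), `var_a`, `var_b`, `cov_ab`, `z`, `pvalue`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop_input("scores_a, scores_b and labels must cover the same samples")
  ra <- roc_auc(scores_a, labels)
  rb <- roc_auc(scores_b, labels)
  n1 <- length(ra$v_case); n0 <- length(ra$v_control)
  cov_ab <- cov(ra$v_case, rb$v_case) / n1 +
    cov(ra$v_control, rb$v_control) / n0
  v <- ra$var_auc + rb$var_auc - 2 * cov_ab
  delta <- ra$auc - rb$auc
  if (v <= 0) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(v)
    p <- min(2 * pnorm(-abs(z)), 1)
  }
  structure(list(auc_a = ra$auc, auc_b = rb$auc, delta = delta,
                 var_a = ra$var_auc, var_b = rb$var_auc, cov_ab = cov_ab,
                 z = z, pvalue = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.4f vs %.4f (delta %+.4f), z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$delta, x$z, x$pvalue))
  invisible(x)
}

#' Pairwise DeLong comparison matrix
#'
#' All model pairs on one cohort, long format, plot-ready.
#'
#' @param scores named list of per-sample score (or probability)
#'   vectors on identical samples.
#' @param labels binary labels (1 = case).
#' @param target label of the target cohort for the output table.
#' @param alpha significance flag level (default 0.05; raw p-values,
#'   no multiplicity correction).
#' @return data frame with one row per unordered model pair: `target`,
#'   `model_a`, `model_b`, `auc_a`, `auc_b`, `delta_auc`, `z`, `pvalue`,
#'   `significant`.
#' @export
comparison_matrix <- function(scores, labels, target = "cohort", alpha = 0.05) {
  stopifnot(is.list(scores), length(scores) >= 2, !is.null(names(scores)))
  nm <- names(scores)
  pairs <- utils::combn(nm, 2)
  rows <- apply(pairs, 2, function(p) {
    d <- delong_compare(scores[[p[1]]], scores[[p[2]]], labels)
    data.frame(target = target, model_a = p[1], model_b = p[2],
               auc_a = d$auc_a, auc_b = d$auc_b, delta_auc = d$delta,
               z = d$z, pvalue = d$pvalue,
               significant = d$pvalue < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full evaluation report for one PRS model on one cohort
#'
#' Bundles the association fit, discrimination and operating-point
#' metrics for one model: logistic association (OR per SD with 95% CI),
#' AUC with DeLong SE computed on the full-model fitted probabilities
#' (set `use_fitted = FALSE` for the raw PRS ROC), and the
#' top-leftmost operating point (accuracy with exact 95% CI, balanced
#' accuracy, sensitivity, specificity).
#'
#' @inheritParams fit_association
#' @param prevalence population prevalence for the liability-scale R^2
#'   entries, or `NULL` to omit.
#' @param use_fitted compute the ROC on fitted probabilities of the
#'   covariate-adjusted model (default) rather than the raw PRS.
#' @return an `eval_report` list; see fields in the description.
#' @export
evaluate_prs <- function(cohort, prs, covariate_set = c("pcs", "admixture"),
                         prevalence = NULL, use_fitted = TRUE) {
  covariate_set <- match.arg(covariate_set)
  assoc <- fit_association(cohort, prs, covariate_set)
  y <- cohort$samples$phenotype
  sc <- if (use_fitted) assoc$fitted else {
    i <- match(cohort$samples$sample_id, prs$sample_id)
    prs$z_score[i]
  }
  roc <- roc_auc(sc, y)
  op <- operating_point(roc, sc, y)
  structure(list(
    auc = roc$auc, auc_se = roc$auc_se,
    or_per_sd = assoc$or_per_sd, or_ci = assoc$or_ci,
    coefficient = assoc$coefficient, se = assoc$se, pvalue = assoc$pvalue,
    operating_threshold = op$threshold,
    accuracy = op$accuracy, accuracy_ci = op$accuracy_ci,
    balanced_accuracy = op$balanced_accuracy,
    sensitivity = op$sensitivity, specificity = op$specificity,
    covariate_set = covariate_set,
    scores = sc,
    n_valid_predictors = attr(prs, "n_valid_predictors"),
    base_label = attr(prs, "base_label") %||% "base",
    target_label = cohort$ancestry_label), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s on %s, %s covariates]\n", x$base_label,
              x$target_label, x$covariate_set))
  cat(sprintf("  AUC %.3f | OR/SD %.2f (%.2f-%.2f) | acc %.3f (%.3f-%.3f)\n",
              x$auc, x$or_per_sd, x$or_ci[1], x$or_ci[2],
              x$accuracy, x$accuracy_ci[1], x$accuracy_ci[2]))
  cat(sprintf("  balanced %.3f | sens %.3f | spec %.3f\n",
              x$balanced_accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' @rdname evaluate_prs
#' @param reports list of `eval_report`s.
#' @param path output TSV path.
#' @export
write_eval_reports <- function(reports, path) {
  rows <- lapply(reports, function(r)
    data.frame(target = r$target_label, base = r$base_label,
               covariates = r$covariate_set, n_predictors =
                 r$n_valid_predictors %||% NA,
               auc = r$auc, auc_se = r$auc_se,
               or_per_sd = r$or_per_sd, or_low = r$or_ci[1],
               or_high = r$or_ci[2], coefficient = r$coefficient,
               se = r$se, pvalue = r$pvalue,
               accuracy = r$accuracy, acc_low = r$accuracy_ci[1],
               acc_high = r$accuracy_ci[2],
               balanced_accuracy = r$balanced_accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
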