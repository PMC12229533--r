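#' Specification for polygenic-score power calculations
#'
#' Parameters of the two-stage design analyzed by the Dudbridge (2013)
#' polygenic-score power methodology: per-marker effects are estimated
#' as log odds ratios in a case-control training sample and the
#' resulting score is tested for association with case status in an
#' independent target sample of the same size (the equal-split
#' convention).
#'
#' @param n_markers number of markers in the score.
#' @param h2 liability-scale variance explained by the score's markers.
#' @param prevalence population disease prevalence K.
#' @param case_fraction_train,case_fraction_target case proportion in
#'   the training and target samples (default 0.5, i.e. 1:1
#'   case-control ascertainment in both).
#' @param alpha significance level of the association test.
#' @param target_power power to achieve in [min_sample_size()].
#' @param null_fraction fraction of markers contributing no effect; the
#'   score's effective explained variance is `h2 * (1 - null_fraction)`
#'   while all markers contribute estimation noise.
#' @return a `power_spec` list.
#' @export
power_spec <- function(n_markers, h2, prevalence,
                       case_fraction_train = 0.5,
                       case_fraction_target = 0.5,
                       alpha = 0.05, target_power = 0.8,
                       null_fraction = 0) {
  stopifnot(n_markers >= 1, h2 >= 0, h2 < 1,
            prevalence > 0, prevalence < 1,
            case_fraction_train > 0, case_fraction_train < 1,
            case_fraction_target > 0, case_fraction_target < 1,
            alpha > 0, alpha < 1, target_power > 0, target_power < 1,
            null_fraction >= 0, null_fraction < 1)
  structure(list(n_markers = n_markers, h2 = h2, prevalence = prevalence,
                 case_fraction_train = case_fraction_train,
                 case_fraction_target = case_fraction_target,
                 alpha = alpha, target_power = target_power,
                 null_fraction = null_fraction),
            class = "power_spec")
}

# truncated-normal moments of liability above/below the threshold
liability_moments <- function(K) {
  t <- qnorm(1 - K); z <- dnorm(t)
  i_case <- z / K                 # mean liability of cases
  i_ctrl <- -z / (1 - K)          # mean liability of controls
  v_case <- 1 - i_case * (i_case - t)
  v_ctrl <- 1 + t * i_ctrl - i_ctrl^2
  list(t = t, z = z, i_case = i_case, i_ctrl = i_ctrl,
       delta = i_case - i_ctrl, v_case = v_case, v_ctrl = v_ctrl)
}

#' Power of the PRS-disease association test
#'
#' Computes the expected squared correlation between the estimated score
#' and case status in the target sample under the liability-threshold
#' model, then the power of the 1-df association test with
#' non-centrality `n * rho^2 / (1 - rho^2)`.
#'
#' The score's weights are per-marker log odds ratios estimated in the
#' training sample: for a marker explaining liability variance `b^2`,
#' the log OR per standardized dosage is `b * delta` with
#' `delta = z / (K (1 - K))` the case-control difference in mean
#' liability, and its sampling variance is `1 / (n P1 (1 - P1))`. The
#' score-phenotype correlation in the ascertained target sample uses
#' the truncated-liability case/control means and variances, so the
#' observed-scale R^2 reflects both the between-group separation and
#' the within-group variance of the score.
#'
#' @param spec a [power_spec()].
#' @param n_total sample size of the training sample and of the target
#'   sample (each; the equal-split convention).
#' @return power in `[alpha, 1)`; exactly `alpha` when `h2 = 0`.
#' @export
prs_association_power <- function(spec, n_total) {
  stopifnot(inherits(spec, "power_spec"), n_total >= 2)
  vg <- spec$h2 * (1 - spec$null_fraction)
  if (vg == 0) return(spec$alpha)
  m1 <- liability_moments(spec$prevalence)
  P1 <- spec$case_fraction_train
  P2 <- spec$case_fraction_target

  # training: weights w_j = beta_j * delta + e_j on the log-OR scale
  signal <- vg * m1$delta^2
  noise <- spec$n_markers / (n_total * P1 * (1 - P1))
  # correlation of the estimated score with liability
  r2_liab <- signal / (signal + noise) * vg
  r <- sqrt(r2_liab)

  # target: ascertained case-control mixture of the standardized score
  mu_case <- r * m1$i_case
  mu_ctrl <- r * m1$i_ctrl
  v_case <- 1 - r^2 * (1 - m1$v_case)
  v_ctrl <- 1 - r^2 * (1 - m1$v_ctrl)
  v_mix <- P2 * v_case + (1 - P2) * v_ctrl +
    P2 * (1 - P2) * (mu_case - mu_ctrl)^2
  r2_obs <- P2 * (1 - P2) * (mu_case - mu_ctrl)^2 / v_mix

  ncp <- n_total * r2_obs / (1 - r2_obs)
  pchisq(qchisq(1 - spec$alpha, df = 1), df = 1, ncp = ncp,
         lower.tail = FALSE)
}

#' Minimum sample size for a target power
#'
#' Smallest total sample size (training and target samples each of this
#' size) whose [prs_association_power()] meets `spec$target_power`, by
#' bisection followed by a +/-5 linear scan. Monotonicity of power in n
#' is verified at the bracket ends.
#'
#' @param spec a [power_spec()].
#' @param n_max search ceiling (default 1e8).
#' @return integer sample size.
#' @export
min_sample_size <- function(spec, n_max = 1e8) {
  stopifnot(inherits(spec, "power_spec"))
  lo <- 2
  if (prs_association_power(spec, lo) >= spec$target_power) return(lo)
  hi <- 4
  while (prs_association_power(spec, hi) < spec$target_power) {
    hi <- hi * 2
    if (hi > n_max)
      stop_input("target power %.2f unreachable below n = %g",
                 spec$target_power, n_max)
  }
  if (prs_association_power(spec, hi) < prs_association_power(spec, lo))
    stop_input("power is not monotone on the search bracket")
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (prs_association_power(spec, mid) >= spec$target_power) hi <- mid
    else lo <- mid
  }
  # defensive linear scan around the bisection answer
  for (n in seq(max(2, hi - 5), hi + 5)) {
    if (prs_association_power(spec, n) >= spec$target_power) return(as.integer(n))
  }
  as.integer(hi)
}
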