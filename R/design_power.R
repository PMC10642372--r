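# sample-size and power arithmetic for the 1:M matched case-control design

#' Weighted expected prevalence
#'
#' Mixes class-conditional prevalences by class weights: with weights
#' (w1, w2) over adenoma morphology classes and conditional prevalences
#' (p1, p2) of the molecular feature, the expected marginal prevalence is
#' w1 p1 + w2 p2.
#'
#' @param weights numeric pair summing to 1 (tolerance 1e-9).
#' @param prevalences numeric pair of conditional prevalences in [0, 1].
#' @return the weighted prevalence.
#' @examples
#' expected_prevalence(c(0.48, 0.52), c(0.25, 0.03))  # 0.136
#' @export
expected_prevalence <- function(weights, prevalences) {
  stopifnot(length(weights) == 2L, length(prevalences) == 2L)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1", call. = FALSE)
  }
  .assert_prob(prevalences, "prevalences")
  sum(weights * prevalences)
}

#' Shift two prevalences to a target odds ratio
#'
#' Starting from null-hypothesis prevalences in cases and controls, shifts
#' the case prevalence up and the control prevalence down until their odds
#' ratio equals \code{target_or}, while preserving either the arithmetic
#' mean of the two (default) or the size-weighted mean of a 1:M design.
#' Solved by root-finding on the case prevalence (the log odds ratio is
#' strictly monotone along the constraint line).
#'
#' @param p_case0,p_ctrl0 null prevalences in (0, 1).
#' @param target_or target odds ratio (> 0).
#' @param constraint \code{"preserve_arithmetic_mean"} (default) or
#'   \code{"preserve_weighted_mean"} (weights 1 : M).
#' @param M controls per case, used by the weighted-mean constraint.
#' @return named numeric \code{c(p_case, p_ctrl)} satisfying the odds-ratio
#'   and mean constraints to 1e-10.
#' @examples
#' shift_to_target_or(0.167, 0.131, 3)  # approx (0.215, 0.083)
#' @export
shift_to_target_or <- function(p_case0, p_ctrl0, target_or,
                               constraint = c("preserve_arithmetic_mean",
                                              "preserve_weighted_mean"),
                               M = 2) {
  constraint <- match.arg(constraint)
  for (p in c(p_case0, p_ctrl0)) {
    if (!(p > 0 && p < 1)) stop("prevalences must lie in (0, 1)",
                                call. = FALSE)
  }
  if (target_or <= 0) stop("target_or must be > 0", call. = FALSE)
  # constraint line: p_ctrl = a - b * p_case
  if (constraint == "preserve_arithmetic_mean") {
    a <- p_case0 + p_ctrl0
    b <- 1
  } else {
    mbar <- (p_case0 + M * p_ctrl0) / (1 + M)
    a <- (1 + M) * mbar / M
    b <- 1 / M
  }
  odds <- function(p) p / (1 - p)
  f <- function(p1) {
    p2 <- a - b * p1
    log(odds(p1)) - log(odds(p2)) - log(target_or)
  }
  eps <- 1e-12
  lo <- max(eps, (a - 1) / b + eps)
  hi <- min(1 - eps, a / b - eps)
  if (!(lo < hi) || f(lo) > 0 || f(hi) < 0) {
    stop("no solution in (0, 1) for the requested odds ratio",
         call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  p_case <- root
  p_ctrl <- a - b * root
  achieved <- odds(p_case) / odds(p_ctrl)
  if (abs(achieved - target_or) > 1e-10 * max(1, target_or)) {
    stop("root-finding failed to reach the target odds ratio",
         call. = FALSE)
  }
  c(p_case = p_case, p_ctrl = p_ctrl)
}

#' Analytic power for comparing two exposure prevalences
#'
#' Normal-approximation power for detecting a difference between the
#' exposure prevalence of cases and controls with a two-sided level-alpha
#' test. The default (\code{variant = "pooled"}) uses the pooled-variance
#' standard error under the null in both roles:
#' power = Phi(|p1 - p2| / SE0 - z_{1 - alpha/2}) with
#' SE0 = sqrt(pbar (1 - pbar) (1/n1 + 1/n2)) and pbar the size-weighted
#' mean. \code{variant = "unpooled"} uses the alternative-hypothesis
#' standard error for the power term:
#' Phi((|p1 - p2| - z SE0) / SE1), SE1 = sqrt(p1 q1/n1 + p2 q2/n2).
#'
#' @param p_case,p_ctrl exposure prevalences in (0, 1).
#' @param n_cases number of cases (>= 2).
#' @param n_controls number of controls; defaults to \code{M * n_cases} but
#'   may be set freely (matched designs do not always achieve exactly M
#'   controls per case).
#' @param M controls per case, used only for the default \code{n_controls}.
#' @param alpha two-sided significance level, default 0.05.
#' @param variant \code{"pooled"} (default) or \code{"unpooled"}.
#' @return the power, a probability.
#' @examples
#' analytic_power(0.32, 0.13, n_cases = 69, n_controls = 137)  # about 0.90
#' @export
analytic_power <- function(p_case, p_ctrl, n_cases, n_controls = NULL,
                           M = 2, alpha = 0.05,
                           variant = c("pooled", "unpooled")) {
  variant <- match.arg(variant)
  for (p in c(p_case, p_ctrl)) {
    if (!(p > 0 && p < 1)) stop("prevalences must lie in (0, 1)",
                                call. = FALSE)
  }
  n_cases <- .assert_scalar_count(n_cases, "n_cases", min = 2)
  if (is.null(n_controls)) n_controls <- M * n_cases
  n_controls <- .assert_scalar_count(n_controls, "n_controls", min = 2)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)",
                                      call. = FALSE)
  diff <- abs(p_case - p_ctrl)
  pbar <- (n_cases * p_case + n_controls * p_ctrl) / (n_cases + n_controls)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n_cases + 1 / n_controls))
  z <- stats::qnorm(1 - alpha / 2)
  if (variant == "pooled") {
    stats::pnorm(diff / se0 - z)
  } else {
    se1 <- sqrt(p_case * (1 - p_case) / n_cases +
                  p_ctrl * (1 - p_ctrl) / n_controls)
    stats::pnorm((diff - z * se0) / se1)
  }
}

#' Simulated power of the matched score test
#'
#' Monte-Carlo power for the 1:M matched design: each replicate draws
#' \code{n_cases} matched sets in which the case's exposure is
#' Bernoulli(\code{p_case}) and each of the M controls' is
#' Bernoulli(\code{p_ctrl}) independently, then applies the conditional
#' score test (equivalently the Cochran-Mantel-Haenszel statistic) at level
#' \code{alpha}. Sets with zero within-set information contribute nothing,
#' as in \code{\link{score_test}}.
#'
#' @param p_case,p_ctrl exposure prevalences.
#' @param n_cases matched sets per replicate.
#' @param M controls per case, default 2.
#' @param alpha two-sided level, default 0.05.
#' @param reps Monte-Carlo replicates (>= 100), default 2000.
#' @param seed integer seed.
#' @return list with \code{power} (rejection fraction), \code{mc_se}
#'   (binomial Monte-Carlo standard error), \code{reps}.
#' @export
simulate_power <- function(p_case, p_ctrl, n_cases, M = 2, alpha = 0.05,
                           reps = 2000, seed = 1L) {
  .assert_prob(p_case, "p_case")
  .assert_prob(p_ctrl, "p_ctrl")
  n_cases <- .assert_scalar_count(n_cases, "n_cases")
  M <- .assert_scalar_count(M, "M")
  reps <- .assert_scalar_count(reps, "reps", min = 100)
  set.seed(seed)
  size <- M + 1
  crit <- stats::qchisq(1 - alpha, 1)
  reject <- logical(reps)
  for (r in seq_len(reps)) {
    xc <- stats::rbinom(n_cases, 1L, p_case)
    xm <- matrix(stats::rbinom(n_cases * M, 1L, p_ctrl), ncol = M)
    m <- xc + rowSums(xm)
    # score and information at beta = 0 for binary exposure in 1:M sets
    U <- sum(xc - m / size)
    info <- sum(m * (size - m)) / size^2
    reject[r] <- info > 0 && U^2 / info > crit
  }
  pw <- mean(reject)
  list(power = pw, mc_se = sqrt(pw * (1 - pw) / reps), reps = reps)
}

#' Sample size to estimate a prevalence with a target standard error
#'
#' The standard formula n = p (1 - p) / SE^2 for the number of subjects
#' needed so that the estimate of a prevalence p has standard error SE.
#'
#' @param p anticipated prevalence.
#' @param se target standard error.
#' @return list with the exact \code{n} and the rounded-up
#'   \code{n_required}.
#' @export
prevalence_sample_size <- function(p, se) {
  .assert_prob(p, "p")
  if (se <= 0) stop("se must be > 0", call. = FALSE)
  n <- p * (1 - p) / se^2
  list(n = n, n_required = ceiling(n))
}

#' Full design report for the matched study
#'
#' Reproduces the design arithmetic in one pass: weighted null prevalences
#' of the molecular feature in the whole cohort, in cases and in controls;
#' the shift of the case/control prevalences to the target odds ratio; the
#' analytic power of the planned design (both variants); prevalence-
#' estimation sample sizes; and optionally the simulated power.
#'
#' @param weights_cohort,weights_case,weights_control morphology-class
#'   weight pairs (advanced, non-advanced).
#' @param prevalence_given_AA,prevalence_given_nAA conditional prevalences
#'   of the molecular feature.
#' @param target_or target odds ratio, default 3.
#' @param alpha two-sided level, default 0.05.
#' @param n_cases,n_controls planned sample sizes.
#' @param M controls per case, default 2.
#' @param planned_p_case,planned_p_ctrl optional explicit design
#'   prevalences; when given they are used for the power calculations
#'   instead of the shifted pair.
#' @param simulate if \code{TRUE}, add simulated power (\code{reps},
#'   \code{seed} forwarded to \code{\link{simulate_power}}).
#' @param reps,seed simulation controls.
#' @return a list of class \code{design_report}.
#' @export
design_report <- function(weights_cohort = c(0.48, 0.52),
                          weights_case = c(0.62, 0.38),
                          weights_control = c(0.46, 0.54),
                          prevalence_given_AA = 0.25,
                          prevalence_given_nAA = 0.03,
                          target_or = 3, alpha = 0.05,
                          n_cases = 69, n_controls = 137, M = 2,
                          planned_p_case = NULL, planned_p_ctrl = NULL,
                          simulate = FALSE, reps = 2000, seed = 1L) {
  prev <- c(prevalence_given_AA, prevalence_given_nAA)
  null_prev <- list(
    cohort = expected_prevalence(weights_cohort, prev),
    cases = expected_prevalence(weights_case, prev),
    controls = expected_prevalence(weights_control, prev)
  )
  shifted <- shift_to_target_or(null_prev$cases, null_prev$controls,
                                target_or)
  p1 <- if (is.null(planned_p_case)) shifted[["p_case"]] else planned_p_case
  p2 <- if (is.null(planned_p_ctrl)) shifted[["p_ctrl"]] else planned_p_ctrl
  out <- list(
    null_prevalence = null_prev,
    shifted = as.list(shifted),
    design = list(p_case = p1, p_ctrl = p2, n_cases = n_cases,
                  n_controls = n_controls, M = M, alpha = alpha,
                  target_or = target_or),
    power_pooled = analytic_power(p1, p2, n_cases, n_controls,
                                  alpha = alpha, variant = "pooled"),
    power_unpooled = analytic_power(p1, p2, n_cases, n_controls,
                                    alpha = alpha, variant = "unpooled"),
    prevalence_estimation = list(
      AA = prevalence_sample_size(prevalence_given_AA, 0.025),
      nAA = prevalence_sample_size(prevalence_given_nAA, 0.0125)
    )
  )
  if (simulate) {
    out$power_simulated <- simulate_power(p1, p2, n_cases, M = M,
                                          alpha = alpha, reps = reps,
                                          seed = seed)
  }
  class(out) <- "design_report"
  out
}

#' @export
print.design_report <- function(x, ...) {
  cat("Matched case-control design report\n")
  cat(sprintf("  null prevalence: cohort %.1f%%, cases %.1f%%, controls %.1f%%\n",
              100 * x$null_prevalence$cohort, 100 * x$null_prevalence$cases,
              100 * x$null_prevalence$controls))
  cat(sprintf("  shifted to OR %.3g: cases %.3f, controls %.3f\n",
              x$design$target_or, x$shifted$p_case, x$shifted$p_ctrl))
  cat(sprintf("  design %d cases / %d controls at alpha %.2g\n",
              x$design$n_cases, x$design$n_controls, x$design$alpha))
  cat(sprintf("  analytic power: %.1f%% (pooled), %.1f%% (unpooled)\n",
              100 * x$power_pooled, 100 * x$power_unpooled))
  if (!is.null(x$power_simulated)) {
    cat(sprintf("  simulated power: %.1f%% (MC SE %.2f%%, %d reps)\n",
                100 * x$power_simulated$power,
                100 * x$power_simulated$mc_se, x$power_simulated$reps))
  }
  invisible(x)
}
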