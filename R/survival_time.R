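# Kaplan-Meier product-limit estimation, the log-rank test, and the
# time-window-stratified matched odds-ratio analysis

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator S(t) = prod_{t_i <= t}
#' (1 - d_i / n_i) over the distinct event times. At tied times, events are
#' handled before censorings: a subject censored at t is still at risk for
#' an event at t.
#'
#' @param times non-negative observation times.
#' @param events logical (or 0/1) event indicators; \code{FALSE} means
#'   censored.
#' @return an object of class \code{km_estimate}: \code{times} (ascending
#'   distinct event times), \code{survival}, \code{at_risk} and
#'   \code{n_events} at those times, plus \code{n} and the input range.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' km$survival  # 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  if (length(times) != length(events)) {
    stop("times and events must have equal length", call. = FALSE)
  }
  if (any(times < 0) || anyNA(times)) {
    stop("times must be non-negative and complete", call. = FALSE)
  }
  events <- as.logical(events)
  if (anyNA(events)) stop("events must be logical", call. = FALSE)
  tev <- sort(unique(times[events]))
  at_risk <- vapply(tev, function(t) sum(times >= t), numeric(1))
  n_events <- vapply(tev, function(t) sum(events & times == t), numeric(1))
  surv <- cumprod(1 - n_events / at_risk)
  structure(list(times = tev, survival = surv, at_risk = at_risk,
                 n_events = n_events, n = length(times),
                 max_time = max(times)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> n = %d, %d event time(s)\n",
              x$n, length(x$times)))
  print(utils::head(as.data.frame(x), 10))
  if (length(x$times) > 10) cat("...\n")
  invisible(x)
}

#' @rdname km_estimate
#' @param x a \code{km_estimate}.
#' @param ... unused.
#' @export
as.data.frame.km_estimate <- function(x, ...) {
  data.frame(time = x$times, survival = x$survival,
             at_risk = x$at_risk, n_events = x$n_events)
}

#' Evaluate a Kaplan-Meier estimate at arbitrary times
#'
#' @param km a \code{km_estimate}.
#' @param t times at which to evaluate S(t) (right-continuous step
#'   function; S = 1 before the first event).
#' @return survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  idx <- findInterval(t, km$times)
  c(1, km$survival)[idx + 1L]
}

#' Log-rank test for k groups
#'
#' The standard log-rank chi-square comparing survival between groups: at
#' each distinct event time the observed per-group event counts are
#' compared with their hypergeometric expectations, and the summed
#' differences are combined through the summed covariance matrix. With k
#' groups the statistic has k - 1 degrees of freedom.
#'
#' @param groups group labels (>= 2 distinct values, each present).
#' @param times observation times.
#' @param events logical event indicators.
#' @return an object of class \code{logrank_test}: \code{chi2}, \code{df},
#'   \code{p}, and per-group \code{observed}/\code{expected} event counts.
#' @export
logrank_test <- function(groups, times, events) {
  if (!(length(groups) == length(times) &&
        length(times) == length(events))) {
    stop("groups, times, events must have equal length", call. = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tabulate(g, nlevels(g)) == 0L)) {
    stop("every group needs at least one observation", call. = FALSE)
  }
  events <- as.logical(events)
  k <- nlevels(g)
  tev <- sort(unique(times[events]))
  OE <- numeric(k)
  O <- numeric(k)
  E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in tev) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n_g <- tabulate(g[at_risk], k)
    d <- sum(events & times == t)
    d_g <- tabulate(g[events & times == t], k)
    e_g <- d * n_g / n
    O <- O + d_g
    E <- E + e_g
    OE <- OE + (d_g - e_g)
    if (n > 1) {
      frac <- n_g / n
      V <- V + d * (n - d) / (n - 1) * (diag(frac) - tcrossprod(frac))
    }
  }
  idx <- seq_len(k - 1L)
  Vsub <- V[idx, idx, drop = FALSE]
  chi2 <- if (all(abs(OE) < 1e-12) || all(Vsub == 0)) 0 else {
    as.numeric(t(OE[idx]) %*% solve(Vsub, OE[idx]))
  }
  structure(list(chi2 = chi2, df = k - 1L,
                 p = stats::pchisq(chi2, k - 1L, lower.tail = FALSE),
                 observed = stats::setNames(O, levels(g)),
                 expected = stats::setNames(E, levels(g))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4f on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = round(x$expected, 2), row.names = NULL))
  invisible(x)
}

#' Default follow-up windows for the stratified time analysis
#'
#' Half-open-from-the-left intervals (lo, hi] over the case's event time:
#' within the first year, the second, the third, and beyond three years.
#'
#' @return a data.frame with columns \code{label}, \code{lo}, \code{hi}.
#' @export
default_time_windows <- function() {
  data.frame(label = c("<=1y", ">1-<=2y", ">2-<=3y", ">3y"),
             lo = c(0, 1, 2, 3),
             hi = c(1, 2, 3, Inf))
}

#' Time-window-stratified matched odds ratios
#'
#' Splits the matched sets by the window containing the case's event time
#' (intervals (lo, hi]) and fits the conditional-logistic model separately
#' in each window, asking whether the covariate effect is concentrated
#' shortly after baseline. Windows with no sets, or none with within-set
#' covariate variation, are flagged and skipped.
#'
#' @param data long matched table with \code{set}, \code{case},
#'   \code{index_time} and covariates.
#' @param spec a \code{\link{design_spec}}.
#' @param windows data.frame with \code{label}, \code{lo}, \code{hi}
#'   (disjoint, ordered); default \code{\link{default_time_windows}}.
#' @param ... passed to \code{\link{fit_clogit}}.
#' @return an object of class \code{windowed_or}: per-window list with the
#'   number of cases/controls and either the \code{clogit_fit} or the skip
#'   reason, plus a flat summary table (\code{$table}) of per-window ORs.
#' @export
stratified_window_or <- function(data, spec,
                                 windows = default_time_windows(), ...) {
  stopifnot(all(c("label", "lo", "hi") %in% names(windows)))
  w <- windows[order(windows$lo), , drop = FALSE]
  if (any(w$lo[-1L] < w$hi[-nrow(w)])) {
    stop("windows must be disjoint", call. = FALSE)
  }
  if (!("index_time" %in% names(data))) {
    stop("matched data needs an index_time column", call. = FALSE)
  }
  set_time <- tapply(data$index_time, .set_index(data), `[`, 1L)
  results <- list()
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    lab <- windows$label[i]
    in_w <- names(set_time)[set_time > windows$lo[i] &
                              set_time <= windows$hi[i]]
    sub <- data[data$set %in% in_w, , drop = FALSE]
    if (nrow(sub) == 0L) {
      results[[lab]] <- list(label = lab, n_sets = 0L, fitted = FALSE,
                             reason = "no sets in window")
      next
    }
    fit <- tryCatch(fit_clogit(sub, spec, ...), error = function(e) e)
    if (inherits(fit, "error")) {
      results[[lab]] <- list(label = lab, n_sets = length(in_w),
                             n_cases = sum(sub$case),
                             n_controls = sum(!sub$case),
                             fitted = FALSE, reason = conditionMessage(fit))
      next
    }
    results[[lab]] <- list(label = lab, n_sets = length(in_w),
                           n_cases = sum(sub$case),
                           n_controls = sum(!sub$case),
                           fitted = TRUE, fit = fit)
    tab <- fit$or_ci
    tab <- cbind(window = lab, n_cases = sum(sub$case),
                 n_controls = sum(!sub$case), tab)
    rows[[length(rows) + 1L]] <- tab
  }
  table <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(list(windows = results, table = table), class = "windowed_or")
}

#' @export
print.windowed_or <- function(x, ...) {
  for (wi in x$windows) {
    if (isTRUE(wi$fitted)) {
      cat(sprintf("window %s: %d cases / %d controls\n",
                  wi$label, wi$n_cases, wi$n_controls))
      print(wi$fit)
    } else {
      cat(sprintf("window %s: not fitted (%s)\n", wi$label, wi$reason))
    }
  }
  invisible(x)
}
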