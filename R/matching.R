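# incidence density (risk-set) matching for the nested case-control sample

#' Controls eligible for a given case
#'
#' A pool member is an eligible control for a case when it has the same sex,
#' its baseline age is within \code{age_window} years of the case's
#' (closed interval, ages compared as stored), its follow-up lasts at least
#' until the case's event time (the risk-set condition), and it is not the
#' case itself. Under \code{control_policy = "never_cases"} subjects who
#' ever develop the event are excluded outright; under \code{"risk_set"}
#' (textbook incidence density sampling) later cases are eligible while
#' still event-free, i.e. when their own event time is strictly after the
#' case's.
#'
#' @param case a single-row subject (data.frame row or list) with
#'   \code{id}, \code{sex}, \code{age_at_baseline}, \code{event},
#'   \code{event_time_years}.
#' @param pool data.frame of candidate subjects (same columns, plus
#'   \code{followup_years}).
#' @param age_window maximum absolute age difference in years, default 5.
#' @param control_policy \code{"never_cases"} (default) or
#'   \code{"risk_set"}.
#' @return the eligible rows of \code{pool}, sorted by \code{id}.
#' @export
eligible_controls <- function(case, pool, age_window = 5,
                              control_policy = c("never_cases", "risk_set")) {
  control_policy <- match.arg(control_policy)
  if (nrow(pool) == 0L) stop("empty candidate pool", call. = FALSE)
  index_time <- case$event_time_years
  ok <- pool$sex == case$sex &
    abs(pool$age_at_baseline - case$age_at_baseline) <= age_window &
    pool$followup_years >= index_time &
    pool$id != case$id
  ok <- ok & if (control_policy == "never_cases") {
    !pool$event
  } else {
    !pool$event | pool$event_time_years > index_time
  }
  out <- pool[ok, , drop = FALSE]
  out[order(out$id), , drop = FALSE]
}

#' Incidence-density match controls to cases
#'
#' Builds the nested case-control sample: every case is matched to
#' \code{M} controls drawn uniformly at random (seeded) from its eligible
#' risk set (\code{\link{eligible_controls}}). Cases are processed in
#' ascending order of event time (ties broken by id), so the output does
#' not depend on input row order. Under
#' \code{reuse_policy = "without_replacement"} a control serves in at most
#' one matched set; under \code{"with_replacement"} it may recur across
#' sets. Cases with fewer than \code{M} eligible controls are dropped
#' (\code{shortfall_policy = "drop"}) or kept with the controls found
#' (\code{"keep"}); either way they are listed in the match report.
#'
#' @param cohort data.frame of subjects (as from
#'   \code{\link{generate_cohort}}).
#' @param M controls per case, default 2.
#' @param age_window maximum absolute age difference, default 5 years.
#' @param seed integer seed for control sampling.
#' @param reuse_policy \code{"without_replacement"} (default) or
#'   \code{"with_replacement"}.
#' @param shortfall_policy \code{"drop"} (default) or \code{"keep"}.
#' @param control_policy passed to \code{\link{eligible_controls}}.
#' @return an object of class \code{matched_sets}: \code{$sets}, a long
#'   data.frame (set_id, role, subject_id, index_time); and \code{$report},
#'   a list with counts of matched/dropped/short cases, the per-case
#'   eligibility counts, and the ids of unmatched cases.
#' @examples
#' coh <- generate_cohort(cohort_params(800, seed = 3))
#' ms <- match_cases(coh, M = 2, seed = 3)
#' ms$report$n_matched
#' @export
match_cases <- function(cohort, M = 2, age_window = 5, seed = 1L,
                        reuse_policy = c("without_replacement",
                                         "with_replacement"),
                        shortfall_policy = c("drop", "keep"),
                        control_policy = c("never_cases", "risk_set")) {
  reuse_policy <- match.arg(reuse_policy)
  shortfall_policy <- match.arg(shortfall_policy)
  control_policy <- match.arg(control_policy)
  M <- .assert_scalar_count(M, "M")
  cases <- cohort[cohort$event, , drop = FALSE]
  if (nrow(cases) == 0L) stop("cohort contains no cases", call. = FALSE)
  cases <- cases[order(cases$event_time_years, cases$id), , drop = FALSE]

  set.seed(seed)
  used <- character(0)
  rows <- list()
  eligibility <- integer(nrow(cases))
  dropped <- character(0)
  short <- character(0)
  for (k in seq_len(nrow(cases))) {
    case <- cases[k, , drop = FALSE]
    elig <- eligible_controls(case, cohort, age_window = age_window,
                              control_policy = control_policy)
    if (reuse_policy == "without_replacement") {
      elig <- elig[!(elig$id %in% used), , drop = FALSE]
    }
    eligibility[k] <- nrow(elig)
    if (nrow(elig) < M && shortfall_policy == "drop") {
      dropped <- c(dropped, case$id)
      next
    }
    n_take <- min(M, nrow(elig))
    if (n_take == 0L) {
      dropped <- c(dropped, case$id)
      next
    }
    if (n_take < M) short <- c(short, case$id)
    picked <- elig$id[sample.int(nrow(elig), n_take)]
    used <- c(used, picked)
    set_id <- sprintf("set%04d", length(rows) + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      set_id = set_id,
      role = c("case", rep("control", n_take)),
      subject_id = c(case$id, picked),
      index_time = case$event_time_years
    )
  }
  sets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_id = character(0), role = character(0),
               subject_id = character(0), index_time = numeric(0))
  report <- list(
    n_cases = nrow(cases),
    n_matched = length(unique(sets$set_id)),
    n_dropped = length(dropped),
    n_short = length(short),
    M = M, age_window = age_window,
    reuse_policy = reuse_policy, shortfall_policy = shortfall_policy,
    control_policy = control_policy,
    dropped_case_ids = dropped,
    eligibility_counts = stats::setNames(eligibility, cases$id)
  )
  structure(list(sets = sets, report = report), class = "matched_sets")
}

#' @export
print.matched_sets <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<matched_sets> %d/%d cases matched 1:%d ",
                     "(%d dropped, %d short); %d subjects in sets\n"),
              r$n_matched, r$n_cases, r$M, r$n_dropped, r$n_short,
              nrow(x$sets)))
  invisible(x)
}

#' Re-audit a matched sample against the eligibility rules
#'
#' Verifies, set by set, that every control in \code{sets} would again be
#' returned by \code{\link{eligible_controls}} for its case, that each set
#' has exactly one case, and (under \code{without_replacement}) that no
#' control id recurs across sets.
#'
#' @param matched a \code{matched_sets} object.
#' @param cohort the cohort the sets were drawn from.
#' @return \code{TRUE} invisibly, or an error describing the violation.
#' @export
audit_matched_sets <- function(matched, cohort) {
  stopifnot(inherits(matched, "matched_sets"))
  sets <- matched$sets
  r <- matched$report
  rownames(cohort) <- cohort$id
  for (sid in unique(sets$set_id)) {
    s <- sets[sets$set_id == sid, , drop = FALSE]
    case_id <- s$subject_id[s$role == "case"]
    if (length(case_id) != 1L) stop("set ", sid, " lacks a unique case")
    case <- cohort[case_id, , drop = FALSE]
    if (!case$event) stop("case ", case_id, " has no event")
    ctrl <- s$subject_id[s$role == "control"]
    elig <- eligible_controls(case, cohort, age_window = r$age_window,
                              control_policy = r$control_policy)
    bad <- setdiff(ctrl, elig$id)
    if (length(bad)) {
      stop("set ", sid, ": control(s) fail eligibility: ",
           paste(bad, collapse = ", "))
    }
    if (case_id %in% ctrl) stop("set ", sid, ": case reused as own control")
  }
  if (r$reuse_policy == "without_replacement") {
    ctrl_all <- sets$subject_id[sets$role == "control"]
    if (anyDuplicated(ctrl_all)) {
      stop("control id reused across sets under without_replacement")
    }
  }
  invisible(TRUE)
}

#' Attach cohort covariates to a matched sample
#'
#' Expands a \code{matched_sets} object into the long analysis table used
#' by the conditional-logistic fitters: one row per set member with
#' \code{set}, \code{case} (logical), \code{index_time} and the cohort's
#' covariate columns.
#'
#' @param matched a \code{matched_sets} object.
#' @param cohort the source cohort.
#' @return a data.frame, one row per matched subject.
#' @export
matched_data <- function(matched, cohort) {
  stopifnot(inherits(matched, "matched_sets"))
  sets <- matched$sets
  idx <- match(sets$subject_id, cohort$id)
  if (anyNA(idx)) stop("matched subject missing from cohort", call. = FALSE)
  covars <- cohort[idx, setdiff(names(cohort), "true_arm_events"),
                   drop = FALSE]
  out <- cbind(data.frame(set = sets$set_id,
                          case = sets$role == "case",
                          index_time = sets$index_time),
               covars)
  rownames(out) <- NULL
  out
}
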