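# synthetic adenoma surveillance cohort: baseline covariates, arm-level
# copy-number truth, exponential time-to-event with covariate effects, and
# binned log2-ratio profiles consistent with the truth

#' Parameters for the synthetic cohort generator
#'
#' Bundles and validates the generator's parameters. The defaults emulate
#' the structure of a national adenoma surveillance cohort: about half of
#' baseline adenomas advanced, molecular high risk (>= 2 CAEs) in roughly a
#' third of advanced and a tenth of non-advanced adenomas, ages truncated-
#' normal around 69 with a minimum of 40, 44\% male, and exponential
#' time-to-event with log-hazard linear in covariates plus staggered-entry
#' administrative censoring yielding a median follow-up near 13 years.
#'
#' @param n_subjects number of cohort members.
#' @param p_advanced probability a baseline adenoma is advanced.
#' @param p_cae_high_given_AA,p_cae_high_given_nAA probability of molecular
#'   high risk (>= 2 CAEs) given advanced / non-advanced morphology.
#' @param log_or named numeric vector of log rate ratios on the event
#'   hazard; names refer to generated covariates (\code{advanced},
#'   \code{high_cae}, \code{high_cna}, \code{high_gain}, \code{high_loss},
#'   or \code{age}, the latter per year centred at the age mean). For the
#'   rare events simulated here these rate ratios are interchangeable with
#'   odds ratios in the matched analysis.
#' @param baseline_hazard events per person-year at reference covariates.
#' @param censoring_horizon_years administrative censoring horizon for the
#'   earliest-entering subject.
#' @param accrual_years length of the staggered entry period; each
#'   subject's censoring time is uniform on
#'   (censoring_horizon_years - accrual_years, censoring_horizon_years).
#' @param age_distribution numeric \code{c(mean, sd, min)} of the truncated
#'   normal age distribution.
#' @param sex_ratio probability male.
#' @param cae_extra_prob among molecular high-risk subjects the CAE count is
#'   2 + Binomial(5, cae_extra_prob).
#' @param p_one_cae_low probability a molecular low-risk subject carries
#'   exactly one CAE (otherwise zero).
#' @param background_rate per-arm probability of a non-CAE background
#'   alteration (direction-constrained so it never changes the CAE count).
#' @param seed integer seed.
#' @return a validated list of class \code{cohort_params}.
#' @export
cohort_params <- function(n_subjects,
                          p_advanced = 0.505,
                          p_cae_high_given_AA = 0.318,
                          p_cae_high_given_nAA = 0.103,
                          log_or = c(advanced = log(2.9),
                                     high_loss = log(2.3)),
                          baseline_hazard = 0.003,
                          censoring_horizon_years = 20.5,
                          accrual_years = 15,
                          age_distribution = c(mean = 69, sd = 10, min = 40),
                          sex_ratio = 0.44,
                          cae_extra_prob = 0.2,
                          p_one_cae_low = 0.35,
                          background_rate = 0.04,
                          seed = 1L) {
  n_subjects <- .assert_scalar_count(n_subjects, "n_subjects")
  .assert_prob(p_advanced, "p_advanced")
  .assert_prob(p_cae_high_given_AA, "p_cae_high_given_AA")
  .assert_prob(p_cae_high_given_nAA, "p_cae_high_given_nAA")
  .assert_prob(sex_ratio, "sex_ratio")
  .assert_prob(cae_extra_prob, "cae_extra_prob")
  .assert_prob(p_one_cae_low, "p_one_cae_low")
  .assert_prob(background_rate, "background_rate")
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0) {
    stop("baseline_hazard must be > 0", call. = FALSE)
  }
  if (censoring_horizon_years <= 0) {
    stop("censoring_horizon_years must be > 0", call. = FALSE)
  }
  if (length(log_or) && is.null(names(log_or))) {
    stop("log_or must be a named vector", call. = FALSE)
  }
  age_distribution <- stats::setNames(as.numeric(age_distribution),
                                      c("mean", "sd", "min"))
  structure(as.list(environment()), class = "cohort_params")
}

# covariates log_or may reference
.LOGOR_COVARIATES <- c("advanced", "high_cae", "high_cna", "high_gain",
                       "high_loss", "age")

#' Generate a synthetic adenoma cohort
#'
#' Draws one subject per row: sex, truncated-normal age, adenoma morphology,
#' a true arm-event set sampled so that the >= 2 CAE rule reproduces the
#' requested conditional prevalences, and an exponential event time with
#' log-hazard linear in the covariates named in \code{params$log_or},
#' administratively censored under staggered entry. Identical parameters
#' (including seed) reproduce the cohort field by field.
#'
#' @param params a \code{\link{cohort_params}} object.
#' @param arm_map arm definitions (default packaged hg38 map); used to name
#'   the background-alteration arms.
#' @return a data.frame of class \code{cohort}, one row per subject, with
#'   baseline covariates, the derived molecular classification of the
#'   simulation truth, \code{event}, \code{event_time_years} and
#'   \code{followup_years}, plus a \code{true_arm_events} list column of
#'   \code{\link{arm_events}} objects.
#' @examples
#' coh <- generate_cohort(cohort_params(500, seed = 7))
#' mean(coh$morphology == "advanced")
#' @export
generate_cohort <- function(params, arm_map = read_arm_map()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_subjects
  id <- sprintf("S%05d", seq_len(n))
  sex <- ifelse(stats::runif(n) < params$sex_ratio, "male", "female")
  ad <- params$age_distribution
  # inverse-CDF sampling of the truncated normal on [min, Inf)
  lo <- stats::pnorm((ad["min"] - ad["mean"]) / ad["sd"])
  age <- ad["mean"] + ad["sd"] *
    stats::qnorm(stats::runif(n, lo, 1))
  age <- as.numeric(age)
  morphology <- ifelse(stats::runif(n) < params$p_advanced,
                       "advanced", "non_advanced")
  p_high <- ifelse(morphology == "advanced",
                   params$p_cae_high_given_AA, params$p_cae_high_given_nAA)
  mol_high <- stats::runif(n) < p_high

  truth <- vector("list", n)
  for (i in seq_len(n)) {
    truth[[i]] <- .sample_arm_events(id[i], mol_high[i], params, arm_map)
  }
  cls <- lapply(truth, classify_molecular)

  cohort <- data.frame(
    id = id, sex = sex, age_at_baseline = age, morphology = morphology,
    cae_count = vapply(cls, `[[`, integer(1), "cae_count"),
    n_gains = vapply(cls, `[[`, integer(1), "n_gains"),
    n_losses = vapply(cls, `[[`, integer(1), "n_losses"),
    n_cna = vapply(cls, `[[`, integer(1), "n_cna"),
    high_cae = vapply(cls, `[[`, logical(1), "high_cae"),
    high_cna = vapply(cls, `[[`, logical(1), "high_cna"),
    high_gain = vapply(cls, `[[`, logical(1), "high_gain"),
    high_loss = vapply(cls, `[[`, logical(1), "high_loss"),
    stringsAsFactors = FALSE
  )

  lp <- .linear_predictor(cohort, params$log_or,
                          age_center = params$age_distribution["mean"])
  rate <- params$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n) / rate
  cens_lo <- max(0, params$censoring_horizon_years - params$accrual_years)
  t_cens <- stats::runif(n, cens_lo, params$censoring_horizon_years)
  cohort$event <- t_event <= t_cens
  cohort$event_time_years <- pmin(t_event, t_cens)
  cohort$followup_years <- cohort$event_time_years
  cohort$true_arm_events <- I(truth)
  attr(cohort, "params") <- params
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

# hazard linear predictor from named log rate-ratios
.linear_predictor <- function(cohort, log_or, age_center) {
  lp <- numeric(nrow(cohort))
  for (nm in names(log_or)) {
    if (!(nm %in% .LOGOR_COVARIATES)) {
      stop("log_or names must be among: ",
           paste(.LOGOR_COVARIATES, collapse = ", "), call. = FALSE)
    }
    x <- if (nm == "age") {
      cohort$age_at_baseline - age_center
    } else if (nm == "advanced") {
      as.numeric(cohort$morphology == "advanced")
    } else {
      as.numeric(cohort[[nm]])
    }
    lp <- lp + log_or[[nm]] * x
  }
  lp
}

# sample one subject's true arm events; the CAE count is >= 2 exactly when
# mol_high, and background alterations never touch a CAE arm in the CAE
# direction, so the planted high/low label is always respected
.sample_arm_events <- function(sample_id, mol_high, params, arm_map) {
  cae <- cae_definition()
  k <- if (mol_high) {
    2L + stats::rbinom(1L, 5L, params$cae_extra_prob)
  } else {
    stats::rbinom(1L, 1L, params$p_one_cae_low)
  }
  status <- stats::setNames(rep("neutral", nrow(arm_map)), arm_map$arm)
  keep <- intersect(cae$arm, names(status))
  if (length(keep) < nrow(cae)) {
    stop("arm map lacks CAE arm(s): ",
         paste(setdiff(cae$arm, keep), collapse = ", "), call. = FALSE)
  }
  if (k > 0L) {
    pick <- sample.int(nrow(cae), k)
    status[cae$arm[pick]] <- cae$direction[pick]
  }
  untouched <- names(status)[status == "neutral"]
  bg <- untouched[stats::runif(length(untouched)) < params$background_rate]
  for (a in bg) {
    i <- match(a, cae$arm)
    status[a] <- if (!is.na(i)) {
      # background on a CAE arm goes in the non-CAE direction only
      if (cae$direction[i] == "gain") "loss" else "gain"
    } else if (stats::runif(1) < 0.5) "gain" else "loss"
  }
  arm_events(sample_id, status)
}

#' Generate binned copy-number profiles from cohort truth
#'
#' Tiles every arm of \code{arm_map} with fixed-width bins (0-based
#' half-open; the terminal bin of an arm is truncated at the arm end) and
#' assigns each bin the segment mean implied by the subject's true arm
#' events plus i.i.d. Gaussian noise. With \code{noise_sd = 0} the
#' classification pipeline recovers the simulation truth exactly.
#'
#' @param subjects a \code{cohort} (or any data.frame with \code{id} and a
#'   \code{true_arm_events} list column).
#' @param arm_map arm definitions; profiles tile exactly these arms.
#' @param bin_width bin width in bp, default 1e6.
#' @param noise_sd standard deviation of the per-bin Gaussian noise.
#' @param seed integer seed.
#' @param gain_mean,loss_mean log2-ratio segment means encoding an arm gain
#'   (default log2(3/2), one extra copy) and loss (default -1, one lost
#'   copy of two).
#' @return a named list of \code{\link{cn_profile}} objects, one per
#'   subject.
#' @export
generate_profiles <- function(subjects, arm_map = read_arm_map(),
                              bin_width = 1e6, noise_sd = 0.1, seed = 1L,
                              gain_mean = log2(3 / 2), loss_mean = -1.0) {
  if (!("true_arm_events" %in% names(subjects))) {
    stop("subjects need a true_arm_events column", call. = FALSE)
  }
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  .validate_arm_map(arm_map)
  set.seed(seed)
  template <- .bin_template(arm_map, bin_width)
  out <- vector("list", nrow(subjects))
  names(out) <- subjects$id
  for (i in seq_len(nrow(subjects))) {
    truth <- subjects$true_arm_events[[i]]
    stopifnot(inherits(truth, "arm_events"))
    unknown <- setdiff(names(truth$status)[truth$status != "neutral"],
                       arm_map$arm)
    if (length(unknown)) {
      stop("true arm events reference arm(s) absent from the arm map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mu <- c(gain = gain_mean, loss = loss_mean, neutral = 0)
    arm_status <- truth$status[template$arm]
    arm_status[is.na(arm_status)] <- "neutral"
    lr <- mu[arm_status]
    if (noise_sd > 0) lr <- lr + stats::rnorm(nrow(template), 0, noise_sd)
    out[[i]] <- cn_profile(subjects$id[i],
                           data.frame(chrom = template$chrom,
                                      start = template$start,
                                      end = template$end,
                                      log2ratio = as.numeric(lr)))
  }
  out
}

# fixed-width tiling of each arm, reused across samples
.bin_template <- function(arm_map, bin_width) {
  pieces <- lapply(seq_len(nrow(arm_map)), function(i) {
    starts <- seq(arm_map$start[i], arm_map$end[i] - 1, by = bin_width)
    data.frame(chrom = arm_map$chrom[i],
               start = starts,
               end = pmin(starts + bin_width, arm_map$end[i]),
               arm = arm_map$arm[i])
  })
  do.call(rbind, pieces)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(paste0("<cohort> %d subjects: %.1f%% advanced, %.1f%% ",
                     "molecular high-risk, %d events, median follow-up ",
                     "%.1f y\n"),
              nrow(x), 100 * mean(x$morphology == "advanced"),
              100 * mean(x$high_cae), sum(x$event),
              stats::median(x$followup_years)))
  invisible(x)
}
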