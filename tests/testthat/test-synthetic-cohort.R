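# cohort generator: prevalence structure, determinism, event-time model,
# and the profile round trip

test_that("empirical prevalences converge to the requested parameters", {
  coh <- generate_cohort(cohort_params(20000, seed = 17))
  # binomial 4*SE tolerances at n = 20000
  expect_lt(abs(mean(coh$morphology == "advanced") - 0.505),
            4 * sqrt(0.505 * 0.495 / 20000))
  aa <- coh$morphology == "advanced"
  expect_lt(abs(mean(coh$high_cae[aa]) - 0.318),
            4 * sqrt(0.318 * 0.682 / sum(aa)))
  expect_lt(abs(mean(coh$high_cae[!aa]) - 0.103),
            4 * sqrt(0.103 * 0.897 / sum(!aa)))
  expect_true(all(coh$age_at_baseline >= 40))
  expect_true(all(coh$event_time_years <= coh$followup_years))
  expect_true(all((coh$event_time_years == coh$followup_years)[!coh$event]))
  # administrative censoring keeps the median follow-up near 13 years
  expect_lt(abs(median(coh$followup_years) - 13), 1.5)
})

test_that("zero conditional prevalence yields no molecular high-risk truth", {
  coh <- generate_cohort(cohort_params(500, p_cae_high_given_AA = 0,
                                       p_cae_high_given_nAA = 0, seed = 2))
  expect_true(all(coh$cae_count < 2))
  expect_false(any(coh$high_cae))
})

test_that("the generator is deterministic given the seed", {
  p <- cohort_params(300, seed = 99)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1, c2)
  pr1 <- generate_profiles(c1[1:3, ], bin_width = 1e7, noise_sd = 0.1,
                           seed = 7)
  pr2 <- generate_profiles(c1[1:3, ], bin_width = 1e7, noise_sd = 0.1,
                           seed = 7)
  expect_identical(pr1, pr2)
})

test_that("parameter validation rejects impossible inputs", {
  expect_error(cohort_params(0), "n_subjects")
  expect_error(cohort_params(10, p_advanced = 1.2), "p_advanced")
  expect_error(cohort_params(10, baseline_hazard = -1), "baseline_hazard")
  expect_error(generate_cohort(cohort_params(10, log_or = c(bogus = 1))),
               "log_or")
})

test_that("event fraction is monotone in hazard and in a positive log OR", {
  frac <- function(bh, lo) {
    mean(generate_cohort(cohort_params(4000, baseline_hazard = bh,
                                       log_or = c(high_cae = lo),
                                       seed = 5))$event)
  }
  by_hazard <- c(frac(0.001, log(2)), frac(0.003, log(2)), frac(0.01, log(2)))
  expect_true(all(diff(by_hazard) > 0))
  by_or <- c(frac(0.003, 0), frac(0.003, log(2)), frac(0.003, log(6)))
  expect_true(all(diff(by_or) >= 0))
  expect_gt(by_or[3], by_or[1])
})

test_that("noiseless profiles round-trip to the simulation truth exactly", {
  coh <- generate_cohort(cohort_params(40, seed = 21))
  arms <- read_arm_map()
  profs <- generate_profiles(coh, arms, bin_width = 5e6, noise_sd = 0,
                             seed = 3)
  for (i in seq_len(nrow(coh))) {
    ev <- derive_arm_events(call_bins(profs[[i]]), arms)
    expect_identical(ev$status, coh$true_arm_events[[i]]$status)
  }
})

test_that("arm events are recovered under realistic noise", {
  coh <- generate_cohort(cohort_params(200, seed = 31))
  arms <- read_arm_map()
  profs <- generate_profiles(coh, arms, bin_width = 5e6, noise_sd = 0.05,
                             seed = 13)
  n_arms_ok <- 0L
  n_arms <- 0L
  for (i in seq_len(nrow(coh))) {
    ev <- derive_arm_events(call_bins(profs[[i]]), arms)
    truth <- coh$true_arm_events[[i]]$status
    n_arms_ok <- n_arms_ok + sum(ev$status == truth[names(ev$status)])
    n_arms <- n_arms + length(ev$status)
  }
  expect_gte(n_arms_ok / n_arms, 0.95)
})

test_that("per-bin call accuracy under noise matches the Gaussian model", {
  coh <- generate_cohort(cohort_params(100, seed = 41))
  arms <- read_arm_map()
  sd <- 0.05
  profs <- generate_profiles(coh, arms, bin_width = 1e7, noise_sd = sd,
                             seed = 19)
  clean <- generate_profiles(coh, arms, bin_width = 1e7, noise_sd = 0,
                             seed = 19)
  ok <- 0L
  tot <- 0L
  p_neutral <- 0
  for (i in seq_len(nrow(coh))) {
    want <- call_bins(clean[[i]])$call
    got <- call_bins(profs[[i]])$call
    ok <- ok + sum(got == want)
    tot <- tot + length(want)
    p_neutral <- p_neutral + sum(want == "normal")
  }
  # expected accuracy: neutral bins miscalled when |N(0, sd)| >= 0.1;
  # altered bins (means +-0.58 / -1) essentially never miscalled
  frac_neutral <- p_neutral / tot
  expected <- 1 - frac_neutral * 2 * pnorm(-0.1 / sd)
  expect_lt(abs(ok / tot - expected), 0.005)
  expect_gt(ok / tot, 0.94)
})

test_that("profiles tile the arm map with sorted fixed-width bins", {
  # event-free truth so a small arm map suffices
  coh <- generate_cohort(cohort_params(2, p_cae_high_given_AA = 0,
                                       p_cae_high_given_nAA = 0,
                                       p_one_cae_low = 0,
                                       background_rate = 0, seed = 8))
  map <- mini_arm_map()
  pr <- generate_profiles(coh, map, bin_width = 7e6, noise_sd = 0,
                          seed = 1)[[1]]
  expect_true(all(pr$end > pr$start))
  for (ch in unique(pr$chrom)) {
    b <- pr[pr$chrom == ch, ]
    expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  # coverage equals the arm map span
  expect_equal(sum(pr$end - pr$start), sum(map$end - map$start))
  # truth referencing an arm missing from the map is a data error
  tiny <- map[map$arm == "8p", ]
  with_event <- data.frame(id = "z1")
  with_event$true_arm_events <- I(list(arm_events("z1", c(`8q` = "gain"))))
  expect_error(generate_profiles(with_event, tiny, bin_width = 7e6,
                                 noise_sd = 0, seed = 1),
               "absent from the arm map")
})

test_that("cohort tables round-trip through TSV", {
  coh <- generate_cohort(cohort_params(50, seed = 12))
  f <- tempfile(fileext = ".tsv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(back$id, coh$id)
  expect_equal(back$event, coh$event)
  expect_equal(back$event_time_years, coh$event_time_years,
               tolerance = 1e-12)
  expect_equal(back$cae_count, coh$cae_count)
})
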