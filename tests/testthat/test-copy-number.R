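# arm map, bin calling, arm-event derivation, CAE scoring, risk flags

test_that("packaged hg38 arm map has the expected structure", {
  arms <- read_arm_map()
  expect_equal(nrow(arms), 39)  # 44 autosome arms minus 5 acrocentric p
  expect_true(all(c("8p", "8q", "13q", "15q", "17p", "18q", "20q") %in%
                    arms$arm))
  expect_false(any(c("13p", "14p", "15p", "21p", "22p") %in% arms$arm))
  expect_true(all(arms$end > arms$start))
  with_acro <- read_arm_map(exclude_acrocentric = FALSE)
  expect_equal(nrow(with_acro), 44)
})

test_that("arm map reader rejects overlapping definitions", {
  bad <- tempfile(fileext = ".txt")
  writeLines(c("chr1\t0\t100\tp11\tgneg", "chr1\t50\t200\tp12\tgneg",
               "chr1\t200\t300\tq11\tgneg"), bad)
  # p bands merge, so overlap must come from a malformed q/p interleave
  writeLines(c("chr1\t0\t100\tp11\tgneg", "chr1\t50\t200\tq11\tgneg"), bad)
  expect_error(read_arm_map(bad), "overlap")
})

test_that("bin calling thresholds log ratios as specified", {
  p <- cn_profile("s1", data.frame(
    chrom = "chr8", start = c(0, 1e5, 2e5, 3e5), end = c(1e5, 2e5, 3e5, 4e5),
    log2ratio = c(0.30, -0.05, -0.25, 0.10)))
  called <- call_bins(p, gain_threshold = 0.10, loss_threshold = -0.10)
  expect_equal(called$call, c("gain", "normal", "loss", "gain"))
  # idempotent: re-calling changes nothing
  expect_identical(call_bins(called)$call, called$call)
  expect_error(call_bins(cn_profile("s2", data.frame(
    chrom = "chr8", start = 0, end = 1e5, log2ratio = NA_real_))),
    "missing log2ratio")
})

test_that("bin order permutation does not change arm events", {
  prof <- mini_profile("s1", list(`8q` = rep("gain", 10),
                                  `17p` = c(rep("loss", 7), rep("normal", 3))))
  shuffled <- as.data.frame(prof)[sample(nrow(prof)), ]
  prof2 <- cn_profile("s1", shuffled)
  e1 <- derive_arm_events(prof, mini_arm_map())
  e2 <- derive_arm_events(prof2, mini_arm_map())
  expect_identical(e1$status, e2$status)
})

test_that("arm-event rule: fraction threshold, direction contest, ties", {
  map <- mini_arm_map()
  # unanimous gain
  e <- derive_arm_events(mini_profile("a", list(`13q` = rep("gain", 10))),
                         map)
  expect_equal(unname(e$status["13q"]), "gain")
  # 30% gain below min_fraction -> neutral
  e <- derive_arm_events(mini_profile("b", list(
    `13q` = c(rep("gain", 3), rep("normal", 7)))), map)
  expect_equal(unname(e$status["13q"]), "neutral")
  # 60% gain vs 40% loss: larger fraction wins
  e <- derive_arm_events(mini_profile("c", list(
    `13q` = c(rep("gain", 6), rep("loss", 4)))), map)
  expect_equal(unname(e$status["13q"]), "gain")
  # exact 50/50 tie -> neutral
  e <- derive_arm_events(mini_profile("d", list(
    `13q` = c(rep("gain", 5), rep("loss", 5)))), map)
  expect_equal(unname(e$status["13q"]), "neutral")
  # uncovered arms are neutral
  expect_equal(unname(e$status["8p"]), "neutral")
  # stricter fraction threshold flips a 60% call to neutral
  e <- derive_arm_events(mini_profile("e", list(
    `13q` = c(rep("gain", 6), rep("loss", 4)))), map, min_fraction = 0.7)
  expect_equal(unname(e$status["13q"]), "neutral")
  expect_error(derive_arm_events(mini_profile("f",
    list(`13q` = rep("gain", 10))), map, min_fraction = 0.3), "min_fraction")
})

test_that("CAE counting is direction specific and bounded by 7", {
  expect_equal(count_cae(c(`8q` = "gain", `13q` = "gain", `17p` = "loss")), 3)
  expect_equal(count_cae(c(`8q` = "neutral", `1p` = "neutral")), 0)
  # wrong directions do not count
  expect_equal(count_cae(c(`8p` = "gain", `13q` = "loss")), 0)
  # property: bounded by 7 and by n_cna over random status maps
  arms <- read_arm_map()$arm
  set.seed(42)
  for (i in 1:50) {
    status <- setNames(sample(c("gain", "loss", "neutral"), length(arms),
                              replace = TRUE), arms)
    ev <- arm_events(sprintf("r%d", i), status)
    expect_lte(ev$cae_count, 7)
    expect_lte(ev$cae_count, ev$n_cna)
    expect_equal(ev$n_cna, ev$n_gains + ev$n_losses)
  }
})

test_that("molecular risk flags apply their thresholds independently", {
  mk <- function(status) classify_molecular(arm_events("x", status))
  r <- mk(c(`8q` = "gain", `13q` = "gain"))
  expect_true(r$high_cae)
  expect_false(r$high_cna)  # 2 CNAs < 3
  r <- mk(c(`8q` = "gain", `1p` = "loss", `4q` = "loss", `5p` = "loss"))
  expect_false(r$high_cae)  # 1 CAE
  expect_true(r$high_loss)  # 3 losses
  expect_true(r$high_cna)
  r <- mk(c(`1p` = "gain", `2q` = "gain", `4p` = "loss"))
  expect_true(r$high_cna)   # 2 + 1 >= 3
  expect_false(r$high_gain)
  expect_false(r$high_loss)
  # monotone in their counts
  r2 <- mk(c(`1p` = "gain", `2q` = "gain", `4p` = "loss", `6q` = "loss",
             `17p` = "loss"))
  expect_true(r2$high_loss && r2$high_cna)
})

test_that("morphology x molecular crosstab reproduces printed percentages", {
  # construct labels with the study's cell counts: 85/27/182/235
  dat <- data.frame(
    morphology = rep(c("advanced", "non_advanced", "advanced",
                       "non_advanced"), c(85, 27, 182, 235)),
    high_cae = rep(c(TRUE, TRUE, FALSE, FALSE), c(85, 27, 182, 235)))
  xt <- crosstab_morphology_molecular(dat)
  expect_equal(unname(xt$counts["High", ]), c(85, 27))
  expect_equal(unname(xt$col_pct["High", "advanced"]), 31.8)
  expect_equal(unname(xt$col_pct["High", "non_advanced"]), 10.3)
  expect_equal(unname(xt$overall_pct["High"]), 21.2)
  expect_equal(unname(xt$row_pct["High", "advanced"]), 75.9)
  expect_equal(sum(xt$counts), 529)
})

test_that("crosstab handles degenerate inputs", {
  all_low <- data.frame(morphology = c("advanced", "non_advanced"),
                        high_cae = c(FALSE, FALSE))
  xt <- crosstab_morphology_molecular(all_low)
  expect_equal(unname(xt$counts["High", ]), c(0, 0))
  expect_equal(unname(xt$col_pct["High", ]), c(0, 0))
  one <- crosstab_morphology_molecular(
    data.frame(morphology = "advanced", high_cae = TRUE))
  expect_equal(unname(one$col_pct["High", "advanced"]), 100)
  expect_error(crosstab_morphology_molecular(
    data.frame(morphology = "weird", high_cae = TRUE)), "morphology")
})

test_that("SEG round trip preserves segment means and arm events", {
  map <- mini_arm_map()
  prof <- call_bins(mini_profile("s9", list(`8q` = rep("gain", 10),
                                            `17p` = rep("loss", 10))))
  f <- tempfile(fileext = ".seg")
  write_seg(list(prof), f)
  back <- read_seg(f)[["s9"]]
  e1 <- derive_arm_events(prof, map)
  e2 <- derive_arm_events(call_bins(back), map)
  expect_identical(e1$status, e2$status)
})
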