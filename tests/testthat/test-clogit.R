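# conditional likelihood, Newton fitting, score test, concordance

test_that("conditional log-likelihood closed forms hold", {
  # beta = 0: every member equally likely -> -n log(size)
  d <- random_matched_instance(7, size = 3, seed = 1)
  ll0 <- conditional_loglik(c(0, 0), d,
                            design_spec(term_numeric("x1"),
                                        term_numeric("x2")))
  expect_equal(ll0$value, -7 * log(3), tolerance = 1e-12)
  # one 1:2 set, exposed case, unexposed controls, beta = log 3:
  # P = 3 / (3 + 1 + 1) = 3/5
  d1 <- data.frame(set = "s", case = c(TRUE, FALSE, FALSE), x = c(1, 0, 0))
  ll <- conditional_loglik(log(3), d1, design_spec(term_numeric("x")))
  expect_equal(ll$value, log(3 / 5), tolerance = 1e-12)
})

test_that("likelihood value matches the enumeration oracle to 1e-10", {
  for (seed in 1:20) {
    d <- random_matched_instance(5, size = sample(2:4, 1), seed = seed)
    beta <- rnorm(2, sd = 0.8)
    got <- conditional_loglik(beta, d, design_spec(term_numeric("x1"),
                                                   term_numeric("x2")))
    expect_equal(got$value, enum_loglik(beta, d, c("x1", "x2")),
                 tolerance = 1e-10)
  }
})

test_that("gradient and hessian agree with finite differences", {
  spec <- design_spec(term_numeric("x1"), term_numeric("x2"))
  for (seed in c(3, 7, 11)) {
    d <- random_matched_instance(20, size = 3, seed = seed)
    beta <- rnorm(2, sd = 0.5)
    got <- conditional_loglik(beta, d, spec)
    f <- function(b) conditional_loglik(b, d, spec)$value
    expect_equal(got$gradient, setNames(fd_gradient(f, beta), c("x1", "x2")),
                 tolerance = 1e-6)
    fd_hess <- rbind(
      fd_gradient(function(b) conditional_loglik(b, d, spec)$gradient[1],
                  beta),
      fd_gradient(function(b) conditional_loglik(b, d, spec)$gradient[2],
                  beta))
    expect_equal(unname(got$hessian), unname(fd_hess), tolerance = 1e-5)
    # concavity: hessian negative semidefinite
    expect_true(all(eigen(got$hessian, symmetric = TRUE)$values < 1e-10))
  }
})

test_that("fitting matches the classical matched-pairs estimator", {
  # 1:1 sets with one binary covariate: beta-hat = log(discordant ratio)
  set.seed(5)
  n <- 400
  d <- data.frame(
    set = rep(sprintf("p%03d", 1:n), each = 2),
    case = rep(c(TRUE, FALSE), n),
    x = rbinom(2 * n, 1, 0.4))
  xc <- d$x[d$case]
  xk <- d$x[!d$case]
  n10 <- sum(xc == 1 & xk == 0)  # case exposed, control not
  n01 <- sum(xc == 0 & xk == 1)
  fit <- fit_clogit(d, design_spec(term_numeric("x")))
  expect_equal(unname(fit$beta), log(n10 / n01), tolerance = 1e-8)
})

test_that("fit agrees with an established conditional-logistic oracle", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  d <- simulate_matched_sets(300, M = 2, p_exposure = 0.3, or = 2.5,
                             seed = 14)
  d$x2 <- rnorm(nrow(d))
  spec <- design_spec(term_numeric("exposure"), term_numeric("x2"))
  fit <- fit_clogit(d, spec)
  oracle <- survival::clogit(case ~ exposure + x2 + strata(set), data = d)
  expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-6)
  expect_equal(fit$loglik, oracle$loglik[2], tolerance = 1e-6)
})

test_that("Wald intervals and p-values follow from beta and se", {
  d <- simulate_matched_sets(500, M = 2, p_exposure = 0.3, or = 3, seed = 4)
  fit <- fit_clogit(d, design_spec(term_numeric("exposure")))
  ci <- fit$or_ci
  expect_equal(ci$or, exp(ci$beta))
  expect_equal(ci$lower95, exp(ci$beta - qnorm(0.975) * ci$se))
  expect_equal(ci$upper95, exp(ci$beta + qnorm(0.975) * ci$se))
  expect_true(ci$lower95 <= ci$or && ci$or <= ci$upper95)
  expect_lte(fit$loglik, 0)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("degenerate designs raise the specified errors", {
  # complete separation: every case exposed, every control unexposed
  d <- data.frame(set = rep(sprintf("s%d", 1:25), each = 3),
                  case = rep(c(TRUE, FALSE, FALSE), 25),
                  x = rep(c(1, 0, 0), 25))
  expect_error(fit_clogit(d, design_spec(term_numeric("x"))),
               "separation.*'x'")
  # exposure constant within every set: no information
  d2 <- data.frame(set = rep(c("a", "b"), each = 3),
                   case = rep(c(TRUE, FALSE, FALSE), 2),
                   x = rep(c(1, 0), each = 3))
  expect_error(fit_clogit(d2, design_spec(term_numeric("x"))),
               "no informative sets")
  expect_error(score_test(d2, "x"), "zero information")
  # a set with two cases is malformed
  d3 <- data.frame(set = "s", case = c(TRUE, TRUE, FALSE), x = c(1, 0, 0))
  expect_error(fit_clogit(d3, design_spec(term_numeric("x"))),
               "exactly one case")
})

test_that("score test equals the CMH statistic on binary exposures", {
  d <- simulate_matched_sets(150, M = 2, p_exposure = 0.3, or = 2, seed = 9)
  got <- score_test(d, "exposure")
  oracle <- mantelhaen.test(factor(d$exposure), factor(d$case),
                            factor(d$set), correct = FALSE)
  expect_equal(got$chi2, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(got$p, oracle$p.value, tolerance = 1e-9)
})

test_that("score statistic vanishes when observed equals expected", {
  # every member exposed with the same pattern: case exposure equals the
  # within-set mean in every set
  d <- data.frame(set = rep(c("a", "b"), each = 2),
                  case = rep(c(TRUE, FALSE), 2),
                  x = c(1, 0, 0, 1))
  st <- score_test(d, "x")
  expect_equal(st$chi2, 0, tolerance = 1e-12)
})

test_that("score-test type-I error is nominal under the null", {
  # null: case and control exposure prevalences identical
  sim <- simulate_power(0.25, 0.25, n_cases = 69, M = 2, alpha = 0.05,
                        reps = 1000, seed = 77)
  expect_gt(sim$power, 0.03)
  expect_lt(sim$power, 0.07)
})

test_that("matched concordance behaves at its extremes and under noise", {
  d <- data.frame(set = rep(sprintf("s%d", 1:10), each = 3),
                  case = rep(c(TRUE, FALSE, FALSE), 10),
                  x = rep(c(1, 0, 0), 10))
  fit <- list(beta = c(x = 1))
  spec <- design_spec(term_numeric("x"))
  expect_equal(matched_concordance(fit, d, spec), 1.0)
  d0 <- d
  d0$x <- 1  # constant predictor: all ties
  expect_equal(matched_concordance(fit, d0, spec), 0.5)
  # random predictor over many sets concentrates near 1/2
  set.seed(3)
  dr <- data.frame(set = rep(sprintf("s%04d", 1:1000), each = 3),
                   case = rep(c(TRUE, FALSE, FALSE), 1000),
                   x = rnorm(3000))
  expect_lt(abs(matched_concordance(fit, dr, spec) - 0.5), 0.05)
})

test_that("interaction and combined-category encodings expand correctly", {
  d <- data.frame(set = rep(c("a", "b"), each = 3),
                  case = rep(c(TRUE, FALSE, FALSE), 2),
                  adv = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                  mol = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  X <- build_design(d, design_spec(term_indicator("adv"),
                                   term_indicator("mol"),
                                   term_interaction("adv", "mol")))
  expect_equal(colnames(X), c("adv", "mol", "adv:mol"))
  expect_equal(X[, "adv:mol"], X[, "adv"] * X[, "mol"])
  Xc <- build_design(d, design_spec(term_combined("adv", "mol")))
  expect_equal(ncol(Xc), 3)  # 4 cells minus the reference
  expect_true(all(rowSums(Xc) <= 1))
  # reference cell rows have all-zero encoding
  ref_rows <- !d$adv & !d$mol
  expect_true(all(Xc[ref_rows, ] == 0))
  expect_error(build_design(d, design_spec(term_interaction("adv", "nope"))),
               "undefined design column")
  expect_error(build_design(d, design_spec(term_numeric("missing_col"))),
               "not found")
})
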