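test_that("odds-to-probability conversion follows the defining formula", {
  expect_equal(odds_to_probability(1), 0.5)
  expect_equal(odds_to_probability(0), 0)
  expect_equal(odds_to_probability(3), 0.75)
  expect_error(odds_to_probability(-0.1), "non-negative")
  # strictly increasing and inverse to p/(1-p)
  o <- seq(0, 20, by = 0.25)
  p <- odds_to_probability(o)
  expect_true(all(diff(p) > 0))
  expect_equal(p / (1 - p), o, tolerance = 1e-12)
})

test_that("binary-exposure logistic OR equals the 2x2 cross-product ratio", {
  d <- table2x2_data(20, 80, 10, 90)
  r <- suppressMessages(fit_binomial(d, "case", "exposed"))
  expect_equal(r$estimate, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_equal(r$n_used, 200L)
  # Wald CI reproduces the classic Woolf interval
  se <- sqrt(1/20 + 1/80 + 1/10 + 1/90)
  expect_equal(r$se_log, se, tolerance = 1e-6)
  expect_equal(r$ci_low, exp(log(2.25) - qnorm(0.975) * se), tolerance = 1e-6)
  expect_equal(r$ci_high, exp(log(2.25) + qnorm(0.975) * se), tolerance = 1e-6)
})

test_that("degenerate model inputs are rejected", {
  d <- table2x2_data(20, 80, 10, 90)
  d$flat <- 1
  expect_error(suppressMessages(fit_binomial(d, "case", "flat")),
               "zero variance")
  d$all_true <- TRUE
  expect_error(suppressMessages(fit_binomial(d, "all_true", "exposed")),
               "both levels")
  # perfect separation
  ds <- data.frame(x = c(1:10, 11:20), y = rep(c(FALSE, TRUE), each = 10))
  expect_error(suppressMessages(fit_binomial(ds, "y", "x")), "separation")
})

test_that("two-category multinomial RRR equals the binomial OR", {
  set.seed(77)
  n <- 400
  d <- data.frame(A2 = rnorm(n, 8, 2.5))
  d$frail <- runif(n) < plogis(-3 + 0.3 * d$A2)
  d$four_category <- factor(ifelse(d$frail, "EBF-only", "nonfrail"),
                            levels = c("nonfrail", "EBF-only"))
  rb <- suppressMessages(fit_binomial(d, "frail", "A2"))
  rm <- suppressMessages(fit_multinomial(d, "four_category", "A2"))
  expect_equal(nrow(rm), 1L)
  expect_equal(rm$effect_type, "RRR")
  expect_equal(rm$baseline_category, "nonfrail")
  expect_lt(abs(log(rm$estimate) - log(rb$estimate)), 1e-6)
  expect_lt(abs(rm$se_log - rb$se_log), 1e-6)
})

test_that("multinomial fit reports one RRR per non-baseline category", {
  co <- generate_cohort(cohort_spec(500, seed = 12))
  d <- analysis_table(co$features, co$outcomes)
  r <- suppressMessages(suppressWarnings(fit_multinomial(d, "four_category", "A2")))
  expect_true(all(r$category %in% c("EBF-only", "SBF-only", "both")))
  expect_true(all(r$ci_low <= r$estimate & r$estimate <= r$ci_high))
  expect_true(all(r$estimate > 0))
  # planted effect: larger A2 with sarcopenia-based frailty
  expect_gt(r$estimate[r$category == "SBF-only"], 1)
})

test_that("exposure rescaling transforms the log coefficient exactly", {
  co <- generate_cohort(cohort_spec(600, seed = 15))
  d <- analysis_table(co$features, co$outcomes)
  r1 <- suppressMessages(fit_binomial(d, "sbf_frail", "A2"))
  d2 <- d; d2$A2 <- d2$A2 / 10
  r2 <- suppressMessages(fit_binomial(d2, "sbf_frail", "A2"))
  expect_equal(log(r2$estimate), 10 * log(r1$estimate), tolerance = 1e-6)
  # standardize_exposure reports the per-SD effect
  rs <- suppressMessages(fit_binomial(d, "sbf_frail", "A2",
                                      standardize_exposure = TRUE))
  expect_equal(log(rs$estimate), sd(d$A2[!is.na(d$A2)]) * log(r1$estimate),
               tolerance = 1e-6)
})

test_that("predicted multinomial probabilities sum to one", {
  odds <- matrix(c(0.5, 2, 0.1, 1, 3, 0.2), nrow = 2, byrow = TRUE)
  pr <- multinomial_probabilities(odds)
  expect_equal(rowSums(pr), c(1, 1))
  expect_true(all(pr > 0 & pr < 1))
  expect_error(multinomial_probabilities(matrix(-1)), ">= 0")
})

test_that("rows with indeterminate outcome or missing exposure are excluded", {
  d <- table2x2_data(20, 80, 10, 90)
  d$case[1:5] <- NA
  d$exposed[6:7] <- NA
  expect_message(r <- fit_binomial(d, "case", "exposed"), "excluded 7")
  expect_equal(r$n_used, 193L)
})
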