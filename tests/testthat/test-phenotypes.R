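test_that("scored statuses match a brute-force enumerator on all 64 combos", {
  grid <- expand.grid(w = 0:1, e = 0:1, c_ = 0:1, g = 0:1, wk = 0:1, a = 0:1)
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    rec <- record_for_combo(gr$w, gr$e, gr$c_, gr$g, gr$wk, gr$a)
    truth <- brute_force_phenotype(gr$w, gr$e, gr$c_, gr$g, gr$wk, gr$a)
    res <- score_phenotypes(rec)
    expect_equal(res$ebf_criteria_met, truth$ebf_met)
    expect_equal(as.character(res$ebf_status), truth$ebf)
    expect_equal(res$sbf_criteria_met, truth$sbf_met)
    expect_equal(as.character(res$sbf_status), truth$sbf)
    expect_equal(res$hbf_e, truth$hbf_e)
    expect_equal(res$hbf_s, truth$hbf_s)
    expect_equal(as.character(res$four_category), truth$four)
  }
})

test_that("cutoff boundaries follow the recorded strictness conventions", {
  # weight loss: 4.5 kg inclusive, 5% strict
  expect_equal(score_ebf(4.5, 4, FALSE)$criteria_met, 1L)
  expect_equal(score_ebf(4.4, 5, FALSE)$criteria_met, 0L)
  expect_equal(score_ebf(4.4, 5.01, FALSE)$criteria_met, 1L)
  expect_equal(as.character(score_ebf(5, NA, TRUE)$status), "frail")
  # grip cutoffs strict: 28 kg (men) / 18 kg (women) are not yet low
  ok <- score_sbf(c("male", "female"), FALSE, c(28, 18), 1.2, FALSE, FALSE)
  expect_equal(ok$criteria_met, c(0L, 0L))
  low <- score_sbf(c("male", "female"), FALSE, c(27.9, 17.9), 1.2, FALSE, FALSE)
  expect_equal(low$criteria_met, c(1L, 1L))
  # gait strict below 1.0 m/s
  expect_equal(score_sbf("male", FALSE, 30, 1.0, FALSE, FALSE)$criteria_met, 0L)
  expect_equal(score_sbf("male", FALSE, 30, 0.999, FALSE, FALSE)$criteria_met, 1L)
})

test_that("non-ambulatory subjects count as low mobility without a gait value", {
  r <- score_sbf("female", FALSE, 25, NA, TRUE, FALSE)
  expect_equal(r$criteria_met, 1L)
  expect_equal(as.character(r$status), "prefrail")
})

test_that("missing required items yield indeterminate statuses", {
  expect_true(is.na(score_ebf(NA, NA, TRUE)$status))
  expect_true(is.na(score_ebf(2, NA, FALSE)$status))  # weight loss unresolvable
  expect_false(is.na(score_ebf(5, NA, FALSE)$status)) # kg alone settles it
  expect_true(is.na(score_sbf("male", FALSE, NA, 1.2, FALSE, FALSE)$status))
  hy <- derive_hybrids(factor(NA, levels = c("robust", "prefrail", "frail")),
                       factor("frail", levels = c("robust", "prefrail", "frail")))
  expect_true(is.na(hy$hbf_e) && is.na(hy$four_category))
})

test_that("hybrid rules and the four-category outcome are consistent", {
  ebf <- rep(c("robust", "prefrail", "frail"), each = 3)
  sbf <- rep(c("robust", "prefrail", "frail"), times = 3)
  hy <- derive_hybrids(ebf, sbf)
  expect_equal(hy$hbf_e, ebf == "frail" & sbf != "robust")
  expect_equal(hy$hbf_s, sbf == "frail" & ebf != "robust")
  expect_equal(hy$hbf_e & hy$hbf_s, as.character(hy$four_category) == "both")
  expect_equal(as.character(hy$four_category[ebf == "frail" & sbf == "prefrail"]),
               "EBF-only")
  expect_equal(as.character(hy$four_category[1]), "nonfrail")
})

test_that("meeting an additional criterion never moves a status toward robust", {
  rank <- function(s) match(as.character(s), c("robust", "prefrail", "frail"))
  grid <- expand.grid(w = 0:1, e = 0:1, c_ = 0:1, g = 0:1, wk = 0:1, a = 0:1)
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    base <- score_phenotypes(record_for_combo(gr$w, gr$e, gr$c_, gr$g, gr$wk,
                                              gr$a))
    for (flag in c("w", "e", "c_", "g", "wk", "a")) {
      if (gr[[flag]] == 1) next
      gr2 <- gr; gr2[[flag]] <- 1
      more <- score_phenotypes(record_for_combo(gr2$w, gr2$e, gr2$c_, gr2$g,
                                                gr2$wk, gr2$a))
      expect_gte(rank(more$ebf_status), rank(base$ebf_status))
      expect_gte(rank(more$sbf_status), rank(base$sbf_status))
    }
  }
})
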