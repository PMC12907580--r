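mk_metrics <- function(trec_peak = 38.0, hr_peak = 115, plateau = 0.1,
                       tcr60 = 0.35, tcr120 = 0.35) {
  data.frame(trec_peak = trec_peak, hr_peak = hr_peak,
             plateau_delta = plateau, tcr_t60 = tcr60, tcr_t120 = tcr120)
}

test_that("the builtin registry carries the seven published criteria", {
  reg <- builtin_criteria()
  expect_length(reg, 7)
  expect_equal(reg$trec_385$thresholds, 38.5)
  expect_equal(reg$hr_150$thresholds, 150)
  expect_equal(reg$plateau_045$thresholds, 0.45)
  expect_equal(reg$tcr_t120$thresholds, 0.279)
  expect_equal(reg$tcr_t60$thresholds, 0.32)
  expect_equal(reg$schermann$thresholds, c(0.25, 120, 38.2))
  expect_identical(reg$pht$kind, "supplied")
})

test_that("criterion evaluation honours the printed comparators at the boundary", {
  reg <- builtin_criteria()
  expect_identical(evaluate_criterion(mk_metrics(trec_peak = 38.5),
                                      reg$trec_385), "HI")
  expect_identical(evaluate_criterion(mk_metrics(trec_peak = 38.49),
                                      reg$trec_385), "HT")
  expect_identical(evaluate_criterion(mk_metrics(tcr60 = 0.320),
                                      reg$tcr_t60), "HI")
  expect_identical(evaluate_criterion(mk_metrics(tcr60 = 0.321),
                                      reg$tcr_t60), "HT")
  # composite: tolerant only when every clause stays below its cut-off
  hot <- mk_metrics(trec_peak = 38.3, hr_peak = 125, plateau = 0.3)
  expect_identical(evaluate_criterion(hot, reg$schermann), "HI")
  # a single exceedance (here heart rate) already removes tolerant status
  expect_identical(evaluate_criterion(mk_metrics(trec_peak = 38.1,
                                                 hr_peak = 125,
                                                 plateau = 0.2),
                                      reg$schermann), "HI")
  # a metrics row strictly inside the tolerant region passes everything
  cool <- mk_metrics(trec_peak = 38.1, hr_peak = 119, plateau = 0.20)
  for (cr in reg) {
    if (cr$kind != "supplied") {
      expect_identical(evaluate_criterion(cool, cr), "HT")
    }
  }
  expect_error(evaluate_criterion(cool, reg$pht), "supplied")
  expect_error(evaluate_criterion(data.frame(trec_peak = 38), reg$hr_150),
               "hr_peak")
})

test_that("classification of a handcrafted cohort reproduces the expected grid", {
  metrics <- data.frame(
    participant_id = c("P1", "P1", "P2", "P2"),
    timepoint = rep(c("PreHA", "PostHA"), 2),
    sex = c("F", "F", "M", "M"),
    trec_peak = c(38.6, 38.1, 38.3, 38.0),
    hr_peak = c(155, 125, 118, 110),
    plateau_delta = c(0.5, 0.2, 0.3, 0.1),
    tcr_t60 = c(0.25, 0.33, 0.34, 0.36),
    tcr_t120 = c(0.25, 0.30, 0.33, 0.35),
    stringsAsFactors = FALSE
  )
  pht <- data.frame(participant_id = rep(c("P1", "P2"), each = 2),
                    timepoint = rep(c("PreHA", "PostHA"), 2),
                    criterion = "pht",
                    label = c("HI", "BHT", "HT", "HT"),
                    stringsAsFactors = FALSE)
  cls <- classify_cohort(metrics, pht)
  expect_setequal(unique(cls$criterion), names(builtin_criteria()))
  lab <- function(id, tp, cr) {
    cls$label[cls$participant_id == id & cls$timepoint == tp &
                cls$criterion == cr]
  }
  expect_identical(lab("P1", "PreHA", "trec_385"), "HI")
  expect_identical(lab("P1", "PreHA", "hr_150"), "HI")
  expect_identical(lab("P1", "PreHA", "plateau_045"), "HI")
  expect_identical(lab("P1", "PreHA", "tcr_t60"), "HI")
  expect_identical(lab("P1", "PreHA", "schermann"), "HI")
  expect_identical(lab("P2", "PreHA", "trec_385"), "HT")
  expect_identical(lab("P2", "PreHA", "schermann"), "HI") # 38.3 >= 38.2
  expect_identical(lab("P2", "PostHA", "schermann"), "HT") # all below
  expect_identical(lab("P1", "PostHA", "pht"), "BHT")
  expect_identical(unique(cls$provenance[cls$criterion == "pht"]),
                   "supplied")

  # borderline labels merge into the intolerant class by default
  r <- hi_rates(cls, by = c("criterion", "timepoint"))
  expect_equal(r$pct_hi[r$criterion == "pht" & r$timepoint == "PostHA"], 50)
  r2 <- hi_rates(cls, by = c("criterion", "timepoint"), bht_as_hi = FALSE)
  expect_equal(r2$pct_hi[r2$criterion == "pht" & r2$timepoint == "PostHA"], 0)

  # duplicated supplied entries are rejected
  expect_error(classify_cohort(metrics, rbind(pht, pht[1, ])), "duplicate")
  # incomplete supplied coverage drops the criterion with a warning
  expect_warning(cls6 <- classify_cohort(metrics, pht[1:3, ]), "dropped")
  expect_false("pht" %in% cls6$criterion)
  expect_warning(cls0 <- classify_cohort(metrics, NULL), "dropped")
  expect_length(unique(cls0$criterion), 6)
})

test_that("rate arithmetic matches the printed examples and an all-tolerant cohort gives 0", {
  cls <- data.frame(participant_id = sprintf("P%02d", 1:40),
                    timepoint = "PreHA", criterion = "plateau_045",
                    label = c(rep("HI", 6), rep("HT", 34)),
                    stringsAsFactors = FALSE)
  r <- hi_rates(cls, by = "criterion")
  expect_equal(r$pct_hi, 15.0)
  cls$label <- c(rep("HI", 36), rep("HT", 4))
  expect_equal(hi_rates(cls, by = "criterion")$pct_hi, 90.0)
  cls$label <- "HT"
  expect_equal(hi_rates(cls, by = "criterion")$pct_hi, 0)
})

test_that("raising a >= threshold (or lowering a <= threshold) never adds intolerant labels", {
  set.seed(21)
  metrics <- data.frame(trec_peak = stats::runif(50, 37.8, 39.2),
                        hr_peak = stats::runif(50, 100, 180),
                        tcr_t60 = stats::runif(50, 0.25, 0.40))
  count_hi <- function(cr) {
    sum(vapply(seq_len(nrow(metrics)), function(i) {
      evaluate_criterion(metrics[i, ], cr)
    }, character(1)) == "HI")
  }
  ge_counts <- vapply(seq(38.0, 39.4, 0.2), function(th) {
    count_hi(heattol:::new_criterion("t", "threshold_ge", "trec_peak", th))
  }, numeric(1))
  expect_true(all(diff(ge_counts) <= 0))
  le_counts <- vapply(seq(0.40, 0.24, -0.04), function(th) {
    count_hi(heattol:::new_criterion("t", "threshold_le", "tcr_t60", th))
  }, numeric(1))
  expect_true(all(diff(le_counts) <= 0))
})

test_that("the experimental sex-adjusted registry is separate and flagged", {
  reg <- sex_adjusted_criteria()
  expect_length(reg, 2)
  expect_equal(reg$trec_387$thresholds, 38.7)
  expect_equal(reg$hr_170$thresholds, 170)
  expect_match(reg$trec_387$source, "unvalidated")
})
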