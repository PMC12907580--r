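test_that("trajectory kinetics solve the printed endpoint triples", {
  k <- solve_trec_kinetics(36.98, 38.12, 38.41)
  expect_equal(k$tau, 43.8, tolerance = 1e-2)
  expect_equal(k$deq, 1.53, tolerance = 1e-2)
  # forward simulation recovers the inputs
  expect_equal(trec_trajectory(60, 36.98, k$deq, k$tau), 38.12)
  expect_equal(trec_trajectory(120, 36.98, k$deq, k$tau), 38.41)
  # implied final-hour rise deq * (x - x^2)
  x <- exp(-60 / k$tau)
  expect_equal(k$deq * (x - x^2), 38.41 - 38.12)

  # fully plateaued by 60 min: tau collapses to the step limit
  k0 <- solve_trec_kinetics(37, 38.2, 38.2)
  expect_equal(k0$tau, 0)
  expect_equal(trec_trajectory(c(0, 60, 120), 37, k0$deq, k0$tau),
               c(37, 38.2, 38.2))
  expect_error(solve_trec_kinetics(37, 37.5, 38.6), "< 2")
  expect_error(solve_trec_kinetics(37, 37, 38), "exceed")

  h <- solve_hr_kinetics(96, 143, 149)
  expect_equal(hr_trajectory(c(0, 60, 120), 96, h$fast, h$drift),
               c(96, 143, 149))
})

test_that("default parameters reproduce the printed cell means exactly in the noise-free model", {
  p <- default_params()
  targets <- list(
    F_PreHA = c(37.09, 38.29, 38.50, 96, 143, 149),
    M_PreHA = c(36.86, 37.94, 38.31, 82, 117, 126),
    F_PostHA = c(36.92, 37.97, 38.13, 89, 122, 125),
    M_PostHA = c(36.73, 37.75, 37.97, 85, 105, 109)
  )
  for (sex in c("F", "M")) {
    for (tp in c("PreHA", "PostHA")) {
      cell <- p$cells[[sex]][[tp]]
      t0 <- cell$trec_baseline_mean + cell$trec_t0_offset
      tr <- trec_trajectory(c(0, 60, 120), t0, cell$trec_deq_mean,
                            cell$trec_tau_mean)
      hr <- hr_trajectory(c(0, 60, 120), cell$hr_t0_mean, cell$hr_fast_mean,
                          cell$hr_drift_mean, p$hr_tau)
      expect_equal(c(tr, hr), targets[[paste(sex, tp, sep = "_")]],
                   tolerance = 1e-8)
    }
  }
})

test_that("generation is deterministic in the seed and respects counts", {
  p <- default_params()
  a <- generate_cohort(4, 3, p, seed = 101)
  b <- generate_cohort(4, 3, p, seed = 101)
  expect_identical(a, b)
  c2 <- generate_cohort(4, 3, p, seed = 102)
  expect_false(identical(a$sessions$trec_c, c2$sessions$trec_c))

  expect_equal(nrow(a$participants), 7)
  expect_equal(table(a$participants$sex)[["F"]], 4)
  expect_equal(nrow(a$meta), 14)
  expect_equal(nrow(a$sessions), 14 * 25)

  empty <- generate_cohort(0, 0, p, seed = 1)
  expect_equal(nrow(empty$participants), 0)
  expect_equal(nrow(empty$sessions), 0)
  expect_error(generate_cohort(-1, 0, p, seed = 1), ">= 0")
})

test_that("noise-free temperature trajectories are non-decreasing", {
  p <- default_params()
  p$noise$trec <- 0
  p$noise$hr <- 0
  co <- generate_cohort(10, 10, p, seed = 3)
  for (k in split(co$sessions, paste(co$sessions$participant_id,
                                     co$sessions$timepoint))) {
    expect_true(all(diff(k$trec_c[order(k$t_min)]) >= -1e-12))
  }
})

test_that("pre/post correlation rho = 1 shares subject effects exactly, rho = 0 decouples them", {
  p <- default_params()
  p$noise$trec <- 0
  p$rho <- 1
  co <- generate_cohort(60, 0, p, seed = 17)
  m <- co$meta
  cell_pre <- p$cells$F$PreHA
  cell_post <- p$cells$F$PostHA
  z_pre <- (m$baseline_trec_c[m$timepoint == "PreHA"] -
              cell_pre$trec_baseline_mean) / cell_pre$trec_baseline_sd
  z_post <- (m$baseline_trec_c[m$timepoint == "PostHA"] -
               cell_post$trec_baseline_mean) / cell_post$trec_baseline_sd
  expect_equal(z_pre, z_post, tolerance = 1e-10)

  p$rho <- 0
  co0 <- generate_cohort(600, 0, p, seed = 18)
  m0 <- co0$meta
  z0_pre <- (m0$baseline_trec_c[m0$timepoint == "PreHA"] -
               cell_pre$trec_baseline_mean) / cell_pre$trec_baseline_sd
  z0_post <- (m0$baseline_trec_c[m0$timepoint == "PostHA"] -
                cell_post$trec_baseline_mean) / cell_post$trec_baseline_sd
  expect_lt(abs(stats::cor(z0_pre, z0_post)), 0.1)
})

test_that("large-cohort sample means recover the calibration targets", {
  # 5000 per sex; simultaneous check over 4 cells x 7 endpoint means with a
  # Bonferroni-adjusted 3-SE bound (28 comparisons; a per-comparison 2-SE
  # bound would falsely trip a correctly calibrated generator about half the
  # time).
  p <- default_params()
  co <- generate_cohort(5000, 5000, p, seed = 19)
  s <- co$sessions
  sx <- co$participants$sex[match(s$participant_id, co$participants$id)]
  m <- co$meta
  msx <- co$participants$sex[match(m$participant_id, co$participants$id)]
  for (sex in c("F", "M")) {
    for (tp in c("PreHA", "PostHA")) {
      cell <- p$cells[[sex]][[tp]]
      d <- s[sx == sex & s$timepoint == tp, ]
      t0 <- cell$trec_baseline_mean + cell$trec_t0_offset
      tr_t <- trec_trajectory(c(0, 60, 120), t0, cell$trec_deq_mean,
                              cell$trec_tau_mean)
      hr_t <- hr_trajectory(c(0, 60, 120), cell$hr_t0_mean,
                            cell$hr_fast_mean, cell$hr_drift_mean, p$hr_tau)
      base <- m$baseline_trec_c[msx == sex & m$timepoint == tp]
      checks <- rbind(
        c(mean(base), cell$trec_baseline_mean, stats::sd(base)),
        t(vapply(1:3, function(j) {
          v <- d$trec_c[d$t_min == c(0, 60, 120)[j]]
          c(mean(v), tr_t[j], stats::sd(v))
        }, numeric(3))),
        t(vapply(1:3, function(j) {
          v <- d$hr_bpm[d$t_min == c(0, 60, 120)[j]]
          c(mean(v), hr_t[j], stats::sd(v))
        }, numeric(3)))
      )
      z <- abs(checks[, 1] - checks[, 2]) / (checks[, 3] / sqrt(5000))
      expect_true(all(z < 3), label = paste("cell", sex, tp))
    }
  }
  # anthropometric means likewise
  for (sex in c("F", "M")) {
    an <- p$anthro[[sex]]
    pp <- co$participants[co$participants$sex == sex, ]
    for (v in names(an)) {
      se <- stats::sd(pp[[v]]) / sqrt(nrow(pp))
      expect_lt(abs(mean(pp[[v]]) - an[[v]][1]), 3 * se)
    }
  }
})

test_that("cohorts round-trip through CSV and violations are reported by name", {
  p <- default_params()
  co <- generate_cohort(1, 1, p, seed = 55)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$participants, co$participants)
  expect_equal(back$sessions, co$sessions)
  expect_equal(back$meta, co$meta)

  # non-monotone times name the offending participant and timepoint
  bad <- co
  i <- which(bad$sessions$participant_id == "M0001" &
               bad$sessions$timepoint == "PostHA")
  bad$sessions$t_min[i[2]] <- 0
  dir2 <- withr::local_tempdir()
  write_cohort(bad, dir2)
  expect_error(read_cohort(dir2), "M0001.*PostHA")

  # a missing post-acclimation session is readable but flagged incomplete
  partial <- co
  drop <- partial$sessions$participant_id == "F0001" &
    partial$sessions$timepoint == "PostHA"
  partial$sessions <- partial$sessions[!drop, ]
  dir3 <- withr::local_tempdir()
  write_cohort(partial, dir3)
  expect_message(got <- read_cohort(dir3), "incomplete")
  expect_identical(attr(got, "incomplete"), "F0001")

  # missing columns are named
  unlink(file.path(dir3, "sessions.csv"))
  utils::write.csv(data.frame(participant_id = "x", timepoint = "PreHA"),
                   file.path(dir3, "sessions.csv"), row.names = FALSE)
  expect_error(read_cohort(dir3), "t_min")
})
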