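# Published sex- and timepoint-specific calibration targets. Temperature and
# heart-rate entries are group means (SDs in *_sd) at the pre-exercise
# baseline, exercise start (T0), 60 and 120 min. Anthropometrics are the
# cohort descriptive table (21 females, 19 males, well-trained adults).
calibration_targets <- function() {
  cells <- expand.grid(sex = c("F", "M"), timepoint = c("PreHA", "PostHA"),
                       stringsAsFactors = FALSE)
  trec <- data.frame(
    sex = c("F", "M", "F", "M"),
    timepoint = c("PreHA", "PreHA", "PostHA", "PostHA"),
    baseline = c(37.01, 36.82, 36.88, 36.71),
    baseline_sd = c(0.31, 0.38, 0.46, 0.31),
    t0 = c(37.09, 36.86, 36.92, 36.73),
    t0_sd = c(0.35, 0.39, 0.45, 0.32),
    t60 = c(38.29, 37.94, 37.97, 37.75),
    t60_sd = c(0.35, 0.45, 0.46, 0.33),
    t120 = c(38.50, 38.31, 38.13, 37.97),
    t120_sd = c(0.37, 0.56, 0.46, 0.39)
  )
  hr <- data.frame(
    sex = c("F", "M", "F", "M"),
    timepoint = c("PreHA", "PreHA", "PostHA", "PostHA"),
    t0 = c(96, 82, 89, 85),
    t0_sd = c(17, 10, 18, 10),
    t60 = c(143, 117, 122, 105),
    t60_sd = c(19, 16, 20, 13),
    t120 = c(149, 126, 125, 109),
    t120_sd = c(22, 21, 16, 14)
  )
  rel_intensity <- data.frame(
    sex = c("F", "M", "F", "M"),
    timepoint = c("PreHA", "PreHA", "PostHA", "PostHA"),
    mean = c(40.74, 34.60, 37.30, 33.89),
    sd = c(6.46, 4.63, 6.56, 5.44)
  )
  anthro <- list(
    F = list(age = c(24.0, 3.7), height_cm = c(164.1, 5.7),
             mass_kg = c(59.5, 5.4), lean_mass_kg = c(41.9, 4.5),
             fat_pct = c(25.8, 4.8), vo2max = c(44.5, 5.1),
             vvo2max = c(12.9, 1.5), resting_hr = c(80, 14)),
    M = list(age = c(22.3, 3.3), height_cm = c(179.0, 7.6),
             mass_kg = c(79.5, 10.1), lean_mass_kg = c(65.3, 7.0),
             fat_pct = c(15.7, 5.3), vo2max = c(51.4, 5.7),
             vvo2max = c(15.0, 1.7), resting_hr = c(70, 11))
  )
  env <- list(
    PreHA = list(ambient = c(39.11, 0.86), rh = c(40.58, 3.72),
                 wbgt = c(31.65, 1.57)),
    PostHA = list(ambient = c(39.44, 0.88), rh = c(39.67, 5.78),
                  wbgt = c(31.65, 0.95))
  )
  # Sweat rate per unit body surface area (L/h/m2) by sex; the published
  # values come from the acclimation sessions and serve as synthetic stand-in
  # defaults for the HTT sessions, which have no printed sweat statistics.
  sweat <- list(F = c(0.58, 0.14), M = c(0.75, 0.17))
  list(cells = cells, trec = trec, hr = hr, rel_intensity = rel_intensity,
       anthro = anthro, env = env, sweat = sweat)
}

#' Default synthetic-cohort generator parameters
#'
#' Builds the full parameter set of the cohort generator, calibrated so that
#' the implied population means of baseline temperature, temperature at
#' exercise start / 60 / 120 min, and heart rate at the same time points
#' equal the published group means in every sex-by-timepoint cell. Trajectory
#' kinetics are solved per cell with [solve_trec_kinetics()] and
#' [solve_hr_kinetics()]; between-subject spread is attributed to the
#' starting level and the rise magnitude (temperature) or the level, fast
#' component and drift (heart rate), with component SDs solved from the
#' published endpoint SDs (clamped at zero where those are non-monotone).
#'
#' By default the temperature time constant does not vary between subjects
#' (`trec_tau_sd = 0`): the printed endpoints cannot identify both a
#' magnitude and a kinetic variance component, and a random time constant
#' enters the model nonlinearly, biasing the implied endpoint means. Setting
#' `trec_tau_sd > 0` draws subject time constants from a log-normal
#' distribution (median at the cell value).
#'
#' @return An object of class `htt_params`: a list with per-cell trajectory
#'   parameters (`cells`), per-sex anthropometric distributions (`anthro`),
#'   sweat/hydration, oxygen-uptake and environment settings, the
#'   within-subject pre/post correlation `rho` (default 0.6), measurement
#'   noise SDs (`noise`: 0.05 degrees C and 2 bpm per sample) and physiologic
#'   truncation limits.
#' @examples
#' p <- default_params()
#' p$cells$F$PreHA$trec_tau_mean
#' @export
default_params <- function() {
  tg <- calibration_targets()
  cells <- list(F = list(), M = list())
  for (i in seq_len(nrow(tg$cells))) {
    sex <- tg$cells$sex[i]
    tp <- tg$cells$timepoint[i]
    tr <- tg$trec[tg$trec$sex == sex & tg$trec$timepoint == tp, ]
    hr <- tg$hr[tg$hr$sex == sex & tg$hr$timepoint == tp, ]
    ri <- tg$rel_intensity[tg$rel_intensity$sex == sex &
                             tg$rel_intensity$timepoint == tp, ]
    kin <- solve_trec_kinetics(tr$t0, tr$t60, tr$t120)
    x120 <- if (kin$tau > 0) exp(-120 / kin$tau) else 0
    deq_sd <- sqrt(max(tr$t120_sd^2 - tr$t0_sd^2, 0)) / (1 - x120)
    hk <- solve_hr_kinetics(hr$t0, hr$t60, hr$t120)
    va <- max(hr$t60_sd^2 - hr$t0_sd^2, 0)
    vb <- max(hr$t120_sd^2 - hr$t0_sd^2, 0)
    v_drift <- max((vb - va) / 10800, 0)
    v_fast <- max(va - 3600 * v_drift, 0)
    cells[[sex]][[tp]] <- list(
      trec_baseline_mean = tr$baseline, trec_baseline_sd = tr$baseline_sd,
      trec_t0_offset = tr$t0 - tr$baseline,
      trec_deq_mean = kin$deq, trec_deq_sd = deq_sd,
      trec_tau_mean = kin$tau, trec_tau_sd = 0,
      hr_t0_mean = hr$t0, hr_t0_sd = hr$t0_sd,
      hr_fast_mean = hk$fast, hr_fast_sd = sqrt(v_fast),
      hr_drift_mean = hk$drift, hr_drift_sd = sqrt(v_drift),
      rel_intensity_mean = ri$mean, rel_intensity_sd = ri$sd
    )
  }
  structure(list(
    cells = cells,
    anthro = tg$anthro,
    sweat = tg$sweat,
    env = tg$env,
    hydration = list(usg_mean = 1.012, usg_sd = 0.005,
                     fluid_l = 0.5, urine_mean = 0.10, urine_sd = 0.05),
    vo2 = list(rer_mean = 0.85, rer_sd = 0.03, sample_sd = 0.03),
    rho = 0.6,
    hr_tau = 10,
    noise = list(trec = 0.05, hr = 2),
    limits = list(trec = c(35.5, 41), hr = c(40, 220)),
    grid = seq(0, 120, by = 5),
    duration = 120
  ), class = "htt_params")
}

validate_params <- function(params) {
  stopifnot(inherits(params, "htt_params"))
  for (sex in c("F", "M")) {
    for (tp in c("PreHA", "PostHA")) {
      cell <- params$cells[[sex]][[tp]]
      if (is.null(cell)) {
        stop(sprintf("params missing cell %s/%s", sex, tp), call. = FALSE)
      }
      sds <- c(cell$trec_baseline_sd, cell$trec_deq_sd, cell$trec_tau_sd,
               cell$hr_t0_sd, cell$hr_fast_sd, cell$hr_drift_sd,
               cell$rel_intensity_sd)
      if (any(sds < 0)) {
        stop(sprintf("negative SD in cell %s/%s", sex, tp), call. = FALSE)
      }
      if (cell$trec_tau_mean < 0) {
        stop(sprintf("negative tau in cell %s/%s", sex, tp), call. = FALSE)
      }
    }
  }
  if (params$rho < 0 || params$rho > 1) {
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  }
  if (params$noise$trec < 0 || params$noise$hr < 0) {
    stop("measurement noise SDs must be >= 0", call. = FALSE)
  }
  invisible(params)
}
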