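# Latent subject effects, in a fixed order. Each is a standard normal scaled
# by the corresponding cell SD; pre/post values share correlation rho.
.latents <- c("base", "deq", "tau", "h0", "fast", "drift", "ri", "sweat")

# Map a latent z-vector to one session's subject-level parameters.
cell_draw <- function(cell, z) {
  tau <- if (cell$trec_tau_sd > 0) {
    # log-normal, median at the cell value, CV from trec_tau_sd / mean
    sdlog <- sqrt(log1p((cell$trec_tau_sd / cell$trec_tau_mean)^2))
    exp(log(cell$trec_tau_mean) + sdlog * z[["tau"]])
  } else {
    cell$trec_tau_mean
  }
  baseline <- cell$trec_baseline_mean + cell$trec_baseline_sd * z[["base"]]
  list(
    baseline = baseline,
    t0 = baseline + cell$trec_t0_offset,
    deq = cell$trec_deq_mean + cell$trec_deq_sd * z[["deq"]],
    tau = tau,
    h0 = cell$hr_t0_mean + cell$hr_t0_sd * z[["h0"]],
    fast = cell$hr_fast_mean + cell$hr_fast_sd * z[["fast"]],
    drift = cell$hr_drift_mean + cell$hr_drift_sd * z[["drift"]],
    ri = cell$rel_intensity_mean + cell$rel_intensity_sd * z[["ri"]]
  )
}

# Physiologic admissibility of a noise-free session draw.
draw_ok <- function(d, limits) {
  trec_end <- d$t0 + d$deq * (1 - if (d$tau > 0) exp(-120 / d$tau) else 0)
  hr_end <- d$h0 + d$fast + d$drift * 120
  d$deq > 0 &&
    d$t0 >= limits$trec[1] && d$t0 + d$deq <= limits$trec[2] &&
    trec_end <= limits$trec[2] &&
    d$h0 >= limits$hr[1] && d$h0 <= limits$hr[2] &&
    hr_end >= limits$hr[1] && hr_end <= limits$hr[2] &&
    d$ri > 5
}

#' Generate a seeded synthetic HTT cohort
#'
#' Draws participants with sex-specific anthropometrics and, for each, a
#' pre-acclimation and a post-acclimation heat tolerance test session.
#' Temperature follows a mono-exponential rise to plateau and heart rate a
#' fast on-kinetics plus drift model, with per-cell parameters calibrated to
#' the published sex-by-timepoint group means (see [default_params()]).
#' Subject-level effects are shared across the two timepoints with
#' correlation `params$rho`; series are sampled on a 5-min grid over
#' 0--120 min with additive measurement noise. Draws producing temperatures
#' outside 35.5--41 degrees C or heart rates outside 40--220 bpm are
#' resampled.
#'
#' @param n_female,n_male Number of participants per sex (>= 0).
#' @param params An `htt_params` object, see [default_params()].
#' @param seed Integer seed; identical inputs give bit-identical cohorts.
#' @return An object of class `htt_cohort`: a list of three data frames,
#'   `participants` (one row per participant), `sessions` (long-format
#'   temperature/heart-rate samples) and `meta` (per-session baseline,
#'   sweat/hydration, oxygen uptake and environment records).
#' @examples
#' cohort <- generate_cohort(3, 3, default_params(), seed = 1)
#' head(cohort$sessions)
#' @export
generate_cohort <- function(n_female, n_male, params = default_params(),
                            seed) {
  if (n_female < 0 || n_male < 0) {
    stop("participant counts must be >= 0", call. = FALSE)
  }
  validate_params(params)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))

  np <- n_female + n_male
  sexes <- rep(c("F", "M"), c(n_female, n_male))
  ids <- c(sprintf("F%04d", seq_len(n_female)),
           sprintf("M%04d", seq_len(n_male)))
  grid <- params$grid
  ng <- length(grid)
  tps <- c("PreHA", "PostHA")

  participants <- data.frame(
    id = character(np), sex = sexes, age = numeric(np),
    height_cm = numeric(np), mass_kg = numeric(np),
    lean_mass_kg = numeric(np), fat_pct = numeric(np),
    vo2max = numeric(np), vvo2max = numeric(np), resting_hr = numeric(np),
    stringsAsFactors = FALSE
  )
  participants$id <- ids

  meta_n <- np * 2L
  meta <- data.frame(
    participant_id = rep(ids, each = 2L),
    timepoint = rep(tps, times = np),
    baseline_trec_c = numeric(meta_n), mass_pre_kg = numeric(meta_n),
    mass_post_kg = numeric(meta_n), fluid_l = numeric(meta_n),
    urine_l = numeric(meta_n), usg = numeric(meta_n),
    ambient_c = numeric(meta_n), rh_pct = numeric(meta_n),
    wbgt_c = numeric(meta_n), vo2_30_lmin = numeric(meta_n),
    rer_30 = numeric(meta_n), vo2_90_lmin = numeric(meta_n),
    rer_90 = numeric(meta_n), stringsAsFactors = FALSE
  )

  ns <- meta_n * ng
  sessions <- data.frame(
    participant_id = rep(ids, each = 2L * ng),
    timepoint = rep(rep(tps, each = ng), times = np),
    t_min = rep(grid, times = meta_n),
    trec_c = numeric(ns), hr_bpm = numeric(ns), stringsAsFactors = FALSE
  )

  rho <- params$rho
  rho_c <- sqrt(1 - rho^2)
  nl <- length(.latents)

  for (i in seq_len(np)) {
    sex <- sexes[i]
    an <- params$anthro[[sex]]
    repeat {
      a <- vapply(an, function(ms) stats::rnorm(1, ms[1], ms[2]), numeric(1))
      if (a[["height_cm"]] > 0 && a[["mass_kg"]] > 0 &&
          a[["vo2max"]] > 0 && a[["vvo2max"]] > 0 &&
          a[["fat_pct"]] > 0 && a[["fat_pct"]] < 100 &&
          a[["lean_mass_kg"]] > 0 && a[["resting_hr"]] > 30) break
    }
    participants[i, names(an)] <- a[names(an)]
    bsa <- bsa_mosteller(a[["height_cm"]], a[["mass_kg"]])

    z <- stats::setNames(numeric(nl), .latents)
    for (tp_i in seq_along(tps)) {
      tp <- tps[tp_i]
      cell <- params$cells[[sex]][[tp]]
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tp_i == 1L) {
          z_tp <- stats::setNames(stats::rnorm(nl), .latents)
        } else {
          w <- stats::rnorm(nl)
          z_tp <- rho * z + rho_c * w
        }
        d <- cell_draw(cell, z_tp)
        sweat_ms <- params$sweat[[sex]]
        wbsr_bsa_i <- sweat_ms[1] + sweat_ms[2] * z_tp[["sweat"]]
        if ((draw_ok(d, params$limits) && wbsr_bsa_i > 0.05) ||
            tries > 200L) break
        if (rho >= 1 && tp_i == 2L) {
          stop("post-acclimation draw inadmissible with rho = 1",
               call. = FALSE)
        }
      }
      if (tp_i == 1L) z <- z_tp

      row <- (i - 1L) * 2L + tp_i
      trec <- trec_trajectory(grid, d$t0, d$deq, d$tau) +
        stats::rnorm(ng, 0, params$noise$trec)
      hr <- hr_trajectory(grid, d$h0, d$fast, d$drift, params$hr_tau) +
        stats::rnorm(ng, 0, params$noise$hr)
      idx <- ((row - 1L) * ng + 1L):(row * ng)
      sessions$trec_c[idx] <- trec
      sessions$hr_bpm[idx] <- hr

      wbsl_i <- wbsr_bsa_i * bsa * (params$duration / 60)
      urine <- max(stats::rnorm(1, params$hydration$urine_mean,
                                params$hydration$urine_sd), 0)
      usg <- min(max(stats::rnorm(1, params$hydration$usg_mean,
                                  params$hydration$usg_sd), 1.000), 1.060)
      vo2_l <- d$ri / 100 * a[["vo2max"]] * a[["mass_kg"]] / 1000
      env <- params$env[[tp]]
      meta$baseline_trec_c[row] <- d$baseline
      meta$mass_pre_kg[row] <- a[["mass_kg"]]
      meta$mass_post_kg[row] <- a[["mass_kg"]] - wbsl_i +
        params$hydration$fluid_l - urine
      meta$fluid_l[row] <- params$hydration$fluid_l
      meta$urine_l[row] <- urine
      meta$usg[row] <- usg
      meta$ambient_c[row] <- stats::rnorm(1, env$ambient[1], env$ambient[2])
      meta$rh_pct[row] <- stats::rnorm(1, env$rh[1], env$rh[2])
      meta$wbgt_c[row] <- stats::rnorm(1, env$wbgt[1], env$wbgt[2])
      meta$vo2_30_lmin[row] <- vo2_l + stats::rnorm(1, 0, params$vo2$sample_sd)
      meta$rer_30[row] <- stats::rnorm(1, params$vo2$rer_mean,
                                       params$vo2$rer_sd)
      meta$vo2_90_lmin[row] <- vo2_l + stats::rnorm(1, 0, params$vo2$sample_sd)
      meta$rer_90[row] <- stats::rnorm(1, params$vo2$rer_mean,
                                       params$vo2$rer_sd)
    }
  }

  structure(list(participants = participants, sessions = sessions,
                 meta = meta), class = "htt_cohort")
}

#' Extract one session from a cohort
#'
#' @param cohort An `htt_cohort`.
#' @param participant_id Participant identifier.
#' @param timepoint `"PreHA"` or `"PostHA"`.
#' @return A session list with `trec_series` and `hr_series` (`htt_ts`),
#'   `baseline_trec`, `duration` and all per-session metadata fields.
#' @export
get_session <- function(cohort, participant_id, timepoint) {
  stopifnot(inherits(cohort, "htt_cohort"))
  s <- cohort$sessions[cohort$sessions$participant_id == participant_id &
                         cohort$sessions$timepoint == timepoint, ]
  m <- cohort$meta[cohort$meta$participant_id == participant_id &
                     cohort$meta$timepoint == timepoint, ]
  if (nrow(s) == 0L || nrow(m) != 1L) {
    stop(sprintf("no session for participant %s at %s", participant_id,
                 timepoint), call. = FALSE)
  }
  s <- s[order(s$t_min), ]
  c(list(participant_id = participant_id, timepoint = timepoint,
         trec_series = time_series(s$t_min, s$trec_c, max_gap = 10),
         hr_series = time_series(s$t_min, s$hr_bpm, max_gap = 10),
         baseline_trec = m$baseline_trec_c,
         duration = diff(range(s$t_min))),
    as.list(m[setdiff(names(m), c("participant_id", "timepoint",
                                  "baseline_trec_c"))]))
}

#' Write a cohort to CSV files
#'
#' Writes `participants.csv`, `sessions.csv` (long format: one row per
#' sample) and `session_meta.csv` into `path`.
#'
#' @param cohort An `htt_cohort`.
#' @param path Directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "htt_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$participants, file.path(path, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$sessions, file.path(path, "sessions.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$meta, file.path(path, "session_meta.csv"),
                   row.names = FALSE)
  invisible(path)
}

.cohort_schema <- list(
  participants = c("id", "sex", "age", "height_cm", "mass_kg",
                   "lean_mass_kg", "fat_pct", "vo2max", "vvo2max",
                   "resting_hr"),
  sessions = c("participant_id", "timepoint", "t_min", "trec_c", "hr_bpm"),
  session_meta = c("participant_id", "timepoint", "baseline_trec_c",
                   "mass_pre_kg", "mass_post_kg", "fluid_l", "urine_l",
                   "usg", "ambient_c", "rh_pct", "wbgt_c", "vo2_30_lmin",
                   "rer_30", "vo2_90_lmin", "rer_90")
)

#' Read a cohort from CSV files
#'
#' Reads the three files written by [write_cohort()], validating the schema
#' (missing columns are reported field by field) and that sampling times are
#' strictly increasing within each session (violations are reported with
#' participant and timepoint). Participants missing one of the two timepoints
#' are readable but flagged: the returned cohort carries an `incomplete`
#' attribute listing them.
#'
#' @param path Directory containing `participants.csv`, `sessions.csv` and
#'   `session_meta.csv`.
#' @return An `htt_cohort`.
#' @export
read_cohort <- function(path) {
  files <- c(participants = "participants.csv", sessions = "sessions.csv",
             session_meta = "session_meta.csv")
  tabs <- list()
  for (nm in names(files)) {
    fp <- file.path(path, files[[nm]])
    if (!file.exists(fp)) stop(sprintf("missing file: %s", fp), call. = FALSE)
    tab <- utils::read.csv(fp, stringsAsFactors = FALSE)
    missing_cols <- setdiff(.cohort_schema[[nm]], names(tab))
    if (length(missing_cols)) {
      stop(sprintf("%s: missing column(s): %s", files[[nm]],
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    tabs[[nm]] <- tab
  }
  sess <- tabs$sessions
  key <- interaction(sess$participant_id, sess$timepoint, drop = TRUE)
  for (k in levels(key)) {
    t_k <- sess$t_min[key == k]
    if (any(diff(t_k) <= 0)) {
      bad <- sess[key == k, ][1, ]
      stop(sprintf(
        "non-monotone sampling times for participant %s, timepoint %s",
        bad$participant_id, bad$timepoint), call. = FALSE)
    }
  }
  cohort <- structure(list(participants = tabs$participants, sessions = sess,
                           meta = tabs$session_meta), class = "htt_cohort")
  have <- unique(sess[c("participant_id", "timepoint")])
  counts <- table(have$participant_id)
  incomplete <- names(counts)[counts < 2L]
  if (length(incomplete)) {
    message("incomplete cohort: missing sessions for ",
            paste(incomplete, collapse = ", "))
    attr(cohort, "incomplete") <- incomplete
  }
  cohort
}
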