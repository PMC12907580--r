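#' Derived metrics for every session in a cohort
#'
#' Runs [session_metrics()] on each (participant, timepoint) session and
#' appends the body-size, sweat, calorimetry and hydration columns: Mosteller
#' body surface area, whole-body sweat loss and rate (raw and per BSA), net
#' metabolic heat production (absolute and per BSA, from the mean of the two
#' in-test oxygen-uptake samples), relative exercise intensity and the
#' hydration screening label.
#'
#' @param cohort An `htt_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @return A `data.frame`, one row per (participant, timepoint), with
#'   `participant_id`, `timepoint`, `sex` and every derived-metric column.
#' @export
cohort_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "htt_cohort"))
  meta <- cohort$meta
  part <- cohort$participants
  sess <- cohort$sessions
  key_s <- paste(sess$participant_id, sess$timepoint)
  split_idx <- split(seq_len(nrow(sess)), key_s)

  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    idx <- split_idx[[paste(m$participant_id, m$timepoint)]]
    if (is.null(idx)) {
      stop(sprintf("no samples for participant %s at %s", m$participant_id,
                   m$timepoint), call. = FALSE)
    }
    s <- sess[idx, ]
    s <- s[order(s$t_min), ]
    session <- list(trec_series = time_series(s$t_min, s$trec_c, max_gap = 10),
                    hr_series = time_series(s$t_min, s$hr_bpm, max_gap = 10),
                    baseline_trec = m$baseline_trec_c,
                    duration = diff(range(s$t_min)))
    dm <- session_metrics(session)

    p <- part[part$id == m$participant_id, ]
    bsa <- bsa_mosteller(p$height_cm, p$mass_kg)
    wbsl_l <- wbsl(m$mass_pre_kg, m$mass_post_kg, m$fluid_l, m$urine_l)
    wbsr_lh <- wbsr(wbsl_l, session$duration)
    vo2_l <- mean(c(m$vo2_30_lmin, m$vo2_90_lmin))
    rer <- mean(c(m$rer_30, m$rer_90))
    hp <- metabolic_heat_production(vo2_l, rer, m$mass_pre_kg, 5, 0.02, bsa)
    rel <- relative_intensity(vo2_l * 1000 / m$mass_pre_kg, p$vo2max)

    rows[[i]] <- cbind(
      data.frame(participant_id = m$participant_id, timepoint = m$timepoint,
                 sex = p$sex, stringsAsFactors = FALSE),
      dm,
      data.frame(bsa_m2 = bsa, wbsl_l = wbsl_l, wbsr_lh = wbsr_lh,
                 wbsl_bsa = wbsl_l / bsa, wbsr_bsa = wbsr_lh / bsa,
                 mhp_w = hp$net_heat_production, mhp_wm2 = hp$per_bsa,
                 rel_intensity_pct = rel,
                 hydration_label = hydration_screen(m$usg),
                 stringsAsFactors = FALSE)
    )
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate a cohort and write it to disk
#'
#' Thin pipeline wrapper: generates a seeded synthetic cohort and writes the
#' three cohort CSV files plus a JSON run manifest recording the seed, the
#' counts and a hash of the generator parameters.
#'
#' @param path Output directory.
#' @param n_female,n_male Participants per sex.
#' @param seed Integer seed (required; all randomness flows through it).
#' @param params Generator parameters, default [default_params()].
#' @return The cohort, invisibly.
#' @export
htt_simulate <- function(path, n_female, n_male, seed,
                         params = default_params()) {
  cohort <- generate_cohort(n_female, n_male, params, seed = seed)
  write_cohort(cohort, path)
  manifest <- list(
    stage = "simulate", seed = as.integer(seed),
    n_female = as.integer(n_female), n_male = as.integer(n_male),
    params_hash = param_hash(params),
    n_participants = nrow(cohort$participants),
    n_sessions = nrow(cohort$meta),
    package_version = as.character(utils::packageVersion("heattol"))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}

param_hash <- function(params) {
  # stable content fingerprint without extra dependencies
  s <- paste(utils::capture.output(utils::str(params, digits.d = 12)),
             collapse = "\n")
  sum(utf8ToInt(gsub("\\s", "", s)) * (seq_along(utf8ToInt(gsub("\\s", "", s))) %% 97 + 1))
}

#' Analyze a cohort end to end
#'
#' Chains metrics, classification and cohort statistics, writing
#' `metrics.csv`, `classification.csv`, `rates.csv`, `summary_stats.csv` and
#' a JSON manifest to `out`. Rates are reported per criterion by timepoint
#' and by sex-by-timepoint, plus the mean percentage across criteria;
#' summary statistics cover paired pre/post comparisons and female-male
#' comparisons (Bonferroni-adjusted over the sex family) for the principal
#' metrics, and the Yates chi-square comparing pooled pre/post intolerance
#' frequency.
#'
#' @param cohort An `htt_cohort`, or a directory path readable by
#'   [read_cohort()].
#' @param out Output directory.
#' @param supplied_labels Optional supplied-label table (see
#'   [classify_cohort()]); without it the supplied-only PHT criterion is
#'   dropped with a warning and means are over the six computable criteria.
#' @param registry Criteria registry, default [builtin_criteria()].
#' @param bht_as_hi Group borderline labels with intolerant in rates.
#' @return A list with elements `metrics`, `classification`, `rates`,
#'   `mean_rates` and `summary_stats`, invisibly.
#' @export
htt_analyze <- function(cohort, out, supplied_labels = NULL,
                        registry = builtin_criteria(), bht_as_hi = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  metrics <- cohort_metrics(cohort)
  cls <- classify_cohort(metrics, supplied_labels, registry)

  rates_tp <- hi_rates(cls, by = c("criterion", "timepoint"), bht_as_hi)
  rates_sex <- hi_rates(cls, by = c("criterion", "sex", "timepoint"),
                        bht_as_hi)
  rates <- rbind(
    cbind(data.frame(sex = "All", stringsAsFactors = FALSE),
          rates_tp)[c("criterion", "sex", "timepoint", "n_hi", "n",
                      "pct_hi")],
    rates_sex[c("criterion", "sex", "timepoint", "n_hi", "n", "pct_hi")]
  )
  mean_rates <- do.call(rbind, lapply(split(rates, rates[c("sex", "timepoint")]),
    function(d) data.frame(sex = d$sex[1], timepoint = d$timepoint[1],
                           n_criteria = nrow(d),
                           mean_pct_hi = mean_hi_percentage(d$pct_hi))))
  row.names(mean_rates) <- NULL

  summary_stats <- summarize_cohort(metrics, cls, bht_as_hi)

  utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
  utils::write.csv(cls, file.path(out, "classification.csv"),
                   row.names = FALSE)
  utils::write.csv(rates, file.path(out, "rates.csv"), row.names = FALSE)
  utils::write.csv(summary_stats, file.path(out, "summary_stats.csv"),
                   row.names = FALSE)
  manifest <- list(stage = "analyze",
                   n_sessions = nrow(cohort$meta),
                   n_criteria = length(unique(cls$criterion)),
                   bht_as_hi = bht_as_hi,
                   package_version =
                     as.character(utils::packageVersion("heattol")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metrics = metrics, classification = cls, rates = rates,
                 mean_rates = mean_rates, summary_stats = summary_stats))
}

summarize_cohort <- function(metrics, cls, bht_as_hi = TRUE) {
  vars <- c("trec_t120", "trec_peak", "plateau_delta", "trec_ror",
            "hr_t120", "hr_peak", "tcr_t60", "tcr_t120")
  pre <- metrics[metrics$timepoint == "PreHA", ]
  post <- metrics[metrics$timepoint == "PostHA", ]
  out <- list()
  paired_ok <- nrow(pre) >= 3 && all(pre$participant_id %in%
                                       post$participant_id)
  for (v in vars) {
    if (paired_ok) {
      ord <- match(pre$participant_id, post$participant_id)
      cp <- compare_paired(pre[[v]], post[[v]][ord])
      out[[paste0(v, "_prepost")]] <-
        data.frame(comparison = "PreHA vs PostHA (paired)", variable = v,
                   cp, p_adjusted = NA_real_)
    }
  }
  sex_rows <- list()
  for (tp in unique(metrics$timepoint)) {
    d <- metrics[metrics$timepoint == tp, ]
    if (length(unique(d$sex)) == 2L &&
        min(table(d$sex)) >= 3L) {
      for (v in vars) {
        cg <- compare_groups(d[[v]][d$sex == "F"], d[[v]][d$sex == "M"])
        sex_rows[[paste(v, tp)]] <-
          data.frame(comparison = paste0("F vs M (", tp, ")"), variable = v,
                     cg, p_adjusted = NA_real_)
      }
    }
  }
  if (length(sex_rows)) {
    sx <- do.call(rbind, sex_rows)
    sx$p_adjusted <- bonferroni(sx$p_value, m = nrow(sx))
    out$sex <- sx
  }
  hi_levels <- if (bht_as_hi) c("HI", "BHT") else "HI"
  tab <- with(cls, table(factor(timepoint, c("PreHA", "PostHA")),
                         factor(label %in% hi_levels, c(TRUE, FALSE))))
  if (all(dim(tab) == c(2L, 2L)) && sum(tab) > 0) {
    cs <- chi_square_yates(unclass(tab))
    out$chi <- data.frame(comparison = "HI frequency PreHA vs PostHA",
                          variable = "classification", method = cs$method,
                          statistic = cs$statistic, p_value = cs$p_value,
                          effect = NA_real_, p_adjusted = NA_real_)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}

#' Heatmap-ready classification matrix
#'
#' Reshapes the long classification matrix into a participants-by-criteria
#' grid ordered for display: participants by sex and then by their mean
#' intolerance count (most intolerant first), criteria in registry order.
#' Optionally renders the heatmap with three colour levels (tolerant,
#' borderline, intolerant) when the pheatmap package is available.
#'
#' @param classification Long-format matrix from [classify_cohort()] or the
#'   path to a `classification.csv`.
#' @param timepoint Which timepoint to display, default `"PreHA"`.
#' @param plot Render with pheatmap (requires the package), default `FALSE`.
#' @return A `data.frame` grid of labels (participants as rows), invisibly
#'   when plotted.
#' @export
htt_figure1 <- function(classification, timepoint = "PreHA", plot = FALSE) {
  if (is.character(classification)) {
    classification <- utils::read.csv(classification,
                                      stringsAsFactors = FALSE)
  }
  cls <- classification[classification$timepoint == timepoint, ]
  if (nrow(cls) == 0L) {
    return(data.frame())
  }
  crits <- unique(classification$criterion)
  ids <- unique(cls$participant_id)
  grid <- matrix("HT", nrow = length(ids), ncol = length(crits),
                 dimnames = list(ids, crits))
  for (i in seq_len(nrow(cls))) {
    grid[cls$participant_id[i], cls$criterion[i]] <- cls$label[i]
  }
  hi_count <- rowSums(grid != "HT")
  sex <- if (!is.null(cls$sex)) {
    cls$sex[match(ids, cls$participant_id)]
  } else rep("", length(ids))
  ord <- order(sex, -hi_count, ids)
  grid <- grid[ord, , drop = FALSE]
  out <- data.frame(participant_id = rownames(grid), sex = sex[ord],
                    grid, row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (plot && requireNamespace("pheatmap", quietly = TRUE)) {
    num <- matrix(match(grid, c("HT", "BHT", "HI")) - 1, nrow = nrow(grid),
                  dimnames = dimnames(grid))
    pheatmap::pheatmap(num, cluster_rows = FALSE, cluster_cols = FALSE,
                       legend_breaks = 0:2,
                       legend_labels = c("HT", "BHT", "HI"),
                       color = c("#2166AC", "#92C5DE", "#B2182B"))
    return(invisible(out))
  }
  out
}
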