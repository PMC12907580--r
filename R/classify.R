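new_criterion <- function(name, kind, variables = character(),
                          thresholds = numeric(), source = "") {
  if (kind != "supplied" && any(!is.finite(thresholds))) {
    stop("thresholds must be finite", call. = FALSE)
  }
  if (kind == "composite_all" && length(variables) < 2L) {
    stop("a composite criterion needs at least two clauses", call. = FALSE)
  }
  structure(list(name = name, kind = kind, variables = variables,
                 thresholds = thresholds, source = source),
            class = "htt_criterion")
}

#' The published heat-intolerance criteria battery
#'
#' Returns the registry of seven classification criteria applied to each
#' session: peak rectal temperature >= 38.5 C, peak heart rate >= 150 bpm, a
#' final-hour temperature rise >= 0.45 C, thermal-circulatory ratio <= 0.279
#' C/bpm at 120 min and <= 0.32 C/bpm at 60 min, the stringent composite
#' (tolerant only while the final-hour rise stays below 0.25 C, peak heart
#' rate below 120 bpm and peak temperature below 38.2 C; any exceedance
#' classifies the session intolerant, making this the strictest gate for
#' granting tolerant status and the criterion with the highest intolerance
#' rates), and
#' the proprietary probability-of-heat-tolerance (PHT) score, which cannot be
#' computed from the data and must be supplied as external labels.
#'
#' Temperature and heart-rate thresholds are evaluated against session peaks:
#' any exceedance during the test classifies the session, the conservative
#' reading consistent with the test's safety intent.
#'
#' @return A named list of `htt_criterion` objects, class `htt_criteria`.
#' @examples
#' names(builtin_criteria())
#' @export
builtin_criteria <- function() {
  structure(list(
    trec_385 = new_criterion("trec_385", "threshold_ge", "trec_peak", 38.5,
                             "Druyan 2013"),
    hr_150 = new_criterion("hr_150", "threshold_ge", "hr_peak", 150,
                           "Druyan 2013"),
    plateau_045 = new_criterion("plateau_045", "threshold_ge",
                                "plateau_delta", 0.45, "Druyan 2013"),
    tcr_t120 = new_criterion("tcr_t120", "threshold_le", "tcr_t120", 0.279,
                             "Ketko 2023"),
    tcr_t60 = new_criterion("tcr_t60", "threshold_le", "tcr_t60", 0.32,
                            "Ketko 2023"),
    schermann = new_criterion("schermann", "composite_all",
                              c("plateau_delta", "hr_peak", "trec_peak"),
                              c(0.25, 120, 38.2), "Schermann 2018"),
    pht = new_criterion("pht", "supplied", source = "Schermann 2018")
  ), class = "htt_criteria")
}

#' Experimental sex-adjusted thresholds
#'
#' An optional registry implementing the proposed female-adjusted cut-offs
#' (tolerance at peak temperature <= 38.7 C and peak heart rate <= 170 bpm,
#' i.e. intolerance above those values). These are unvalidated proposals, not
#' part of the default battery; sensitivity and specificity have not been
#' established.
#'
#' @return An `htt_criteria` registry with two criteria.
#' @export
sex_adjusted_criteria <- function() {
  structure(list(
    trec_387 = new_criterion("trec_387", "threshold_ge", "trec_peak", 38.7,
                             "proposed, unvalidated"),
    hr_170 = new_criterion("hr_170", "threshold_ge", "hr_peak", 170,
                           "proposed, unvalidated")
  ), class = "htt_criteria")
}

#' Evaluate one criterion on one session's metrics
#'
#' Threshold criteria label a session heat-intolerant (`"HI"`) when the
#' metric is `>=` (kind `threshold_ge`) or `<=` (kind `threshold_le`) its
#' threshold, with boundary equality counting as intolerant exactly as the
#' published comparators state. A composite criterion labels a session
#' tolerant only when every clause stays below its cut-off: any single
#' exceedance yields `"HI"`. Otherwise the label is heat-tolerant (`"HT"`).
#'
#' @param metrics A one-row `data.frame` (or list) of derived metrics, e.g. a
#'   row of [cohort_metrics()].
#' @param criterion An `htt_criterion` from a registry.
#' @return `"HI"` or `"HT"`.
#' @export
evaluate_criterion <- function(metrics, criterion) {
  stopifnot(inherits(criterion, "htt_criterion"))
  if (criterion$kind == "supplied") {
    stop(sprintf("criterion '%s' is supplied-label only and cannot be computed",
                 criterion$name), call. = FALSE)
  }
  vals <- vapply(criterion$variables, function(v) {
    if (is.null(metrics[[v]]) || !is.finite(metrics[[v]])) {
      stop(sprintf("metric field '%s' required by criterion '%s' is missing",
                   v, criterion$name), call. = FALSE)
    }
    metrics[[v]]
  }, numeric(1))
  hi <- switch(criterion$kind,
    threshold_ge = vals[1] >= criterion$thresholds[1],
    threshold_le = vals[1] <= criterion$thresholds[1],
    composite_all = any(vals >= criterion$thresholds),
    stop(sprintf("unknown criterion kind '%s'", criterion$kind),
         call. = FALSE)
  )
  if (hi) "HI" else "HT"
}

#' Build the full classification matrix for a cohort
#'
#' Applies every computable criterion in the registry to each
#' (participant, timepoint) row of a metrics table, and merges supplied
#' labels (e.g. the proprietary PHT score, which may take the third level
#' `"BHT"`, borderline heat-tolerant). A supplied criterion that does not
#' cover every (participant, timepoint) pair is dropped with a warning.
#'
#' @param metrics A metrics table as returned by [cohort_metrics()]
#'   (columns `participant_id`, `timepoint`, plus metric fields).
#' @param supplied_labels Optional `data.frame` with columns
#'   `participant_id`, `timepoint`, `criterion`, `label` providing labels for
#'   supplied-kind criteria. Duplicated (participant, timepoint, criterion)
#'   entries are an error.
#' @param registry An `htt_criteria` registry, default [builtin_criteria()].
#' @return Long-format `data.frame` with columns `participant_id`,
#'   `timepoint`, `criterion`, `label` (`"HT"`, `"BHT"` or `"HI"`) and
#'   `provenance` (`"computed"` or `"supplied"`), carrying `sex` when present
#'   in `metrics`.
#' @export
classify_cohort <- function(metrics, supplied_labels = NULL,
                            registry = builtin_criteria()) {
  stopifnot(inherits(registry, "htt_criteria"))
  keys <- metrics[c("participant_id", "timepoint")]
  out <- list()
  for (cr in registry) {
    if (cr$kind == "supplied") {
      if (is.null(supplied_labels) ||
          !any(supplied_labels$criterion == cr$name)) {
        warning(sprintf(
          "no supplied labels for criterion '%s'; criterion dropped",
          cr$name), call. = FALSE)
        next
      }
      sl <- supplied_labels[supplied_labels$criterion == cr$name, ]
      if (anyDuplicated(sl[c("participant_id", "timepoint")])) {
        stop(sprintf("duplicate supplied labels for criterion '%s'",
                     cr$name), call. = FALSE)
      }
      idx <- match(paste(keys$participant_id, keys$timepoint),
                   paste(sl$participant_id, sl$timepoint))
      if (anyNA(idx)) {
        warning(sprintf(
          "supplied labels for '%s' do not cover every session; criterion dropped",
          cr$name), call. = FALSE)
        next
      }
      lab <- sl$label[idx]
      if (!all(lab %in% c("HT", "BHT", "HI"))) {
        stop(sprintf("supplied labels for '%s' must be HT, BHT or HI",
                     cr$name), call. = FALSE)
      }
      out[[cr$name]] <- data.frame(keys, criterion = cr$name, label = lab,
                                   provenance = "supplied",
                                   stringsAsFactors = FALSE)
    } else {
      lab <- vapply(seq_len(nrow(metrics)), function(i) {
        evaluate_criterion(metrics[i, ], cr)
      }, character(1))
      out[[cr$name]] <- data.frame(keys, criterion = cr$name, label = lab,
                                   provenance = "computed",
                                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!is.null(metrics$sex)) {
    res$sex <- metrics$sex[match(res$participant_id, metrics$participant_id)]
  }
  res
}

#' Heat-intolerance classification rates
#'
#' Percentage of sessions labelled heat-intolerant, by any stratification of
#' criterion, sex and timepoint. Borderline labels are grouped with the
#' intolerant class by default, matching the published aggregation rule.
#'
#' @param classification Long-format matrix from [classify_cohort()].
#' @param by Character vector of stratification columns, any subset of
#'   `c("criterion", "sex", "timepoint")`.
#' @param bht_as_hi Count `"BHT"` labels as intolerant (default `TRUE`).
#' @return `data.frame` with the stratification columns plus `n_hi`, `n` and
#'   `pct_hi`. Empty strata do not occur by construction; strata are the
#'   observed combinations.
#' @export
hi_rates <- function(classification, by = c("criterion", "timepoint"),
                     bht_as_hi = TRUE) {
  stopifnot(nrow(classification) > 0,
            all(by %in% c("criterion", "sex", "timepoint")))
  hi_levels <- if (bht_as_hi) c("HI", "BHT") else "HI"
  hi <- classification$label %in% hi_levels
  g <- classification[by]
  agg <- stats::aggregate(hi, by = as.list(g), FUN = function(v) {
    c(n_hi = sum(v), n = length(v))
  })
  out <- data.frame(agg[by], n_hi = agg$x[, "n_hi"], n = agg$x[, "n"])
  out$pct_hi <- 100 * out$n_hi / out$n
  out[do.call(order, out[by]), , drop = FALSE]
}
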