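#' Detect events and summarise one session
#'
#' Convenience wrapper running the per-session stages: I-VT
#' classification at the native rate for the gaze-shift variables, and
#' (for 120 Hz recordings) spline up-sampling to 1200 Hz followed by
#' re-classification for the peak-velocity/amplitude index.
#'
#' @param session A `gaze_session` from [simulate_session()], or a list
#'   with `recording`, `trials`, `participant`.
#' @param threshold I-VT velocity threshold, deg/s.
#' @param amplitude_min Amplitude gate for the velocity ratio, degrees.
#' @param min_valid_trials Participant inclusion threshold per condition.
#' @param median_filter Apply the 3-sample median pre-filter before
#'   velocity computation.
#' @param compute_ratio Compute the arousal index (skipped automatically
#'   at 60 Hz, where peak velocity is unrecoverable).
#' @return List: `events` (native rate), `shift_results`, `ratios`
#'   (`NULL` when skipped), `summary` (participant-by-condition rows).
#' @export
process_session <- function(session, threshold = 30, amplitude_min = 4,
                            min_valid_trials = 5, median_filter = TRUE,
                            compute_ratio = TRUE) {
  rec <- session$recording
  events <- classify_ivt(rec, threshold = threshold,
                         median_filter = median_filter)
  shifts <- session_shift_results(rec, events, session$trials)
  ratios <- NULL
  if (compute_ratio && sampling_rate(rec) == 120) {
    up <- upsample_spline(if (median_filter) median_filter3(rec) else rec)
    ev_up <- classify_ivt(up, threshold = threshold, median_filter = FALSE)
    ratios <- peak_velocity_ratio(ev_up, session$trials,
                                  amplitude_min = amplitude_min,
                                  participant = session$participant)
  }
  summary <- summarize_participant(shifts, ratios,
                                   min_valid_trials = min_valid_trials,
                                   participant = session$participant)
  list(events = events, shift_results = shifts, ratios = ratios,
       summary = summary)
}

#' Summarise a whole cohort
#'
#' Runs [process_session()] on every session and binds the
#' participant-by-condition summaries with group labels.  Condition rows
#' failing the minimum-valid-trials rule are flagged `excluded` (and
#' dropped by [analyze_cohort()]).
#'
#' @param cohort A `gaze_cohort` from [simulate_cohort()].
#' @param ... Passed to [process_session()].
#' @return Data.frame of summaries with a `group` column.
#' @export
summarize_cohort <- function(cohort, ...) {
  out <- lapply(cohort$sessions, function(s) process_session(s, ...)$summary)
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  out$group <- cohort$participants$group[match(out$participant,
                                               cohort$participants$participant)]
  out
}

# One nested comparison on a summary data.frame; returns a labelled row.
.contrast_row <- function(dv, contrast, data, full_f, null_f,
                          group = "participant") {
  full <- fit_random_intercept(full_f, data, group)
  null <- fit_random_intercept(null_f, data, group)
  cmp <- compare_models(full, null)
  cbind(data.frame(dv = dv, contrast = contrast, stringsAsFactors = FALSE),
        cmp)
}

#' Planned model comparisons for a two-group cohort
#'
#' Runs the study's analysis plan on participant-by-condition summaries:
#' for the shift proportion and latency, the cued-region effect, the
#' group effect, and the group-by-cued-region interaction (each tested by
#' comparing the model with the effect of interest to the next most
#' complex model without it), plus the within-first-group cued-region
#' follow-up (the "is the eye bias absent?" test); for the
#' velocity/amplitude ratio, the group and condition effects.
#' Benjamini-Hochberg pass flags at `q` are appended over all reported
#' p-values; uncorrected p-values are reported.
#'
#' @param summaries Output of [summarize_cohort()] (excluded rows are
#'   dropped here).
#' @param q False discovery rate for the BH flags.
#' @param bias_group Group label for the within-group bias follow-up;
#'   defaults to the first group level.
#' @return Data.frame with columns `dv`, `contrast`, `chi2`, `df`, `p`,
#'   `b`, `se`, `bf10`, `bf01`, `f2`, `converged`, `bh_pass`.
#' @export
analyze_cohort <- function(summaries, q = 0.05, bias_group = NULL) {
  d <- summaries[!summaries$excluded, , drop = FALSE]
  d$group <- factor(d$group)
  d$condition <- factor(d$condition)
  if (is.null(bias_group)) bias_group <- levels(d$group)[1]
  rows <- list()

  prop <- d[is.finite(d$prop_shift), , drop = FALSE]
  rows$p1 <- .contrast_row("prop_shift", "cued_region", prop,
                           prop_shift ~ group + condition,
                           prop_shift ~ group)
  rows$p2 <- .contrast_row("prop_shift", "group", prop,
                           prop_shift ~ group + condition,
                           prop_shift ~ condition)
  rows$p3 <- .contrast_row("prop_shift", "group_x_cued_region", prop,
                           prop_shift ~ group * condition,
                           prop_shift ~ group + condition)
  bias <- prop[prop$group == bias_group, , drop = FALSE]
  rows$p4 <- .contrast_row("prop_shift",
                           paste0("cued_region_within_", bias_group), bias,
                           prop_shift ~ condition, prop_shift ~ 1)

  lat <- d[is.finite(d$mean_latency), , drop = FALSE]
  if (length(unique(lat$condition)) == 2 && nrow(lat) > 4) {
    rows$l1 <- .contrast_row("latency", "cued_region", lat,
                             mean_latency ~ group + condition,
                             mean_latency ~ group)
    rows$l2 <- .contrast_row("latency", "group", lat,
                             mean_latency ~ group + condition,
                             mean_latency ~ condition)
    rows$l3 <- .contrast_row("latency", "group_x_cued_region", lat,
                             mean_latency ~ group * condition,
                             mean_latency ~ group + condition)
  }

  rat <- d[is.finite(d$mean_ratio), , drop = FALSE]
  if (nrow(rat) > 4) {
    rows$r1 <- .contrast_row("velocity_ratio", "group", rat,
                             mean_ratio ~ group + condition,
                             mean_ratio ~ condition)
    rows$r2 <- .contrast_row("velocity_ratio", "cued_region", rat,
                             mean_ratio ~ group + condition,
                             mean_ratio ~ group)
  }

  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$bh_pass <- bh_adjust(out$p, q = q)
  out
}

#' Run configuration for the full pipeline
#'
#' Defaults are the analysis constants of the emulated study: 30 deg/s
#' I-VT threshold, 4 degree amplitude gate, 5 valid trials minimum,
#' alpha 0.05, FDR 0.05.
#'
#' @param cohort A [cohort_config()] (simulation input), or `NULL` when
#'   reading previously simulated data from `in_dir`.
#' @param threshold,amplitude_min,min_valid_trials,alpha,fdr_q Analysis
#'   constants.
#' @param median_filter Pre-filter noisy recordings before velocity
#'   computation.
#' @param seed Integer seed for the run.
#' @param out_dir Output directory (`NULL` for no file output).
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config_ws_td(), threshold = 30,
                       amplitude_min = 4, min_valid_trials = 5,
                       alpha = 0.05, fdr_q = 0.05, median_filter = TRUE,
                       seed = 1, out_dir = NULL) {
  structure(list(cohort = cohort, threshold = threshold,
                 amplitude_min = amplitude_min,
                 min_valid_trials = min_valid_trials, alpha = alpha,
                 fdr_q = fdr_q, median_filter = median_filter,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' simulate -> detect -> arousal/shifts -> analyze, deterministically
#' from the config seed.  When `out_dir` is set, writes `events.csv`
#' (all sessions, native rate), `summaries.csv`, `results.csv` and a
#' `manifest.json` recording the configuration, seed and package version
#' for provenance.  When the cohort samples at 60 Hz the arousal stage is
#' skipped (peak velocity is unrecoverable at 60 Hz) and the skip is
#' recorded in the manifest.
#'
#' @param config A [run_config()].
#' @return List: `cohort`, `summaries`, `results`, `skipped` (character
#'   vector of skipped stages with reasons), `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- config$seed
  cohort <- simulate_cohort(cohort_cfg)

  rates <- vapply(cohort$sessions,
                  function(s) sampling_rate(s$recording), numeric(1))
  skipped <- character()
  compute_ratio <- all(rates == 120)
  if (!compute_ratio) {
    skipped <- c(skipped,
                 "arousal: data sampled at 60 Hz were not included in the peak velocity analyses")
  }

  per <- lapply(cohort$sessions, function(s) {
    process_session(s, threshold = config$threshold,
                    amplitude_min = config$amplitude_min,
                    min_valid_trials = config$min_valid_trials,
                    median_filter = config$median_filter,
                    compute_ratio = compute_ratio)
  })
  summaries <- do.call(rbind, c(lapply(per, `[[`, "summary"),
                                make.row.names = FALSE))
  summaries$group <- cohort$participants$group[
    match(summaries$participant, cohort$participants$participant)]

  results <- analyze_cohort(summaries, q = config$fdr_q)

  manifest <- list(
    package = "gazeorient",
    version = as.character(utils::packageVersion("gazeorient")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    threshold = config$threshold,
    amplitude_min = config$amplitude_min,
    min_valid_trials = config$min_valid_trials,
    alpha = config$alpha, fdr_q = config$fdr_q,
    median_filter = config$median_filter,
    groups = lapply(cohort_cfg$groups, function(g) g["n"]),
    skipped = skipped
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    all_events <- do.call(rbind, c(lapply(names(per), function(id) {
      ev <- per[[id]]$events
      cbind(data.frame(participant = id, stringsAsFactors = FALSE), ev)
    }), make.row.names = FALSE))
    utils::write.csv(all_events, file.path(config$out_dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(cohort = cohort, summaries = summaries, results = results,
       skipped = skipped, manifest = manifest)
}
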