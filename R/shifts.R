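#' Assign a gaze point to an AOI
#'
#' Rectangle containment with inclusive boundaries.
#'
#' @param x,y Gaze position in degrees (vectorised).
#' @param aois An [aoi_set()].
#' @return Character vector: `"eyes"`, `"mouth"` or `"outside"`.
#' @export
assign_aoi <- function(x, y, aois) {
  stopifnot(inherits(aois, "aoi_set"))
  inside <- function(r) {
    x >= r["x_min"] & x <= r["x_max"] & y >= r["y_min"] & y <= r["y_max"]
  }
  out <- rep("outside", length(x))
  out[inside(aois$mouth)] <- "mouth"
  out[inside(aois$eyes)] <- "eyes"
  out
}

# Samples of one trial's stimulus epoch.
trial_epoch <- function(recording, trial, epoch = 1.5) {
  sel <- recording$t >= trial$onset & recording$t < trial$onset + epoch
  recording[sel, , drop = FALSE]
}

#' Trial validity
#'
#' The source paradigm never defines its "valid trial" criterion; here a
#' trial is valid iff (a) gaze at stimulus onset (the nearest valid
#' sample within `onset_tol` seconds of onset) lies inside the cued AOI,
#' and (b) at least `min_valid_frac` of the stimulus-epoch samples are
#' valid.  Both criteria are configurable.
#'
#' @param recording A [gaze_recording()] for the session.
#' @param trial One trial row (list or one-row data.frame with `onset`
#'   and `condition`).
#' @param aois AOI layout for the trial; defaults to
#'   [default_aoi_set()] for the trial's condition.
#' @param min_valid_frac Minimum fraction of valid samples.
#' @param onset_tol Search window around stimulus onset, seconds.
#' @param epoch Stimulus epoch length, seconds.
#' @return Logical.
#' @export
trial_validity <- function(recording, trial, aois = NULL,
                           min_valid_frac = 0.5, onset_tol = 0.05,
                           epoch = 1.5) {
  if (is.null(aois)) aois <- default_aoi_set(trial$condition)
  seg <- trial_epoch(recording, trial, epoch)
  if (nrow(seg) == 0) return(FALSE)
  if (mean(seg$valid) < min_valid_frac) return(FALSE)
  near <- which(seg$valid & abs(seg$t - trial$onset) <= onset_tol)
  if (length(near) == 0) return(FALSE)
  i <- near[which.min(abs(seg$t[near] - trial$onset))]
  cued <- if (trial$condition == "eyes_cued") "eyes" else "mouth"
  assign_aoi(seg$x[i], seg$y[i], aois) == cued
}

#' First gaze shift out of the cued AOI
#'
#' Finds the first saccade after stimulus onset whose onset position lies
#' inside the cued AOI and whose landing position (the centroid of the
#' following fixation, or the saccade endpoint if none follows) lies
#' outside it.  Latency is the interval from stimulus onset to saccade
#' onset, in ms.  Shifts landing outside both AOIs are flagged
#' (`target = "outside"`) and are excluded from the proportion and
#' latency analyses downstream, as such landings are treated in the
#' paradigm.  Anticipatory shifts (latency < 80 ms) are flagged and, by
#' default, retained.
#'
#' @param events Event table from [classify_ivt()].
#' @param trial One trial row (`onset`, `condition`).
#' @param aois AOI layout; defaults to [default_aoi_set()] for the
#'   trial's condition.
#' @param epoch Search window after stimulus onset, seconds.
#' @param drop_anticipatory Treat shifts with latency < `anticipatory_ms`
#'   as no shift.
#' @param anticipatory_ms Anticipatory-latency flag threshold, ms.
#' @return One-row data.frame: `shift_made`, `target` (`"eyes"`,
#'   `"mouth"`, `"outside"` or `"none"`), `latency` (ms, `NA` when no
#'   shift), `anticipatory`.
#' @export
first_gaze_shift <- function(events, trial, aois = NULL, epoch = 1.5,
                             drop_anticipatory = FALSE,
                             anticipatory_ms = 80) {
  if (is.null(aois)) aois <- default_aoi_set(trial$condition)
  cued <- if (trial$condition == "eyes_cued") "eyes" else "mouth"
  no_shift <- data.frame(shift_made = FALSE, target = "none",
                         latency = NA_real_, anticipatory = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(events) == 0) return(no_shift)
  win <- events$onset >= trial$onset & events$onset < trial$onset + epoch
  sacc <- which(win & events$kind == "saccade")
  for (j in sacc) {
    if (assign_aoi(events$x_onset[j], events$y_onset[j], aois) != cued) next
    nxt <- which(events$kind == "fixation" & events$onset >= events$offset[j] - 1e-9)
    if (length(nxt)) {
      k <- nxt[1]
      land <- assign_aoi(events$centroid_x[k], events$centroid_y[k], aois)
    } else {
      land <- assign_aoi(events$x_offset[j], events$y_offset[j], aois)
    }
    if (land == cued) next
    latency <- (events$onset[j] - trial$onset) * 1000
    anticipatory <- latency < anticipatory_ms
    if (anticipatory && drop_anticipatory) next
    return(data.frame(shift_made = TRUE, target = land, latency = latency,
                      anticipatory = anticipatory, stringsAsFactors = FALSE))
  }
  no_shift
}

#' Per-trial shift results for a session
#'
#' Applies [trial_validity()] and [first_gaze_shift()] to every trial of
#' a session.
#'
#' @param recording A [gaze_recording()].
#' @param events Event table from [classify_ivt()] on the same
#'   recording.
#' @param trials Trial metadata data.frame (`trial`, `condition`,
#'   `onset`).
#' @param aoi_args Optional list of arguments to [default_aoi_set()]
#'   (sizes, separation) describing the AOI geometry.
#' @param ... Passed to [trial_validity()] and [first_gaze_shift()]
#'   (`min_valid_frac`, `drop_anticipatory`, ...).
#' @return `trials` with appended columns `valid`, `shift_made`,
#'   `target`, `latency` (ms), `anticipatory`.
#' @export
session_shift_results <- function(recording, events, trials,
                                  aoi_args = list(), ...) {
  dots <- list(...)
  tv_args <- dots[names(dots) %in% c("min_valid_frac", "onset_tol", "epoch")]
  fg_args <- dots[names(dots) %in% c("epoch", "drop_anticipatory",
                                     "anticipatory_ms")]
  res <- lapply(seq_len(nrow(trials)), function(i) {
    trial <- trials[i, , drop = FALSE]
    aois <- do.call(default_aoi_set,
                    c(list(condition = trial$condition), aoi_args))
    valid <- do.call(trial_validity,
                     c(list(recording = recording, trial = trial,
                            aois = aois), tv_args))
    fg <- do.call(first_gaze_shift,
                  c(list(events = events, trial = trial, aois = aois),
                    fg_args))
    cbind(trial, data.frame(valid = valid), fg, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Participant-by-condition summaries
#'
#' Aggregates per-trial shift results into the dependent variables: the
#' proportion of valid trials with a first gaze shift to the non-cued
#' AOI, the mean latency of those shifts, and (if supplied) the mean
#' peak-velocity/amplitude ratio.  Trials whose first shift landed
#' outside both AOIs are excluded entirely.  A condition contributing
#' fewer than `min_valid_trials` valid trials (default 5) is flagged
#' `excluded` and should be dropped from group analyses.
#'
#' @param shift_results Output of [session_shift_results()].
#' @param ratios Optional output of [peak_velocity_ratio()] for the same
#'   participant.
#' @param min_valid_trials Minimum valid trials per condition.
#' @param participant Identifier (taken from `shift_results` if present).
#' @return Data.frame with one row per condition: `participant`,
#'   `condition`, `n_valid`, `n_shift`, `prop_shift`, `mean_latency`
#'   (ms), `mean_ratio`, `n_saccades`, `excluded`.
#' @export
summarize_participant <- function(shift_results, ratios = NULL,
                                  min_valid_trials = 5,
                                  participant = NULL) {
  if (is.null(participant)) {
    participant <- if ("participant" %in% names(shift_results)) {
      shift_results$participant[1]
    } else NA_character_
  }
  conds <- unique(shift_results$condition)
  rows <- lapply(conds, function(cn) {
    tr <- shift_results[shift_results$condition == cn, , drop = FALSE]
    noncued <- if (cn == "eyes_cued") "mouth" else "eyes"
    usable <- tr$valid & !(tr$shift_made & tr$target == "outside")
    tr <- tr[usable, , drop = FALSE]
    n_valid <- nrow(tr)
    shifts <- tr$shift_made & tr$target == noncued
    n_shift <- sum(shifts)
    data.frame(
      participant = participant, condition = cn,
      n_valid = n_valid, n_shift = n_shift,
      prop_shift = if (n_valid) n_shift / n_valid else NA_real_,
      mean_latency = if (n_shift) mean(tr$latency[shifts]) else NA_real_,
      excluded = n_valid < min_valid_trials,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(ratios)) {
    m <- match(out$condition, ratios$condition)
    out$mean_ratio <- ratios$mean_ratio[m]
    out$n_saccades <- ratios$n_saccades[m]
  } else {
    out$mean_ratio <- NA_real_
    out$n_saccades <- NA_integer_
  }
  out
}

#' Latency agreement diagnostic
#'
#' Pearson correlation between the latency to orient to the non-cued AOI
#' and the latency to orient from the cued region to any location (the
#' first departure regardless of landing), a quality check on the
#' landing-based exclusion rule: when off-AOI landings are rare the two
#' latencies are nearly identical and r approaches 1.
#'
#' @param latency_to_aoi,latency_to_any Paired latency vectors (ms); `NA`
#'   pairs are dropped.
#' @return List with `r` (NA with a flag when fewer than 3 pairs) and
#'   `n_pairs`.
#' @export
latency_agreement <- function(latency_to_aoi, latency_to_any) {
  ok <- is.finite(latency_to_aoi) & is.finite(latency_to_any)
  n <- sum(ok)
  if (n < 3) {
    return(list(r = NA_real_, n_pairs = n, insufficient = TRUE))
  }
  list(r = stats::cor(latency_to_aoi[ok], latency_to_any[ok]),
       n_pairs = n, insufficient = FALSE)
}
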