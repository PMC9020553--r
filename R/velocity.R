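#' Cubic-spline up-sampling of a 120 Hz recording to 1200 Hz
#'
#' Peak saccadic velocity is systematically missed at 120 Hz because the
#' velocity maximum falls between samples; interpolating the position
#' signal onto a 10x denser grid before differentiating recovers it.
#' Each contiguous run of valid samples is interpolated independently
#' with a cubic spline (Forsythe-Malcolm-Moler end conditions); original
#' sample values are reproduced exactly at their own timestamps and gaps
#' are propagated, never interpolated across.
#'
#' Recordings declared at 60 Hz are refused: peak velocity cannot be
#' recovered at that rate even after up-sampling, so 60 Hz data are
#' excluded from the peak-velocity analyses.
#'
#' @param recording A [gaze_recording()] at 120 Hz.
#' @param factor Up-sampling factor (default 10, i.e. 1200 Hz).
#' @param method Spline method passed to [stats::splinefun()].
#' @return A [gaze_recording()] at `120 * factor` Hz.
#' @export
upsample_spline <- function(recording, factor = 10, method = "fmm") {
  rate <- sampling_rate(recording)
  if (is.null(rate) || rate != 120) {
    stop("refusing to up-sample: peak velocity requires 120 Hz input ",
         "(data sampled at 60 Hz are not included in peak velocity analyses)")
  }
  new_rate <- rate * factor
  t_new <- seq(recording$t[1], recording$t[nrow(recording)],
               by = 1 / new_rate)
  x_new <- rep(NA_real_, length(t_new))
  y_new <- rep(NA_real_, length(t_new))
  valid_new <- rep(FALSE, length(t_new))

  r <- rle(recording$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  t_base <- recording$t[1]
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    i0 <- starts[j]; i1 <- ends[j]
    lo <- ceiling((recording$t[i0] - t_base) * new_rate - 1e-6) + 1
    hi <- floor((recording$t[i1] - t_base) * new_rate + 1e-6) + 1
    if (hi < lo) next
    sel <- lo:min(hi, length(t_new))
    if (i1 - i0 + 1 < 2) {
      # single isolated sample: carry it over where the grid touches it
      x_new[sel] <- recording$x[i0]
      y_new[sel] <- recording$y[i0]
    } else {
      tt <- recording$t[i0:i1]
      fx <- stats::splinefun(tt, recording$x[i0:i1], method = method)
      fy <- stats::splinefun(tt, recording$y[i0:i1], method = method)
      x_new[sel] <- fx(t_new[sel])
      y_new[sel] <- fy(t_new[sel])
    }
    valid_new[sel] <- TRUE
  }
  gaze_recording(t_new, x_new, y_new, valid_new, rate = new_rate)
}

#' Peak-velocity/amplitude arousal index
#'
#' Mean over qualifying saccades of peak velocity divided by amplitude
#' (units 1/s), the tonic-arousal index: lower values indicate
#' hypo-arousal.  All saccades with amplitude strictly exceeding
#' `amplitude_min` (default 4 degrees) detected during a trial's
#' stimulus epoch contribute, regardless of direction.  Saccades are
#' expected to come from up-sampled (or natively high-rate) data so the
#' peak is not undersampled.
#'
#' @param events Event table from [classify_ivt()].
#' @param trials Trial metadata (columns `condition`, `onset`); saccades
#'   are assigned to the trial whose stimulus epoch (onset to onset +
#'   `epoch`) contains their onset.  If `NULL`, all saccades pool into a
#'   single `"all"` condition.
#' @param amplitude_min Amplitude gate in degrees (strict inequality).
#' @param epoch Stimulus epoch length, seconds.
#' @param participant Identifier copied into the output.
#' @return A data.frame with one row per condition: `participant`,
#'   `condition`, `mean_ratio` (1/s, `NA` when no saccade qualifies) and
#'   `n_saccades`.
#' @export
peak_velocity_ratio <- function(events, trials = NULL, amplitude_min = 4,
                                epoch = 1.5, participant = NA_character_) {
  sac <- events[events$kind == "saccade" &
                  events$amplitude > amplitude_min, , drop = FALSE]
  if (is.null(trials)) {
    conds <- "all"
    cond_of <- rep("all", nrow(sac))
  } else {
    conds <- unique(trials$condition)
    cond_of <- rep(NA_character_, nrow(sac))
    for (i in seq_len(nrow(trials))) {
      inside <- sac$onset >= trials$onset[i] &
        sac$onset < trials$onset[i] + epoch
      cond_of[inside] <- trials$condition[i]
    }
    sac <- sac[!is.na(cond_of), , drop = FALSE]
    cond_of <- cond_of[!is.na(cond_of)]
  }
  out <- lapply(conds, function(cn) {
    s <- sac[cond_of == cn, , drop = FALSE]
    data.frame(participant = participant, condition = cn,
               mean_ratio = if (nrow(s)) mean(s$peak_velocity / s$amplitude)
                            else NA_real_,
               n_saccades = nrow(s), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
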