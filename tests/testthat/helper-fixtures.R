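# Shared fixtures: analytic saccade recordings and matching utilities.

# One raised-cosine saccade embedded in a noiseless 1 s fixation.
# `phase` in [0, 1) offsets the saccade onset within a sample period so
# tests can probe grid-alignment effects.
mk_saccade_recording <- function(A, rate, phase = 0, onset = 0.4,
                                 D = saccade_duration(A),
                                 direction = c(1, 0), noise_sd = 0) {
  t <- seq(0, 1, by = 1 / rate)
  s <- saccade_displacement(t - (onset + phase / rate), A, D)
  nrm <- sqrt(sum(direction^2))
  x <- s * direction[1] / nrm
  y <- s * direction[2] / nrm
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(t), 0, noise_sd)
    y <- y + stats::rnorm(length(t), 0, noise_sd)
  }
  gaze_recording(t, x, y, rate = rate)
}

# Match detected saccades to true onsets; returns per-true-onset the
# index of the closest detected saccade and its onset error (seconds).
match_saccades <- function(events, true_onsets) {
  sac <- events[events$kind == "saccade", , drop = FALSE]
  out <- data.frame(true_onset = true_onsets, det = NA_integer_,
                    err = NA_real_)
  for (i in seq_along(true_onsets)) {
    if (nrow(sac) == 0) break
    d <- abs(sac$onset - true_onsets[i])
    j <- which.min(d)
    out$det[i] <- j
    out$err[i] <- d[j]
  }
  out
}
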