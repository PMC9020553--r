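#' Raised-cosine saccade kinematics
#'
#' The generator uses a symmetric raised-cosine velocity profile,
#' `v(t) = (V_p / 2) * (1 - cos(2 * pi * t / D))` for `t` in `[0, D]`,
#' whose peak velocity has the closed form `V_p = 2 * A / D`.  This gives
#' every downstream stage an exact analytic oracle for peak velocity and
#' displacement.
#'
#' @param tau Time since saccade onset, seconds (vectorised).
#' @param A Amplitude in degrees.
#' @param D Duration in seconds.
#' @return `saccade_speed()` returns instantaneous angular speed (deg/s);
#'   `saccade_displacement()` the displacement travelled since onset
#'   (deg).  Both are 0 before onset and clamp at `tau >= D`.
#' @export
saccade_speed <- function(tau, A, D) {
  v <- (A / D) * (1 - cos(2 * pi * tau / D))
  v[tau < 0 | tau > D] <- 0
  v
}

#' @rdname saccade_speed
#' @export
saccade_displacement <- function(tau, A, D) {
  s <- A * (tau / D - sin(2 * pi * tau / D) / (2 * pi))
  s[tau < 0] <- 0
  s[tau > D] <- A
  s
}

#' Main-sequence saccade duration
#'
#' Linear main-sequence model `D = D0 + k * A`, by default
#' `D = 0.021 s + 0.0022 s/deg * A`, which places peak velocities of
#' 4-12 degree saccades in the physiological 100-500 deg/s range.  A
#' peak-velocity scaling below 1 (hypo-arousal) is realised by inflating
#' the duration at fixed amplitude, since `V_p = 2 * A / D`.
#'
#' @param A Amplitude, degrees.
#' @param D0 Intercept, seconds.
#' @param k Slope, seconds per degree.
#' @param vp_scale Multiplicative peak-velocity scaling (1 = typical).
#' @return Duration in seconds.
#' @export
saccade_duration <- function(A, D0 = 0.021, k = 0.0022, vp_scale = 1) {
  (D0 + k * A) / vp_scale
}

#' Sample a raised-cosine saccade trajectory
#'
#' @param A Amplitude in degrees (0 gives a stationary segment).
#' @param D Duration in seconds; must be positive.
#' @param rate Sampling rate in Hz (60, 120 or 1200).
#' @param direction Unit direction vector (x, y); normalised internally.
#' @return A data.frame with columns `t`, `x`, `y` (position along the
#'   trajectory starting at the origin) and `v` (analytic angular speed).
#'   The final sample reaches displacement `A` exactly.
#' @examples
#' tr <- simulate_saccade(8, 0.050, 1200)
#' max(tr$v)  # = 2 * 8 / 0.050 = 320 deg/s
#' @export
simulate_saccade <- function(A, D, rate, direction = c(1, 0)) {
  if (!is.finite(D) || D <= 0) stop("saccade duration must be positive")
  if (A < 0) stop("saccade amplitude must be non-negative")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a non-zero vector")
  direction <- direction / nrm
  t <- seq(0, ceiling(D * rate) / rate, by = 1 / rate)
  s <- saccade_displacement(t, A, D)
  if (A == 0) s <- rep(0, length(t))
  data.frame(t = t,
             x = s * direction[1],
             y = s * direction[2],
             v = if (A == 0) rep(0, length(t)) else saccade_speed(t, A, D))
}

#' Participant-level generator parameters
#'
#' Defaults describe a typically developing adult in the cued
#' face-viewing paradigm: a bias to orient to the eyes (shifts to the
#' eyes on mouth-cued trials are more likely and faster than shifts away
#' from the eyes on eyes-cued trials), per-sample isotropic fixation
#' noise, and independent per-sample dropout.
#'
#' @param p_shift_to_eyes Probability that a mouth-cued trial contains a
#'   first gaze shift to the eyes.
#' @param p_shift_from_eyes Probability that an eyes-cued trial contains
#'   a first gaze shift away from the eyes (to the mouth).
#' @param latency_to_eyes_mean,latency_to_eyes_sd Mean/SD (seconds) of
#'   the shifted log-normal latency of shifts to the eyes.
#' @param latency_from_eyes_mean,latency_from_eyes_sd Same for shifts
#'   away from the eyes.
#' @param latency_shift Shift (seconds) of the log-normal latency
#'   distribution; keeps latencies above a physiological floor.
#' @param vp_scale Multiplicative peak-velocity scaling at fixed
#'   amplitude (durations inflate by `1 / vp_scale`); values below 1
#'   emulate tonic hypo-arousal.
#' @param noise_sd Fixation noise SD per axis, degrees.
#' @param dropout Probability that any sample is invalid.
#' @param blink_rate Probability per trial of one contiguous blink gap.
#' @param blink_dur Blink gap duration, seconds.
#' @param p_land_outside Probability that an executed shift lands outside
#'   both AOIs (such trials are excluded downstream, mirroring the
#'   paradigm in which off-AOI landings are rare).
#' @param rate Sampling rate, 60 or 120 Hz.
#' @param D0,k Main-sequence duration parameters (see
#'   [saccade_duration()]).
#' @return A list of class `participant_params`.
#' @export
participant_params <- function(p_shift_to_eyes = 0.75,
                               p_shift_from_eyes = 0.45,
                               latency_to_eyes_mean = 0.45,
                               latency_to_eyes_sd = 0.15,
                               latency_from_eyes_mean = 0.60,
                               latency_from_eyes_sd = 0.20,
                               latency_shift = 0.10,
                               vp_scale = 1,
                               noise_sd = 0.3,
                               dropout = 0.02,
                               blink_rate = 0,
                               blink_dur = 0.15,
                               p_land_outside = 0.02,
                               rate = 120,
                               D0 = 0.021, k = 0.0022) {
  p <- list(p_shift_to_eyes = p_shift_to_eyes,
            p_shift_from_eyes = p_shift_from_eyes,
            latency_to_eyes_mean = latency_to_eyes_mean,
            latency_to_eyes_sd = latency_to_eyes_sd,
            latency_from_eyes_mean = latency_from_eyes_mean,
            latency_from_eyes_sd = latency_from_eyes_sd,
            latency_shift = latency_shift,
            vp_scale = vp_scale, noise_sd = noise_sd, dropout = dropout,
            blink_rate = blink_rate, blink_dur = blink_dur,
            p_land_outside = p_land_outside, rate = rate, D0 = D0, k = k)
  for (nm in c("p_shift_to_eyes", "p_shift_from_eyes", "dropout",
               "blink_rate", "p_land_outside")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be a probability in [0, 1]")
  }
  if (p$noise_sd < 0) stop("noise_sd must be non-negative")
  if (p$vp_scale <= 0) stop("vp_scale must be positive")
  if (!p$rate %in% c(60, 120)) stop("rate must be 60 or 120 Hz")
  class(p) <- "participant_params"
  p
}

# Draw from a shifted log-normal with target mean m and SD s (seconds).
rlatency <- function(n, m, s, shift) {
  mu <- m - shift
  if (mu <= 0) stop("latency mean must exceed the distribution shift")
  sdlog <- sqrt(log(1 + (s / mu)^2))
  meanlog <- log(mu) - sdlog^2 / 2
  shift + stats::rlnorm(n, meanlog, sdlog)
}

# Uniform landing point inside an AOI rectangle, shrunk by a margin so
# noisy samples stay inside.
draw_landing <- function(rect, margin = 0.5) {
  c(stats::runif(1, rect["x_min"] + margin, rect["x_max"] - margin),
    stats::runif(1, rect["y_min"] + margin, rect["y_max"] - margin))
}

#' Simulate one cued trial
#'
#' Each trial is 1 s of fixation on a central cross followed by a 1.5 s
#' face stimulus positioned so that gaze starts inside the cued AOI
#' (which is centred on the cross location).  With the
#' condition-appropriate probability the trial contains exactly one
#' saccade from the cued AOI to the other AOI (or, rarely, to a point
#' outside both) at a drawn latency; fixation jitter and dropout are then
#' applied.  Uses the current RNG stream.
#'
#' @param condition `"eyes_cued"` or `"mouth_cued"`.
#' @param params A [participant_params()].
#' @param t0 Trial start time in seconds.
#' @param aois AOI layout for the trial; defaults to
#'   [default_aoi_set()] for `condition`.
#' @param start_pos Gaze position (degrees) at trial start.  When it is
#'   away from the cross, a return saccade to the cross is generated
#'   about 250 ms into the fixation period (as a participant re-fixating
#'   the cross after the previous trial); its kinematics are recorded in
#'   the ground truth.
#' @return A list with elements `samples` (data.frame `t`, `x`, `y`,
#'   `valid`) and `truth` (one-row data.frame with the ground-truth shift
#'   indicator, target, latency in seconds, amplitude, duration, peak
#'   velocity, and the return-saccade onset/amplitude/peak velocity when
#'   one occurred).
#' @export
simulate_trial <- function(condition = c("eyes_cued", "mouth_cued"),
                           params = participant_params(), t0 = 0,
                           aois = NULL, start_pos = c(0, 0)) {
  condition <- match.arg(condition)
  if (is.null(aois)) aois <- default_aoi_set(condition)
  rate <- params$rate
  n <- round(2.5 * rate)
  t_rel <- (seq_len(n) - 1) / rate
  stim_on <- 1.0

  cued <- if (condition == "eyes_cued") "eyes" else "mouth"
  other <- if (cued == "eyes") "mouth" else "eyes"
  p_shift <- if (condition == "mouth_cued") params$p_shift_to_eyes else params$p_shift_from_eyes

  shift_made <- stats::runif(1) < p_shift
  target <- "none"
  latency <- NA_real_; A <- NA_real_; D <- NA_real_; Vp <- NA_real_
  x <- rep(0, n); y <- rep(0, n)

  # re-fixation of the cross at the start of the fixation period
  ret_onset <- NA_real_; ret_A <- NA_real_; ret_Vp <- NA_real_
  A0 <- sqrt(sum(start_pos^2))
  if (A0 > 0.5) {
    ret_lat <- rlatency(1, 0.25, 0.05, params$latency_shift)
    ret_D <- saccade_duration(A0, params$D0, params$k, params$vp_scale)
    tau0 <- t_rel - ret_lat
    s0 <- saccade_displacement(tau0, A0, ret_D)
    frac <- 1 - s0 / A0                      # 1 at start_pos, 0 at cross
    x <- x + start_pos[1] * frac
    y <- y + start_pos[2] * frac
    ret_onset <- t0 + ret_lat; ret_A <- A0; ret_Vp <- 2 * A0 / ret_D
  }

  if (shift_made) {
    target <- if (stats::runif(1) < params$p_land_outside) "outside" else other
    land <- if (target == "outside") {
      # lateral to the gap between the AOIs, clear of both rectangles
      c(sample(c(-7, 7), 1), if (condition == "eyes_cued") 2.5 else -2.5)
    } else {
      draw_landing(aois[[other]])
    }
    A <- sqrt(sum(land^2))
    D <- saccade_duration(A, params$D0, params$k, params$vp_scale)
    if (condition == "mouth_cued") {
      lm <- params$latency_to_eyes_mean; ls <- params$latency_to_eyes_sd
    } else {
      lm <- params$latency_from_eyes_mean; ls <- params$latency_from_eyes_sd
    }
    for (i in 1:100) {
      latency <- rlatency(1, lm, ls, params$latency_shift)
      if (latency + D < 1.45) break
    }
    Vp <- 2 * A / D
    tau <- t_rel - (stim_on + latency)
    s <- saccade_displacement(tau, A, D)
    dir <- land / A
    x <- x + s * dir[1]
    y <- y + s * dir[2]
  }

  if (params$noise_sd > 0) {
    x <- x + stats::rnorm(n, 0, params$noise_sd)
    y <- y + stats::rnorm(n, 0, params$noise_sd)
  }
  valid <- stats::runif(n) > params$dropout
  if (params$blink_rate > 0 && stats::runif(1) < params$blink_rate) {
    b0 <- stats::runif(1, 0, 2.5 - params$blink_dur)
    valid[t_rel >= b0 & t_rel < b0 + params$blink_dur] <- FALSE
  }

  list(
    samples = data.frame(t = t0 + t_rel, x = x, y = y, valid = valid),
    truth = data.frame(condition = condition, shift_made = shift_made,
                       target = target, latency = latency,
                       amplitude = A, duration = D, peak_velocity = Vp,
                       onset_abs = t0 + stim_on + latency,
                       return_onset = ret_onset, return_amplitude = ret_A,
                       return_peak_velocity = ret_Vp),
    end_pos = if (shift_made) land else c(0, 0)
  )
}

#' Simulate a full experimental session
#'
#' One session is 60 trials, 30 per cueing condition.  Ten actor
#' identities each appear six times, displaying angry, happy and neutral
#' expressions equally often (20 trials per emotion); each
#' actor-by-emotion pairing occurs once per condition.  Trial order is
#' randomised.  Trials are concatenated at 2.5 s intervals into one
#' continuous recording.
#'
#' @param params A [participant_params()].
#' @param seed Optional integer seed; the same seed reproduces the
#'   session exactly.
#' @param participant Participant identifier stored in the outputs.
#' @return A list of class `gaze_session` with elements `recording`
#'   (a [gaze_recording()]), `trials` (metadata with per-trial stimulus
#'   onset), `truth` (ground truth rows from [simulate_trial()]) and
#'   `params`.
#' @export
simulate_session <- function(params = participant_params(), seed = NULL,
                             participant = "p1") {
  if (!is.null(seed)) set.seed(seed)
  design <- expand.grid(actor = paste0("actor", sprintf("%02d", 1:10)),
                        emotion = c("angry", "happy", "neutral"),
                        condition = c("eyes_cued", "mouth_cued"),
                        stringsAsFactors = FALSE)
  design <- design[sample.int(nrow(design)), , drop = FALSE]
  trial_dur <- 2.5

  samples <- vector("list", nrow(design))
  truths <- vector("list", nrow(design))
  pos <- c(0, 0)
  for (i in seq_len(nrow(design))) {
    t0 <- (i - 1) * trial_dur
    tr <- simulate_trial(design$condition[i], params, t0 = t0,
                         start_pos = pos)
    samples[[i]] <- tr$samples
    truths[[i]] <- tr$truth
    pos <- tr$end_pos
  }
  smp <- do.call(rbind, samples)
  truth <- do.call(rbind, truths)
  truth$trial <- seq_len(nrow(design))
  trials <- data.frame(trial = seq_len(nrow(design)),
                       participant = participant,
                       condition = design$condition,
                       emotion = design$emotion,
                       actor = design$actor,
                       t_start = (seq_len(nrow(design)) - 1) * trial_dur,
                       onset = (seq_len(nrow(design)) - 1) * trial_dur + 1.0,
                       stringsAsFactors = FALSE)
  truth <- truth[, c("trial", setdiff(names(truth), "trial"))]
  structure(
    list(recording = gaze_recording(smp$t, smp$x, smp$y, smp$valid,
                                    rate = params$rate),
         trials = trials, truth = truth, params = params,
         participant = participant),
    class = "gaze_session"
  )
}

#' Cohort configuration
#'
#' Describes one or more participant groups for [simulate_cohort()].
#' Each group carries a sample size and group-mean generator parameters;
#' participant heterogeneity (the random-intercept structure downstream
#' models rely on) is injected as logit-normal jitter on the shift
#' probabilities, log-normal jitter on latency means, and log-normal
#' jitter on the peak-velocity scaling.
#'
#' @param groups Named list; each element a list with `n` (participants)
#'   and any [participant_params()] overrides.
#' @param sd_logit_p Between-participant SD of shift probabilities on the
#'   logit scale.
#' @param sd_log_latency Between-participant SD of latency means on the
#'   log scale.
#' @param sd_log_vp Between-participant SD of `vp_scale` on the log
#'   scale.
#' @param seed Integer seed for the whole cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(groups, sd_logit_p = 0.5, sd_log_latency = 0.15,
                          sd_log_vp = 0.08, seed = 1) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list")
  }
  for (g in names(groups)) {
    if (is.null(groups[[g]]$n) || groups[[g]]$n < 1) {
      stop("group '", g, "' must have n >= 1")
    }
    ov <- setdiff(names(groups[[g]]), "n")
    bad <- setdiff(ov, names(formals(participant_params)))
    if (length(bad)) stop("unknown participant parameter(s): ",
                          paste(bad, collapse = ", "))
    probs <- intersect(ov, c("p_shift_to_eyes", "p_shift_from_eyes",
                             "dropout", "blink_rate", "p_land_outside"))
    for (nm in probs) {
      v <- groups[[g]][[nm]]
      if (v < 0 || v > 1) stop("config error: ", nm, " in group '", g,
                               "' must lie in [0, 1]")
    }
  }
  structure(list(groups = groups, sd_logit_p = sd_logit_p,
                 sd_log_latency = sd_log_latency, sd_log_vp = sd_log_vp,
                 seed = seed),
            class = "cohort_config")
}

#' Two-group cohort emulating the study design
#'
#' A Williams-syndrome-like group with no eye bias (equal shift
#' probabilities and latencies in both conditions) and reduced peak
#' saccadic velocity, against a typically-developed-adult-like group with
#' an eye bias.  Default sample sizes follow the study (37 vs 50); the
#' default peak-velocity scaling 0.757 is the ratio of the reported group
#' means of the velocity/amplitude index (22.45 / 29.67).
#'
#' @param n_ws,n_td Group sample sizes.
#' @param vp_scale_ws Peak-velocity scaling of the WS-like group.
#' @param seed Cohort seed.
#' @param ... Passed to [cohort_config()].
#' @return A [cohort_config()].
#' @export
cohort_config_ws_td <- function(n_ws = 37, n_td = 50, vp_scale_ws = 0.757,
                                seed = 1, ...) {
  cohort_config(
    groups = list(
      WS = list(n = n_ws, p_shift_to_eyes = 0.5, p_shift_from_eyes = 0.5,
                latency_to_eyes_mean = 0.55, latency_from_eyes_mean = 0.55,
                latency_to_eyes_sd = 0.18, latency_from_eyes_sd = 0.18,
                vp_scale = vp_scale_ws),
      TD = list(n = n_td)
    ),
    seed = seed, ...
  )
}

#' Simulate a cohort of sessions
#'
#' Draws participant-level parameters around each group's means (see
#' [cohort_config()]) and generates one full session per participant.
#' Fully reproducible from the config seed.
#'
#' @param config A [cohort_config()].
#' @return A list of class `gaze_cohort` with `sessions` (list of
#'   [simulate_session()] results), `participants` (data.frame with
#'   `participant`, `group`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sessions <- list()
  parts <- list()
  idx <- 0
  for (g in names(config$groups)) {
    grp <- config$groups[[g]]
    base <- do.call(participant_params, grp[setdiff(names(grp), "n")])
    for (i in seq_len(grp$n)) {
      idx <- idx + 1
      pp <- base
      jit_p <- function(p) stats::plogis(stats::qlogis(p) +
                                           stats::rnorm(1, 0, config$sd_logit_p))
      pp$p_shift_to_eyes <- jit_p(base$p_shift_to_eyes)
      pp$p_shift_from_eyes <- jit_p(base$p_shift_from_eyes)
      lat_mult <- exp(stats::rnorm(1, 0, config$sd_log_latency))
      pp$latency_to_eyes_mean <- base$latency_to_eyes_mean * lat_mult
      pp$latency_from_eyes_mean <- base$latency_from_eyes_mean * lat_mult
      pp$vp_scale <- base$vp_scale * exp(stats::rnorm(1, 0, config$sd_log_vp))
      id <- sprintf("%s_%03d", g, i)
      sessions[[id]] <- simulate_session(pp, seed = NULL, participant = id)
      parts[[id]] <- data.frame(participant = id, group = g,
                                stringsAsFactors = FALSE)
    }
  }
  structure(list(sessions = sessions,
                 participants = do.call(rbind, c(parts, make.row.names = FALSE)),
                 config = config),
            class = "gaze_cohort")
}
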