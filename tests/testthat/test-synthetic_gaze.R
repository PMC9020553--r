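test_that("raised-cosine saccade obeys its closed-form kinematics", {
  # A = 8 deg, D = 50 ms: V_p = 2A/D = 320 deg/s, V_p/A = 40 1/s
  tr <- simulate_saccade(8, 0.050, 1200)
  expect_equal(max(tr$v), 320, tolerance = 1e-2)
  expect_equal(max(tr$v) / 8, 40, tolerance = 1e-2)
  # total displacement equals A
  expect_equal(tr$x[nrow(tr)], 8, tolerance = 1e-6)
  # numerical quadrature of the sampled speed recovers the amplitude
  dt <- diff(tr$t)
  area <- sum((tr$v[-1] + tr$v[-length(tr$v)]) / 2 * dt)
  expect_equal(area, 8, tolerance = 8 * 0.005)

  # zero amplitude -> stationary
  tr0 <- simulate_saccade(0, 0.050, 120)
  expect_true(all(tr0$v == 0))
  expect_true(all(tr0$x == 0 & tr0$y == 0))

  expect_error(simulate_saccade(8, 0, 120), "positive")
  expect_error(simulate_saccade(8, -0.01, 120), "positive")
})

test_that("main-sequence durations make the velocity/amplitude ratio fall with amplitude", {
  A <- seq(2, 14, by = 0.5)
  ratio <- 2 * A / saccade_duration(A) / A      # V_p / A = 2 / D
  expect_true(all(diff(ratio) < 0))
  # peak velocities in the physiological range at the paradigm's
  # inter-AOI amplitudes (roughly 4-10 degrees)
  vp <- 2 * A / saccade_duration(A)
  expect_true(all(vp[A >= 4 & A <= 10] > 100 & vp[A >= 4 & A <= 10] < 500))
})

test_that("deterministic trial parameterisations yield exact ground truth", {
  # shift probability 0: gaze never leaves the cued AOI
  pp0 <- participant_params(p_shift_to_eyes = 0, p_shift_from_eyes = 0,
                            noise_sd = 0, dropout = 0)
  set.seed(1)
  tr <- simulate_trial("mouth_cued", pp0)
  expect_false(tr$truth$shift_made)
  expect_true(all(abs(tr$samples$x) < 1e-12 & abs(tr$samples$y) < 1e-12))

  # shift probability 1 with a degenerate latency distribution
  pp1 <- participant_params(p_shift_to_eyes = 1, p_land_outside = 0,
                            latency_to_eyes_mean = 0.4,
                            latency_to_eyes_sd = 1e-6,
                            noise_sd = 0, dropout = 0)
  set.seed(2)
  tr1 <- simulate_trial("mouth_cued", pp1)
  expect_true(tr1$truth$shift_made)
  expect_equal(tr1$truth$target, "eyes")
  expect_equal(tr1$truth$latency, 0.4, tolerance = 1e-3)
  # ground-truth consistency: emitted samples reach the landing point
  expect_equal(tr1$truth$peak_velocity,
               2 * tr1$truth$amplitude / tr1$truth$duration)
  last <- nrow(tr1$samples)
  end_disp <- sqrt(tr1$samples$x[last]^2 + tr1$samples$y[last]^2)
  expect_equal(end_disp, tr1$truth$amplitude, tolerance = 1e-9)
})

test_that("trial epochs are 1 s fixation plus 1.5 s stimulus", {
  pp <- participant_params()
  set.seed(3)
  tr <- simulate_trial("eyes_cued", pp, t0 = 10)
  expect_equal(min(tr$samples$t), 10)
  expect_equal(nrow(tr$samples), round(2.5 * pp$rate))
  expect_equal(max(tr$samples$t), 10 + 2.5 - 1 / pp$rate)
  # the drawn shift (if any) always starts inside the stimulus epoch
  if (tr$truth$shift_made) {
    expect_gt(tr$truth$onset_abs, 10 + 1.0)
    expect_lt(tr$truth$onset_abs, 10 + 2.5)
  }
})

test_that("a session reproduces the balanced 60-trial paradigm", {
  ses <- simulate_session(participant_params(), seed = 10)
  expect_equal(nrow(ses$trials), 60)
  expect_equal(unname(table(ses$trials$condition)["eyes_cued"]), 30L)
  expect_equal(unname(table(ses$trials$condition)["mouth_cued"]), 30L)
  expect_equal(as.integer(table(ses$trials$emotion)), c(20L, 20L, 20L))
  expect_true(all(table(ses$trials$actor) == 6))
  expect_true(all(table(ses$trials$actor, ses$trials$emotion) == 2))
  # continuous strictly increasing recording
  expect_true(all(diff(ses$recording$t) > 0))
})

test_that("sessions are reproducible from the seed and differ across seeds", {
  a <- simulate_session(participant_params(), seed = 7)
  b <- simulate_session(participant_params(), seed = 7)
  c <- simulate_session(participant_params(), seed = 8)
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$recording$x, c$recording$x))
})

test_that("cohorts honour group sizes and validate probabilities", {
  cfg <- cohort_config(groups = list(g1 = list(n = 3), g2 = list(n = 2)),
                       seed = 1)
  coh <- simulate_cohort(cfg)
  expect_equal(length(coh$sessions), 5)
  expect_equal(as.integer(table(coh$participants$group)), c(3L, 2L))
  expect_error(cohort_config(groups = list(g = list(n = 2,
                                                    p_shift_to_eyes = 1.4))),
               "config error")
  expect_error(cohort_config(groups = list(g = list(n = 0))), "n >= 1")
  # the study-sized preset: 37 + 50 participants
  preset <- cohort_config_ws_td()
  expect_equal(preset$groups$WS$n + preset$groups$TD$n, 87)
})

test_that("peak-velocity scaling is recovered in the ground truth", {
  cfg <- cohort_config(
    groups = list(slow = list(n = 6, vp_scale = 0.75, p_shift_to_eyes = 1,
                              p_shift_from_eyes = 1),
                  typical = list(n = 6, p_shift_to_eyes = 1,
                                 p_shift_from_eyes = 1)),
    sd_log_vp = 0.02, seed = 4)
  coh <- simulate_cohort(cfg)
  ratio_of <- function(ids) {
    mean(unlist(lapply(coh$sessions[ids], function(s) {
      tt <- s$truth[s$truth$shift_made, ]
      tt$peak_velocity / tt$amplitude
    })))
  }
  grp <- split(coh$participants$participant, coh$participants$group)
  rel <- ratio_of(grp$slow) / ratio_of(grp$typical)
  expect_equal(rel, 0.75, tolerance = 0.05)
})

test_that("null group effects leave summary distributions indistinguishable", {
  # same generating parameters in both groups: two-sample test on the
  # ground-truth shift rates should not reject at alpha = 0.05 in most
  # seeds (checked over a few seeds to keep runtime bounded)
  ps <- vapply(1:5, function(seed) {
    cfg <- cohort_config(groups = list(a = list(n = 8), b = list(n = 8)),
                         seed = 100 + seed)
    coh <- simulate_cohort(cfg)
    rate_of <- function(s) mean(s$truth$shift_made)
    r <- vapply(coh$sessions, rate_of, numeric(1))
    g <- coh$participants$group
    stats::t.test(r[g == "a"], r[g == "b"])$p.value
  }, numeric(1))
  expect_gt(sum(ps > 0.05), 3)
})
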