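aois_ec <- default_aoi_set("eyes_cued")
aois_mc <- default_aoi_set("mouth_cued")

test_that("AOI assignment uses inclusive rectangle containment", {
  # eyes centre
  expect_equal(assign_aoi(0, 0, aois_ec), "eyes")
  # point exactly on the mouth AOI edge counts as mouth
  expect_equal(assign_aoi(3, 5, aois_ec), "mouth")
  expect_equal(assign_aoi(0, unname(aois_ec$mouth["y_min"]), aois_ec),
               "mouth")
  # far away
  expect_equal(assign_aoi(20, 20, aois_ec), "outside")
  # vectorised
  expect_equal(assign_aoi(c(0, 20), c(0, 20), aois_ec),
               c("eyes", "outside"))
})

test_that("trial validity needs cued-AOI gaze at onset and enough valid samples", {
  pp <- participant_params(noise_sd = 0.1, dropout = 0)
  set.seed(11)
  tr <- simulate_trial("eyes_cued", pp)
  rec <- gaze_recording(tr$samples$t, tr$samples$x, tr$samples$y,
                        tr$samples$valid, 120)
  trial <- list(onset = 1.0, condition = "eyes_cued")
  expect_true(trial_validity(rec, trial))

  # gaze parked on the mouth at onset of an eyes-cued trial -> invalid
  rec_off <- gaze_recording(tr$samples$t, tr$samples$x,
                            tr$samples$y + 5, tr$samples$valid, 120)
  expect_false(trial_validity(rec_off, trial))

  # only 30% of epoch samples valid -> invalid at the 50% default
  v <- tr$samples$valid
  epoch <- which(tr$samples$t >= 1.0)
  v[epoch[seq_along(epoch) %% 10 >= 3]] <- FALSE
  rec_sparse <- gaze_recording(tr$samples$t, tr$samples$x, tr$samples$y,
                               v, 120)
  expect_false(trial_validity(rec_sparse, trial))
})

test_that("first gaze shift finds the departure saccade and its latency", {
  pp <- participant_params(p_shift_to_eyes = 1, p_land_outside = 0,
                           latency_to_eyes_mean = 0.4,
                           latency_to_eyes_sd = 1e-6,
                           noise_sd = 0, dropout = 0)
  set.seed(12)
  tr <- simulate_trial("mouth_cued", pp)
  rec <- gaze_recording(tr$samples$t, tr$samples$x, tr$samples$y,
                        tr$samples$valid, 120)
  ev <- classify_ivt(rec)
  trial <- list(onset = 1.0, condition = "mouth_cued")
  fg <- first_gaze_shift(ev, trial)
  expect_true(fg$shift_made)
  expect_equal(fg$target, "eyes")
  expect_equal(fg$latency, 400, tolerance = 1000 / 120)  # within 1 sample
  expect_false(fg$anticipatory)

  # no saccade leaves the cued AOI -> no shift
  pp0 <- participant_params(p_shift_to_eyes = 0, p_shift_from_eyes = 0,
                            noise_sd = 0, dropout = 0)
  tr0 <- simulate_trial("mouth_cued", pp0)
  rec0 <- gaze_recording(tr0$samples$t, tr0$samples$x, tr0$samples$y,
                         tr0$samples$valid, 120)
  fg0 <- first_gaze_shift(classify_ivt(rec0), trial)
  expect_false(fg0$shift_made)
  expect_equal(fg0$target, "none")
  expect_true(is.na(fg0$latency))
})

test_that("shifts landing outside both AOIs are flagged and excluded downstream", {
  pp <- participant_params(p_shift_to_eyes = 1, p_land_outside = 1,
                           noise_sd = 0, dropout = 0)
  set.seed(13)
  tr <- simulate_trial("mouth_cued", pp)
  rec <- gaze_recording(tr$samples$t, tr$samples$x, tr$samples$y,
                        tr$samples$valid, 120)
  ev <- classify_ivt(rec)
  fg <- first_gaze_shift(ev, list(onset = 1.0, condition = "mouth_cued"))
  expect_true(fg$shift_made)
  expect_equal(fg$target, "outside")

  res <- data.frame(condition = "mouth_cued", valid = TRUE,
                    shift_made = TRUE, target = "outside", latency = 400)
  summ <- summarize_participant(res, participant = "p")
  expect_equal(summ$n_valid, 0)   # excluded from numerator and denominator
})

test_that("participant summaries implement the inclusion rules", {
  mk <- function(cond, n_valid, n_shift, n_invalid = 0) {
    noncued <- if (cond == "eyes_cued") "mouth" else "eyes"
    data.frame(
      condition = cond,
      valid = c(rep(TRUE, n_valid), rep(FALSE, n_invalid)),
      shift_made = c(rep(TRUE, n_shift), rep(FALSE, n_valid - n_shift),
                     rep(FALSE, n_invalid)),
      target = c(rep(noncued, n_shift), rep("none", n_valid - n_shift),
                 rep("none", n_invalid)),
      latency = c(seq(300, by = 10, length.out = n_shift),
                  rep(NA, n_valid - n_shift + n_invalid))
    )
  }
  # 10 valid mouth-cued trials with 6 shifts -> proportion 0.6
  s <- summarize_participant(mk("mouth_cued", 10, 6), participant = "p")
  expect_equal(s$prop_shift, 0.6)
  expect_equal(s$mean_latency, mean(seq(300, by = 10, length.out = 6)))
  expect_false(s$excluded)

  # fewer than five valid trials -> condition excluded
  s4 <- summarize_participant(mk("eyes_cued", 4, 2), participant = "p")
  expect_true(s4$excluded)
  s5 <- summarize_participant(mk("eyes_cued", 5, 2), participant = "p")
  expect_false(s5$excluded)

  # zero shifts: proportion 0, latency undefined
  s0 <- summarize_participant(mk("mouth_cued", 8, 0), participant = "p")
  expect_equal(s0$prop_shift, 0)
  expect_true(is.na(s0$mean_latency))
})

test_that("latency agreement behaves at the limits and on simulated cohorts", {
  expect_equal(latency_agreement(c(300, 400, 500), c(300, 400, 500))$r, 1)
  # orthogonalised toy vectors: r ~ 0
  a <- c(1, -1, 1, -1, 1, -1)
  b <- c(1, 1, -1, -1, 1, 1) - mean(c(1, 1, -1, -1, 1, 1))
  expect_lt(abs(latency_agreement(400 + 50 * a, 400 + 50 * b)$r), 0.35)
  # too few pairs -> flagged
  la <- latency_agreement(c(1, 2), c(1, 2))
  expect_true(la$insufficient)
  expect_true(is.na(la$r))

  # simulated session where nearly all departures land in the other AOI:
  # latency-to-AOI and latency-to-anywhere agree almost perfectly
  pp <- participant_params(p_shift_to_eyes = 0.9, p_shift_from_eyes = 0.9,
                           p_land_outside = 0.05)
  ses <- simulate_session(pp, seed = 21)
  ev <- classify_ivt(ses$recording, median_filter = TRUE)
  sh <- session_shift_results(ses$recording, ev, ses$trials)
  lat_any <- sh$latency[sh$shift_made]
  lat_aoi <- ifelse(sh$target[sh$shift_made] == "outside", NA,
                    sh$latency[sh$shift_made])
  la2 <- latency_agreement(lat_aoi, lat_any)
  expect_gt(la2$r, 0.99)
})

test_that("recovered shift proportion converges to the generating probability", {
  # pool five sessions of one fixed participant: 300 trials, 150/condition
  pp <- participant_params(p_shift_to_eyes = 0.7, p_shift_from_eyes = 0.3)
  all_sh <- do.call(rbind, lapply(1:5, function(k) {
    ses <- simulate_session(pp, seed = 500 + k)
    ev <- classify_ivt(ses$recording, median_filter = TRUE)
    session_shift_results(ses$recording, ev, ses$trials)
  }))
  s <- summarize_participant(all_sh, min_valid_trials = 5,
                             participant = "pooled")
  p_mc <- s$prop_shift[s$condition == "mouth_cued"]
  p_ec <- s$prop_shift[s$condition == "eyes_cued"]
  expect_equal(p_mc, 0.7, tolerance = 0.12)
  expect_equal(p_ec, 0.3, tolerance = 0.12)
})

test_that("latency recovery is unbiased to within one sample on clean data", {
  pp <- participant_params(p_shift_to_eyes = 1, p_shift_from_eyes = 1,
                           p_land_outside = 0, noise_sd = 0, dropout = 0)
  ses <- simulate_session(pp, seed = 31)
  ev <- classify_ivt(ses$recording)
  sh <- session_shift_results(ses$recording, ev, ses$trials)
  tru <- ses$truth
  got <- sh$shift_made & tru$shift_made
  bias <- mean(sh$latency[got] - tru$latency[got] * 1000)
  expect_lt(abs(bias), 1000 / 120)
})
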