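# A ramp trial: rest at start_angle, constant-velocity stretch to 180 deg,
# optional EMG burst of given amplitude from burst_at onward.
ramp_trial <- function(v = 100, fs = 1000, start_angle = 40, rest_s = 0.7,
                       burst_at = NA, burst_amp = 20, emg_sd = 1,
                       seed = 1, id = "t1") {
  set.seed(seed)
  n_rest <- round(rest_s * fs)
  ramp <- seq(start_angle, 180, by = v / fs)
  angle <- c(rep(start_angle, n_rest), ramp, rep(180, round(0.2 * fs)))
  emg <- rnorm(length(angle), 0, emg_sd)
  if (!is.na(burst_at)) emg[burst_at:length(emg)] <- emg[burst_at:length(emg)] + burst_amp
  stretch_trial(pmin(angle, 180), emg, fs, id, "moderate")
}

test_that("detect_onset finds a sustained burst within a short latency", {
  # burst planted at sample 1000, well after stretch start (~700)
  tr <- ramp_trial(burst_at = 1000, seed = 2)
  onset <- detect_onset(tr)
  expect_true(onset >= 1000 && onset <= 1002)
})

test_that("detect_onset rejects flat EMG and sub-persistence excursions", {
  # no burst at all
  expect_true(is.na(detect_onset(ramp_trial(seed = 3))))
  # a 10 ms excursion does not meet the 25 ms persistence rule
  tr <- ramp_trial(seed = 4)
  tr$emg[1000:1009] <- tr$emg[1000:1009] + 20
  expect_true(is.na(detect_onset(tr)))
  # constant EMG: degenerate recording is an error, not a silent zero
  flat <- ramp_trial(seed = 5)
  flat$emg[] <- 1
  expect_error(detect_onset(flat), "SD is zero")
})

test_that("raising the detection threshold never yields an earlier onset", {
  tr <- ramp_trial(burst_at = 1000, burst_amp = 6, seed = 6)
  onsets <- vapply(c(2, 3, 4, 5), function(k) {
    o <- detect_onset(tr, k_sd = k)
    if (is.na(o)) Inf else as.numeric(o)
  }, numeric(1))
  expect_true(all(diff(onsets) >= 0))
})

test_that("dynamic_threshold reads angle and velocity off the ramp", {
  tr <- ramp_trial(v = 100, seed = 7)
  onset <- which(tr$angle >= 120)[1]
  th <- dynamic_threshold(tr, onset)
  expect_equal(th$angle_deg, tr$angle[onset])
  expect_lt(abs(th$angle_deg - 120), 0.2)
  expect_lt(abs(th$velocity_dps - 100), 0.5)
  # noisy goniometer: velocity still within 5% after smoothing
  set.seed(8)
  tr2 <- tr
  tr2$angle <- pmin(pmax(tr$angle + rnorm(length(tr$angle), 0, 0.2), 0), 180)
  th2 <- dynamic_threshold(tr2, onset)
  expect_lt(abs(th2$velocity_dps - 100) / 100, 0.05)
  # constant trace: velocity 0 (rejected downstream)
  tr3 <- ramp_trial(seed = 9)
  expect_equal(dynamic_threshold(tr3, 100)$velocity_dps, 0, tolerance = 1e-9)
  expect_error(dynamic_threshold(tr, 1), "range")
})

test_that("estimate_tsrt recovers an exact linear threshold relation", {
  th <- data.frame(velocity_dps = c(50, 100, 150),
                   angle_deg = c(120, 100, 80))
  est <- estimate_tsrt(th, min_trials = 3)
  expect_equal(est$tsrt_deg, 140, tolerance = 1e-9)
  expect_equal(est$slope, -0.4, tolerance = 1e-9)
  expect_equal(est$r_squared, 1)
  expect_equal(est$residual_sd, 0, tolerance = 1e-9)
  expect_true(est$in_range)
  expect_equal(est$n_trials_used, 3L)
  # a threshold extrapolating beyond 180 deg is kept, flagged out of range
  th2 <- data.frame(velocity_dps = c(50, 100, 150),
                    angle_deg = 190 - 0.1 * c(50, 100, 150))
  expect_false(estimate_tsrt(th2, 3)$in_range)
  expect_error(estimate_tsrt(th[1:2, ], 3), "usable")
  th3 <- data.frame(velocity_dps = rep(100, 5), angle_deg = 1:5)
  expect_error(estimate_tsrt(th3, 3), "identical")
})

test_that("intercept recovery is accurate and unbiased at protocol noise", {
  # fixed-seed single protocol: within 4 degrees of the planted threshold
  set.seed(107)
  est <- estimate_tsrt(simulate_thresholds(107.4, -0.3, 3, 20), 5)
  expect_lt(abs(est$tsrt_deg - 107.4), 4)
  # 200 replicates: mean absolute intercept error below 1.5 degrees
  # (the full 500-replicate run backs the acceptance suite)
  set.seed(211)
  err <- replicate(200, {
    e <- estimate_tsrt(simulate_thresholds(107.4, -0.3, 3, 20), 5)
    e$tsrt_deg - 107.4
  })
  expect_lt(mean(abs(err)), 1.5)
})

test_that("trial order does not affect the estimate", {
  set.seed(13)
  th <- simulate_thresholds(100, -0.3, 3, 20)
  est1 <- estimate_tsrt(th, 5)
  est2 <- estimate_tsrt(th[sample(nrow(th)), ], 5)
  expect_equal(est1$tsrt_deg, est2$tsrt_deg, tolerance = 1e-12)
  expect_equal(est1$slope, est2$slope, tolerance = 1e-12)
})

test_that("run_protocol chains detection, thresholds and regression", {
  spec <- synthetic_spec()
  spec$stretch$angle_noise_sd <- 0
  trials <- generate_stretch_cohort(107.4, spec, seed = 41)
  est <- run_protocol(trials)
  expect_equal(est$n_trials_used, 20L)
  # noiseless chain recovers the planted threshold to a tenth of a degree
  expect_lt(abs(est$tsrt_deg - 107.4), 0.1)
  expect_equal(est$exclusions$no_onset, 0L)
  # planted threshold outside the range: no bursts, too few usable trials
  spec2 <- synthetic_spec()
  spec2$stretch$angle_noise_sd <- 0
  silent <- generate_stretch_cohort(260, spec2, seed = 42)
  expect_error(run_protocol(silent), "usable")
  expect_error(run_protocol(list()), "no stretch trials")
})

test_that("trials without a reflex burst are excluded and tallied", {
  spec <- synthetic_spec()
  spec$stretch$angle_noise_sd <- 0
  good <- generate_stretch_cohort(107.4, spec, seed = 43)[1:8]
  silent <- generate_stretch_cohort(260, spec, seed = 44)[1:12]
  est <- run_protocol(c(good, silent), min_trials = 5)
  expect_equal(est$n_trials_used, 8L)
  expect_equal(est$exclusions$no_onset, 12L)
  expect_error(run_protocol(c(good[1:3], silent), min_trials = 5), "usable")
})

test_that("trial TSV round-trip preserves the estimate", {
  spec <- synthetic_spec()
  spec$stretch$angle_noise_sd <- 1
  trials <- generate_stretch_cohort(110, spec, seed = 45)[1:6]
  dir <- tempfile("trials_")
  dir.create(dir)
  man <- data.frame(trial_id = character(0), file = character(0),
                    nominal_speed = character(0))
  for (tr in trials) {
    f <- paste0(tr$trial_id, ".tsv")
    tt <- seq_along(tr$angle) / tr$fs
    write.table(data.frame(time_s = tt, angle_deg = tr$angle, emg = tr$emg),
                file.path(dir, f), sep = "\t", row.names = FALSE)
    man <- rbind(man, data.frame(trial_id = tr$trial_id, file = f,
                                 nominal_speed = tr$nominal_speed))
  }
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE)
  back <- read_trials(file.path(dir, "manifest.tsv"))
  expect_length(back, 6L)
  est1 <- run_protocol(trials, min_trials = 5)
  est2 <- run_protocol(back, min_trials = 5)
  expect_equal(est2$tsrt_deg, est1$tsrt_deg, tolerance = 1e-6)
})
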