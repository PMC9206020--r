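# Moving average with shrinking windows at the edges, so the output has the
# same length and no NA padding. sides = 2 centers the window (used for the
# angle trace); sides = 1 is causal/trailing (used for the EMG envelope, so
# a burst cannot raise the envelope before it starts).
moving_average <- function(x, width, sides = 2L) {
  width <- max(1L, as.integer(width))
  n <- length(x)
  cs <- cumsum(c(0, x))
  if (sides == 2L) {
    half <- width %/% 2L
    lo <- pmax(1L, seq_len(n) - half)
    hi <- pmin(n, seq_len(n) + half)
  } else {
    lo <- pmax(1L, seq_len(n) - width + 1L)
    hi <- seq_len(n)
  }
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Construct a passive-stretch trial
#'
#' One recording of an elbow stretch toward full extension (180 deg):
#' goniometer angle and surface EMG of the stretched flexor, sampled at a
#' fixed rate.
#'
#' @param angle numeric vector, elbow angle in degrees within \[0, 180\].
#' @param emg numeric vector, same length, arbitrary amplitude units.
#' @param fs sampling rate in Hz.
#' @param trial_id identifier string.
#' @param nominal_speed `"slow"`, `"moderate"` or `"fast"`.
#' @return a `stretch_trial`.
#' @export
stretch_trial <- function(angle, emg, fs, trial_id = "trial",
                          nominal_speed = c("slow", "moderate", "fast")) {
  nominal_speed <- match.arg(nominal_speed)
  stopifnot(length(angle) == length(emg), length(angle) >= 2L, fs > 0)
  if (any(!is.finite(angle)) || any(!is.finite(emg))) {
    stop("angle and emg traces must be finite")
  }
  if (any(angle < 0) || any(angle > 180)) stop("angle must lie in [0, 180] degrees")
  structure(list(trial_id = as.character(trial_id), fs = fs,
                 angle = as.numeric(angle), emg = as.numeric(emg),
                 nominal_speed = nominal_speed),
            class = "stretch_trial")
}

# Smoothed angular velocity trace (deg/s): moving-average smoothing of the
# angle followed by a central first difference.
angle_velocity <- function(trial, angle_smooth_ms = 50) {
  sm <- moving_average(trial$angle, round(angle_smooth_ms * trial$fs / 1000))
  n <- length(sm)
  v <- numeric(n)
  v[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / 2 * trial$fs
  v[1] <- v[2]
  v[n] <- v[n - 1]
  v
}

# First sample where the smoothed angular velocity exceeds vel_thresh
# (deg/s), marking the start of the imposed stretch.
stretch_start <- function(trial, vel_thresh = 5, angle_smooth_ms = 50) {
  v <- angle_velocity(trial, angle_smooth_ms)
  idx <- which(v > vel_thresh)
  if (length(idx) == 0L) return(NA_integer_)
  idx[1]
}

#' Detect reflex EMG onset in a stretch trial
#'
#' The EMG is full-wave rectified and smoothed with a short causal
#' (trailing) moving-average envelope, so a burst cannot raise the envelope
#' before it begins. Background level and variability are measured in a baseline
#' window immediately preceding stretch start (first sample where smoothed
#' angular velocity exceeds 5 deg/s). The reflex onset is the first sample
#' after stretch start at which the envelope rises and remains `k_sd`
#' standard deviations above the background mean for `persist_ms`
#' milliseconds.
#'
#' @param trial a `stretch_trial`.
#' @param baseline_window_ms baseline duration before stretch start
#'   (default 200 ms).
#' @param k_sd threshold in baseline standard deviations (default 3).
#' @param persist_ms required supra-threshold duration (default 25 ms).
#' @param envelope_ms EMG envelope moving-average width (default 5 ms, kept
#'   short relative to the persistence window so that envelope
#'   autocorrelation cannot satisfy the persistence rule by itself).
#' @param angle_smooth_ms angle smoothing width for the velocity trace
#'   (default 50 ms).
#' @param vel_thresh stretch-start velocity criterion in deg/s (default 5).
#' @return onset sample index, or `NA_integer_` if no onset satisfies the
#'   persistence rule.
#' @export
detect_onset <- function(trial, baseline_window_ms = 200, k_sd = 3,
                         persist_ms = 25, envelope_ms = 5,
                         angle_smooth_ms = 50, vel_thresh = 5) {
  fs <- trial$fs
  n_persist <- max(1L, as.integer(round(persist_ms * fs / 1000)))
  env <- moving_average(abs(trial$emg), round(envelope_ms * fs / 1000),
                        sides = 1L)
  start <- stretch_start(trial, vel_thresh, angle_smooth_ms)
  if (is.na(start)) stop(sprintf("trial '%s': no stretch phase found", trial$trial_id))
  n_base <- max(2L, as.integer(round(baseline_window_ms * fs / 1000)))
  b0 <- max(1L, start - n_base)
  if (b0 >= start) stop(sprintf("trial '%s': no baseline window before stretch start", trial$trial_id))
  base <- env[b0:(start - 1L)]
  if (stats::sd(base) == 0) {
    stop(sprintf("trial '%s': degenerate recording, baseline EMG SD is zero", trial$trial_id))
  }
  thr <- mean(base) + k_sd * stats::sd(base)
  above <- env >= thr
  # run length of consecutive supra-threshold samples starting at each t
  n <- length(above)
  run <- integer(n)
  for (t in n:1) run[t] <- if (above[t]) (if (t < n) run[t + 1L] else 0L) + 1L else 0L
  cand <- which(run >= n_persist)
  cand <- cand[cand >= start]
  if (length(cand) == 0L) return(NA_integer_)
  cand[1]
}

#' Dynamic stretch-reflex threshold of one trial
#'
#' The (angle, velocity) pair at reflex onset: the raw angle at the onset
#' sample, and the angular velocity there from a centered five-point finite
#' difference on the smoothed angle trace.
#'
#' @param trial a `stretch_trial`.
#' @param onset onset sample from [detect_onset()].
#' @param angle_smooth_ms angle smoothing width (default 50 ms).
#' @return list with `trial_id`, `onset_sample`, `angle_deg`,
#'   `velocity_dps`.
#' @export
dynamic_threshold <- function(trial, onset, angle_smooth_ms = 50) {
  n <- length(trial$angle)
  if (is.na(onset) || onset < 3L || onset > n - 2L) {
    stop(sprintf("trial '%s': onset outside the differentiable range", trial$trial_id))
  }
  sm <- moving_average(trial$angle, round(angle_smooth_ms * trial$fs / 1000))
  vel <- (sm[onset - 2L] - 8 * sm[onset - 1L] + 8 * sm[onset + 1L] - sm[onset + 2L]) /
    12 * trial$fs
  list(trial_id = trial$trial_id, onset_sample = as.integer(onset),
       angle_deg = trial$angle[onset], velocity_dps = vel)
}

#' Extrapolate the tonic stretch reflex threshold
#'
#' Ordinary least squares of dynamic threshold angle on stretch velocity;
#' the intercept is the TSRT — the angle at which the stretch reflex would
#' activate at zero velocity. A smaller TSRT angle means more severe
#' spasticity. Intercepts above the 180 deg biomechanical range are
#' returned as-is with `in_range = FALSE` (the threshold of a non-spastic
#' muscle lies outside the range).
#'
#' @param thresholds data frame with columns `angle_deg` and `velocity_dps`
#'   (one row per usable trial), or a list of [dynamic_threshold()] results.
#' @param min_trials minimum usable trials (default 5).
#' @return a `tsrt_estimate` with `tsrt_deg`, `slope`, `n_trials_used`,
#'   `r_squared`, `residual_sd`, `in_range`.
#' @export
estimate_tsrt <- function(thresholds, min_trials = 5L) {
  if (!is.data.frame(thresholds)) {
    thresholds <- do.call(rbind, lapply(thresholds, function(th) {
      data.frame(angle_deg = th$angle_deg, velocity_dps = th$velocity_dps)
    }))
    if (is.null(thresholds)) {
      thresholds <- data.frame(angle_deg = numeric(0),
                               velocity_dps = numeric(0))
    }
  }
  thresholds <- thresholds[is.finite(thresholds$velocity_dps) &
                             thresholds$velocity_dps > 0, , drop = FALSE]
  n <- nrow(thresholds)
  if (n < min_trials) {
    stop(sprintf("only %d usable dynamic thresholds; %d required", n, min_trials))
  }
  if (stats::sd(thresholds$velocity_dps) == 0) {
    stop("all stretch velocities identical: regression slope unidentifiable")
  }
  fit <- stats::lm(angle_deg ~ velocity_dps, data = thresholds)
  # a perfect (noiseless) fit is a valid calibration input, not a problem
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  tsrt <- unname(stats::coef(fit)[1])
  structure(list(tsrt_deg = tsrt, slope = unname(stats::coef(fit)[2]),
                 n_trials_used = n, r_squared = sm$r.squared,
                 residual_sd = sm$sigma, in_range = tsrt <= 180),
            class = "tsrt_estimate")
}

#' @export
print.tsrt_estimate <- function(x, ...) {
  cat(sprintf("TSRT %.1f deg (slope %.3f deg per deg/s, %d trials, R^2 %.3f)%s\n",
              x$tsrt_deg, x$slope, x$n_trials_used, x$r_squared,
              if (x$in_range) "" else " [outside biomechanical range]"))
  invisible(x)
}

#' Run the full TSRT protocol over a series of stretch trials
#'
#' Detects reflex onset per trial, extracts dynamic thresholds, excludes
#' unusable trials, and extrapolates the TSRT. Three exclusion categories
#' are tallied: `no_onset` (no EMG burst satisfied the persistence rule),
#' `bad_velocity` (non-positive stretch velocity at onset), and
#' `early_onset` (the burst began within `early_margin_deg` of the trial's
#' starting angle, meaning the muscle was already active at stretch onset —
#' incomplete relaxation, or a dynamic threshold at or below the starting
#' position — so no threshold crossing was actually observed).
#'
#' @param trials list of `stretch_trial` objects.
#' @param baseline_window_ms,k_sd,persist_ms,envelope_ms,angle_smooth_ms,vel_thresh
#'   onset-detection parameters, see [detect_onset()].
#' @param early_margin_deg minimum angular excursion (degrees) between the
#'   starting position and a credible dynamic threshold (default 5).
#' @param min_trials minimum usable trials (default 5).
#' @return a `tsrt_estimate` with extra fields `exclusions` (list
#'   `no_onset`, `bad_velocity`, `early_onset`) and `thresholds` (the
#'   per-trial dynamic thresholds used).
#' @export
run_protocol <- function(trials, baseline_window_ms = 200, k_sd = 3,
                         persist_ms = 25, envelope_ms = 5,
                         angle_smooth_ms = 50, vel_thresh = 5,
                         early_margin_deg = 5, min_trials = 5L) {
  if (length(trials) == 0L) stop("no stretch trials provided")
  used <- list()
  no_onset <- 0L
  bad_velocity <- 0L
  early_onset <- 0L
  for (tr in trials) {
    onset <- detect_onset(tr, baseline_window_ms, k_sd, persist_ms,
                          envelope_ms, angle_smooth_ms, vel_thresh)
    if (is.na(onset) || onset < 3L || onset > length(tr$angle) - 2L) {
      no_onset <- no_onset + 1L
      next
    }
    th <- dynamic_threshold(tr, onset, angle_smooth_ms)
    if (th$angle_deg <= tr$angle[1] + early_margin_deg) {
      early_onset <- early_onset + 1L
      next
    }
    if (!is.finite(th$velocity_dps) || th$velocity_dps <= 0) {
      bad_velocity <- bad_velocity + 1L
      next
    }
    used[[length(used) + 1L]] <- th
  }
  est <- estimate_tsrt(used, min_trials)
  est$exclusions <- list(no_onset = no_onset, bad_velocity = bad_velocity,
                         early_onset = early_onset)
  est$thresholds <- do.call(rbind, lapply(used, function(th) {
    data.frame(trial_id = th$trial_id, onset_sample = th$onset_sample,
               angle_deg = th$angle_deg, velocity_dps = th$velocity_dps,
               stringsAsFactors = FALSE)
  }))
  est
}

#' Read stretch trials from a manifest
#'
#' The manifest is a TSV with columns `trial_id`, `file`, `nominal_speed`;
#' each trial file is a TSV with columns `time_s`, `angle_deg`, `emg`.
#' The sampling rate is inferred from the time column and validated as
#' uniform.
#'
#' @param manifest_path path to the manifest TSV; trial files are resolved
#'   relative to it.
#' @return list of `stretch_trial` objects.
#' @export
read_trials <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("trial_id", "file", "nominal_speed") %in% names(man)))
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base, f)
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    stopifnot(all(c("time_s", "angle_deg", "emg") %in% names(tab)))
    dt <- diff(tab$time_s)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1] + 1e-12) {
      stop(sprintf("trial '%s': non-uniform sampling", man$trial_id[i]))
    }
    stretch_trial(tab$angle_deg, tab$emg, fs = 1 / dt[1],
                  trial_id = man$trial_id[i],
                  nominal_speed = man$nominal_speed[i])
  })
}
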