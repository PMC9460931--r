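# Synthetic treadmill-gait generator with ground truth.
#
# Signal shapes are stylized, not biomechanically fitted: what matters for
# testing is that event timing, the thrust amplitude and the swing-speed
# scale are known exactly, so recovery, homogeneity and monotonicity can be
# asserted against ground truth. Per stride:
#   VT  : Gaussian impact transient centred exactly at heel contact, on top
#         of a constant gravity offset
#   AP  : biphasic push-off feature whose dominant (negative) lobe is
#         centred exactly at toe-off
#   ML  : half-sine thrust pulse occupying the first half of stance, peak
#         `thrust_amplitude_ms2`, on top of a small constant gravity
#         projection (exercises the no-mean-removal convention)
#   gyro: smooth half-sine swing envelopes, sagittal dominant with frontal
#         and horizontal at 25% amplitude, scaled by `swing_speed_scale`
# plus independent Gaussian noise per channel, low-passed at 30 Hz. Femur
# channels are the tibial gait shapes at 70% amplitude with its own noise.

#' Configuration of the synthetic gait generator
#'
#' Analytic consequences used as oracles elsewhere: with the half-sine
#' thrust pulse and ML offset g0, the noise-free stRMS is
#' `sqrt(g0^2 + A^2/2 + (4/pi) g0 A)`; with sagittal peak V and 25%
#' secondary planes, the noise-free mean v-swRMS is
#' `0.5 * V * swing_speed_scale / sqrt(2)`.
#'
#' @param n_strides Number of complete strides (default 16; at least 14 are
#'   needed to select a stable run of 10).
#' @param stride_time_s Stride duration (s, default 1.1).
#' @param stance_fraction Stance fraction of the gait cycle (default 0.60).
#' @param sampling_rate_hz Sampling rate (Hz, default 200).
#' @param thrust_amplitude_ms2 Peak of the early-stance ML thrust pulse
#'   (m/s^2, default 2.2 -- calibrated to a healthy-like stRMS near
#'   2 m/s^2).
#' @param swing_speed_scale Multiplier on all angular-velocity envelopes
#'   (default 1).
#' @param speed_coupling Exponent coupling the acceleration amplitudes
#'   (thrust, impact, push-off) to `swing_speed_scale` (default 1): a
#'   faster-swinging limb hits the ground harder, which is exactly the
#'   confound the adjusted index divides out. `thrust_amplitude_ms2` is
#'   therefore the speed-normalized thrust amplitude. Set 0 to decouple.
#' @param impact_amplitude_ms2 Peak of the VT heel-contact transient
#'   (default 8).
#' @param pushoff_amplitude_ms2 Magnitude of the AP push-off lobe
#'   (default 5).
#' @param swing_peak_degs Sagittal swing envelope peak at scale 1
#'   (deg/s, default 246 -- calibrated so the mean three-plane v-swRMS is
#'   near 87 deg/s).
#' @param noise_sd_ms2,noise_sd_degs Pre-filter noise SDs (defaults 0.3
#'   m/s^2 and 3 deg/s).
#' @param ml_offset_ms2 Constant ML gravity projection (default 0.5).
#' @param vt_offset_ms2 Constant VT gravity component (default 9.81).
#' @param pad_s Quiet lead-in/out padding (s, default 1.5).
#' @param femur_scale Femur gait-shape amplitude relative to tibia
#'   (default 0.7).
#' @param subject_id,session_label Metadata labels.
#' @param seed Integer seed for the noise draw, or `NULL` to use the
#'   current RNG state (as [generate_cohort()] does).
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(n_strides = 16L, stride_time_s = 1.1,
                        stance_fraction = 0.60, sampling_rate_hz = 200,
                        thrust_amplitude_ms2 = 2.2, swing_speed_scale = 1,
                        speed_coupling = 1,
                        impact_amplitude_ms2 = 8, pushoff_amplitude_ms2 = 5,
                        swing_peak_degs = 246, noise_sd_ms2 = 0.3,
                        noise_sd_degs = 3, ml_offset_ms2 = 0.5,
                        vt_offset_ms2 = 9.81, pad_s = 1.5,
                        femur_scale = 0.7, subject_id = "sim",
                        session_label = "day1", seed = 1L) {
  if (stance_fraction <= 0.35 || stance_fraction >= 0.85) {
    stop("`stance_fraction` must lie in (0.35, 0.85)", call. = FALSE)
  }
  if (n_strides < 1L || stride_time_s <= 0 || sampling_rate_hz <= 0 ||
      thrust_amplitude_ms2 < 0 || swing_speed_scale <= 0 ||
      noise_sd_ms2 < 0 || noise_sd_degs < 0 || pad_s < 0) {
    stop("invalid generator configuration", call. = FALSE)
  }
  structure(as.list(environment()), class = "gait_config")
}

.gauss <- function(t, mu, sigma) exp(-((t - mu)^2) / (2 * sigma^2))

.band_noise <- function(n, sd, rate) {
  if (sd == 0) return(numeric(n))
  x <- stats::rnorm(n, 0, sd)
  if (rate > 60 && n > 28L) x <- lowpass_filter(x, rate, cutoff = 30) else x
}

#' Generate one synthetic gait trial (tibia + femur) with ground truth
#'
#' @param config A [gait_config()].
#' @return A list of class `synthetic_gait` with elements `tibia` and
#'   `femur` ([imu_recording()]s), `events` (ground-truth
#'   `heel_contacts` / `toe_offs` in seconds) and `config`.
#' @export
generate_recording <- function(config = gait_config()) {
  stopifnot(inherits(config, "gait_config"))
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)
  rate <- cf$sampling_rate_hz
  total <- cf$n_strides * cf$stride_time_s + 2 * cf$pad_s
  n <- floor(total * rate) + 1L
  t <- (seq_len(n) - 1L) / rate

  hc <- cf$pad_s + (0:cf$n_strides) * cf$stride_time_s
  to <- hc[seq_len(cf$n_strides)] + cf$stance_fraction * cf$stride_time_s

  # faster swing => proportionally larger impact accelerations
  acc_gain <- cf$swing_speed_scale^cf$speed_coupling
  thrust <- acc_gain * cf$thrust_amplitude_ms2
  impact <- acc_gain * cf$impact_amplitude_ms2
  pushoff <- acc_gain * cf$pushoff_amplitude_ms2

  vt <- rep(cf$vt_offset_ms2, n)
  ap <- numeric(n)
  ml <- rep(cf$ml_offset_ms2, n)
  sag <- numeric(n)
  half_st <- 0.5 * cf$stance_fraction * cf$stride_time_s
  swing_dur <- (1 - cf$stance_fraction) * cf$stride_time_s
  for (k in seq_len(cf$n_strides + 1L)) {
    vt <- vt + impact * .gauss(t, hc[k], 0.018)
  }
  for (k in seq_len(cf$n_strides)) {
    ap <- ap - pushoff * .gauss(t, to[k], 0.025) +
      0.5 * pushoff * .gauss(t, to[k] - 0.08, 0.030)
    u <- (t - hc[k]) / half_st
    in_pulse <- u >= 0 & u < 1
    ml[in_pulse] <- ml[in_pulse] + thrust * sin(pi * u[in_pulse])
    w <- (t - to[k]) / swing_dur
    in_swing <- w >= 0 & w < 1
    sag[in_swing] <- sag[in_swing] +
      cf$swing_peak_degs * cf$swing_speed_scale * sin(pi * w[in_swing])
  }
  fro <- -0.25 * sag
  hor <- 0.25 * sag

  mk_rec <- function(site, scale) {
    g <- function(x, off) off + scale * (x - off)   # scale gait shapes, keep offsets
    imu_recording(
      time_s = t,
      acc_ap = scale * ap + .band_noise(n, cf$noise_sd_ms2, rate),
      acc_ml = g(ml, cf$ml_offset_ms2) + .band_noise(n, cf$noise_sd_ms2, rate),
      acc_vt = g(vt, cf$vt_offset_ms2) + .band_noise(n, cf$noise_sd_ms2, rate),
      gyr_sag = scale * sag + .band_noise(n, cf$noise_sd_degs, rate),
      gyr_fro = scale * fro + .band_noise(n, cf$noise_sd_degs, rate),
      gyr_hor = scale * hor + .band_noise(n, cf$noise_sd_degs, rate),
      meta = imu_meta(site = site, side = "left",
                      sampling_rate_hz = rate, subject_id = cf$subject_id,
                      session_label = cf$session_label)
    )
  }
  out <- list(
    tibia = mk_rec("tibia", 1),
    femur = mk_rec("femur", cf$femur_scale),
    events = list(heel_contacts = hc, toe_offs = to),
    config = cf
  )
  class(out) <- "synthetic_gait"
  out
}

#' @export
print.synthetic_gait <- function(x, ...) {
  cf <- x$config
  cat(sprintf("Synthetic gait trial: %d strides of %.2f s at %g Hz (thrust %.2f m/s^2, swing scale %.2f)\n",
              cf$n_strides, cf$stride_time_s, cf$sampling_rate_hz,
              cf$thrust_amplitude_ms2, cf$swing_speed_scale))
  invisible(x)
}

#' Configuration of a synthetic two-group cohort
#'
#' Group-level distributions of the two ground-truth parameters that drive
#' the index (thrust amplitude and swing-speed scale), shared nuisance
#' distributions, and within-subject between-session jitter to support
#' test-retest (ICC) experiments. The defaults emulate the published
#' two-group separation: knee-OA subjects with a larger speed-normalized
#' thrust but markedly slower swing, so their raw stRMS is slightly
#' *smaller* than in healthy adults while their adjusted A-RMS is clearly
#' larger -- the pattern that motivates the adjustment; 16 subjects per
#' group.
#'
#' @param n_per_group Subjects per group (default 16).
#' @param oa,healthy Lists with `thrust_mean`, `thrust_sd`, `swing_mean`,
#'   `swing_sd` for each group's parameter distributions.
#' @param stride_time_mean,stride_time_sd Between-subject stride-time
#'   distribution (s).
#' @param session_thrust_sd,session_swing_sd Within-subject between-session
#'   jitter SDs.
#' @param n_sessions Sessions per subject (default 2).
#' @param n_strides Strides per recording (default 16).
#' @param noise_sd_ms2,noise_sd_degs Noise levels passed to
#'   [gait_config()].
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 16L,
                          oa = list(thrust_mean = 2.92, thrust_sd = 1.00,
                                    swing_mean = 0.61, swing_sd = 0.09),
                          healthy = list(thrust_mean = 2.2, thrust_sd = 0.65,
                                         swing_mean = 1.0, swing_sd = 0.13),
                          stride_time_mean = 1.1, stride_time_sd = 0.05,
                          session_thrust_sd = 0.15, session_swing_sd = 0.04,
                          n_sessions = 2L, n_strides = 16L,
                          noise_sd_ms2 = 0.3, noise_sd_degs = 3,
                          seed = 1L) {
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic two-group cohort with full provenance
#'
#' Draws each subject's true thrust amplitude and swing-speed scale from
#' their group's distributions, then each session's effective parameters
#' with within-subject jitter, and generates all recordings. Identical
#' configuration and seed give an identical cohort.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort`: `subjects` (each with
#'   `subject_id`, `group`, true parameters, and per-session
#'   `synthetic_gait` trials) and `manifest` (one row per subject-session
#'   with true parameters).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  set.seed(cf$seed)
  subjects <- list()
  manifest <- list()
  sid <- 0L
  for (grp in c("oa", "healthy")) {
    par <- cf[[grp]]
    for (j in seq_len(cf$n_per_group)) {
      sid <- sid + 1L
      id <- sprintf("%s%02d", ifelse(grp == "oa", "P", "H"), j)
      thrust <- max(0, stats::rnorm(1L, par$thrust_mean, par$thrust_sd))
      swing <- max(0.2, stats::rnorm(1L, par$swing_mean, par$swing_sd))
      stride_t <- min(1.6, max(0.8, stats::rnorm(1L, cf$stride_time_mean,
                                                 cf$stride_time_sd)))
      sessions <- list()
      for (s in seq_len(cf$n_sessions)) {
        lab <- paste0("day", s)
        th_s <- max(0, thrust + stats::rnorm(1L, 0, cf$session_thrust_sd))
        sw_s <- max(0.15, swing + stats::rnorm(1L, 0, cf$session_swing_sd))
        trial <- generate_recording(gait_config(
          n_strides = cf$n_strides, stride_time_s = stride_t,
          thrust_amplitude_ms2 = th_s, swing_speed_scale = sw_s,
          noise_sd_ms2 = cf$noise_sd_ms2, noise_sd_degs = cf$noise_sd_degs,
          subject_id = id, session_label = lab, seed = NULL))
        sessions[[lab]] <- trial
        manifest[[length(manifest) + 1L]] <- data.frame(
          subject_id = id, group = grp, session = lab,
          true_thrust = th_s, true_swing = sw_s, stride_time_s = stride_t,
          stringsAsFactors = FALSE)
      }
      subjects[[id]] <- list(subject_id = id, group = grp,
                             true_thrust = thrust, true_swing = swing,
                             stride_time_s = stride_t, sessions = sessions)
    }
  }
  structure(list(subjects = subjects, manifest = do.call(rbind, manifest),
                 config = cf),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d per group), %d session(s) each\n",
              length(x$subjects), x$config$n_per_group, x$config$n_sessions))
  invisible(x)
}

#' Run the thrust pipeline over a synthetic cohort
#'
#' Convenience bridge from [generate_cohort()] to the statistics layer:
#' runs [varus_thrust()] on every subject-session and returns a tidy table
#' of computed indices joined with the ground-truth parameters.
#'
#' @param cohort A `synthetic_cohort`.
#' @param site `"tibia"` or `"femur"`.
#' @param sessions Session labels to analyse (default: all).
#' @param n_strides Strides per analysis (default 10).
#' @param ... Passed to [varus_thrust()].
#' @return A data frame with one row per subject-session: `subject_id`,
#'   `group`, `session`, `site`, `st_rms_ml`, `mean_v_sw_rms`, `a_rms`,
#'   `true_thrust`, `true_swing`.
#' @export
compute_cohort_indices <- function(cohort, site = c("tibia", "femur"),
                                   sessions = NULL, n_strides = 10L, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  site <- match.arg(site)
  rows <- list()
  for (sub in cohort$subjects) {
    for (lab in names(sub$sessions)) {
      if (!is.null(sessions) && !(lab %in% sessions)) next
      trial <- sub$sessions[[lab]]
      fit <- varus_thrust(trial$tibia,
                          femur = if (site == "femur") trial$femur else NULL,
                          n_strides = n_strides, ...)
      res <- fit$results[[site]]
      mrow <- cohort$manifest[cohort$manifest$subject_id == sub$subject_id &
                                cohort$manifest$session == lab, ]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sub$subject_id, group = sub$group, session = lab,
        site = site, st_rms_ml = res$st_rms_ml,
        mean_v_sw_rms = res$mean_v_sw_rms, a_rms = res$a_rms,
        true_thrust = mrow$true_thrust, true_swing = mrow$true_swing,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
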