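# The varus-thrust index layer.
#
# Per stride:
#   stRMS     = RMS of the unfiltered mediolateral acceleration over the
#               first half of the stance phase (m/s^2)
#   v-swRMS_p = RMS of the 20 Hz low-passed angular velocity in plane p over
#               the swing phase (deg/s), p in {sagittal, frontal, horizontal}
#   A-RMS     = stRMS / mean of the three v-swRMS values  (m/s/deg)
#
# No mean removal before the RMS by default: the index is defined on the raw
# extracted acceleration, so any quasi-static (gravity projection) component
# in ML is retained. `demean = TRUE` enables per-window mean removal for
# sensitivity analyses.

#' Root mean square
#'
#' `sqrt(mean(x^2))`, without mean removal.
#'
#' @param x Numeric vector, length at least 1.
#' @return Non-negative scalar.
#' @export
rms <- function(x) {
  if (!length(x)) stop("cannot take the RMS of an empty sequence", call. = FALSE)
  sqrt(mean(x^2))
}

# indices of samples with from <= t < to (half-open window)
.window_idx <- function(time_s, from, to) {
  which(time_s >= from & time_s < to)
}

.check_window_extent <- function(time_s, win) {
  if (win[1L] < time_s[1L] || win[2L] > time_s[length(time_s)] + 1e-9) {
    stop("window outside recording extent", call. = FALSE)
  }
}

#' RMS of mediolateral acceleration over the first half of stance
#'
#' Computes the stRMS contribution of one stride: the RMS of the raw
#' (unfiltered) ML acceleration over the half-open first-half-of-stance
#' window.
#'
#' @param acc_ml Mediolateral acceleration (m/s^2), unfiltered.
#' @param windows A [phase_windows()] object.
#' @param rate Sampling rate (Hz).
#' @param time_s Optional explicit timestamps; defaults to the sample grid
#'   `(seq_along(acc_ml) - 1) / rate`.
#' @param demean Remove the window mean before the RMS (default `FALSE`).
#' @return stRMS in m/s^2.
#' @export
stance_first_half_rms <- function(acc_ml, windows, rate, time_s = NULL,
                                  demean = FALSE) {
  stopifnot(inherits(windows, "phase_windows"))
  if (is.null(time_s)) time_s <- (seq_along(acc_ml) - 1L) / rate
  .check_window_extent(time_s, windows$first_half_stance)
  idx <- .window_idx(time_s, windows$first_half_stance[1L],
                     windows$first_half_stance[2L])
  if (length(idx) < 4L) {
    stop("first-half-stance window contains fewer than 4 samples", call. = FALSE)
  }
  x <- acc_ml[idx]
  if (demean) x <- x - mean(x)
  rms(x)
}

#' RMS of angular velocity over the swing phase
#'
#' Computes one plane's v-swRMS: the full signal is 20 Hz zero-phase
#' low-pass filtered internally (so callers cannot forget the filter), then
#' the RMS is taken over the half-open swing window.
#'
#' @param gyr_plane Angular velocity of one plane (deg/s), unfiltered.
#' @param windows A [phase_windows()] object.
#' @param rate Sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz, default 20).
#' @param time_s Optional explicit timestamps (see
#'   [stance_first_half_rms()]).
#' @return v-swRMS in deg/s.
#' @export
swing_angular_velocity_rms <- function(gyr_plane, windows, rate, cutoff = 20,
                                       time_s = NULL) {
  stopifnot(inherits(windows, "phase_windows"))
  if (is.null(time_s)) time_s <- (seq_along(gyr_plane) - 1L) / rate
  .check_window_extent(time_s, windows$swing)
  xf <- lowpass_filter(gyr_plane, rate, cutoff = cutoff)
  idx <- .window_idx(time_s, windows$swing[1L], windows$swing[2L])
  if (length(idx) < 4L) {
    stop("swing window contains fewer than 4 samples", call. = FALSE)
  }
  rms(xf[idx])
}

#' Speed-adjusted thrust index A-RMS
#'
#' Divides the first-half-of-stance ML acceleration RMS by the mean of the
#' three swing-phase angular-velocity RMS values, removing the coupling of
#' impact acceleration with limb swing speed.
#'
#' @param st_rms stRMS (m/s^2).
#' @param v_sw_rms Numeric triple of v-swRMS values
#'   (sagittal, frontal, horizontal; deg/s), all non-negative with positive
#'   mean.
#' @return A-RMS in m/s/deg, i.e. (m/s^2)/(deg/s).
#' @export
adjusted_rms <- function(st_rms, v_sw_rms) {
  if (length(v_sw_rms) != 3L || any(v_sw_rms < 0)) {
    stop("`v_sw_rms` must be three non-negative plane values", call. = FALSE)
  }
  m <- mean(v_sw_rms)
  if (m <= 0) stop("degenerate swing: mean angular-velocity RMS is zero", call. = FALSE)
  st_rms / m
}

# per-stride metrics for one target recording, using tibia-derived windows
.stride_metrics <- function(rec_target, sel, cutoff_hz, demean) {
  t <- rec_target$data$time_s
  rate <- rec_target$meta$sampling_rate_hz
  gyr_f <- lapply(rec_target$data[c("gyr_sag", "gyr_fro", "gyr_hor")],
                  lowpass_filter, rate = rate, cutoff = cutoff_hz)
  ml <- rec_target$data$acc_ml
  out <- lapply(seq_len(nrow(sel)), function(i) {
    st_idx <- .window_idx(t, sel$hc_start[i], sel$half_stance_end[i])
    sw_idx <- .window_idx(t, sel$toe_off[i], sel$hc_end[i])
    if (length(st_idx) < 4L || length(sw_idx) < 4L) {
      stop(sprintf("stride %d: phase window contains fewer than 4 samples",
                   sel$stride[i]), call. = FALSE)
    }
    x <- ml[st_idx]
    if (demean) x <- x - mean(x)
    st <- rms(x)
    v <- vapply(gyr_f, function(g) rms(g[sw_idx]), numeric(1L))
    data.frame(stride = sel$stride[i],
               n_st = length(st_idx), n_sw = length(sw_idx),
               st_rms_ml = st,
               v_sw_rms_sag = v[[1L]], v_sw_rms_fro = v[[2L]],
               v_sw_rms_hor = v[[3L]],
               mean_v_sw_rms = mean(v),
               a_rms = adjusted_rms(st, v))
  })
  do.call(rbind, out)
}

#' Per-subject thrust metrics from tibia-derived stride windows
#'
#' Computes per-stride stRMS, three-plane v-swRMS and A-RMS for a target
#' recording (tibia or femur of the same limb and session) over the strides
#' selected from the tibial recording, then aggregates. Under
#' `"mean_of_strides"` (default) the index is computed per stride and the
#' per-stride A-RMS values averaged; under `"pooled_samples"` the phase
#' windows of all strides are concatenated and a single index computed.
#'
#' @param rec_tibia The tibial [imu_recording()] the strides were derived
#'   from (used only for a timestamp-compatibility check).
#' @param rec_target The recording whose channels are measured (tibia or
#'   femur).
#' @param strides A `stride_set` from [select_stable_strides()], with event
#'   times on `rec_tibia`'s time base.
#' @param aggregation `"mean_of_strides"` or `"pooled_samples"`.
#' @param cutoff_hz Angular-velocity low-pass cutoff (default 20 Hz).
#' @param demean Per-window mean removal before the acceleration RMS
#'   (default `FALSE`).
#' @return An object of class `subject_thrust_result`: subject/site/session
#'   labels, the per-stride metrics data frame, and aggregated `st_rms_ml`,
#'   `v_sw_rms_*`, `mean_v_sw_rms`, `a_rms`.
#' @export
compute_subject_result <- function(rec_tibia, rec_target, strides,
                                   aggregation = c("mean_of_strides",
                                                   "pooled_samples"),
                                   cutoff_hz = 20, demean = FALSE) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(rec_tibia, "imu_recording"),
            inherits(rec_target, "imu_recording"),
            inherits(strides, "stride_set"))
  sel <- strides[strides$selected, , drop = FALSE]
  if (!nrow(sel)) stop("no selected strides", call. = FALSE)
  t <- rec_target$data$time_s
  if (min(sel$hc_start) < t[1L] || max(sel$hc_end) > t[length(t)] + 1e-9) {
    stop("timestamp ranges incompatible: stride windows fall outside the target recording",
         call. = FALSE)
  }
  per_stride <- .stride_metrics(rec_target, sel, cutoff_hz, demean)
  if (aggregation == "mean_of_strides") {
    agg <- colMeans(per_stride[, c("st_rms_ml", "v_sw_rms_sag",
                                   "v_sw_rms_fro", "v_sw_rms_hor",
                                   "mean_v_sw_rms", "a_rms")])
  } else {
    rate <- rec_target$meta$sampling_rate_hz
    gyr_f <- lapply(rec_target$data[c("gyr_sag", "gyr_fro", "gyr_hor")],
                    lowpass_filter, rate = rate, cutoff = cutoff_hz)
    st_idx <- unlist(lapply(seq_len(nrow(sel)), function(i)
      .window_idx(t, sel$hc_start[i], sel$half_stance_end[i])))
    sw_idx <- unlist(lapply(seq_len(nrow(sel)), function(i)
      .window_idx(t, sel$toe_off[i], sel$hc_end[i])))
    x <- rec_target$data$acc_ml[st_idx]
    if (demean) x <- x - mean(x)
    st <- rms(x)
    v <- vapply(gyr_f, function(g) rms(g[sw_idx]), numeric(1L))
    agg <- c(st_rms_ml = st, v_sw_rms_sag = v[[1L]], v_sw_rms_fro = v[[2L]],
             v_sw_rms_hor = v[[3L]], mean_v_sw_rms = mean(v),
             a_rms = adjusted_rms(st, v))
  }
  structure(list(
    subject_id = rec_target$meta$subject_id,
    site = rec_target$meta$site,
    session_label = rec_target$meta$session_label,
    n_strides = nrow(sel),
    aggregation = aggregation,
    per_stride = per_stride,
    st_rms_ml = unname(agg[["st_rms_ml"]]),
    v_sw_rms_sag = unname(agg[["v_sw_rms_sag"]]),
    v_sw_rms_fro = unname(agg[["v_sw_rms_fro"]]),
    v_sw_rms_hor = unname(agg[["v_sw_rms_hor"]]),
    mean_v_sw_rms = unname(agg[["mean_v_sw_rms"]]),
    a_rms = unname(agg[["a_rms"]])
  ), class = "subject_thrust_result")
}

#' @export
print.subject_thrust_result <- function(x, ...) {
  cat(sprintf("Thrust metrics (%s, subject '%s', session '%s', %d strides, %s):\n",
              x$site, x$subject_id, x$session_label, x$n_strides,
              x$aggregation))
  cat(sprintf("  stRMS (ML)      %8.3f m/s^2\n", x$st_rms_ml))
  cat(sprintf("  mean v-swRMS    %8.2f deg/s\n", x$mean_v_sw_rms))
  cat(sprintf("  A-RMS           %8.4f m/s/deg\n", x$a_rms))
  invisible(x)
}

#' Pipeline control parameters
#'
#' Collects the tunable detection and selection thresholds of the pipeline
#' in one place. The defaults are the committed interpretation validated
#' against the synthetic generator's ground truth.
#'
#' @param event_cutoff_hz Low-pass cutoff for the event-detection copy of
#'   the VT/AP channels (Hz).
#' @param prominence_frac Relative peak-prominence threshold for heel
#'   contacts.
#' @param min_separation_frac Minimum heel-contact separation as a fraction
#'   of the stride period.
#' @param toe_off_window Toe-off search window as fractions of the
#'   heel-contact interval.
#' @param duration_tol Stride-duration tolerance for the stable-walking
#'   gate.
#' @param stance_range Plausible stance-fraction interval.
#' @param lag_range Stride-period autocorrelation search range (s).
#' @param demean Per-window mean removal before the acceleration RMS.
#' @return A list of class `thrust_control`.
#' @export
thrust_control <- function(event_cutoff_hz = 10, prominence_frac = 0.5,
                           min_separation_frac = 0.7,
                           toe_off_window = c(0.40, 0.80),
                           duration_tol = 0.15,
                           stance_range = c(0.35, 0.85),
                           lag_range = c(0.6, 2.5), demean = FALSE) {
  structure(list(event_cutoff_hz = event_cutoff_hz,
                 prominence_frac = prominence_frac,
                 min_separation_frac = min_separation_frac,
                 toe_off_window = toe_off_window,
                 duration_tol = duration_tol,
                 stance_range = stance_range,
                 lag_range = lag_range,
                 demean = demean),
            class = "thrust_control")
}

#' Quantify varus thrust from IMU gait recordings
#'
#' The end-to-end pipeline: estimate the stride period from the tibial VT
#' channel, detect heel contacts (VT) and toe-offs (AP), select a run of
#' stable strides, and compute the per-stride and aggregated stRMS,
#' v-swRMS and A-RMS for the tibia (and femur, if supplied -- femur indices
#' reuse the tibia-derived events, as events are only detected from tibial
#' channels).
#'
#' @param tibia Tibial [imu_recording()] (events and tibial indices).
#' @param femur Optional femoral [imu_recording()] of the same limb and
#'   session, assumed time-synchronized with `tibia`.
#' @param n_strides Number of stable strides to analyse (default 10).
#' @param cutoff_hz Angular-velocity low-pass cutoff (default 20 Hz).
#' @param aggregation `"mean_of_strides"` (default) or `"pooled_samples"`.
#' @param control A [thrust_control()] list of detection thresholds.
#' @return An object of class `varus_thrust` with elements `results` (named
#'   list of [compute_subject_result()] objects per site), `strides` (the
#'   `stride_set` with its selection log), `events`, `period_s`, and the
#'   effective configuration. Supports `print()`, `summary()`, `coef()` and
#'   `plot()`.
#' @examples
#' sim <- generate_recording(gait_config(seed = 42))
#' fit <- varus_thrust(sim$tibia, sim$femur)
#' fit
#' coef(fit)
#' @export
varus_thrust <- function(tibia, femur = NULL, n_strides = 10L,
                         cutoff_hz = 20,
                         aggregation = c("mean_of_strides", "pooled_samples"),
                         control = thrust_control()) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(tibia, "imu_recording"))
  if (!is.null(femur)) stopifnot(inherits(femur, "imu_recording"))
  rate <- tibia$meta$sampling_rate_hz
  t0 <- tibia$data$time_s[1L]

  period <- estimate_stride_period(tibia$data$acc_vt, rate,
                                   lag_range = control$lag_range)
  hc <- detect_heel_contacts(tibia$data$acc_vt, rate, period,
                             prominence_frac = control$prominence_frac,
                             min_separation_frac = control$min_separation_frac,
                             event_cutoff_hz = control$event_cutoff_hz)
  to <- detect_toe_offs(tibia$data$acc_ap, rate, hc,
                        window = control$toe_off_window,
                        event_cutoff_hz = control$event_cutoff_hz)
  # map from the sample grid to the recording's absolute time base
  events <- gait_events(hc + t0, structure(as.numeric(to) + t0,
                                           reason = attr(to, "reason")))
  strides <- select_stable_strides(events, n_strides = n_strides, rate = rate,
                                   duration_tol = control$duration_tol,
                                   stance_range = control$stance_range)
  results <- list(
    tibia = compute_subject_result(tibia, tibia, strides,
                                   aggregation = aggregation,
                                   cutoff_hz = cutoff_hz,
                                   demean = control$demean)
  )
  if (!is.null(femur)) {
    results$femur <- compute_subject_result(tibia, femur, strides,
                                            aggregation = aggregation,
                                            cutoff_hz = cutoff_hz,
                                            demean = control$demean)
  }
  structure(list(
    results = results,
    strides = strides,
    events = events,
    period_s = period,
    recordings = list(tibia = tibia, femur = femur),
    n_strides = n_strides,
    cutoff_hz = cutoff_hz,
    aggregation = aggregation,
    control = control,
    call = match.call()
  ), class = "varus_thrust")
}

#' @export
print.varus_thrust <- function(x, ...) {
  cat("Varus-thrust assessment\n")
  cat(sprintf("  stride period %.3f s; %d strides analysed (%s)\n",
              x$period_s, x$n_strides, x$aggregation))
  for (res in x$results) {
    cat(sprintf("  %-6s stRMS %6.3f m/s^2   mean v-swRMS %7.2f deg/s   A-RMS %7.4f m/s/deg\n",
                res$site, res$st_rms_ml, res$mean_v_sw_rms, res$a_rms))
  }
  invisible(x)
}

#' @export
coef.varus_thrust <- function(object, ...) {
  t(vapply(object$results, function(r)
    c(st_rms_ml = r$st_rms_ml, mean_v_sw_rms = r$mean_v_sw_rms,
      a_rms = r$a_rms), numeric(3L)))
}

#' @export
summary.varus_thrust <- function(object, ...) {
  structure(list(fit = object), class = "summary.varus_thrust")
}

#' @export
print.summary.varus_thrust <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat(sprintf("\nStride selection (period %.3f s):\n", fit$period_s))
  sel <- fit$strides[fit$strides$selected, , drop = FALSE]
  cat(sprintf("  selected strides %s; durations %.3f-%.3f s; stance fractions %.2f-%.2f\n",
              paste(range(sel$stride), collapse = "-"),
              min(sel$duration), max(sel$duration),
              min(sel$stance_fraction), max(sel$stance_fraction)))
  rej <- fit$strides[!fit$strides$selected, , drop = FALSE]
  if (nrow(rej)) {
    tab <- table(rej$reason)
    cat("  not selected:", paste(sprintf("%s (%d)", names(tab), tab),
                                 collapse = ", "), "\n")
  }
  for (res in fit$results) {
    cat(sprintf("\nPer-stride metrics (%s):\n", res$site))
    print(res$per_stride, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Plot a varus-thrust assessment
#'
#' Tibial ML acceleration against time with the first-half-of-stance
#' windows shaded and heel-contact / toe-off events marked.
#'
#' @param x A `varus_thrust` object.
#' @param site `"tibia"` or `"femur"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.varus_thrust <- function(x, site = "tibia", ...) {
  rec <- x$recordings[[site]]
  if (is.null(rec)) stop("no ", site, " recording in this fit", call. = FALSE)
  t <- rec$data$time_s
  ml <- rec$data$acc_ml
  graphics::plot(t, ml, type = "l", col = "grey30",
                 xlab = "time (s)", ylab = "ML acceleration (m/s^2)",
                 main = sprintf("Varus thrust: %s ML acceleration", site), ...)
  sel <- x$strides[x$strides$selected, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    graphics::rect(sel$hc_start[i], min(ml), sel$half_stance_end[i], max(ml),
                   col = grDevices::adjustcolor("seagreen", 0.25), border = NA)
  }
  graphics::abline(v = sel$hc_start, col = "steelblue", lty = 3)
  graphics::abline(v = sel$toe_off, col = "firebrick", lty = 3)
  graphics::legend("topright",
                   legend = c("first half of stance", "heel contact", "toe-off"),
                   fill = c(grDevices::adjustcolor("seagreen", 0.25), NA, NA),
                   border = NA, lty = c(NA, 3, 3),
                   col = c(NA, "steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Tidy one-row summary of thrust results
#'
#' Flattens a `varus_thrust` fit into the results-CSV row format
#' (`subject_id, site, session, n_strides, st_rms_ml, v_sw_rms_sag,
#' v_sw_rms_fro, v_sw_rms_hor, mean_v_sw_rms, a_rms`), one row per site.
#'
#' @param fit A `varus_thrust` object.
#' @return A data frame.
#' @export
thrust_results_table <- function(fit) {
  stopifnot(inherits(fit, "varus_thrust"))
  do.call(rbind, lapply(fit$results, function(r) data.frame(
    subject_id = r$subject_id, site = r$site, session = r$session_label,
    n_strides = r$n_strides, st_rms_ml = r$st_rms_ml,
    v_sw_rms_sag = r$v_sw_rms_sag, v_sw_rms_fro = r$v_sw_rms_fro,
    v_sw_rms_hor = r$v_sw_rms_hor, mean_v_sw_rms = r$mean_v_sw_rms,
    a_rms = r$a_rms, stringsAsFactors = FALSE)))
}
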