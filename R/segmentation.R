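# Gait-event detection and stride selection from tibial acceleration.
#
# Event times follow the sample-grid convention: the time of an event is the
# timestamp of the extremal sample, (index - 1) / rate for vector input (no
# sub-sample interpolation -- at 200 Hz that precision is below the method's
# noise floor).

# indices of strict-left / weak-right local maxima
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

# topographic prominence of each peak: height above the higher of the two
# minima separating it from taller terrain (or the signal edge)
.peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    rmin <- h
    i <- p + 1L
    while (i <= length(x) && x[i] <= h) {
      if (x[i] < rmin) rmin <- x[i]
      i <- i + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1L))
}

#' Estimate the stride period from vertical tibial acceleration
#'
#' Autocorrelation of the mean-removed vertical (VT) signal; the stride
#' period is the lag of the highest autocorrelation peak within a
#' physiological lag range (default 0.6-2.5 s).
#'
#' @param acc_vt Vertical acceleration signal (m/s^2).
#' @param rate Sampling rate (Hz).
#' @param lag_range Lag search range in seconds.
#' @param min_peak Minimum normalized autocorrelation for a credible gait
#'   peak; below this the signal is considered aperiodic.
#' @return Stride period in seconds.
#' @export
estimate_stride_period <- function(acc_vt, rate, lag_range = c(0.6, 2.5),
                                   min_peak = 0.2) {
  n <- length(acc_vt)
  if (n < 5 * rate) {
    stop("recording too short for period estimation: need at least 5 s",
         call. = FALSE)
  }
  x <- acc_vt - mean(acc_vt)
  lag_max <- min(n - 1L, ceiling(lag_range[2L] * rate))
  ac <- drop(stats::acf(x, lag.max = lag_max, plot = FALSE,
                        demean = FALSE)$acf)
  # ac[k + 1] is the autocorrelation at lag k samples
  peaks <- .local_maxima(ac) - 1L
  lo <- max(2L, floor(lag_range[1L] * rate))
  peaks <- peaks[peaks >= lo & peaks <= lag_max]
  peaks <- peaks[ac[peaks + 1L] >= min_peak]
  if (!length(peaks)) stop("no periodic gait detected", call. = FALSE)
  best <- peaks[which.max(ac[peaks + 1L])]
  best / rate
}

#' Detect heel contacts from vertical tibial acceleration
#'
#' Peaks of a 10 Hz zero-phase low-passed copy of the VT signal, retained if
#' their topographic prominence is at least `prominence_frac` times a robust
#' stride-scale amplitude (the median per-window peak-to-trough over windows
#' one stride period long) and separated by at least
#' `min_separation_frac * period`. The threshold is relative to the data, so
#' detection is invariant to a positive rescaling of the signal.
#'
#' @param acc_vt Vertical acceleration signal (m/s^2), unfiltered.
#' @param rate Sampling rate (Hz).
#' @param period Stride period in seconds (from
#'   [estimate_stride_period()]).
#' @param prominence_frac Relative prominence threshold (default 0.5).
#' @param min_separation_frac Minimum peak separation as a fraction of the
#'   stride period (default 0.7).
#' @param event_cutoff_hz Cutoff of the detection low-pass (default 10 Hz).
#' @return Heel-contact times in seconds (sample-grid convention).
#' @export
detect_heel_contacts <- function(acc_vt, rate, period,
                                 prominence_frac = 0.5,
                                 min_separation_frac = 0.7,
                                 event_cutoff_hz = 10) {
  xf <- lowpass_filter(acc_vt, rate, cutoff = event_cutoff_hz)
  w <- max(2L, round(period * rate))
  nw <- max(1L, floor(length(xf) / w))
  amp <- stats::median(vapply(seq_len(nw), function(i) {
    seg <- xf[seq.int((i - 1L) * w + 1L, i * w)]
    max(seg) - min(seg)
  }, numeric(1L)))
  peaks <- .local_maxima(xf)
  if (length(peaks)) {
    prom <- .peak_prominence(xf, peaks)
    keep <- peaks[prom >= prominence_frac * amp & prom > 0]
  } else {
    keep <- integer()
  }
  # enforce minimum separation, keeping taller peaks first
  min_sep <- min_separation_frac * period * rate
  sel <- integer()
  for (p in keep[order(xf[keep], decreasing = TRUE)]) {
    if (!length(sel) || all(abs(p - sel) >= min_sep)) sel <- c(sel, p)
  }
  sel <- sort(sel)
  if (length(sel) < 3L) {
    stop("insufficient strides: fewer than 3 heel contacts detected",
         call. = FALSE)
  }
  (sel - 1L) / rate
}

#' Detect toe-offs from anteroposterior tibial acceleration
#'
#' For each consecutive heel-contact pair, the toe-off is the time of the
#' largest-magnitude extremum of a 10 Hz low-passed copy of the AP signal
#' within the window 40-80% of the heel-contact interval (the push-off
#' feature sits there for any plausible stance fraction).
#'
#' @param acc_ap Anteroposterior acceleration signal (m/s^2), unfiltered.
#' @param rate Sampling rate (Hz).
#' @param heel_contacts Heel-contact times in seconds (at least 2).
#' @param window Search window as fractions of the stride interval.
#' @param event_cutoff_hz Cutoff of the detection low-pass (default 10 Hz).
#' @return Numeric vector of toe-off times, one per heel-contact pair, `NA`
#'   where the stride was rejected; the character attribute `"reason"`
#'   holds the per-stride rejection reason (`""` when accepted).
#' @export
detect_toe_offs <- function(acc_ap, rate, heel_contacts,
                            window = c(0.40, 0.80), event_cutoff_hz = 10) {
  if (length(heel_contacts) < 2L) {
    stop("need at least 2 heel contacts", call. = FALSE)
  }
  xf <- lowpass_filter(acc_ap, rate, cutoff = event_cutoff_hz)
  t <- (seq_along(xf) - 1L) / rate
  m <- length(heel_contacts) - 1L
  to <- rep(NA_real_, m)
  reason <- character(m)
  for (i in seq_len(m)) {
    d <- heel_contacts[i + 1L] - heel_contacts[i]
    a <- heel_contacts[i] + window[1L] * d
    b <- heel_contacts[i] + window[2L] * d
    idx <- which(t >= a & t <= b)
    if (!length(idx)) {
      reason[i] <- "degenerate stride interval"
      next
    }
    seg <- xf[idx]
    if (diff(range(seg)) == 0 || max(abs(seg)) == 0) {
      reason[i] <- "no toe-off feature"
      next
    }
    to[i] <- t[idx[which.max(abs(seg))]]
  }
  structure(to, reason = reason)
}

#' Gait events container
#'
#' Pairs heel-contact times with the toe-off of each heel-contact interval
#' and asserts the interleaving invariant
#' `heel_contacts[i] < toe_offs[i] < heel_contacts[i + 1]` for every
#' complete stride.
#'
#' @param heel_contacts Increasing heel-contact times (s).
#' @param toe_offs Toe-off times (s), length `length(heel_contacts) - 1`,
#'   `NA` for rejected strides; rejection reasons may be carried in the
#'   `"reason"` attribute as produced by [detect_toe_offs()].
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(heel_contacts, toe_offs) {
  heel_contacts <- as.numeric(heel_contacts)
  if (any(diff(heel_contacts) <= 0)) {
    stop("heel contacts must be strictly increasing", call. = FALSE)
  }
  reason <- attr(toe_offs, "reason")
  toe_offs <- as.numeric(toe_offs)
  if (length(toe_offs) != length(heel_contacts) - 1L) {
    stop("need one toe-off slot per heel-contact interval", call. = FALSE)
  }
  ok <- !is.na(toe_offs)
  if (any(toe_offs[ok] <= heel_contacts[-length(heel_contacts)][ok]) ||
      any(toe_offs[ok] >= heel_contacts[-1L][ok])) {
    stop("events do not interleave: need hc[i] < to[i] < hc[i+1]",
         call. = FALSE)
  }
  if (is.null(reason)) reason <- ifelse(ok, "", "rejected")
  structure(list(heel_contacts = heel_contacts, toe_offs = toe_offs,
                 reason = reason),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Gait events: %d heel contacts, %d/%d toe-offs accepted\n",
              length(x$heel_contacts), sum(!is.na(x$toe_offs)),
              length(x$toe_offs)))
  invisible(x)
}

#' Select a run of stable strides
#'
#' Implements the "ten strides during stable walking" rule: the first two
#' and last two complete strides are discarded (gait initiation/termination
#' transients); among the remainder, the first run of `n_strides`
#' consecutive strides whose durations are all within `duration_tol` of the
#' median stride duration and whose stance fractions lie in `stance_range`
#' is retained. Every candidate stride's accept/reject reason is logged.
#'
#' @param events A [gait_events()] object.
#' @param n_strides Number of strides to retain (default 10).
#' @param rate Sampling rate (Hz), used to reject strides whose phase
#'   windows would contain fewer than `min_samples` samples.
#' @param duration_tol Relative tolerance on stride duration (default 0.15).
#' @param stance_range Open interval of plausible stance fractions.
#' @param min_samples Minimum samples per phase window (default 4).
#' @return An object of class `stride_set`: a data frame with one row per
#'   candidate stride (`hc_start`, `toe_off`, `hc_end`, `duration`,
#'   `stance_fraction`, `half_stance_end`, `selected`, `reason`).
#' @export
select_stable_strides <- function(events, n_strides = 10L, rate,
                                  duration_tol = 0.15,
                                  stance_range = c(0.35, 0.85),
                                  min_samples = 4L) {
  stopifnot(inherits(events, "gait_events"))
  hc <- events$heel_contacts
  to <- events$toe_offs
  m <- length(to)
  cand <- data.frame(
    stride = seq_len(m),
    hc_start = hc[-length(hc)],
    toe_off = to,
    hc_end = hc[-1L]
  )
  cand$duration <- cand$hc_end - cand$hc_start
  cand$stance_fraction <- (cand$toe_off - cand$hc_start) / cand$duration
  cand$half_stance_end <- cand$hc_start + 0.5 * (cand$toe_off - cand$hc_start)
  reason <- ifelse(is.na(to), paste0("incomplete: ", events$reason), "")

  complete <- which(!is.na(to))
  if (length(complete) < n_strides + 4L) {
    stop(sprintf(
      "insufficient strides: %d complete strides detected, need at least %d",
      length(complete), n_strides + 4L), call. = FALSE)
  }
  edge <- complete[c(1L, 2L, length(complete) - 1L, length(complete))]
  inner <- setdiff(complete, edge)
  reason[edge] <- "edge discard"

  med <- stats::median(cand$duration[inner])
  ok <- logical(m)
  for (i in inner) {
    if (abs(cand$duration[i] - med) > duration_tol * med) {
      reason[i] <- "duration outlier"
    } else if (cand$stance_fraction[i] <= stance_range[1L] ||
               cand$stance_fraction[i] >= stance_range[2L]) {
      reason[i] <- "stance fraction out of range"
    } else if (floor(0.5 * (cand$toe_off[i] - cand$hc_start[i]) * rate) < min_samples ||
               floor((cand$hc_end[i] - cand$toe_off[i]) * rate) < min_samples) {
      reason[i] <- "phase window too short"
    } else {
      ok[i] <- TRUE
    }
  }

  # first run of n_strides consecutive qualifying strides
  start <- NA_integer_
  run_len <- 0L
  longest <- 0L
  for (i in seq_len(m)) {
    run_len <- if (ok[i]) run_len + 1L else 0L
    longest <- max(longest, run_len)
    if (run_len == n_strides) {
      start <- i - n_strides + 1L
      break
    }
  }
  if (is.na(start)) {
    stop(sprintf(
      "no run of %d stable consecutive strides (longest qualifying run: %d)",
      n_strides, longest), call. = FALSE)
  }
  selected <- seq.int(start, start + n_strides - 1L)
  cand$selected <- FALSE
  cand$selected[selected] <- TRUE
  reason[ok & !cand$selected] <- "not in selected run"
  reason[cand$selected] <- "selected"
  cand$reason <- reason
  structure(cand, class = c("stride_set", "data.frame"),
            n_strides = n_strides, rate = rate)
}

#' @export
print.stride_set <- function(x, ...) {
  sel <- x[x$selected, , drop = FALSE]
  cat(sprintf("Stride set: %d candidate strides, %d selected\n",
              nrow(x), nrow(sel)))
  if (nrow(sel)) {
    cat(sprintf("  selected strides %d-%d; mean duration %.3f s, mean stance fraction %.2f\n",
                min(sel$stride), max(sel$stride), mean(sel$duration),
                mean(sel$stance_fraction)))
  }
  invisible(x)
}

#' Phase windows of a stride
#'
#' Half-open windows used by the thrust index: first half of stance
#' `[hc_start, hc_start + 0.5 * (toe_off - hc_start))` and swing
#' `[toe_off, hc_end)`. A sample at time `t` belongs to a window iff
#' `start <= t < end`.
#'
#' @param hc_start,toe_off,hc_end Event times of one stride (s).
#' @return An object of class `phase_windows`: a list with elements
#'   `first_half_stance` and `swing`, each a `c(start, end)` pair.
#' @export
phase_windows <- function(hc_start, toe_off, hc_end) {
  if (!(hc_start < toe_off && toe_off < hc_end)) {
    stop("need hc_start < toe_off < hc_end", call. = FALSE)
  }
  structure(list(
    first_half_stance = c(hc_start, hc_start + 0.5 * (toe_off - hc_start)),
    swing = c(toe_off, hc_end)
  ), class = "phase_windows")
}
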