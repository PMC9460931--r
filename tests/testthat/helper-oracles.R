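# Independent oracles and small fixtures used across the suite.

# brute-force RMS with explicit loop (no vectorized shortcuts)
brute_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  sqrt(s / length(x))
}

# explicitly recompute half-open window indices by looping over samples
brute_window_idx <- function(time_s, from, to) {
  out <- integer()
  for (j in seq_along(time_s)) {
    if (time_s[j] >= from && time_s[j] < to) out <- c(out, j)
  }
  out
}

# Mann-Whitney U / (n1 * n2) by direct pair counting, ties counted 0.5
brute_auc <- function(pos, neg) {
  u <- 0
  for (p in pos) for (q in neg) {
    u <- u + (p > q) + 0.5 * (p == q)
  }
  u / (length(pos) * length(neg))
}

# noise-free analytic index values implied by the generator's shapes
analytic_st_rms <- function(cf) {
  a <- cf$thrust_amplitude_ms2 * cf$swing_speed_scale^cf$speed_coupling
  g0 <- cf$ml_offset_ms2
  sqrt(g0^2 + a^2 / 2 + (4 / pi) * g0 * a)
}
analytic_mean_vsw <- function(cf) {
  0.5 * cf$swing_peak_degs * cf$swing_speed_scale / sqrt(2)
}

# match each true event to the nearest detection; recall within a tolerance
event_recall <- function(truth, detected, tol_s) {
  if (!length(truth)) return(NA_real_)
  hits <- vapply(truth, function(tt) any(abs(detected - tt) <= tol_s),
                 logical(1L))
  mean(hits)
}

quiet_fit <- function(...) suppressWarnings(varus_thrust(...))
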