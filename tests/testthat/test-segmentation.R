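test_that("the zero-phase low-pass keeps the passband and kills the stopband", {
  rate <- 200
  t <- (0:999) / rate
  expect_equal(lowpass_filter(rep(3.7, 1000), rate), rep(3.7, 1000),
               tolerance = 1e-8)
  s5 <- sin(2 * pi * 5 * t)
  y5 <- lowpass_filter(s5, rate, cutoff = 20)
  mid <- 200:800
  expect_lt(abs(max(abs(y5[mid])) - 1), 0.01)
  s60 <- sin(2 * pi * 60 * t)
  y60 <- lowpass_filter(s60, rate, cutoff = 20)
  expect_lt(max(abs(y60[mid])), 0.03)
  expect_error(lowpass_filter(rnorm(10), rate), "too short.*minimum")
  expect_error(lowpass_filter(rnorm(1000), rate = 30, cutoff = 20),
               "twice the cutoff")
})

test_that("stride period is recovered from the VT autocorrelation", {
  sim <- generate_recording(gait_config(stride_time_s = 1.1, seed = 3L))
  T1 <- estimate_stride_period(sim$tibia$data$acc_vt, 200)
  expect_gte(T1, 1.04)
  expect_lte(T1, 1.16)
  # faster gait with doubled noise
  sim2 <- generate_recording(gait_config(stride_time_s = 0.9,
                                         noise_sd_ms2 = 0.6, seed = 4L))
  T2 <- estimate_stride_period(sim2$tibia$data$acc_vt, 200)
  expect_gte(T2, 0.85)
  expect_lte(T2, 0.95)
  set.seed(9L)
  expect_error(estimate_stride_period(rnorm(2000), 200),
               "no periodic gait detected")
  expect_error(estimate_stride_period(rnorm(100), 200), "too short")
})

test_that("heel contacts are recovered within +/-15 ms at default noise", {
  cf <- gait_config(n_strides = 20L, seed = 5L)
  sim <- generate_recording(cf)
  vt <- sim$tibia$data$acc_vt
  T0 <- estimate_stride_period(vt, 200)
  hc <- detect_heel_contacts(vt, 200, T0)
  truth <- sim$events$heel_contacts
  expect_equal(event_recall(truth, hc, 0.015), 1)
  # no spurious detections either
  expect_equal(event_recall(hc, truth, 0.015), 1)
  expect_error(detect_heel_contacts(rep(0, 2000), 200, 1.1),
               "insufficient strides")
})

test_that("heel-contact detection stays reliable with doubled noise", {
  cf <- gait_config(n_strides = 20L, noise_sd_ms2 = 0.6, noise_sd_degs = 6,
                    seed = 6L)
  sim <- generate_recording(cf)
  vt <- sim$tibia$data$acc_vt
  hc <- detect_heel_contacts(vt, 200, estimate_stride_period(vt, 200))
  truth <- sim$events$heel_contacts
  expect_gte(event_recall(truth, hc, 0.025), 0.95)  # recall
  expect_gte(event_recall(hc, truth, 0.025), 0.95)  # precision
})

test_that("toe-offs land near truth and track the stance fraction", {
  for (sf in c(0.60, 0.62)) {
    sim <- generate_recording(gait_config(stance_fraction = sf, seed = 7L))
    tib <- sim$tibia$data
    hc <- detect_heel_contacts(tib$acc_vt, 200,
                               estimate_stride_period(tib$acc_vt, 200))
    to <- detect_toe_offs(tib$acc_ap, 200, hc)
    ok <- !is.na(to)
    expect_gte(mean(ok), 0.9)
    err <- vapply(to[ok], function(x) min(abs(x - sim$events$toe_offs)),
                  numeric(1L))
    expect_lte(max(err), 0.025)
    frac <- (to[ok] - hc[-length(hc)][ok]) / diff(hc)[ok]
    expect_true(all(frac > sf - 0.05 & frac < sf + 0.05))
  }
})

test_that("a featureless AP channel rejects every stride", {
  hc <- seq(1, 12, by = 1.1)
  to <- detect_toe_offs(rep(0, 2800), 200, hc)
  expect_true(all(is.na(to)))
  expect_true(all(attr(to, "reason") == "no toe-off feature"))
  expect_error(detect_toe_offs(rep(0, 2800), 200, hc[1L]),
               "at least 2 heel contacts")
})

test_that("stable-stride selection follows the first-qualifying-run rule", {
  mk_events <- function(durs, sf = 0.6) {
    hc <- c(0, cumsum(durs))
    gait_events(hc, hc[-length(hc)] + sf * durs)
  }
  # 16 clean strides, select 10 -> strides 3-12
  ev <- mk_events(rep(1.1, 16))
  ss <- select_stable_strides(ev, n_strides = 10L, rate = 200)
  expect_equal(ss$stride[ss$selected], 3:12)
  expect_equal(ss$reason[c(1, 2, 15, 16)], rep("edge discard", 4))
  expect_equal(ss$reason[13:14], rep("not in selected run", 2))
  # stride 7 lengthened by 30%: runs 3-6 and 8-14 are both shorter than 10
  durs <- rep(1.1, 16); durs[7L] <- 1.1 * 1.3
  expect_error(select_stable_strides(mk_events(durs), 10L, rate = 200),
               "longest qualifying run: 7")
  # exactly 14 complete strides forces the middle 10
  ss <- select_stable_strides(mk_events(rep(1.1, 14)), 10L, rate = 200)
  expect_equal(ss$stride[ss$selected], 3:12)
  # too few strides
  expect_error(select_stable_strides(mk_events(rep(1.1, 12)), 10L, rate = 200),
               "insufficient strides")
  # interleaving invariant holds on every selected stride
  sel <- ss[ss$selected, ]
  expect_true(all(sel$hc_start < sel$toe_off & sel$toe_off < sel$hc_end))
})

test_that("an implausible stance fraction is gated out", {
  hc <- c(0, cumsum(rep(1.1, 16)))
  to <- hc[1:16] + 0.6 * 1.1
  to[8L] <- hc[8L] + 0.95 * 1.1          # stance fraction 0.95
  expect_error(select_stable_strides(gait_events(hc, to), 10L, rate = 200),
               "longest qualifying run")
  ss <- select_stable_strides(gait_events(hc, to), 5L, rate = 200)
  expect_equal(ss$reason[8L], "stance fraction out of range")
})

test_that("event detection is translation-equivariant and scale-invariant", {
  sim <- generate_recording(gait_config(seed = 8L))
  vt <- sim$tibia$data$acc_vt
  rate <- 200
  T0 <- estimate_stride_period(vt, rate)
  hc <- detect_heel_contacts(vt, rate, T0)
  # scale invariance: thresholds are data-relative
  hc_scaled <- detect_heel_contacts(3.7 * vt, rate, T0)
  expect_identical(hc_scaled, hc)
  ap <- sim$tibia$data$acc_ap
  expect_identical(as.numeric(detect_toe_offs(2.5 * ap, rate, hc)),
                   as.numeric(detect_toe_offs(ap, rate, hc)))
  # translation equivariance: delay by k samples
  k <- 37L
  vt_shift <- c(rep(vt[1L], k), vt[seq_len(length(vt) - k)])
  hc_shift <- detect_heel_contacts(vt_shift, rate, T0)
  expect_equal(hc_shift, hc + k / rate, tolerance = 1e-12)
})

test_that("event recovery holds across a seed sweep at default noise", {
  # smaller sweep than the acceptance suite, but same contract
  recalls_hc <- recalls_to <- numeric(10)
  for (s in 1:10) {
    sim <- generate_recording(gait_config(seed = 100L + s))
    tib <- sim$tibia$data
    T0 <- estimate_stride_period(tib$acc_vt, 200)
    hc <- detect_heel_contacts(tib$acc_vt, 200, T0)
    to <- detect_toe_offs(tib$acc_ap, 200, hc)
    recalls_hc[s] <- event_recall(sim$events$heel_contacts, hc, 0.015)
    recalls_to[s] <- event_recall(sim$events$toe_offs,
                                  to[!is.na(to)], 0.025)
  }
  expect_gte(mean(recalls_hc), 0.98)
  expect_gte(mean(recalls_to), 0.95)
})
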