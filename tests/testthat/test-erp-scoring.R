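# Build a two-channel continuous signal holding given epoch waveforms at
# given onsets, zero elsewhere.
make_continuous <- function(epoch_fcz, epoch_pz, onsets_ms, rate = 1000,
                            window = c(-200, 600), total_ms = NULL) {
  step <- 1000 / rate
  if (is.null(total_ms)) total_ms <- max(onsets_ms) + 1000
  n <- as.integer(round(total_ms / step))
  sig <- matrix(0, 2, n, dimnames = list(c("FCz", "Pz"), NULL))
  for (k in seq_along(onsets_ms)) {
    i0 <- as.integer(round((onsets_ms[k] + window[1]) / step)) + 1L
    idx <- i0:(i0 + length(epoch_fcz) - 1L)
    sig["FCz", idx] <- epoch_fcz
    sig["Pz", idx] <- epoch_pz
  }
  sig
}

test_that("segmentation yields 800-ms baselined epochs", {
  rate <- 1000
  n_ep <- 800
  # constant signal: zero after baseline correction
  sig <- matrix(7.3, 2, 5000, dimnames = list(c("FCz", "Pz"), NULL))
  es <- segment_and_baseline(sig, c(1000, 2500), rate)
  expect_equal(dim(es$data), c(2, 2, n_ep))
  expect_true(all(abs(es$data) < 1e-12))
  expect_equal(length(epoch_times(es)), n_ep)

  # epoch sample count scales with the sampling rate
  sig250 <- matrix(0, 2, 2000, dimnames = list(c("FCz", "Pz"), NULL))
  es250 <- segment_and_baseline(sig250, 3000, sampling_rate = 250)
  expect_equal(dim(es250$data)[3], 800 * 250 / 1000)

  # linear ramp: closed form after baseline subtraction
  ramp <- matrix(rep(seq_len(3000) * 0.01, each = 2), 2, byrow = FALSE,
                 dimnames = list(c("FCz", "Pz"), NULL))
  ramp[1, ] <- seq_len(3000) * 0.01
  ramp[2, ] <- seq_len(3000) * 0.01
  es <- segment_and_baseline(ramp, 1000, rate)
  times <- epoch_times(es)
  # sample at time t is ramp value 0.01*(1000+t+1); baseline mean over
  # t in [-200,-1] is 0.01*(1000-100.5+1)
  expected <- 0.01 * (1000 + times + 1) - 0.01 * (1000 - 100.5 + 1)
  expect_equal(as.numeric(es$data[1, 1, ]), expected, tolerance = 1e-9)

  # onsets too close to the recording edge are dropped with a warning
  expect_warning(es2 <- segment_and_baseline(sig, c(100, 2500), rate),
                 "dropped")
  expect_equal(dim(es2$data)[1], 1L)
  expect_equal(attr(es2, "dropped"), 1L)
})

test_that("scoring is invariant to a constant offset before baselining", {
  times_ms <- seq(-200, 799)  # construction grid, 1 kHz
  ep <- -3 * exp(-((times_ms - 260)^2) / (2 * 20^2))
  ep <- ep[1:800]
  sig1 <- make_continuous(ep, ep, 1000)
  sig2 <- sig1 + 42
  for (keys in 1) {
    tk <- data.frame(session = "immediate", feedback_valence = "negative",
                     learnability = "learnable", trial_index = 0)
    s1 <- score_epochs(segment_and_baseline(sig1, 1000, trial_keys = tk))
    s2 <- score_epochs(segment_and_baseline(sig2, 1000, trial_keys = tk))
    expect_equal(s1$frn_amplitude, s2$frn_amplitude, tolerance = 1e-9)
    expect_equal(s1$p3b_amplitude, s2$p3b_amplitude, tolerance = 1e-9)
  }
})

test_that("artifact rejection applies the four amplitude thresholds", {
  n <- 800
  t_ms <- seq_len(n) - 201
  smooth <- 5 * sin(2 * pi * 7 * t_ms / 1000)  # 7 Hz, 5 uV: clean
  base <- array(0, dim = c(5, 2, n), dimnames = list(NULL, c("FCz", "Pz"),
                                                     NULL))
  for (i in 1:5) for (ch in 1:2) base[i, ch, ] <- smooth
  base[2, 1, 400] <- 150                      # absolute amplitude
  base[3, 1, ] <- 0.02 * sin(2 * pi * 7 * t_ms / 1000)  # flat (< 0.1 uV)
  base[4, 1, ] <- smooth + c(rep(0, 399), rep(80, n - 399))  # 80 uV step
  base[5, 1, ] <- 60 * sin(2 * pi * 2 * t_ms / 1000)  # 120 uV range, slow
  es <- epoch_set(base)
  mask <- reject_artifacts(es)
  expect_identical(mask, c(FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("FRN peak detection finds the most negative strict local minimum", {
  times <- seq(-200, 599)
  trough <- function(center, depth = 3, width = 20)
    -depth * exp(-((times - center)^2) / (2 * width^2))
  expect_equal(frn_peak_latency(trough(260), times), 260)
  # monotone segment inside the window: no peak
  expect_true(is.na(frn_peak_latency(-0.01 * times, times)))
  # two exactly equal troughs: earliest wins
  two <- numeric(length(times))
  two[times %in% c(239, 241, 299, 301)] <- -1
  two[times %in% c(240, 300)] <- -3
  expect_equal(frn_peak_latency(two, times), 240)
  # endpoints excluded: trough exactly at 350 does not count
  edge <- trough(350, width = 8)
  expect_true(is.na(frn_peak_latency(edge, times)) ||
                frn_peak_latency(edge, times) < 350)
})

test_that("single-trial FRN is the 40-ms mean around the peak", {
  times <- seq(-200, 599)
  expect_equal(single_trial_frn(rep(2.5, length(times)), times, 260), 2.5)
  # window spans exactly 41 samples at 1 kHz (20 ms either side)
  x <- as.numeric(times >= 240 & times <= 280)
  expect_equal(single_trial_frn(x, times, 260), 1)
  expect_equal(sum(times >= 240 & times <= 280), 41L)
  # linear ramp: symmetric mean equals the value at the peak latency
  ramp <- 0.05 * times
  expect_equal(single_trial_frn(ramp, times, 260), 0.05 * 260)
  expect_true(is.na(single_trial_frn(ramp, times, NA_real_)))
})

test_that("P3 amplitude is the 300-500 ms window mean", {
  times <- seq(-200, 599)
  expect_equal(p3_amplitude(rep(1.7, length(times)), times), 1.7)
  ind <- as.numeric(times >= 300 & times <= 500)
  expect_equal(p3_amplitude(ind, times), 1)
  # toy five-sample window: hand-computed arithmetic mean
  t5 <- c(300, 350, 400, 450, 500)
  expect_equal(p3_amplitude(c(1, 2, 3, 4, 5), t5), 3)
})

test_that("condition averages without a detectable peak flag outliers", {
  n <- 800
  dat <- array(0, dim = c(3, 2, n), dimnames = list(NULL, c("FCz", "Pz"),
                                                    NULL))
  t_ms <- seq(-200, 599)
  for (i in 1:3) dat[i, 1, ] <- -0.01 * t_ms  # monotone: no local minimum
  keys <- data.frame(session = "immediate",
                     feedback_valence = "negative",
                     learnability = "learnable", trial_index = 0:2)
  sc <- score_epochs(epoch_set(dat, trial_keys = keys))
  expect_true(all(sc$outlier_flag))
  expect_true(all(is.na(sc$frn_amplitude)))
  expect_true(all(!is.na(sc$p3a_amplitude)))  # P3 never depends on the peak
})

test_that("epoch sets survive the TSV + sidecar round trip", {
  set.seed(9)
  dat <- array(rnorm(4 * 2 * 200), dim = c(4, 2, 200),
               dimnames = list(NULL, c("FCz", "Pz"), NULL))
  keys <- data.frame(participant_id = "p1", session = "immediate",
                     trial_index = 0:3)
  es <- epoch_set(dat, sampling_rate = 250, trial_keys = keys,
                  rejection_mask = c(FALSE, TRUE, FALSE, FALSE))
  path <- tempfile(fileext = ".tsv")
  write_epochs(es, path)
  back <- read_epochs(path)
  expect_equal(back$data, es$data, tolerance = 1e-12)
  expect_identical(back$rejection_mask, es$rejection_mask)
  expect_equal(back$sampling_rate, 250)
  expect_equal(back$trial_keys$trial_index, 0:3)
})
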