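test_that("cohort simulation is bitwise reproducible under a fixed seed", {
  a <- simulate_cohort(2, 2, config = task_config(n_blocks = 3), seed = 6)
  b <- simulate_cohort(2, 2, config = task_config(n_blocks = 3), seed = 6)
  expect_identical(a$events, b$events)
  expect_identical(a$agents, b$agents)
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_events(a$events, p1); write_events(b$events, p2)
  expect_identical(readLines(p1), readLines(p2))
  c_ <- simulate_cohort(2, 2, config = task_config(n_blocks = 3), seed = 7)
  expect_false(identical(a$events$response, c_$events$response))
})

test_that("sessions respect counterbalancing, block counts and set switches", {
  co <- simulate_cohort(2, 2, seed = 23)
  ev <- co$events
  # both sessions for every participant; order alternates by parity
  for (p in unique(ev$participant_id))
    expect_setequal(unique(ev$session[ev$participant_id == p]),
                    c("immediate", "delayed"))
  first_ses <- ev$session[ev$participant_id == "pat01"][1]
  second_ses <- ev$session[ev$participant_id == "pat02"][1]
  expect_false(first_ses == second_ses)
  # no session exceeds 9 blocks; a ninth block only without criterion pass
  blocks <- tapply(ev$block, interaction(ev$participant_id, ev$session),
                   max)
  expect_true(all(blocks <= 9))
  # set switches introduce fresh stimulus ids and keep old trials flagged
  sw <- ev[ev$stimulus_set == 2, ]
  if (nrow(sw) > 0) {
    expect_true(all(sw$stimulus_id > 4))
    expect_true(all(ev$stimulus_id[ev$stimulus_set == 1] <= 4))
  }
})

test_that("fast learners beat the criterion and chance agents do not learn", {
  fast <- simulate_cohort(2, 2, param_dist = list(beta_fixed = 8,
                                                  alpha_fixed = 0.4),
                          invalid_rate = 0, seed = 29)
  ba <- block_accuracy(fast$events)
  late <- ba$accuracy[ba$block >= 6]
  expect_gt(mean(late, na.rm = TRUE), 65)

  slow <- simulate_cohort(2, 2, param_dist = list(beta_fixed = 0,
                                                  alpha_fixed = 0.3),
                          invalid_rate = 0, seed = 30)
  ba0 <- block_accuracy(slow$events)
  expect_lt(abs(mean(ba0$accuracy, na.rm = TRUE) - 50), 5)
})

test_that("conditional-slope coefficients reproduce requested cell slopes", {
  slopes <- c(control.positive = 0.98, control.negative = 0,
              patient.positive = 0, patient.negative = 0)
  terms <- upe_slope_terms(slopes)
  codes <- c(control = -0.5, patient = 0.5, positive = 0.5, negative = -0.5)
  for (cell in names(slopes)) {
    lv <- strsplit(cell, ".", fixed = TRUE)[[1]]
    g <- codes[[lv[1]]]; v <- codes[[lv[2]]]
    got <- terms[["upe"]] + g * terms[["group:upe"]] +
      v * terms[["feedback_valence:upe"]] +
      g * v * terms[["group:feedback_valence:upe"]]
    expect_equal(got, unname(slopes[cell]), tolerance = 1e-12)
  }
  # three-moderator solve reproduces an 8-cell pattern
  s8 <- c(control.positive.immediate = 1.18, control.positive.delayed = 2.36,
          control.negative.delayed = -0.97, control.negative.immediate = 0,
          patient.positive.immediate = 0, patient.positive.delayed = 0,
          patient.negative.delayed = 0, patient.negative.immediate = 0)
  t8 <- upe_slope_terms(s8)
  expect_equal(length(t8), 8L)
  # evaluate through an explicit design row instead of assuming term order
  eval_cell <- function(g, v, t) {
    vals <- c(group = g, feedback_valence = v, feedback_timing = t)
    sum(vapply(names(t8), function(tm) {
      vars <- setdiff(strsplit(tm, ":", fixed = TRUE)[[1]], "upe")
      t8[[tm]] * prod(vals[vars])
    }, numeric(1)))
  }
  expect_equal(eval_cell(-0.5, 0.5, 0.5), 2.36, tolerance = 1e-12)
  expect_equal(eval_cell(-0.5, -0.5, -0.5), 0, tolerance = 1e-12)
  expect_equal(eval_cell(0.5, 0.5, 0.5), 0, tolerance = 1e-12)
})

test_that("noiseless amplitudes equal the design linear predictor", {
  co <- simulate_cohort(2, 2, config = task_config(n_blocks = 2), seed = 33)
  ev <- true_trial_pes(co$events, co$agents)
  eff <- effect_spec(random_intercept_sd = c(frn = 0, p3a = 0, p3b = 0),
                     residual_sd = c(frn = 0, p3a = 0, p3b = 0))
  erp <- simulate_erp_amplitudes(ev, eff, seed = 1)
  coefs <- eff$coefficients$frn
  mu <- rep(0, nrow(erp))
  for (tm in names(coefs)) {
    mu <- mu + if (tm == "(Intercept)") coefs[[tm]] else
      coefs[[tm]] * Reduce(`*`, erp[strsplit(tm, ":", fixed = TRUE)[[1]]])
  }
  expect_equal(erp$frn_amplitude, mu, tolerance = 1e-12)
  # valence effect appears as an exact group-mean difference, averaged
  # over the balanced coded factors it interacts with
  expect_error(simulate_erp_amplitudes(
    ev, effect_spec(frn = c(no_such_column = 1)), seed = 1),
    "unknown column")
})

test_that("continuous EEG round trip recovers planted amplitudes and peaks", {
  co <- simulate_cohort(1, 1, config = task_config(n_blocks = 2), seed = 35)
  ev <- true_trial_pes(co$events, co$agents)
  erp <- simulate_erp_amplitudes(ev, seed = 2)
  wf <- waveform_spec(sampling_rate = 500, noise_sd = 0)
  eeg <- simulate_continuous_eeg(erp, wf, seed = 3)
  rec <- eeg[[1]]
  es <- segment_and_baseline(rec$continuous, rec$onsets_ms,
                             sampling_rate = 500,
                             trial_keys = rec$trial_keys)
  sc <- score_epochs(es)
  m <- merge(sc, rec$trial_keys[, c("trial_index", "frn_amplitude",
                                    "p3a_amplitude", "p3b_amplitude")],
             by = "trial_index", suffixes = c("", ".tru"))
  expect_equal(m$frn_amplitude, m$frn_amplitude.tru, tolerance = 1e-9)
  expect_equal(m$p3a_amplitude, m$p3a_amplitude.tru, tolerance = 1e-9)
  expect_equal(m$p3b_amplitude, m$p3b_amplitude.tru, tolerance = 1e-9)
  expect_true(all(sc$frn_peak_latency == 250))
})

test_that("injected spikes are rejected at the planted rate", {
  co <- simulate_cohort(2, 2, config = task_config(n_blocks = 2), seed = 37)
  ev <- true_trial_pes(co$events, co$agents)
  erp <- simulate_erp_amplitudes(ev, seed = 2)
  wf <- waveform_spec(sampling_rate = 250, noise_sd = 1, spike_rate = 0.1)
  eeg <- simulate_continuous_eeg(erp, wf, seed = 5)
  planted <- unlist(lapply(eeg, `[[`, "spiked"))
  flagged <- unlist(lapply(eeg, function(rec) {
    es <- segment_and_baseline(rec$continuous, rec$onsets_ms,
                               sampling_rate = 250,
                               trial_keys = rec$trial_keys)
    reject_artifacts(es)
  }))
  # every spiked trial violates the 100 uV rule; 1 uV noise does not
  expect_identical(flagged, unname(planted))
  expect_lt(abs(mean(flagged) - 0.1), 0.06)
})

test_that("epochs would overlap when the ITI is too short", {
  co <- simulate_cohort(1, 0, config = task_config(n_blocks = 2), seed = 39)
  ev <- true_trial_pes(co$events, co$agents)
  erp <- simulate_erp_amplitudes(ev, seed = 1)
  expect_error(simulate_continuous_eeg(erp, waveform_spec(iti_ms = 500)),
               "overlap")
})
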