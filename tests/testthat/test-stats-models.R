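# Small balanced repeated-measures generator with known fixed effects.
sim_design <- function(n_per_group = 10, m = 24, b_timing = 0,
                       b_valence = 0, sd_id = 1, sd_eps = 1, seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(2 * n_per_group))
  d <- expand.grid(participant_id = ids, obs = seq_len(m),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(match(d$participant_id, ids) <= n_per_group,
                    "patient", "control")
  d$session <- sample(c("immediate", "delayed"), nrow(d), replace = TRUE)
  d$feedback_valence <- sample(c("positive", "negative"), nrow(d),
                               replace = TRUE)
  d$block <- sample(1:8, nrow(d), replace = TRUE)
  d <- code_predictors(d)
  u <- rnorm(length(ids), 0, sd_id)
  d$y <- u[match(d$participant_id, ids)] +
    b_timing * d$feedback_timing + b_valence * d$feedback_valence +
    rnorm(nrow(d), 0, sd_eps)
  d
}

test_that("simple coding maps levels to +/-0.5 and standardizes block", {
  d <- data.frame(group = c("patient", "control"),
                  session = c("delayed", "immediate"),
                  feedback_valence = c("positive", "negative"),
                  learnability = c("learnable", "unlearnable"),
                  response_type = c("correct", "false"),
                  block = c(1, 8))
  cd <- code_predictors(d)
  expect_equal(cd$group, c(0.5, -0.5))
  expect_equal(cd$feedback_timing, c(0.5, -0.5))
  expect_equal(cd$feedback_valence, c(0.5, -0.5))
  expect_equal(cd$learnability, c(0.5, -0.5))
  expect_equal(cd$response_type, c(0.5, -0.5))

  blocks <- data.frame(block = rep(1:8, each = 3))
  cb <- code_predictors(blocks)
  expect_equal(mean(cb$block_z), 0, tolerance = 1e-12)
  expect_equal(sd(cb$block_z), 1, tolerance = 1e-12)

  expect_error(code_predictors(data.frame(group = "sham")), "unknown group")
})

test_that("intercept-only model on balanced data recovers the grand mean", {
  d <- sim_design(n_per_group = 8, m = 20, seed = 3)
  res <- fit_mlm(d, mlm_spec(y ~ 1, ~1))
  # REML intercept on balanced data equals the mean of participant means
  pm <- tapply(d$y, d$participant_id, mean)
  expect_equal(unname(res$coefficients["(Intercept)", "estimate"]),
               mean(pm), tolerance = 1e-6)
})

test_that("planted fixed effects are recovered within their CI", {
  d <- sim_design(n_per_group = 12, m = 40, b_timing = 1.0, b_valence = 0.6,
                  seed = 7)
  res <- fit_mlm(d, mlm_spec(y ~ feedback_timing * feedback_valence,
                             ~ 1 + feedback_timing))
  co <- res$coefficients
  for (term in c("feedback_timing", "feedback_valence")) {
    truth <- if (term == "feedback_timing") 1.0 else 0.6
    expect_lt(abs(co[term, "estimate"] - truth), 2.2 * co[term, "se"])
  }
  expect_true(all(res$coefficients$p >= 0 & res$coefficients$p <= 1))
})

test_that("with balanced noise-free factors, main effects equal mean
           differences", {
  d <- expand.grid(participant_id = sprintf("s%d", 1:6),
                   session = c("immediate", "delayed"),
                   feedback_valence = c("positive", "negative"),
                   rep = 1:4, stringsAsFactors = FALSE)
  d <- code_predictors(d)
  d$y <- 2 + 1.4 * d$feedback_timing - 0.8 * d$feedback_valence
  res <- fit_mlm(d, mlm_spec(y ~ feedback_timing * feedback_valence, ~1))
  diff_t <- mean(d$y[d$feedback_timing > 0]) - mean(d$y[d$feedback_timing < 0])
  expect_equal(unname(res$coefficients["feedback_timing", "estimate"]),
               diff_t, tolerance = 1e-8)
  expect_equal(unname(res$coefficients["feedback_valence", "estimate"]),
               -0.8, tolerance = 1e-8)
})

test_that("stepwise reduction deletes random terms but never fixed ones", {
  # random structure far richer than the generative process forces
  # singular fits and a reduction cascade
  d <- sim_design(n_per_group = 6, m = 16, b_timing = 0.5, seed = 11)
  spec <- mlm_spec(y ~ feedback_timing * feedback_valence,
                   ~ 1 + feedback_timing * feedback_valence)
  res <- fit_mlm(d, spec)
  expect_true(length(res$dropped) >= 1)
  # interactions leave before main effects
  if (length(res$dropped))
    expect_equal(res$dropped[1], "feedback_timing:feedback_valence")
  expect_setequal(rownames(res$coefficients),
                  c("(Intercept)", "feedback_timing", "feedback_valence",
                    "feedback_timing:feedback_valence"))

  # the deletion queue itself: higher order first, last-listed first
  expect_equal(
    rlerp:::reduction_order(~ 1 + a + b + a:b),
    c("a:b", "b", "a"))
  expect_equal(
    rlerp:::reduction_order(~ 1 + a * b + c),
    c("a:b", "c", "b", "a"))
})

test_that("simple slopes equal hand-computed coefficient combinations", {
  d <- sim_design(n_per_group = 10, m = 30, b_timing = 0.8, seed = 13)
  d$y <- d$y + 1.5 * d$feedback_timing * d$feedback_valence
  res <- fit_mlm(d, mlm_spec(y ~ feedback_timing * feedback_valence, ~1))
  ss <- probe_simple_slopes(res, "feedback_timing", "feedback_valence")
  co <- res$coefficients$estimate
  names(co) <- rownames(res$coefficients)
  # slope of timing at valence v is b_timing + v * b_interaction
  for (v in c(-0.5, 0.5)) {
    lab <- if (v > 0) "positive" else "negative"
    expect_equal(ss$estimate[ss$feedback_valence == lab],
                 unname(co["feedback_timing"] +
                          v * co["feedback_timing:feedback_valence"]),
                 tolerance = 1e-9)
  }
  # moderator must take part in an interaction with the focal predictor
  expect_error(probe_simple_slopes(res, "feedback_timing", "group"),
               "moderator")
})

test_that("a model whose interaction is zero probes to identical slopes", {
  d <- expand.grid(participant_id = sprintf("s%d", 1:8),
                   session = c("immediate", "delayed"),
                   feedback_valence = c("positive", "negative"),
                   rep = 1:3, stringsAsFactors = FALSE)
  d <- code_predictors(d)
  d$y <- 1 + 0.9 * d$feedback_timing   # no interaction in truth, noise-free
  res <- fit_mlm(d, mlm_spec(y ~ feedback_timing * feedback_valence, ~1))
  ss <- probe_simple_slopes(res, "feedback_timing", "feedback_valence")
  expect_equal(ss$estimate[1], ss$estimate[2], tolerance = 1e-8)
  expect_equal(ss$estimate[1], 0.9, tolerance = 1e-8)
})

test_that("influence screening flags a planted deviant participant", {
  d <- sim_design(n_per_group = 8, m = 20, seed = 17)
  res0 <- fit_mlm(d, mlm_spec(y ~ feedback_timing, ~1))
  inf0 <- screen_influence(res0)
  expect_true(all(inf0$cooks_distance >= 0))
  # this homogeneous draw produces no flags at the 4/n cutoff
  expect_equal(sum(inf0$flagged), 0L)

  # shift one participant's response by 10 SD: it becomes the sole flag
  d2 <- d
  d2$y[d2$participant_id == "s03"] <- d2$y[d2$participant_id == "s03"] + 10
  res <- fit_mlm(d2, mlm_spec(y ~ feedback_timing, ~1))
  inf <- screen_influence(res)
  worst <- inf$unit[which.max(inf$cooks_distance)]
  expect_equal(worst, "s03")
  expect_true(inf$flagged[inf$unit == "s03"])
  expect_equal(sum(inf$flagged), 1L)

  # observation-level distances are available too
  obs <- screen_influence(res0, level = "observation")
  expect_equal(nrow(obs), res0$n_obs)
  expect_true(all(obs$cooks_distance >= 0))
})

test_that("the five study model templates fit the synthetic study", {
  st <- simulate_study(5, 5, config = task_config(n_blocks = 4), seed = 19)
  tpl <- mlm_templates()

  acc <- code_predictors(merge(
    block_accuracy(st$events),
    unique(st$events[, c("participant_id", "group", "session")])))
  r_acc <- fit_mlm(acc, tpl$accuracy)
  expect_true(all(is.finite(r_acc$coefficients$estimate)))

  sw <- choice_switching(st$events)
  sw <- merge(sw, unique(st$events[, c("participant_id", "group")]))
  sw <- code_predictors(sw[!is.na(sw$switch) & !is.na(sw$response_type), ])
  r_sw <- fit_mlm(sw, tpl$switching)
  # 2^5 terms when every factor cell has support; small simulations may
  # lose a high-order column to rank deficiency
  expect_gte(nrow(r_sw$coefficients), 31L)
  expect_true(all(is.finite(r_sw$coefficients$estimate)))

  r_frn <- fit_mlm(st$erp, tpl$frn)
  r_p3a <- fit_mlm(st$erp, tpl$p3a)
  r_p3b <- fit_mlm(st$erp, tpl$p3b)
  for (r in list(r_frn, r_p3a, r_p3b)) {
    expect_equal(nrow(r$coefficients), 32L)
    expect_true(all(r$coefficients$p >= 0 & r$coefficients$p <= 1))
  }
  # FRN model recovers the planted valence effect within CI at this n
  co <- r_frn$coefficients
  expect_lt(abs(co["feedback_valence", "estimate"] - 0.65),
            3 * co["feedback_valence", "se"])

  # results serialize with metadata
  path <- tempfile(fileext = ".tsv")
  write_mlm_result(r_frn, path)
  meta <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  expect_equal(meta$n_groups, 10L)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 32L)
})
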