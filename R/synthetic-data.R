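#' Planted fixed-effect structure for the synthetic single-trial ERPs
#'
#' Coefficients are keyed by model term in the coded design
#' (see [code_predictors()]); any term absent from a vector defaults to
#' zero. The defaults plant the effect structure the analysis is built to
#' detect: a feedback-valence effect on the FRN; a group effect (more
#' negative FRN in patients); a feedback-timing effect on the FRN present in
#' controls only (timing x group interaction); and unsigned-PE coding that
#' is present for positive feedback in controls (conditional slope 0.98 for
#' FRN, 1.95 for P3a) and absent in patients. The P3b plants
#' timing-dependent unsigned-PE coding in controls only (conditional slopes
#' 1.18 / 2.36 / -0.97 / 0 for positive-immediate / positive-delayed /
#' negative-delayed / negative-immediate feedback).
#'
#' @param frn,p3a,p3b Named numeric vectors of fixed-effect coefficients
#'   (microvolts) keyed by term.
#' @param random_intercept_sd Named numeric vector: SD of the by-participant
#'   random intercept per outcome, microvolts.
#' @param residual_sd Named numeric vector: residual SD per outcome,
#'   microvolts.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(frn = NULL, p3a = NULL, p3b = NULL,
                        random_intercept_sd = c(frn = 6, p3a = 6, p3b = 6),
                        residual_sd = c(frn = 5, p3a = 5, p3b = 5)) {
  if (is.null(frn))
    frn <- c("(Intercept)" = 2.9, feedback_valence = 0.65, group = -1.61,
             feedback_timing = -1.1, "group:feedback_timing" = 2.06,
             upe_slope_terms(c(control.positive = 0.98, control.negative = 0,
                               patient.positive = 0, patient.negative = 0)))
  if (is.null(p3a))
    p3a <- c("(Intercept)" = 5.2, feedback_valence = 0.57,
             upe_slope_terms(c(control.positive = 1.95, control.negative = 0,
                               patient.positive = 0, patient.negative = 0)))
  if (is.null(p3b))
    p3b <- c("(Intercept)" = 4.5,
             upe_slope_terms(c(control.positive.immediate = 1.18,
                               control.positive.delayed = 2.36,
                               control.negative.delayed = -0.97,
                               control.negative.immediate = 0,
                               patient.positive.immediate = 0,
                               patient.positive.delayed = 0,
                               patient.negative.delayed = 0,
                               patient.negative.immediate = 0)))
  stopifnot(all(random_intercept_sd >= 0), all(residual_sd >= 0))
  structure(list(coefficients = list(frn = frn, p3a = p3a, p3b = p3b),
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd),
            class = "effect_spec")
}

#' Convert conditional unsigned-PE slopes into interaction coefficients
#'
#' Given the desired conditional slope of the unsigned PE in each cell of a
#' group x valence (x timing) crossing under +/-0.5 simple coding, solves
#' for the `upe` main effect and its interactions with the moderators so
#' that the linear model reproduces those slopes exactly.
#'
#' @param slopes Named numeric vector; names are dot-separated level labels
#'   drawn from `patient`/`control`, `positive`/`negative`,
#'   `delayed`/`immediate` (e.g. `"control.positive"`), covering the full
#'   crossing of the mentioned factors.
#' @return Named numeric vector of term coefficients (e.g. `"upe"`,
#'   `"group:upe"`, `"group:feedback_valence:upe"`).
#' @export
upe_slope_terms <- function(slopes) {
  lvl_code <- c(patient = 0.5, control = -0.5,
                positive = 0.5, negative = -0.5,
                delayed = 0.5, immediate = -0.5)
  lvl_var <- c(patient = "group", control = "group",
               positive = "feedback_valence", negative = "feedback_valence",
               delayed = "feedback_timing", immediate = "feedback_timing")
  parts <- strsplit(names(slopes), ".", fixed = TRUE)
  vars <- unique(unlist(lapply(parts, function(p) unname(lvl_var[p]))))
  if (anyNA(vars)) stop("upe_slope_terms: unknown level label", call. = FALSE)
  # design row per cell over all subsets of the moderator variables
  subsets <- lapply(0:length(vars), function(k)
    utils::combn(vars, k, simplify = FALSE))
  subsets <- unlist(subsets, recursive = FALSE)
  X <- vapply(subsets, function(sub) {
    vapply(parts, function(p) {
      codes <- lvl_code[p]
      names(codes) <- lvl_var[p]
      prod(codes[sub])
    }, numeric(1))
  }, numeric(length(slopes)))
  if (length(slopes) != length(subsets))
    stop("upe_slope_terms: slopes must cover the full factor crossing",
         call. = FALSE)
  coefs <- solve(X, unname(slopes))
  term_names <- vapply(subsets, function(sub)
    paste(c(sub, "upe"), collapse = ":"), character(1))
  stats::setNames(coefs, term_names)
}

#' Waveform description for synthetic continuous EEG
#'
#' Each trial's epoch is built from a frontocentral FRN component (a
#' smooth dip centered in the FRN scoring window whose 40-ms windowed mean
#' equals the planted single-trial FRN amplitude, riding on a
#' zero-window-mean trough anchor that guarantees a detectable negative
#' peak at the planted center), a P3 component (smooth positive bump whose
#' 300-500 ms mean equals the planted P3a amplitude at the frontocentral
#' site and P3b at the centroparietal site), and Gaussian white noise.
#'
#' @param sampling_rate Hz (default 1000).
#' @param frn_center FRN component center, ms post-feedback (default 250;
#'   must lie inside the 200-350 ms search window).
#' @param frn_halfwidth Half-width of the FRN dip, ms (default 20, matching
#'   the scoring window).
#' @param p3_window P3 component support and scoring window, ms.
#' @param anchor_depth Depth scale of the trough anchor, microvolts.
#' @param noise_sd Gaussian noise SD, microvolts.
#' @param iti_ms Onset-to-onset spacing in the continuous signal, ms; `NULL`
#'   derives it from the session's feedback delay (delay + 2500 ms).
#' @param spike_rate Fraction of trials receiving an injected artifact
#'   spike.
#' @param spike_uv Spike amplitude, microvolts (default 200, violating the
#'   +/-100 threshold).
#' @return A list of class `waveform_spec`.
#' @export
waveform_spec <- function(sampling_rate = 1000, frn_center = 250,
                          frn_halfwidth = 20, p3_window = c(300, 500),
                          anchor_depth = 100, noise_sd = 1, iti_ms = NULL,
                          spike_rate = 0, spike_uv = 200) {
  if (frn_center <= 200 || frn_center >= 350)
    stop("waveform_spec: frn_center must lie inside the 200-350 ms window",
         call. = FALSE)
  structure(list(sampling_rate = sampling_rate, frn_center = frn_center,
                 frn_halfwidth = frn_halfwidth, p3_window = p3_window,
                 anchor_depth = anchor_depth, noise_sd = noise_sd,
                 iti_ms = iti_ms, spike_rate = spike_rate,
                 spike_uv = spike_uv),
            class = "waveform_spec")
}

#' Simulate a cohort of RW/softmax agents completing both task sessions
#'
#' Every participant completes the immediate and the delayed session with
#' session order counterbalanced by participant parity. Choices are drawn
#' from the softmax over Rescorla-Wagner-updated action values; learning
#' rates are drawn per stimulus and feedback valence from a beta
#' distribution and the inverse temperature from the gamma distribution
#' used as the fitting prior. A small fraction of trials is made invalid
#' (too fast, too slow, multiple presses, or no response) to exercise the
#' exclusion rules. The learning-criterion logic is applied online: a
#' criterion-triggered stimulus-set switch introduces fresh stimuli (ids
#' offset by `n_stimuli`) with re-initialized action values, and a ninth
#' block is appended when the criterion is never exceeded.
#'
#' Patients and controls differ only through the planted ERP effect
#' coefficients downstream, not behaviorally, unless distinct parameter
#' distributions are supplied.
#'
#' @param n_patients,n_controls Group sizes.
#' @param config A [task_config()] (the immediate/delayed delay is set per
#'   session internally).
#' @param param_dist List with `alpha_shape1`, `alpha_shape2` (beta
#'   distribution of learning rates), `beta_shape`, `beta_scale` (gamma
#'   distribution of the inverse temperature, truncated to \[0, 50\]).
#'   Optional `alpha_fixed` / `beta_fixed` entries pin all learning rates or
#'   the inverse temperature to a constant (e.g. `beta_fixed = 0` for chance
#'   responders).
#' @param invalid_rate Fraction of trials made invalid.
#' @param seed Integer seed; output is bitwise reproducible.
#' @return List with `events` (trial-level data.frame) and `agents`
#'   (long data.frame of true parameters: one row per participant x session
#'   x stimulus with `alpha_neg`, `alpha_pos`, `beta`).
#' @export
simulate_cohort <- function(n_patients = 21, n_controls = 25,
                            config = task_config(),
                            param_dist = list(alpha_shape1 = 2,
                                              alpha_shape2 = 4,
                                              beta_shape = 2, beta_scale = 3),
                            invalid_rate = 0.03, seed = 1L) {
  validate_task_config(config)
  ids <- c(sprintf("pat%02d", seq_len(n_patients)),
           sprintf("con%02d", seq_len(n_controls)))
  groups <- rep(c("patient", "control"), c(n_patients, n_controls))

  with_seed(seed, {
    all_events <- vector("list", length(ids))
    all_agents <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      sessions <- if (i %% 2L == 1L) c("immediate", "delayed")
                  else c("delayed", "immediate")
      ev <- list(); ag <- list()
      for (ses in sessions) {
        cfg <- config
        cfg$feedback_delay_ms <- if (ses == "immediate") 500 else 6500
        sim <- simulate_session(ids[i], groups[i], ses, cfg, param_dist,
                                invalid_rate)
        ev[[ses]] <- sim$events
        ag[[ses]] <- sim$agent
      }
      # keep presentation order (session order), not list-name order
      all_events[[i]] <- do.call(rbind, ev[sessions])
      all_agents[[i]] <- do.call(rbind, ag[sessions])
    }
    events <- do.call(rbind, all_events)
    rownames(events) <- NULL
    agents <- do.call(rbind, all_agents)
    rownames(agents) <- NULL
    list(events = events, agents = agents)
  })
}

# One participant-session; consumes the ambient RNG stream.
# param_dist may carry alpha_fixed / beta_fixed overrides (used to force
# chance responders or fast learners in tests and demonstrations).
simulate_session <- function(participant_id, group, session, cfg, param_dist,
                             invalid_rate) {
  n_learnable <- cfg$n_stimuli %/% 2L
  draw_alphas <- function(stim_ids) {
    k <- length(stim_ids)
    a <- if (!is.null(param_dist$alpha_fixed))
      matrix(param_dist$alpha_fixed, k, 2)
    else matrix(stats::rbeta(2 * k, param_dist$alpha_shape1,
                             param_dist$alpha_shape2), k, 2)
    data.frame(participant_id = participant_id, group = group,
               session = session, stimulus_id = stim_ids,
               alpha_neg = a[, 1], alpha_pos = a[, 2],
               stringsAsFactors = FALSE)
  }
  beta <- if (!is.null(param_dist$beta_fixed)) param_dist$beta_fixed
  else min(stats::rgamma(1, shape = param_dist$beta_shape,
                         scale = param_dist$beta_scale), 50)

  agent <- draw_alphas(seq_len(cfg$n_stimuli))
  correct_side <- stats::setNames(
    sample(c("left", "right"), n_learnable, replace = TRUE),
    seq_len(n_learnable))
  Q <- new.env(parent = emptyenv())
  qval <- function(s) {
    key <- as.character(s)
    if (is.null(Q[[key]])) Q[[key]] <- c(left = 0.5, right = 0.5)
    Q[[key]]
  }

  stim_set <- 1L
  offset <- 0L
  trial_rows <- list()
  block_acc <- numeric(0)
  b <- 0L
  n_blocks_total <- cfg$n_blocks
  trial_counter <- 0L

  while (b < n_blocks_total) {
    b <- b + 1L
    stim_order <- sample(rep(seq_len(cfg$n_stimuli),
                             cfg$trials_per_block / cfg$n_stimuli))
    nt <- length(stim_order)
    v_response <- character(nt); v_rt <- numeric(nt)
    v_presses <- integer(nt); v_feedback <- rep(NA_character_, nt)
    v_correct <- rep(NA, nt); v_fix <- numeric(nt)
    for (k in seq_len(nt)) {
      s_local <- stim_order[k]
      s <- s_local + offset
      learnable <- s_local <= n_learnable
      q <- qval(s)
      p_right <- stats::plogis(beta * (q[["right"]] - q[["left"]]))
      response <- if (stats::runif(1) < p_right) "right" else "left"
      rt <- stats::rlnorm(1, log(700), 0.35)
      rt <- min(max(rt, cfg$rt_min_ms + 1), cfg$rt_max_ms - 1)
      n_presses <- 1L
      if (stats::runif(1) < invalid_rate) {
        kind <- sample(c("fast", "slow", "multi", "none"), 1)
        if (kind == "fast") rt <- stats::runif(1, 0, cfg$rt_min_ms - 1e-9)
        if (kind == "slow") rt <- stats::runif(1, cfg$rt_max_ms + 1,
                                               cfg$rt_max_ms + 500)
        if (kind == "multi") n_presses <- 2L
        if (kind == "none") { response <- "none"; rt <- NA_real_ }
      }
      valid <- validate_trial(rt, n_presses, response, cfg)
      if (response != "none") {
        v_feedback[k] <- draw_feedback(
          if (learnable) "learnable" else "unlearnable", response,
          if (learnable) correct_side[[as.character(s_local)]] else "left",
          cfg)
        r <- as.integer(v_feedback[k] == "positive")
        a_row <- agent[agent$stimulus_id == s, , drop = FALSE]
        alpha <- if (r == 1L) a_row$alpha_pos else a_row$alpha_neg
        qq <- qval(s)
        qq[[response]] <- qq[[response]] + alpha * (r - qq[[response]])
        Q[[as.character(s)]] <- qq
      }
      if (learnable && valid && response != "none")
        v_correct[k] <- response == correct_side[[as.character(s_local)]]
      v_response[k] <- response
      v_rt[k] <- rt
      v_presses[k] <- n_presses
      v_fix[k] <- stats::runif(1, cfg$fixation_range_ms[1],
                               cfg$fixation_range_ms[2])
    }
    block <- data.frame(
      participant_id = participant_id, group = group, session = session,
      block = b, trial_index = trial_counter + seq_len(nt) - 1L,
      stimulus_id = stim_order + offset,
      learnability = ifelse(stim_order <= n_learnable, "learnable",
                            "unlearnable"),
      stimulus_set = stim_set, response = v_response, rt_ms = v_rt,
      n_presses = v_presses,
      valid = validate_trial(v_rt, v_presses, v_response, cfg),
      correct = v_correct, feedback_valence = v_feedback,
      fixation_ms = v_fix, feedback_delay_ms = cfg$feedback_delay_ms,
      stringsAsFactors = FALSE)
    trial_counter <- trial_counter + nt
    trial_rows[[length(trial_rows) + 1L]] <- block

    use <- block$learnability == "learnable" & block$valid
    block_acc <- c(block_acc,
                   if (any(use)) mean(block$correct[use]) else NA_real_)
    action <- apply_learning_criterion(block_acc, cfg)
    if (action == "switch_stimulus_set" && stim_set == 1L) {
      stim_set <- 2L
      offset <- cfg$n_stimuli
      new_ids <- seq_len(cfg$n_stimuli) + offset
      agent <- rbind(agent, draw_alphas(new_ids))
      correct_side <- stats::setNames(
        sample(c("left", "right"), n_learnable, replace = TRUE),
        seq_len(n_learnable))
    } else if (action == "add_ninth_block" && n_blocks_total == cfg$n_blocks) {
      n_blocks_total <- cfg$n_blocks + 1L
    }
  }
  events <- do.call(rbind, trial_rows)
  agent$beta <- beta
  list(events = events, agent = agent)
}

#' Per-trial prediction errors from the true generative parameters
#'
#' Replays each participant-session's valid, responded trials through
#' [compute_trial_pes()] with the agent's true parameters and joins
#' `q_chosen`, `delta` and `upe` back onto the events table (`NA` for
#' trials that were excluded or unanswered).
#'
#' @param events,agents Output of [simulate_cohort()].
#' @param upe_center Passed to [compute_trial_pes()].
#' @return The events data.frame with `q_chosen`, `delta`, `upe` columns.
#' @export
true_trial_pes <- function(events, agents,
                           upe_center = "abs_minus_half") {
  events$q_chosen <- NA_real_
  events$delta <- NA_real_
  events$upe <- NA_real_
  key <- interaction(events$participant_id, events$session, drop = TRUE)
  for (lev in levels(key)) {
    rows <- which(key == lev & events$valid &
                    !is.na(events$feedback_valence))
    if (!length(rows)) next
    tr <- events[rows, , drop = FALSE]
    ag <- agents[agents$participant_id == tr$participant_id[1] &
                   agents$session == tr$session[1], , drop = FALSE]
    seen <- sort(unique(tr$stimulus_id))
    ag <- ag[match(seen, ag$stimulus_id), , drop = FALSE]
    params <- agent_params(
      alpha = matrix(c(ag$alpha_neg, ag$alpha_pos), ncol = 2,
                     dimnames = list(seen, c("neg", "pos"))),
      beta = ag$beta[1])
    pes <- compute_trial_pes(tr, params, upe_center = upe_center)
    events$q_chosen[rows] <- pes$q_chosen
    events$delta[rows] <- pes$delta
    events$upe[rows] <- pes$upe
  }
  events
}

#' Simulate single-trial ERP amplitudes from a planted linear model
#'
#' For each outcome (FRN, P3a, P3b) the amplitude is the design linear
#' predictor under the coded terms of [effect_spec()], plus a
#' by-participant random intercept and Gaussian residual noise, drawn
#' independently per outcome. Rows without a defined unsigned PE (invalid
#' or unanswered trials) receive no amplitude.
#'
#' @param events_pe Events joined to PEs ([true_trial_pes()] output).
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#' @return Data.frame: the scored trials (valid with feedback) with coded
#'   design columns and `frn_amplitude`, `p3a_amplitude`, `p3b_amplitude`.
#' @export
simulate_erp_amplitudes <- function(events_pe, effects = effect_spec(),
                                    seed = 1L) {
  scored <- events_pe[events_pe$valid & !is.na(events_pe$upe), , drop = FALSE]
  design <- code_predictors(scored)
  outcome_col <- c(frn = "frn_amplitude", p3a = "p3a_amplitude",
                   p3b = "p3b_amplitude")
  participants <- unique(design$participant_id)

  with_seed(seed, {
    for (oc in names(outcome_col)) {
      coefs <- effects$coefficients[[oc]]
      mu <- linear_predictor(design, coefs)
      ranef <- stats::setNames(
        stats::rnorm(length(participants), 0,
                     effects$random_intercept_sd[[oc]]),
        participants)
      noise <- stats::rnorm(nrow(design), 0, effects$residual_sd[[oc]])
      design[[outcome_col[[oc]]]] <-
        mu + ranef[design$participant_id] + noise
    }
    design
  })
}

# Evaluate sum(coef * product of coded columns named in the term).
linear_predictor <- function(design, coefs) {
  mu <- rep(0, nrow(design))
  for (term in names(coefs)) {
    if (term == "(Intercept)") { mu <- mu + coefs[[term]]; next }
    vars <- strsplit(term, ":", fixed = TRUE)[[1]]
    missing_vars <- setdiff(vars, names(design))
    if (length(missing_vars))
      stop("simulate_erp_amplitudes: term '", term,
           "' references unknown column(s): ",
           paste(missing_vars, collapse = ", "), call. = FALSE)
    mu <- mu + coefs[[term]] * Reduce(`*`, design[vars])
  }
  mu
}

#' Embed planted single-trial amplitudes into continuous two-channel EEG
#'
#' Builds one continuous frontocentral + centroparietal (FCz/Pz-role)
#' signal per participant-session: each trial contributes an FRN dip and P3
#' bump scaled so that segmenting, baselining and scoring the resulting
#' epochs recovers the planted amplitudes (exactly so at `noise_sd = 0`),
#' with the condition-average FRN peak at the planted center. Optionally
#' injects large spikes into a random subset of trials to plant artifact
#' violations.
#'
#' @param erp_table Output of [simulate_erp_amplitudes()] (needs
#'   `participant_id`, `session`, `trial_index`, the three amplitudes, and
#'   the design factors used downstream).
#' @param waveform A [waveform_spec()].
#' @param seed Integer seed (noise and spike placement).
#' @return List of records, one per participant-session: `participant_id`,
#'   `session`, `continuous` (2 x time matrix, rows `FCz`, `Pz`),
#'   `onsets_ms`, `trial_keys` (rows of `erp_table`), `spiked` (logical
#'   per trial).
#' @export
simulate_continuous_eeg <- function(erp_table, waveform = waveform_spec(),
                                    seed = 1L) {
  rate <- waveform$sampling_rate
  step <- 1000 / rate
  epoch_window <- c(-200, 600)
  n_ep <- as.integer(round(diff(epoch_window) / step))
  times <- seq(epoch_window[1], epoch_window[2] - step, by = step)

  # FRN shapes on the +/- half-width support around the center
  frn_sel <- times >= waveform$frn_center - waveform$frn_halfwidth &
    times <= waveform$frn_center + waveform$frn_halfwidth
  phi <- 0.5 * (1 + cos(pi * (times[frn_sel] - waveform$frn_center) /
                          waveform$frn_halfwidth))
  m1 <- mean(phi)
  m2 <- mean(phi^2)
  u_frn <- phi / m1                        # windowed mean 1
  anchor <- -(phi^2 - (m2 / m1) * phi)     # windowed mean 0, dip at center

  p3_sel <- times >= waveform$p3_window[1] & times <= waveform$p3_window[2]
  p3c <- mean(waveform$p3_window)
  p3h <- diff(waveform$p3_window) / 2
  psi <- 0.5 * (1 + cos(pi * (times[p3_sel] - p3c) / p3h))
  u_p3 <- psi / mean(psi)

  a_max <- max(abs(erp_table$frn_amplitude), 0, na.rm = TRUE)
  D <- max(waveform$anchor_depth, 1.6 * a_max / m1)

  key <- interaction(erp_table$participant_id, erp_table$session,
                     drop = TRUE)
  with_seed(seed, {
    lapply(levels(key), function(lev) {
      rows <- which(key == lev)
      tab <- erp_table[rows, , drop = FALSE]
      tab <- tab[order(tab$trial_index), , drop = FALSE]
      n_tr <- nrow(tab)
      delay <- if (tab$session[1] == "delayed") 6500 else 500
      iti <- if (is.null(waveform$iti_ms)) delay + 2500 else waveform$iti_ms
      if (iti < diff(epoch_window))
        stop("simulate_continuous_eeg: inter-trial interval shorter than ",
             "the epoch; epochs would overlap", call. = FALSE)
      onsets <- 400 + iti * (seq_len(n_tr) - 1L)
      n_total <- as.integer(round((onsets[n_tr] + 800) / step)) + 1L
      sig <- matrix(stats::rnorm(2L * n_total, 0, waveform$noise_sd),
                    nrow = 2, dimnames = list(c("FCz", "Pz"), NULL))
      spiked <- stats::runif(n_tr) < waveform$spike_rate
      for (j in seq_len(n_tr)) {
        i0 <- as.integer(round((onsets[j] + epoch_window[1]) / step)) + 1L
        idx <- i0:(i0 + n_ep - 1L)
        ep_fcz <- numeric(n_ep)
        a <- tab$frn_amplitude[j]
        ep_fcz[frn_sel] <- a * u_frn + D * anchor
        ep_fcz[p3_sel] <- ep_fcz[p3_sel] + tab$p3a_amplitude[j] * u_p3
        ep_pz <- numeric(n_ep)
        ep_pz[p3_sel] <- tab$p3b_amplitude[j] * u_p3
        if (spiked[j]) {
          at <- sample(which(times > 0), 1)
          ep_fcz[at] <- ep_fcz[at] + waveform$spike_uv
        }
        sig["FCz", idx] <- sig["FCz", idx] + ep_fcz
        sig["Pz", idx] <- sig["Pz", idx] + ep_pz
      }
      list(participant_id = tab$participant_id[1], session = tab$session[1],
           continuous = sig, onsets_ms = onsets, trial_keys = tab,
           spiked = spiked)
    })
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [simulate_cohort()], [true_trial_pes()] and
#' [simulate_erp_amplitudes()] (and optionally [simulate_continuous_eeg()])
#' under one seed, optionally writing the events TSV, amplitude TSV and
#' epoch files into a directory ready for the analysis scripts.
#'
#' @param n_patients,n_controls Group sizes.
#' @param config A [task_config()].
#' @param effects An [effect_spec()].
#' @param waveform A [waveform_spec()], or `NULL` to skip continuous EEG.
#' @param seed Integer seed.
#' @param dir Output directory, or `NULL` to return objects only.
#' @return List with `events`, `agents`, `erp` (single-trial amplitude
#'   table) and, when requested, `eeg` (continuous records).
#' @export
simulate_study <- function(n_patients = 21, n_controls = 25,
                           config = task_config(), effects = effect_spec(),
                           waveform = NULL, seed = 1L, dir = NULL) {
  cohort <- simulate_cohort(n_patients, n_controls, config, seed = seed)
  events <- true_trial_pes(cohort$events, cohort$agents)
  erp <- simulate_erp_amplitudes(events, effects, seed = seed + 1L)
  eeg <- if (!is.null(waveform))
    simulate_continuous_eeg(erp, waveform, seed = seed + 2L)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_events(events, file.path(dir, "events.tsv"))
    utils::write.table(erp, file.path(dir, "single_trial_erp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out <- list(events = events, agents = cohort$agents, erp = erp)
  if (!is.null(waveform)) out$eeg <- eeg
  out
}
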