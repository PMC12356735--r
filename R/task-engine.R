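#' Configuration of the probabilistic feedback-based learning task
#'
#' The task presents four abstract stimuli per block: two "learnable" stimuli
#' for which one response side yields positive feedback 90% of the time (10%
#' for the other side), and two distractors that deliver random 50/50 feedback
#' independent of the response. A session comprises eight blocks of 40 trials
#' (320 trials); a ninth block is appended when the learning criterion of 65%
#' correct is never exceeded, and a fresh stimulus set is introduced when it
#' is exceeded within the first two blocks. Feedback follows the response
#' after 500 ms (immediate session) or 6500 ms (delayed session).
#'
#' @param n_blocks Number of blocks per session.
#' @param trials_per_block Trials per block; must be divisible by `n_stimuli`.
#' @param n_stimuli Number of stimuli (half learnable, half distractor).
#' @param p_reward_correct Probability of positive feedback when the correct
#'   side is chosen for a learnable stimulus. The incorrect side receives
#'   positive feedback with probability `1 - p_reward_correct`.
#' @param p_reward_distractor Probability of positive feedback for a
#'   distractor, regardless of response.
#' @param learning_criterion Proportion correct that must be strictly exceeded.
#' @param criterion_block Last block at which exceeding the criterion triggers
#'   a stimulus-set switch.
#' @param feedback_delay_ms Response-to-feedback delay in ms: 500 (immediate)
#'   or 6500 (delayed).
#' @param rt_min_ms,rt_max_ms Valid response-time window in ms.
#' @param fixation_range_ms Uniform jitter bounds for the fixation cross, ms.
#' @param reward_pos_label,reward_neg_label Feedback display labels.
#'
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_blocks = 8L,
                        trials_per_block = 40L,
                        n_stimuli = 4L,
                        p_reward_correct = 0.90,
                        p_reward_distractor = 0.50,
                        learning_criterion = 0.65,
                        criterion_block = 2L,
                        feedback_delay_ms = 500,
                        rt_min_ms = 100,
                        rt_max_ms = 3000,
                        fixation_range_ms = c(500, 1500),
                        reward_pos_label = "+20ct",
                        reward_neg_label = "−10ct") {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    n_stimuli = as.integer(n_stimuli),
    p_reward_correct = p_reward_correct,
    p_reward_distractor = p_reward_distractor,
    learning_criterion = learning_criterion,
    criterion_block = as.integer(criterion_block),
    feedback_delay_ms = feedback_delay_ms,
    rt_min_ms = rt_min_ms,
    rt_max_ms = rt_max_ms,
    fixation_range_ms = fixation_range_ms,
    reward_pos_label = reward_pos_label,
    reward_neg_label = reward_neg_label
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  probs <- c(cfg$p_reward_correct, cfg$p_reward_distractor,
             cfg$learning_criterion)
  if (any(probs < 0 | probs > 1))
    stop("task_config: probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$n_blocks < 1L || cfg$trials_per_block < 1L || cfg$n_stimuli < 1L)
    stop("task_config: counts must be positive", call. = FALSE)
  if (cfg$trials_per_block %% cfg$n_stimuli != 0L)
    stop("task_config: trials_per_block must be divisible by n_stimuli ",
         "(equal stimulus presentation)", call. = FALSE)
  if (cfg$n_stimuli %% 2L != 0L)
    stop("task_config: n_stimuli must be even (learnable/distractor halves)",
         call. = FALSE)
  if (!cfg$feedback_delay_ms %in% c(500, 6500))
    stop("task_config: feedback_delay_ms must be 500 or 6500", call. = FALSE)
  if (cfg$rt_min_ms >= cfg$rt_max_ms)
    stop("task_config: rt_min_ms must be below rt_max_ms", call. = FALSE)
  invisible(cfg)
}

#' Read a task configuration from a YAML file
#'
#' Keys mirror the arguments of [task_config()]; missing keys fall back to
#' the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `task_config`.
#' @export
read_task_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(task_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("read_task_config: unknown keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(task_config, vals)
}

#' Generate a pseudo-random stimulus presentation schedule
#'
#' Each block presents every stimulus equally often
#' (`trials_per_block / n_stimuli` times) in randomized order, and each trial
#' carries a fixation duration drawn uniformly from `fixation_range_ms`.
#' Stimuli `1..n_stimuli/2` are learnable, the rest are distractors.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is reproducible given
#'   `(config, seed)`.
#' @return A data.frame of class `task_schedule` with columns `block`,
#'   `trial_index` (0-based within session), `stimulus_id`, `learnability`,
#'   `fixation_ms`.
#' @export
generate_schedule <- function(config = task_config(), seed = 1L) {
  validate_task_config(config)
  reps <- config$trials_per_block / config$n_stimuli
  n_learnable <- config$n_stimuli %/% 2L
  out <- with_seed(seed, {
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      stim <- sample(rep(seq_len(config$n_stimuli), reps))
      data.frame(block = b, stimulus_id = stim)
    })
    sched <- do.call(rbind, blocks)
    sched$fixation_ms <- stats::runif(nrow(sched),
                                      config$fixation_range_ms[1],
                                      config$fixation_range_ms[2])
    sched
  })
  out$trial_index <- seq_len(nrow(out)) - 1L
  out$learnability <- ifelse(out$stimulus_id <= n_learnable,
                             "learnable", "unlearnable")
  out <- out[, c("block", "trial_index", "stimulus_id", "learnability",
                 "fixation_ms")]
  class(out) <- c("task_schedule", "data.frame")
  out
}

#' Draw feedback valence for one trial
#'
#' Distractor stimuli return positive feedback with probability
#' `p_reward_distractor` regardless of the response. Learnable stimuli return
#' positive feedback with probability `p_reward_correct` when the chosen side
#' matches the stimulus's correct side, and `1 - p_reward_correct` otherwise.
#'
#' Consumes one uniform draw from R's global RNG stream.
#'
#' @param learnability `"learnable"` or `"unlearnable"`.
#' @param response `"left"` or `"right"`.
#' @param correct_side The stimulus's rewarded side (ignored for distractors).
#' @param config A [task_config()].
#' @return `"positive"` or `"negative"`.
#' @export
draw_feedback <- function(learnability, response, correct_side = "left",
                          config = task_config()) {
  stopifnot(response %in% c("left", "right"))
  p_pos <- if (identical(learnability, "unlearnable")) {
    config$p_reward_distractor
  } else if (identical(response, correct_side)) {
    config$p_reward_correct
  } else {
    1 - config$p_reward_correct
  }
  if (stats::runif(1) < p_pos) "positive" else "negative"
}

#' Apply the learning-criterion rule to a sequence of block accuracies
#'
#' Accuracy (proportion correct among valid learnable trials) strictly above
#' `learning_criterion` within the first `criterion_block` blocks triggers a
#' stimulus-set switch; never exceeding it through the final scheduled block
#' appends a ninth block; otherwise the session simply continues.
#'
#' @param block_accuracies Numeric vector of per-block proportions in the
#'   order the blocks were run (may be shorter than `n_blocks` mid-session).
#' @param config A [task_config()].
#' @return `"switch_stimulus_set"`, `"add_ninth_block"`, or `"continue"`.
#' @export
apply_learning_criterion <- function(block_accuracies, config = task_config()) {
  if (length(block_accuracies) == 0L)
    stop("apply_learning_criterion: empty accuracy sequence", call. = FALSE)
  n <- length(block_accuracies)
  early <- block_accuracies[seq_len(min(n, config$criterion_block))]
  if (any(early > config$learning_criterion, na.rm = TRUE))
    return("switch_stimulus_set")
  if (n >= config$n_blocks &&
      !any(block_accuracies > config$learning_criterion, na.rm = TRUE))
    return("add_ninth_block")
  "continue"
}

#' Trial validity per the task's exclusion rules
#'
#' A trial is invalid when the response came within 100 ms of stimulus onset,
#' later than 3000 ms, with multiple presses, or not at all.
#'
#' @param rt_ms Response time in ms (`NA` when no response was given).
#' @param n_presses Number of button presses.
#' @param response `"left"`, `"right"`, or `"none"`.
#' @param config A [task_config()] supplying the RT window.
#' @return Logical flag (vectorized).
#' @export
validate_trial <- function(rt_ms, n_presses = 1L, response = "left",
                           config = task_config()) {
  no_resp <- is.na(rt_ms) | response == "none"
  !(no_resp | rt_ms < config$rt_min_ms | rt_ms > config$rt_max_ms |
      n_presses > 1L)
}

#' Write / read a trial-level events table
#'
#' Tab-separated UTF-8 with missing values written as `"n/a"`, one row per
#' trial with the fields produced by [simulate_cohort()].
#'
#' @param events A data.frame of trial records.
#' @param path Output path.
#' @return `path`, invisibly (`write_events`); the events data.frame
#'   (`read_events`).
#' @export
write_events <- function(events, path) {
  out <- events
  for (nm in names(out)) {
    v <- out[[nm]]
    if (is.numeric(v)) v <- format(v, digits = 15, trim = TRUE,
                                   scientific = FALSE)
    v[is.na(out[[nm]])] <- "n/a"
    out[[nm]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  for (nm in c("valid", "correct"))
    if (nm %in% names(ev)) ev[[nm]] <- as.logical(ev[[nm]])
  ev
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
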