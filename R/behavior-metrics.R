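#' Block-wise accuracy on valid learnable trials
#'
#' Accuracy is the percentage of correct responses among valid learnable
#' trials per block, corrected for misses, multiple responses and too-fast
#' responding (those trials leave the denominator entirely). Distractor
#' trials never enter. Blocks without any valid learnable trial yield `NA`.
#'
#' @param trials Data.frame of trial records with columns `participant_id`,
#'   `session`, `block`, `learnability`, `valid`, `correct`.
#' @return Data.frame with `participant_id`, `session`, `block`,
#'   `n_valid_learnable`, `accuracy` (percent).
#' @export
block_accuracy <- function(trials) {
  grp <- trials[, c("participant_id", "session", "block")]
  key <- interaction(grp, drop = TRUE, lex.order = TRUE)
  use <- trials$learnability == "learnable" & trials$valid
  out <- do.call(rbind, lapply(levels(key), function(lev) {
    rows <- key == lev
    head_row <- grp[which(rows)[1], , drop = FALSE]
    n <- sum(rows & use)
    head_row$n_valid_learnable <- n
    head_row$accuracy <- if (n == 0L) NA_real_ else
      100 * sum(trials$correct[rows & use]) / n
    head_row
  }))
  rownames(out) <- NULL
  out
}

#' Single-trial choice switching
#'
#' For each valid trial, `switch` records whether the response in the next
#' valid trial with the same stimulus (within the same participant-session
#' and stimulus set) differed from the current response. Invalid trials are
#' skipped when searching forward because they carry no comparable response;
#' the final valid occurrence of each stimulus has no successor and yields
#' `NA`. Response type (correct/false) is carried along for modelling and is
#' `NA` on distractor trials, where correctness is undefined.
#'
#' @param trials Data.frame of trial records ordered by presentation, with
#'   columns `participant_id`, `session`, `block`, `trial_index`,
#'   `stimulus_id`, `stimulus_set`, `learnability`, `response`, `valid`,
#'   `correct`, `feedback_valence`.
#' @return Data.frame of switch records for valid trials: join keys plus
#'   `switch` (0/1 or `NA`), `feedback_valence`, `response_type`
#'   (`"correct"`/`"false"`/`NA`), `learnability`, `block`.
#' @export
choice_switching <- function(trials) {
  ses_key <- interaction(trials$participant_id, trials$session,
                         trials$stimulus_set, trials$stimulus_id, drop = TRUE)
  trials$.row <- seq_len(nrow(trials))
  valid_rows <- trials[trials$valid, , drop = FALSE]
  ord <- order(valid_rows$.row)
  valid_rows <- valid_rows[ord, , drop = FALSE]

  switch_flag <- rep(NA_integer_, nrow(valid_rows))
  key <- ses_key[valid_rows$.row]
  for (lev in unique(key)) {
    idx <- which(key == lev)
    if (length(idx) > 1L) {
      resp <- valid_rows$response[idx]
      switch_flag[idx[-length(idx)]] <-
        as.integer(resp[-length(resp)] != resp[-1])
    }
  }

  data.frame(
    participant_id = valid_rows$participant_id,
    session = valid_rows$session,
    block = valid_rows$block,
    trial_index = valid_rows$trial_index,
    stimulus_id = valid_rows$stimulus_id,
    learnability = valid_rows$learnability,
    switch = switch_flag,
    feedback_valence = valid_rows$feedback_valence,
    response_type = ifelse(valid_rows$learnability == "learnable",
                           ifelse(valid_rows$correct, "correct", "false"),
                           NA_character_),
    stringsAsFactors = FALSE
  )
}
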