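# Independent oracles, written before the implementations they check and
# kept deliberately different in style: explicit per-trial loops, explicit
# exponentials, no shared code with the package internals.

# Step-by-step replay of the RW/softmax likelihood for one trial sequence.
# trials: data.frame with stimulus_id, response ("left"/"right"),
# feedback_valence ("positive"/"negative"). alpha: matrix with rownames =
# stimulus ids and columns neg, pos. Returns the penalized negative
# log-likelihood plus per-trial quantities.
oracle_replay <- function(trials, alpha, beta, q_init = 0.5,
                          gamma_shape = 2, gamma_scale = 3) {
  Q <- list()
  nll <- 0
  p_all <- delta_all <- q_all <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    sid <- as.character(trials$stimulus_id[i])
    if (is.null(Q[[sid]])) Q[[sid]] <- c(left = q_init, right = q_init)
    ch <- trials$response[i]
    other <- if (ch == "left") "right" else "left"
    num <- exp(beta * Q[[sid]][[ch]])
    den <- num + exp(beta * Q[[sid]][[other]])
    p <- num / den
    nll <- nll - log(p)
    r <- if (trials$feedback_valence[i] == "positive") 1 else 0
    a <- alpha[sid, if (r == 1) "pos" else "neg"]
    d <- r - Q[[sid]][[ch]]
    q_all[i] <- Q[[sid]][[ch]]
    p_all[i] <- p
    delta_all[i] <- d
    Q[[sid]][[ch]] <- Q[[sid]][[ch]] + a * d
  }
  list(pnll = nll - log(dgamma(beta, shape = gamma_shape,
                               scale = gamma_scale)),
       nll = nll, p = p_all, delta = delta_all, q_chosen = q_all)
}

# Brute-force pairing oracle for choice switching: for each valid trial,
# scan forward for the next valid trial with the same stimulus (same
# participant, session and stimulus set) and compare response sides.
oracle_switch <- function(trials) {
  out <- rep(NA_integer_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    if (!trials$valid[i]) next
    for (j in seq_len(nrow(trials))) {
      if (j <= i) next
      same <- trials$participant_id[j] == trials$participant_id[i] &&
        trials$session[j] == trials$session[i] &&
        trials$stimulus_set[j] == trials$stimulus_set[i] &&
        trials$stimulus_id[j] == trials$stimulus_id[i]
      if (same && trials$valid[j]) {
        out[i] <- as.integer(trials$response[j] != trials$response[i])
        break
      }
    }
  }
  out
}

# Minimal trial-table constructor for toy sequences.
toy_trials <- function(stimulus, response, feedback,
                       participant = "p1", session = "immediate") {
  data.frame(participant_id = participant, session = session,
             block = 1L, trial_index = seq_along(stimulus) - 1L,
             stimulus_id = stimulus, stimulus_set = 1L,
             learnability = ifelse(stimulus <= 2, "learnable", "unlearnable"),
             response = response, rt_ms = 800, n_presses = 1L, valid = TRUE,
             correct = NA, feedback_valence = feedback,
             stringsAsFactors = FALSE)
}
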