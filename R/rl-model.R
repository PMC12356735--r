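#' Rescorla-Wagner agent parameters
#'
#' Learning rates are specific to each stimulus and feedback valence (so a
#' four-stimulus session carries eight alphas) and a single softmax inverse
#' temperature is shared across stimuli. Action values start at `q_init` for
#' every (stimulus, action) pair; with rewards coded 1 (positive feedback) /
#' 0 (negative), `q_init = 0.5` makes the first prediction error for any
#' stimulus have magnitude 0.5 and leaves the first choice unbiased.
#'
#' @param alpha Numeric matrix `n_stimuli x 2` of learning rates in \[0, 1\];
#'   column `"neg"` applies after negative feedback, column `"pos"` after
#'   positive feedback. Rows are named by stimulus id.
#' @param beta Inverse temperature in \[0, 50\].
#' @param q_init Initial action value (default 0.5).
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(alpha, beta, q_init = 0.5) {
  alpha <- as.matrix(alpha)
  if (ncol(alpha) != 2L)
    stop("agent_params: alpha must have two columns (neg, pos)", call. = FALSE)
  colnames(alpha) <- c("neg", "pos")
  if (any(alpha < 0 | alpha > 1))
    stop("agent_params: learning rates must lie in [0, 1]", call. = FALSE)
  if (beta < 0 || beta > 50)
    stop("agent_params: beta must lie in [0, 50]", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, q_init = q_init),
            class = "agent_params")
}

#' Fitting configuration for the penalized RW/softmax model
#'
#' @param gamma_shape,gamma_scale Parameters of the gamma prior on beta whose
#'   log-density is added to the log-likelihood (MAP estimation; defaults
#'   shape 2, scale 3, discouraging implausibly large inverse temperatures).
#' @param n_starts Number of multi-start initial points, drawn uniformly
#'   within the parameter bounds.
#' @param tol Relative convergence tolerance passed to the optimizer.
#' @param seed Integer seed controlling the multi-start draws.
#' @param upe_center Direction of the unsigned-PE centering transform:
#'   `"abs_minus_half"` (default; uPE = |delta| - 0.5, increasing with
#'   surprise) or `"half_minus_abs"` (uPE = 0.5 - |delta|).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(gamma_shape = 2, gamma_scale = 3, n_starts = 20L,
                       tol = 1e-8, seed = 1L,
                       upe_center = c("abs_minus_half", "half_minus_abs")) {
  if (gamma_shape <= 0 || gamma_scale <= 0)
    stop("fit_config: gamma parameters must be positive", call. = FALSE)
  structure(list(gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 n_starts = as.integer(n_starts), tol = tol,
                 seed = as.integer(seed),
                 upe_center = match.arg(upe_center)),
            class = "fit_config")
}

#' One Rescorla-Wagner update
#'
#' `delta = reward - q`; `q_next = q + alpha * delta`.
#'
#' @param q Current action value.
#' @param reward Coded reward (1 positive, 0 negative).
#' @param alpha Learning rate in \[0, 1\].
#' @return A list with `q_next` and `delta`.
#' @export
rw_update <- function(q, reward, alpha) {
  if (any(alpha < 0 | alpha > 1))
    stop("rw_update: alpha must lie in [0, 1]", call. = FALSE)
  delta <- reward - q
  list(q_next = q + alpha * delta, delta = delta)
}

#' Softmax choice probability for the chosen action
#'
#' `p = exp(beta q_chosen) / (exp(beta q_chosen) + exp(beta q_other))`,
#' evaluated through the logistic of `beta * (q_chosen - q_other)` so that
#' large `beta` cannot overflow.
#'
#' @param q_chosen,q_other Action values.
#' @param beta Inverse temperature, >= 0.
#' @return Probability of the chosen action.
#' @export
softmax_prob <- function(q_chosen, q_other, beta) {
  stopifnot(beta >= 0)
  stats::plogis(beta * (q_chosen - q_other))
}

# Convert a participant-session trial table into replay arrays.
# Requires columns stimulus_id, response ("left"/"right"), feedback_valence.
replay_inputs <- function(trials) {
  if (nrow(trials) == 0L)
    stop("no trials to model", call. = FALSE)
  stim_ids <- sort(unique(trials$stimulus_id))
  list(
    stim = match(trials$stimulus_id, stim_ids) - 1L,
    choice = ifelse(trials$response == "right", 1L, 0L),
    reward = ifelse(trials$feedback_valence == "positive", 1L, 0L),
    stim_ids = stim_ids
  )
}

params_to_vec <- function(params) c(as.vector(params$alpha), params$beta)

# Align an alpha matrix to the stimuli present in a trial sequence; rows
# are matched by name so a sequence may use any subset of the fitted (or
# true) stimuli.
alpha_for_stimuli <- function(alpha, stim_ids) {
  ids <- as.character(stim_ids)
  rn <- rownames(alpha)
  if (is.null(rn)) {
    if (nrow(alpha) != length(ids))
      stop("alpha rows must cover the distinct stimuli in the trials",
           call. = FALSE)
    return(alpha)
  }
  if (!all(ids %in% rn))
    stop("alpha rows must cover the distinct stimuli in the trials",
         call. = FALSE)
  alpha[ids, , drop = FALSE]
}

vec_to_params <- function(par, stim_ids, q_init = 0.5) {
  K <- length(stim_ids)
  # guard against optimizer round-off a hair outside the box
  alpha <- matrix(pmin(pmax(par[seq_len(2 * K)], 0), 1), nrow = K,
                  dimnames = list(stim_ids, c("neg", "pos")))
  agent_params(alpha, beta = min(max(par[2 * K + 1], 0), 50), q_init = q_init)
}

#' Penalized negative log-likelihood of a trial sequence
#'
#' Replays the Rescorla-Wagner learner through the (valid) trials of one
#' participant-session, accumulating `-log p(choice)` under the softmax rule,
#' and subtracts the log gamma density of beta:
#' `-sum_t log p(choice_t) - log GammaPDF(beta; shape, scale)`.
#'
#' @param params An [agent_params()].
#' @param trials Data.frame with columns `stimulus_id`, `response`,
#'   `feedback_valence`, ordered by presentation; valid trials only.
#' @param config A [fit_config()] supplying the gamma prior.
#' @return Scalar penalized negative log-likelihood.
#' @export
penalized_nll <- function(params, trials, config = fit_config()) {
  inp <- replay_inputs(trials)
  alpha <- alpha_for_stimuli(params$alpha, inp$stim_ids)
  rep <- rw_replay_cpp(inp$stim, inp$choice, inp$reward, alpha,
                       params$beta, params$q_init, FALSE)
  rep$nll - stats::dgamma(params$beta, shape = config$gamma_shape,
                          scale = config$gamma_scale, log = TRUE)
}

#' Fit the RW/softmax model for one participant-session
#'
#' Bounded multi-start local optimization (L-BFGS-B) of [penalized_nll()]:
#' `n_starts` initial points are drawn uniformly within the bounds
#' (alphas in \[0, 1\], beta in \[0, 50\]) under `config$seed`, the best
#' objective wins, and ties go to the earliest start. Per-trial trajectories
#' (action values, signed PE delta, centered unsigned PE, choice probability)
#' are regenerated from the fitted parameters.
#'
#' @param trials Valid trials of one participant-session (see
#'   [penalized_nll()]).
#' @param config A [fit_config()].
#' @param q_init Initial action value.
#' @return A list of class `fit_result`: `params`, `objective` (penalized),
#'   `nll` (unpenalized), `converged`, `n_starts_ok`, and `trajectories`
#'   (data.frame aligned to the input rows).
#' @export
fit_participant <- function(trials, config = fit_config(), q_init = 0.5) {
  inp <- replay_inputs(trials)
  K <- length(inp$stim_ids)
  npar <- 2L * K + 1L
  lower <- c(rep(0, 2 * K), 1e-6)
  upper <- c(rep(1, 2 * K), 50)

  objfun <- function(par) {
    rep <- rw_replay_cpp(inp$stim, inp$choice, inp$reward,
                         matrix(par[seq_len(2 * K)], nrow = K),
                         par[npar], q_init, FALSE)
    rep$nll - stats::dgamma(par[npar], shape = config$gamma_shape,
                            scale = config$gamma_scale, log = TRUE)
  }

  starts <- with_seed(config$seed, {
    matrix(stats::runif(config$n_starts * npar, rep(lower, each = config$n_starts),
                        rep(upper, each = config$n_starts)),
           nrow = config$n_starts)
  })

  best <- NULL
  n_ok <- 0L
  for (i in seq_len(config$n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], objfun, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = config$tol / .Machine$double.eps,
                                  maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, objective = NA_real_, nll = NA_real_,
                          converged = FALSE, n_starts_ok = 0L,
                          trajectories = NULL),
                     class = "fit_result"))
  }

  params <- vec_to_params(best$par, inp$stim_ids, q_init)
  traj <- compute_trial_pes(trials, params, upe_center = config$upe_center)
  structure(list(params = params,
                 objective = best$value,
                 nll = best$value + stats::dgamma(params$beta,
                                                  shape = config$gamma_shape,
                                                  scale = config$gamma_scale,
                                                  log = TRUE),
                 converged = n_ok > 0L,
                 n_starts_ok = n_ok,
                 trajectories = traj),
            class = "fit_result")
}

#' Per-trial prediction-error regressors from fixed parameters
#'
#' Replays the learner with the given parameters and returns the signed PE
#' `delta = R - Q` together with the centered unsigned PE. With rewards coded
#' \{0, 1\} the signed PE lies in \[-1, 1\] and the centered unsigned PE in
#' \[-0.5, 0.5\].
#'
#' @param trials Valid trials of one participant-session.
#' @param params An [agent_params()] (true or fitted).
#' @param upe_center `"abs_minus_half"` (default, `|delta| - 0.5`) or
#'   `"half_minus_abs"` (`0.5 - |delta|`).
#' @return Data.frame with `q_chosen`, `q_unchosen`, `delta`, `upe`,
#'   `p_choice`, one row per input trial.
#' @export
compute_trial_pes <- function(trials, params,
                              upe_center = c("abs_minus_half",
                                             "half_minus_abs")) {
  upe_center <- match.arg(upe_center)
  inp <- replay_inputs(trials)
  alpha <- alpha_for_stimuli(params$alpha, inp$stim_ids)
  rep <- rw_replay_cpp(inp$stim, inp$choice, inp$reward, alpha,
                       params$beta, params$q_init, TRUE)
  upe <- abs(rep$delta) - 0.5
  if (upe_center == "half_minus_abs") upe <- -upe
  data.frame(q_chosen = rep$q_chosen, q_unchosen = rep$q_unchosen,
             delta = rep$delta, upe = upe, p_choice = rep$p_choice)
}

#' Serialize a fit result
#'
#' Writes parameters, objective and convergence information as JSON and the
#' per-trial trajectory table as TSV next to it (suffix `_trials.tsv`),
#' joinable to the events table on `trial_index`.
#'
#' @param fit A `fit_result`.
#' @param path Output path for the JSON file.
#' @param trial_index Optional trial indices for the trajectory rows.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path, trial_index = NULL) {
  meta <- list(alpha = fit$params$alpha, beta = fit$params$beta,
               q_init = fit$params$q_init, objective = fit$objective,
               nll = fit$nll, converged = fit$converged,
               n_starts_ok = fit$n_starts_ok)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  traj <- fit$trajectories
  if (!is.null(traj)) {
    traj$trial_index <- if (is.null(trial_index)) seq_len(nrow(traj)) - 1L
                        else trial_index
    utils::write.table(traj, sub("\\.json$", "_trials.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
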