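#' Simple coding of the design factors
#'
#' Applies the study's centered +/-0.5 coding so that every fixed main
#' effect is an average over the levels of the other factors: group
#' (+0.5 patient / -0.5 control), feedback timing (+0.5 delayed / -0.5
#' immediate), feedback valence (+0.5 positive / -0.5 negative),
#' learnability (+0.5 learnable / -0.5 unlearnable), response type (+0.5
#' correct / -0.5 false). Block (1..n) is standardized over the modeled rows
#' (`block_z`); the centered unsigned PE passes through unchanged.
#'
#' @param data Data.frame holding any of the columns `group`, `session`,
#'   `feedback_valence`, `learnability`, `response_type`, `block`, `upe`.
#'   `session` (`"immediate"`/`"delayed"`) is coded as `feedback_timing`.
#' @return The data.frame with numeric coded columns added (`group`,
#'   `feedback_timing`, `feedback_valence`, `learnability`, `response_type`
#'   replaced by their codes; `block_z` appended).
#' @export
code_predictors <- function(data) {
  code <- function(x, pos, neg, name) {
    if (is.numeric(x)) {
      if (!all(x %in% c(-0.5, 0.5) | is.na(x)))
        stop("code_predictors: numeric ", name,
             " must already be coded +/-0.5", call. = FALSE)
      return(x)
    }
    bad <- setdiff(unique(x[!is.na(x)]), c(pos, neg))
    if (length(bad))
      stop("code_predictors: unknown ", name, " level(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    ifelse(is.na(x), NA_real_, ifelse(x == pos, 0.5, -0.5))
  }
  if ("group" %in% names(data))
    data$group <- code(data$group, "patient", "control", "group")
  if ("session" %in% names(data))
    data$feedback_timing <- code(data$session, "delayed", "immediate",
                                 "session")
  if ("feedback_valence" %in% names(data))
    data$feedback_valence <- code(data$feedback_valence, "positive",
                                  "negative", "feedback_valence")
  if ("learnability" %in% names(data))
    data$learnability <- code(data$learnability, "learnable", "unlearnable",
                              "learnability")
  if ("response_type" %in% names(data))
    data$response_type <- code(data$response_type, "correct", "false",
                               "response_type")
  if ("block" %in% names(data))
    data$block_z <- as.vector(scale(data$block))
  data
}

#' Mixed-model specification
#'
#' @param fixed Fixed-effects formula (response on the left), e.g.
#'   `accuracy ~ group * feedback_timing * block_z`.
#' @param random One-sided formula for the by-participant random effects,
#'   e.g. `~ 1 + feedback_timing * block_z`.
#' @param group Name of the grouping variable (default `"participant_id"`).
#' @return A list of class `mlm_spec`.
#' @export
mlm_spec <- function(fixed, random = ~1, group = "participant_id") {
  structure(list(fixed = stats::as.formula(fixed),
                 random = stats::as.formula(random),
                 group = group),
            class = "mlm_spec")
}

#' The study's five mixed-model templates
#'
#' Accuracy, choice switching, and the three single-trial ERP outcomes (FRN,
#' P3a, P3b), each with its maximal by-participant random structure. All
#' predictors are assumed coded by [code_predictors()].
#'
#' @return Named list of [mlm_spec()] objects.
#' @export
mlm_templates <- function() {
  list(
    accuracy = mlm_spec(
      accuracy ~ group * feedback_timing * block_z,
      ~ 1 + feedback_timing * block_z),
    switching = mlm_spec(
      switch ~ group * feedback_timing * feedback_valence * response_type *
        block_z,
      ~ 1 + feedback_timing + feedback_valence + response_type +
        feedback_valence:response_type),
    frn = mlm_spec(
      frn_amplitude ~ group * feedback_timing * upe * feedback_valence *
        learnability,
      ~ 1 + feedback_timing * feedback_valence + learnability +
        feedback_valence:learnability + feedback_timing:learnability),
    p3a = mlm_spec(
      p3a_amplitude ~ group * feedback_timing * upe * feedback_valence *
        learnability,
      ~ 1 + feedback_timing + feedback_valence),
    p3b = mlm_spec(
      p3b_amplitude ~ group * feedback_timing * upe * feedback_valence *
        learnability,
      ~ 1 + feedback_timing + feedback_valence + upe + feedback_timing:upe)
  )
}

# Random-effect term labels ordered for stepwise deletion: interactions
# before main effects, higher order first, last-listed first within an order.
reduction_order <- function(random) {
  tt <- stats::terms(random)
  labels <- attr(tt, "term.labels")
  ord <- attr(tt, "order")
  if (!length(labels)) return(character(0))
  labels[order(-ord, -seq_along(labels))]
}

compose_formula <- function(fixed, random_terms, group, has_intercept = TRUE) {
  rhs <- paste(c(if (has_intercept) "1" else "0", random_terms),
               collapse = " + ")
  stats::as.formula(paste(deparse(fixed, width.cutoff = 500L), "+ (", rhs,
                          "|", group, ")"),
                    env = environment(fixed))
}

# Fit one candidate structure, trying the default optimizer then bobyqa.
# Returns list(model, ok, singular, messages).
try_structure <- function(formula, data, reml) {
  fit_once <- function(optimizer) {
    warns <- character(0)
    # evaluated arguments keep the stored call self-contained, so that
    # downstream refits (influence/update) do not chase local symbols
    m <- withCallingHandlers(
      tryCatch(
        do.call(lmerTest::lmer,
                list(formula = formula, data = data, REML = reml,
                     control = lme4::lmerControl(optimizer = optimizer))),
        error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(m, "error"))
      return(list(model = NULL, ok = FALSE, singular = FALSE,
                  messages = conditionMessage(m)))
    conv_fail <- any(grepl("converge", warns, ignore.case = TRUE))
    sing <- lme4::isSingular(m)
    list(model = m, ok = !conv_fail && !sing, singular = sing,
         messages = warns)
  }
  res <- fit_once("nloptwrap")
  if (!res$ok) {
    res2 <- fit_once("bobyqa")
    if (res2$ok || (is.null(res$model) && !is.null(res2$model))) res <- res2
  }
  res
}

#' Fit a linear mixed model with stepwise random-effect reduction
#'
#' Attempts the maximal random structure in `spec`; on a convergence failure
#' or singular fit (after retrying with the bobyqa optimizer) random terms
#' are deleted one at a time — interactions before main effects, higher
#' order first, last-listed first within an order — until a stable fit is
#' reached. The fixed-effects formula is never altered. The intercept-only
#' random structure is accepted as the terminal fallback even when singular
#' (flagged). Fixed-effect inference uses Satterthwaite approximate degrees
#' of freedom.
#'
#' @param data Coded design table (see [code_predictors()]).
#' @param spec An [mlm_spec()].
#' @param reml Use REML (default TRUE).
#' @return A list of class `mlm_result`: `model` (lmerModLmerTest),
#'   `coefficients` (estimate, SE, df, t, p per fixed effect), `random`
#'   (realized random-effect formula string), `singular`, `converged`,
#'   `dropped` (deleted random terms in order), `n_obs`, `n_groups`.
#' @export
fit_mlm <- function(data, spec, reml = TRUE) {
  stopifnot(inherits(spec, "mlm_spec"))
  resp <- all.vars(spec$fixed)[1]
  used <- unique(c(all.vars(spec$fixed), all.vars(spec$random), spec$group))
  used <- intersect(used, names(data))
  data <- data[stats::complete.cases(data[, used, drop = FALSE]), ,
               drop = FALSE]
  if (length(unique(data[[spec$group]])) < 2L)
    stop("fit_mlm: need at least two groups (participants)", call. = FALSE)
  if (stats::var(data[[resp]], na.rm = TRUE) == 0)
    stop("fit_mlm: degenerate (constant) response", call. = FALSE)

  queue <- reduction_order(spec$random)
  terms_now <- attr(stats::terms(spec$random), "term.labels")
  dropped <- character(0)
  last_form <- NULL
  res <- NULL
  repeat {
    form <- compose_formula(spec$fixed, terms_now, spec$group)
    last_form <- form
    res <- try_structure(form, data, reml)
    if (res$ok) break
    if (!length(terms_now)) break  # intercept-only: terminal fallback
    victim <- queue[queue %in% terms_now][1]
    dropped <- c(dropped, victim)
    terms_now <- setdiff(terms_now, victim)
  }
  if (is.null(res$model))
    stop("fit_mlm: no random structure could be fitted; last attempted: ",
         deparse(last_form), call. = FALSE)

  co <- as.data.frame(summary(res$model)$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")
  structure(list(model = res$model,
                 coefficients = co,
                 random = paste(c("1", terms_now), collapse = " + "),
                 singular = res$singular,
                 converged = res$ok || !length(terms_now),
                 dropped = dropped,
                 n_obs = nrow(res$model@frame),
                 n_groups = lme4::ngrps(res$model)[[1]],
                 spec = spec),
            class = "mlm_result")
}

#' @exportS3Method base::print
print.mlm_result <- function(x, ...) {
  cat("Linear mixed model:", deparse(x$spec$fixed), "\n")
  cat("Random (realized): (", x$random, "|", x$spec$group, ")\n")
  if (length(x$dropped))
    cat("Dropped random terms:", paste(x$dropped, collapse = ", "), "\n")
  if (x$singular) cat("Note: singular terminal fit\n")
  cat(x$n_obs, "observations,", x$n_groups, "groups\n\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

# Default probe levels for the standard simple-coded factors.
coding_levels <- function(var) {
  std <- list(
    group = c(control = -0.5, patient = 0.5),
    feedback_timing = c(immediate = -0.5, delayed = 0.5),
    feedback_valence = c(negative = -0.5, positive = 0.5),
    learnability = c(unlearnable = -0.5, learnable = 0.5),
    response_type = c(false = -0.5, correct = 0.5)
  )
  if (var %in% names(std)) return(std[[var]])
  stats::setNames(c(-0.5, 0.5), paste0(var, c("-", "+")))
}

#' Simple slopes of a focal predictor at moderator levels
#'
#' For every combination of moderator levels, the conditional slope of the
#' focal predictor is the linear combination of fixed-effect coefficients
#' obtained by differentiating the fixed part with respect to the focal
#' variable and evaluating all remaining variables at the probe point
#' (moderators at their level codes, everything else at its centered zero).
#' Standard errors, Satterthwaite degrees of freedom and p-values come from
#' the fitted model's coefficient covariance via [lmerTest::contest1D()].
#'
#' @param result An [fit_mlm()] result.
#' @param focal Name of the focal predictor (e.g. `"upe"`).
#' @param moderators Character vector of moderator variables.
#' @param levels Named list of named numeric level codes per moderator;
#'   defaults to the standard +/-0.5 codes.
#' @return Data.frame: one row per moderator-level combination with the
#'   moderator labels, `estimate`, `se`, `df`, `t`, `p`.
#' @export
probe_simple_slopes <- function(result, focal, moderators,
                                levels = NULL) {
  model <- result$model
  fixed_terms <- attr(stats::terms(result$spec$fixed), "term.labels")
  term_vars <- strsplit(fixed_terms, ":", fixed = TRUE)
  all_vars <- unique(unlist(term_vars))
  if (!focal %in% all_vars)
    stop("probe_simple_slopes: focal predictor not in the model",
         call. = FALSE)
  if (!all(moderators %in% all_vars))
    stop("probe_simple_slopes: moderator(s) not in the model: ",
         paste(setdiff(moderators, all_vars), collapse = ", "),
         call. = FALSE)
  has_interaction <- any(vapply(term_vars, function(v)
    focal %in% v && all(moderators %in% v), logical(1)))
  if (!has_interaction)
    stop("probe_simple_slopes: no focal x moderators interaction in the model",
         call. = FALSE)

  if (is.null(levels))
    levels <- stats::setNames(lapply(moderators, coding_levels), moderators)
  coef_names <- names(lme4::fixef(model))
  grid <- expand.grid(lapply(levels, names), stringsAsFactors = FALSE)

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    point <- stats::setNames(
      vapply(moderators, function(m) levels[[m]][[grid[i, m]]], numeric(1)),
      moderators)
    L <- stats::setNames(numeric(length(coef_names)), coef_names)
    for (j in seq_along(fixed_terms)) {
      vars <- term_vars[[j]]
      if (!focal %in% vars) next
      others <- setdiff(vars, focal)
      if (!all(others %in% moderators)) next  # other vars sit at centered 0
      L[fixed_terms[j]] <- prod(point[others])
    }
    ct <- lmerTest::contest1D(model, unname(L), ddf = "Satterthwaite")
    cbind(grid[i, , drop = FALSE],
          data.frame(estimate = ct$Estimate, se = ct$`Std. Error`,
                     df = ct$df, t = ct$`t value`, p = ct$`Pr(>|t|)`))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Influence screening by Cook's distance
#'
#' Cook's distances from the fitted mixed model, either per participant
#' (leave-one-participant-out, the default — influential units are whole
#' subjects in a repeated-measures design) or per observation. Values above
#' `threshold` (default 4/n at the chosen level) are flagged. Flags are
#' reported, never acted on — removal is the caller's choice.
#'
#' @param result An [fit_mlm()] result.
#' @param level `"participant"` (group deletion) or `"observation"`.
#' @param threshold Flagging cutoff; default `4 / n` where n is the number
#'   of participants or observations.
#' @return Data.frame with `unit` (participant id or observation row),
#'   `cooks_distance`, `flagged`; the cutoff is kept in the `"threshold"`
#'   attribute.
#' @export
screen_influence <- function(result, level = c("participant", "observation"),
                             threshold = NULL) {
  level <- match.arg(level)
  model <- result$model
  if (level == "participant") {
    # pass the model frame explicitly: the fitting call's data symbol is
    # not resolvable when influence() re-evaluates it
    inf <- stats::influence(model, groups = result$spec$group,
                            data = model@frame)
    d <- stats::cooks.distance(inf)
    units <- rownames(inf[[paste0("fixed.effects[-", result$spec$group,
                                  "]")]])
    if (is.null(units))
      units <- as.character(unique(model@frame[[result$spec$group]]))
    if (length(units) != length(d)) units <- as.character(seq_along(d))
  } else {
    d <- stats::cooks.distance(model)
    units <- as.character(seq_along(d))
  }
  if (is.null(threshold)) threshold <- 4 / length(d)
  out <- data.frame(unit = units, cooks_distance = as.numeric(d),
                    flagged = as.numeric(d) > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

#' Write an mlm_result's coefficient table and metadata
#'
#' TSV coefficient table plus a JSON metadata sidecar (realized random
#' structure, n, singular flag).
#'
#' @param result An [fit_mlm()] result.
#' @param path TSV output path; metadata goes to the same path with `.json`.
#' @return `path`, invisibly.
#' @export
write_mlm_result <- function(result, path) {
  co <- cbind(term = rownames(result$coefficients), result$coefficients)
  utils::write.table(co, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(fixed = deparse(result$spec$fixed, width.cutoff = 500L),
         random = result$random, singular = result$singular,
         converged = result$converged, dropped = result$dropped,
         n_obs = result$n_obs, n_groups = result$n_groups),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
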