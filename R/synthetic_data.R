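# Synthetic stand-in for the study's behavioral dataset: group choice logs
# generated with the task's exact generative structure and choices sampled
# from any of the four candidate models.

# Study-condition defaults for the generating parameters, per model.
# Group means sit at the reported central tendencies for this task (the
# winning three-weight trade-off model's medians); the w5 mean is clamped
# just inside the unit interval because the logit transform is undefined at
# the boundary. Between-subject SDs are fixed at quartile-spread-implied
# values (IQR / 1.349 under normality).
default_group_params <- function(model_id) {
  switch(model_id,
    trade3 = list(
      mean = c(tau = 2.833, c_int = 5.891, w3 = 0.834, w5 = 0.995, w7 = 0.264),
      sd = c(tau = 1.35, c_int = 0.95, w3 = 0.08, w5 = 0.38, w7 = 0.21)),
    trade1 = list(
      mean = c(tau = 2.833, c_int = 5.891, w = 0.5),
      sd = c(tau = 1.35, c_int = 0.95, w = 0.25)),
    optimal = list(mean = c(tau = 2.833), sd = c(tau = 1.35)),
    immediate = list(
      mean = c(tau = 2.833, c_int = 5.891),
      sd = c(tau = 1.35, c_int = 0.95))
  )
}

#' Group simulation design
#'
#' Describes a synthetic study: the number of subjects and trials, the
#' generating choice model, the group-level distribution its parameters are
#' drawn from, and the master seed. Defaults reproduce the study design
#' (23 subjects, 3 sessions of 36 trials each) with the three-weight
#' trade-off model as generator.
#'
#' Per-subject parameters are drawn from a Gaussian in unconstrained
#' (transform) space, so every draw respects its native domain. Native
#' means/SDs are mapped through the transforms by the delta method, with the
#' mapped SD clipped to `[0.05, 3]` to keep the transform-space spread finite
#' near domain boundaries.
#'
#' @param n_subjects Number of subjects (default 23).
#' @param n_sessions Sessions per subject (default 3).
#' @param trials_per_session Trials per session (default 36).
#' @param model Generating model id.
#' @param param_means,param_sds Named native-space group means and
#'   between-subject SDs; model-specific defaults are used for any
#'   parameter not supplied.
#' @param seed Master seed; every per-subject stream derives from it.
#' @param rule Contingency update rule for the task engine and solver.
#' @return A `group_design` object.
#' @export
group_design <- function(n_subjects = 23L, n_sessions = 3L,
                         trials_per_session = 36L, model = "trade3",
                         param_means = NULL, param_sds = NULL, seed = 1L,
                         rule = "literal") {
  spec <- model_spec(model)
  defaults <- default_group_params(spec$model_id)
  means <- defaults$mean
  sds <- defaults$sd
  if (!is.null(param_means)) means[names(param_means)] <- param_means
  if (!is.null(param_sds)) sds[names(param_sds)] <- param_sds
  stopifnot(n_subjects >= 1L, n_sessions >= 1L, trials_per_session >= 1L)
  # map to unconstrained space: mu_u = t(mu), sd_u = sd * |t'(mu)| clipped
  mu_u <- to_unconstrained(spec, means)
  deriv <- vapply(seq_len(spec$n_params), function(i) {
    m <- means[[spec$param_names[i]]]
    switch(spec$transforms[i],
      log = 1 / m,
      identity = 1,
      logit = 1 / (max(m, 1e-3) * max(1 - m, 1e-3)))
  }, numeric(1))
  sd_u <- pmin(pmax(sds[spec$param_names] * deriv, 0.05), 3)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_sessions = as.integer(n_sessions),
    trials_per_session = as.integer(trials_per_session),
    model = spec$model_id, spec = spec,
    param_means = means, param_sds = sds,
    mu_u = mu_u, sd_u = stats::setNames(sd_u, spec$param_names),
    seed = as.integer(seed), rule = rule
  ), class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat(sprintf(
    "<group_design> %d subjects x %d trials (%d sessions of %d), model %s, seed %d\n",
    x$n_subjects, x$n_sessions * x$trials_per_session, x$n_sessions,
    x$trials_per_session, x$model, x$seed))
  cat("  group means (native):",
      paste(sprintf("%s=%.3f", names(x$param_means), x$param_means),
            collapse = " "), "\n")
  invisible(x)
}

#' Simulate one synthetic subject
#'
#' Draws the subject's parameters from the group distribution, then plays
#' the configured number of trials through the task engine, sampling each
#' free-choice action from the generating model's acceptance probability and
#' enforcing nogo responses after budget exhaustion. Fully determined by the
#' design's master seed and the subject index.
#'
#' @param design A [group_design()].
#' @param subject_index Subject number (1-based).
#' @return List with `log` (choice-log data.frame) and `params` (the
#'   subject's true native parameters).
#' @export
generate_subject <- function(design, subject_index) {
  stopifnot(inherits(design, "group_design"),
            subject_index >= 1L, subject_index <= design$n_subjects)
  spec <- design$spec
  rng <- get_rng_state()
  on.exit(set_rng_state(rng))
  set.seed(derive_seed(design$seed, subject_index))

  u <- design$mu_u + design$sd_u * stats::rnorm(spec$n_params)
  params <- to_native(spec, stats::setNames(u, spec$param_names))
  # EV lookup array indexed [offers_seen + 1, n_accepted + 1, m + 1, value]
  ev <- ev_table(rule = design$rule)
  ev_arr <- array(NA_real_, dim = c(9, 6, 3, 3))
  ev_arr[cbind(ev$offers_seen + 1L, ev$n_accepted + 1L, ev$m + 1L,
               match(ev$IR, TOKEN_VALUES))] <- ev$EV
  probs_m <- rbind(offer_probs(0), offer_probs(1), offer_probs(2))
  monotone <- design$rule == "monotone"
  no_update <- design$rule == "none"

  n_trials <- design$n_sessions * design$trials_per_session
  total <- 0L
  # preallocated record columns (9 offers max per trial)
  trial_c <- session_c <- index_c <- value_c <- m_c <- integer(9L * n_trials)
  go_c <- forced_c <- logical(9L * n_trials)
  n_offers_c <- budget_c <- integer(9L * n_trials)
  for (t in seq_len(n_trials)) {
    n_offers <- sample(7:9, 1L)
    budget <- sample(4:6, 1L)
    a <- 0L
    m <- 0L
    for (i in seq_len(n_offers)) {
      value <- sample(TOKEN_VALUES, 1L, prob = probs_m[m + 1L, ])
      forced <- a >= budget
      if (forced) {
        go <- FALSE
      } else {
        evv <- if (spec$model_id == "immediate") 0 else {
          ev_arr[i, a + 1L, m + 1L, match(value, TOKEN_VALUES)]
        }
        v <- dv_core(spec, params,
                     list(EV = evv, IR = value, w_idx = match(value, TOKEN_VALUES)))
        go <- stats::runif(1) < stats::plogis(params[["tau"]] * v)
      }
      total <- total + 1L
      index_c[total] <- i
      value_c[total] <- value
      m_c[total] <- m
      go_c[total] <- go
      forced_c[total] <- forced
      trial_c[total] <- t
      n_offers_c[total] <- n_offers
      budget_c[total] <- budget
      # contingency update (inline for speed; mirrors update_m)
      if (go && !no_update && i > 1L && (i - 1L - a) < 3L) {
        cand <- if (value == 5L) 1L else if (value == 7L) 2L else m
        m <- if (monotone) max(m, cand) else cand
      }
      if (go) a <- a + 1L
    }
  }
  keep <- seq_len(total)
  log <- data.frame(
    subject_id = sprintf("S%02d", subject_index),
    trial = trial_c[keep],
    session = ((trial_c[keep] - 1L) %/% design$trials_per_session) + 1L,
    offer_index = index_c[keep],
    offer_value = value_c[keep],
    m_at_offer = m_c[keep],
    action = ifelse(go_c[keep], "go", "nogo"),
    forced = forced_c[keep],
    n_offers = n_offers_c[keep],
    budget = budget_c[keep]
  )
  list(log = log, params = params)
}

#' Simulate a synthetic group dataset
#'
#' Concatenated subject choice logs plus the truth table of generating
#' parameters, byte-identical across runs with the same design.
#'
#' @param design A [group_design()].
#' @return List with `log` (choice-log data.frame over all subjects),
#'   `truth` (data.frame `subject_id`, `parameter`, `true_value`) and
#'   `design`.
#' @export
generate_group <- function(design) {
  stopifnot(inherits(design, "group_design"))
  subs <- lapply(seq_len(design$n_subjects), generate_subject, design = design)
  log <- do.call(rbind, lapply(subs, `[[`, "log"))
  truth <- do.call(rbind, lapply(seq_along(subs), function(i) {
    data.frame(subject_id = sprintf("S%02d", i),
               parameter = names(subs[[i]]$params),
               true_value = unname(subs[[i]]$params))
  }))
  rownames(log) <- rownames(truth) <- NULL
  list(log = log, truth = truth, design = design)
}
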