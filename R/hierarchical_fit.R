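# Hierarchical Type-II maximum-likelihood (random-effects) fitting.
#
# Group-level Gaussian priors over the unconstrained parameters are
# estimated by Expectation-Maximization: the E-step computes each subject's
# MAP estimate and a Laplace (Gaussian) approximation of their posterior,
# the M-step moment-matches the group mean and variance to those posteriors.
# Model comparison uses the integrated BIC (iBIC) built from the Laplace-
# approximated group marginal likelihood; goodness of fit is summarized by
# the Cox-Snell pseudo-r-squared against a per-subject intercept-only
# baseline.

# Default (pre-EM) group prior in unconstrained space: weakly informative,
# centered at tau = 1, c_int = 5 (the middle token value), w = 0.5.
default_prior <- function(spec) {
  mu <- vapply(seq_len(spec$n_params), function(i) {
    switch(spec$transforms[i], log = 0, identity = 5, logit = 0)
  }, numeric(1))
  sigma2 <- vapply(seq_len(spec$n_params), function(i) {
    switch(spec$transforms[i], log = 2.25, identity = 9, logit = 2.25)
  }, numeric(1))
  list(mu = stats::setNames(mu, spec$param_names),
       sigma2 = stats::setNames(sigma2, spec$param_names))
}

# Negative log-posterior (unnormalized) and gradient in unconstrained space.
neg_log_post <- function(spec, u, fc, prior) {
  nll_unconstrained(spec, u, fc) +
    sum((u - prior$mu)^2 / (2 * prior$sigma2))
}

neg_log_post_grad <- function(spec, u, fc, prior) {
  nll_grad_unconstrained(spec, u, fc) + (u - prior$mu) / prior$sigma2
}

# Symmetrize a Hessian and floor its eigenvalues so it is positive definite.
pd_hessian <- function(H, floor = 1e-6) {
  H <- (H + t(H)) / 2
  e <- eigen(H, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  list(H = e$vectors %*% (vals * t(e$vectors)), logdet = sum(log(vals)),
       inv_diag = diag(e$vectors %*% ((1 / vals) * t(e$vectors))),
       floored = any(e$values < floor))
}

#' Fit one subject's MAP parameter estimate
#'
#' Maximizes log-likelihood plus log group-prior density in unconstrained
#' space by quasi-Newton optimization with analytic gradients and multiple
#' starting points, returning the best optimum and the finite-difference
#' negative Hessian (local curvature) there.
#'
#' @param spec A [model_spec()].
#' @param data One subject's choice-log data.frame (at least one free
#'   choice).
#' @param prior Group prior: list with named vectors `mu` and `sigma2` in
#'   unconstrained space. Defaults to a weakly informative prior.
#' @param starts Matrix of additional unconstrained starting points (one per
#'   row); the prior mean is always included.
#' @return List with `u` (unconstrained MAP), `native`, `neg_log_post`,
#'   `ll` (data log-likelihood at the MAP), `hessian`, `converged`,
#'   `n_choices`.
#' @export
fit_subject_map <- function(spec, data, prior = default_prior(spec),
                            starts = NULL) {
  fc <- free_choices(spec, data)
  fit_subject_map_fc(spec, fc, prior, starts)
}

fit_subject_map_fc <- function(spec, fc, prior, starts = NULL) {
  start_list <- rbind(matrix(prior$mu, nrow = 1), starts)
  # Box bounds on the unconstrained scale keep exp/logit transforms finite.
  lower <- rep(-20, spec$n_params)
  upper <- rep(20, spec$n_params)
  fn <- function(u) {
    v <- neg_log_post(spec, stats::setNames(u, spec$param_names), fc, prior)
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(u) {
    g <- neg_log_post_grad(spec, stats::setNames(u, spec$param_names), fc, prior)
    g[!is.finite(g)] <- 0
    g
  }
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(start_list))) {
    opt <- tryCatch(
      stats::optim(pmin(pmax(start_list[i, ], lower), upper),
                   fn = fn, gr = gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("subject-level optimization failed from all starts", call. = FALSE)
  u <- stats::setNames(best$par, spec$param_names)
  H <- stats::optimHess(best$par, fn = fn, gr = gr)
  list(
    u = u,
    native = to_native(spec, u),
    neg_log_post = best$value,
    ll = -nll_unconstrained(spec, u, fc),
    hessian = H,
    converged = any_conv,
    n_choices = length(fc$y)
  )
}

# Laplace approximation of one subject's log marginal likelihood
# log integral L(theta) N(theta; mu, sigma2) dtheta.
laplace_log_marginal <- function(fit, prior) {
  d <- length(fit$u)
  log_prior <- sum(stats::dnorm(fit$u, prior$mu, sqrt(prior$sigma2), log = TRUE))
  pd <- pd_hessian(fit$hessian)
  fit$ll + log_prior + d / 2 * log(2 * pi) - pd$logdet / 2
}

#' Hierarchical EM fit of a choice model to group data
#'
#' Alternates per-subject MAP estimation with Laplace posterior
#' approximations (E-step) and moment-matching updates of the group-level
#' Gaussian mean and variance per parameter (M-step) until every group
#' hyperparameter changes by less than `tol`, or `max_iter` iterations.
#' Subjects are processed in sorted `subject_id` order and restart points
#' are shared across subjects, so the result is invariant to row order.
#'
#' @param spec A [model_spec()] or a model id string.
#' @param data Group choice-log data.frame with a `subject_id` column
#'   (at least 2 subjects); long-term values are joined automatically.
#' @param n_restarts Optimizer starting points per subject on the first
#'   E-step (prior mean plus `n_restarts - 1` seeded draws); later E-steps
#'   warm-start from the previous MAP.
#' @param max_iter,tol EM convergence controls (absolute change on all group
#'   hyperparameters).
#' @param var_floor Lower bound on group variances, preventing prior
#'   collapse; a flag records when it binds.
#' @param seed Integer seed for the restart draws (the only randomness).
#' @return An `em_fit` object: list with `model_id`, `spec`, `prior`
#'   (`mu`, `sigma2`), `subjects` (per-subject MAP data.frame, native and
#'   unconstrained), `subject_fits`, `log_marginal` (summed Laplace
#'   integrals), `ibic`, `n_choices`, `pseudo_r2` (per subject),
#'   `pseudo_r2_group`, `objective_trace`, `iterations`, `converged`,
#'   `variance_floor_hit`.
#' @export
em_fit <- function(spec, data, n_restarts = 5L, max_iter = 100L, tol = 1e-4,
                   var_floor = 1e-6, seed = 1L) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  if (!all(c("EV", "n_accepted_prior") %in% names(data))) {
    data <- augment_choice_log(data)
  }
  ids <- sort(unique(data$subject_id))
  if (length(ids) < 2L) stop("hierarchical fitting needs at least 2 subjects", call. = FALSE)
  fcs <- lapply(ids, function(id) {
    free_choices(spec, data[data$subject_id == id, , drop = FALSE])
  })

  d <- spec$n_params
  prior <- default_prior(spec)
  # Shared deterministic restart directions (standard normal), drawn once.
  z <- local({
    rng <- get_rng_state()
    on.exit(set_rng_state(rng))
    set.seed(as.integer(seed) %% .Machine$integer.max)
    matrix(stats::rnorm((max(n_restarts, 1L) - 1L) * d), ncol = d)
  })

  fits <- vector("list", length(ids))
  trace <- numeric()
  converged <- FALSE
  floor_hit <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    sd_u <- sqrt(prior$sigma2)
    for (i in seq_along(ids)) {
      starts <- if (iter == 1L) {
        if (nrow(z)) sweep(z, 2, sd_u, `*`) + matrix(prior$mu, nrow(z), d, byrow = TRUE)
      } else {
        matrix(fits[[i]]$u, nrow = 1) # warm start; prior mean added inside
      }
      fits[[i]] <- fit_subject_map_fc(spec, fcs[[i]], prior, starts)
    }
    trace <- c(trace, sum(vapply(fits, laplace_log_marginal, numeric(1),
                                 prior = prior)))
    # M-step: moment-match group mean/variance to the Laplace posteriors.
    U <- do.call(rbind, lapply(fits, `[[`, "u"))
    S <- do.call(rbind, lapply(fits, function(f) pd_hessian(f$hessian)$inv_diag))
    mu_new <- colMeans(U)
    sigma2_new <- colMeans(U^2 + S) - mu_new^2
    if (any(sigma2_new < var_floor)) floor_hit <- TRUE
    sigma2_new <- pmax(sigma2_new, var_floor)
    delta <- max(abs(c(mu_new - prior$mu, sigma2_new - prior$sigma2)))
    prior <- list(mu = stats::setNames(mu_new, spec$param_names),
                  sigma2 = stats::setNames(sigma2_new, spec$param_names))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # Final E-step under the converged prior, so estimates match the prior.
  for (i in seq_along(ids)) {
    fits[[i]] <- fit_subject_map_fc(spec, fcs[[i]], prior,
                                    matrix(fits[[i]]$u, nrow = 1))
  }
  log_marg <- vapply(fits, laplace_log_marginal, numeric(1), prior = prior)
  trace <- c(trace, sum(log_marg))

  n_choices <- sum(vapply(fits, `[[`, integer(1), "n_choices"))
  natives <- do.call(rbind, lapply(fits, `[[`, "native"))
  us <- do.call(rbind, lapply(fits, `[[`, "u"))
  subjects <- data.frame(subject_id = rep(ids, each = d),
                         parameter = rep(spec$param_names, length(ids)),
                         value = as.vector(t(natives)),
                         unconstrained = as.vector(t(us)))
  lls <- vapply(fits, `[[`, numeric(1), "ll")
  ll0 <- vapply(fcs, baseline_ll, numeric(1))
  ns <- vapply(fits, `[[`, integer(1), "n_choices")
  r2 <- pseudo_r2(lls, ll0, ns)

  out <- structure(list(
    model_id = spec$model_id,
    spec = spec,
    prior = prior,
    subjects = subjects,
    subject_fits = stats::setNames(fits, ids),
    subject_ids = ids,
    log_marginal = sum(log_marg),
    n_choices = n_choices,
    k = 2L * d,
    pseudo_r2 = stats::setNames(r2, ids),
    objective_trace = trace,
    iterations = iter,
    converged = converged,
    variance_floor_hit = floor_hit
  ), class = "em_fit")
  out$ibic <- ibic(out)
  out$pseudo_r2_group <- mean(r2)
  out
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("<em_fit> model %s: %d subjects, %d free choices\n",
              x$model_id, length(x$subject_ids), x$n_choices))
  cat(sprintf("  log marginal = %.2f, iBIC = %.2f, mean pseudo-r2 = %.3f\n",
              x$log_marginal, x$ibic, x$pseudo_r2_group))
  cat(sprintf("  EM: %d iterations, %sconverged%s\n", x$iterations,
              if (x$converged) "" else "NOT ",
              if (x$variance_floor_hit) " (variance floor hit)" else ""))
  mu_native <- to_native(x$spec, x$prior$mu)
  cat("  group means (native):",
      paste(sprintf("%s=%.3f", names(mu_native), mu_native), collapse = " "), "\n")
  invisible(x)
}

#' Integrated Bayesian Information Criterion
#'
#' `iBIC = -2 * log marginal likelihood + k * log(n)` where the group
#' marginal likelihood integrates each subject's likelihood over the fitted
#' group prior (Laplace approximation), `k` counts the group-level
#' hyperparameters (a mean and a variance per parameter) and `n` is the
#' total number of free choices pooled over subjects. Smaller is better.
#'
#' @param fit An [em_fit()] result.
#' @param n_total_choices Pooled free-choice count; defaults to the count
#'   stored in the fit.
#' @return Scalar iBIC.
#' @export
ibic <- function(fit, n_total_choices = fit$n_choices) {
  stopifnot(inherits(fit, "em_fit"))
  if (!is.finite(fit$log_marginal)) {
    stop("non-finite integrated likelihood; see fit diagnostics", call. = FALSE)
  }
  -2 * fit$log_marginal + fit$k * log(n_total_choices)
}

#' Cox-Snell pseudo-r-squared
#'
#' `1 - exp(2 * (ll_baseline - ll_model) / n)`: a likelihood-based
#' goodness-of-fit measure relative to a baseline model, 0 when the model
#' adds nothing over the baseline.
#'
#' @param ll_model,ll_baseline Log-likelihoods (vectorized).
#' @param n_choices Number of choices entering each likelihood.
#' @return Pseudo-r-squared value(s).
#' @export
pseudo_r2 <- function(ll_model, ll_baseline, n_choices) {
  stopifnot(all(n_choices > 0))
  1 - exp(2 * (ll_baseline - ll_model) / n_choices)
}

# Intercept-only baseline: constant accept probability fit by maximum
# likelihood (the empirical accept rate), evaluated on a free-choice list
# or a subject's data.frame.
baseline_ll <- function(data) {
  y <- if (is.data.frame(data)) {
    free_choices(model_spec("optimal"), data)$y
  } else {
    data$y
  }
  p <- mean(y)
  n1 <- sum(y)
  n0 <- length(y) - n1
  ll <- 0
  if (n1 > 0) ll <- ll + n1 * log(p)
  if (n0 > 0) ll <- ll + n0 * log(1 - p)
  ll
}

#' Fit and rank candidate choice models on group data
#'
#' Fits each model by [em_fit()] on the same data and tabulates the number
#' of group hyperparameters, the integrated group log-likelihood, iBIC, and
#' the group-mean Cox-Snell pseudo-r-squared with a bootstrap 95% confidence
#' interval over subjects, sorted by iBIC ascending (best first).
#'
#' @param data Group choice-log data.frame.
#' @param models Character vector of model ids to compare.
#' @param n_boot Bootstrap resamples for the pseudo-r2 confidence interval.
#' @param seed Seed for fitting restarts and the bootstrap.
#' @param ... Passed to [em_fit()].
#' @return List with `table` (the ranking data.frame) and `fits` (named list
#'   of `em_fit` objects).
#' @export
compare_models <- function(data, models = MODEL_IDS, n_boot = 2000L,
                           seed = 1L, ...) {
  if (!all(c("EV", "n_accepted_prior") %in% names(data))) {
    data <- augment_choice_log(data)
  }
  fits <- lapply(models, function(mid) em_fit(mid, data, seed = seed, ...))
  names(fits) <- models
  rng <- get_rng_state()
  on.exit(set_rng_state(rng))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rows <- lapply(fits, function(f) {
    r2 <- f$pseudo_r2
    boots <- vapply(seq_len(n_boot), function(b) {
      mean(r2[sample.int(length(r2), replace = TRUE)])
    }, numeric(1))
    ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    data.frame(model_id = f$model_id, k = f$k, n_params = f$spec$n_params,
               log_marginal = f$log_marginal, ibic = f$ibic,
               pseudo_r2 = mean(r2), pseudo_r2_lo = ci[1], pseudo_r2_hi = ci[2])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$ibic), ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Parameter summary table across subjects
#'
#' Quartile summary (25th percentile, median, 75th percentile) of the
#' per-subject MAP estimates in native space, one row per parameter.
#'
#' @param fit An [em_fit()] result.
#' @return data.frame with columns `parameter`, `q25`, `median`, `q75`.
#' @export
parameter_summary <- function(fit) {
  stopifnot(inherits(fit, "em_fit"))
  out <- do.call(rbind, lapply(fit$spec$param_names, function(pn) {
    v <- fit$subjects$value[fit$subjects$parameter == pn]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(parameter = pn, q25 = q[1], median = q[2], q75 = q[3])
  }))
  rownames(out) <- NULL
  out
}
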