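# Descriptive and regression analyses of choice: state-wise acceptance
# grids, the decorrelated-offer subset, robust logistic regression of
# choice on immediate and long-term value, and group-level t-tests.

#' State-wise acceptance grid
#'
#' Pooled probability of accepting at every (offer index, prior rejections,
#' offer value) state under the uniform offer distribution (`m = 0`), i.e.
#' before any contingency penalty has been instantiated. Forced (post-budget)
#' records are excluded. Cells with fewer than `min_count` observations are
#' flagged as excluded for display; the flag never removes data from any
#' regression.
#'
#' @param data Choice-log data.frame.
#' @param min_count Minimum observations for a cell to be display-included
#'   (default 15).
#' @return data.frame with one row per cell: `offer_index` (1-9),
#'   `n_rejected` (0-8), `offer_value` (3, 5, 7), `n_obs`, `n_go`,
#'   `p_accept` (`NA` for empty cells), `included`.
#' @export
acceptance_grid <- function(data, min_count = 15L) {
  if (!("n_rejected_prior" %in% names(data))) data <- augment_choice_log(data)
  free <- data[!as.logical(data$forced) & data$m_at_offer == 0L, , drop = FALSE]
  grid <- expand.grid(offer_index = 1:9, n_rejected = 0:8,
                      offer_value = c(3L, 5L, 7L))
  grid <- grid[grid$n_rejected < grid$offer_index, ]
  key_grid <- paste(grid$offer_index, grid$n_rejected, grid$offer_value)
  if (nrow(free)) {
    key_data <- paste(free$offer_index, free$n_rejected_prior, free$offer_value)
    go <- as.integer(free$action == "go")
    n_obs <- tapply(go, key_data, length)
    n_go <- tapply(go, key_data, sum)
    idx <- match(key_grid, names(n_obs))
    grid$n_obs <- ifelse(is.na(idx), 0L, as.integer(n_obs[idx]))
    grid$n_go <- ifelse(is.na(idx), 0L, as.integer(n_go[idx]))
  } else {
    grid$n_obs <- 0L
    grid$n_go <- 0L
  }
  grid$p_accept <- ifelse(grid$n_obs > 0, grid$n_go / grid$n_obs, NA_real_)
  grid$included <- grid$n_obs >= min_count
  grid <- grid[order(grid$offer_value, grid$offer_index, grid$n_rejected), ]
  rownames(grid) <- NULL
  grid
}

#' Decorrelated offer subset
#'
#' Free-choice records at offer indexes 2 and 3 presented under the uniform
#' distribution (`m = 0`): the early-trial states where immediate and
#' long-term value are maximally decorrelated (accepting a 7 is costly,
#' accepting a 5 is not), and hence where the demand for self-control is
#' greatest.
#'
#' @param data Choice-log data.frame.
#' @return The selected subset, in (subject, trial, offer) order.
#' @export
select_decorrelated_offers <- function(data) {
  if (!("n_rejected_prior" %in% names(data))) data <- augment_choice_log(data)
  out <- data[!as.logical(data$forced) &
                data$offer_index %in% 2:3 &
                data$m_at_offer == 0L, , drop = FALSE]
  out <- out[order(out$subject_id, out$trial, out$offer_index), ]
  rownames(out) <- NULL
  out
}

# Iteratively reweighted least squares for logistic regression, with an
# optional robust bisquare down-weighting of large Pearson residuals.
#
# The plain maximum-likelihood fit is computed first (with complete-
# separation detection); robust reweighting then iterates from it. Because
# fully iterated bisquare weights can zero out every contrarian observation
# and send a binary-response fit to infinity, a diverging robust iteration
# falls back to the one-step robust estimate (a single reweighted solve at
# the maximum-likelihood fit), which bounds the influence of outlying
# observations while remaining finite.
irls_logistic <- function(X, y, robust = TRUE, tune = 4.685,
                          max_iter = 100L, tol = 1e-8) {
  p_cols <- ncol(X)
  fail <- function(separated, rank_deficient) {
    list(beta = rep(NA_real_, p_cols), se = rep(NA_real_, p_cols),
         converged = FALSE, separated = separated,
         rank_deficient = rank_deficient)
  }
  wls_step <- function(beta, w_rob = NULL) {
    eta <- as.vector(X %*% beta)
    mu <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
    w <- mu * (1 - mu)
    if (!is.null(w_rob)) w <- w * w_rob
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-10)
    XtW <- t(X * w)
    fisher <- XtW %*% X
    if (rcond(fisher) < 1e-12) return(NULL)
    list(beta = as.vector(solve(fisher, XtW %*% z)), fisher = fisher)
  }
  bisquare <- function(beta) {
    mu <- pmin(pmax(stats::plogis(as.vector(X %*% beta)), 1e-10), 1 - 1e-10)
    # Pearson residuals are variance-1 under the model: fixed scale
    u <- (y - mu) / sqrt(mu * (1 - mu)) / tune
    ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }

  # -- plain maximum-likelihood IRLS ----------------------------------------
  beta <- numeric(p_cols)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    step <- wls_step(beta)
    if (is.null(step)) return(fail(FALSE, TRUE))
    delta <- max(abs(step$beta - beta))
    beta <- step$beta
    eta <- as.vector(X %*% beta)
    if (all(ifelse(y == 1, stats::plogis(eta) > 1 - 1e-8,
                   stats::plogis(eta) < 1e-8)) || max(abs(eta)) > 1e4) {
      return(fail(TRUE, FALSE))
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # plain logistic IRLS converges quickly whenever the MLE exists; failure
  # to converge indicates (quasi-)separation with a divergent MLE
  if (!converged) return(fail(TRUE, FALSE))
  beta_ml <- beta

  # -- robust reweighting ---------------------------------------------------
  if (robust) {
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      step <- wls_step(beta, bisquare(beta))
      if (is.null(step)) {
        converged <- FALSE
        break
      }
      delta <- max(abs(step$beta - beta))
      beta <- step$beta
      if (max(abs(as.vector(X %*% beta))) > 100) {
        converged <- FALSE
        break
      }
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      # one-step robust estimate from the maximum-likelihood fit
      step <- wls_step(beta_ml, bisquare(beta_ml))
      if (is.null(step)) return(fail(FALSE, TRUE))
      beta <- step$beta
      converged <- TRUE
    }
  }

  eta <- as.vector(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
  w <- mu * (1 - mu)
  if (robust) w <- w * bisquare(beta)
  cov_beta <- tryCatch(solve(t(X * w) %*% X), error = function(e) NULL)
  se <- if (is.null(cov_beta)) rep(NA_real_, p_cols) else sqrt(diag(cov_beta))
  list(beta = beta, se = se, converged = converged, separated = FALSE,
       rank_deficient = FALSE)
}

#' Robust logistic regression of choice on immediate and long-term value
#'
#' Per-subject logistic regression of the go/nogo response on the offer's
#' immediate value (`IR`, its face value) and long-term value (`EV`, from
#' the optimal agent), both competing for variance. Fitted by iteratively
#' reweighted least squares; with `robust = TRUE` (default) a bisquare
#' weighting of large Pearson residuals down-weights high-leverage
#' observations, with `robust = FALSE` the fit is plain maximum-likelihood
#' logistic regression. Regressors are entered unstandardized unless
#' `standardize = TRUE`.
#'
#' @param data Choice-log data.frame for one or more subjects.
#' @param robust Use the bisquare robust weighting (default `TRUE`).
#' @param standardize Z-score the regressors per subject before fitting.
#' @param decorrelated_only Restrict to [select_decorrelated_offers()].
#' @return data.frame with one row per subject and term (`intercept`, `IR`,
#'   `EV`): `beta`, `se`, `converged`, `separated`, `excluded` (subjects
#'   flagged for separation, rank deficiency, or one-sided responses are
#'   excluded from group tests).
#' @export
robust_logistic <- function(data, robust = TRUE, standardize = FALSE,
                            decorrelated_only = FALSE) {
  if (!("EV" %in% names(data))) data <- augment_choice_log(data)
  data <- if (decorrelated_only) {
    select_decorrelated_offers(data)
  } else {
    data[!as.logical(data$forced), , drop = FALSE]
  }
  ids <- sort(unique(data$subject_id))
  rows <- lapply(ids, function(id) {
    d <- data[data$subject_id == id, , drop = FALSE]
    y <- as.numeric(d$action == "go")
    ir <- as.numeric(d$offer_value)
    ev <- as.numeric(d$EV)
    base <- data.frame(subject_id = id, term = c("intercept", "IR", "EV"),
                       beta = NA_real_, se = NA_real_, converged = FALSE,
                       separated = FALSE, excluded = TRUE)
    if (length(unique(y)) < 2L) {
      attr(base, "note") <- "one-sided responses"
      return(base)
    }
    if (stats::sd(ev) == 0 || stats::sd(ir) == 0) {
      warning(sprintf("subject %s: constant regressor; excluded", id),
              call. = FALSE)
      return(base)
    }
    if (standardize) {
      ir <- as.vector(scale(ir))
      ev <- as.vector(scale(ev))
    }
    X <- cbind(1, ir, ev)
    fit <- irls_logistic(X, y, robust = robust)
    if (fit$separated) {
      warning(sprintf("subject %s: complete separation; excluded from group test", id),
              call. = FALSE)
    }
    base$beta <- fit$beta
    base$se <- fit$se
    base$converged <- fit$converged
    base$separated <- fit$separated
    base$excluded <- fit$separated || fit$rank_deficient || anyNA(fit$beta)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group one-sample t-test on regression coefficients
#'
#' Two-sided one-sample t-test of per-subject betas against zero, with
#' `df = n - 1`.
#'
#' @param betas Numeric vector of per-subject coefficients.
#' @return List with `t`, `df`, `p`, `mean`, `n`, and `degenerate` (`TRUE`
#'   when the betas have zero variance, in which case `t`/`p` are `NA`).
#' @export
group_ttest <- function(betas) {
  betas <- betas[is.finite(betas)]
  n <- length(betas)
  if (n < 2L) stop("group test needs at least 2 subjects", call. = FALSE)
  if (stats::sd(betas) == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, mean = mean(betas),
                n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(betas, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(betas), n = n, degenerate = FALSE)
}

#' Full behavioral analysis of a choice-log dataset
#'
#' Convenience wrapper: acceptance grid, per-subject robust logistic
#' regressions (all free choices and the decorrelated subset), and group
#' t-tests on the IR and EV coefficients.
#'
#' @param data Choice-log data.frame.
#' @param min_count Grid display threshold, see [acceptance_grid()].
#' @param robust Robust weighting in the regressions.
#' @return List with `grid`, `regression`, `regression_decorrelated`,
#'   `group_tests` (data.frame: subset, term, mean beta, t, df, p, n).
#' @export
analyze_choices <- function(data, min_count = 15L, robust = TRUE) {
  data <- augment_choice_log(data)
  grid <- acceptance_grid(data, min_count = min_count)
  reg_all <- robust_logistic(data, robust = robust)
  reg_dec <- robust_logistic(data, robust = robust, decorrelated_only = TRUE)
  tests <- do.call(rbind, lapply(
    list(all = reg_all, decorrelated = reg_dec), function(reg) {
      do.call(rbind, lapply(c("IR", "EV"), function(term) {
        b <- reg$beta[reg$term == term & !reg$excluded]
        if (length(b) < 2L) {
          return(data.frame(term = term, mean_beta = mean(b), t = NA_real_,
                            df = length(b) - 1L, p = NA_real_,
                            n = length(b)))
        }
        tt <- group_ttest(b)
        data.frame(term = term, mean_beta = tt$mean, t = tt$t, df = tt$df,
                   p = tt$p, n = tt$n)
      }))
    }))
  tests$subset <- rep(c("all", "decorrelated"), each = 2)
  rownames(tests) <- NULL
  list(grid = grid, regression = reg_all, regression_decorrelated = reg_dec,
       group_tests = tests[, c("subset", "term", "mean_beta", "t", "df", "p", "n")])
}
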