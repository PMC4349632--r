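# The four candidate observation models mapping decision values to accept
# probabilities, their parameter transforms, and likelihoods on choice logs.
#
# All models share the softmax observation rule P(go) = 1/(1 + exp(-tau*V_A))
# and differ in the decision value V_A:
#   immediate:  V_A = IR - c_int                         (tau, c_int)
#   optimal:    V_A = EV                                 (tau)
#   trade1:     V_A = EV*w + (IR - c_int)*(1 - w)        (tau, c_int, w)
#   trade3:     as trade1 with w in {w3, w5, w7} by IR   (tau, c_int, w3, w5, w7)

MODEL_IDS <- c("immediate", "optimal", "trade1", "trade3")

#' Choice-model specification
#'
#' Describes one of the four candidate models: its parameter names, native
#' domains and the transforms that map them to unconstrained fitting space
#' (`log` for the temperature `tau > 0`, identity for the value intercept
#' `c_int`, logit for trade weights in `[0, 1]`).
#'
#' @param model_id One of `"immediate"`, `"optimal"`, `"trade1"`, `"trade3"`.
#' @return A `model_spec` object: list with `model_id`, `param_names`,
#'   `transforms`, `n_params`.
#' @export
model_spec <- function(model_id = MODEL_IDS) {
  model_id <- match.arg(model_id)
  params <- switch(model_id,
    immediate = c(tau = "log", c_int = "identity"),
    optimal = c(tau = "log"),
    trade1 = c(tau = "log", c_int = "identity", w = "logit"),
    trade3 = c(tau = "log", c_int = "identity",
               w3 = "logit", w5 = "logit", w7 = "logit")
  )
  structure(list(
    model_id = model_id,
    param_names = names(params),
    transforms = unname(params),
    n_params = length(params)
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %s\n", x$model_id,
              paste(sprintf("%s (%s)", x$param_names, x$transforms),
                    collapse = ", ")))
  invisible(x)
}

# Clamp for the logit transform: native weights are mapped into the open
# unit interval before taking qlogis.
.W_EPS <- 1e-12

#' Parameter transforms between native and unconstrained space
#'
#' `to_unconstrained()` maps a native parameter vector into the unconstrained
#' space used for fitting (log for positive parameters, logit for unit-
#' interval parameters); `to_native()` inverts it. The round trip is exact to
#' floating precision away from domain boundaries.
#'
#' @param spec A [model_spec()].
#' @param params Named numeric vector in native (`to_unconstrained`) or
#'   unconstrained (`to_native`) space, names matching `spec$param_names`.
#' @return Named numeric vector in the other space.
#' @export
to_unconstrained <- function(spec, params) {
  stopifnot(inherits(spec, "model_spec"))
  params <- params[spec$param_names]
  if (anyNA(params)) stop("missing parameters for model ", spec$model_id, call. = FALSE)
  out <- numeric(spec$n_params)
  for (i in seq_len(spec$n_params)) {
    out[i] <- switch(spec$transforms[i],
      log = {
        if (params[i] <= 0) stop("`tau` must be positive", call. = FALSE)
        log(params[i])
      },
      identity = params[i],
      logit = {
        if (params[i] < 0 || params[i] > 1) {
          stop("trade weights must lie in [0, 1]", call. = FALSE)
        }
        stats::qlogis(min(max(params[i], .W_EPS), 1 - .W_EPS))
      })
  }
  stats::setNames(out, spec$param_names)
}

#' @rdname to_unconstrained
#' @export
to_native <- function(spec, params) {
  stopifnot(inherits(spec, "model_spec"))
  params <- params[spec$param_names]
  out <- numeric(spec$n_params)
  for (i in seq_len(spec$n_params)) {
    out[i] <- switch(spec$transforms[i],
      log = exp(params[i]),
      identity = params[i],
      logit = stats::plogis(params[i]))
  }
  stats::setNames(out, spec$param_names)
}

#' Softmax acceptance probability
#'
#' `P(go) = 1 / (1 + exp(-tau * V_A))`, numerically stable for arbitrarily
#' large `|tau * V_A|`.
#'
#' @param V_A Decision value(s) of accepting.
#' @param tau Temperature (inverse noise), `tau >= 0`; `tau = 0` yields 0.5
#'   everywhere.
#' @return Acceptance probabilities in `[0, 1]`, vectorized over `V_A`.
#' @export
p_accept <- function(V_A, tau) {
  if (any(tau < 0)) stop("`tau` must be nonnegative", call. = FALSE)
  stats::plogis(tau * V_A)
}

#' Decision value of accepting under a choice model
#'
#' @param spec A [model_spec()].
#' @param params Named native-space parameter vector.
#' @param EV Long-term value(s) from the optimal agent (ignored by the
#'   immediate model).
#' @param IR Face value(s) of the current offer (3, 5 or 7).
#' @return Decision values `V_A`, vectorized over records.
#' @export
decision_value <- function(spec, params, EV, IR) {
  stopifnot(inherits(spec, "model_spec"))
  switch(spec$model_id,
    immediate = IR - params[["c_int"]],
    optimal = EV,
    trade1 = {
      w <- params[["w"]]
      EV * w + (IR - params[["c_int"]]) * (1 - w)
    },
    trade3 = {
      w <- unname(c(`3` = params[["w3"]], `5` = params[["w5"]],
                    `7` = params[["w7"]])[as.character(IR)])
      EV * w + (IR - params[["c_int"]]) * (1 - w)
    })
}

# Extract the free-choice records (with EV joined) a likelihood needs.
# `w_idx` maps each record's offer value onto (w3, w5, w7) positions so the
# hot likelihood path avoids name-based lookups.
free_choices <- function(spec, data, decorrelated_only = FALSE) {
  if (!all(c("EV", "offer_value", "action", "forced") %in% names(data))) {
    data <- augment_choice_log(data)
  }
  keep <- !as.logical(data$forced)
  if (decorrelated_only) {
    keep <- keep & data$offer_index %in% 2:3 & data$m_at_offer == 0L
  }
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0L) stop("no free-choice records in the data", call. = FALSE)
  list(
    y = as.numeric(data$action == "go"),
    IR = as.numeric(data$offer_value),
    EV = as.numeric(data$EV),
    w_idx = match(data$offer_value, TOKEN_VALUES)
  )
}

#' Negative log-likelihood of a choice model
#'
#' Sums `-log P(observed action)` over all free-choice records (forced
#' nogo responses after budget exhaustion carry no information and are
#' excluded). Probabilities are floored at 1e-12 so the likelihood is
#' always finite.
#'
#' @param spec A [model_spec()].
#' @param params Named native-space parameter vector.
#' @param data Choice-log data.frame; long-term values are joined via
#'   [augment_choice_log()] if not already present.
#' @param decorrelated_only Restrict to the decorrelated offer subset
#'   (indexes 2-3 under the uniform distribution) for sensitivity analysis.
#' @return Scalar negative log-likelihood.
#' @examples
#' # a model assigning probability 1/2 to each of n choices has nll n*log(2)
#' @export
choice_nll <- function(spec, params, data, decorrelated_only = FALSE) {
  fc <- free_choices(spec, data, decorrelated_only)
  nll_core(spec, params, fc)
}

# Decision values on a prepared free-choice list (hot path).
dv_core <- function(spec, params, fc) {
  switch(spec$model_id,
    immediate = fc$IR - params[["c_int"]],
    optimal = fc$EV,
    trade1 = {
      w <- params[["w"]]
      fc$EV * w + (fc$IR - params[["c_int"]]) * (1 - w)
    },
    trade3 = {
      w <- c(params[["w3"]], params[["w5"]], params[["w7"]])[fc$w_idx]
      fc$EV * w + (fc$IR - params[["c_int"]]) * (1 - w)
    })
}

# Core likelihood on a prepared free-choice list; hot path for fitting.
nll_core <- function(spec, params, fc) {
  v <- dv_core(spec, params, fc)
  p <- stats::plogis(params[["tau"]] * v)
  p_obs <- p * fc$y + (1 - p) * (1 - fc$y)
  -sum(log(pmax(p_obs, 1e-12)))
}

# Negative log-likelihood and analytic gradient in unconstrained space.
# d nll / dz_i = (p_i - y_i) with z = tau * V_A; chain rule through the
# transforms: dtau/du = tau, dw/du = w(1-w), dc/du = 1.
nll_unconstrained <- function(spec, u, fc) {
  nll_core(spec, to_native(spec, u), fc)
}

nll_grad_unconstrained <- function(spec, u, fc) {
  params <- to_native(spec, u)
  tau <- params[["tau"]]
  v <- dv_core(spec, params, fc)
  p <- stats::plogis(tau * v)
  dz <- p - fc$y # d nll / dz per record
  g <- numeric(spec$n_params)
  names(g) <- spec$param_names
  g["tau"] <- sum(dz * v) * tau # dz/du_tau = tau * V_A
  if (spec$model_id == "immediate") {
    g["c_int"] <- -tau * sum(dz)
  } else if (spec$model_id == "trade1") {
    w <- params[["w"]]
    g["c_int"] <- -tau * (1 - w) * sum(dz)
    g["w"] <- tau * sum(dz * (fc$EV - (fc$IR - params[["c_int"]]))) * (w * (1 - w))
  } else if (spec$model_id == "trade3") {
    wv <- c(params[["w3"]], params[["w5"]], params[["w7"]])[fc$w_idx]
    g["c_int"] <- -tau * sum(dz * (1 - wv))
    dvdw <- dz * (fc$EV - (fc$IR - params[["c_int"]]))
    for (i in 1:3) {
      w <- params[[paste0("w", TOKEN_VALUES[i])]]
      g[2L + i] <- tau * sum(dvdw[fc$w_idx == i]) * (w * (1 - w))
    }
  }
  g
}
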