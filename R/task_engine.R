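# Generative engine for the sequential offer go/nogo task: trial structure,
# contingency-dependent offer sampling, action-driven contingency updates,
# budget enforcement and payout.

# Token values an offer can take.
TOKEN_VALUES <- c(3L, 5L, 7L)

#' Offer-value distribution for a contingency state
#'
#' Each contingency state `m` indexes a discrete probability distribution over
#' the three possible token values (3, 5, 7) of the forthcoming offer:
#' `m = 0` is the uniform trial-onset distribution, `m = 1` the moderate
#' penalty instantiated by an early acceptance of a 5-token offer, and
#' `m = 2` the severe penalty instantiated by an early acceptance of a
#' 7-token offer.
#'
#' @param m Contingency index, one of 0, 1, 2.
#' @return Named numeric vector of length 3 (names `"3"`, `"5"`, `"7"`)
#'   giving the probability of each token value. Probabilities sum to 1;
#'   `m = 0` returns exact thirds.
#' @examples
#' offer_probs(0)
#' offer_probs(2)["3"] # 0.9
#' @export
offer_probs <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || !(m %in% 0:2)) {
    stop("`m` must be a single contingency index in {0, 1, 2}", call. = FALSE)
  }
  switch(as.character(as.integer(m)),
    "0" = c("3" = 1 / 3, "5" = 1 / 3, "7" = 1 / 3),
    "1" = c("3" = 0.50, "5" = 0.25, "7" = 0.25),
    "2" = c("3" = 0.90, "5" = 0.05, "7" = 0.05)
  )
}

#' Contingency-state update rule
#'
#' Applies the task's explicit contingency rule after a response. The state
#' `m` changes only when a 5- or 7-token offer is accepted ("go"), and not on
#' the first offer of a trial nor once three or more previous offers have been
#' rejected. Accepting a 5-token offer sets `m = 1`, accepting a 7-token offer
#' sets `m = 2`. The function is pure: it returns the new index and mutates
#' nothing.
#'
#' The rule as stated is literal in the most recent choice, so accepting a
#' 5-token offer while `m = 2` relaxes the penalty back to `m = 1`. Set
#' `rule = "monotone"` to forbid such improvement (the state can then only
#' worsen), or `rule = "none"` to switch the contingency off entirely (used
#' for the no-penalty limit of the optimal agent).
#'
#' @param m Current contingency index in 0..2.
#' @param action `"go"` (accept) or `"nogo"` (reject).
#' @param offer_value Token value of the offer acted upon (3, 5 or 7).
#' @param offer_index 1-based position of the offer within the trial.
#' @param n_rejected Number of offers rejected before this one.
#' @param rule Update rule: `"literal"` (default), `"monotone"` or `"none"`.
#' @return Updated contingency index (integer in 0..2).
#' @examples
#' update_m(0, "go", 7, offer_index = 3, n_rejected = 0) # 2
#' update_m(0, "go", 7, offer_index = 1, n_rejected = 0) # 0 (first offer)
#' update_m(0, "go", 7, offer_index = 5, n_rejected = 3) # 0 (lock-in)
#' @export
update_m <- function(m, action, offer_value, offer_index, n_rejected,
                     rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  m <- as.integer(m)
  if (!(m %in% 0:2)) stop("`m` must be in {0, 1, 2}", call. = FALSE)
  if (!(action %in% c("go", "nogo"))) {
    stop("`action` must be \"go\" or \"nogo\"", call. = FALSE)
  }
  if (!(offer_value %in% TOKEN_VALUES)) {
    stop("`offer_value` must be one of 3, 5, 7", call. = FALSE)
  }
  if (offer_index < 1L || n_rejected < 0L) {
    stop("invalid `offer_index` or `n_rejected`", call. = FALSE)
  }
  if (rule == "none") return(m)
  if (action != "go" || offer_index == 1L || n_rejected >= 3L) return(m)
  m_new <- if (offer_value == 5L) 1L else if (offer_value == 7L) 2L else m
  if (rule == "monotone") max(m, m_new) else m_new
}

#' Draw trial configurations
#'
#' The number of offers in a trial (7-9) and the accept budget (4-6) are
#' drawn uniformly and independently, so all nine combinations are equally
#' likely. Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param n Number of configurations to draw.
#' @return A data.frame with integer columns `n_offers` and `budget`.
#' @export
draw_trial_config <- function(n = 1L) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1L)
  data.frame(
    n_offers = sample(7:9, n, replace = TRUE),
    budget = sample(4:6, n, replace = TRUE)
  )
}

#' Sample offer token values under a contingency state
#'
#' @param m Contingency index in 0..2.
#' @param n Number of values to draw.
#' @return Integer vector of token values in {3, 5, 7}.
#' @export
sample_offer <- function(m, n = 1L) {
  probs <- offer_probs(m)
  sample(TOKEN_VALUES, n, replace = TRUE, prob = probs)
}

# -- trial state machine -----------------------------------------------------

#' Start a trial
#'
#' Creates the state presented at the first offer of a trial. The first
#' offer's value is drawn from the uniform distribution (`m = 0`) unless
#' given.
#'
#' @param n_offers Number of offers in the trial (7-9).
#' @param budget Accept budget (4-6), strictly less than `n_offers`.
#' @param first_value Optional token value for the first offer; drawn from
#'   `offer_probs(0)` when `NULL`.
#' @param rule Contingency update rule, see [update_m()].
#' @return A `trial_state` object: a list with fields `n_offers`, `budget`,
#'   `offer_index`, `n_accepted`, `n_rejected`, `m`, `budget_exhausted`,
#'   `current_offer_value`, `done` and the accumulating `records` data.frame.
#' @export
new_trial <- function(n_offers, budget, first_value = NULL,
                      rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  n_offers <- as.integer(n_offers)
  budget <- as.integer(budget)
  if (n_offers < 7L || n_offers > 9L) stop("`n_offers` must be in 7..9", call. = FALSE)
  if (budget < 4L || budget > 6L) stop("`budget` must be in 4..6", call. = FALSE)
  if (budget >= n_offers) stop("`budget` must be smaller than `n_offers`", call. = FALSE)
  if (is.null(first_value)) first_value <- sample_offer(0L)
  stopifnot(first_value %in% TOKEN_VALUES)
  structure(list(
    n_offers = n_offers, budget = budget, rule = rule,
    offer_index = 1L, n_accepted = 0L, n_rejected = 0L, m = 0L,
    budget_exhausted = FALSE, current_offer_value = as.integer(first_value),
    done = FALSE,
    records = data.frame(
      offer_index = integer(), offer_value = integer(), m_at_offer = integer(),
      action = character(), forced = logical()
    )
  ), class = "trial_state")
}

#' Advance a trial by one response
#'
#' Records the response to the current offer (coerced to a forced nogo when
#' the accept budget is exhausted), applies the contingency update, and draws
#' the next offer's value from the updated distribution. Stepping past the
#' final offer is an error; check `state$done`.
#'
#' @param state A `trial_state` from [new_trial()].
#' @param action `"go"` or `"nogo"` (ignored, recorded as forced nogo, once
#'   the budget is exhausted).
#' @param next_value Optional token value for the next offer (for replay);
#'   sampled from the updated contingency distribution when `NULL`.
#' @return The updated `trial_state`.
#' @export
step_trial <- function(state, action, next_value = NULL) {
  stopifnot(inherits(state, "trial_state"))
  if (state$done) stop("trial is complete; cannot step past the final offer", call. = FALSE)
  if (!(action %in% c("go", "nogo"))) stop("`action` must be \"go\" or \"nogo\"", call. = FALSE)

  forced <- state$budget_exhausted
  if (forced) action <- "nogo"

  value <- state$current_offer_value
  m_next <- update_m(state$m, action, value, state$offer_index,
                     state$n_rejected, rule = state$rule)

  state$records <- rbind(state$records, data.frame(
    offer_index = state$offer_index, offer_value = value,
    m_at_offer = state$m, action = action, forced = forced
  ))
  if (action == "go") state$n_accepted <- state$n_accepted + 1L
  else state$n_rejected <- state$n_rejected + 1L
  state$m <- m_next
  state$budget_exhausted <- state$n_accepted >= state$budget

  if (state$offer_index == state$n_offers) {
    state$done <- TRUE
    state$current_offer_value <- NA_integer_
  } else {
    state$offer_index <- state$offer_index + 1L
    if (is.null(next_value)) next_value <- sample_offer(state$m)
    stopifnot(next_value %in% TOKEN_VALUES)
    state$current_offer_value <- as.integer(next_value)
  }
  state
}

#' Simulate one complete trial under a choice policy
#'
#' @param n_offers,budget Trial configuration; drawn via [draw_trial_config()]
#'   when `NULL`.
#' @param choose Function `(state) -> "go"|"nogo"` called at every free
#'   (within-budget) offer; it receives the current `trial_state`. Defaults to
#'   always rejecting.
#' @param rule Contingency update rule, see [update_m()].
#' @return A completed `trial_state` whose `records` data.frame has one row
#'   per offer and additional columns `n_offers` and `budget`.
#' @export
simulate_trial <- function(n_offers = NULL, budget = NULL,
                           choose = function(state) "nogo",
                           rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  if (is.null(n_offers) || is.null(budget)) {
    cfg <- draw_trial_config(1L)
    if (is.null(n_offers)) n_offers <- cfg$n_offers
    if (is.null(budget)) budget <- cfg$budget
  }
  state <- new_trial(n_offers, budget, rule = rule)
  while (!state$done) {
    action <- if (state$budget_exhausted) "nogo" else choose(state)
    state <- step_trial(state, action)
  }
  state$records$n_offers <- state$n_offers
  state$records$budget <- state$budget
  state
}

#' Total tokens won in a trial
#'
#' Sums the values of accepted offers after checking the log's invariants
#' (complete record list, accepts within budget, forced flags only as a
#' trailing suffix of nogo responses).
#'
#' @param trial A completed `trial_state`, or its `records` data.frame with
#'   `n_offers` and `budget` columns.
#' @return Integer token total.
#' @export
trial_payout <- function(trial) {
  records <- if (inherits(trial, "trial_state")) {
    if (!trial$done) stop("trial log is incomplete", call. = FALSE)
    cbind(trial$records, n_offers = trial$n_offers, budget = trial$budget)
  } else {
    trial
  }
  n_offers <- unique(records$n_offers)
  budget <- unique(records$budget)
  stopifnot(length(n_offers) == 1L, length(budget) == 1L)
  if (nrow(records) != n_offers) stop("trial log is incomplete", call. = FALSE)
  n_go <- sum(records$action == "go")
  if (n_go > budget) stop("trial log violates the accept budget", call. = FALSE)
  if (any(records$forced & records$action == "go")) {
    stop("forced records must be nogo", call. = FALSE)
  }
  if (is.unsorted(records$forced)) {
    stop("forced flags must form a suffix of the record list", call. = FALSE)
  }
  as.integer(sum(records$offer_value[records$action == "go"]))
}

# -- choice-log schema, validation and i/o -----------------------------------

CHOICE_LOG_COLUMNS <- c(
  "subject_id", "trial", "session", "offer_index", "offer_value",
  "m_at_offer", "action", "forced", "n_offers", "budget"
)

#' Validate a long-format choice log
#'
#' Checks the serialized trial-log schema and its invariants: required
#' columns, value domains (token values, contingency indices, offer counts
#' 7-9, budgets 4-6), one record per offer index, accepts within budget,
#' forced records forming an all-nogo suffix exactly after budget exhaustion,
#' and a contingency trajectory consistent with [update_m()].
#'
#' @param data A choice-log data.frame (see [write_choice_log()] for the
#'   schema).
#' @param rule Contingency update rule the log is checked against.
#' @return Character vector of problems; empty when the log is valid.
#' @export
validate_choice_log <- function(data, rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  problems <- character()
  missing <- setdiff(CHOICE_LOG_COLUMNS, names(data))
  if (length(missing)) {
    return(sprintf("missing required columns: %s", paste(missing, collapse = ", ")))
  }
  if (nrow(data) == 0L) return("log contains no records")

  bad <- which(!(data$offer_value %in% TOKEN_VALUES))
  if (length(bad)) problems <- c(problems, sprintf(
    "offer_value outside {3,5,7} at rows: %s", paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!(data$m_at_offer %in% 0:2))
  if (length(bad)) problems <- c(problems, sprintf(
    "m_at_offer outside {0,1,2} at rows: %s", paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!(data$action %in% c("go", "nogo")))
  if (length(bad)) problems <- c(problems, sprintf(
    "action outside {go,nogo} at rows: %s", paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!(data$n_offers %in% 7:9) | !(data$budget %in% 4:6))
  if (length(bad)) problems <- c(problems, sprintf(
    "n_offers/budget outside the 7-9 / 4-6 design at rows: %s",
    paste(utils::head(bad, 5), collapse = ", ")))
  if (length(problems)) return(problems)

  key <- paste(data$subject_id, data$trial)
  rows_by_trial <- split(seq_len(nrow(data)), key)
  for (rows in rows_by_trial) {
    tr <- data[rows, ]
    lab <- sprintf("subject %s trial %s", tr$subject_id[1], tr$trial[1])
    ord <- order(tr$offer_index)
    tr <- tr[ord, ]
    rows <- rows[ord]
    if (!identical(as.integer(tr$offer_index), seq_len(tr$n_offers[1]))) {
      problems <- c(problems, sprintf(
        "%s: offer_index is not 1..n_offers (rows %s)", lab,
        paste(range(rows), collapse = "-")))
      next
    }
    go <- tr$action == "go"
    if (sum(go) > tr$budget[1]) {
      problems <- c(problems, sprintf(
        "%s: %d accepts exceed budget %d (rows %s)", lab, sum(go), tr$budget[1],
        paste(range(rows), collapse = "-")))
    }
    exhausted <- c(FALSE, cumsum(go) >= tr$budget[1])[seq_len(nrow(tr))]
    forced <- as.logical(tr$forced)
    if (!identical(forced, exhausted)) {
      problems <- c(problems, sprintf(
        "%s: forced flags do not match budget exhaustion (rows %s)", lab,
        paste(range(rows), collapse = "-")))
    }
    if (any(forced & go)) {
      problems <- c(problems, sprintf("%s: forced records must be nogo", lab))
    }
    m <- 0L
    n_rej <- 0L
    for (i in seq_len(nrow(tr))) {
      if (tr$m_at_offer[i] != m) {
        problems <- c(problems, sprintf(
          "%s: m_at_offer %d at offer %d inconsistent with the update rule (expected %d, row %d)",
          lab, tr$m_at_offer[i], tr$offer_index[i], m, rows[i]))
        break
      }
      m <- update_m(m, tr$action[i], tr$offer_value[i], tr$offer_index[i],
                    n_rej, rule = rule)
      if (tr$action[i] == "nogo") n_rej <- n_rej + 1L
    }
  }
  problems
}

assert_choice_log <- function(data, rule = "literal") {
  problems <- validate_choice_log(data, rule = rule)
  if (length(problems)) {
    stop("invalid choice log:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a choice log
#'
#' Long-format CSV (or JSON mirror) with columns `subject_id`, `trial`,
#' `session`, `offer_index`, `offer_value`, `m_at_offer`, `action` (go/nogo),
#' `forced` (0/1), `n_offers`, `budget`. UTF-8, header row mandatory.
#'
#' @param data Choice-log data.frame.
#' @param path Output/input file path; format chosen by extension
#'   (`.json` for JSON, CSV otherwise).
#' @param validate Validate against the schema (default `TRUE`).
#' @return `write_choice_log()` returns `path` invisibly; `read_choice_log()`
#'   returns the data.frame.
#' @export
write_choice_log <- function(data, path, validate = TRUE) {
  if (validate) assert_choice_log(data)
  out <- data[, CHOICE_LOG_COLUMNS]
  out$forced <- as.integer(out$forced)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "columns", digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_choice_log
#' @export
read_choice_log <- function(path, validate = TRUE) {
  data <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  data$forced <- as.logical(data$forced)
  if (validate) assert_choice_log(data)
  data
}

#' Annotate a choice log with model quantities
#'
#' Adds, per record, the number of prior accepts and rejections within the
#' trial, and joins the optimal agent's values at the record's belief state:
#' `EV` (long-term value of accepting), `V_R` and `V_AF`. These are the
#' decision-value inputs of every choice model.
#'
#' @param data Validated choice-log data.frame.
#' @param rule Contingency update rule used by the solver.
#' @return The input with columns `n_accepted_prior`, `n_rejected_prior`,
#'   `EV`, `V_R`, `V_AF` appended.
#' @export
augment_choice_log <- function(data, rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  ord <- order(data$subject_id, data$trial, data$offer_index)
  data <- data[ord, ]
  go <- as.integer(data$action == "go")
  key <- paste(data$subject_id, data$trial)
  cum_go <- stats::ave(go, key, FUN = cumsum)
  data$n_accepted_prior <- as.integer(cum_go - go)
  data$n_rejected_prior <- as.integer(data$offer_index - 1L - data$n_accepted_prior)
  ev <- ev_table(rule = rule)
  idx <- match(
    paste(data$offer_index - 1L, data$n_accepted_prior, data$m_at_offer,
          data$offer_value),
    paste(ev$offers_seen, ev$n_accepted, ev$m, ev$IR)
  )
  # Forced records beyond the free-choice state space (e.g. after a sixth
  # accept) carry no decision value; they are excluded from all likelihoods.
  if (any(is.na(idx) & !data$forced)) {
    stop("free-choice records map outside the reachable state space",
         call. = FALSE)
  }
  data$EV <- ev$EV[idx]
  data$V_R <- ev$V_R[idx]
  data$V_AF <- ev$V_AF[idx]
  rownames(data) <- NULL
  data
}
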