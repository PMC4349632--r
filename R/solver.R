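# Belief-state dynamic programming for the optimal agent.
#
# The player never observes the trial's true offer count (7-9) or accept
# budget (4-6) directly; both are represented by uniform count beliefs that
# shift left as offers pass and accepts are spent. A state is the pair of
# count beliefs plus the contingency index m and its update-eligibility
# context. Because both beliefs are deterministic functions of the number of
# offers seen and accepts used, states are keyed by integer counts and the
# value recursion is memoized on that key.

#' Count belief
#'
#' Probability distribution over a nonnegative integer count (offers
#' remaining, accepts remaining).
#'
#' @param support Strictly increasing integer counts.
#' @param probs Matching nonnegative weights summing to 1 (tolerance 1e-12).
#' @return A `count_belief` object (list with `support`, `probs`).
#' @export
count_belief <- function(support, probs) {
  support <- as.integer(support)
  probs <- as.numeric(probs)
  if (length(support) != length(probs) || length(support) == 0L) {
    stop("`support` and `probs` must be non-empty and of equal length", call. = FALSE)
  }
  if (is.unsorted(support, strictly = TRUE)) {
    stop("`support` must be strictly increasing", call. = FALSE)
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12) {
    stop("`probs` must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(list(support = support, probs = probs), class = "count_belief")
}

#' Shift a count belief left by one
#'
#' Conditional update after a count is consumed: `P'(c) = P(c + 1) / Z`.
#' A uniform belief remains uniform but shifts to the left; mass that would
#' fall on zero is dropped and the rest renormalized.
#'
#' @param belief A [count_belief()].
#' @return The shifted `count_belief`.
#' @export
shift_belief <- function(belief) {
  stopifnot(inherits(belief, "count_belief"))
  keep <- belief$support > 1L
  z <- sum(belief$probs[keep])
  if (z <= 0) {
    stop("shift undefined: no mass above 1 (terminal state)", call. = FALSE)
  }
  count_belief(belief$support[keep] - 1L, belief$probs[keep] / z)
}

#' Probability that more than one count remains
#'
#' `P(count > 1)`: the probability that the process continues past the
#' current step. The value recursion terminates when this is 0 for either
#' belief.
#'
#' @param belief A [count_belief()].
#' @return Probability in `[0, 1]`.
#' @export
p_continue <- function(belief) {
  stopifnot(inherits(belief, "count_belief"))
  sum(belief$probs[belief$support > 1L])
}

# Beliefs after s offers seen / a accepts used are pure left-shifts of the
# trial-onset uniforms; compute them directly from counts.
offers_belief <- function(offers_seen) {
  b <- count_belief(7:9, rep(1 / 3, 3))
  if (offers_seen > 0L) for (i in seq_len(offers_seen)) b <- shift_belief(b)
  b
}

accepts_belief <- function(n_accepted) {
  b <- count_belief(4:6, rep(1 / 3, 3))
  if (n_accepted > 0L) for (i in seq_len(n_accepted)) b <- shift_belief(b)
  b
}

#' Belief state of the optimal agent
#'
#' The agent's state at an offer: belief `O` over offers remaining, belief
#' `A` over accepts remaining, the contingency index `m`, the capped count
#' of prior rejections that governs update eligibility, and whether this is
#' the first offer. Both beliefs are determined by the counts of offers seen
#' and accepts used, which therefore form the canonical state key.
#'
#' @param offers_seen Offers already responded to (0-8).
#' @param n_accepted Accepts already used (0-5), at most `offers_seen`.
#' @param m Contingency index in 0..2.
#' @return A `belief_state` object.
#' @examples
#' initial_beliefs()
#' belief_state(offers_seen = 1, n_accepted = 0, m = 0) # second offer
#' @export
belief_state <- function(offers_seen = 0L, n_accepted = 0L, m = 0L) {
  offers_seen <- as.integer(offers_seen)
  n_accepted <- as.integer(n_accepted)
  m <- as.integer(m)
  if (offers_seen < 0L || offers_seen > 8L) {
    stop("`offers_seen` must be in 0..8", call. = FALSE)
  }
  if (n_accepted < 0L || n_accepted > 5L || n_accepted > offers_seen) {
    stop("`n_accepted` must be in 0..5 and at most `offers_seen`", call. = FALSE)
  }
  if (!(m %in% 0:2)) stop("`m` must be in {0, 1, 2}", call. = FALSE)
  structure(list(
    O = offers_belief(offers_seen),
    A = accepts_belief(n_accepted),
    m = m,
    offers_seen = offers_seen,
    n_accepted = n_accepted,
    n_rejected_capped = min(offers_seen - n_accepted, 3L),
    is_first_offer = offers_seen == 0L
  ), class = "belief_state")
}

#' @rdname belief_state
#' @export
initial_beliefs <- function() belief_state(0L, 0L, 0L)

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf(
    "<belief_state> offers_seen=%d n_accepted=%d m=%d (rejected %d%s)\n",
    x$offers_seen, x$n_accepted, x$m, x$n_rejected_capped,
    if (x$is_first_offer) ", first offer" else ""))
  cat("  O:", paste(sprintf("%d:%.3f", x$O$support, x$O$probs), collapse = " "), "\n")
  cat("  A:", paste(sprintf("%d:%.3f", x$A$support, x$A$probs), collapse = " "), "\n")
  invisible(x)
}

# Memoization caches, one per update rule.
.solver_caches <- new.env(parent = emptyenv())

solver_cache <- function(rule) {
  if (is.null(.solver_caches[[rule]])) {
    .solver_caches[[rule]] <- new.env(parent = emptyenv())
  }
  .solver_caches[[rule]]
}

# Core memoized recursion over the canonical integer key (s, a, m).
#
# SV(s, a, m) = sum_r M_m(r) * max( P(o>1) * SV(s+1, a, m),
#                                   r + P(o>1) * P(a>1) * SV(s+1, a+1, m_r) )
# where m_r is the contingency after accepting value r at offer index s + 1
# with s - a prior rejections, and the reject branch implicitly increments
# the rejection count because s advances while a does not. Terminal states
# (P(o>1) = 0) are worth the mean of the current offer distribution, since
# the final offer is always worth accepting when an accept remains.
sv_counts <- function(s, a, m, rule) {
  cache <- solver_cache(rule)
  key <- paste(s, a, m, sep = ".")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)

  pm <- offer_probs(m)
  p_o <- p_continue(offers_belief(s))
  value <- if (p_o <= 0) {
    sum(pm * TOKEN_VALUES)
  } else {
    p_a <- p_continue(accepts_belief(a))
    reject_v <- p_o * sv_counts(s + 1L, a, m, rule)
    accept_v <- vapply(TOKEN_VALUES, function(r) {
      cont <- if (p_a > 0) {
        m_r <- update_m(m, "go", r, offer_index = s + 1L,
                        n_rejected = s - a, rule = rule)
        p_o * p_a * sv_counts(s + 1L, a + 1L, m_r, rule)
      } else 0
      r + cont
    }, numeric(1))
    sum(pm * pmax(reject_v, accept_v))
  }
  cache[[key]] <- value
  value
}

#' State value of the optimal agent
#'
#' Expected total tokens obtainable from a belief state onward under the
#' optimal policy, computed by the memoized finite-horizon recursion over
#' the left-shifting count beliefs. The expectation runs over the
#' forthcoming offer's value; for each value the agent takes the better of
#' rejecting (belief over offers remaining shifts) and accepting (both
#' beliefs shift, the contingency updates).
#'
#' @param state A [belief_state()].
#' @param rule Contingency update rule, see [update_m()].
#' @return Expected tokens (scalar).
#' @export
state_value <- function(state, rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  stopifnot(inherits(state, "belief_state"))
  sv_counts(state$offers_seen, state$n_accepted, state$m, rule)
}

#' Action values at a belief state
#'
#' `value_reject()` is the expected future reward of rejecting the current
#' offer (`V_R`); `value_accept_future()` is the expected future reward after
#' accepting an offer of value `r`, excluding its face value (`V_AF`);
#' `long_term_value()` is the expected-value difference of accepting versus
#' rejecting, `EV = V_AF + IR - V_R`, the task's long-term value of a go
#' response.
#'
#' @param state A [belief_state()].
#' @param r,IR Token value of the current offer (3, 5 or 7).
#' @param rule Contingency update rule, see [update_m()].
#' @return Scalar value in expected tokens.
#' @examples
#' s2 <- belief_state(offers_seen = 1, n_accepted = 0, m = 0)
#' long_term_value(s2, 7) # negative: accepting 7 early is penalized
#' long_term_value(s2, 5) # positive
#' @export
value_reject <- function(state, rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  stopifnot(inherits(state, "belief_state"))
  p_o <- p_continue(state$O)
  if (p_o <= 0) return(0)
  p_o * sv_counts(state$offers_seen + 1L, state$n_accepted, state$m, rule)
}

#' @rdname value_reject
#' @export
value_accept_future <- function(state, r, rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  stopifnot(inherits(state, "belief_state"), r %in% TOKEN_VALUES)
  p_o <- p_continue(state$O)
  p_a <- p_continue(state$A)
  if (p_o <= 0 || p_a <= 0) return(0)
  m_r <- update_m(state$m, "go", r, offer_index = state$offers_seen + 1L,
                  n_rejected = state$offers_seen - state$n_accepted, rule = rule)
  p_o * p_a * sv_counts(state$offers_seen + 1L, state$n_accepted + 1L, m_r, rule)
}

#' @rdname value_reject
#' @export
long_term_value <- function(state, IR, rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  value_accept_future(state, IR, rule = rule) + IR - value_reject(state, rule = rule)
}

#' Brute-force state value (verification oracle)
#'
#' Recomputes [state_value()] by exhaustive un-memoized recursion directly on
#' explicit belief objects, with the contingency rule written out inline.
#' Shares no cache or state-keying with the production solver; used to verify
#' it.
#'
#' @param state A [belief_state()].
#' @param rule Contingency update rule.
#' @return Expected tokens (scalar).
#' @export
brute_force_sv <- function(state, rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  stopifnot(inherits(state, "belief_state"))
  values <- c(3, 5, 7)
  recurse <- function(O, A, m, n_rej, first) {
    pm <- switch(as.character(m),
      "0" = c(1, 1, 1) / 3, "1" = c(0.5, 0.25, 0.25), "2" = c(0.9, 0.05, 0.05))
    p_o <- sum(O$probs[O$support > 1])
    if (p_o <= 0) return(sum(pm * values))
    p_a <- sum(A$probs[A$support > 1])
    O2 <- shift_belief(O)
    rej <- p_o * recurse(O2, A, m, min(n_rej + 1, 3), FALSE)
    total <- 0
    for (i in 1:3) {
      r <- values[i]
      acc <- r
      if (p_a > 0) {
        m_r <- m
        if (!first && n_rej < 3 && rule != "none") {
          cand <- if (r == 5) 1L else if (r == 7) 2L else m
          m_r <- if (rule == "monotone") max(m, cand) else cand
        }
        acc <- acc + p_o * p_a * recurse(O2, shift_belief(A), m_r, n_rej, FALSE)
      }
      total <- total + pm[i] * max(rej, acc)
    }
    total
  }
  recurse(state$O, state$A, state$m, state$n_rejected_capped, state$is_first_offer)
}

# -- state enumeration and tables --------------------------------------------

#' Enumerate reachable belief states
#'
#' Breadth-first enumeration of every (offers_seen, n_accepted, m) state
#' reachable from the trial-onset state via accept/reject transitions, i.e.
#' every state at which a free choice can occur.
#'
#' @param rule Contingency update rule.
#' @return data.frame with columns `offers_seen`, `n_accepted`,
#'   `n_rejected`, `m`, `is_first_offer`.
#' @export
reachable_states <- function(rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  seen <- new.env(parent = emptyenv())
  frontier <- list(c(0L, 0L, 0L))
  seen[["0.0.0"]] <- TRUE
  out <- list(c(0L, 0L, 0L))
  while (length(frontier)) {
    nxt <- list()
    for (st in frontier) {
      s <- st[1]; a <- st[2]; m <- st[3]
      if (s >= 8L) next
      kids <- list(c(s + 1L, a, m)) # reject
      if (a < 5L) { # accept remains a free-choice state only while a + 1 <= 5
        m_r <- vapply(TOKEN_VALUES, function(r) {
          update_m(m, "go", r, offer_index = s + 1L, n_rejected = s - a,
                   rule = rule)
        }, integer(1))
        for (mm in unique(m_r)) kids <- c(kids, list(c(s + 1L, a + 1L, mm)))
      }
      for (k in kids) {
        key <- paste(k, collapse = ".")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out <- c(out, list(k))
          nxt <- c(nxt, list(k))
        }
      }
    }
    frontier <- nxt
  }
  states <- do.call(rbind, out)
  df <- data.frame(offers_seen = states[, 1], n_accepted = states[, 2],
                   m = states[, 3])
  df$n_rejected <- pmin(df$offers_seen - df$n_accepted, 3L)
  df$is_first_offer <- df$offers_seen == 0L
  df <- df[order(df$offers_seen, df$n_accepted, df$m),
           c("offers_seen", "n_accepted", "n_rejected", "m", "is_first_offer")]
  rownames(df) <- NULL
  df
}

#' Optimal policy and value table
#'
#' Enumerates all reachable belief states crossed with the three possible
#' current-offer values and tabulates `V_R`, `V_AF`, `EV` and the optimal
#' action (accept iff `EV >= 0`; exact indifference is resolved to accept).
#'
#' @param rule Contingency update rule.
#' @param path Optional CSV output path (values rounded to 3 decimals on
#'   export only).
#' @return data.frame with columns `offers_seen`, `n_accepted`, `n_rejected`,
#'   `m`, `is_first_offer`, `IR`, `V_R`, `V_AF`, `EV`, `action`.
#' @export
optimal_policy_table <- function(rule = c("literal", "monotone", "none"),
                                 path = NULL) {
  rule <- match.arg(rule)
  states <- reachable_states(rule = rule)
  tab <- merge(states, data.frame(IR = TOKEN_VALUES))
  tab <- tab[order(tab$offers_seen, tab$n_accepted, tab$m, tab$IR), ]
  vals <- t(mapply(function(s, a, m, ir) {
    st <- belief_state(s, a, m)
    vr <- value_reject(st, rule = rule)
    vaf <- value_accept_future(st, ir, rule = rule)
    c(vr, vaf, vaf + ir - vr)
  }, tab$offers_seen, tab$n_accepted, tab$m, tab$IR))
  tab$V_R <- vals[, 1]
  tab$V_AF <- vals[, 2]
  tab$EV <- vals[, 3]
  tab$action <- ifelse(tab$EV >= 0, "go", "nogo")
  rownames(tab) <- NULL
  if (!is.null(path)) {
    out <- tab
    out[c("V_R", "V_AF", "EV")] <- lapply(out[c("V_R", "V_AF", "EV")], round, 3)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  tab
}

#' Long-term value lookup table
#'
#' Per reachable state and offer value: `V_R`, `V_AF`, `EV`. Used to join
#' solver values onto choice logs before likelihood evaluation.
#'
#' @param rule Contingency update rule.
#' @return data.frame keyed by (`offers_seen`, `n_accepted`, `m`, `IR`).
#' @export
ev_table <- function(rule = c("literal", "monotone", "none")) {
  rule <- match.arg(rule)
  key <- paste0("ev_table_", rule)
  hit <- .solver_caches[[key]]
  if (is.null(hit)) {
    hit <- optimal_policy_table(rule = rule)[
      , c("offers_seen", "n_accepted", "m", "IR", "V_R", "V_AF", "EV")]
    .solver_caches[[key]] <- hit
  }
  hit
}
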