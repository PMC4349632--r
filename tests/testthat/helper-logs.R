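# Build deterministic, invariant-satisfying choice logs by replaying chosen
# offer values and actions through the trial state machine.

make_trial_log <- function(values, actions, n_offers = length(values),
                           budget = 4L, subject = "S01", trial = 1L,
                           session = 1L, rule = "literal") {
  stopifnot(length(values) == n_offers, length(actions) == n_offers)
  state <- new_trial(n_offers, budget, first_value = values[1], rule = rule)
  for (i in seq_len(n_offers)) {
    nxt <- if (i < n_offers) values[i + 1] else NULL
    state <- step_trial(state, actions[i], next_value = nxt)
  }
  rec <- state$records
  data.frame(subject_id = subject, trial = trial, session = session,
             offer_index = rec$offer_index, offer_value = rec$offer_value,
             m_at_offer = rec$m_at_offer, action = rec$action,
             forced = rec$forced, n_offers = n_offers, budget = budget)
}

# Concatenate trial logs with sequential trial numbers.
make_subject_log <- function(trials, subject = "S01") {
  do.call(rbind, lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    tr$trial <- i
    tr$subject_id <- subject
    tr
  }))
}

# A small, fast synthetic group for fitting tests.
small_group <- function(n_subjects = 6L, trials = 24L, model = "trade1",
                        seed = 42L, ...) {
  generate_group(group_design(
    n_subjects = n_subjects, n_sessions = 1L, trials_per_session = trials,
    model = model, seed = seed, ...))
}
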