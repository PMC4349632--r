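# Task engine: contingency distributions, update rule, trial mechanics.

test_that("offer distributions match the instructed contingencies", {
  expect_equal(unname(offer_probs(0)), rep(1 / 3, 3))
  expect_equal(unname(offer_probs(1)), c(0.50, 0.25, 0.25))
  expect_equal(unname(offer_probs(2)), c(0.90, 0.05, 0.05))
  for (m in 0:2) expect_equal(sum(offer_probs(m)), 1)
  expect_error(offer_probs(3), "contingency index")
  expect_error(offer_probs(-1), "contingency index")
})

test_that("contingency update follows the instructed rule", {
  # accepting a 7 (not first offer, < 3 rejections) triggers the harsh shift
  expect_identical(update_m(0, "go", 7, offer_index = 3, n_rejected = 0), 2L)
  # accepting a 5 triggers the moderate shift
  expect_identical(update_m(0, "go", 5, offer_index = 2, n_rejected = 0), 1L)
  # first offer is exempt
  expect_identical(update_m(0, "go", 7, offer_index = 1, n_rejected = 0), 0L)
  # three or more prior rejections lock the distribution
  expect_identical(update_m(0, "go", 7, offer_index = 5, n_rejected = 3), 0L)
  expect_identical(update_m(1, "go", 7, offer_index = 6, n_rejected = 4), 1L)
  # rejecting never shifts m; accepting a 3 never shifts m
  expect_identical(update_m(0, "nogo", 7, offer_index = 2, n_rejected = 0), 0L)
  expect_identical(update_m(0, "go", 3, offer_index = 2, n_rejected = 0), 0L)
  # literal most-recent-choice rule lets a 5 relax a harsh state
  expect_identical(update_m(2, "go", 5, offer_index = 4, n_rejected = 1), 1L)
  # ... unless the monotone variant is requested
  expect_identical(
    update_m(2, "go", 5, offer_index = 4, n_rejected = 1, rule = "monotone"), 2L)
  expect_identical(
    update_m(0, "go", 7, offer_index = 4, n_rejected = 1, rule = "none"), 0L)
})

test_that("trial configurations are uniform and independent over the design", {
  set.seed(11)
  cfg <- draw_trial_config(90000L)
  expect_true(all(cfg$n_offers %in% 7:9))
  expect_true(all(cfg$budget %in% 4:6))
  # each of the 9 combinations within 3 standard errors of 1/9
  freq <- table(cfg$n_offers, cfg$budget) / nrow(cfg)
  expect_length(freq, 9L)
  se <- sqrt((1 / 9) * (8 / 9) / nrow(cfg))
  expect_true(all(abs(freq - 1 / 9) < 3 * se))
  # determinism under a fixed seed
  set.seed(77)
  a <- draw_trial_config(50L)
  set.seed(77)
  b <- draw_trial_config(50L)
  expect_identical(a, b)
})

test_that("offer sampling follows the contingency distribution", {
  set.seed(5)
  x <- sample_offer(2, 10000L)
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(mean(x == 3) - 0.9), 3 * se)
  set.seed(6)
  y <- sample_offer(0, 10000L)
  expect_setequal(unique(y), c(3, 5, 7))
  set.seed(9)
  a <- sample_offer(1, 100L)
  set.seed(9)
  b <- sample_offer(1, 100L)
  expect_identical(a, b)
})

test_that("stepping a trial enforces the budget and updates the contingency", {
  # accepting a 7 on the first offer leaves m unchanged
  st <- new_trial(7, 4, first_value = 7)
  st <- step_trial(st, "go", next_value = 7)
  expect_identical(st$m, 0L)
  expect_identical(st$n_accepted, 1L)
  # accepting a 7 on the second offer shifts m to 2
  st <- step_trial(st, "go", next_value = 3)
  expect_identical(st$m, 2L)
  # exhausting the budget coerces further responses to forced nogo
  st <- new_trial(7, 4, first_value = 5)
  for (i in 1:4) st <- step_trial(st, "go", next_value = 5)
  expect_true(st$budget_exhausted)
  st <- step_trial(st, "go", next_value = 5) # attempted go is coerced
  rec <- st$records
  expect_identical(rec$action[5], "nogo")
  expect_true(rec$forced[5])
  # stepping past the final offer errors
  st <- step_trial(st, "nogo", next_value = 3)
  st <- step_trial(st, "nogo")
  expect_true(st$done)
  expect_error(step_trial(st, "nogo"), "final offer")
})

test_that("trial payout sums accepted values and enforces log invariants", {
  log <- make_trial_log(values = c(7, 3, 5, 3, 3, 3, 3),
                        actions = c("go", "nogo", "go", "go", rep("nogo", 3)))
  expect_identical(trial_payout(log), 15L)
  all_nogo <- simulate_trial(8, 5, choose = function(s) "nogo")
  expect_identical(trial_payout(all_nogo), 0L)
  expect_identical(sum(all_nogo$records$action == "go"), 0L)
  # hand-built log with accepts exceeding the budget is rejected
  bad <- log
  bad$action <- "go"
  expect_error(trial_payout(bad), "budget")
  expect_error(trial_payout(log[1:3, ]), "incomplete")
})

test_that("simulated trials satisfy the structural invariants", {
  set.seed(101)
  for (i in 1:40) {
    p_go <- runif(1)
    tr <- simulate_trial(choose = function(s) {
      if (runif(1) < p_go) "go" else "nogo"
    })
    rec <- tr$records
    expect_identical(nrow(rec), tr$n_offers)
    expect_lte(sum(rec$action == "go"), tr$budget)
    # forced flags form a suffix, all nogo
    expect_false(is.unsorted(rec$forced))
    expect_true(all(rec$action[rec$forced] == "nogo"))
    # m trajectory consistent with update_m, locked after 3 rejections
    m <- 0L
    n_rej <- 0L
    for (j in seq_len(nrow(rec))) {
      expect_identical(rec$m_at_offer[j], m)
      if (n_rej >= 3L) {
        m_next <- update_m(m, rec$action[j], rec$offer_value[j], j, n_rej)
        expect_identical(m_next, m)
      }
      m <- update_m(m, rec$action[j], rec$offer_value[j], j, n_rej)
      if (rec$action[j] == "nogo") n_rej <- n_rej + 1L
    }
  }
})

test_that("choice-log validation flags broken invariants with row context", {
  g <- small_group(n_subjects = 2L, trials = 6L)
  expect_length(validate_choice_log(g$log), 0L)
  # accepts exceeding the budget
  bad <- g$log
  bad$action <- "go"
  bad$forced <- FALSE
  expect_true(any(grepl("exceed budget", validate_choice_log(bad))))
  # inconsistent contingency trajectory
  bad2 <- g$log
  bad2$m_at_offer[2] <- (bad2$m_at_offer[2] + 1L) %% 3L
  expect_true(any(grepl("inconsistent with the update rule",
                        validate_choice_log(bad2))))
  # missing columns reported
  expect_match(validate_choice_log(g$log[, 1:4]), "missing required columns")
})

test_that("choice logs round-trip through CSV and JSON", {
  g <- small_group(n_subjects = 2L, trials = 5L)
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_choice_log(g$log, csv)
  write_choice_log(g$log, json)
  back_csv <- read_choice_log(csv)
  back_json <- read_choice_log(json)
  for (back in list(back_csv, back_json)) {
    expect_identical(nrow(back), nrow(g$log))
    expect_equal(back$offer_value, g$log$offer_value)
    expect_equal(back$action, g$log$action)
    expect_equal(back$forced, as.logical(g$log$forced))
  }
  unlink(c(csv, json))
})

test_that("augmentation recounts prior accepts/rejections correctly", {
  g <- small_group(n_subjects = 3L, trials = 10L)
  aug <- augment_choice_log(g$log)
  # independent recount per record
  for (k in sample(nrow(aug), 50L)) {
    row <- aug[k, ]
    hist <- aug[aug$subject_id == row$subject_id & aug$trial == row$trial &
                  aug$offer_index < row$offer_index, ]
    expect_identical(row$n_accepted_prior, sum(hist$action == "go"))
    expect_identical(row$n_rejected_prior, sum(hist$action == "nogo"))
  }
  # joined EV agrees with the solver at the record's belief state
  free <- aug[!aug$forced, ]
  for (k in sample(nrow(free), 20L)) {
    row <- free[k, ]
    st <- belief_state(row$offer_index - 1L, row$n_accepted_prior, row$m_at_offer)
    expect_equal(row$EV, long_term_value(st, row$offer_value))
  }
})
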