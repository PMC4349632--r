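# Acceptance grids, decorrelated-offer selection, robust logistic
# regression, group tests.

test_that("grid cells pool acceptance counts with the display threshold", {
  # 20 trials: first offer (value 3) rejected, then a value-7 offer at
  # index 2 accepted in 12 and rejected in 8; rest rejected
  trials <- lapply(1:20, function(i) {
    make_trial_log(values = c(3, 7, rep(3, 5)),
                   actions = c("nogo", if (i <= 12) "go" else "nogo",
                               rep("nogo", 5)))
  })
  log <- make_subject_log(trials)
  grid <- acceptance_grid(log, min_count = 15)
  cell <- grid[grid$offer_index == 2 & grid$n_rejected == 1 &
                 grid$offer_value == 7, ]
  expect_identical(cell$n_obs, 20L)
  expect_equal(cell$p_accept, 0.6)
  expect_true(cell$included)
  # with only 14 trials the same cell is excluded from display
  log14 <- make_subject_log(trials[1:14])
  grid14 <- acceptance_grid(log14, min_count = 15)
  cell14 <- grid14[grid14$offer_index == 2 & grid14$n_rejected == 1 &
                     grid14$offer_value == 7, ]
  expect_identical(cell14$n_obs, 14L)
  expect_false(cell14$included)
  # all-nogo data: every populated cell has probability zero
  nogo <- make_subject_log(lapply(1:16, function(i) {
    make_trial_log(values = rep(3, 7), actions = rep("nogo", 7))
  }))
  gn <- acceptance_grid(nogo)
  expect_true(all(gn$p_accept[gn$n_obs > 0] == 0))
})

test_that("the grid is restricted to uniform-distribution free choices", {
  # accepting a 5 at index 2 shifts m; later offers must not enter the grid
  log <- make_subject_log(lapply(1:16, function(i) {
    make_trial_log(values = c(3, 5, 7, 3, 3, 3, 3),
                   actions = c("nogo", "go", rep("nogo", 5)))
  }))
  grid <- acceptance_grid(log, min_count = 1)
  expect_identical(sum(grid$n_obs), 2L * 16L) # only indexes 1 and 2 qualify
  # independent recount on a simulated dataset
  g <- small_group(n_subjects = 3L, trials = 20L, seed = 14)
  aug <- augment_choice_log(g$log)
  grid2 <- acceptance_grid(g$log, min_count = 5)
  free <- aug[!aug$forced & aug$m_at_offer == 0, ]
  for (k in sample(which(grid2$n_obs > 0), 10L)) {
    cell <- grid2[k, ]
    sel <- free[free$offer_index == cell$offer_index &
                  free$n_rejected_prior == cell$n_rejected &
                  free$offer_value == cell$offer_value, ]
    expect_identical(cell$n_obs, nrow(sel))
    expect_equal(cell$p_accept, mean(sel$action == "go"))
  }
})

test_that("decorrelated-offer selection applies index, state and forcing rules", {
  g <- small_group(n_subjects = 2L, trials = 20L, seed = 15)
  aug <- augment_choice_log(g$log)
  sel <- select_decorrelated_offers(g$log)
  expect_true(all(sel$offer_index %in% 2:3))
  expect_true(all(sel$m_at_offer == 0))
  expect_true(all(!sel$forced))
  # complement check: no qualifying record left behind
  should <- aug[!aug$forced & aug$offer_index %in% 2:3 & aug$m_at_offer == 0, ]
  expect_identical(nrow(sel), nrow(should))
  # order invariance
  set.seed(2)
  sel2 <- select_decorrelated_offers(g$log[sample(nrow(g$log)), ])
  expect_equal(sel2$EV, sel$EV)
  expect_equal(sel2$trial, sel$trial)
})

test_that("regression recovers positive value effects and handles nulls", {
  # choices driven by both immediate and long-term value
  g <- generate_group(group_design(
    n_subjects = 2L, n_sessions = 1L, trials_per_session = 250L,
    model = "trade1", seed = 16,
    param_means = c(tau = 1.5, c_int = 5, w = 0.5),
    param_sds = c(tau = 0.01, c_int = 0.01, w = 0.01)))
  reg <- robust_logistic(g$log)
  expect_true(all(reg$beta[reg$term == "IR"] > 0))
  expect_true(all(reg$beta[reg$term == "EV"] > 0))
  expect_true(all(!reg$excluded))
  # coin-flip choices: betas indistinguishable from zero
  coin <- generate_group(group_design(
    n_subjects = 2L, n_sessions = 1L, trials_per_session = 250L,
    model = "optimal", seed = 17,
    param_means = c(tau = 1e-4), param_sds = c(tau = 1e-6)))
  reg0 <- robust_logistic(coin$log)
  for (term in c("IR", "EV")) {
    b <- reg0[reg0$term == term, ]
    expect_true(all(abs(b$beta) < 3 * b$se))
  }
  # plain (non-robust) fit agrees with glm on the same data
  one <- augment_choice_log(coin$log)
  one <- one[one$subject_id == "S01" & !one$forced, ]
  ours <- robust_logistic(one, robust = FALSE)
  ref <- glm(I(action == "go") ~ offer_value + EV, binomial(), data = one)
  expect_equal(ours$beta, unname(coef(ref)), tolerance = 1e-5)
})

test_that("degenerate regression inputs are flagged, not fatal", {
  g <- small_group(n_subjects = 1L, trials = 30L, seed = 18)
  aug <- augment_choice_log(g$log)
  aug$EV <- 1.5 # constant regressor
  expect_warning(reg <- robust_logistic(aug), "constant regressor")
  expect_true(all(reg$excluded))
  # one-sided responders are excluded silently
  nogo <- make_subject_log(lapply(1:10, function(i) {
    make_trial_log(values = rep(5, 7), actions = rep("nogo", 7))
  }))
  reg2 <- robust_logistic(nogo)
  expect_true(all(reg2$excluded))
})

test_that("group t-tests behave at their boundary cases", {
  sym <- c(-2, -1, 1, 2)
  tt <- group_ttest(sym)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_identical(tt$df, 3)
  flat <- group_ttest(rep(0.4, 5))
  expect_true(flat$degenerate)
  expect_equal(flat$mean, 0.4)
  expect_error(group_ttest(0.3), "at least 2")
})

test_that("value effects reach group significance at the study scale", {
  g <- generate_group(group_design(
    n_subjects = 23L, n_sessions = 1L, trials_per_session = 36L,
    model = "trade1", seed = 19,
    param_means = c(tau = 1.5, c_int = 5, w = 0.5),
    param_sds = c(tau = 0.3, c_int = 0.3, w = 0.1)))
  res <- analyze_choices(g$log)
  tests <- res$group_tests
  both <- tests[tests$subset == "all", ]
  expect_true(all(both$p < 0.05))
  expect_true(all(both$mean_beta > 0))
})

test_that("the fitted betas mirror the generating value signal", {
  # optimal-model choices load on EV, immediate-model choices on IR
  opt <- generate_group(group_design(
    n_subjects = 2L, n_sessions = 1L, trials_per_session = 250L,
    model = "optimal", seed = 20,
    param_means = c(tau = 2), param_sds = c(tau = 0.01)))
  reg_opt <- robust_logistic(opt$log, standardize = TRUE)
  imm <- generate_group(group_design(
    n_subjects = 2L, n_sessions = 1L, trials_per_session = 250L,
    model = "immediate", seed = 20,
    param_means = c(tau = 2, c_int = 5), param_sds = c(tau = 0.01, c_int = 0.01)))
  reg_imm <- robust_logistic(imm$log, standardize = TRUE)
  mean_beta <- function(reg, term) mean(reg$beta[reg$term == term & !reg$excluded])
  expect_gt(mean_beta(reg_opt, "EV"), mean_beta(reg_opt, "IR"))
  expect_gt(mean_beta(reg_imm, "IR"), mean_beta(reg_imm, "EV"))
})
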