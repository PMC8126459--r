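test_that("public goods payoffs match hand-worked compositions", {
  p <- tiny_params(4)

  all_coop <- play_economic_game(mixed_state(4, 0), p)
  expect_equal(all_coop$total_pot, 4)
  expect_equal(all_coop$share_per_agent, 2)
  expect_equal(all_coop$payoff, rep(11, 4))

  all_free <- play_economic_game(mixed_state(0, 4), p)
  expect_equal(all_free$total_pot, 0)
  expect_equal(all_free$payoff, rep(10, 4))

  mixed <- play_economic_game(mixed_state(2, 2), p)
  expect_equal(mixed$total_pot, 2)
  expect_equal(mixed$share_per_agent, 1)
  expect_equal(mixed$payoff, c(10, 10, 11, 11))
})

test_that("parameter validation names the offending field", {
  expect_error(model_params(group_size = 1), "group_size")
  expect_error(model_params(contribution_fraction = 0), "contribution_fraction")
  expect_error(model_params(contribution_fraction = 1.2), "contribution_fraction")
  expect_error(model_params(pot_multiplier = 0.5), "pot_multiplier")
  expect_error(model_params(fine_ratio = -1), "fine_ratio")
  expect_error(model_params(proposal_sd = -0.1), "proposal_sd")
  expect_error(model_params(fitness_floor = 0), "fitness_floor")
  expect_error(model_params(forecast_horizon = 0), "forecast_horizon")
})

test_that("within one round every free-rider out-earns every cooperator by the contribution", {
  # with a common pot, the only payoff difference at v = 0 is the foregone
  # contribution a itself
  p <- n100_params()
  a <- p$contribution_fraction * p$budget
  for (n_c in c(1, 37, 99)) {
    led <- play_economic_game(mixed_state(n_c, 100 - n_c), p)
    gap <- min(led$payoff[!mixed_state(n_c, 100 - n_c)$cooperator]) -
      max(led$payoff[mixed_state(n_c, 100 - n_c)$cooperator])
    expect_equal(gap, a, tolerance = 1e-12)
  }
})

test_that("punisher selection covers every free-rider once, never self, both types eligible", {
  set.seed(42)
  p <- tiny_params(6)
  st <- mixed_state(3, 3)
  led <- play_economic_game(st, p)

  seen_coop_punisher <- FALSE
  seen_free_punisher <- FALSE
  for (i in 1:500) {
    asg <- select_punishers(st, led)
    expect_equal(nrow(asg), 3)
    expect_setequal(asg[, "target"], which(!st$cooperator))
    expect_true(all(asg[, "punisher"] != asg[, "target"]))
    seen_coop_punisher <- seen_coop_punisher ||
      any(st$cooperator[asg[, "punisher"]])
    seen_free_punisher <- seen_free_punisher ||
      any(!st$cooperator[asg[, "punisher"]])
  }
  expect_true(seen_coop_punisher)
  expect_true(seen_free_punisher)

  # no free-riders: nothing to assign
  expect_equal(nrow(select_punishers(mixed_state(4, 0), led)), 0)

  # two mutual free-riders: the only legal assignment
  st2 <- mixed_state(0, 2)
  asg2 <- select_punishers(st2, play_economic_game(st2, tiny_params(2)))
  expect_equal(asg2[, "punisher"], c(2L, 1L), ignore_attr = TRUE)
})

test_that("punisher choice is uniform over the eligible agents", {
  set.seed(7)
  p <- tiny_params(4)
  st <- mixed_state(3, 1)  # agent 4 is the lone free-rider
  led <- play_economic_game(st, p)
  n_draws <- 2e4
  picks <- replicate(n_draws, select_punishers(st, led)[1, "punisher"])
  freq <- tabulate(picks, 4) / n_draws
  se <- sqrt((1 / 3) * (2 / 3) / n_draws)
  expect_equal(freq[4], 0)
  expect_true(all(abs(freq[1:3] - 1 / 3) < 3 * se + 1e-3))
})

test_that("punishment arithmetic matches the stated costs and fines", {
  p <- tiny_params(4)
  st <- mixed_state(3, 1, v = 1)
  led0 <- play_economic_game(st, p)
  set.seed(1)
  asg <- select_punishers(st, led0)
  led <- apply_punishment(led0, asg, 1, p)
  expect_equal(led$payoff[asg[1, "punisher"]],
               led0$payoff[asg[1, "punisher"]] - 1)
  expect_equal(led$payoff[4], led0$payoff[4] - 2)
  expect_equal(sum(led0$payoff) - sum(led$payoff), 3)

  # v = 0 leaves the ledger unchanged
  led_zero <- apply_punishment(led0, asg, 0, p)
  expect_identical(led_zero$payoff, led0$payoff)

  # two mutual free-riders at v = 1: each pays 1 as punisher + 2 as target
  p2 <- tiny_params(2)
  st2 <- mixed_state(0, 2, v = 1)
  led2 <- play_economic_game(st2, p2)
  asg2 <- select_punishers(st2, led2)
  led2 <- apply_punishment(led2, asg2, 1, p2)
  expect_equal(led2$payoff, c(7, 7))
})

test_that("ledger total equals N b + (m-1) C - (1 + fine_ratio) v n_f on randomized rounds", {
  set.seed(99)
  for (i in 1:400) {
    n <- sample(2:40, 1)
    prm <- model_params(group_size = n,
                        budget = runif(1, 1, 20),
                        contribution_fraction = runif(1, 0.05, 1),
                        pot_multiplier = runif(1, 1, n),
                        fine_ratio = runif(1, 0, 4))
    n_c <- sample(0:n, 1)
    v <- sample(c(0, runif(1, 0, 3)), 1)
    st <- mixed_state(n_c, n - n_c, v = v, shuffle = TRUE)
    led <- play_economic_game(st, prm)
    n_f <- n - n_c
    if (v > 0 && n_f > 0) {
      led <- apply_punishment(led, select_punishers(st, led), v, prm)
      expected <- n * prm$budget + (prm$pot_multiplier - 1) * led$total_pot -
        (1 + prm$fine_ratio) * v * n_f
    } else {
      expected <- n * prm$budget + (prm$pot_multiplier - 1) * led$total_pot
    }
    expect_equal(sum(led$payoff), expected, tolerance = 1e-9)
  }
})
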