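test_that("scheduling returns distinct ids and cancellation removes an agent's events", {
  q <- event_queue()
  ids <- vapply(1:5, function(i) eq_schedule(q, "action", agent = i %% 2, 3), integer(1))
  expect_identical(length(unique(ids)), 5L)
  expect_identical(length(q$id), 5L)
  removed <- eq_cancel(q, agent = 1)
  expect_identical(removed, 3L)            # events 1, 3, 5 belong to agent 1
  expect_identical(length(q$id), 2L)
  id <- eq_schedule(q, "death", agent = 9, 1)
  eq_cancel_event(q, id)
  expect_identical(length(q$id), 2L)       # net unchanged
  expect_error(eq_schedule(q, "x", 1, 0), "mean_wait")
  expect_error(eq_schedule(q, "x", 1, -2), "mean_wait")
})

test_that("events owned by a removed agent never fire", {
  set.seed(1)
  q <- event_queue()
  eq_schedule(q, "a", agent = 1, mean_wait = 0.01)  # would win every race
  eq_schedule(q, "b", agent = 2, mean_wait = 10)
  eq_cancel(q, agent = 1)
  for (i in 1:50) {
    ev <- eq_draw(q, t = 0)
    expect_identical(ev$agent, 2L)
    eq_schedule(q, "b", agent = 2, mean_wait = 10)
  }
})

test_that("the exponential race has the right waiting times and winner odds", {
  set.seed(2)
  # single event with mean wait tau: advances are Exp(tau) on average
  tau <- 4
  adv <- replicate(1e4, {
    q <- event_queue()
    eq_schedule(q, "a", 1, tau)
    eq_draw(q, t = 0)$time
  })
  expect_lt(abs(mean(adv) - tau), 3 * tau / sqrt(1e4))
  # two events, mean waits 1 and 3: first wins with probability 3/4
  wins <- replicate(1e4, {
    q <- event_queue()
    eq_schedule(q, "fast", 1, 1)
    eq_schedule(q, "slow", 2, 3)
    eq_draw(q, t = 0)$type == "fast"
  })
  expect_lt(abs(mean(wins) - 0.75), 3 * sqrt(0.75 * 0.25 / 1e4))
})

test_that("a frozen three-event race matches rate proportions and total rate", {
  set.seed(3)
  waits <- c(1, 2, 5)
  rates <- 1 / waits
  probs <- rates / sum(rates)
  n <- 1e4
  picks <- integer(n); adv <- numeric(n)
  for (i in seq_len(n)) {
    q <- event_queue()
    for (j in 1:3) eq_schedule(q, as.character(j), j, waits[j])
    ev <- eq_draw(q, t = 0)
    picks[i] <- as.integer(ev$type); adv[i] <- ev$time
  }
  emp <- tabulate(picks, 3) / n
  for (j in 1:3)
    expect_lt(abs(emp[j] - probs[j]), 3 * sqrt(probs[j] * (1 - probs[j]) / n))
  m <- 1 / sum(rates)                      # race minimum mean
  expect_lt(abs(mean(adv) - m), 3 * m / sqrt(n))
})

test_that("the queue race is deterministic under a fixed seed", {
  trace <- function() {
    set.seed(77)
    q <- event_queue()
    for (j in 1:4) eq_schedule(q, paste0("e", j), j, j)
    out <- list(); t <- 0
    for (i in 1:20) {
      ev <- eq_draw(q, t)
      t <- ev$time
      out[[i]] <- c(ev$type, format(t, digits = 17))
      eq_schedule(q, ev$type, ev$agent, ev$mean_wait)
    }
    out
  }
  expect_identical(trace(), trace())
})

test_that("logistic throttling is linear, clipped and only applied to births", {
  expect_identical(logistic_throttle(0.2, 0, 1000), 0.2)
  expect_identical(logistic_throttle(0.2, 500, 1000), 0.1)
  expect_identical(logistic_throttle(0.2, 1000, 1000), 0)
  expect_identical(logistic_throttle(0.2, 1500, 1000), 0)   # clipped at zero
  n <- seq(0, 2000, by = 50)
  eff <- logistic_throttle(1, n, 1000)
  expect_true(all(diff(eff) <= 0))                          # nonincreasing
  expect_error(logistic_throttle(1, 10, 0), "capacity")
  expect_error(logistic_throttle(1, -1, 10), ">= 0")
})

test_that("a pure logistic birth-death population saturates below its capacity", {
  set.seed(5)
  K <- 200; birth <- 1; death_wait <- 50
  n <- 10; t <- 0; traj <- n
  while (t < 2000 && n > 0) {
    q <- event_queue()
    rb <- logistic_throttle(birth, n, K)
    if (rb > 0) eq_schedule(q, "birth", 1, 1 / rb)
    eq_schedule(q, "death", 2, death_wait / n)
    ev <- eq_draw(q, t)
    t <- ev$time
    n <- n + if (ev$type == "birth") 1 else -1
    traj <- c(traj, n)
  }
  expect_true(all(traj <= K))
  # equilibrium n* solves birth*(1-n/K) = n/death_wait -> n* = 40
  m <- mean(tail(traj, 500))
  expect_gt(m, 20); expect_lt(m, 80)
})
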