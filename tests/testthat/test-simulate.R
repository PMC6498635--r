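test_that("the initial census matches the configured world and lymphocytes arrive at day 10", {
  s <- simulate_immune(fast_params(t_max = 300), seed = 1)
  ts <- s$timeseries
  first <- ts[1, ]
  expect_equal(first$t, 0)
  expect_equal(first$nW, 450)              # three self populations of 150
  expect_equal(first[, c("nR", "nB", "nAb", "nTh", "nIL")],
               data.frame(nR = 0, nB = 0, nAb = 0, nTh = 0, nIL = 0),
               ignore_attr = TRUE)
  # no circulating B or Th cells before step 100 (day 10)
  pre <- ts[ts$t < 100, ]
  expect_true(all(pre$nB == 0) && all(pre$nTh == 0))
  post <- ts[ts$t >= 200, ]
  expect_true(any(post$nB > 0) && any(post$nTh > 0))
})

test_that("a run is a deterministic function of parameters and seed", {
  p <- fast_params(snapshot_at = 500)
  a <- simulate_immune(p, seed = 99)
  b <- simulate_immune(p, seed = 99)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$bcells, b$bcells)
  expect_identical(a$thcells, b$thcells)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$snapshots, b$snapshots)
  c <- simulate_immune(p, seed = 100)
  expect_false(identical(a$timeseries, c$timeseries))
})

test_that("re-running with the same seed writes byte-identical output files", {
  p <- fast_params()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_run(simulate_immune(p, seed = 4), d1)
  write_run(simulate_immune(p, seed = 4), d2)
  for (f in c("timeseries.tsv", "summary.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the recording stride controls the number of time-series rows", {
  s <- simulate_immune(sim_params(t_max = 100, record_every = 10), seed = 2)
  expect_identical(nrow(s$timeseries), 11L)        # t_max/stride + 1
  expect_equal(s$timeseries$t, seq(0, 100, by = 10))
  s1 <- simulate_immune(sim_params(t_max = 200, record_every = 1), seed = 2)
  expect_identical(nrow(s1$timeseries), 201L)
})

test_that("population counts are conserved and never negative", {
  s <- simulate_immune(sim_params(t_max = 2000), seed = 3)
  # every decrement is a logged death/kill: births - deaths = final - initial
  expect_equal(s$self_counts, 150 + s$self_births - s$self_deaths)
  lg <- as.list(s$ledger)
  expect_equal(nrow(s$bcells),
               lg$b_births - lg$b_deaths - lg$b_to_plasma)
  expect_equal(nrow(s$plasma), lg$b_to_plasma - lg$plasma_deaths)
  expect_equal(nrow(s$thcells), lg$th_births - lg$th_deaths)
  expect_equal(unname(s$pools["antibody"]), lg$ab_produced - lg$ab_decayed)
  expect_equal(unname(s$pools["danger"]),
               lg$danger_emitted - lg$danger_consumed - lg$danger_decayed)
  ts <- s$timeseries
  expect_true(all(as.matrix(ts) >= 0 | is.na(as.matrix(ts))))
  # division counters are nondecreasing
  for (k in c("weak_T", "weak_B", "intermediate_T", "intermediate_B",
              "strong_T", "strong_B"))
    expect_true(all(diff(ts[[k]]) >= 0))
})

test_that("injections raise the foreign census at their scheduled times", {
  inf <- data.frame(time = c(100, 200), count = c(350, 350),
                    divwait = c(1e6, 1e6), x = 150, y = -150)
  s <- simulate_immune(sim_params(t_max = 260, infections = inf,
                                  record_every = 1), seed = 5)
  ts <- s$timeseries
  expect_equal(ts$nR[ts$t == 99], 0)
  expect_equal(ts$nR[ts$t == 100], 350)
  expect_gt(ts$nR[ts$t == 200], ts$nR[ts$t == 199])
  # a zero-count injection is a no-op
  s0 <- simulate_immune(sim_params(t_max = 150, infections =
    data.frame(time = 100, count = 0, divwait = 60, x = 10, y = 0)), seed = 5)
  expect_true(all(s0$timeseries$nR == 0))
})

test_that("identically shaped simultaneous injections merge their counts", {
  inf <- data.frame(time = c(100, 100), count = c(120, 80),
                    divwait = c(1e6, 1e6), x = 150, y = -150)
  s <- simulate_immune(sim_params(t_max = 140, infections = inf), seed = 6)
  expect_equal(s$timeseries$nR[s$timeseries$t == 100], 200)
  expect_identical(sum(s$foreign$injected == 2), 1L)   # one row absorbed
})

test_that("the census accessor agrees with the recorded series", {
  s <- simulate_immune(fast_params(), seed = 7)
  cz <- census(s)
  expect_named(cz, c("nW", "nR", "nB", "nAb", "nTh", "nIL", "nM"))
  last <- s$timeseries[nrow(s$timeseries), ]
  expect_equal(unname(cz["nW"]), last$nW)
  expect_equal(unname(cz["nB"]), last$nB)
  expect_equal(unname(census(s, t = 0)["nW"]), 450)
})

test_that("snapshots record the lattice content at the requested times", {
  s <- simulate_immune(fast_params(snapshot_at = c(50, 400)), seed = 8)
  expect_identical(length(s$snapshots), 2L)
  early <- s$snapshots[["50"]]
  expect_true(all(early$kind %in% c("self")))          # no lymphocytes yet
  late <- s$snapshots[["400"]]
  expect_true(all(c("TCR", "BCR", "self") %in% late$kind))
  expect_equal(sum(late$count[late$kind == "self"]),
               census(s, t = 400)[["nW"]], tolerance = 1e-9)
})
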