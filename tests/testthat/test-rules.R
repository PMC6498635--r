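# selection, division and interaction rules, checked against exact
# enumeration oracles on the reduced 100 x 100 lattice

test_that("B-cell negative selection deletes exactly the mirror-ball union", {
  # survivor fraction under uniform births equals the enumerated complement
  p <- small_world_params(weakrepr = 0, t_max = 2000, taubm = 0.5,
                          record_every = 100)
  s <- simulate_immune(p, seed = 21)
  lg <- as.list(s$ledger)
  attempts <- lg$b_births + lg$b_negsel_deleted
  expect_gt(attempts, 2000)
  pts <- lattice_points(100)
  selfm <- as.matrix(p$self[, c("x", "y")])
  expected <- mean(min_mirror_dist(pts, selfm) < p$b_negsel_radius)
  observed <- lg$b_negsel_deleted / attempts
  expect_lt(abs(observed - expected),
            3 * sqrt(expected * (1 - expected) / attempts))
  # and the surviving repertoire shows empty exclusion balls
  d <- min_mirror_dist(as.matrix(s$bcells[, c("x", "y")]), selfm)
  expect_true(all(d >= p$b_negsel_radius))
})

test_that("disabling negative selection admits the forbidden repertoire", {
  p <- small_world_params(weakrepr = 0, b_negsel = 0, t_max = 2000,
                          taubm = 0.5, record_every = 100)
  s <- simulate_immune(p, seed = 22)
  expect_identical(unname(s$ledger["b_negsel_deleted"]), 0)
  selfm <- as.matrix(p$self[, c("x", "y")])
  d <- min_mirror_dist(as.matrix(s$bcells[, c("x", "y")]), selfm)
  expect_true(any(d < p$b_negsel_radius))
})

test_that("thymic selection survivor fractions match the enumerated areas", {
  pts <- lattice_points(100)
  p <- small_world_params(weakrepr = 0, t_max = 2000, tauthm = 0.5,
                          record_every = 100)
  selfm <- as.matrix(p$self[, c("x", "y")])
  dstar <- min_mirror_dist(pts, selfm)
  # self-centered: delete inside the rings, mark the annulus regulatory
  s <- simulate_immune(p, seed = 23)
  lg <- as.list(s$ledger)
  attempts <- lg$th_births + lg$th_thymic_deleted
  exp_del <- mean(dstar < p$ring_inner)
  obs_del <- lg$th_thymic_deleted / attempts
  expect_lt(abs(obs_del - exp_del), 3 * sqrt(exp_del * (1 - exp_del) / attempts))
  exp_reg <- mean(dstar >= p$ring_inner & dstar <= p$ring_outer) /
    mean(dstar >= p$ring_inner)
  nth <- nrow(s$thcells)
  obs_reg <- sum(s$thcells$regulatory) / nth
  expect_lt(abs(obs_reg - exp_reg), 3 * sqrt(exp_reg * (1 - exp_reg) / nth))
  # conventional: annulus and interior both deleted, nobody regulatory
  pc <- small_world_params(model = "crs", t_max = 2000, tauthm = 0.5,
                           record_every = 100)
  sc <- simulate_immune(pc, seed = 24)
  lgc <- as.list(sc$ledger)
  attempts_c <- lgc$th_births + lgc$th_thymic_deleted
  exp_del_c <- mean(dstar <= p$ring_outer)
  obs_del_c <- lgc$th_thymic_deleted / attempts_c
  expect_lt(abs(obs_del_c - exp_del_c),
            3 * sqrt(exp_del_c * (1 - exp_del_c) / attempts_c))
  expect_identical(sum(sc$thcells$regulatory), 0L)
})

test_that("every surviving regulatory cell sits in a characteristic annulus", {
  p <- sim_params(t_max = 2800, record_every = 100)
  s <- simulate_immune(p, seed = 25)
  th <- s$thcells
  reg <- th[th$regulatory == 1, ]
  expect_gt(nrow(reg), 10)
  selfm <- as.matrix(p$self[, c("x", "y")])
  d <- min_mirror_dist(as.matrix(reg[, c("x", "y")]), selfm)
  expect_true(all(d >= p$ring_inner & d <= p$ring_outer))
})

test_that("receptor mutation is a lattice-clamped sphere displacement", {
  # pmut = 0: offspring receptor always equals the parent receptor
  m0 <- mutate_shape_cpp(400, 100, 500, 5, 6, 0, 1000)
  expect_true(all(m0[, 1] == 400 & m0[, 2] == 100))
  set.seed(31)
  m <- mutate_shape_cpp(400, 100, 4000, 5, 6, 1, 1000)
  d <- pmax(abs(m[, 1] - 400), abs(m[, 2] - 100))
  expect_true(all(d %in% 5:6))                     # magnitudes within range
  expect_true(all(table(d) > 0))
  # uniform over the 8m points of each sphere (chi-square)
  ring5 <- m[d == 5, ]
  key <- paste(ring5[, 1], ring5[, 2])
  expect_identical(length(unique(key)), 40L)
  expect_gt(stats::chisq.test(table(key))$p.value, 0.01)
  # mutation can improve affinity: some offspring of a parent at distance 20
  # from a target mirror land strictly closer
  set.seed(32)
  mm <- mutate_shape_cpp(420, 100, 2000, 5, 6, 1, 1000)
  d2 <- pmax(abs(mm[, 1] - 400), abs(mm[, 2] - 100))
  expect_gt(mean(d2 < 20), 0)
  expect_true(all(abs(d2 - 20) <= 6))
  # clamping at the boundary keeps offspring on the lattice
  edge <- mutate_shape_cpp(0, -500, 1000, 5, 6, 1, 1000)
  expect_true(all(edge[, 1] >= 0 & edge[, 2] >= -500))
})

test_that("marrow T-helper output scales inversely with its waiting time", {
  # with selection effectively disabled and no throttle, the birth flux is
  # (t - t_immigration)/tauthm; compare tauthm = 5 against 30
  births <- sapply(c(5, 30), function(tm) {
    p <- sim_params(tauthm = tm, ring_inner = 0, ring_outer = 0,
                    weakrepr = 0, kth = 1e6, t_max = 2000,
                    record_every = 500)
    as.list(simulate_immune(p, seed = 61)$ledger)$th_births
  })
  ratio <- births[1] / births[2]
  se <- ratio * sqrt(1 / births[1] + 1 / births[2])   # Poisson error
  expect_lt(abs(ratio - 6), 3 * se)
})

test_that("the conventional preset never performs weak or intermediate divisions", {
  inf <- data.frame(time = 1000, count = 350, divwait = 60, x = 150, y = -150)
  p <- sim_params(model = "crs", t_max = 2000, infections = inf,
                  record_every = 100)
  s <- simulate_immune(p, seed = 26)
  cz <- s$counters
  expect_identical(unname(cz[c("weak_T", "weak_B",
                               "intermediate_T", "intermediate_B")]),
                   rep(0, 4))
  # danger signals and interleukins are never emitted either
  expect_true(all(s$timeseries$nIL == 0))
  expect_identical(unname(s$ledger["il_emitted"]), 0)
})

test_that("disabling the self-centered channels reduces the model to the conventional one", {
  # same seed, same switches: the four-parameter switch plus a zeroed danger
  # burst must give the identical trajectory as the conventional preset,
  # showing the extra machinery is fully inert when disabled
  inf <- data.frame(time = 500, count = 200, divwait = 60, x = 150, y = -150)
  p_off <- sim_params(medrepr = 0, weakrepr = 0, comptype = 1, tauthm = 30,
                      danger_burst = 0, t_max = 1500, infections = inf)
  p_crs <- sim_params(model = "crs", t_max = 1500, infections = inf)
  a <- simulate_immune(p_off, seed = 27)
  b <- simulate_immune(p_crs, seed = 27)
  expect_identical(a$counters, b$counters)
  expect_identical(a$timeseries, b$timeseries)
})

test_that("antibodies exist only with plasma cells and share their shapes", {
  # homeostasis: no plasma cells, no antibodies
  s <- simulate_immune(fast_params(), seed = 28)
  expect_identical(nrow(s$plasma), 0L)
  expect_true(all(s$timeseries$nAb == 0))
  # infected run with immortal plasma: antibody pool shapes are plasma shapes
  inf <- data.frame(time = 2000, count = 350, divwait = 60, x = 150, y = -150)
  p <- sim_params(t_max = 2500, infections = inf, plasma_life = 1e6,
                  record_every = 100)
  si <- simulate_immune(p, seed = 31)
  if (nrow(si$antibodies)) {
    abk <- paste(si$antibodies$x, si$antibodies$y)
    plk <- paste(si$plasma$x, si$plasma$y)
    expect_true(all(abk %in% plk))
  }
  expect_gt(nrow(si$plasma), 0)
})
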