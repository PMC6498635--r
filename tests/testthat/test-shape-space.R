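test_that("Chebyshev distance matches direct evaluation and printed self coordinates", {
  expect_identical(linf_dist(c(0, 0), c(3, -4)), 4L)
  expect_identical(linf_dist(c(550, 300), c(850, 150)), 300L)
  expect_identical(linf_dist(c(12, -7), c(12, -7)), 0L)
  # vectorised over rows
  a <- rbind(c(0, 0), c(550, 300))
  b <- rbind(c(3, -4), c(850, 150))
  expect_identical(linf_dist(a, b), c(4L, 300L))
})

test_that("distance satisfies the metric axioms on random lattice points", {
  set.seed(42)
  z <- random_shape(300, N = 1000)
  i <- sample(300, 100, replace = TRUE)
  j <- sample(300, 100, replace = TRUE)
  k <- sample(300, 100, replace = TRUE)
  dij <- linf_dist(z[i, ], z[j, ])
  dji <- linf_dist(z[j, ], z[i, ])
  dik <- linf_dist(z[i, ], z[k, ])
  dkj <- linf_dist(z[k, ], z[j, ])
  expect_identical(dij, dji)                       # symmetry
  expect_true(all(dij[i == j] == 0L))
  expect_true(all((dij == 0L) == (z[i, 1] == z[j, 1] & z[i, 2] == z[j, 2])))
  expect_true(all(dij <= dik + dkj))               # triangle inequality
})

test_that("mirror complementarity is an involution with the expected geometry", {
  expect_identical(mirror_shape(c(550, 300)), c(550, -300))
  expect_identical(mirror_shape(c(700, -200)), c(700, 200))
  set.seed(7)
  z <- random_shape(200)
  expect_identical(mirror_shape(mirror_shape(z)), z)
  # distance from a shape to its own mirror is 2|y|, zero exactly on the axis
  expect_identical(linf_dist(z, mirror_shape(z)), as.integer(2 * abs(z[, 2])))
})

test_that("binding radius test is exact at the boundary and monotone in radius", {
  expect_true(binds_within(c(550, -300), c(550, 300), 0))
  expect_false(binds_within(c(560, -300), c(550, 300), 9))   # distance 10
  expect_true(binds_within(c(560, -300), c(550, 300), 10))
  set.seed(11)
  r <- random_shape(100); l <- random_shape(100)
  for (d in c(0, 5, 50, 400)) {
    hit_d <- binds_within(r, l, d)
    expect_true(all(binds_within(r, l, d + 7)[hit_d]))       # monotonicity
  }
  expect_error(binds_within(c(0, 0), c(0, 0), -1), "nonnegative")
})

test_that("receptors binding a fixed ligand fill the mirror-centred ball", {
  N <- 30
  pts <- lattice_points(N)
  ligand <- c(14, 6)
  for (radius in c(0, 2, 5)) {
    hits <- binds_within(pts, matrix(ligand, 1), radius)
    ball <- abs(pts[, 1] - 14) <= radius & abs(pts[, 2] + 6) <= radius
    expect_identical(which(hits), which(ball))
    expect_identical(sum(hits), as.integer((2 * radius + 1)^2))  # interior ball
  }
  # ball clipped at the lattice corner: x and y both truncated to 3 values
  edge <- sum(binds_within(pts, matrix(c(0, 15), 1), 2))
  expect_identical(edge, as.integer(3 * 3))
})

test_that("uniform repertoire draws are reproducible, in bounds and uniform", {
  set.seed(123); a <- random_shape(1000, 1000)
  set.seed(123); b <- random_shape(1000, 1000)
  expect_identical(a, b)
  expect_true(all(a[, 1] >= 0 & a[, 1] <= 1000))
  expect_true(all(a[, 2] >= -500 & a[, 2] <= 500))
  set.seed(99)
  z <- random_shape(1e5, 1000)
  cx <- table(cut(z[, 1], breaks = seq(-0.5, 1000.5, length.out = 11)))
  cy <- table(cut(z[, 2], breaks = seq(-500.5, 500.5, length.out = 11)))
  expect_gt(stats::chisq.test(cx)$p.value, 0.01)
  expect_gt(stats::chisq.test(cy)$p.value, 0.01)
})

test_that("lattice validation rejects malformed sizes and off-grid points", {
  expect_error(shape_lattice(3), "even")
  expect_error(shape_lattice(0), "even")
  lat <- shape_lattice(100)
  expect_error(linf_dist(c(101, 0), c(0, 0), lattice = lat), "off lattice")
  expect_error(linf_dist(c(5, 51), c(0, 0), lattice = lat), "off lattice")
  expect_silent(linf_dist(c(100, -50), c(0, 50), lattice = lat))
})

test_that("snapshot writer emits the TSV columns", {
  snap <- data.frame(kind = c("TCR", "self"), x = c(1, 55), y = c(2, 30),
                     count = c(1, 150))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_snapshot(snap, f)
  back <- utils::read.delim(f)
  expect_identical(names(back), c("kind", "x", "y", "count"))
  expect_identical(nrow(back), 2L)
})
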