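# shared fixtures and small oracles built in code

# a reduced world on a 100 x 100 lattice with scaled-down selection geometry;
# exact survivor fractions are enumerable on this lattice
small_world_params <- function(...) {
  sim_params(
    N = 100,
    self = data.frame(x = c(55, 70, 85), y = c(30, -20, 15),
                      count = c(150, 150, 150), divwait = c(50, 50, 50),
                      capacity = c(1000, 1000, 1000)),
    b_negsel_radius = 5, ring_inner = 5, ring_outer = 8, thrad = 8,
    r0 = 15, ab_radius = 10, rminnew = 2, rminsprd = 2,
    ...
  )
}

# enumerate every lattice point of an N-lattice; returns a 2-column matrix
lattice_points <- function(N) {
  as.matrix(expand.grid(x = 0:N, y = -(N / 2):(N / 2)))
}

# minimum l-infinity distance from each point to the mirror images of the
# given self shapes (brute-force oracle)
min_mirror_dist <- function(pts, self_xy) {
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(self_xy))) {
    di <- pmax(abs(pts[, 1] - self_xy[i, 1]), abs(pts[, 2] + self_xy[i, 2]))
    d <- pmin(d, di)
  }
  d
}

# brute-force one-sided Fisher tail using exact binomial coefficients
# (safe for table totals <= 40)
fisher_bruteforce <- function(w1, l1, w2, l2) {
  W <- w1 + w2; L <- l1 + l2; n1 <- w1 + l1; n <- W + L
  if (W == 0 || L == 0 || n1 == 0 || n1 == n) return(1)
  i <- w1:min(W, n1)
  sum(choose(W, i) * choose(L, n1 - i)) / choose(n, n1)
}

# default ERS params at a reduced horizon for cheap dynamic tests
fast_params <- function(...) sim_params(t_max = 600, record_every = 10, ...)
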