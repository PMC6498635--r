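#' Derive independent per-replicate seeds
#'
#' @param seed master seed.
#' @param n number of seeds.
#' @return integer vector of `n` seeds in `1..2^31-2`.
#' @keywords internal
replicate_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

default_infection_shape <- c(150L, -150L)

# conventional round-half-up to match reported table formatting
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

with_infections <- function(params, times, count, divwait,
                            shape = default_infection_shape) {
  params$infections <- data.frame(
    time = times, count = count, divwait = divwait,
    x = shape[1L], y = shape[2L])
  validate_sim_params(params)
  params
}

#' Repeated-infection immune memory experiment
#'
#' Runs `reps` independent simulations of the self-centered model, each
#' with two injections of the same pathogen (by default 350 cells with a
#' mean division wait of 60 steps, at days 300 and 315). Among the runs
#' that cleared both infections, it reports the mean and standard deviation
#' of the elimination times of the first and second infection and the
#' two-tailed Welch p-value for the equality of the two means. A faster
#' second elimination is the signature of B-cell memory.
#'
#' @param reps number of replicate simulations (>= 2).
#' @param params base parameters (default [sim_params()], self-centered).
#' @param seed master seed; replicate seeds are derived from it.
#' @param days the two injection days (multiplied by 10 to get steps).
#' @param count,divwait pathogen initial size and mean division wait;
#'   default to `params$nr` and `params$tr`.
#' @param shape pathogen lattice coordinates.
#' @return a list with `cleared_both`, `reps`, `mean1`, `sd1`, `mean2`,
#'   `sd2`, `p_value`, and `runs`, a per-run data frame (win, elimination
#'   times, death time).
#' @export
run_memory_experiment <- function(reps = 100, params = sim_params(),
                                  seed = 1, days = c(300, 315),
                                  count = params$nr, divwait = params$tr,
                                  shape = default_infection_shape) {
  if (reps < 2) stop("reps must be >= 2", call. = FALSE)
  stopifnot(length(days) == 2L, days[2L] > days[1L])
  p <- with_infections(params, times = days * 10, count = count,
                       divwait = divwait, shape = shape)
  seeds <- replicate_seeds(seed, reps)
  runs <- vector("list", reps)
  for (r in seq_len(reps)) {
    s <- simulate_immune(p, seed = seeds[r])
    oc <- classify_outcome(s)
    runs[[r]] <- data.frame(
      run = r, seed = seeds[r], win = oc$win,
      elim1 = oc$elim_times[1L], elim2 = oc$elim_times[2L],
      death_time = if (is.na(oc$death_time)) NA_real_ else oc$death_time)
  }
  runs <- do.call(rbind, runs)
  both <- runs[runs$win & !is.na(runs$elim1) & !is.na(runs$elim2), ]
  out <- list(cleared_both = nrow(both), reps = reps, runs = runs)
  if (nrow(both) >= 2L) {
    out$mean1 <- mean(both$elim1); out$sd1 <- stats::sd(both$elim1)
    out$mean2 <- mean(both$elim2); out$sd2 <- stats::sd(both$elim2)
    out$p_value <- welch_t_test(both$elim1, both$elim2)$p.value
  } else {
    out$mean1 <- out$sd1 <- out$mean2 <- out$sd2 <- out$p_value <- NA_real_
  }
  out
}

#' Self-centered versus conventional model survival grid
#'
#' For each arm (an initial pathogen count `f_cells` and a mean division
#' wait `div_time`), runs `reps` simulations under the self-centered (ERS)
#' preset and `reps` under the conventional (CRS) preset, with a single
#' injection at `day`. Wins are tallied per model and compared with the
#' one-sided Fisher exact test for win enrichment in the self-centered arm.
#'
#' @param arms data frame with columns `f_cells` and `div_time`.
#' @param reps replicates per model per arm.
#' @param params base parameters; model switches are applied per arm.
#' @param seed master seed.
#' @param day injection day (steps = `day * 10`).
#' @param shape pathogen lattice coordinates.
#' @return a data frame with one row per arm: win counts, win ratio
#'   (ERS/CRS, `Inf` when CRS never wins) and the Fisher p-value.
#' @export
run_comparison_grid <- function(arms = data.frame(f_cells = 350, div_time = 50),
                                reps = 100, params = sim_params(), seed = 1,
                                day = 300, shape = default_infection_shape) {
  stopifnot(all(c("f_cells", "div_time") %in% names(arms)), reps >= 1)
  seeds <- replicate_seeds(seed, reps * 2L * nrow(arms))
  si <- 0L
  res <- vector("list", nrow(arms))
  base_ers <- params_with_model(params, "ers")
  base_crs <- params_with_model(params, "crs")
  for (a in seq_len(nrow(arms))) {
    wins <- c(ers = 0L, crs = 0L)
    for (model in c("ers", "crs")) {
      base <- if (model == "ers") base_ers else base_crs
      p <- with_infections(base, times = day * 10,
                           count = arms$f_cells[a],
                           divwait = arms$div_time[a], shape = shape)
      for (r in seq_len(reps)) {
        si <- si + 1L
        s <- simulate_immune(p, seed = seeds[si])
        if (classify_outcome(s)$win) wins[model] <- wins[model] + 1L
      }
    }
    ratio <- if (wins["crs"] == 0L) Inf else unname(wins["ers"] / wins["crs"])
    pval <- fisher_one_sided(wins["ers"], reps - wins["ers"],
                             wins["crs"], reps - wins["crs"])
    res[[a]] <- data.frame(
      f_cells = arms$f_cells[a], div_time = arms$div_time[a], reps = reps,
      ers_wins = unname(wins["ers"]), crs_wins = unname(wins["crs"]),
      ratio = round_half_up(ratio, 3), p_value = pval)
  }
  do.call(rbind, res)
}

# re-derive a parameter set under the other model preset, keeping overrides
params_with_model <- function(params, model) {
  p <- params
  if (model == "crs") {
    p$medrepr <- 0; p$weakrepr <- 0; p$comptype <- 1; p$tauthm <- 30
  } else {
    d <- default_sim_params()
    p$medrepr <- d$medrepr; p$weakrepr <- d$weakrepr
    p$comptype <- d$comptype; p$tauthm <- d$tauthm
  }
  p$model <- model
  validate_sim_params(p)
  p
}

#' Parameter ranges for the sensitivity analysis
#'
#' The 13 critical parameters with their defaults and uniform sampling
#' ranges; the default of each lies at the centre of its range.
#'
#' @return a data frame with columns `parameter`, `type`, `default`,
#'   `min`, `max`.
#' @export
sensitivity_ranges <- function() {
  data.frame(
    parameter = c("r0", "pmem", "crnew", "rminnew", "crspread", "rminsprd",
                  "thrad", "pmut", "taub0", "tauth0", "tcrit_stress",
                  "nr", "tr"),
    type = c("int", "float", "float", "int", "float", "int", "int",
             "float", "float", "float", "float", "int", "float"),
    default = c(150, 0.3, 0.9, 5, 0.9, 5, 80, 0.4, 5, 2, 2, 350, 60),
    min = c(50, 0.1, 0.1, 1, 0.1, 1, 50, 0.1, 1, 1, 1, 200, 40),
    max = c(250, 0.5, 1.7, 9, 1.7, 10, 250, 0.7, 9, 9, 3, 500, 80)
  )
}

#' Uniform-sampling sensitivity analysis
#'
#' Samples the 13 critical parameters independently and uniformly over
#' their ranges (integers uniformly on the integer grid), runs each sampled
#' configuration to day 305 with an infection of random type at day 300
#' (size `nr` and division wait `tr` take their sampled values; the shape
#' is uniform on the antigen lattice), and correlates inputs with the seven
#' output variables observed at the end of the run.
#'
#' @param n number of sampled simulations (>= 2).
#' @param params base parameters for the non-sampled keys.
#' @param seed master seed.
#' @param ranges a data frame as returned by [sensitivity_ranges()].
#' @param end_day simulation horizon in days (default 305).
#' @param infection_day injection day (default 300).
#' @return a list with `data` (one row per run: sampled inputs and
#'   outputs), `correlations` (13 x 7 Pearson matrix) and `rounded` (the
#'   same rounded to one decimal).
#' @export
run_sensitivity <- function(n = 500, params = sim_params(), seed = 1,
                            ranges = sensitivity_ranges(),
                            end_day = 305, infection_day = 300) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (any(ranges$min > ranges$max))
    stop("inverted sensitivity range", call. = FALSE)
  seeds <- replicate_seeds(seed, n)
  outputs <- c("nW", "nR", "nB", "nAb", "nTh", "nIL", "nM")
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    set.seed(seeds[r])
    draw <- stats::setNames(numeric(nrow(ranges)), ranges$parameter)
    for (k in seq_len(nrow(ranges))) {
      draw[k] <- if (ranges$type[k] == "int")
        sample(seq.int(ranges$min[k], ranges$max[k]), 1L)
      else stats::runif(1L, ranges$min[k], ranges$max[k])
    }
    shape <- as.integer(random_shape(1L, params$N))
    p <- params
    for (nm in ranges$parameter) p[[nm]] <- unname(draw[nm])
    p$t_max <- end_day * 10
    p$record_every <- 50
    p$snapshot_at <- numeric(0)
    p <- with_infections(p, times = infection_day * 10,
                         count = draw[["nr"]], divwait = draw[["tr"]],
                         shape = shape)
    run_seed <- (seeds[r] + 7L) %% 2147483646L + 1L
    s <- simulate_immune(p, seed = run_seed)
    cz <- census(s)
    rows[[r]] <- c(draw, cz[outputs])
  }
  dat <- as.data.frame(do.call(rbind, rows))
  # an output with zero variance across runs yields NA correlations
  cors <- suppressWarnings(stats::cor(dat[, ranges$parameter], dat[, outputs],
                                      method = "pearson"))
  list(data = dat, correlations = cors, rounded = round(cors, 1))
}
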