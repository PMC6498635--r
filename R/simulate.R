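#' Run one stochastic simulation of the humoral immune response
#'
#' Simulates the model defined by a [sim_params()] set from conception
#' (`t = 0`) to `t_max` (default 5000 steps; one step is 0.1 day). The world
#' starts with the configured self-antigen populations and a growing bone
#' marrow; B and T helper cells emigrate into circulation from step
#' `t_immigration` (day 10) after negative (B) and thymic (Th) selection.
#' Pathogen injections listed in `params$infections` enter at their
#' scheduled times. The run ends at `t_max`, or earlier if any pathogen
#' population reaches the lethal threshold (`death_threshold`, default
#' 4000 cells), which is recorded as host death.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed; a run is a deterministic function of
#'   `(params, seed)`. Defaults to `params$seed` when that is set.
#' @return an object of class `immune_sim` with components:
#' \describe{
#'   \item{timeseries}{data frame sampled every `record_every` steps with
#'     columns `t`, the census outputs `nW` (self cells), `nR` (foreign
#'     cells), `nB` (B lineage incl. plasma), `nAb` (antibodies), `nTh`
#'     (T helper cells), `nIL` (danger-signal pool), `nM` (marrow cells),
#'     and the cumulative division counters `weak_T`, `weak_B`,
#'     `intermediate_T`, `intermediate_B`, `strong_T`, `strong_B`.}
#'   \item{foreign}{one row per scheduled injection: injection time, size,
#'     division wait, shape, final and peak counts, and `elim_time`, the
#'     time from injection until the population first fell below
#'     `elim_threshold` (NA if it never did).}
#'   \item{bcells, thcells, plasma, antibodies}{final repertoire tables.}
#'   \item{counters, ledger, pools, ring_counts}{final cumulative division
#'     counters, the birth/death bookkeeping used by conservation checks,
#'     soluble pool sizes, and per-self-population regulatory ring counts.}
#'   \item{death_time}{time of host death, or `NA` when the host survived.}
#' }
#' @examples
#' \donttest{
#' p <- sim_params(t_max = 500)
#' s <- simulate_immune(p, seed = 1)
#' head(s$timeseries)
#' }
#' @export
simulate_immune <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(seed)) seed <- params$seed
  if (is.null(seed) || is.na(seed))
    stop("supply a seed (argument or params$seed)", call. = FALSE)
  set.seed(as.integer(seed))
  cfg <- params
  cfg$self <- as.matrix(params$self[, c("x", "y", "count", "divwait", "capacity")])
  cfg$infections <- as.matrix(params$infections[, c("time", "count", "divwait", "x", "y")])
  raw <- sim_run_cpp(cfg)

  ts <- as.data.frame(raw$timeseries)
  names(ts) <- c("t", "nW", "nR", "nB", "nAb", "nTh", "nIL", "nM",
                 "weak_T", "weak_B", "intermediate_T", "intermediate_B",
                 "strong_T", "strong_B")
  fg <- as.data.frame(raw$foreign)
  names(fg) <- c("time", "count0", "divwait", "x", "y", "injected",
                 "final_count", "max_count", "elim_time")
  bc <- as.data.frame(raw$bcells); names(bc) <- c("x", "y", "state")
  th <- as.data.frame(raw$thcells); names(th) <- c("x", "y", "state", "regulatory")
  pl <- as.data.frame(raw$plasma); names(pl) <- c("x", "y")
  ab <- as.data.frame(raw$antibodies); names(ab) <- c("x", "y", "count")
  snaps <- lapply(raw$snapshots, function(s) {
    data.frame(kind = c("TCR", "BCR", "self", "foreign")[s$kind + 1L],
               x = s$x, y = s$y, count = s$count)
  })
  if (length(snaps)) names(snaps) <- vapply(raw$snapshots, function(s)
    format(s$time), character(1))

  structure(list(
    timeseries = ts, foreign = fg, bcells = bc, thcells = th, plasma = pl,
    antibodies = ab, pools = raw$pools, counters = raw$counters,
    ledger = raw$ledger, ring_counts = raw$ring_counts,
    self_counts = raw$self_counts, self_births = raw$self_births,
    self_deaths = raw$self_deaths, snapshots = snaps,
    death_time = raw$death_time, end_time = raw$end_time,
    params = params, seed = as.integer(seed)
  ), class = "immune_sim")
}

#' @export
print.immune_sim <- function(x, ...) {
  cz <- census(x)
  cat("<immune_sim>", x$params$model, "model, seed", x$seed,
      "| end time", format(x$end_time), "\n")
  if (!is.na(x$death_time))
    cat("  host died at t =", format(x$death_time),
        "(pathogen reached", x$params$death_threshold, "cells)\n")
  cat("  final census:",
      paste(names(cz), unname(round(cz)), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Census of the seven output variables
#'
#' Returns the model's seven observables: `nW` (self cells, summed over the
#' self populations), `nR` (foreign cells), `nB` (B cells in all states,
#' plasma included), `nAb` (antibodies), `nTh` (T helper cells), `nIL`
#' (danger-signal pool) and `nM` (bone marrow cells).
#'
#' @param sim an `immune_sim` object.
#' @param t optional time; when given, the census is read from the recorded
#'   time series at the latest record not after `t`, otherwise the final
#'   state is used.
#' @return a named numeric vector of length 7.
#' @export
census <- function(sim, t = NULL) {
  stopifnot(inherits(sim, "immune_sim"))
  if (!is.null(t)) {
    ts <- sim$timeseries
    i <- max(which(ts$t <= t + 1e-9))
    return(unlist(ts[i, c("nW", "nR", "nB", "nAb", "nTh", "nIL", "nM")]))
  }
  c(nW = sum(sim$self_counts),
    nR = sum(sim$foreign$final_count[sim$foreign$injected == 1]),
    nB = nrow(sim$bcells) + nrow(sim$plasma),
    nAb = unname(sim$pools["antibody"]),
    nTh = nrow(sim$thcells),
    nIL = unname(sim$pools["danger"]),
    nM = unname(sim$pools["marrow"]))
}

#' Write run outputs as TSV files
#'
#' Emits `timeseries.tsv` (census and division counters per recorded step)
#' and `summary.tsv` (per-injection outcome classification and the final
#' census), plus one `snapshot_<t>.tsv` per collected lattice snapshot.
#'
#' @param sim an `immune_sim` object.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_run <- function(sim, dir) {
  stopifnot(inherits(sim, "immune_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$timeseries, file.path(dir, "timeseries.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  outcome <- if (nrow(sim$foreign)) {
    if (classify_outcome(sim)$win) "win" else "loss"
  } else "uninfected"
  fin <- census(sim)
  sm <- data.frame(
    key = c("model", "seed", "end_time", "outcome", "death_time",
            if (nrow(sim$foreign))
              paste0("elim_time_", seq_len(nrow(sim$foreign))),
            names(fin)),
    value = c(sim$params$model, sim$seed, sim$end_time, outcome,
              sim$death_time, sim$foreign$elim_time, unname(fin))
  )
  utils::write.table(sm, file.path(dir, "summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(sim$snapshots))
    write_snapshot(sim$snapshots[[nm]],
                   file.path(dir, paste0("snapshot_", nm, ".tsv")))
  invisible(dir)
}
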