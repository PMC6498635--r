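#' Classify the outcome of an infected run
#'
#' A run counts as a *win* when every injected pathogen population fell
#' below the elimination threshold (strictly under 50 cells by default)
#' before the end of the run and none of them ever reached the lethal
#' threshold (4000 cells). It is a *loss* when any population reached the
#' lethal threshold (host death) or still stood at or above the elimination
#' threshold at the horizon. Elimination times are measured from each
#' population's injection time to its first crossing below the threshold;
#' crossings are detected at event granularity inside the simulator, so the
#' classification does not depend on the time-series sampling stride.
#'
#' @param x an `immune_sim` object, or a numeric vector of population
#'   counts for the series method.
#' @param ... passed between methods.
#' @return a list of class `outcome_record` with elements `win` (logical),
#'   `elim_times` (numeric, NA where a population was never eliminated),
#'   `death_time` (NA unless the host died) and `n_infections`.
#' @examples
#' classify_outcome(c(350, 420, 60, 49), times = 3000:3003,
#'                  injection_time = 3000)
#' @export
classify_outcome <- function(x, ...) UseMethod("classify_outcome")

#' @rdname classify_outcome
#' @export
classify_outcome.immune_sim <- function(x, ...) {
  fg <- x$foreign
  if (nrow(fg) == 0L)
    stop("run has no infections; outcome undefined", call. = FALSE)
  p <- x$params
  dead <- !is.na(x$death_time) || any(fg$max_count >= p$death_threshold)
  eliminated <- !is.na(fg$elim_time)
  win <- !dead && all(eliminated)
  structure(list(win = win, elim_times = fg$elim_time,
                 death_time = x$death_time, n_infections = nrow(fg)),
            class = "outcome_record")
}

#' @rdname classify_outcome
#' @param times times at which `x` was observed (same length as `x`).
#' @param injection_time injection time of the population; counts before it
#'   are ignored.
#' @param elim_threshold,death_threshold elimination (strictly-below) and
#'   lethal (at-or-above) thresholds; defaults 50 and 4000.
#' @param t_max horizon; defaults to the last observation time.
#' @export
classify_outcome.default <- function(x, times = seq_along(x) - 1,
                                     injection_time = times[1L],
                                     elim_threshold = 50,
                                     death_threshold = 4000,
                                     t_max = times[length(times)], ...) {
  stopifnot(length(x) == length(times), length(x) >= 1L)
  keep <- times >= injection_time
  x <- x[keep]; times <- times[keep]
  death <- which(x >= death_threshold)
  death_time <- if (length(death)) times[death[1L]] else NA_real_
  below <- which(x < elim_threshold & times <= t_max)
  elim <- if (length(below)) times[below[1L]] - injection_time else NA_real_
  win <- is.na(death_time) && !is.na(elim)
  structure(list(win = win, elim_times = elim, death_time = death_time,
                 n_infections = 1L), class = "outcome_record")
}

#' @export
print.outcome_record <- function(x, ...) {
  cat("<outcome_record>", if (x$win) "win" else "loss",
      "| elimination times:", paste(format(x$elim_times), collapse = ", "),
      if (!is.na(x$death_time)) paste("| death at", format(x$death_time)) else "",
      "\n")
  invisible(x)
}
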