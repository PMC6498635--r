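#' Scheduled-event queue with exponential waiting-time race
#'
#' The simulation advances by a continuous-time race between all pending
#' events: an event with mean waiting time `tau` has rate `1/tau`, the next
#' event to fire is chosen with probability proportional to its rate, and
#' the clock advances by an exponential draw with mean `1/sum(rates)` (the
#' race minimum). Because exponential clocks are memoryless, this is
#' equivalent to drawing an independent exponential waiting time for each
#' pending event and firing the earliest.
#'
#' `event_queue()` creates an empty queue; [eq_schedule()], [eq_cancel()]
#' and [eq_draw()] operate on it by reference. The compiled simulation core
#' used by [simulate_immune()] implements the identical race over aggregated
#' event channels; this R-level queue is the reference implementation of the
#' same semantics and is convenient for small models and for testing.
#'
#' @return an event queue object (an environment).
#' @examples
#' q <- event_queue()
#' eq_schedule(q, "division", agent = 1L, mean_wait = 3)
#' eq_schedule(q, "death", agent = 1L, mean_wait = 10)
#' set.seed(1)
#' eq_draw(q, t = 0)
#' @export
event_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$next_id <- 1L
  q$id <- integer(0)
  q$type <- character(0)
  q$agent <- integer(0)
  q$rate <- numeric(0)
  class(q) <- "event_queue"
  q
}

#' @export
print.event_queue <- function(x, ...) {
  cat("<event_queue>", length(x$id), "pending event(s)\n")
  invisible(x)
}

#' Queue operations
#'
#' @param q an [event_queue()].
#' @param type event type label (one per behavioural rule, e.g.
#'   `"b_action"`, `"division"`, `"death"`).
#' @param agent integer id of the owning agent or population.
#' @param mean_wait expected waiting time of the event, in time steps;
#'   must be strictly positive.
#' @return `eq_schedule()` returns the integer id of the scheduled event.
#' @seealso [event_queue()]
#' @export
eq_schedule <- function(q, type, agent, mean_wait) {
  stopifnot(inherits(q, "event_queue"))
  if (!is.finite(mean_wait) || mean_wait <= 0)
    stop("mean_wait must be > 0", call. = FALSE)
  id <- q$next_id
  q$next_id <- id + 1L
  q$id <- c(q$id, id)
  q$type <- c(q$type, as.character(type))
  q$agent <- c(q$agent, as.integer(agent))
  q$rate <- c(q$rate, 1 / mean_wait)
  id
}

#' @rdname eq_schedule
#' @param id event id to remove (for `eq_cancel_event`).
#' @return `eq_cancel()` removes every event owned by `agent` (the queue
#'   contract when an agent dies) and returns the number removed;
#'   `eq_cancel_event()` removes a single event by id.
#' @export
eq_cancel <- function(q, agent) {
  keep <- q$agent != as.integer(agent)
  n <- sum(!keep)
  q$id <- q$id[keep]; q$type <- q$type[keep]
  q$agent <- q$agent[keep]; q$rate <- q$rate[keep]
  n
}

#' @rdname eq_schedule
#' @export
eq_cancel_event <- function(q, id) {
  keep <- q$id != as.integer(id)
  n <- sum(!keep)
  q$id <- q$id[keep]; q$type <- q$type[keep]
  q$agent <- q$agent[keep]; q$rate <- q$rate[keep]
  n
}

#' @rdname eq_schedule
#' @param t current simulation time.
#' @return `eq_draw()` returns `NULL` on an empty queue (simulation end);
#'   otherwise a list with the fired event (`id`, `type`, `agent`,
#'   `mean_wait`) and the advanced clock `time`. The fired event is removed
#'   from the queue; recurring events are re-armed by the caller.
#' @export
eq_draw <- function(q, t = 0) {
  stopifnot(inherits(q, "event_queue"))
  n <- length(q$id)
  if (n == 0L) return(NULL)
  total <- sum(q$rate)
  dt <- stats::rexp(1L, rate = total)
  i <- if (n == 1L) 1L else sample.int(n, 1L, prob = q$rate / total)
  ev <- list(id = q$id[i], type = q$type[i], agent = q$agent[i],
             mean_wait = 1 / q$rate[i], time = t + dt)
  eq_cancel_event(q, q$id[i])
  ev
}

#' Logistic throttling of birth rates
#'
#' Per-capita birth rates are damped linearly as a population approaches its
#' carrying capacity: the effective rate is `base_rate * max(0, 1 - n/K)`.
#' Death rates are never throttled. This keeps all population sizes inside
#' a biologically feasible range without hard caps.
#'
#' @param base_rate per-capita (or per-channel) birth rate.
#' @param n current population size (nonnegative).
#' @param K carrying capacity (strictly positive).
#' @return the effective rate, nonincreasing in `n` and zero for `n >= K`.
#' @examples
#' logistic_throttle(0.2, 0, 1000)    # = 0.2
#' logistic_throttle(0.2, 500, 1000)  # = 0.1
#' logistic_throttle(0.2, 1000, 1000) # = 0
#' @export
logistic_throttle <- function(base_rate, n, K) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("carrying capacity K must be > 0", call. = FALSE)
  if (any(n < 0)) stop("population size n must be >= 0", call. = FALSE)
  base_rate * pmax(0, 1 - n / K)
}
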