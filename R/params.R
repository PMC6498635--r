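#' Simulation parameters
#'
#' Builds a validated parameter set for [simulate_immune()]. Every constant
#' of the model is exposed here; defaults reproduce the self-centered (ERS)
#' configuration used throughout the package documentation. The conventional
#' (CRS) model differs by exactly four switches, applied by
#' `sim_params(model = "crs")`: `medrepr 1 -> 0` and `weakrepr 1 -> 0`
#' (intermediate and weak divisions off), `comptype 0 -> 1` (thymic
#' selection becomes negative-only) and `tauthm 5 -> 30` (slower T helper
#' output from the marrow, compensating the wider surviving repertoire).
#'
#' @section Core parameters:
#' \describe{
#'   \item{r0}{action (binding) radius of B cells on the antigen lattice
#'     (default 150). Larger values let B cells reach more self antigens and
#'     push the system toward autoimmunity.}
#'   \item{pmem}{probability that a strong-division offspring becomes a
#'     memory B cell (default 0.3).}
#'   \item{pmut}{probability that a division mutates the offspring receptor
#'     (default 0.4).}
#'   \item{rminnew, crnew}{mutation offset magnitudes for intermediate and
#'     strong divisions are uniform integers in
#'     `[rminnew, round(rminnew/crnew)]` (defaults 5, 0.9).}
#'   \item{rminsprd, crspread}{the analogous magnitude range for weak
#'     (homeostatic) divisions (defaults 5, 0.9).}
#'   \item{thrad}{T helper action radius on the peptide lattice
#'     (default 80).}
#'   \item{taub0, tauth0}{mean waiting times between two actions of a B
#'     cell (5) and of a Th cell (2), in steps of 0.1 day.}
#'   \item{tauthm, taubm}{mean waiting times between two marrow births of
#'     Th cells (5; 30 under CRS) and of B cells (5).}
#'   \item{tcrit_stress}{critical time a foreign-presenting B cell may stay
#'     without regulatory contact before it activates and emits danger
#'     signals (default 2 steps).}
#'   \item{nr, tr}{default infection size (350 cells) and mean waiting time
#'     between two pathogen divisions (60 steps), used when an infection
#'     entry omits them.}
#' }
#'
#' @section Selection geometry:
#' `b_negsel_radius` (50) is the radius of the central exclusion ball used
#' by B-cell negative selection (`b_negsel = 0` disables it, the
#' autoimmunity knockout); `ring_inner`/`ring_outer` (50/80) bound the
#' characteristic annulus around each self-peptide mirror image in which
#' thymic positive selection marks emigrants as regulatory (self-centered
#' model only).
#'
#' @param model `"ers"` (self-centered, the default) or `"crs"`
#'   (conventional); applies the four-parameter switch before `...`.
#' @param ... named parameter overrides (see Details and
#'   [default_sim_params()] for the complete key list).
#' @param self a data frame with columns `x`, `y`, `count`, `divwait`,
#'   `capacity`, one row per self-antigen population. The default is the
#'   three non-immune self populations at (550, 300), (700, -200),
#'   (850, 150), 150 cells each.
#' @param infections a data frame with columns `time`, `count`, `divwait`,
#'   `x`, `y`, one row per scheduled pathogen injection (empty by default).
#' @return an object of class `sim_params` (a named list).
#' @examples
#' p <- sim_params()                     # default self-centered model
#' p_crs <- sim_params(model = "crs")    # conventional model switch
#' p2 <- sim_params(t_max = 1000, record_every = 10)
#' @export
sim_params <- function(model = c("ers", "crs"), ..., self = NULL,
                       infections = NULL) {
  model <- match.arg(model)
  p <- default_sim_params()
  if (model == "crs") {
    p$medrepr <- 0; p$weakrepr <- 0; p$comptype <- 1; p$tauthm <- 30
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  }
  if (!is.null(self)) p$self <- as.data.frame(self)
  if (!is.null(infections)) p$infections <- as.data.frame(infections)
  rownames(p$self) <- NULL
  rownames(p$infections) <- NULL
  p$model <- if (p$comptype == 0) "ers" else "crs"
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

#' Default parameter values
#'
#' @return a plain named list holding every parameter and its default; see
#'   [sim_params()] for meanings.
#' @export
default_sim_params <- function() {
  list(
    # model switches
    model = "ers", comptype = 0, medrepr = 1, weakrepr = 1,
    # action / binding
    r0 = 150, thrad = 80, taub0 = 5, tauth0 = 2,
    # mutation
    pmut = 0.4, rminnew = 5, crnew = 0.9, rminsprd = 5, crspread = 0.9,
    # memory / plasma
    pmem = 0.3, s_plasma = 3, plasma_life = 40,
    # marrow output and immigration
    tauthm = 5, taubm = 10, t_immigration = 100,
    marrow_init = 10, tau_marrow = 50, k_marrow = 500,
    # selection geometry
    b_negsel = 1, b_negsel_radius = 50, ring_inner = 50, ring_outer = 80,
    # lymphocyte demography
    kb = 2000, kth = 2000, b_life = 1000, th_life = 1000,
    # activation control / danger / interleukins
    tau_control = 1, tcrit_stress = 2,
    danger_burst = 10, il_burst = 10, k_danger = 500, k_il = 500,
    tau_danger_act = 5, tau_danger_decay = 10,
    tau_il_act = 5, tau_il_decay = 5,
    # division probabilities and affinity weighting
    p_weak_div = 0.3, p_th_weak_div = 0.05, p_th_strong_div = 0.5,
    p_contraction = 0.9,
    k_treg = 100, aff_exp = 2, act_speedup = 24,
    # antibodies
    ab_burst = 10, tau_abprod = 1, tau_ab_act = 10, ab_kill = 10,
    tau_ab_decay = 20, ab_radius = 100, k_ab = 5000,
    # pathogens and outcome thresholds
    nr = 350, tr = 60, k_foreign = 100000,
    elim_threshold = 50, death_threshold = 4000,
    # engine
    N = 1000, t_max = 5000, seed = NA_real_, record_every = 1,
    debug_log = 0, snapshot_at = numeric(0),
    # initial world
    self = data.frame(
      x = c(550, 700, 850), y = c(300, -200, 150),
      count = c(150, 150, 150), divwait = c(50, 50, 50),
      capacity = c(1000, 1000, 1000)
    ),
    infections = data.frame(
      time = numeric(0), count = numeric(0), divwait = numeric(0),
      x = numeric(0), y = numeric(0)
    )
  )
}

prob_keys <- c("pmem", "pmut", "p_weak_div", "p_th_weak_div",
               "p_th_strong_div", "p_contraction")
wait_keys <- c("taub0", "tauth0", "tauthm", "taubm", "tau_marrow",
               "tau_control", "tau_danger_act", "tau_danger_decay",
               "tau_il_act", "tau_il_decay", "tau_abprod", "tau_ab_act",
               "tau_ab_decay", "tcrit_stress", "tr", "b_life", "th_life",
               "plasma_life")
flag_keys <- c("comptype", "medrepr", "weakrepr", "b_negsel", "debug_log")
capacity_keys <- c("kb", "kth", "k_treg", "k_marrow", "k_danger", "k_il",
                   "k_ab", "k_foreign")

validate_sim_params <- function(p) {
  num1 <- function(key) {
    v <- p[[key]]
    if (length(v) != 1L || !is.numeric(v) || is.na(v))
      stop("parameter '", key, "' must be a single number", call. = FALSE)
    v
  }
  for (k in prob_keys) {
    v <- num1(k)
    if (v < 0 || v > 1)
      stop("parameter '", k, "' must be a probability in [0, 1]", call. = FALSE)
  }
  for (k in wait_keys) {
    if (num1(k) <= 0)
      stop("parameter '", k, "' must be a positive waiting time", call. = FALSE)
  }
  for (k in flag_keys) {
    if (!num1(k) %in% c(0, 1))
      stop("parameter '", k, "' must be 0 or 1", call. = FALSE)
  }
  for (k in capacity_keys) {
    if (num1(k) <= 0)
      stop("parameter '", k, "' (carrying capacity) must be > 0", call. = FALSE)
  }
  for (k in c("r0", "thrad", "rminnew", "rminsprd", "s_plasma", "ab_burst",
              "ab_kill", "t_max", "record_every", "act_speedup")) {
    if (num1(k) < 1) stop("parameter '", k, "' must be >= 1", call. = FALSE)
  }
  for (k in c("b_negsel_radius", "ring_inner", "ring_outer", "ab_radius",
              "nr", "marrow_init", "t_immigration", "aff_exp",
              "danger_burst", "il_burst")) {
    if (num1(k) < 0) stop("parameter '", k, "' must be >= 0", call. = FALSE)
  }
  for (k in c("crnew", "crspread")) {
    if (num1(k) <= 0) stop("parameter '", k, "' must be > 0", call. = FALSE)
  }
  if (p$ring_inner > p$ring_outer)
    stop("ring_inner must not exceed ring_outer", call. = FALSE)
  if (num1("elim_threshold") >= num1("death_threshold"))
    stop("elim_threshold must be below death_threshold", call. = FALSE)
  shape_lattice(p$N)  # validates N
  lat <- shape_lattice(p$N)
  stopifnot(is.data.frame(p$self), is.data.frame(p$infections))
  need_self <- c("x", "y", "count", "divwait", "capacity")
  if (!all(need_self %in% names(p$self)))
    stop("self populations need columns ", paste(need_self, collapse = ", "),
         call. = FALSE)
  if (nrow(p$self) < 1L) stop("at least one self population is required", call. = FALSE)
  check_on_lattice(cbind(p$self$x, p$self$y), lat)
  if (any(p$self$count < 0) || any(p$self$divwait <= 0) || any(p$self$capacity <= 0))
    stop("invalid self population row", call. = FALSE)
  need_inf <- c("time", "count", "divwait", "x", "y")
  if (!all(need_inf %in% names(p$infections)))
    stop("infections need columns ", paste(need_inf, collapse = ", "),
         call. = FALSE)
  if (nrow(p$infections)) {
    check_on_lattice(cbind(p$infections$x, p$infections$y), lat)
    if (any(p$infections$count < 0) || any(p$infections$divwait <= 0) ||
        any(p$infections$time < 0))
      stop("invalid infection row", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> model:", x$model,
      sprintf("(comptype=%d medrepr=%d weakrepr=%d tauthm=%g)\n",
              x$comptype, x$medrepr, x$weakrepr, x$tauthm))
  cat("  lattice N =", x$N, "| t_max =", x$t_max,
      "| self populations:", nrow(x$self),
      "| infections:", nrow(x$infections), "\n")
  invisible(x)
}

#' Read and write parameter files
#'
#' The parameter file dialect is one `key value` pair per line; `#` starts
#' a comment and blank lines are ignored. Three compound keys are allowed:
#' `model ers|crs` applies the four-parameter model switch, `self x y count
#' divwait capacity` adds a self population (the first `self` line replaces
#' the built-in three), and `infect time count divwait [x y]` schedules a
#' pathogen injection (shape defaults to `(150, -150)` if omitted; count
#' and divwait default to `nr` and `tr` when given as `.`). `snapshot_at`
#' takes a space-separated list of times. Missing keys take the documented
#' defaults; unknown keys and out-of-range values are errors naming the
#' offending line.
#'
#' @param path path to a parameter file (or use `text`).
#' @param text the file content as a character scalar or vector of lines.
#' @return `parse_params()` returns a validated [sim_params()] object.
#' @examples
#' p <- parse_params(text = c("model crs", "t_max 1000", "# comment"))
#' p$tauthm  # 30, set by the model switch
#' @export
parse_params <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("supply 'path' or 'text'", call. = FALSE)
    text <- readLines(path, warn = FALSE)
  } else if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  defaults <- default_sim_params()
  scalar_keys <- names(defaults)[vapply(defaults, function(v)
    is.numeric(v) && length(v) == 1L, logical(1))]
  model <- "ers"
  overrides <- list()
  self_rows <- NULL
  inf_rows <- NULL
  snap <- NULL
  for (i in seq_along(text)) {
    line <- sub("#.*$", "", text[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    toks <- strsplit(line, "[[:space:]]+")[[1L]]
    key <- toks[1L]
    vals <- toks[-1L]
    err <- function(msg) stop(sprintf("parameter file line %d: %s", i, msg),
                              call. = FALSE)
    if (key == "model") {
      if (length(vals) != 1L || !vals %in% c("ers", "crs"))
        err("model must be 'ers' or 'crs'")
      model <- vals
    } else if (key == "self") {
      if (length(vals) != 5L) err("self needs: x y count divwait capacity")
      v <- suppressWarnings(as.numeric(vals))
      if (anyNA(v)) err("malformed self values")
      self_rows <- rbind(self_rows, v)
    } else if (key == "infect") {
      if (!length(vals) %in% c(3L, 5L))
        err("infect needs: time count divwait [x y]")
      vals[vals == "."] <- NA
      v <- suppressWarnings(as.numeric(vals))
      if (is.na(v[1L])) err("malformed infect time")
      if (length(v) == 3L) v <- c(v, 150, -150)
      inf_rows <- rbind(inf_rows, v)
    } else if (key == "snapshot_at") {
      v <- suppressWarnings(as.numeric(vals))
      if (anyNA(v)) err("malformed snapshot_at values")
      snap <- v
    } else if (key %in% scalar_keys) {
      if (length(vals) != 1L) err(paste0("'", key, "' takes one value"))
      v <- suppressWarnings(as.numeric(vals))
      if (is.na(v)) err(paste0("malformed value for '", key, "'"))
      overrides[[key]] <- v
    } else {
      err(paste0("unknown key '", key, "'"))
    }
  }
  args <- c(list(model = model), overrides)
  if (!is.null(self_rows)) {
    colnames(self_rows) <- c("x", "y", "count", "divwait", "capacity")
    args$self <- as.data.frame(self_rows)
  }
  if (!is.null(inf_rows)) {
    colnames(inf_rows) <- c("time", "count", "divwait", "x", "y")
    inf <- as.data.frame(inf_rows)
    nr0 <- if (!is.null(overrides$nr)) overrides$nr else defaults$nr
    tr0 <- if (!is.null(overrides$tr)) overrides$tr else defaults$tr
    inf$count[is.na(inf$count)] <- nr0
    inf$divwait[is.na(inf$divwait)] <- tr0
    args$infections <- inf
  }
  if (!is.null(snap)) args$snapshot_at <- snap
  p <- tryCatch(do.call(sim_params, args),
                error = function(e) stop("invalid parameter file: ",
                                         conditionMessage(e), call. = FALSE))
  p
}

#' @rdname parse_params
#' @param p a [sim_params()] object.
#' @return `format_params()` returns the parameter file text (a character
#'   vector of lines) such that `parse_params(text = format_params(p))`
#'   reproduces `p`; `write_params()` writes it to `path` and returns the
#'   path invisibly.
#' @export
format_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  defaults <- default_sim_params()
  scalar_keys <- names(defaults)[vapply(defaults, function(v)
    is.numeric(v) && length(v) == 1L, logical(1))]
  scalar_keys <- setdiff(scalar_keys, "seed")
  lines <- c(paste("model", p$model),
             vapply(scalar_keys, function(k)
               paste(k, format(p[[k]], digits = 15)), character(1)))
  if (!is.na(p$seed)) lines <- c(lines, paste("seed", format(p$seed)))
  lines <- c(lines, apply(p$self, 1L, function(r)
    paste("self", paste(format(unname(r), digits = 15), collapse = " "))))
  if (nrow(p$infections))
    lines <- c(lines, apply(p$infections, 1L, function(r)
      paste("infect", paste(format(unname(r), digits = 15), collapse = " "))))
  if (length(p$snapshot_at))
    lines <- c(lines, paste("snapshot_at",
                            paste(format(p$snapshot_at), collapse = " ")))
  unname(lines)
}

#' @rdname parse_params
#' @export
write_params <- function(p, path) {
  writeLines(format_params(p), path)
  invisible(path)
}
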