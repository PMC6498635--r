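#' One-sided Fisher exact test on a 2x2 win/loss table
#'
#' Computes the upper hypergeometric tail probability of observing at least
#' as many wins in the first column as seen, given the table margins:
#' \deqn{p = \sum_{i=a}^{\min(W, n_1)} \binom{W}{i} \binom{L}{n_1-i} /
#'       \binom{W+L}{n_1}}
#' where `a` is the observed win count of column 1, `W`/`L` the win/loss
#' row totals and `n_1` the column-1 total. Terms are accumulated in log
#' space (via [lchoose()] and a log-sum-exp), so tails far below the double
#' underflow threshold of intermediate factorials are computed accurately.
#'
#' @param wins1,losses1 wins and losses of the first arm (the one whose
#'   win enrichment is tested).
#' @param wins2,losses2 wins and losses of the second arm.
#' @param table alternatively, a 2x2 matrix `rbind(c(wins1, wins2),
#'   c(losses1, losses2))`.
#' @return the one-sided p-value. A table with a zero margin returns 1.
#' @examples
#' fisher_one_sided(417, 83, 225, 275)   # ~4.48e-38
#' fisher_one_sided(5, 0, 0, 5)          # 1/252
#' @export
fisher_one_sided <- function(wins1, losses1, wins2, losses2, table = NULL) {
  if (!is.null(table)) {
    stopifnot(is.matrix(table), all(dim(table) == 2L))
    wins1 <- table[1L, 1L]; wins2 <- table[1L, 2L]
    losses1 <- table[2L, 1L]; losses2 <- table[2L, 2L]
  }
  cells <- c(wins1, losses1, wins2, losses2)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("table cells must be nonnegative integers", call. = FALSE)
  a <- wins1
  W <- wins1 + wins2          # win row total
  L <- losses1 + losses2      # loss row total
  n1 <- wins1 + losses1       # column-1 total
  n <- W + L
  if (W == 0 || L == 0 || n1 == 0 || n1 == n) return(1)
  hi <- min(W, n1)
  i <- a:hi
  logterms <- lchoose(W, i) + lchoose(L, n1 - i) - lchoose(n, n1)
  m <- max(logterms)
  exp(m + log(sum(exp(logterms - m))))
}

#' Welch two-sample t-test (two-tailed)
#'
#' The unequal-variance t statistic with Satterthwaite degrees of freedom,
#' used to compare mean elimination times between the first and second
#' infection. Identical degenerate samples (both variances zero, equal
#' means) return p = 1 by convention.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return a list with `statistic`, `df` and `p.value`.
#' @examples
#' welch_t_test(rnorm(20), rnorm(20))
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  if (vx + vy == 0) {
    p <- if (mean(x) == mean(y)) 1 else 0
    return(list(statistic = if (p == 1) 0 else Inf, df = NA_real_,
                p.value = p))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = tstat, df = df,
       p.value = 2 * stats::pt(-abs(tstat), df))
}
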