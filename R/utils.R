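# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round a percentage half-up to an integer
#'
#' Integer percentages are reported with ties rounded away from zero
#' (half-up), e.g. `268/851` of detected lncRNAs becomes 31 percent.
#'
#' @param x Numeric vector of percentages.
#' @return Integer vector.
#' @export
#' @examples
#' pct_round(100 * 268 / 851) # 31
pct_round <- function(x) {
  stopifnot(is.numeric(x))
  as.integer(floor(x + 0.5))
}

# stop() with a consistent prefix naming the offending stage/input
abort <- function(...) stop(sprintf(...), call. = FALSE)

# check a data frame has the required columns, error naming the missing one
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    abort("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}

# Vectorised Welch two-sample t-test p-values (two-sided), tolerant of
# zero-variance rows: equal means -> p = 1, separated constant groups -> p = 0.
welch_p <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  unname(p)
}

# deterministic child seed derived from a base seed (kept below 2^31)
child_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}
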