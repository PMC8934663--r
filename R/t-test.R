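#' Two-sample Student's t test on efficiency weights
#'
#' The per-cell statistic of the feature model: guides carrying a given
#' nucleotide at a given position (`x`) versus all remaining guides (`y`),
#' compared on their mean efficiencies. The classical pooled-variance form is
#' the default; Welch's unequal-variance form is available as an option.
#'
#' Degenerate inputs (either group smaller than 2, or zero pooled variance so
#' the statistic is incomputable) yield an *undefined* outcome — `NA`
#' statistics with `defined = FALSE` — rather than an error, so fixed PAM
#' positions flow through the pipeline silently.
#'
#' @param x,y numeric vectors of weights (percent efficiencies) for the
#'   in-group and out-group.
#' @param var_equal logical; `TRUE` (default) for the pooled-variance
#'   Student's t, `FALSE` for Welch.
#' @param alternative `"two.sided"` (default) or `"one.sided"`. The one-sided
#'   p-value is the tail probability in the observed direction,
#'   `pt(-|t|, df)`; the direction itself is carried in the sign of `t`.
#' @return list with `t`, `df`, `p`, `defined`.
#' @examples
#' kp_t_test(c(90, 80), c(20, 30, 10))  # t ~ 7.8, p ~ 0.0044
#' @export
kp_t_test <- function(x, y, var_equal = TRUE,
                      alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("weights must be finite")
  }
  n1 <- length(x); n2 <- length(y)
  undefined <- list(t = NA_real_, df = NA_real_, p = NA_real_, defined = FALSE)
  if (n1 < 2L || n2 < 2L) return(undefined)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    if (sp2 <= 0) {
      # no spread at all: equal means carry no signal (t = 0, p = 1);
      # distinct means make the statistic incomputable
      if (m1 == m2) return(list(t = 0, df = df, p = 1, defined = TRUE))
      return(undefined)
    }
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    if (se2 <= 0) {
      if (m1 == m2) {
        return(list(t = 0, df = n1 + n2 - 2, p = 1, defined = TRUE))
      }
      return(undefined)
    }
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    se <- sqrt(se2)
  }
  t <- (m1 - m2) / se
  p <- stats::pt(-abs(t), df)
  if (alternative == "two.sided") p <- 2 * p
  p <- min(p, 1)
  list(t = t, df = df, p = p, defined = TRUE)
}
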