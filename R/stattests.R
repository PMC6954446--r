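#' @title Statistical tests used by the signal analyses
#' @description Closed-form implementations of the two-sample
#'   Kolmogorov-Smirnov test (asymptotic p), Welch's two-sample t test and
#'   the one-sample t test. Implemented directly so the test suite can check
#'   them against the independent `stats` implementations; zero-variance
#'   degenerate inputs follow the conventions documented per function.
#' @name stattests
NULL

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference between the two empirical
#' CDFs; the p-value uses the asymptotic Kolmogorov distribution with
#' effective sample size `n*m/(n+m)`.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            !anyNA(x), !anyNA(y))
  grid <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(grid)
  Fy <- stats::ecdf(y)(grid)
  D <- max(abs(Fx - Fy))
  en <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(en) * D
  if (lambda == 0) {
    p <- 1
  } else {
    j <- seq_len(100)
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(max(p, 0), 1)
  }
  list(statistic = D, p.value = p)
}

#' Welch two-sample t test (two-tailed)
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom. When both
#' samples have zero variance: p = 1 if the means are equal (t = 0), else
#' t is infinite with p = 0.
#'
#' @param a,b numeric samples, each with at least 2 values.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  dm <- mean(a) - mean(b)
  if (va + vb == 0) {
    if (dm == 0) return(list(statistic = 0, df = NA_real_, p.value = 1))
    return(list(statistic = sign(dm) * Inf, df = NA_real_, p.value = 0))
  }
  t <- dm / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' One-sample t test against a reference mean (two-tailed)
#'
#' Used to compare a site's replicate signals against the genome-average
#' signal. Zero sample variance: p = 1 when the sample mean equals `mu`
#' (t = 0), else t infinite with p = 0.
#'
#' @param a numeric sample with at least 2 values.
#' @param mu reference mean.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
one_sample_t_test <- function(a, mu) {
  stopifnot(length(a) >= 2L, is.numeric(mu), length(mu) == 1L)
  s <- stats::sd(a)
  dm <- mean(a) - mu
  if (s == 0) {
    if (dm == 0) return(list(statistic = 0, df = length(a) - 1, p.value = 1))
    return(list(statistic = sign(dm) * Inf, df = length(a) - 1, p.value = 0))
  }
  t <- dm / (s / sqrt(length(a)))
  df <- length(a) - 1
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}
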