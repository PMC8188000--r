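#' @include AllClasses.R
NULL

#' Mann-Whitney rank test for virtual vs observed samples
#'
#' Two-tailed rank-sum test with midrank ties. The p-value is exact
#' (distribution of the U statistic) for combined sample sizes up to 20
#' without ties, and otherwise uses the normal approximation with tie
#' correction and continuity correction. \code{W} is reported in the
#' smaller-rank-sum convention (the smaller of the two samples' rank
#' sums); \code{U} is the first sample's Mann-Whitney statistic.
#'
#' @param a,b numeric samples (non-empty).
#' @return list with \code{U}, \code{W}, \code{p}, and \code{method}
#'   ("exact" or "normal approximation").
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))$p   # 1/3
#' @export
mannWhitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  R1 <- sum(r[seq_len(m)])
  R2 <- sum(r) - R1
  U1 <- R1 - m * (m + 1) / 2
  hasTies <- anyDuplicated(c(a, b)) > 0L
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical in both samples")
    return(list(U = U1, W = min(R1, R2), p = 1,
                method = "degenerate"))
  }
  if (!hasTies && N <= 20) {
    p <- if (U1 > m * n / 2) 1 - stats::pwilcox(U1 - 1, m, n)
         else stats::pwilcox(U1, m, n)
    p <- min(1, 2 * p)
    method <- "exact"
  } else {
    tie <- table(r)
    mu <- m * n / 2
    sigma2 <- m * n / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    cc <- sign(U1 - mu) * 0.5
    z <- (U1 - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(U = U1, W = min(R1, R2), p = p, method = method)
}

#' Summary statistics of a home-range metric sample
#'
#' The distribution summaries reported for home-range core areas,
#' perimeters and pairwise overlaps: sample size, mean, median,
#' inter-quartile range (linear-interpolation quartiles, R type 7) and
#' the sign of skew assessed as \code{sign(mean - median)}.
#'
#' @param values non-empty numeric vector.
#' @return list with \code{n}, \code{mean}, \code{median}, \code{iqr},
#'   \code{skewnessSign}.
#' @examples
#' summarizeSample(c(1, 2, 3, 10))
#' @export
summarizeSample <- function(values) {
  if (!length(values)) stop("empty sample")
  list(n = length(values), mean = mean(values),
       median = stats::median(values),
       iqr = unname(stats::quantile(values, 0.75, type = 7) -
                    stats::quantile(values, 0.25, type = 7)),
       skewnessSign = sign(mean(values) - stats::median(values)))
}

#' Compare virtual and observed distributions
#'
#' Convenience wrapper producing the comparison report used for output
#' verification: summary statistics of both samples plus the two-tailed
#' Mann-Whitney test.
#'
#' @param virtual,observed numeric samples (e.g. pairwise overlap
#'   percentages of virtual and wild birds).
#' @return list with \code{virtual}, \code{observed} (each a
#'   [summarizeSample()] result) and \code{test} (a [mannWhitney()]
#'   result).
#' @export
compareDistributions <- function(virtual, observed) {
  list(virtual = summarizeSample(virtual),
       observed = summarizeSample(observed),
       test = mannWhitney(virtual, observed))
}
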