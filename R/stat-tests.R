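# Two-sample test wrappers shared by the subset analyses: Welch's unequal-
# variance t-test with an epsilon-variance guard for degenerate (constant)
# groups, and the Mann-Whitney U test with a guard for all-tied samples.

#' Welch two-sample t-test with degenerate-input guard
#'
#' Calls [stats::t.test()] with `var.equal = FALSE`. When both groups are
#' constant, `t.test()` refuses; here equal constants give `t = 0, p = 1`,
#' and distinct constants are compared under a small epsilon variance so
#' that extreme separations still yield a (vanishingly small) p-value.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param eps variance floor used only when both groups are constant.
#' @return list with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_test <- function(x, y, eps = 1e-12) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("welch_test requires at least 2 observations per group",
         call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  mx <- mean(x); my <- mean(y)
  if (vx <= eps && vy <= eps) {
    if (isTRUE(all.equal(mx, my))) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  mean_x = mx, mean_y = my))
    }
    nx <- length(x); ny <- length(y)
    se2 <- eps / nx + eps / ny
    tt <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((eps / nx)^2 / (nx - 1) + (eps / ny)^2 / (ny - 1))
    return(list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
                mean_x = mx, mean_y = my))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mx, mean_y = my)
}

#' Mann-Whitney U test with all-tied guard
#'
#' Calls [stats::wilcox.test()] (exact for small untied samples, normal
#' approximation with tie correction otherwise). When every observation in
#' both groups is identical the statistic is the null expectation
#' `n1 * n2 / 2` and `p = 1`.
#'
#' @param x,y numeric vectors.
#' @return list with `U` (statistic of the first sample) and `p`
#'   (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("mann_whitney_u requires non-empty groups", call. = FALSE)
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(ht$statistic), p = ht$p.value)
}

# vectorized Welch t-test from group means/variances/sizes (used by the
# process-specificity criterion on 0/1 indicator counts)
welch_from_moments <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df),
              ifelse(m1 == m2, 1, 0))
  t_stat[se2 == 0 & m1 == m2] <- 0
  t_stat[se2 == 0 & m1 != m2] <- ifelse(m1 > m2, Inf, -Inf)[se2 == 0 & m1 != m2]
  list(t = t_stat, df = df, p = p)
}
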