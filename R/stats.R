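#' Percent change in the influx constant
#'
#' `(baseline - post) / baseline * 100`: positive when the second scan is
#' lower than baseline, negative when it is higher. A group whose mean
#' rises under challenge therefore has a negative mean percent change.
#'
#' @param ki_baseline baseline Ki values (min^-1, > 0).
#' @param ki_post post/second-scan Ki values (min^-1).
#' @return Percent change, same length as the inputs.
#' @export
percent_change <- function(ki_baseline, ki_post) {
  if (any(!is.finite(ki_baseline)) || any(ki_baseline <= 0))
    stop("baseline Ki must be positive")
  (ki_baseline - ki_post) / ki_baseline * 100
}

#' Correlation with two-tailed p-value
#'
#' Pearson (p from the t-distribution transform of r) or Spearman (p from
#' the asymptotic t approximation on the rank correlation). Exclusions are
#' applied by position id and recorded in the result; no observation is
#' ever removed automatically.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @param ids optional identifiers, parallel to `x`.
#' @param exclude ids to drop before computing.
#' @return List with `r`, `n`, `p_two_tailed`, `method`, `excluded_ids`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      ids = NULL, exclude = character(0)) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.null(ids)) ids <- as.character(seq_along(x))
  keep <- !(ids %in% exclude)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("insufficient data: need >= 3 pairs after exclusions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, n = n, p_two_tailed = p, method = method,
       excluded_ids = as.character(exclude))
}

#' Paired t-test on two scans
#'
#' t on the within-subject differences `pre - post`, df = n - 1,
#' two-tailed p.
#'
#' @param pre,post numeric vectors of equal length (>= 2).
#' @return List with `t`, `df`, `p_two_tailed`, `kind = "paired"`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  n <- length(pre)
  if (n < 2L) stop("insufficient data: need >= 2 pairs")
  d <- pre - post
  if (all(d == d[1]) && d[1] != 0)
    stop("degenerate input: zero difference variance")
  if (stats::sd(d) == 0) {
    # identical vectors: t = 0 by convention
    return(list(t = 0, df = n - 1, p_two_tailed = 1, kind = "paired"))
  }
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tstat, df = n - 1,
       p_two_tailed = 2 * stats::pt(-abs(tstat), df = n - 1),
       kind = "paired")
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (equal-variance) t from group means, SDs and sizes,
#' df = n1 + n2 - 2; useful when only printed summaries are available
#' (e.g. injected-activity tables). Welch's unequal-variance form is
#' available behind `welch = TRUE`.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @param welch use the Welch-Satterthwaite form instead of pooling.
#' @return List with `t`, `df`, `p_two_tailed`, `kind`.
#' @export
two_sample_t_summary <- function(m1, s1, n1, m2, s2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("insufficient data: both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be >= 0")
  if (s1 == 0 && s2 == 0) stop("degenerate input: both SDs zero")
  if (welch) {
    se2 <- s1^2 / n1 + s2^2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = tstat, df = df,
       p_two_tailed = 2 * stats::pt(-abs(tstat), df = df),
       kind = "two_sample_summary")
}

#' Test-retest reliability: intraclass correlation and variability
#'
#' ICC from the two-way subjects-by-scans ANOVA mean squares
#' (McGraw-Wong): the default `"agreement"` variant is ICC(A,1) (two-way,
#' absolute agreement, single measures), which penalises a systematic
#' scan-to-scan offset; `"consistency"` is ICC(C,1), invariant to a common
#' offset. Test-retest variability (TRV) is the mean over subjects of
#' `|s1 - s2| / ((s1 + s2)/2) * 100`.
#'
#' @param scan1,scan2 paired measurements, length >= 3.
#' @param icc_variant `"agreement"` or `"consistency"`.
#' @return List with `icc`, `icc_variant`, `trv_percent`, `n`.
#' @export
reliability <- function(scan1, scan2, icc_variant = c("agreement", "consistency")) {
  icc_variant <- match.arg(icc_variant)
  if (length(scan1) != length(scan2)) stop("scans must have equal length")
  n <- length(scan1)
  if (n < 3L) stop("insufficient data: need >= 3 subjects")
  dat <- c(scan1, scan2)
  if (stats::sd(dat) == 0) stop("degenerate input: zero total variance")
  k <- 2
  row_means <- (scan1 + scan2) / 2
  col_means <- c(mean(scan1), mean(scan2))
  grand <- mean(dat)
  msr <- k * sum((row_means - grand)^2) / (n - 1)          # subjects
  msc <- n * sum((col_means - grand)^2) / (k - 1)          # scans
  sse <- sum((scan1 - row_means - col_means[1] + grand)^2) +
         sum((scan2 - row_means - col_means[2] + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- switch(icc_variant,
    agreement   = (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)),
    consistency = (msr - mse) / (msr + (k - 1) * mse)
  )
  trv <- mean(abs(scan1 - scan2) / ((scan1 + scan2) / 2)) * 100
  list(icc = icc, icc_variant = icc_variant, trv_percent = trv, n = n)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS statistic of the data against a Normal with the *sample*
#' mean and SD. Because the reference parameters are estimated, the
#' classical KS null distribution does not apply; the p-value is computed
#' by Monte Carlo (the Lilliefors correction): `nsim` Normal samples of
#' the same size are drawn, the statistic recomputed for each, and
#' `p = (1 + #{D_sim >= D}) / (nsim + 1)`. The RNG state is saved and
#' restored around the simulation, and the simulation stream is fixed, so
#' the p-value is a deterministic function of the data and `nsim`.
#'
#' @param x numeric vector, length >= 3, non-zero variance.
#' @param nsim Monte-Carlo replicates for the p-value.
#' @return List with `statistic` (D) and `p` .
#' @export
ks_normality <- function(x, nsim = 1999) {
  n <- length(x)
  if (n < 3L) stop("insufficient data: need >= 3 observations")
  if (stats::sd(x) == 0) stop("degenerate input: zero variance")
  D <- .lilliefors_stat(x)
  sims <- with_local_seed(20170207L, {
    vapply(seq_len(nsim), function(i) .lilliefors_stat(stats::rnorm(n)), numeric(1))
  })
  list(statistic = D, p = (1 + sum(sims >= D)) / (nsim + 1))
}

.lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(max(seq_len(n) / n - p), max(p - (seq_len(n) - 1) / n))
}
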