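#' @include conditions.R
NULL

#' Intraclass correlation coefficient from a ratings matrix
#'
#' Single-rater ICCs in the Shrout-Fleiss convention, computed from the
#' two-way ANOVA mean squares of a complete targets x raters matrix
#' (rows = targets, columns = raters or repeated sessions):
#' \deqn{ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE)}
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)}
#' Model "3,1" treats raters as fixed (intra-tester reliability of one
#' reader's repeated sessions); model "2,1" treats raters as random and
#' penalises systematic between-rater shifts (inter-tester reliability).
#'
#' @param x numeric matrix, n targets x k raters, no missing cells,
#'   n >= 2 and k >= 2
#' @param model "3,1" or "2,1"
#' @return the ICC (a single number)
#' @examples
#' m <- cbind(1:6, (1:6) + 0.5)
#' icc(m, "3,1")   # 1: constant offset is forgiven by model 3
#' icc(m, "2,1") < 1
#' @export
icc <- function(x, model = c("3,1", "2,1")) {
  model <- match.arg(model)
  x <- as.matrix(x)
  .assert(is.numeric(x) && !anyNA(x), "x must be a complete numeric matrix")
  n <- nrow(x)
  k <- ncol(x)
  .assert(n >= 2L && k >= 2L, "need at least 2 targets and 2 raters")
  g <- mean(x)
  SST <- sum((x - g)^2)
  if (SST <= 1e-12 * max(1, g^2))
    .cdiStop("cdiUndefinedStatistic", "zero total variance: ICC undefined")
  SSR <- k * sum((rowMeans(x) - g)^2)
  SSC <- n * sum((colMeans(x) - g)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (model == "3,1")
    (MSR - MSE) / (MSR + (k - 1) * MSE)
  else
    (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

#' Standardized response mean
#'
#' SRM = mean change / sd of change (sample sd, n - 1 denominator). A
#' responsiveness index: the sign follows the direction of change.
#'
#' @param changes numeric vector of change scores, length >= 2
#' @return the SRM
#' @examples
#' srm(c(-1, -2, -3))
#' @export
srm <- function(changes) {
  .assert(is.numeric(changes) && length(changes) >= 2L && !anyNA(changes),
          "changes must be a numeric vector of length >= 2")
  s <- stats::sd(changes)
  if (s <= 0)
    .cdiStop("cdiUndefinedStatistic", "zero sd of change: SRM undefined")
  mean(changes) / s
}

#' Spearman rank correlation
#'
#' Pearson correlation of midrank-transformed values (average ranks for
#' ties).
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return the correlation in [-1, 1]
#' @export
spearmanCor <- function(x, y) {
  .assert(is.numeric(x) && is.numeric(y) && length(x) == length(y) &&
            length(x) >= 3L && !anyNA(x) && !anyNA(y),
          "x and y must be equal-length numeric vectors (n >= 3, no NA)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .cdiStop("cdiUndefinedStatistic",
             "constant vector: correlation undefined")
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Linear trend of an outcome over an ordinal grade
#'
#' Ordinary least squares of the outcome on the grade treated as a
#' continuous covariate; the reported p-value is the two-sided slope
#' t-test on n - 2 degrees of freedom.
#'
#' @param values per-knee outcome
#' @param grade per-knee ordinal grade (numeric)
#' @return list(slope, se, t, p, n)
#' @export
linearTrend <- function(values, grade) {
  .assert(is.numeric(values) && is.numeric(grade) &&
            length(values) == length(grade) && !anyNA(values) &&
            !anyNA(grade), "values and grade must be equal-length numeric")
  if (length(values) < 3L)
    .cdiStop("cdiValidationError", "need at least 3 observations")
  if (length(unique(grade)) < 2L)
    .cdiStop("cdiValidationError",
             "need at least 2 distinct grades for a trend")
  fit <- stats::lm(values ~ grade)
  co <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(co["grade", "Estimate"]),
       se = unname(co["grade", "Std. Error"]),
       t = unname(co["grade", "t value"]),
       p = unname(co["grade", "Pr(>|t|)"]),
       n = length(values))
}

#' Independent two-sample t-test
#'
#' Welch's test by default (no equal-variance assumption); the pooled
#' variant is available for sensitivity analysis.
#'
#' @param a,b numeric vectors, each of length >= 2
#' @param variant "welch" (default) or "pooled"
#' @return list(t, df, p, meanA, meanB)
#' @export
twoSampleT <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  .assert(is.numeric(a) && is.numeric(b) && length(a) >= 2L &&
            length(b) >= 2L && !anyNA(a) && !anyNA(b),
          "each group needs >= 2 numeric values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                meanA = mean(a), meanB = mean(b)))
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanA = mean(a), meanB = mean(b))
}

#' Stratified summary of an outcome with a linear-trend test
#'
#' Per-stratum n, mean and sd of an outcome over an ordinal stratifier
#' (e.g. JSN or KL grade), plus the linear trend p-value across strata.
#' Empty strata are reported with n = 0 and excluded from the trend.
#'
#' @param records data.frame of subject records
#' @param stratifier name of the ordinal grade column
#' @param outcome name of the outcome column
#' @param levels grade levels to report (default: observed range)
#' @return list(table = data.frame(grade, n, mean, sd), trend = result of
#'   \code{\link{linearTrend}} or NULL when fewer than 2 non-empty strata)
#' @export
groupSummary <- function(records, stratifier, outcome, levels = NULL) {
  .assert(is.data.frame(records) &&
            all(c(stratifier, outcome) %in% names(records)),
          "records must contain the stratifier and outcome columns")
  g <- records[[stratifier]]
  y <- records[[outcome]]
  keep <- !is.na(g) & !is.na(y)
  g <- g[keep]; y <- y[keep]
  if (is.null(levels)) levels <- sort(unique(g))
  tab <- data.frame(grade = levels,
                    n = vapply(levels, function(l) sum(g == l), integer(1)))
  tab$mean <- vapply(levels, function(l)
    if (any(g == l)) mean(y[g == l]) else NA_real_, numeric(1))
  tab$sd <- vapply(levels, function(l)
    if (sum(g == l) > 1) stats::sd(y[g == l]) else NA_real_, numeric(1))
  trend <- if (length(unique(g)) >= 2L && length(g) >= 3L)
    linearTrend(y, as.numeric(g)) else NULL
  list(table = tab, trend = trend)
}

#' Percent reduction of a comparison mean relative to a reference mean
#'
#' 100 * (1 - comparison/reference), rounded to the nearest integer for
#' reporting (e.g. how much lower the mean CDI of a severe stratum is than
#' the no-narrowing stratum).
#'
#' @param reference reference mean (> 0)
#' @param comparison comparison mean
#' @return integer percent reduction
#' @examples
#' percentReduction(1177.40, 762.74)   # 35
#' @export
percentReduction <- function(reference, comparison) {
  .assert(is.numeric(reference) && length(reference) == 1L &&
            is.finite(reference), "reference must be a single number")
  if (reference <= 0)
    .cdiStop("cdiValidationError", "reference mean must be positive")
  .assert(is.numeric(comparison) && length(comparison) == 1L &&
            is.finite(comparison), "comparison must be a single number")
  as.integer(round(100 * (1 - comparison / reference)))
}

#' Reconstruct a sample with exact mean and sd
#'
#' Utility for reproducing summary-based statistics (e.g. an SRM from a
#' published mean and sd): returns a vector of length n with exactly the
#' requested sample mean and sd.
#'
#' @param mean,sd target sample moments (sd > 0, n - 1 denominator)
#' @param n sample size (>= 2)
#' @return numeric vector of length n
#' @examples
#' x <- sampleWithMoments(-35.73, 50.14, 74)
#' round(srm(x), 2)   # -0.71
#' @export
sampleWithMoments <- function(mean, sd, n = 30L) {
  .assert(n >= 2L, "n must be >= 2")
  .assert(sd > 0, "sd must be positive")
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}
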