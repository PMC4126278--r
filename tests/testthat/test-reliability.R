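# Published change summaries (mean, sd, printed SRM) for femur / tibia /
# tibiofemoral CDI change, split by progression status under JSN and KL
# grading, used as worked examples for the SRM.
srmSummaries <- data.frame(
  region = rep(c("femur", "tibia", "tibiofemoral"), 4),
  grading = rep(c("jsn", "jsn", "kl", "kl"), each = 3),
  progression = rep(c(FALSE, TRUE, FALSE, TRUE), each = 3),
  n = rep(c(74, 25, 58, 39), each = 3),
  mean = c(-35.73, -10.86, -46.58, -87.82, -63.83, -151.7,
           -40.53, -15.86, -56.39, -64.06, -37.23, -101.3),
  sd = c(50.14, 23.99, 57.48, 68.62, 46.02, 90.95,
         49.84, 33.21, 64.12, 70.06, 43.34, 96.68),
  srm = c(-0.71, -0.45, -0.81, -1.28, -1.39, -1.67,
          -0.81, -0.48, -0.88, -0.91, -0.86, -1.05))

# Independent ANOVA oracle for the ICC: mean squares from stats::aov.
iccOracle <- function(x, model) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  target = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ target + rater, data = d))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  if (model == "3,1") (MSR - MSE) / (MSR + (k - 1) * MSE)
  else (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

test_that("ICC handles agreement, offsets, and matches the ANOVA oracle", {
  perfect <- cbind(1:6, 1:6, 1:6)
  expect_equal(icc(perfect, "3,1"), 1)
  expect_equal(icc(perfect, "2,1"), 1)

  # a constant between-rater offset: consistency forgives, agreement not
  shifted <- cbind(1:6, (1:6) + 2)
  expect_equal(icc(shifted, "3,1"), 1)
  expect_lt(icc(shifted, "2,1"), 1)

  set.seed(4)
  for (i in 1:20) {
    m <- matrix(rnorm(18, sd = 2), 6, 3) + rnorm(6, sd = 5)
    expect_equal(icc(m, "3,1"), iccOracle(m, "3,1"), tolerance = 1e-10)
    expect_equal(icc(m, "2,1"), iccOracle(m, "2,1"), tolerance = 1e-10)
  }

  expect_error(icc(matrix(1, 4, 3)), class = "cdiUndefinedStatistic")
  expect_error(icc(matrix(1:3, 3, 1)), class = "cdiValidationError")
})

test_that("ICC is invariant to target order and converges with n", {
  set.seed(8)
  m <- matrix(rnorm(40), 20, 2) + rnorm(20, sd = 3)
  expect_equal(icc(m, "2,1"), icc(m[sample(20), ], "2,1"))

  # planted variance components: between-target sd 3, error sd 1
  # -> analytic ICC = 9 / 10
  reps <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    x <- matrix(rnorm(400), 200, 2) + rnorm(200, sd = 3)
    icc(x, "3,1")
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.9), 0.02)
})

test_that("SRM reproduces the published worked examples to 2 dp", {
  for (i in seq_len(nrow(srmSummaries))) {
    x <- sampleWithMoments(srmSummaries$mean[i], srmSummaries$sd[i], srmSummaries$n[i])
    expect_equal(round(srm(x), 2), srmSummaries$srm[i],
                 info = paste(srmSummaries$region[i], srmSummaries$grading[i],
                              srmSummaries$progression[i]))
  }
  expect_error(srm(rep(3, 5)), class = "cdiUndefinedStatistic")
  x <- rnorm(20)
  expect_equal(srm(-x), -srm(x))
  expect_equal(srm(x[sample(20)]), srm(x))
})

test_that("Spearman correlation uses midranks and flags constants", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearmanCor(x, 2 * x + 1), 1)
  expect_equal(spearmanCor(x, -x^3), -1)

  # tie-laden case against a brute-force midrank computation
  xt <- c(1, 2, 2, 3, 3, 3, 4)
  yt <- c(2, 1, 4, 4, 5, 7, 7)
  midrank <- function(z) vapply(z, function(zi)
    mean(which(sort(z) == zi)), numeric(1))
  rx <- midrank(xt); ry <- midrank(yt)
  brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearmanCor(xt, yt), brute, tolerance = 1e-12)
  expect_equal(spearmanCor(xt, yt),
               suppressWarnings(cor(xt, yt, method = "spearman")))

  expect_error(spearmanCor(rep(1, 5), x), class = "cdiUndefinedStatistic")
})

test_that("linear trend recovers a planted slope and its closed form", {
  set.seed(21)
  grade <- rep(0:3, each = 10)
  y <- 1000 - 100 * grade + rnorm(40, sd = 30)
  tr <- linearTrend(y, grade)
  expect_lt(abs(tr$slope - (-100)), 3 * tr$se)
  expect_lt(tr$p, 0.01)
  expect_identical(tr$n, 40L)

  # closed-form OLS oracle
  slopeHat <- sum((grade - mean(grade)) * (y - mean(y))) /
    sum((grade - mean(grade))^2)
  expect_equal(tr$slope, slopeHat, tolerance = 1e-12)

  # exact linear outcome: p numerically zero
  exact <- linearTrend(5 - 2 * grade, grade)
  expect_lt(exact$p, 1e-10)

  expect_error(linearTrend(y, rep(1, 40)), class = "cdiValidationError")
  expect_error(linearTrend(y[1:2], grade[1:2]),
               class = "cdiValidationError")
})

test_that("two-sample t-test behaves under identity, swap, and planted shift", {
  a <- c(1, 2, 3, 4)
  id <- twoSampleT(a, a)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)

  set.seed(3)
  b <- rnorm(30); c <- rnorm(30, mean = 1)
  w1 <- twoSampleT(b, c)
  w2 <- twoSampleT(c, b)
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$p, w2$p)
  expect_equal(twoSampleT(b, c, "pooled")$df, 58)

  # power at a 1-sd shift, n = 30 per arm: >= 80% of 200 seeded runs
  hits <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    twoSampleT(rnorm(30), rnorm(30, 1))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  expect_error(twoSampleT(1, c(1, 2)), class = "cdiValidationError")
})

test_that("groupSummary stratifies and reports the trend", {
  set.seed(14)
  rec <- data.frame(jsn = rep(0:2, each = 12),
                    y = rep(c(1100, 900, 600), each = 12) + rnorm(36, sd = 50))
  gs <- groupSummary(rec, "jsn", "y", levels = 0:3)
  expect_identical(gs$table$n, c(12L, 12L, 12L, 0L))
  expect_true(is.na(gs$table$mean[4]))
  for (g in 0:2)
    expect_lt(abs(gs$table$mean[g + 1] - c(1100, 900, 600)[g + 1]),
              3 * 50 / sqrt(12))
  expect_lt(gs$trend$p, 0.01)

  single <- groupSummary(data.frame(jsn = rep(1, 5), y = rnorm(5)),
                         "jsn", "y")
  expect_null(single$trend)

  flat <- groupSummary(data.frame(jsn = rep(0:1, each = 5), y = rep(7, 10)),
                       "jsn", "y")
  expect_equal(flat$trend$slope, 0)
})

test_that("percent reduction reproduces the published stratum contrasts", {
  expect_identical(percentReduction(1177.40, 762.74), 35L)
  expect_identical(percentReduction(1177.40, 421.72), 64L)
  expect_identical(percentReduction(500, 500), 0L)
  expect_error(percentReduction(0, 100), class = "cdiValidationError")
  expect_error(percentReduction(-5, 100), class = "cdiValidationError")
})
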