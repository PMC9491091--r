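test_that("the z-score outlier screen removes only extreme points", {
  # one wild point among zeros: |z| > 3 on the full-sample moments
  x <- c(rep(0, 19), 100)
  y <- seq_len(20)
  kept <- screen_outliers(x, y, k = 3)
  expect_equal(kept, 1:19)
  # the same rule on the response side
  kept_y <- screen_outliers(y, x, k = 3)
  expect_equal(kept_y, 1:19)
  # no point beyond 3 SD: everything kept
  set.seed(8)
  a <- rnorm(30); b <- rnorm(30)
  a <- (a - mean(a)) / sd(a) * 0.9   # max |z| < 3 by construction
  expect_equal(screen_outliers(a, b, k = 3), seq_along(a)[
    abs(b - mean(b)) / sd(b) <= 3])
  # infinite cutoff is the identity
  expect_equal(screen_outliers(x, y, k = Inf), 1:20)
  expect_error(screen_outliers(1:3, 1:3), "at least 4")
})

test_that("adjusted R-squared reproduces the analytic value at r=0.66, n=19", {
  expect_equal(round(adjusted_r2(0.66, 19), 2), 0.40)
  # any dataset engineered to r = 0.66 at n = 19 gives the same number
  set.seed(9)
  x <- rnorm(19)
  e <- rnorm(19)
  e <- residuals(lm(e ~ x))            # orthogonalize
  y <- 0.66 * scale(x)[, 1] + sqrt(1 - 0.66^2) * scale(e)[, 1]
  fit <- simple_regression(x, y)
  expect_equal(fit$pearson_r, 0.66, tolerance = 1e-10)
  expect_equal(round(fit$adjusted_r2, 2), 0.40)
  expect_true(fit$adjusted_r2 <= fit$r2)
})

test_that("exact linear data give r = 1 and vanishing p", {
  x <- seq(0.5, 1.5, length.out = 10)
  fit <- simple_regression(x, 2 * x + 1)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-12)
  expect_lt(fit$p_raw, 1e-12)
  # regression of x on x: r exactly 1
  expect_equal(simple_regression(x, x)$pearson_r, 1)
  expect_error(simple_regression(rep(1, 5), 1:5), "zero variance")
  expect_error(simple_regression(1:3, 1:3), "at least 4")
})

test_that("the parametric p agrees with an exhaustive permutation p at n=5", {
  x <- c(0.52, 0.61, 0.70, 0.88, 0.95)
  y <- c(3, 9, 4, 12, 11)
  fit <- simple_regression(x, y)
  # enumerate all 120 orderings of y
  orderings <- as.matrix(expand.grid(rep(list(1:5), 5)))
  orderings <- orderings[apply(orderings, 1, function(r)
    length(unique(r)) == 5), ]
  r_obs <- abs(cor(x, y))
  r_null <- apply(orderings, 1, function(o) abs(cor(x, y[o])))
  p_perm <- mean(r_null >= r_obs - 1e-12)
  # the exhaustive permutation p is exact; at n = 5 the t-based p is an
  # approximation and agrees only to within a few hundredths
  expect_lt(abs(fit$p_raw - p_perm), 0.06)
})

test_that("the nine-assessment battery applies Bonferroni-9 and skips gaps", {
  set.seed(12)
  n <- 100
  dvr <- rnorm(n, 0.7, 0.1)
  cohort <- data.frame(subject_id = sprintf("s%03d", 1:n),
                       group = "CH", stringsAsFactors = FALSE)
  for (a in ASSESSMENTS) cohort[[a]] <- rnorm(n)
  # only MoCA_attention carries a true correlation with DVR
  rho <- 0.66
  z <- scale(dvr)[, 1]
  cohort$MoCA_attention <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  cohort$NPI[1:98] <- NA   # too few pairs -> skipped
  cohort$movement_artifact <- FALSE
  cohort$technical_issue <- FALSE
  names(dvr) <- cohort$subject_id

  out <- run_assessment_battery(cohort, dvr)
  res <- out$results
  expect_equal(nrow(res), 9)
  expect_equal(res$p_bonferroni,
               ifelse(is.na(res$p_raw), NA, pmin(1, 9 * res$p_raw)))
  expect_true(res$skipped[res$assessment == "NPI"])
  expect_match(res$skip_reason[res$assessment == "NPI"], "complete pairs")
  sig <- res$assessment[!res$skipped & res$p_bonferroni < 0.05]
  expect_equal(sig, "MoCA_attention")
  expect_true(all(res$adjusted_r2 <= res$r2, na.rm = TRUE))
  # diagnostics carry standardized residuals per fitted assessment
  expect_true(all(c("fitted", "std_residual") %in% names(out$diagnostics)))

  dup <- cbind(cohort, data.frame(GDS = 1))
  names(dup)[ncol(dup)] <- "GDS"
  expect_error(run_assessment_battery(dup, dvr), "duplicate")
})

test_that("only the truly associated assessment survives across replicates", {
  # power of the battery at n = 100, true r = 0.66: detection of the MoCA
  # signal should be near-certain, false positives rare
  set.seed(77)
  n <- 100
  hits <- 0; fp <- 0
  for (rep in 1:50) {
    dvr <- rnorm(n, 0.7, 0.1)
    cohort <- data.frame(subject_id = sprintf("s%03d", 1:n),
                         group = "CH", stringsAsFactors = FALSE)
    for (a in ASSESSMENTS) cohort[[a]] <- rnorm(n)
    z <- scale(dvr)[, 1]
    cohort$MoCA_attention <- 0.66 * z + sqrt(1 - 0.66^2) * rnorm(n)
    names(dvr) <- cohort$subject_id
    res <- run_assessment_battery(cohort, dvr)$results
    sig <- res$assessment[!res$skipped & res$p_bonferroni < 0.05]
    hits <- hits + ("MoCA_attention" %in% sig)
    fp <- fp + length(setdiff(sig, "MoCA_attention"))
  }
  expect_gte(hits / 50, 0.8)
  expect_lte(fp / 50, 0.2)
})

test_that("estimated correlation is consistent on synthetic cohorts", {
  set.seed(99)
  rho <- 0.5
  rs <- vapply(1:200, function(i) {
    x <- rnorm(500)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(500)
    simple_regression(x, y)$pearson_r
  }, numeric(1))
  expect_lt(abs(mean(rs) - rho), 0.05)
})
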