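test_that("log2 fold rise follows the clamping and placebo conventions", {
  expect_equal(derive_log2_fold_rise(4, 16, "vaccine"), 2)
  expect_equal(derive_log2_fold_rise(16, 8, "vaccine"), 0) # fold rise < 1 clamped
  expect_equal(derive_log2_fold_rise(4, 16, "control"), 0) # controls assigned 1
  expect_error(derive_log2_fold_rise(0, 16, "vaccine"), "positive")
  # non-negative everywhere, identically 0 on the control arm
  set.seed(11)
  b <- exp(rnorm(200)); p <- exp(rnorm(200))
  arm <- sample(c("vaccine", "control"), 200, replace = TRUE)
  fr <- derive_log2_fold_rise(b, p, arm)
  expect_true(all(fr >= 0))
  expect_true(all(fr[arm == "control"] == 0))
})

test_that("center_scale standardises with the n-1 denominator and is idempotent", {
  expect_equal(as.numeric(center_scale(c(1, 2, 3))), c(-1, 0, 1))
  expect_error(center_scale(c(5, 5, 5)), "constant")
  set.seed(4)
  v <- rnorm(50, mean = 7, sd = 3)
  out <- center_scale(v)
  expect_lt(abs(mean(out)), 1e-12)
  expect_equal(sd(out), 1)
  expect_equal(as.numeric(center_scale(as.numeric(out))), as.numeric(out),
    tolerance = 1e-12)
})

test_that("average titer requires scaling metadata and averages rows", {
  m <- matrix(rnorm(40), ncol = 4)
  expect_error(average_titer(m), "scaled")
  s <- scale_biomarkers(m)
  expect_equal(average_titer(s), rowMeans(s))
  # symmetric row averages to zero
  sym <- matrix(c(0.5, -0.5, 1, -1), nrow = 1)
  attr(sym, "scaled") <- TRUE
  expect_equal(average_titer(sym), 0)
  one <- scale_biomarkers(matrix(rnorm(10), ncol = 1))
  expect_equal(average_titer(one), as.numeric(one))
  # 3-subject 2-column worked example, means computed by hand
  w <- matrix(c(-1, 0, 1, 1, 0, -1), ncol = 2)
  ws <- scale_biomarkers(w)
  expect_equal(average_titer(ws), c(0, 0, 0))
})

test_that("VIF matches the 1/(1-r^2) closed form and an OLS oracle", {
  x <- c(1, -1, 1, -1, 1, -1, 1, -1)
  y <- c(1, 1, -1, -1, 1, 1, -1, -1) # exactly orthogonal to x
  expect_equal(unname(vif(cbind(x, y))), c(1, 1), tolerance = 1e-10)
  # any 2-column input: VIF = 1/(1 - cor^2)
  set.seed(9)
  for (rep in 1:5) {
    a <- rnorm(60)
    b <- 0.8 * a + rnorm(60, sd = sqrt(1 - 0.64))
    expected <- 1 / (1 - stats::cor(a, b)^2)
    expect_equal(unname(vif(cbind(a, b))), rep(expected, 2), tolerance = 1e-10)
  }
  # 4-column case against a direct regression R^2 oracle
  set.seed(10)
  z <- MASS::mvrnorm(100, rep(0, 4),
    outer(1:4, 1:4, function(i, j) 0.6^abs(i - j)))
  got <- vif(z)
  oracle <- vapply(1:4, function(j) {
    r2 <- summary(lm(z[, j] ~ z[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(got), oracle, tolerance = 1e-10)
  expect_true(all(got >= 1))
  # perfect collinearity reports Inf instead of failing
  expect_true(is.infinite(suppressWarnings(
    vif(cbind(a = 1:10, b = 2 * (1:10)))
  )[1]))
})

test_that("principal components report sane cumulative variance", {
  set.seed(12)
  m <- scale_biomarkers(matrix(rnorm(400), ncol = 2))
  pc <- principal_components(m, 2)
  expect_equal(pc$cumulative_variance[2], 1, tolerance = 1e-10)
  expect_true(all(diff(pc$cumulative_variance) >= 0))
  # rank-1 input: first component carries everything
  u <- rnorm(50)
  r1 <- cbind(u, 2 * u, -u)
  attr(r1, "scaled") <- TRUE
  expect_equal(principal_components(r1, 1)$cumulative_variance, 1,
    tolerance = 1e-10)
  expect_error(principal_components(m, 0), "at least 1")
  expect_error(principal_components(m, 3), "exceed")
})

test_that("group comparison routes to t-test, Welch, or Mann-Whitney", {
  set.seed(21)
  a <- rnorm(200); b <- rnorm(200, mean = 0.1)
  expect_equal(compare_groups(a, b)$test_name, "t-test")
  b10 <- rnorm(200, sd = sqrt(10))
  expect_equal(compare_groups(a, b10)$test_name, "welch")
  skewed <- exp(rnorm(200, sd = 1.5))
  expect_equal(compare_groups(a, skewed)$test_name, "mann-whitney")
  expect_error(compare_groups(a[1:2], b), "at least 3")
  p <- compare_groups(a, b)$p_value
  expect_true(p >= 0 && p <= 1)
})
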