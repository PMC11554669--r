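test_that("label-symmetric data gives a zero coefficient", {
  # mirrored pairs: swapping the two groups leaves the data law invariant
  tbl <- toy_table(time = c(1, 1, 2, 2, 3, 3), cause = rep(1L, 6),
    x = c(0, 1, 0, 1, 0, 1))
  fit <- fit_cox(tbl, design_spec("x"))
  expect_lt(abs(fit$coefficients[1]), 1e-6)
})

test_that("fit_cox matches a grid scan of the hand-coded partial likelihood", {
  fixtures <- list(
    list(time = c(3, 1, 4, 6, 2, 5), cause = c(1, 0, 1, 0, 1, 1),
      x = c(0.5, -1, 2, 0, 1.5, -0.5)),
    list(time = c(2, 4, 6, 8), cause = c(1, 1, 0, 1), x = c(1, 0, 1, 0)),
    list(time = c(1, 3, 5, 7, 9), cause = c(1, 1, 1, 1, 1),
      x = c(0, -1.5, 2, 1, -0.5)),
    list(time = c(10, 20, 30, 40, 50, 60, 70, 80),
      cause = c(0, 1, 0, 1, 1, 0, 1, 0),
      x = c(0.3, 1.2, -0.7, 0.9, -1.4, 0.1, 2.0, -0.2))
  )
  for (fx in fixtures) {
    tbl <- toy_table(fx$time, fx$cause, fx$x)
    fit <- fit_cox(tbl, design_spec("x"))
    oracle <- cox_grid_argmax(fx$x, fx$time, as.integer(fx$cause > 0))
    expect_lt(abs(unname(fit$coefficients[1]) - oracle), 1e-4)
  }
})

test_that("monotone likelihood is flagged, never returned as converged", {
  # all events in the low-x half, none elsewhere: beta diverges
  tbl <- toy_table(time = c(1, 2, 3, 4, 100, 100, 100, 100),
    cause = c(1, 1, 1, 1, 0, 0, 0, 0),
    x = c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_warning(fit <- fit_cox(tbl, design_spec("x")), "converge|infinite")
  expect_false(fit$converged)
})

test_that("AIC identity and covariance symmetry/PSD hold across fits", {
  set.seed(31)
  tbl <- simulate_trial(trial_config(n_vaccine = 150, n_control = 150,
    base_rate = 4e-4), seed = 31)
  for (spec in list(design_spec("titer"), design_spec("titer", "quadratic"),
    design_spec("titer", covariates = "group"))) {
    fit <- fit_cox(tbl, spec)
    expect_equal(fit$aic, 2 * length(fit$coefficients) - 2 * fit$loglik)
    expect_lt(max(abs(fit$vcov - t(fit$vcov))), 1e-10)
    expect_true(all(eigen(fit$vcov, symmetric = TRUE,
      only.values = TRUE)$values >= -1e-10))
  }
})

test_that("cause-specific fits equal fit_cox on recoded data and respect relabeling", {
  cfg <- trial_config(n_vaccine = 200, n_control = 200, base_rate = 4e-4,
    competing = list(list(rate = 2e-4, beta_t = 0.2)))
  tbl <- simulate_trial(cfg, seed = 33)
  expect_gt(sum(tbl$cause == 2), 0)
  cs <- fit_cause_specific(tbl, design_spec("titer"), 1)
  recoded <- tbl
  recoded$cause <- ifelse(tbl$cause == 1, 1L, 0L)
  direct <- fit_cox(study_table(as.data.frame(recoded), biomarkers = "titer"),
    design_spec("titer"))
  expect_equal(cs$coefficients, direct$coefficients)
  expect_equal(cs$loglik, direct$loglik)
  # single-cause data: cause-specific == composite fit
  single <- simulate_trial(trial_config(n_vaccine = 150, n_control = 150,
    base_rate = 4e-4), seed = 34)
  expect_equal(fit_cause_specific(single, design_spec("titer"), 1)$coefficients,
    fit_cox(single, design_spec("titer"))$coefficients)
  # consistent relabeling of cause codes leaves the fit unchanged
  swapped <- tbl
  swapped$cause <- c(0L, 2L, 1L)[tbl$cause + 1L]
  swapped <- study_table(as.data.frame(swapped), covariates = "group",
    biomarkers = "titer")
  cs_swapped <- fit_cause_specific(swapped, design_spec("titer"), 2)
  expect_equal(cs_swapped$coefficients, cs$coefficients)
  expect_error(fit_cause_specific(tbl, design_spec("titer"), 9), "no events")
})

test_that("model_tests computes nested LRT and Wald tests", {
  tbl <- simulate_trial(trial_config(n_vaccine = 200, n_control = 200,
    base_rate = 4e-4), seed = 35)
  f1 <- fit_cox(tbl, design_spec("titer"))
  f2 <- fit_cox(tbl, design_spec("titer", covariates = "group"))
  expect_equal(model_tests(f1, f1)$lrt_p, 1)
  mt <- model_tests(f1, f2)
  expect_equal(mt$df, 1)
  expect_equal(mt$lrt_stat, 2 * (f2$loglik - f1$loglik))
  expect_equal(nrow(mt$wald), 2)
  expect_error(model_tests(f2, f1), "not nested")
})

test_that("ph diagnostic is valid under PH and detects a reversing effect", {
  tbl <- simulate_trial(trial_config(n_vaccine = 200, n_control = 200,
    base_rate = 4e-4), seed = 36)
  ph <- ph_test(fit_cox(tbl, design_spec("titer")))
  expect_true(all(ph$table$p.value >= 0 & ph$table$p.value <= 1))
  expect_true(ph$global_p >= 0 && ph$global_p <= 1)
  # strong time-varying effect: hazard ratio reverses mid-study
  set.seed(37)
  reject <- 0
  for (r in 1:20) {
    n <- 400
    x <- rnorm(n)
    b <- 1.2; lambda <- 2e-3; t0 <- 250
    t1 <- rexp(n, lambda * exp(b * x))
    t2 <- t0 + rexp(n, lambda * exp(-b * x))
    t_ev <- ifelse(t1 < t0, t1, t2)
    time <- pmin(t_ev, 1000)
    tv <- toy_table(time, as.integer(t_ev <= 1000), x)
    p <- ph_test(suppressWarnings(fit_cox(tv, design_spec("x"))))$table$p.value[1]
    if (p < 0.05) reject <- reject + 1
  }
  expect_gte(reject, 18)
})
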