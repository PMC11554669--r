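# helper: a 1-coefficient fit whose coefficient is set exactly, for
# closed-form checks of the risk-curve and VE arithmetic
fixed_beta_fit <- function(beta, table = NULL) {
  if (is.null(table)) {
    table <- toy_table(time = c(10, 20, 30, 40), cause = c(1, 0, 1, 0),
      x = c(0.5, 1.5, -0.5, 1))
  }
  fit <- suppressWarnings(fit_cox(table, design_spec("x")))
  fit$coefficients[1] <- beta
  fit$vcov[] <- 0
  fit$converged <- TRUE
  fit
}

test_that("risk curve is 1 at the reference and matches closed forms", {
  fit <- fixed_beta_fit(log(0.159))
  rc <- risk_curve(fit, t_ref = 2)
  at_ref <- predict(rc, 2)
  expect_identical(at_ref$hr, 1)
  expect_equal(predict(rc, 3)$hr, 0.159, tolerance = 1e-12)
  # quadratic: beta1 = -0.5, beta2 = 0.05, T_ref = 0 -> rho(2) = exp(-0.8)
  tbl <- toy_table(time = c(10, 20, 30, 40), cause = c(1, 0, 1, 0),
    x = c(0.5, 1.5, -0.5, 1))
  qfit <- suppressWarnings(fit_cox(tbl, design_spec("x", "quadratic")))
  qfit$coefficients[] <- c(-0.5, 0.05)
  qfit$converged <- TRUE
  qrc <- risk_curve(qfit, t_ref = 0)
  expect_equal(predict(qrc, 2)$hr, exp(-0.8), tolerance = 1e-12)
  expect_true(all(predict(qrc, seq(-3, 3, 0.5))$hr > 0))
  # a profile must supply every covariate
  sim <- simulate_trial(trial_config(n_vaccine = 80, n_control = 80,
    base_rate = 4e-4), seed = 65)
  zfit <- fit_cox(sim, design_spec("titer", covariates = "group"))
  expect_error(risk_curve(zfit), "profile missing")
  expect_s3_class(risk_curve(zfit, profile = list(group = 0)), "risk_curve")
})

test_that("case-count VE reproduces worked examples and handles zero counts", {
  expect_equal(round(case_count_ve(5, 983, 12, 1059)$point), 55)
  expect_equal(round(case_count_ve(4, 728, 11, 654)$point), 67)
  expect_equal(case_count_ve(10, 500, 10, 500)$point, 0)
  z <- case_count_ve(0, 1808, 3, 764)
  expect_equal(z$point, 100)
  expect_equal(z$ci_high, 100)
  inf <- case_count_ve(3, 1808, 0, 764)
  expect_identical(inf$point, -Inf)
  expect_identical(inf$ci_low, -Inf)
  expect_warning(und <- case_count_ve(0, 100, 0, 100), "undefined")
  expect_true(und$undefined)
  expect_error(case_count_ve(1, 0, 1, 10), "positive")
  cc <- case_count_ve(5, 983, 12, 1059)
  expect_true(cc$ci_low <= cc$point && cc$point <= cc$ci_high)
})

test_that("immunogenicity VE follows the closed forms of the risk-curve average", {
  # flat curve (beta = 0): VE is exactly 0
  fit0 <- fixed_beta_fit(0)
  expect_equal(immunogenicity_ve(fit0), 0)
  # one vaccinated subject at T_c + 1, one control at T_c, beta = ln(0.159)
  two <- toy_table(time = c(100, 100), cause = c(0L, 0L), x = c(3, 2),
    arm = c("vaccine", "control"))
  fit <- fixed_beta_fit(log(0.159))
  expect_equal(immunogenicity_ve(fit, data = two), (1 - 0.159) * 100,
    tolerance = 1e-10)
  # 8-subject worked set vs hand-summed arithmetic
  tv <- c(2.1, 1.4, 3.0, 0.5); tc <- c(0.2, -0.3, 1.1, 0.6)
  eight <- toy_table(time = rep(50, 8), cause = rep(0L, 8), x = c(tv, tc),
    arm = rep(c("vaccine", "control"), each = 4))
  b <- log(0.4)
  fitb <- fixed_beta_fit(b)
  oracle <- (1 - mean(exp(b * tv)) / mean(exp(b * tc))) * 100
  expect_equal(immunogenicity_ve(fitb, data = eight), oracle, tolerance = 1e-12)
  expect_error(immunogenicity_ve(fitb, data = eight, subgroup = x > 10),
    "each arm")
})

test_that("VE is invariant to the reference value and baseline-hazard scale", {
  tbl <- simulate_trial(trial_config(n_vaccine = 80, n_control = 80,
    base_rate = 4e-4), seed = 61)
  fit <- fit_cox(tbl, design_spec("titer"))
  # T_ref cancels: VE computed from rho with two different references
  ve_from_ref <- function(t_ref) {
    rc <- risk_curve(fit, t_ref = t_ref)
    rho <- predict(rc, tbl$titer)$hr
    (1 - mean(rho[tbl$arm == "vaccine"]) / mean(rho[tbl$arm == "control"])) * 100
  }
  expect_equal(ve_from_ref(0), ve_from_ref(2.5), tolerance = 1e-10)
  expect_equal(ve_from_ref(0), immunogenicity_ve(fit), tolerance = 1e-10)
  # multiplying the baseline hazard shifts every lp by a constant: no effect
  lp <- as.vector(vaxcop:::evaluate_lp(fit, tbl)$lp)
  isv <- tbl$arm == "vaccine"
  expect_equal(vaxcop:::ve_from_lp(exp(lp), isv),
    vaxcop:::ve_from_lp(exp(lp + log(7)), isv), tolerance = 1e-10)
})

test_that("the resampling interval is seeded, degenerate-safe, and ordered", {
  tbl <- simulate_trial(trial_config(n_vaccine = 120, n_control = 120,
    base_rate = 4e-4), seed = 62)
  fit <- fit_cox(tbl, design_spec("titer"))
  a <- ve_confidence_interval(fit, n_bootstrap = 150, seed = 99)
  b <- ve_confidence_interval(fit, n_bootstrap = 150, seed = 99)
  expect_identical(a$replicates, b$replicates)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
  expect_true(a$ci_low <= a$point && a$point <= a$ci_high)
  # zero parameter covariance + identical subjects within arm: width exactly 0
  degen <- toy_table(time = rep(100, 6), cause = rep(0L, 6),
    x = rep(c(2, 0), each = 3), arm = rep(c("vaccine", "control"), each = 3))
  dfit <- fixed_beta_fit(log(0.5), table = toy_table(
    time = c(10, 20, 30, 40), cause = c(1, 0, 1, 0), x = c(0.5, 1.5, -0.5, 1)))
  ve <- ve_confidence_interval(dfit, data = degen, n_bootstrap = 50, seed = 3)
  expect_identical(ve$ci_high - ve$ci_low, 0)
  expect_equal(ve$point, (1 - exp(log(0.5) * 2)) * 100)
})

test_that("vaccination-status VE recovers a uniform hazard ratio", {
  cfg <- trial_config(n_vaccine = 500, n_control = 500, base_rate = 2e-4,
    mu_vaccine = 0, beta_t = 0, beta_vaccine = log(0.5))
  tbl <- simulate_trial(cfg, seed = 63)
  ve <- ve_from_vaccination_status(tbl)$all
  expect_true(ve$ci_low <= 50 && 50 <= ve$ci_high)
  # per-level estimates with a subgroup covariate
  by_group <- ve_from_vaccination_status(tbl, "group")
  expect_equal(length(by_group), 2)
  expect_true(all(vapply(by_group, function(v) v$ci_low <= v$ci_high,
    logical(1))))
  # null vaccine: VE near 0 with CI spanning 0
  null_tbl <- simulate_trial(trial_config(n_vaccine = 500, n_control = 500,
    base_rate = 2e-4, mu_vaccine = 0), seed = 64)
  nv <- ve_from_vaccination_status(null_tbl)$all
  expect_true(nv$ci_low < 0 && nv$ci_high > 0)
  expect_error(ve_from_vaccination_status(tbl[tbl$arm == "vaccine", ]),
    "both arms")
})
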