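#' Fit a Cox proportional-hazards model to a study table
#'
#' Maximises the Cox partial likelihood (Efron tie correction) for the design
#' implied by a [design_spec()], treating any event cause (`cause >= 1`) as
#' the endpoint. The variance is the inverse observed information at the
#' maximum; the AIC is `2k - 2 logPL`. Monotone-likelihood or otherwise
#' non-convergent fits are returned with `converged = FALSE` and a warning,
#' never silently as converged.
#'
#' @param table A [study_table()].
#' @param spec A [design_spec()].
#' @return An object of class `cox_fit`: named coefficients, covariance
#'   matrix, log partial likelihood, AIC, event count, cause code (0 =
#'   composite), the spec, and a convergence record.
#' @seealso [fit_cause_specific()], [fit_fine_gray()], [ph_test()],
#'   [model_tests()]
#' @export
fit_cox <- function(table, spec) {
  event <- as.integer(table$cause > 0)
  cox_engine(table, spec, event, cause = 0L)
}

#' Fit a cause-specific Cox proportional-hazards model
#'
#' Identical to [fit_cox()] with events restricted to one cause; subjects
#' failing from competing causes are censored at their event times. Valid
#' under the assumption that competing-cause censoring is non-informative.
#'
#' @inheritParams fit_cox
#' @param target_cause Integer event code (>= 1) to model.
#' @return A `cox_fit` tagged with `cause = target_cause`.
#' @export
fit_cause_specific <- function(table, spec, target_cause) {
  if (!any(table$cause == target_cause)) {
    abort(paste0("no events of cause ", target_cause, " in the data"))
  }
  event <- as.integer(table$cause == target_cause)
  cox_engine(table, spec, event, cause = as.integer(target_cause))
}

cox_engine <- function(table, spec, event, cause) {
  design <- build_design(table, spec)
  if (sum(event) < 1) abort("no events in the data")
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(table$time, event) ~ design,
      ties = "efron",
      control = survival::coxph.control(eps = 1e-10, iter.max = 50)
    ),
    warning = function(w) {
      if (grepl("infinite|did not converge|converge", conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- coef(fit)
  names(beta) <- colnames(design)
  Sigma <- unname(vcov(fit))
  dimnames(Sigma) <- list(names(beta), names(beta))
  if (any(!is.finite(beta)) || any(!is.finite(Sigma))) diverged <- TRUE
  k <- length(beta)
  ll <- fit$loglik[2]
  out <- structure(list(
    coefficients = beta,
    vcov = Sigma,
    loglik = ll,
    loglik_null = fit$loglik[1],
    aic = 2 * k - 2 * ll,
    n = nrow(table),
    n_events = sum(event),
    cause = cause,
    spec = spec,
    t_cols = attr(design, "t_cols"),
    xlev = attr(design, "xlev"),
    table = table,
    ties = "efron",
    converged = !diverged,
    engine = fit
  ), class = "cox_fit")
  if (diverged) {
    warn("Cox fit did not converge (possible monotone likelihood / separation); inspect coefficients")
  }
  out
}

#' Fit a Fine-Gray subdistribution-hazards model
#'
#' Models the hazard derived from the cumulative incidence function of one
#' cause. Subjects failing from competing causes remain in the risk set after
#' their event with inverse-probability-of-censoring weights G(t)/G(s), where
#' G is the Kaplan-Meier estimator of the censoring distribution pooled
#' across arms. Fitting is by the weighted pseudo-partial likelihood of Fine
#' and Gray via [cmprsk::crr()].
#'
#' @inheritParams fit_cause_specific
#' @return An object of class `fine_gray_fit` (and `cox_fit` for shared
#'   methods) with coefficients gamma, covariance, log pseudo-partial
#'   likelihood, and AIC.
#' @export
fit_fine_gray <- function(table, spec, target_cause) {
  if (!any(table$cause == target_cause)) {
    abort(paste0("no events of cause ", target_cause, " in the data"))
  }
  if (all(table$cause == 0)) abort("all observations censored")
  design <- build_design(table, spec)
  fit <- cmprsk::crr(
    ftime = table$time, fstatus = table$cause,
    cov1 = design, failcode = as.integer(target_cause), cencode = 0L,
    gtol = 1e-10, maxiter = 50
  )
  gamma <- fit$coef
  names(gamma) <- colnames(design)
  Sigma <- fit$var
  dimnames(Sigma) <- list(names(gamma), names(gamma))
  k <- length(gamma)
  ll <- fit$loglik
  out <- structure(list(
    coefficients = gamma,
    vcov = Sigma,
    loglik = ll,
    loglik_null = fit$loglik.null,
    aic = 2 * k - 2 * ll,
    n = nrow(table),
    n_events = sum(table$cause == target_cause),
    cause = as.integer(target_cause),
    spec = spec,
    t_cols = attr(design, "t_cols"),
    xlev = attr(design, "xlev"),
    table = table,
    ties = "breslow",
    converged = isTRUE(fit$converged),
    engine = fit
  ), class = c("fine_gray_fit", "cox_fit"))
  if (!out$converged) warn("Fine-Gray fit did not converge")
  out
}

#' Aalen-Johansen cumulative incidence functions
#'
#' Estimates the cumulative incidence function of each cause together with
#' the overall survival function, using the product construction in which
#' each cause's incidence at an event time is the overall survival just
#' before the time multiplied by the cause-specific hazard at it. The
#' estimates satisfy S(t) + sum_c CIF_c(t) = 1 at every step.
#'
#' @param table A [study_table()].
#' @param mask Optional logical vector selecting a subgroup of rows.
#' @return A tibble of class `cif_estimate` with columns `time`, `surv`, and
#'   one `cif_<k>` column per event cause.
#' @export
estimate_cif <- function(table, mask = NULL) {
  if (!is.null(mask)) table <- table[mask, , drop = FALSE]
  if (nrow(table) == 0) abort("empty group")
  if (all(table$cause == 0)) abort("no events of any cause")
  causes <- sort(unique(table$cause[table$cause > 0]))
  st <- factor(table$cause, levels = c(0, causes))
  sf <- survival::survfit(survival::Surv(table$time, st) ~ 1)
  ps <- sf$pstate
  colnames(ps) <- sf$states
  out <- tibble::tibble(time = sf$time, surv = ps[, "(s0)"])
  for (k in causes) out[[paste0("cif_", k)]] <- ps[, as.character(k)]
  class(out) <- c("cif_estimate", class(out))
  out
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Score test of zero slope in the regression of each term's scaled
#' Schoenfeld residuals on time (identity time transform by default, the
#' variant recorded in the output).
#'
#' @param fit A converged `cox_fit` (not Fine-Gray).
#' @param transform Time transform passed to [survival::cox.zph()];
#'   `"identity"` regresses on time itself.
#' @return An object of class `ph_diagnostic`: a per-term tibble of
#'   chi-square statistics and p-values plus the global test.
#' @export
ph_test <- function(fit, transform = "identity") {
  stopifnot(inherits(fit, "cox_fit"))
  if (inherits(fit, "fine_gray_fit")) {
    abort("PH diagnostics are implemented for Cox fits only")
  }
  if (!fit$converged) abort("fit did not converge")
  if (fit$n_events < 2) abort("need at least 2 events for the PH diagnostic")
  zp <- survival::cox.zph(fit$engine, transform = transform)
  tab <- as.data.frame(zp$table)
  terms <- rownames(tab)
  terms[terms != "GLOBAL"] <- names(fit$coefficients)
  out <- tibble::tibble(
    term = terms, chisq = tab$chisq, df = tab$df, p.value = tab$p
  )
  structure(list(
    table = out[out$term != "GLOBAL", ],
    global_p = out$p.value[out$term == "GLOBAL"],
    transform = transform
  ), class = "ph_diagnostic")
}

#' @export
print.ph_diagnostic <- function(x, ...) {
  cat("<ph_diagnostic> scaled Schoenfeld residuals vs", x$transform, "time\n")
  print(x$table)
  cat(sprintf("global p = %.4g\n", x$global_p))
  invisible(x)
}

#' Likelihood-ratio and Wald tests for nested proportional-hazards fits
#'
#' The likelihood-ratio statistic is twice the difference in log partial
#' likelihood, referred to a chi-square with degrees of freedom equal to the
#' difference in coefficient count; per-term Wald tests come from the full
#' fit's coefficients and standard errors.
#'
#' @param fit_reduced,fit_full Nested fits on the same data (the reduced
#'   model's terms must be a subset of the full model's).
#' @return A list with `lrt_stat`, `df`, `lrt_p`, and a `wald` tibble (term,
#'   estimate, std.error, statistic, p.value) for the full fit.
#' @export
model_tests <- function(fit_reduced, fit_full) {
  if (!all(names(fit_reduced$coefficients) %in% names(fit_full$coefficients))) {
    abort("models are not nested: reduced terms must be a subset of full terms")
  }
  if (fit_reduced$n != fit_full$n || fit_reduced$cause != fit_full$cause) {
    abort("models must be fitted to the same data and cause")
  }
  df <- length(fit_full$coefficients) - length(fit_reduced$coefficients)
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  lrt_p <- if (df == 0) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  se <- sqrt(diag(fit_full$vcov))
  z <- fit_full$coefficients / se
  wald <- tibble::tibble(
    term = names(fit_full$coefficients),
    estimate = unname(fit_full$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z)))
  )
  list(lrt_stat = stat, df = df, lrt_p = lrt_p, wald = wald)
}

# Joint LRT that all biomarker-involving terms are zero, by refitting the
# model with those terms removed (null partial likelihood when nothing is
# left). Used for the CoR verdict and the Prentice biomarker check.
joint_biomarker_test <- function(fit, table) {
  spec <- fit$spec
  if (is.null(spec$biomarker)) abort("fit has no biomarker term")
  inter_keep <- Filter(function(p) !spec$biomarker %in% p, spec$interactions)
  reduced_spec <- design_spec(
    biomarker = NULL, covariates = spec$covariates,
    interactions = inter_keep, vaccination = spec$vaccination
  )
  n_t <- length(fit$t_cols)
  has_terms <- length(reduced_spec$covariates) > 0 ||
    length(reduced_spec$interactions) > 0 || isTRUE(reduced_spec$vaccination)
  ll_reduced <- if (has_terms) {
    refit <- refit_like(fit, table, reduced_spec)
    refit$loglik
  } else {
    fit$loglik_null
  }
  stat <- max(0, 2 * (fit$loglik - ll_reduced))
  list(stat = stat, df = n_t, p = pchisq(stat, df = n_t, lower.tail = FALSE))
}

refit_like <- function(fit, table, spec) {
  if (inherits(fit, "fine_gray_fit")) {
    fit_fine_gray(table, spec, fit$cause)
  } else if (fit$cause > 0) {
    fit_cause_specific(table, spec, fit$cause)
  } else {
    fit_cox(table, spec)
  }
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, conf.level = 0.95, exponentiate = FALSE, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  q <- qnorm(1 - (1 - conf.level) / 2)
  est <- unname(x$coefficients)
  lo <- est - q * se
  hi <- est + q * se
  if (exponentiate) {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  tibble::tibble(
    term = names(x$coefficients),
    estimate = est,
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    conf.low = unname(lo),
    conf.high = unname(hi)
  )
}

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, cause = x$cause,
    logLik = x$loglik, AIC = x$aic,
    ties = x$ties, converged = x$converged
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  kind <- if (inherits(x, "fine_gray_fit")) "fine_gray_fit" else "cox_fit"
  cat(sprintf("<%s> cause = %s, n = %d, events = %d\n", kind,
    if (x$cause == 0) "any" else x$cause, x$n, x$n_events))
  print(tidy(x))
  cat(sprintf("logPL = %.3f, AIC = %.3f, converged = %s\n",
    x$loglik, x$aic, x$converged))
  invisible(x)
}
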