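#' Vaccine-efficacy estimate container
#'
#' Bundles a subgroup VE point estimate (percent) with its confidence
#' interval and provenance (estimation method, bootstrap size, seed).
#'
#' @param point,ci_low,ci_high VE in percent (`(1 - HR) * 100`).
#' @param method `"case_count"`, `"model_vaccination_status"`, or
#'   `"model_immunogenicity"`.
#' @param subgroup Label of the subgroup the estimate refers to.
#' @param n_bootstrap,seed Bootstrap provenance (NA when not applicable).
#' @param ... Extra fields kept in the object.
#' @return An object of class `ve_estimate`.
#' @export
ve_estimate <- function(point, ci_low = NA_real_, ci_high = NA_real_,
                        method = c("case_count", "model_vaccination_status",
                          "model_immunogenicity"),
                        subgroup = "all", n_bootstrap = NA_integer_,
                        seed = NA_integer_, ...) {
  method <- match.arg(method)
  fin <- is.finite(c(ci_low, point, ci_high))
  if (all(fin) && !(ci_low <= point && point <= ci_high)) {
    warn("VE point estimate outside its confidence interval")
  }
  structure(
    list(point = point, ci_low = ci_low, ci_high = ci_high, method = method,
      subgroup = subgroup, n_bootstrap = n_bootstrap, seed = seed, ...),
    class = "ve_estimate"
  )
}

#' @export
print.ve_estimate <- function(x, digits = 1, ...) {
  cat(sprintf("<ve_estimate> [%s] %s: VE = %s%% (95%% CI %s to %s)\n",
    x$method, x$subgroup, format(round(x$point, digits)),
    format(round(x$ci_low, digits)), format(round(x$ci_high, digits))))
  invisible(x)
}

#' @method tidy ve_estimate
#' @export
tidy.ve_estimate <- function(x, ...) {
  tibble::tibble(
    subgroup = x$subgroup, method = x$method, estimate = x$point,
    conf.low = x$ci_low, conf.high = x$ci_high,
    n_bootstrap = x$n_bootstrap, seed = x$seed
  )
}

# Linear predictor of a fit evaluated on new rows; the vaccination-status
# indicator, if the model has one, is evaluated at 0 so that risk curves and
# VE averages condition on immunogenicity and covariates only.
evaluate_lp <- function(fit, newdata, vaccination_at_zero = TRUE) {
  nd <- as.data.frame(newdata)
  if (isTRUE(fit$spec$vaccination) && vaccination_at_zero) nd$arm <- "control"
  if (is.null(nd$arm)) nd$arm <- "control"
  design <- build_design(nd, fit$spec, xlev = fit$xlev %||% list())
  if (!identical(colnames(design), names(fit$coefficients))) {
    abort("profile or new data does not generate the fitted model's terms")
  }
  list(lp = drop(design %*% fit$coefficients), design = design)
}

#' Hazard-ratio risk curve
#'
#' The risk curve rho(T) is the fitted hazard at immunogenicity T relative
#' to the hazard at a reference value T_ref, holding the covariate profile
#' fixed; the baseline hazard cancels. Pointwise confidence intervals use the
#' delta method on the log hazard-ratio difference lp(T) - lp(T_ref).
#'
#' @param fit A converged `cox_fit` or `fine_gray_fit` with a biomarker term.
#' @param profile Named list supplying a value for every covariate in the
#'   model (not the biomarker). The vaccination indicator, if present, is 0.
#' @param t_ref Reference immunogenicity; defaults to the median observed
#'   biomarker value in the fitting data.
#' @return An object of class `risk_curve` with an evaluator usable through
#'   [predict()][predict.risk_curve()] and [autoplot()].
#' @export
risk_curve <- function(fit, profile = list(), t_ref = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) abort("fit did not converge")
  spec <- fit$spec
  if (is.null(spec$biomarker)) abort("fit has no immunogenicity term")
  missing_cov <- setdiff(spec$covariates, names(profile))
  if (length(missing_cov) > 0) {
    abort(paste0("profile missing covariate(s): ",
      paste(missing_cov, collapse = ", ")))
  }
  if (is.null(t_ref)) t_ref <- median(fit$table[[spec$biomarker]])
  structure(
    list(fit = fit, profile = profile, t_ref = t_ref),
    class = "risk_curve"
  )
}

curve_newdata <- function(x, t_values) {
  nd <- tibble::tibble(!!x$fit$spec$biomarker := t_values)
  for (cv in names(x$profile)) nd[[cv]] <- x$profile[[cv]]
  nd
}

#' Evaluate a risk curve
#'
#' @param object A [risk_curve()].
#' @param t_values Immunogenicity values at which to evaluate rho.
#' @param conf.level Pointwise confidence level.
#' @param ... Unused.
#' @return Tibble with columns `t`, `hr`, `conf.low`, `conf.high`.
#' @export
predict.risk_curve <- function(object, t_values, conf.level = 0.95, ...) {
  ev <- evaluate_lp(object$fit, curve_newdata(object, t_values))
  ref <- evaluate_lp(object$fit, curve_newdata(object, object$t_ref))
  d <- sweep(ev$design, 2, drop(ref$design))
  log_hr <- ev$lp - ref$lp
  se <- sqrt(pmax(0, rowSums((d %*% object$fit$vcov) * d)))
  q <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    t = t_values, hr = exp(log_hr),
    conf.low = exp(log_hr - q * se), conf.high = exp(log_hr + q * se)
  )
}

#' @export
print.risk_curve <- function(x, ...) {
  cat(sprintf("<risk_curve> biomarker '%s', T_ref = %g\n",
    x$fit$spec$biomarker, x$t_ref))
  invisible(x)
}

#' @rdname risk_curve
#' @param object A `risk_curve`.
#' @param t_range Range of immunogenicity values to display; defaults to the
#'   observed biomarker range.
#' @param n Grid size.
#' @param ... Unused.
#' @method autoplot risk_curve
#' @export
autoplot.risk_curve <- function(object, t_range = NULL, n = 200, ...) {
  if (is.null(t_range)) {
    t_range <- range(object$fit$table[[object$fit$spec$biomarker]])
  }
  grid <- seq(t_range[1], t_range[2], length.out = n)
  df <- predict(object, grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$hr)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "immunogenicity (log2 scale)",
      y = sprintf("hazard ratio vs T_ref = %.3g", object$t_ref)
    )
}

#' Case-count vaccine efficacy with an exact conditional interval
#'
#' VE from incidence rates: `(1 - (cases_v/py_v) / (cases_c/py_c)) * 100`.
#' The confidence interval conditions on the total case count: given
#' `n = cases_v + cases_c`, the vaccine-arm count is binomial with success
#' probability `theta * py_v / (theta * py_v + py_c)` where `theta` is the
#' incidence-rate ratio; a Clopper-Pearson interval for that proportion is
#' transformed back to the VE scale.
#'
#' @param cases_v,cases_c Case counts in the vaccinated and control arms.
#' @param py_v,py_c Person-years at risk (strictly positive).
#' @param conf.level Confidence level.
#' @param subgroup Label carried into the result.
#' @return A [ve_estimate()] with `method = "case_count"`. With zero cases in
#'   both arms VE is undefined: the point and interval are `NA` and the
#'   result is flagged (`undefined = TRUE`). Zero control cases with vaccine
#'   cases give a point of `-Inf`.
#' @examples
#' case_count_ve(5, 983, 12, 1059) # ~55%
#' @export
case_count_ve <- function(cases_v, py_v, cases_c, py_c, conf.level = 0.95,
                          subgroup = "all") {
  if (py_v <= 0 || py_c <= 0) abort("person-years must be strictly positive")
  if (cases_v < 0 || cases_c < 0) abort("case counts must be non-negative")
  n <- cases_v + cases_c
  if (n == 0) {
    warn("no cases in either arm: case-count VE undefined")
    return(ve_estimate(NA_real_, NA_real_, NA_real_, "case_count",
      subgroup = subgroup, undefined = TRUE))
  }
  irr <- (cases_v / py_v) / (cases_c / py_c) # Inf/NaN-free: cases_c = 0 -> Inf
  point <- if (cases_c == 0 && cases_v > 0) -Inf else (1 - irr) * 100
  ci_p <- binom.test(cases_v, n, conf.level = conf.level)$conf.int
  odds <- ci_p / (1 - ci_p) # p = 1 -> Inf
  theta <- odds * py_c / py_v
  ve_estimate(
    point = point,
    ci_low = (1 - theta[2]) * 100,
    ci_high = (1 - theta[1]) * 100,
    method = "case_count", subgroup = subgroup,
    cases_v = cases_v, py_v = py_v, cases_c = cases_c, py_c = py_c
  )
}

subgroup_mask <- function(data, subgroup_quo) {
  if (rlang::quo_is_null(subgroup_quo)) return(rep(TRUE, nrow(data)))
  mask <- rlang::eval_tidy(subgroup_quo, data = data)
  if (!is.logical(mask) || length(mask) != nrow(data)) {
    abort("subgroup must evaluate to a logical vector over the rows")
  }
  mask & !is.na(mask)
}

# Core of the immunogenicity-based VE estimator: ratio of arm-average
# relative hazards over the subgroup, for an arbitrary coefficient vector.
ve_from_lp <- function(exp_lp, is_vaccine) {
  (1 - mean(exp_lp[is_vaccine]) / mean(exp_lp[!is_vaccine])) * 100
}

#' Immunogenicity-based subgroup vaccine efficacy
#'
#' Estimates VE in a subgroup by averaging the fitted relative hazard over
#' the observed immunogenicity distribution of each arm: the numerator is
#' the mean of rho evaluated at each vaccinated subject's biomarker value and
#' own covariate vector, the denominator the same over control subjects, and
#' `VE = (1 - ratio) * 100`. The reference value and baseline hazard cancel
#' in the ratio, so the estimate is invariant to both.
#'
#' @param fit A converged `cox_fit`/`fine_gray_fit` with a biomarker term
#'   (normally the final correlate-of-risk model; a vaccination-status term,
#'   if present, is evaluated at 0).
#' @param data Study table supplying the immunogenicity and covariate
#'   distributions; defaults to the fitting data.
#' @param subgroup Optional unquoted logical expression in the table's
#'   columns (e.g. `serostatus == "positive"`) restricting the subgroup.
#' @return VE in percent (a single number).
#' @seealso [ve_confidence_interval()] for the resampling interval.
#' @export
immunogenicity_ve <- function(fit, data = fit$table, subgroup = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) abort("fit did not converge")
  mask <- subgroup_mask(data, enquo(subgroup))
  sub <- data[mask, , drop = FALSE]
  is_vaccine <- sub$arm == "vaccine"
  if (sum(is_vaccine) < 1 || sum(!is_vaccine) < 1) {
    abort("subgroup must contain at least one subject in each arm")
  }
  lp <- evaluate_lp(fit, sub)$lp
  ve_from_lp(exp(lp), is_vaccine)
}

#' Bootstrap + parameter-resampling confidence interval for VE
#'
#' Quantifies the uncertainty of [immunogenicity_ve()] from two sources
#' jointly. For each replicate: (a) subjects are resampled with replacement
#' within each arm of the subgroup, carrying their full immunogenicity and
#' covariate records; (b) one coefficient vector is drawn from a
#' multivariate normal with mean at the fitted coefficients and the fit's
#' covariance; (c) the subgroup VE is recomputed. The interval is the 2.5th
#' and 97.5th empirical percentile (inverse-ECDF convention) of the
#' replicate VE values; the point estimate uses the original data and the
#' fitted coefficients.
#'
#' @inheritParams immunogenicity_ve
#' @param n_bootstrap Number of replicates (>= 2); 1000 by default.
#' @param seed Integer seed making the interval exactly reproducible.
#' @param conf.level Confidence level.
#' @param subgroup_label Label stored in the result.
#' @return A [ve_estimate()] with `method = "model_immunogenicity"`.
#' @export
ve_confidence_interval <- function(fit, data = fit$table, subgroup = NULL,
                                   n_bootstrap = 1000, seed = 1,
                                   conf.level = 0.95,
                                   subgroup_label = "all") {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) abort("fit did not converge")
  if (n_bootstrap < 2) abort("n_bootstrap must be at least 2")
  mask <- subgroup_mask(data, enquo(subgroup))
  sub <- data[mask, , drop = FALSE]
  is_vaccine <- sub$arm == "vaccine"
  iv <- which(is_vaccine); ic <- which(!is_vaccine)
  if (length(iv) < 1 || length(ic) < 1) {
    abort("subgroup must contain at least one subject in each arm")
  }
  D <- evaluate_lp(fit, sub)$design
  beta <- fit$coefficients
  Sigma <- fit$vcov
  point <- ve_from_lp(exp(drop(D %*% beta)), is_vaccine)

  set.seed(seed)
  draws <- tryCatch(
    MASS::mvrnorm(n_bootstrap, mu = beta, Sigma = Sigma),
    error = function(e) {
      warn("coefficient covariance not usable for resampling; falling back to a point mass at the estimates")
      matrix(beta, nrow = n_bootstrap, ncol = length(beta), byrow = TRUE)
    }
  )
  draws <- matrix(draws, nrow = n_bootstrap)
  ves <- vapply(seq_len(n_bootstrap), function(b) {
    rv <- sample(iv, length(iv), replace = TRUE)
    rc <- sample(ic, length(ic), replace = TRUE)
    elp <- exp(drop(D %*% draws[b, ]))
    (1 - mean(elp[rv]) / mean(elp[rc])) * 100
  }, numeric(1))
  probs <- c((1 - conf.level) / 2, 1 - (1 - conf.level) / 2)
  ci <- quantile(ves, probs, type = 1, names = FALSE)
  ve_estimate(
    point = point, ci_low = ci[1], ci_high = ci[2],
    method = "model_immunogenicity", subgroup = subgroup_label,
    n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed),
    replicates = ves
  )
}

#' Vaccine efficacy from a vaccination-status hazard model
#'
#' The conventional model-based comparator: VE = (1 - HR) * 100 where HR is
#' the vaccination-status hazard ratio within each level of a subgroup
#' covariate, from a Cox model with vaccination status, the covariate, and
#' their interaction. The interval is Wald on the log-HR scale.
#'
#' @param data A [study_table()] with both arms present.
#' @param covariate Optional subgroup covariate column name; when `NULL` a
#'   single overall estimate is returned.
#' @param conf.level Confidence level.
#' @return A list of [ve_estimate()]s (method `"model_vaccination_status"`),
#'   one per covariate level (or one element named `"all"`).
#' @export
ve_from_vaccination_status <- function(data, covariate = NULL,
                                       conf.level = 0.95) {
  if (length(unique(data$arm)) < 2) abort("both arms must be present")
  vacc <- cbind(vaccination = as.numeric(data$arm == "vaccine"))
  blocks <- list(vacc)
  if (!is.null(covariate)) {
    cvb <- expand_covariate(data[[covariate]], covariate)
    inter <- cvb * as.vector(vacc)
    colnames(inter) <- paste0("vaccination:", colnames(cvb))
    blocks <- c(blocks, list(cvb, inter))
  }
  design <- do.call(cbind, blocks)
  event <- as.integer(data$cause > 0)
  fit <- survival::coxph(
    survival::Surv(data$time, event) ~ design, ties = "efron",
    control = survival::coxph.control(eps = 1e-10, iter.max = 50)
  )
  beta <- coef(fit); names(beta) <- colnames(design)
  Sigma <- vcov(fit); dimnames(Sigma) <- list(names(beta), names(beta))
  q <- qnorm(1 - (1 - conf.level) / 2)

  one_level <- function(label, cvec) {
    lhr <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% Sigma %*% cvec))
    ve_estimate(
      point = (1 - exp(lhr)) * 100,
      ci_low = (1 - exp(lhr + q * se)) * 100,
      ci_high = (1 - exp(lhr - q * se)) * 100,
      method = "model_vaccination_status", subgroup = label
    )
  }

  if (is.null(covariate)) {
    cvec <- setNames(as.numeric(names(beta) == "vaccination"), names(beta))
    return(list(all = one_level("all", cvec)))
  }
  cvb <- expand_covariate(data[[covariate]], covariate)
  out <- list()
  for (lv in sort(unique(as.character(data[[covariate]])))) {
    lv_row <- setNames(
      as.numeric(cvb[match(lv, as.character(data[[covariate]])), , drop = FALSE]),
      colnames(cvb)
    )
    cvec <- setNames(numeric(length(beta)), names(beta))
    cvec["vaccination"] <- 1
    for (cn in names(lv_row)) {
      icol <- paste0("vaccination:", cn)
      if (icol %in% names(cvec)) cvec[icol] <- lv_row[[cn]]
    }
    out[[lv]] <- one_level(paste0(covariate, " = ", lv), cvec)
  }
  out
}
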