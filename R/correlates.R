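#' Assess an immunogenicity biomarker as a correlate of risk
#'
#' Implements a two-stage, AIC-guided model selection. Stage 1 fits
#' biomarker-only models with a linear and a quadratic immunogenicity term
#' and keeps the lower-AIC form unless the AIC difference is below the
#' parsimony margin, in which case the form with fewer parameters is kept
#' (an AIC reduction under 2 is not normally enough to justify an extra
#' coefficient). Stage 2 fits the kept form unadjusted and adjusted for all
#' supplied covariates plus their interactions with the biomarker, selecting
#' again by the same rule. The biomarker is a correlate of risk (CoR) if the
#' joint likelihood-ratio test of all biomarker-involving terms in the final
#' model is significant at `alpha`.
#'
#' @param table A [study_table()].
#' @param biomarker Biomarker column name (the immunogenicity variable T).
#' @param covariates Character vector of candidate adjustment covariates.
#' @param model_family `"cox"` (composite endpoint), `"cause_specific"`, or
#'   `"fine_gray"`.
#' @param target_cause Event code for the competing-risk families.
#' @param alpha Significance level for the CoR verdict.
#' @param parsimony_margin AIC difference below which the model with fewer
#'   parameters is preferred.
#' @return An object of class `cor_result`: the selected fit, a candidate
#'   ledger (one row per attempted model with its AIC), the joint biomarker
#'   p-value, the CoR flag, and per-subgroup flags when biomarker-covariate
#'   interactions are present in the final model.
#' @seealso [prentice_test()]
#' @export
assess_cor <- function(table, biomarker, covariates = character(),
                       model_family = c("cox", "cause_specific", "fine_gray"),
                       target_cause = NULL, alpha = 0.05,
                       parsimony_margin = 2) {
  model_family <- match.arg(model_family)
  if (!biomarker %in% names(table)) {
    abort(paste0("biomarker column '", biomarker, "' not found"))
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (model_family != "cox" && is.null(target_cause)) {
    abort("target_cause is required for cause_specific and fine_gray families")
  }

  fitter <- function(spec) {
    switch(model_family,
      cox = fit_cox(table, spec),
      cause_specific = fit_cause_specific(table, spec, target_cause),
      fine_gray = fit_fine_gray(table, spec, target_cause)
    )
  }

  try_fit <- function(label, stage, spec) {
    fit <- tryCatch(suppressWarnings(fitter(spec)), error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged
    list(
      label = label, stage = stage, spec = spec,
      fit = if (ok) fit else NULL,
      k = if (ok) length(fit$coefficients) else NA_integer_,
      loglik = if (ok) fit$loglik else NA_real_,
      aic = if (ok) fit$aic else NA_real_
    )
  }

  # Stage 1: functional form of T, biomarker only.
  stage1 <- list(
    try_fit("linear", 1L, design_spec(biomarker, "linear")),
    try_fit("quadratic", 1L, design_spec(biomarker, "quadratic"))
  )
  form <- select_by_aic(stage1, parsimony_margin)
  if (is.null(form)) abort("no candidate model converged")

  # Stage 2: unadjusted vs fully covariate-adjusted (with T interactions).
  stage2 <- list(try_fit(paste0(form$label, " unadjusted"), 2L, form$spec))
  if (length(covariates) > 0) {
    adj_spec <- design_spec(
      biomarker, form$spec$term, covariates = covariates,
      interactions = lapply(covariates, function(cv) c(biomarker, cv))
    )
    stage2 <- c(stage2, list(try_fit(paste0(form$label, " adjusted"), 2L, adj_spec)))
  }
  final <- select_by_aic(stage2, parsimony_margin)
  if (is.null(final)) abort("no candidate model converged")

  candidates <- c(stage1, stage2)
  ledger <- purrr::map_dfr(candidates, function(cd) {
    tibble::tibble(
      stage = cd$stage, label = cd$label, k = cd$k,
      loglik = cd$loglik, aic = cd$aic,
      converged = !is.null(cd$fit)
    )
  })
  ledger$selected <- ledger$stage == 2L & ledger$label == final$label

  jt <- joint_biomarker_test(final$fit, table)
  subgroups <- subgroup_cor_table(final$fit, table, alpha)

  structure(list(
    selected = final$fit,
    ledger = ledger,
    immunogenicity_p = jt$p,
    is_cor = jt$p < alpha,
    subgroups = subgroups,
    alpha = alpha,
    model_family = model_family,
    biomarker = biomarker
  ), class = "cor_result")
}

# AIC selection with a parsimony guard: among converged candidates within
# `margin` of the minimum AIC (inclusive: an AIC reduction of exactly the
# margin still does not buy an extra parameter), prefer the fewest
# parameters, ties broken by lower AIC. Invariant to candidate ordering.
select_by_aic <- function(candidates, margin) {
  ok <- Filter(function(cd) !is.null(cd$fit), candidates)
  if (length(ok) == 0) return(NULL)
  aics <- vapply(ok, `[[`, numeric(1), "aic")
  ks <- vapply(ok, `[[`, numeric(1), "k")
  near <- which(aics - min(aics) <= margin)
  pick <- near[order(ks[near], aics[near])][1]
  ok[[pick]]
}

# Per-subgroup CoR verdicts when the final model carries biomarker-covariate
# interactions: a joint Wald test of the T terms evaluated at each level of
# each interacting covariate.
subgroup_cor_table <- function(fit, table, alpha) {
  spec <- fit$spec
  inter_cvs <- unique(unlist(lapply(
    Filter(function(p) spec$biomarker %in% p, spec$interactions),
    function(p) setdiff(p, spec$biomarker)
  )))
  if (length(inter_cvs) == 0) return(NULL)
  base_t <- fit$t_cols[!grepl(":", fit$t_cols, fixed = TRUE)]
  rows <- list()
  for (cv in inter_cvs) {
    vals <- sort(unique(table[[cv]]))
    full_col <- table[[cv]]
    for (lv in vals) {
      # expanded covariate column values at this level
      expd <- expand_covariate(full_col, cv)
      lv_row <- setNames(
        as.numeric(expd[match(lv, full_col), , drop = FALSE]),
        colnames(expd)
      )
      C <- matrix(0, nrow = length(base_t), ncol = length(fit$coefficients),
        dimnames = list(base_t, names(fit$coefficients)))
      for (bt in base_t) {
        C[bt, bt] <- 1
        for (cn in names(lv_row)) {
          icol <- paste0(bt, ":", cn)
          if (icol %in% colnames(C)) C[bt, icol] <- lv_row[[cn]]
        }
      }
      est <- drop(C %*% fit$coefficients)
      V <- C %*% fit$vcov %*% t(C)
      stat <- drop(t(est) %*% solve(V, est))
      p <- pchisq(stat, df = length(base_t), lower.tail = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        covariate = cv, level = as.character(lv),
        chisq = stat, df = length(base_t), p.value = p,
        is_cor = p < alpha
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("<cor_result> biomarker '%s', family %s\n", x$biomarker, x$model_family))
  print(x$ledger)
  cat(sprintf("joint biomarker p = %.4g -> %s a correlate of risk (alpha = %g)\n",
    x$immunogenicity_p, if (x$is_cor) "IS" else "is NOT", x$alpha))
  if (!is.null(x$subgroups)) print(x$subgroups)
  invisible(x)
}

#' @method tidy cor_result
#' @export
tidy.cor_result <- function(x, ...) x$ledger

#' @method glance cor_result
#' @export
glance.cor_result <- function(x, ...) {
  tibble::tibble(
    biomarker = x$biomarker, model_family = x$model_family,
    immunogenicity_p = x$immunogenicity_p, is_cor = x$is_cor,
    alpha = x$alpha, aic = x$selected$aic
  )
}

#' Prentice test for a correlate of protection
#'
#' Adds a vaccination-status indicator to the final correlate-of-risk model
#' and applies the Prentice conditional-independence criterion: the biomarker
#' is a correlate of protection (CoP) if (i) its terms remain jointly
#' significant in the augmented model and (ii) the vaccination-status
#' likelihood-ratio test is not significant, i.e. vaccination carries no
#' residual effect once immunogenicity is controlled for.
#'
#' @param table The [study_table()] the CoR model was fitted to.
#' @param cor A `cor_result` from [assess_cor()].
#' @param alpha Significance level; defaults to the CoR alpha.
#' @return An object of class `cop_result` with the augmented fit,
#'   `vaccination_p`, `biomarker_p`, and the `is_cop` verdict.
#' @export
prentice_test <- function(table, cor, alpha = cor$alpha) {
  stopifnot(inherits(cor, "cor_result"))
  if (length(unique(table$arm)) < 2) {
    abort("Prentice test requires subjects in both arms")
  }
  base_fit <- cor$selected
  if (!base_fit$converged) abort("CoR model did not converge")
  spec <- base_fit$spec
  aug_spec <- design_spec(
    biomarker = spec$biomarker, term = spec$term,
    covariates = spec$covariates, interactions = spec$interactions,
    vaccination = TRUE
  )
  aug_fit <- refit_like(base_fit, table, aug_spec)
  mt <- model_tests(base_fit, aug_fit)
  jt <- joint_biomarker_test(aug_fit, table)
  structure(list(
    base = base_fit,
    augmented = aug_fit,
    vaccination_p = mt$lrt_p,
    biomarker_p = jt$p,
    biomarker_still_significant = jt$p < alpha,
    is_cop = jt$p < alpha && mt$lrt_p >= alpha,
    alpha = alpha
  ), class = "cop_result")
}

#' @export
print.cop_result <- function(x, ...) {
  cat("<cop_result> Prentice conditional-independence test\n")
  cat(sprintf("  vaccination-status LRT p = %.4g (want >= %g)\n",
    x$vaccination_p, x$alpha))
  cat(sprintf("  joint biomarker p        = %.4g (want < %g)\n",
    x$biomarker_p, x$alpha))
  cat(sprintf("  verdict: %s a correlate of protection\n",
    if (x$is_cop) "IS" else "is NOT"))
  invisible(x)
}

#' @method glance cop_result
#' @export
glance.cop_result <- function(x, ...) {
  tibble::tibble(
    vaccination_p = x$vaccination_p, biomarker_p = x$biomarker_p,
    biomarker_still_significant = x$biomarker_still_significant,
    is_cop = x$is_cop, alpha = x$alpha
  )
}
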