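# Independent oracles and small fixture builders shared across tests.

toy_table <- function(time, cause, x, arm = NULL) {
  n <- length(time)
  if (is.null(arm)) arm <- rep(c("vaccine", "control"), length.out = n)
  study_table(
    data.frame(
      subject_id = paste0("t", seq_len(n)), arm = arm,
      time = time, cause = as.integer(cause), x = x
    ),
    biomarkers = "x"
  )
}

# Hand-coded Cox partial log-likelihood for a single covariate and untied
# event times, vectorised over a grid of beta values.
cox_grid_loglik <- function(betas, x, time, event) {
  stopifnot(!anyDuplicated(time[event == 1]))
  E <- exp(outer(x, betas)) # n x B
  ll <- numeric(length(betas))
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * betas - log(colSums(E[risk, , drop = FALSE]))
  }
  ll
}

cox_grid_argmax <- function(x, time, event, lo = -4, hi = 4, step = 1e-4) {
  betas <- seq(lo, hi, by = step)
  betas[which.max(cox_grid_loglik(betas, x, time, event))]
}

# Hand-coded Fine-Gray weighted pseudo-partial log-likelihood for a single
# covariate, target cause 1, and NO independent censoring: subjects failing
# from a competing cause stay in the risk set with weight 1 forever.
fg_grid_argmax <- function(x, time, cause, lo = -4, hi = 4, step = 1e-4) {
  betas <- seq(lo, hi, by = step)
  E <- exp(outer(x, betas))
  ll <- numeric(length(betas))
  for (i in which(cause == 1)) {
    risk <- (time >= time[i]) | (cause != 1 & cause != 0 & time < time[i])
    ll <- ll + x[i] * betas - log(colSums(E[risk, , drop = FALSE]))
  }
  betas[which.max(ll)]
}

# Direct loop implementation of the product-form cumulative incidence
# construction, independent of the survfit-based path.
hand_cif <- function(time, cause) {
  ord <- order(time)
  time <- time[ord]; cause <- cause[ord]
  times <- sort(unique(time[cause > 0]))
  causes <- sort(unique(cause[cause > 0]))
  n <- length(time)
  surv <- 1
  cif <- matrix(0, length(times), length(causes),
    dimnames = list(NULL, paste0("cif_", causes)))
  acc <- setNames(numeric(length(causes)), paste0("cif_", causes))
  for (j in seq_along(times)) {
    tj <- times[j]
    at_risk <- sum(time >= tj)
    for (k in causes) {
      dk <- sum(time == tj & cause == k)
      acc[paste0("cif_", k)] <- acc[paste0("cif_", k)] + surv * dk / at_risk
    }
    d_any <- sum(time == tj & cause > 0)
    surv <- surv * (1 - d_any / at_risk)
    cif[j, ] <- acc
  }
  list(time = times, cif = cif, surv_final = surv)
}
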