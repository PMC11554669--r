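#' Log2 fold rise in antibody titer
#'
#' Derives the log2 fold rise between a baseline and a post-vaccination titer
#' under the convention used for live-attenuated zoster vaccine immunogenicity:
#' fold rises below 1 are clamped to 1 (log2 fold rise 0), since a measured
#' drop in titer is attributed to assay variability, and control-arm subjects
#' are assigned a fold rise of 1 by definition (no vaccine-induced change).
#'
#' @param baseline_titer,post_titer Strictly positive titer values (natural
#'   scale), vectorised.
#' @param arm `"vaccine"` or `"control"` (case-insensitive), recycled.
#' @return Numeric vector of non-negative log2 fold rises; identically 0 on
#'   the control arm.
#' @examples
#' derive_log2_fold_rise(4, 16, "vaccine") # 2
#' derive_log2_fold_rise(16, 8, "vaccine") # clamped to 0
#' derive_log2_fold_rise(4, 16, "control") # 0 by convention
#' @export
derive_log2_fold_rise <- function(baseline_titer, post_titer, arm) {
  if (any(baseline_titer <= 0) || any(post_titer <= 0)) {
    abort("titers must be strictly positive")
  }
  arm <- normalize_arm(arm)
  fr <- pmax(0, log2(post_titer / baseline_titer))
  ifelse(arm == "control", 0, fr)
}

#' Center and scale a numeric vector
#'
#' Subtracts the sample mean and divides by the sample standard deviation
#' (n - 1 denominator), so the result has mean 0 and standard deviation 1.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Centered and scaled numeric vector with attributes `center` and
#'   `scale` recording the statistics used.
#' @export
center_scale <- function(values) {
  if (length(values) < 2) abort("need at least 2 values to center and scale")
  m <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0) abort("cannot scale a constant vector (zero variance)")
  structure((values - m) / s, center = m, scale = s)
}

#' Center and scale the columns of a biomarker matrix
#'
#' Applies [center_scale()] column-wise and retains the per-column means and
#' standard deviations as attributes, making the transformation reproducible
#' and marking the matrix as scaled for [average_titer()].
#'
#' @param x Numeric matrix or data frame of biomarker values (subjects in
#'   rows, e.g. serotype-specific log2 PRNT50 titers in columns).
#' @return Numeric matrix with attributes `center`, `scale`, and
#'   `scaled = TRUE`.
#' @export
scale_biomarkers <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) < 1) abort("biomarker matrix needs at least one column")
  centers <- colMeans(m)
  scales <- apply(m, 2, sd)
  if (any(!is.finite(scales)) || any(scales == 0)) {
    abort("cannot scale constant biomarker column(s)")
  }
  out <- sweep(sweep(m, 2, centers, "-"), 2, scales, "/")
  structure(out, center = centers, scale = scales, scaled = TRUE)
}

#' Average titer across scaled biomarker columns
#'
#' The arithmetic per-subject mean of centered and scaled biomarker columns —
#' the single summary immunogenicity variable used when serotype-specific
#' titers are too correlated to enter a regression together.
#'
#' @param scaled A matrix produced by [scale_biomarkers()] (scaling metadata
#'   required).
#' @return Numeric vector of per-subject means.
#' @export
average_titer <- function(scaled) {
  if (!isTRUE(attr(scaled, "scaled"))) {
    abort("input must be centered and scaled first (see scale_biomarkers())")
  }
  rowMeans(as.matrix(scaled))
}

#' Variance inflation factors
#'
#' Computes, for each column, VIF = 1 / (1 - R^2) where R^2 comes from the
#' ordinary least-squares regression of that column on all others. Used to
#' screen multicollinearity among serotype-specific titers before deciding to
#' collapse them into an average titer or principal components. Perfectly
#' collinear columns yield `Inf` rather than an error.
#'
#' @param predictors Numeric matrix or data frame with >= 2 columns and more
#'   rows than columns.
#' @return Named numeric vector of VIFs, all >= 1.
#' @export
vif <- function(predictors) {
  m <- as.matrix(predictors)
  p <- ncol(m)
  if (p < 2) abort("VIF needs at least two columns")
  if (nrow(m) < p + 1) abort("VIF needs more rows than columns")
  out <- vapply(seq_len(p), function(j) {
    fit <- lm(m[, j] ~ m[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(m) %||% paste0("x", seq_len(p))
  out
}

#' Principal components of scaled biomarkers
#'
#' Projects subjects onto the top-k eigenvectors of the sample covariance of
#' already centered-and-scaled biomarkers (equivalently, the correlation
#' structure of the raw titers), and reports the cumulative proportion of
#' variance explained.
#'
#' @param scaled Centered-and-scaled biomarker matrix (see
#'   [scale_biomarkers()]).
#' @param k Number of components to retain, `1 <= k <= ncol(scaled)`.
#' @return A list with `scores` (subjects x k matrix) and
#'   `cumulative_variance` (length-k non-decreasing vector, final element
#'   <= 1).
#' @export
principal_components <- function(scaled, k) {
  m <- as.matrix(scaled)
  if (k < 1) abort("k must be at least 1")
  if (k > ncol(m)) abort("k cannot exceed the number of columns")
  pc <- prcomp(m, center = FALSE, scale. = FALSE)
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    cumulative_variance = cumsum(prop)[seq_len(k)]
  )
}

#' Two-group comparison with assumption-guided test routing
#'
#' Chooses between the pooled t-test, Welch's t-test, and the Mann-Whitney U
#' test by first screening each group for normality (Kolmogorov-Smirnov test
#' with estimated mean and standard deviation, i.e. the Lilliefors
#' correction) and, when both groups pass, screening homogeneity of variances
#' with Bartlett's test. All tests are two-sided.
#'
#' @param values_a,values_b Numeric vectors with at least 3 observations each.
#' @param alpha Significance level for the normality and variance screens.
#' @return A list with `test_name` (`"t-test"`, `"welch"`, or
#'   `"mann-whitney"`), `p_value`, and the screening p-values.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 3 || length(values_b) < 3) {
    abort("each group needs at least 3 observations")
  }
  # lillie.test requires n >= 4; with exactly 3 points normality is untestable,
  # fall through to the rank test.
  norm_p <- vapply(list(values_a, values_b), function(v) {
    if (length(v) < 4 || sd(v) == 0) return(0)
    nortest::lillie.test(v)$p.value
  }, numeric(1))
  if (any(norm_p < alpha)) {
    ht <- wilcox.test(values_a, values_b, exact = FALSE)
    return(list(test_name = "mann-whitney", p_value = ht$p.value,
      normality_p = norm_p, variance_p = NA_real_))
  }
  var_p <- bartlett.test(list(values_a, values_b))$p.value
  if (var_p < alpha) {
    ht <- t.test(values_a, values_b, var.equal = FALSE)
    list(test_name = "welch", p_value = ht$p.value,
      normality_p = norm_p, variance_p = var_p)
  } else {
    ht <- t.test(values_a, values_b, var.equal = TRUE)
    list(test_name = "t-test", p_value = ht$p.value,
      normality_p = norm_p, variance_p = var_p)
  }
}
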