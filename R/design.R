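#' Specify the terms of a proportional-hazards design
#'
#' Describes how the immunogenicity biomarker enters the linear predictor
#' (linear, quadratic polynomial, log, or square-root transform), which
#' baseline covariates are adjusted for, which interactions are included, and
#' whether a vaccination-status indicator is added (as in the Prentice test).
#'
#' @param biomarker Name of the biomarker column acting as the immunogenicity
#'   variable T, or `NULL` for models without an immunogenicity term.
#' @param term Functional form for T: `"linear"` (T), `"quadratic"` (T and
#'   T^2), `"log"` (log T, requires T > 0), or `"sqrt"` (sqrt T, requires
#'   T >= 0).
#' @param covariates Character vector of covariate column names; categorical
#'   covariates are expanded to reference-coded indicators.
#' @param interactions List of length-2 character vectors naming interacting
#'   columns (each must be the biomarker or a declared covariate).
#' @param vaccination If `TRUE`, append an indicator for `arm == "vaccine"`.
#' @return An object of class `design_spec`.
#' @seealso [build_design()]
#' @export
design_spec <- function(biomarker = NULL,
                        term = c("linear", "quadratic", "log", "sqrt"),
                        covariates = character(),
                        interactions = list(),
                        vaccination = FALSE) {
  term <- match.arg(term)
  declared <- c(biomarker, covariates)
  for (pair in interactions) {
    if (length(pair) != 2 || !all(pair %in% declared)) {
      abort("each interaction must be a pair of declared terms")
    }
  }
  structure(
    list(biomarker = biomarker, term = term, covariates = covariates,
      interactions = interactions, vaccination = vaccination),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  parts <- character()
  if (!is.null(x$biomarker)) parts <- c(parts, paste0(x$term, "(", x$biomarker, ")"))
  parts <- c(parts, x$covariates)
  for (pair in x$interactions) parts <- c(parts, paste(pair, collapse = ":"))
  if (isTRUE(x$vaccination)) parts <- c(parts, "vaccination")
  cat("<design_spec>", paste(parts, collapse = " + "), "\n")
  invisible(x)
}

biomarker_transform_cols <- function(x, name, term) {
  switch(term,
    linear = {
      m <- cbind(x); colnames(m) <- name; m
    },
    quadratic = {
      m <- cbind(x, x^2); colnames(m) <- c(name, paste0(name, "^2")); m
    },
    log = {
      if (any(x <= 0)) abort("log term requires strictly positive biomarker values")
      m <- cbind(log(x)); colnames(m) <- paste0("log(", name, ")"); m
    },
    sqrt = {
      if (any(x < 0)) abort("sqrt term requires non-negative biomarker values")
      m <- cbind(sqrt(x)); colnames(m) <- paste0("sqrt(", name, ")"); m
    }
  )
}

expand_covariate <- function(values, name, levels = NULL) {
  if (is.numeric(values)) {
    m <- cbind(as.numeric(values))
    colnames(m) <- name
    return(m)
  }
  f <- factor(values, levels = levels %||% sort(unique(as.character(values))))
  if (nlevels(f) < 2) abort(paste0("covariate '", name, "' is constant"))
  mm <- vapply(levels(f)[-1], function(lv) as.numeric(f == lv),
    numeric(length(f)))
  mm <- matrix(mm, nrow = length(f),
    dimnames = list(NULL, paste0(name, levels(f)[-1])))
  attr(mm, "levels") <- levels(f)
  mm
}

#' Build a design matrix from a study table
#'
#' Expands a [design_spec()] against a [study_table()] into a numeric design
#' matrix with a deterministic column order: biomarker term(s), covariates
#' (categorical ones reference-coded), interactions, then the
#' vaccination-status indicator. Interaction columns are elementwise products
#' of the columns generated for the two named terms.
#'
#' @param table A [study_table()] (or any data frame with the referenced
#'   columns plus `arm` when a vaccination term is requested).
#' @param spec A [design_spec()].
#' @param xlev Optional named list fixing the level sets of categorical
#'   covariates, so a design built from new data reference-codes exactly as
#'   the fitting data did.
#' @return Numeric matrix (subjects x terms) with attributes `t_cols` (names
#'   of columns involving the biomarker) and `xlev` (realised level sets).
#' @export
build_design <- function(table, spec, xlev = list()) {
  stopifnot(inherits(spec, "design_spec"))
  blocks <- list()
  block_of <- list() # term name -> columns generated for it
  xlev_out <- list()
  if (!is.null(spec$biomarker)) {
    if (!spec$biomarker %in% names(table)) {
      abort(paste0("biomarker column '", spec$biomarker, "' not found"))
    }
    b <- biomarker_transform_cols(table[[spec$biomarker]], spec$biomarker, spec$term)
    blocks <- c(blocks, list(b))
    block_of[[spec$biomarker]] <- b
  }
  for (cv in spec$covariates) {
    if (!cv %in% names(table)) abort(paste0("covariate column '", cv, "' not found"))
    b <- expand_covariate(table[[cv]], cv, levels = xlev[[cv]])
    if (!is.null(attr(b, "levels"))) xlev_out[[cv]] <- attr(b, "levels")
    blocks <- c(blocks, list(b))
    block_of[[cv]] <- b
  }
  for (pair in spec$interactions) {
    b1 <- block_of[[pair[1]]]
    b2 <- block_of[[pair[2]]]
    cols <- list()
    for (i in seq_len(ncol(b1))) {
      for (j in seq_len(ncol(b2))) {
        cols[[length(cols) + 1]] <- b1[, i] * b2[, j]
        names(cols)[length(cols)] <- paste0(colnames(b1)[i], ":", colnames(b2)[j])
      }
    }
    b <- do.call(cbind, cols)
    blocks <- c(blocks, list(b))
  }
  if (isTRUE(spec$vaccination)) {
    b <- cbind(vaccination = as.numeric(table$arm == "vaccine"))
    blocks <- c(blocks, list(b))
  }
  if (length(blocks) == 0) abort("design_spec generates no columns")
  design <- do.call(cbind, blocks)
  rownames(design) <- table$subject_id
  t_cols <- character()
  if (!is.null(spec$biomarker)) {
    t_cols <- grep(spec$biomarker, colnames(design), fixed = TRUE, value = TRUE)
  }
  attr(design, "t_cols") <- t_cols
  attr(design, "xlev") <- xlev_out
  design
}
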