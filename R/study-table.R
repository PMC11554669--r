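#' Subject-level study tables
#'
#' A study table is a tibble with one row per subject and four required
#' columns: `subject_id` (unique identifier), `arm` (`"vaccine"` or
#' `"control"`), `time` (strictly positive follow-up time in days from the
#' post-vaccination landmark visit), and `cause` (integer event code, `0` for
#' censored and `k >= 1` for an event of cause `k`). Any further columns are
#' declared as baseline covariates or immunogenicity biomarkers; the
#' declarations are carried as attributes so downstream model builders know
#' each column's role.
#'
#' @param data A data frame containing at least the four required columns.
#' @param covariates Character vector of covariate column names.
#' @param biomarkers Character vector of biomarker column names (log2 scale
#'   where applicable).
#'
#' @return A tibble of class `study_table` with `covariates` and `biomarkers`
#'   attributes.
#' @examples
#' tbl <- study_table(
#'   data.frame(
#'     subject_id = c("s1", "s2"), arm = c("vaccine", "control"),
#'     time = c(100, 200), cause = c(1L, 0L), titer = c(2.1, 0)
#'   ),
#'   biomarkers = "titer"
#' )
#' @export
study_table <- function(data, covariates = character(), biomarkers = character()) {
  required <- c("subject_id", "arm", "time", "cause")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(c(covariates, biomarkers), names(data))
  if (length(extra) > 0) {
    abort(paste0("declared column(s) not present: ", paste(extra, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  out$subject_id <- as.character(out$subject_id)
  out$arm <- normalize_arm(out$arm)
  out$time <- as.numeric(out$time)
  out$cause <- as.integer(out$cause)
  validate_study_table(out)
  structure(out,
    covariates = covariates, biomarkers = biomarkers,
    class = c("study_table", class(tibble::tibble()))
  )
}

#' @rdname study_table
#' @param x Object to test.
#' @export
is_study_table <- function(x) inherits(x, "study_table")

normalize_arm <- function(arm) {
  a <- tolower(trimws(as.character(arm)))
  bad <- unique(a[!a %in% c("vaccine", "control")])
  if (length(bad) > 0) {
    abort(paste0("unknown arm label(s): ", paste(bad, collapse = ", "),
      " (expected 'vaccine' or 'control', case-insensitive)"))
  }
  a
}

validate_study_table <- function(x) {
  dup <- x$subject_id[duplicated(x$subject_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate subject_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_time <- x$subject_id[!is.finite(x$time) | x$time <= 0]
  if (length(bad_time) > 0) {
    abort(paste0("non-positive time for subject(s): ",
      paste(bad_time, collapse = ", ")))
  }
  if (any(x$cause < 0)) abort("cause codes must be >= 0")
  causes <- sort(unique(x$cause[x$cause > 0]))
  if (length(causes) > 0 && !identical(causes, seq_len(max(causes)))) {
    abort(paste0("event cause codes must form a contiguous set 1..K; got {",
      paste(causes, collapse = ", "), "}"))
  }
  invisible(x)
}

study_covariates <- function(x) attr(x, "covariates") %||% character()
study_biomarkers <- function(x) attr(x, "biomarkers") %||% character()

#' Read a subject-level study table from delimited text
#'
#' Reads a comma- (default) or tab-delimited file with a header row, maps
#' columns onto the study-table schema, and validates the result. Rows with a
#' missing value in any required, covariate, or biomarker column are dropped
#' (complete-case analysis) and the number of exclusions is reported via a
#' message and the `n_dropped` attribute.
#'
#' @param path Path to the delimited file.
#' @param covariates,biomarkers Character vectors naming covariate and
#'   biomarker columns (beyond the required `subject_id`, `arm`, `time`,
#'   `cause`).
#' @param delim Field delimiter, `","` or `"\t"`.
#' @return A [study_table] with attribute `n_dropped` giving the number of
#'   incomplete rows excluded.
#' @seealso [write_study_table()]
#' @export
read_study_table <- function(path, covariates = character(),
                             biomarkers = character(), delim = ",") {
  # base read.table: correctly rounded double parsing, so written tables
  # round-trip bit-identically
  raw <- utils::read.table(path, header = TRUE, sep = delim,
    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("subject_id", "arm", "time", "cause")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s) in ", path, ": ",
      paste(missing_cols, collapse = ", ")))
  }
  used <- c(required, covariates, biomarkers)
  keep <- complete.cases(raw[, intersect(used, names(raw)), drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " row(s) dropped with missing values (complete-case)"))
  }
  out <- study_table(raw[keep, , drop = FALSE],
    covariates = covariates, biomarkers = biomarkers)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a study table to delimited text
#'
#' @param x A [study_table].
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path, delim = ",") {
  stopifnot(is_study_table(x))
  out <- tibble::as_tibble(as.data.frame(x))
  # 17 significant digits round-trip doubles exactly, so read -> write -> read
  # is bit-stable
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' @export
print.study_table <- function(x, ...) {
  n_ev <- sum(x$cause > 0)
  cat(sprintf(
    "<study_table> %d subjects (%d vaccine / %d control), %d events\n",
    nrow(x), sum(x$arm == "vaccine"), sum(x$arm == "control"), n_ev
  ))
  if (length(study_covariates(x)) > 0) {
    cat("covariates:", paste(study_covariates(x), collapse = ", "), "\n")
  }
  if (length(study_biomarkers(x)) > 0) {
    cat("biomarkers:", paste(study_biomarkers(x), collapse = ", "), "\n")
  }
  NextMethod()
}
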