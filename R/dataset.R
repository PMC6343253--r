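#' Construct and validate a long-format MMD trial dataset
#'
#' A trial dataset holds one record per subject-visit: an opaque subject
#' identifier, the visit week, the treatment arm (0 = placebo, 1 = active)
#' and the migraine-day count over the preceding 28-day period. Counts must
#' lie in `0..n_days`.
#'
#' @param data A data.frame with columns `subject_id`, `visit_week`, `arm`,
#'   `mmd` (extra columns are dropped).
#' @param n_days Period length bounding the counts (default 28).
#' @param enforce_bound Reject counts above `n_days` (default `TRUE`). Exact
#'   unbounded-model simulations (see [recovery_config()]) disable this,
#'   since the negative-binomial and Poisson families place (small) mass
#'   above the period length.
#' @return The validated data.frame with class `mmd_dataset` and attribute
#'   `n_days`.
#' @export
mmd_dataset <- function(data, n_days = 28L, enforce_bound = TRUE) {
  problems <- validate_mmd_frame(data, n_days = n_days,
                                 enforce_bound = enforce_bound)
  if (length(problems))
    stop("invalid trial data:\n  ", paste(problems, collapse = "\n  "))
  out <- data.frame(subject_id = as.character(data$subject_id),
                    visit_week = as.integer(data$visit_week),
                    arm = as.integer(data$arm),
                    mmd = as.integer(data$mmd),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$visit_week), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_days = as.integer(n_days),
            class = c("mmd_dataset", "data.frame"))
}

# Row-numbered validation messages; empty character vector when clean.
validate_mmd_frame <- function(data, n_days = 28L, enforce_bound = TRUE) {
  required <- c("subject_id", "visit_week", "arm", "mmd")
  if (!is.data.frame(data))
    return("input is not a data.frame")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    return(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (nrow(data) == 0L) return("dataset has no rows")
  problems <- character(0)
  bad_row <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows))
      sprintf("row %d: %s", utils::head(rows, 5L), msg)
    else character(0)
  }
  num_ok <- function(x) suppressWarnings(as.numeric(as.character(x)))
  vw <- num_ok(data$visit_week); arm <- num_ok(data$arm); mmd <- num_ok(data$mmd)
  problems <- c(problems,
    bad_row(is.na(vw) | vw < 0 | vw != round(vw),
            "visit_week must be a non-negative integer"),
    bad_row(is.na(arm) | !(arm %in% c(0, 1)), "arm must be 0 or 1"),
    bad_row(is.na(mmd) | mmd != round(mmd), "mmd must be an integer"),
    bad_row(!is.na(mmd) & (mmd < 0 | (enforce_bound & mmd > n_days)),
            sprintf("mmd must lie in 0..%d", n_days)))
  problems
}

#' Read a trial dataset from CSV
#'
#' Expects the comma-delimited schema `subject_id,visit_week,arm,mmd` with a
#' mandatory header. Malformed files raise an error naming the offending
#' rows.
#'
#' @param path Path to the CSV file.
#' @param n_days Period length (default 28).
#' @return An [mmd_dataset()].
#' @export
read_mmd_csv <- function(path, n_days = 28L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  mmd_dataset(raw, n_days = n_days)
}

#' Write a trial dataset to CSV
#'
#' @param data An [mmd_dataset()] (or conforming data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mmd_csv <- function(data, path) {
  df <- as.data.frame(data)[, c("subject_id", "visit_week", "arm", "mmd")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.mmd_dataset <- function(x, ...) {
  cat(sprintf("MMD trial dataset: %d observations, %d subjects, weeks %s\n",
              nrow(x), length(unique(x$subject_id)),
              paste(sort(unique(x$visit_week)), collapse = ",")))
  NextMethod()
}
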