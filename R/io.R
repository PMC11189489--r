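# Reading and writing the two tabular schemas used throughout: biopsy
# records (hours) and tumor trajectories (days). Headers carry unit
# suffixes so files are self-describing.

biopsy_cols <- c("animal_id", "time_h", "fl_signal", "payload_signal",
                 "extract_signal")
tumor_cols <- c("animal_id", "group", "day", "volume_mm3")

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
}

#' Read and write biopsy record CSV files
#'
#' The biopsy schema is `animal_id, time_h, fl_signal, payload_signal,
#' extract_signal` (column order free; extra columns kept). Rows with
#' missing or negative times/signals are rejected with a line-numbered
#' warning; a file with no valid rows is an error.
#'
#' @param path CSV file path.
#' @param records A tibble of biopsy records.
#' @param debug Also write the simulation-only `true_recovery` column when
#'   present (default `FALSE`).
#' @return `read_biopsy_csv()` returns a validated tibble;
#'   `write_biopsy_csv()` returns `path` invisibly.
#' @examples
#' rec <- simulate_release_cohort(cohort_design(), half_life_to_rate(43), seed = 1)
#' path <- tempfile(fileext = ".csv")
#' write_biopsy_csv(rec, path)
#' read_biopsy_csv(path)
#' @export
read_biopsy_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, biopsy_cols, sprintf("Biopsy file '%s'", path))
  num <- setdiff(biopsy_cols, "animal_id")
  bad <- rep(FALSE, nrow(df))
  for (col in num) {
    v <- df[[col]]
    bad <- bad | !is.finite(v) | v < 0
  }
  if (any(bad)) {
    warn(sprintf(
      "Rejecting %d malformed row(s) (missing or negative values) at data line(s): %s.",
      sum(bad), paste(which(bad), collapse = ", ")
    ))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) abort("No valid biopsy rows after validation.")
  tibble::as_tibble(df)
}

#' @rdname read_biopsy_csv
#' @export
write_biopsy_csv <- function(records, path, debug = FALSE) {
  require_columns(records, biopsy_cols, "Biopsy data")
  keep <- biopsy_cols
  if (debug && "true_recovery" %in% names(records)) {
    keep <- c(keep, "true_recovery")
  }
  readr::write_csv(records[, keep], path)
  invisible(path)
}

#' Read and write tumor trajectory CSV files
#'
#' The trajectory schema is `animal_id, group, day, volume_mm3` in long
#' format. Days are sorted within animal on load; a duplicated
#' `(animal_id, day)` pair is a schema error, as are non-positive volumes.
#'
#' @param path CSV file path.
#' @param trajectories A tibble of trajectories.
#' @return `read_tumor_csv()` returns a validated tibble sorted by animal
#'   and day; `write_tumor_csv()` returns `path` invisibly.
#' @examples
#' tr <- simulate_tumor_group(group = "vehicle", seed = 1)
#' path <- tempfile(fileext = ".csv")
#' write_tumor_csv(tr, path)
#' read_tumor_csv(path)
#' @export
read_tumor_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(df, tumor_cols, sprintf("Tumor file '%s'", path))
  bad <- !is.finite(df$day) | df$day < 0 | !is.finite(df$volume_mm3) |
    df$volume_mm3 <= 0
  if (any(bad)) {
    warn(sprintf(
      "Rejecting %d malformed row(s) (missing, negative day, or non-positive volume) at data line(s): %s.",
      sum(bad), paste(which(bad), collapse = ", ")
    ))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) abort("No valid trajectory rows after validation.")
  dup <- duplicated(df[, c("animal_id", "day")])
  if (any(dup)) {
    abort(sprintf(
      "Duplicate (animal_id, day) measurement(s): %s.",
      paste(unique(sprintf("%s/day %g", df$animal_id[dup], df$day[dup])),
            collapse = ", ")
    ))
  }
  df |>
    dplyr::arrange(.data$animal_id, .data$day) |>
    tibble::as_tibble()
}

#' @rdname read_tumor_csv
#' @export
write_tumor_csv <- function(trajectories, path) {
  require_columns(trajectories, tumor_cols, "Tumor data")
  readr::write_csv(trajectories[, tumor_cols], path)
  invisible(path)
}
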