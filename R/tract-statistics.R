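#' The descriptive-statistic panel
#'
#' Thirteen textbook descriptive statistics are implemented; the default
#' panel keeps twelve of them, dropping `mean_absolute_deviation`, so that a
#' 50-tract atlas yields the canonical 600 tract measurements per subject
#' (50 tracts x 12 statistics). The panel is an argument everywhere it is
#' used, so any subset of the thirteen can be selected.
#'
#' Conventions: variance and standard deviation use the sample (n - 1)
#' denominator; quartiles use linear interpolation (R's default type 7), so
#' the interquartile range is reproducible bit-for-bit;
#' `median_absolute_deviation` is `median(|x - median(x)|)` without the
#' normal-consistency factor; `root_mean_square` is `sqrt(mean(x^2))`.
#'
#' @return Character vector of statistic names.
#' @examples
#' length(tract_statistic_names())  # 13
#' length(default_statistic_panel())  # 12
#' @export
tract_statistic_names <- function() {
  c("arithmetic_mean", "median", "standard_deviation", "range", "variance",
    "harmonic_mean", "geometric_mean", "interquartile_range", "maximum",
    "minimum", "mean_absolute_deviation", "median_absolute_deviation",
    "root_mean_square")
}

#' @rdname tract_statistic_names
#' @export
default_statistic_panel <- function() {
  setdiff(tract_statistic_names(), "mean_absolute_deviation")
}

#' Compute one descriptive statistic of a voxel value list
#'
#' The harmonic and geometric means are undefined at zero and degenerate for
#' negative input, and FA maps contain exact zeros, so for those two
#' statistics values <= 0 are dropped before computation; all other
#' statistics use the full value list. An empty input (empty tract) yields
#' `NA` with a warning rather than an error, so a subject with a missing
#' tract flows through the measurement matrix as missing values.
#'
#' @param values Numeric vector of voxel FA values.
#' @param stat One of [tract_statistic_names()].
#' @return A single numeric value, or `NA` for degenerate input.
#' @examples
#' compute_statistic(c(0.2, 0.4, 0.8), "geometric_mean")  # 0.4
#' @export
compute_statistic <- function(values, stat) {
  stat <- match.arg(stat, tract_statistic_names())
  values <- as.numeric(values)
  if (length(values) == 0L) {
    warn(sprintf("Empty value list for statistic '%s'; returning NA.", stat),
         class = "fatract_empty_tract")
    return(NA_real_)
  }
  if (stat %in% c("harmonic_mean", "geometric_mean")) {
    values <- values[values > 0]
    if (length(values) == 0L) {
      warn(sprintf("No positive values for '%s'; returning NA.", stat),
           class = "fatract_degenerate_stat")
      return(NA_real_)
    }
  }
  switch(stat,
    arithmetic_mean = mean(values),
    median = median(values),
    standard_deviation = if (length(values) > 1L) sd(values) else 0,
    range = max(values) - min(values),
    variance = if (length(values) > 1L) var(values) else 0,
    harmonic_mean = length(values) / sum(1 / values),
    geometric_mean = exp(mean(log(values))),
    interquartile_range = unname(quantile(values, 0.75, type = 7) -
                                 quantile(values, 0.25, type = 7)),
    maximum = max(values),
    minimum = min(values),
    mean_absolute_deviation = mean(abs(values - mean(values))),
    median_absolute_deviation = median(abs(values - median(values))),
    root_mean_square = sqrt(mean(values^2))
  )
}

measurement_column_name <- function(tract, stat) paste(tract, stat, sep = "|")

#' Identify measurement columns of a measurement matrix
#'
#' Measurement columns are named `"<tract>|<statistic>"`; the id columns
#' `subject_id`, `bmi` and `group` are everything else.
#'
#' @param matrix A measurement-matrix tibble.
#' @return Character vector of measurement column names.
#' @export
measurement_columns <- function(matrix) {
  setdiff(names(matrix), c("subject_id", "bmi", "group"))
}

split_column_name <- function(columns) {
  parts <- strsplit(columns, "|", fixed = TRUE)
  tibble::tibble(
    column = columns,
    tract = vapply(parts, `[[`, "", 1L),
    statistic = vapply(parts, `[[`, "", 2L)
  )
}

#' Assemble the tract measurement matrix
#'
#' Computes every panel statistic over every atlas tract for every subject:
#' one row per subject, one `"<tract>|<statistic>"` column per measurement,
#' ordered atlas-table order x panel order. With the 50-tract ICBM-DTI-81
#' atlas and the default 12-statistic panel this is the 600-column table at
#' the centre of the pipeline. Subjects with an empty tract get `NA` in that
#' tract's columns (with a logged count); such columns are excluded from
#' screening for the affected run.
#'
#' @param subjects Tibble with columns `subject_id`, `bmi` (kg/m^2) and
#'   `group` (`"NW"` or `"OB"`).
#' @param volumes List of [fa_volume()] objects, one per subject row (matched
#'   by position; subject ids must agree when the volumes carry them).
#' @param atlas An [atlas_volume()] sharing the volumes' grid.
#' @param panel Statistic names; default [default_statistic_panel()].
#' @return A tibble of class `tract_matrix`: `subject_id`, `bmi`, `group`,
#'   then the measurement columns.
#' @export
compute_measurement_matrix <- function(subjects, volumes, atlas,
                                       panel = default_statistic_panel()) {
  subjects <- tibble::as_tibble(subjects)
  stopifnot(all(c("subject_id", "bmi", "group") %in% names(subjects)),
            length(volumes) == nrow(subjects))
  panel <- vapply(panel, match.arg, "", choices = tract_statistic_names())
  labels <- atlas$label_table$label
  tracts <- atlas$label_table$tract_name

  rows <- purrr::map(volumes, function(vol) {
    vals_by_tract <- purrr::map(labels, extract_tract_voxels,
                                fa = vol, atlas = atlas)
    unlist(purrr::map(vals_by_tract, function(v) {
      if (length(v) == 0L) {
        rep(NA_real_, length(panel))
      } else {
        vapply(panel, function(s) compute_statistic(v, s), numeric(1))
      }
    }))
  })
  grid <- do.call(rbind, rows)
  colnames(grid) <- as.vector(t(outer(tracts, panel, measurement_column_name)))
  # outer() above builds tract-major order: tract 1 panel..., tract 2 panel...
  n_missing <- sum(is.na(grid))
  if (n_missing > 0) {
    message(sprintf("Measurement matrix contains %d missing values (empty tracts).",
                    n_missing))
  }
  out <- dplyr::bind_cols(
    subjects[c("subject_id", "bmi", "group")],
    tibble::as_tibble(grid)
  )
  class(out) <- c("tract_matrix", class(out))
  out
}

#' Read and write measurement matrices as CSV
#'
#' The serialized layout is `subject_id, bmi, group` followed by the
#' `"<tract>|<statistic>"` columns; write-then-read round-trips.
#'
#' @param matrix A measurement-matrix tibble.
#' @param path CSV file path.
#' @return `read_measurement_matrix()` returns the tibble.
#' @export
write_measurement_matrix <- function(matrix, path) {
  readr::write_csv(matrix, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_measurement_matrix
#' @export
read_measurement_matrix <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0,
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE))
  if (!all(c("subject_id", "bmi", "group") %in% hdr)) {
    abort("Measurement matrix must have subject_id, bmi and group columns.",
          class = "fatract_schema_error")
  }
  out <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  class(out) <- c("tract_matrix", class(out))
  out
}
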