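#' Assemble a tract-by-statistic biomarker matrix
#'
#' The biomarker is the model's regression coefficients laid out on a
#' tract x statistic grid (zero where the model uses no coefficient) plus
#' the model constant — the quantification model's constant is in kg/m^2,
#' the classification model's is dimensionless. Applying the biomarker to a
#' subject's measurement grid by element-wise product summation reproduces
#' the model's prediction exactly.
#'
#' @param model A `tract_model` whose features are `"<tract>|<statistic>"`
#'   column names drawn from `tracts` x `statistics`.
#' @param tracts Ordered tract names (rows of the grid).
#' @param statistics Ordered statistic panel (columns of the grid).
#' @return An object of class `biomarker_matrix`: list with `grid` (numeric
#'   matrix with tract rownames and statistic colnames), `constant`,
#'   `task`, `tracts`, `statistics`.
#' @export
assemble_biomarker <- function(model, tracts,
                               statistics = default_statistic_panel()) {
  stopifnot(inherits(model, "tract_model"))
  grid <- matrix(0, nrow = length(tracts), ncol = length(statistics),
                 dimnames = list(tracts, statistics))
  if (length(model$features)) {
    parts <- split_column_name(model$features)
    bad <- !(parts$tract %in% tracts) | !(parts$statistic %in% statistics)
    if (any(bad)) {
      abort(sprintf("Model feature(s) outside the biomarker grid: %s.",
                    paste(model$features[bad], collapse = ", ")),
            class = "fatract_input_error")
    }
    grid[cbind(parts$tract, parts$statistic)] <- unname(model$coefficients)
  }
  structure(list(grid = grid, constant = model$intercept, task = model$task,
                 tracts = tracts, statistics = statistics),
            class = "biomarker_matrix")
}

#' @export
print.biomarker_matrix <- function(x, ...) {
  cat(sprintf("<biomarker_matrix> %s: %d nonzero cell(s) on %d x %d grid, constant %.4g\n",
              x$task, sum(x$grid != 0), nrow(x$grid), ncol(x$grid),
              x$constant))
  invisible(x)
}

#' Apply a biomarker matrix
#'
#' Element-wise product summation of the coefficient grid with a subject's
#' tract x statistic measurement grid, plus the model constant. For the
#' classification biomarker the result is the raw score `s`; `s < 0`
#' classifies as NW and `s > 0` as OB. Given a measurement-matrix tibble,
#' one prediction per row is returned (only the grid's nonzero cells need
#' measurement columns).
#'
#' @param biomarker A `biomarker_matrix`.
#' @param measurements Either a numeric tract x statistic matrix for one
#'   subject (dimnames covering every nonzero cell) or a measurement-matrix
#'   tibble.
#' @return A single number, or a tibble `subject_id`, `prediction` (plus
#'   `class` for the classification task).
#' @export
apply_biomarker <- function(biomarker, measurements) {
  stopifnot(inherits(biomarker, "biomarker_matrix"))
  if (is.matrix(measurements)) {
    nz <- which(biomarker$grid != 0, arr.ind = TRUE)
    if (nrow(nz)) {
      tr <- rownames(biomarker$grid)[nz[, 1]]
      st <- colnames(biomarker$grid)[nz[, 2]]
      if (!all(tr %in% rownames(measurements)) ||
          !all(st %in% colnames(measurements))) {
        abort("Measurement grid does not cover every nonzero biomarker cell.",
              class = "fatract_schema_error")
      }
      vals <- measurements[cbind(tr, st)]
      if (anyNA(vals)) {
        abort("Missing measurement at a nonzero biomarker cell.",
              class = "fatract_schema_error")
      }
      sum(biomarker$grid[nz] * vals) + biomarker$constant
    } else {
      biomarker$constant
    }
  } else {
    model <- biomarker_as_model(biomarker)
    pred <- predict(model, measurements)
    out <- tibble::tibble(subject_id = measurements$subject_id,
                          prediction = pred)
    if (biomarker$task == "classification") {
      out$class <- ifelse(harden_labels(pred) > 0, "OB", "NW")
    }
    out
  }
}

biomarker_as_model <- function(biomarker) {
  nz <- which(biomarker$grid != 0, arr.ind = TRUE)
  features <- measurement_column_name(rownames(biomarker$grid)[nz[, 1]],
                                      colnames(biomarker$grid)[nz[, 2]])
  structure(
    list(task = biomarker$task, features = features,
         coefficients = setNames(biomarker$grid[nz], features),
         intercept = biomarker$constant),
    class = "tract_model"
  )
}

#' Serialize a biomarker matrix
#'
#' The grid goes to CSV (rows = tracts, columns = statistics, first column
#' `tract`) at 17 significant digits so the round-trip is bit-faithful; the
#' task, constant, panel, tract list and optional provenance go to a JSON
#' sidecar.
#'
#' @param biomarker A `biomarker_matrix`.
#' @param csv_path Grid CSV path.
#' @param json_path Sidecar JSON path.
#' @param provenance Optional named list (search seed/config) stored as-is.
#' @export
write_biomarker <- function(biomarker, csv_path, json_path,
                            provenance = NULL) {
  # format at 17 significant digits so the double round-trip is exact
  chr <- matrix(sprintf("%.17g", biomarker$grid), nrow(biomarker$grid),
                dimnames = dimnames(biomarker$grid))
  df <- dplyr::bind_cols(tibble::tibble(tract = rownames(biomarker$grid)),
                         tibble::as_tibble(chr))
  readr::write_csv(df, csv_path, progress = FALSE)
  jsonlite::write_json(
    list(task = biomarker$task, constant = biomarker$constant,
         statistics = biomarker$statistics, tracts = biomarker$tracts,
         provenance = provenance),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(biomarker)
}

#' @rdname write_biomarker
#' @export
read_biomarker <- function(csv_path, json_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  # base read.csv: correctly-rounded double parsing for the exact round-trip
  df <- utils::read.csv(csv_path, check.names = FALSE,
                        colClasses = "character")
  grid <- apply(as.matrix(df[, -1, drop = FALSE]), c(1, 2), as.numeric)
  rownames(grid) <- df$tract
  structure(list(grid = grid, constant = as.numeric(meta$constant),
                 task = meta$task, tracts = df$tract,
                 statistics = colnames(grid)),
            class = "biomarker_matrix")
}

#' @rdname assemble_biomarker
#' @param x,object A `biomarker_matrix`.
#' @param ... Unused.
#' @method tidy biomarker_matrix
#' @export
tidy.biomarker_matrix <- function(x, ...) {
  nz <- which(x$grid != 0, arr.ind = TRUE)
  tibble::tibble(tract = rownames(x$grid)[nz[, 1]],
                 statistic = colnames(x$grid)[nz[, 2]],
                 coefficient = x$grid[nz])
}

#' @rdname assemble_biomarker
#' @method glance biomarker_matrix
#' @export
glance.biomarker_matrix <- function(x, ...) {
  tibble::tibble(task = x$task, n_nonzero = sum(x$grid != 0),
                 n_tracts = nrow(x$grid), n_statistics = ncol(x$grid),
                 constant = x$constant)
}

#' Heatmap of a biomarker matrix
#'
#' @param object A `biomarker_matrix`.
#' @param ... Unused.
#' @return A ggplot tile map of the nonzero coefficients.
#' @method autoplot biomarker_matrix
#' @export
autoplot.biomarker_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = .data$tract,
                                   fill = .data$coefficient)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s biomarker (constant %.4g)",
                                  object$task, object$constant)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Extract one subject's tract-by-statistic measurement grid
#'
#' Rearranges one row of a measurement matrix into the tract x statistic
#' grid that [apply_biomarker()] consumes.
#'
#' @param matrix Measurement-matrix tibble.
#' @param subject_id Subject to extract.
#' @param tracts,statistics Grid layout; defaults to every tract/statistic
#'   present in the matrix columns.
#' @return A numeric matrix with tract rownames and statistic colnames.
#' @export
measurement_grid <- function(matrix, subject_id, tracts = NULL,
                             statistics = NULL) {
  row <- matrix[matrix$subject_id == subject_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort(sprintf("Subject '%s' not found exactly once.", subject_id),
          class = "fatract_input_error")
  }
  parts <- split_column_name(measurement_columns(matrix))
  tracts <- tracts %||% unique(parts$tract)
  statistics <- statistics %||% unique(parts$statistic)
  grid <- matrix(NA_real_, length(tracts), length(statistics),
                 dimnames = list(tracts, statistics))
  keep <- parts$tract %in% tracts & parts$statistic %in% statistics
  grid[cbind(parts$tract[keep], parts$statistic[keep])] <-
    as.numeric(row[1, parts$column[keep]])
  grid
}
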