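#' Run the full biomarker pipeline
#'
#' Orchestrates the stages end to end — measurement matrix, two-condition
#' screening, stratified split, add/exclude search for the BMI
#' quantification model and the NW/OB classifier, evaluation reports, and
#' the two biomarker matrices — writing every artifact plus a
#' machine-readable manifest into `out_dir`. Re-running with the same
#' inputs and seeds reproduces identical outputs.
#'
#' The input is either a measurement-matrix tibble (or CSV path), or a
#' `synthetic_cohort`; image-mode cohorts and real FA/atlas volumes go
#' through [compute_measurement_matrix()] first.
#'
#' @param input Measurement-matrix tibble, CSV path, or
#'   [generate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @param alpha Screening significance level.
#' @param sizes Split sizes triple.
#' @param split_seed Seed for [stratified_split()].
#' @param config_bmi,config_class [search_config()] for each model.
#' @return The output directory, invisibly; the manifest lists every file
#'   with its MD5 hash, the seeds used, and stage timings.
#' @export
run_pipeline <- function(input, out_dir,
                         alpha = 0.05,
                         sizes = c(80L, 40L, 40L),
                         split_seed = 1L,
                         config_bmi = search_config(),
                         config_class = search_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
            class = "fatract_stage_error", parent = e)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    message(sprintf("[%s] done in %.2fs", name, timings[[name]]))
    out
  }

  matrix <- stage("input", {
    if (inherits(input, "synthetic_cohort")) {
      if (input$mode == "matrix") input$matrix
      else compute_measurement_matrix(input$subjects, input$volumes,
                                      input$atlas)
    } else if (is.character(input)) {
      read_measurement_matrix(input)
    } else {
      input
    }
  })
  write_measurement_matrix(matrix, file.path(out_dir, "measurement_matrix.csv"))

  screening <- stage("screen", choose_measurements(matrix, alpha = alpha))
  write_screening_result(screening, file.path(out_dir, "screening.csv"),
                         file.path(out_dir, "screening.json"))
  candidates <- screening$column[screening$chosen]
  if (length(candidates) == 0L) {
    abort("[stage screen] no measurement passed both conditions.",
          class = "fatract_stage_error")
  }

  split <- stage("split", stratified_split(matrix, sizes = sizes,
                                           seed = split_seed))
  write_split(split, file.path(out_dir, "split.json"))

  search_bmi <- stage("search_bmi",
                      run_search(matrix, split, candidates, "regression",
                                 config_bmi))
  write_search(search_bmi, file.path(out_dir, "model_bmi.json"),
               file.path(out_dir, "trace_bmi.csv"))
  search_class <- stage("search_class",
                        run_search(matrix, split, candidates,
                                   "classification", config_class))
  write_search(search_class, file.path(out_dir, "model_class.json"),
               file.path(out_dir, "trace_class.csv"))

  stage("evaluate", {
    readr::write_csv(evaluate_regression(search_bmi$model, matrix, split),
                     file.path(out_dir, "evaluation_bmi.csv"), progress = FALSE)
    readr::write_csv(evaluate_classification(search_class$model, matrix, split),
                     file.path(out_dir, "evaluation_class.csv"),
                     progress = FALSE)
  })

  stage("biomarkers", {
    parts <- split_column_name(measurement_columns(matrix))
    tracts <- unique(parts$tract)
    panel <- unique(parts$statistic)
    write_biomarker(assemble_biomarker(search_bmi$model, tracts, panel),
                    file.path(out_dir, "biomarker_bmi.csv"),
                    file.path(out_dir, "biomarker_bmi.json"),
                    provenance = list(seed = config_bmi$seed,
                                      restarts = config_bmi$restarts))
    write_biomarker(assemble_biomarker(search_class$model, tracts, panel),
                    file.path(out_dir, "biomarker_class.csv"),
                    file.path(out_dir, "biomarker_class.json"),
                    provenance = list(seed = config_class$seed,
                                      restarts = config_class$restarts))
  })

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("fatract")),
    alpha = alpha, sizes = sizes, split_seed = split_seed,
    seed_bmi = config_bmi$seed, seed_class = config_class$seed,
    restarts_bmi = config_bmi$restarts, restarts_class = config_class$restarts,
    n_subjects = nrow(matrix), n_columns = length(measurement_columns(matrix)),
    n_chosen = attr(screening, "N"),
    timings = timings,
    total_elapsed = round(proc.time()[["elapsed"]] - t0, 3),
    files = setNames(as.list(unname(tools::md5sum(file.path(out_dir, files)))),
                     files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
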